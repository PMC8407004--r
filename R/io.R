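# Format adapters: BED6, bedGraph, FASTQ/FASTA, flat pipeline config.
# All BED-family records are 0-based half-open; writers emit sorted
# records, readers fail with line-numbered messages.

#' Write intervals as BED6
#'
#' @param x Data.frame with `chrom`, `start`, `end` and optionally
#'   `name`, `score`, `strand`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(x, path) {
  validate_fragments(x)
  out <- data.frame(chrom = x$chrom, start = x$start, end = x$end,
                    name = if (is.null(x$name)) "." else x$name,
                    score = if (is.null(x$score)) 0L else x$score,
                    strand = if (is.null(x$strand)) "+" else x$strand,
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file (strict)
#'
#' Thin wrapper over [load_fragments()] keeping name/score/strand
#' columns when present.
#'
#' @param path BED path.
#' @return Data.frame with at least `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  frags <- load_fragments(path)
  lines <- readLines(path)
  keep <- which(nzchar(lines) & !startsWith(lines, "#") &
                  !startsWith(lines, "track"))
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  ncols <- min(lengths(fields))
  if (ncols >= 6L) {
    frags$name <- vapply(fields, `[[`, character(1), 4L)
    frags$score <- as.numeric(vapply(fields, `[[`, character(1), 5L))
    frags$strand <- vapply(fields, `[[`, character(1), 6L)
  }
  frags
}

#' Write a per-base vector as bedGraph
#'
#' Contiguous runs of equal value are compressed into single rows;
#' zero runs are omitted.
#'
#' @param values Numeric per-base vector (position 0 first).
#' @param path Output path.
#' @param chrom Sequence name.
#' @return Invisibly, `path`.
#' @export
write_bedgraph <- function(values, path, chrom = "chr") {
  r <- rle(values)
  end <- cumsum(r$lengths)
  start <- end - r$lengths
  keep <- r$values != 0
  df <- data.frame(chrom = chrom, start = start[keep], end = end[keep],
                   value = r$values[keep])
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph back into a per-base vector
#'
#' @param path bedGraph path.
#' @param genome_length Length of the output vector.
#' @return Numeric vector; positions not covered by any row are 0.
#' @export
read_bedgraph <- function(path, genome_length) {
  lines <- readLines(path)
  keep <- which(nzchar(lines) & !startsWith(lines, "#") &
                  !startsWith(lines, "track"))
  values <- numeric(genome_length)
  if (!length(keep)) return(values)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 4L)
      stop(sprintf("line %d: bedGraph row needs 4 fields", keep[i]),
           call. = FALSE)
    s <- suppressWarnings(as.integer(f[2])); e <- suppressWarnings(as.integer(f[3]))
    v <- suppressWarnings(as.numeric(f[4]))
    if (is.na(s) || is.na(e) || is.na(v) || s >= e || s < 0 ||
        e > genome_length)
      stop(sprintf("line %d: malformed bedGraph row", keep[i]), call. = FALSE)
    values[(s + 1L):e] <- v
  }
  values
}

#' Write reads as Sanger-encoded FASTQ
#'
#' Base qualities are a constant high value (`I`, Q40); downstream
#' steps never use qualities.
#'
#' @param reads Named [Biostrings::DNAStringSet].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fastq <- function(reads, path) {
  qual <- Biostrings::BStringSet(strrep("I", Biostrings::width(reads)))
  Biostrings::writeXStringSet(reads, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Read a FASTQ file
#'
#' @param path FASTQ path.
#' @return A [Biostrings::DNAStringSet] (qualities discarded).
#' @export
read_fastq <- function(path) {
  Biostrings::readDNAStringSet(path, format = "fastq")
}

#' Read a genome FASTA (first record)
#'
#' @param path FASTA path.
#' @return A list: `name`, `sequence` (uppercase character).
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  list(name = sub("\\s.*$", "", names(x)[1]),
       sequence = toupper(as.character(x[[1]])))
}

#' Pipeline configuration
#'
#' Flat key-value configuration holding every module default plus
#' seeds and the condition schedule.  Unknown keys are rejected by
#' name; the object round-trips losslessly through YAML.
#'
#' @param ... Overrides for the defaults listed in
#'   [default_pipeline_config()].
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- default_pipeline_config()
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg[names(dots)] <- dots
  validate_pipeline_config(cfg)
}

#' Default pipeline configuration values
#'
#' The defaults define the package's standard synthetic cell-cycle
#' experiment: a 100 kb genome with twelve planted sites -- one
#' origin-like site occupied almost only before initiation, one
#' attL-proximal-like site occupied transiently 10 min after
#' initiation, and ten constitutive sites -- sequenced as four
#' libraries (0 min, 10 min, 20 min, random).
#'
#' @return Named list of defaults.
#' @export
default_pipeline_config <- function() {
  list(genome_length = 100000L,
       gc_fraction = 0.5,
       read_length = 100L,
       adapter_seq = "AGATCGGAAGAGCACACGTCTGAACTCCAGTCA",
       protected_len_min = 70L,
       protected_len_max = 110L,
       background_fragments = 20000L,
       enrichment_depth = 200L,
       conditions = c("0min", "10min", "20min", "random"),
       ref_condition = "0min",
       ewf = 70L,
       ewt = 110L,
       base_threshold = 80L,
       end_support_min = 3L,
       min_overlap = 3L,
       max_mismatch_rate = 0.1,
       scan_pattern = "WATCARnnnnTTR",
       seed = NA_integer_)
}

validate_pipeline_config <- function(cfg) {
  cfg$conditions <- as.character(unlist(cfg$conditions))
  if (cfg$ewf > cfg$ewt) stop("config error: ewf > ewt", call. = FALSE)
  if (cfg$protected_len_min > cfg$protected_len_max)
    stop("config error: protected_len_min > protected_len_max", call. = FALSE)
  if (cfg$gc_fraction < 0 || cfg$gc_fraction > 1)
    stop("config error: gc_fraction outside [0, 1]", call. = FALSE)
  if (!(cfg$ref_condition %in% cfg$conditions))
    stop("config error: ref_condition not among conditions", call. = FALSE)
  structure(cfg, class = "pipeline_config")
}

#' Write / read a pipeline config as YAML
#'
#' @param cfg A `pipeline_config`.
#' @param path YAML path.
#' @return `write_pipeline_config` returns `path` invisibly;
#'   `read_pipeline_config` returns a validated `pipeline_config`.
#' @export
write_pipeline_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}
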