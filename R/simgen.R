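# Synthetic-data generator: genome, planted binding sites with
# condition-dependent occupancy, protected/background fragments, and
# adapter-containing paired-end reads plus truth files.  Emulates
# in-cell DNase I footprinting libraries: short protected fragments
# (70-110 bp) sequenced as 100 bp paired-end reads, so reads run
# through the fragment into the library adapter.

#' Simulation configuration
#'
#' Bundles the knobs of the synthetic sequencing experiment.  Defaults
#' mirror the assay being emulated: 100 bp paired-end reads over 70-110
#' bp protected fragments, so most reads read through into the adapter.
#'
#' @param genome_length Genome size in bases (circular; the generator
#'   fixes the linearization point so that no fragment spans the join).
#' @param gc_fraction Genome G+C content, in `[0, 1]`.
#' @param read_length Read length in bases.
#' @param adapter_seq Library adapter appended after a fragment shorter
#'   than `read_length`.  Must be at least
#'   `read_length - protected_len_min` long so short fragments are
#'   fully padded.
#' @param protected_len_min,protected_len_max Bounds of the protected
#'   fragment length (bases).
#' @param background_fragments Number of background digestion fragments
#'   per library.
#' @param enrichment_depth Expected number of protected fragments for a
#'   fully occupied site (binomial n).
#' @param seed Integer seed; identical seed and config give
#'   byte-identical outputs.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(genome_length = 100000L,
                       gc_fraction = 0.5,
                       read_length = 100L,
                       adapter_seq = "AGATCGGAAGAGCACACGTCTGAACTCCAGTCA",
                       protected_len_min = 70L,
                       protected_len_max = 110L,
                       background_fragments = 20000L,
                       enrichment_depth = 200L,
                       seed = 1L) {
  stop_if_not_scalar_count(genome_length, "genome_length")
  stop_if_not_scalar_count(read_length, "read_length")
  stop_if_not_scalar_count(seed, "seed", min = 0L)
  if (!is.numeric(gc_fraction) || gc_fraction < 0 || gc_fraction > 1)
    stop("`gc_fraction` must lie in [0, 1]", call. = FALSE)
  if (protected_len_min > protected_len_max)
    stop("`protected_len_min` must be <= `protected_len_max`", call. = FALSE)
  if (nchar(adapter_seq) < read_length - protected_len_min)
    stop("`adapter_seq` must be at least read_length - protected_len_min long",
         call. = FALSE)
  structure(list(genome_length = as.integer(genome_length),
                 gc_fraction = gc_fraction,
                 read_length = as.integer(read_length),
                 adapter_seq = toupper(adapter_seq),
                 protected_len_min = as.integer(protected_len_min),
                 protected_len_max = as.integer(protected_len_max),
                 background_fragments = as.integer(background_fragments),
                 enrichment_depth = as.integer(enrichment_depth),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a random genome sequence
#'
#' Bases are drawn i.i.d. with `P(G) = P(C) = gc_fraction / 2` and
#' `P(A) = P(T) = (1 - gc_fraction) / 2`.
#'
#' @param length Genome length in bases (>= 1).
#' @param gc_fraction Target G+C proportion in `[0, 1]`.
#' @param seed Integer seed; same arguments give the same sequence.
#' @return A single DNA string over `A,C,G,T`.
#' @export
#' @examples
#' g <- generate_genome(50, 0.5, seed = 1)
#' nchar(g)
generate_genome <- function(length, gc_fraction, seed) {
  stop_if_not_scalar_count(length, "length")
  if (!is.numeric(gc_fraction) || length(gc_fraction) != 1L ||
      is.na(gc_fraction) || gc_fraction < 0 || gc_fraction > 1)
    stop("`gc_fraction` must lie in [0, 1]", call. = FALSE)
  set.seed(as.integer(seed))
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  paste(sample(BASES, length, replace = TRUE, prob = p), collapse = "")
}

#' Plant binding sites into a genome
#'
#' Each site spec carries an IUPAC pattern, a 0-based position, a strand
#' and an occupancy map (condition -> probability).  Degenerate codes
#' are instantiated by sampling uniformly from the allowed bases; the
#' genome is unchanged elsewhere.  For a minus-strand site the reverse
#' complement of the instantiated pattern is written on the top strand.
#'
#' @param genome DNA string.
#' @param site_specs A list of lists with elements `site_id`, `pattern`
#'   (IUPAC string), `position` (0-based motif start), `strand`
#'   (`"+"`/`"-"`, default `"+"`), and `occupancy` (named numeric,
#'   condition -> probability in `[0, 1]`).
#' @param seed Integer seed for degenerate-base sampling.
#' @return A list of class `truth_set` with elements `genome` (modified
#'   string), `sites` (data.frame: site_id, position, strand, pattern,
#'   motif, width), and `occupancy` (site x condition matrix).
#' @export
plant_sites <- function(genome, site_specs, seed = 1L) {
  stopifnot(is.character(genome), length(genome) == 1L)
  L <- nchar(genome)
  set.seed(as.integer(seed))
  if (length(site_specs) == 0L) {
    sites <- data.frame(site_id = character(), position = integer(),
                        strand = character(), pattern = character(),
                        motif = character(), width = integer(),
                        stringsAsFactors = FALSE)
    return(structure(list(genome = genome, sites = sites,
                          occupancy = matrix(numeric(), nrow = 0, ncol = 0)),
                     class = "truth_set"))
  }
  rows <- lapply(seq_along(site_specs), function(k) {
    s <- site_specs[[k]]
    pat <- toupper(s$pattern)
    codes <- strsplit(pat, "")[[1]]
    bad <- setdiff(codes, names(IUPAC_CODES))
    if (length(bad))
      stop("illegal IUPAC code(s) in pattern: ", paste(bad, collapse = ","),
           call. = FALSE)
    if (any(s$occupancy < 0 | s$occupancy > 1))
      stop("occupancy values must lie in [0, 1]", call. = FALSE)
    inst <- vapply(codes, function(cc) {
      allowed <- setdiff(IUPAC_CODES[[cc]], "N")
      if (length(allowed) == 1L) allowed else sample(allowed, 1L)
    }, character(1), USE.NAMES = FALSE)
    data.frame(site_id = if (is.null(s$site_id)) paste0("site", k) else s$site_id,
               position = as.integer(s$position),
               strand = if (is.null(s$strand)) "+" else s$strand,
               pattern = pat,
               motif = paste(inst, collapse = ""),
               width = length(codes),
               stringsAsFactors = FALSE)
  })
  sites <- do.call(rbind, rows)
  if (any(sites$position < 0) || any(sites$position + sites$width > L))
    stop("site position + motif length exceeds genome length", call. = FALSE)
  o <- order(sites$position)
  if (any(sites$position[o][-1] < (sites$position + sites$width)[o][-nrow(sites)]))
    stop("overlapping sites are not allowed", call. = FALSE)

  gch <- strsplit(genome, "")[[1]]
  for (k in seq_len(nrow(sites))) {
    ins <- if (sites$strand[k] == "-") revcomp(sites$motif[k]) else sites$motif[k]
    idx <- sites$position[k] + seq_len(sites$width[k])
    gch[idx] <- strsplit(ins, "")[[1]]
  }
  conds <- unique(unlist(lapply(site_specs, function(s) names(s$occupancy))))
  occ <- matrix(0, nrow = nrow(sites), ncol = length(conds),
                dimnames = list(sites$site_id, conds))
  for (k in seq_along(site_specs))
    occ[k, names(site_specs[[k]]$occupancy)] <- site_specs[[k]]$occupancy
  structure(list(genome = paste(gch, collapse = ""), sites = sites,
                 occupancy = occ),
            class = "truth_set")
}

#' Simulate protected and background fragments for one condition
#'
#' For every planted site the number of protected fragments is
#' `Binomial(enrichment_depth, occupancy[condition])`; each fragment has
#' length `Uniform{min..max}` and fully contains the motif, with its
#' start jittered uniformly subject to containment.  Background
#' digestion fragments have uniform starts and the same length law.
#' The genome is circular; the linearization point is fixed by the
#' generator so no fragment spans the join (background starts are drawn
#' from `[0, L - length]`).
#'
#' @param truth A `truth_set` from [plant_sites()].
#' @param condition Condition label; must be present in every site's
#'   occupancy map.
#' @param n_background Number of background fragments.
#' @param enrichment_depth Binomial n for site fragment counts.
#' @param seed Integer seed.
#' @param len_min,len_max Protected fragment length bounds (bases).
#' @return A data.frame of fragments: `chrom`, `start`, `end` (0-based
#'   half-open), `origin` (`"site"`/`"background"`), `site_id`.
#' @export
simulate_fragments <- function(truth, condition, n_background,
                               enrichment_depth, seed = 1L,
                               len_min = 70L, len_max = 110L) {
  stopifnot(inherits(truth, "truth_set"))
  if (enrichment_depth < 0)
    stop("`enrichment_depth` must be >= 0", call. = FALSE)
  L <- nchar(truth$genome)
  if (nrow(truth$sites) && !(condition %in% colnames(truth$occupancy)))
    stop("unknown condition: ", condition, call. = FALSE)
  set.seed(as.integer(seed))
  out <- list()
  for (k in seq_len(nrow(truth$sites))) {
    p <- truth$occupancy[k, condition]
    n <- rbinom(1L, enrichment_depth, p)
    if (n == 0L) next
    mstart <- truth$sites$position[k]
    mend <- mstart + truth$sites$width[k]      # half-open motif interval
    len <- sample(len_min:len_max, n, replace = TRUE)
    # containment: start <= mstart and start + len >= mend
    lo <- pmax(0L, mend - len)
    hi <- pmin(mstart, L - len)
    start <- lo + floor(runif(n) * (hi - lo + 1L))
    out[[length(out) + 1L]] <-
      new_fragments(chrom = "chr", start = start, end = start + len,
                    origin = "site", site_id = truth$sites$site_id[k])
  }
  if (n_background > 0L) {
    len <- sample(len_min:len_max, n_background, replace = TRUE)
    start <- floor(runif(n_background) * (L - len + 1L))
    out[[length(out) + 1L]] <-
      new_fragments(chrom = "chr", start = start, end = start + len,
                    origin = "background", site_id = NA_character_)
  }
  if (!length(out))
    return(new_fragments(origin = character(), site_id = character()))
  frags <- do.call(rbind, out)
  rownames(frags) <- NULL
  frags
}

#' Convert fragments to adapter-padded paired-end reads
#'
#' Read 1 is the top-strand fragment sequence, read 2 the reverse
#' complement of the fragment; a fragment shorter than `read_length` is
#' extended with the leading bases of the adapter (emulating adapter
#' read-through), and a fragment at least `read_length` long yields pure
#' genomic prefixes.
#'
#' @param fragments Fragment data.frame (`chrom`, `start`, `end`).
#' @param genome DNA string the fragments were drawn from.
#' @param read_length Read length in bases.
#' @param adapter_seq Adapter appended after short fragments; must be
#'   long enough to pad the shortest fragment to `read_length`.
#' @return A list with `r1` and `r2` ([Biostrings::DNAStringSet]),
#'   mate IDs matching elementwise.
#' @export
fragments_to_reads <- function(fragments, genome, read_length = 100L,
                               adapter_seq) {
  validate_fragments(fragments)
  L <- nchar(genome)
  if (nrow(fragments) && (any(fragments$start < 0) || any(fragments$end > L)))
    stop("fragment outside genome", call. = FALSE)
  flen <- fragments$end - fragments$start
  if (nrow(fragments) && nchar(adapter_seq) < read_length - min(flen))
    stop("`adapter_seq` too short to pad the shortest fragment", call. = FALSE)
  fragseq <- substring(genome, fragments$start + 1L, fragments$end)
  pad <- pmax(0L, read_length - flen)
  adp <- substring(adapter_seq, 1L, pad)
  r1 <- substring(paste0(fragseq, adp), 1L, read_length)
  r2 <- substring(paste0(revcomp(fragseq), adp), 1L, read_length)
  ids <- sprintf("frag_%06d_%d_%d", seq_len(nrow(fragments)),
                 fragments$start, fragments$end)
  r1 <- Biostrings::DNAStringSet(r1); names(r1) <- ids
  r2 <- Biostrings::DNAStringSet(r2); names(r2) <- ids
  list(r1 = r1, r2 = r2)
}

#' Write a complete simulated library to disk
#'
#' Emits `genome.fasta`, `reads_R1.fastq`/`reads_R2.fastq` (Sanger
#' encoding, constant high quality), `truth_sites.bed` (BED6, score =
#' occupancy x 1000 for the given condition), `truth_fragments.bed`,
#' and a flat key=value `simconfig.txt` echo.
#'
#' @param truth A `truth_set`.
#' @param fragments Fragment data.frame for one condition.
#' @param condition Condition label (used for the BED score column).
#' @param config A `sim_config`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_simulation <- function(truth, fragments, condition, config, dir) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "truth_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(genome = file.path(dir, "genome.fasta"),
             r1 = file.path(dir, "reads_R1.fastq"),
             r2 = file.path(dir, "reads_R2.fastq"),
             sites = file.path(dir, "truth_sites.bed"),
             frags = file.path(dir, sprintf("truth_fragments_%s.bed", condition)),
             config = file.path(dir, "simconfig.txt"))
  gset <- Biostrings::DNAStringSet(truth$genome)
  names(gset) <- "chr"
  Biostrings::writeXStringSet(gset, paths[["genome"]])
  reads <- fragments_to_reads(fragments, truth$genome, config$read_length,
                              config$adapter_seq)
  write_fastq(reads$r1, paths[["r1"]])
  write_fastq(reads$r2, paths[["r2"]])
  sites_bed <- new_fragments(chrom = "chr", start = truth$sites$position,
                             end = truth$sites$position + truth$sites$width,
                             name = truth$sites$site_id,
                             score = as.integer(round(
                               truth$occupancy[, condition] * 1000)),
                             strand = truth$sites$strand)
  write_bed(sites_bed, paths[["sites"]])
  write_bed(new_fragments(chrom = fragments$chrom, start = fragments$start,
                          end = fragments$end,
                          name = ifelse(is.na(fragments$site_id), ".",
                                        fragments$site_id),
                          score = 0L, strand = "+"),
            paths[["frags"]])
  writeLines(c(sprintf("genome_length=%d", config$genome_length),
               sprintf("gc_fraction=%g", config$gc_fraction),
               sprintf("read_length=%d", config$read_length),
               sprintf("adapter_seq=%s", config$adapter_seq),
               sprintf("protected_len_min=%d", config$protected_len_min),
               sprintf("protected_len_max=%d", config$protected_len_max),
               sprintf("background_fragments=%d", config$background_fragments),
               sprintf("enrichment_depth=%d", config$enrichment_depth),
               sprintf("condition=%s", condition),
               sprintf("seed=%d", config$seed)),
             paths[["config"]])
  invisible(paths)
}
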