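# Read preparation: adapter-boundary detection within a read, and
# placement of trimmed read pairs on the reference to recover the
# protected-fragment interval.  Short protected fragments sequenced at
# 100 bp read through into the library adapter, so the genomic/adapter
# boundary inside the read is itself the DNase I digestion edge.

#' Detect the genomic/adapter boundary within a single read
#'
#' Returns the smallest offset `b` such that the read suffix starting at
#' `b` matches a prefix of the adapter: at overlap >= `exact_below`
#' bases, up to `max_mismatch_rate` mismatches (per overlapping base)
#' are allowed; shorter read-end overlaps (down to a single base) must
#' match exactly, so a fragment one base short of the read length still
#' has its single trailing adapter base removed.  When no boundary
#' exists, `boundary` equals the read length.
#'
#' @param read DNA string (one read).
#' @param adapter Adapter DNA string.
#' @param min_overlap Minimum overlap for the mismatch-tolerant path
#'   (>= 3); overlaps below `max(min_overlap, exact_below)` fall back
#'   to the exact-match rule.
#' @param max_mismatch_rate Maximum mismatch proportion for overlaps on
#'   the mismatch-tolerant path.
#' @param exact_below Overlaps shorter than this must match exactly.
#' @return A list of class `trim_result`: `kept_prefix`, `boundary`
#'   (0-based offset of the first adapter base), `adapter_found`.
#' @export
#' @examples
#' trim_adapter("ACGTACGTAGATCG", "AGATCGGAAGAGC")$boundary
trim_adapter <- function(read, adapter, min_overlap = 3L,
                         max_mismatch_rate = 0.1, exact_below = 6L) {
  if (!nzchar(read)) stop("empty read", call. = FALSE)
  if (!nzchar(adapter)) stop("empty adapter", call. = FALSE)
  if (min_overlap < 3L) stop("`min_overlap` must be >= 3", call. = FALSE)
  n <- nchar(read)
  rraw <- charToRaw(toupper(read))
  araw <- charToRaw(toupper(adapter))
  boundary <- n
  lo <- max(exact_below, min_overlap)
  for (b in 0:(n - 1L)) {
    ov <- min(n - b, length(araw))
    mm <- sum(rraw[(b + 1L):(b + ov)] != araw[seq_len(ov)])
    ok <- if (ov < lo) mm == 0L else mm <= max_mismatch_rate * ov
    if (ok) { boundary <- b; break }
  }
  structure(list(kept_prefix = substr(read, 1L, boundary),
                 boundary = as.integer(boundary),
                 adapter_found = boundary < n),
            class = "trim_result")
}

#' Trim adapters from a set of reads
#'
#' Vectorized equivalent of applying [trim_adapter()] to every read:
#' candidate boundaries are scanned in increasing order simultaneously
#' for all reads, so results are identical to the per-read function.
#'
#' @param reads [Biostrings::DNAStringSet] or character vector.
#' @inheritParams trim_adapter
#' @return A data.frame with columns `boundary` and `adapter_found`,
#'   one row per read.
#' @export
trim_reads <- function(reads, adapter, min_overlap = 3L,
                       max_mismatch_rate = 0.1, exact_below = 6L) {
  reads <- toupper(as.character(reads))
  if (!length(reads))
    return(data.frame(boundary = integer(), adapter_found = logical()))
  n <- nchar(reads)
  if (length(unique(n)) > 1L) {
    # mixed lengths: defer to the per-read scan
    boundary <- vapply(reads, function(r)
      trim_adapter(r, adapter, min_overlap, max_mismatch_rate,
                   exact_below)$boundary, integer(1), USE.NAMES = FALSE)
    return(data.frame(boundary = boundary, adapter_found = boundary < n))
  }
  len <- n[1]
  araw <- charToRaw(toupper(adapter))
  # byte matrix: len rows x nreads columns
  rmat <- matrix(charToRaw(paste(reads, collapse = "")), nrow = len)
  boundary <- rep(len, length(reads))
  unresolved <- rep(TRUE, length(reads))
  lo <- max(exact_below, min_overlap)
  for (b in 0:(len - 1L)) {
    ov <- min(len - b, length(araw))
    idx <- which(unresolved)
    if (!length(idx)) break
    mm <- colSums(rmat[(b + 1L):(b + ov), idx, drop = FALSE] !=
                    araw[seq_len(ov)])
    ok <- if (ov < lo) mm == 0L else mm <= max_mismatch_rate * ov
    hit <- idx[ok]
    boundary[hit] <- b
    unresolved[hit] <- FALSE
  }
  data.frame(boundary = as.integer(boundary),
             adapter_found = boundary < n)
}

#' Build an exact-match genome index
#'
#' Stores the reference with a seed length used to anchor candidate
#' placements; matches are verified over the full read, so only perfect
#' full-length placements are ever reported.
#'
#' @param genome DNA string or [Biostrings::DNAString]; single sequence.
#' @param chrom Sequence name used in output fragments.
#' @param seed_k Seed length in bases for candidate anchoring.
#' @return A list of class `genome_index`.
#' @export
genome_index <- function(genome, chrom = "chr", seed_k = 25L) {
  g <- toupper(as.character(genome))
  structure(list(genome = g, dna = Biostrings::DNAString(g),
                 chrom = chrom, length = nchar(g),
                 seed_k = as.integer(seed_k)),
            class = "genome_index")
}

# all 0-based start positions where `query` occurs exactly in the genome
# (forward strand)
perfect_placements <- function(query, index) {
  if (nchar(query) < 1L) return(integer())
  m <- Biostrings::matchPattern(query, index$dna, max.mismatch = 0)
  BiocGenerics::start(m) - 1L
}

#' Place one trimmed read pair on the reference
#'
#' Read 1 must have a unique perfect placement on the forward strand and
#' read 2 (as its reverse complement) a unique perfect placement
#' downstream of it (convergent orientation).  The fragment is
#' `[start of r1, end of r2 placement)`.
#'
#' @param r1_trimmed,r2_trimmed Trimmed read sequences (genomic prefix
#'   only).
#' @param index A `genome_index`.
#' @param max_len Maximum accepted implied fragment length; longer
#'   pairs are reported as discordant.
#' @return A list with `status` (`"mapped"`, `"ambiguous"`,
#'   `"unmapped"`) and, when mapped, `fragment` (one-row data.frame
#'   `chrom`, `start`, `end`).
#' @export
map_read_pair <- function(r1_trimmed, r2_trimmed, index, max_len = 150L) {
  stopifnot(inherits(index, "genome_index"))
  p1 <- perfect_placements(r1_trimmed, index)
  p2 <- perfect_placements(revcomp(r2_trimmed), index)
  if (length(p1) == 0L || length(p2) == 0L) return(list(status = "unmapped"))
  if (length(p1) > 1L || length(p2) > 1L) return(list(status = "ambiguous"))
  start <- p1
  end <- p2 + nchar(r2_trimmed)
  implied <- end - start
  if (implied <= 0L || implied > max_len || p2 < p1)
    return(list(status = "unmapped"))   # discordant orientation/length
  list(status = "mapped",
       fragment = new_fragments(chrom = index$chrom, start = start, end = end))
}

#' Place many trimmed read pairs at once
#'
#' Batch version of [map_read_pair()]: candidate placements are anchored
#' with a fixed-width seed dictionary and verified over the full read,
#' so results agree with the per-pair function.
#'
#' @param r1,r2 Character vectors of trimmed read sequences.
#' @param index A `genome_index`.
#' @param max_len Maximum accepted implied fragment length.
#' @return A list with `fragments` (data.frame of mapped pairs, with a
#'   `pair` column giving the input row) and `status` (per-pair factor:
#'   mapped/ambiguous/unmapped).
#' @export
map_read_pairs <- function(r1, r2, index, max_len = 150L) {
  stopifnot(inherits(index, "genome_index"), length(r1) == length(r2))
  n <- length(r1)
  if (n == 0L)
    return(list(fragments = new_fragments(pair = integer()),
                status = factor(character(),
                                levels = c("mapped", "ambiguous", "unmapped"))))
  r2rc <- revcomp(r2)
  place <- function(qs) {
    # returns list(pos = 0-based unique placement or NA, nhit = count)
    pos <- rep(NA_integer_, length(qs))
    nhit <- integer(length(qs))
    usable <- which(nchar(qs) >= index$seed_k)  # shorter queries: unmapped
    if (!length(usable)) return(list(pos = pos, nhit = nhit))
    k <- index$seed_k
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(substr(qs[usable], 1L, k)))
    hits <- Biostrings::matchPDict(pd, index$dna)
    starts <- BiocGenerics::start(hits)  # IntegerList, 1-based seed starts
    for (u in which(lengths(starts) > 0L)) {
      i <- usable[u]
      s <- starts[[u]]
      # verify full-length exact match at each candidate anchor
      inb <- s + nchar(qs[i]) - 1L <= index$length
      ok <- inb
      ok[inb] <- substring(index$genome, s[inb],
                           s[inb] + nchar(qs[i]) - 1L) == qs[i]
      nhit[i] <- sum(ok)
      if (nhit[i] == 1L) pos[i] <- s[ok] - 1L
    }
    list(pos = pos, nhit = nhit)
  }
  m1 <- place(r1)
  m2 <- place(r2rc)
  status <- rep("unmapped", n)
  status[m1$nhit > 1L | m2$nhit > 1L] <- "ambiguous"
  start <- m1$pos
  end <- m2$pos + nchar(r2)
  concordant <- !is.na(start) & !is.na(end) & m1$nhit == 1L & m2$nhit == 1L &
    end - start > 0L & end - start <= max_len & m2$pos >= m1$pos
  status[concordant] <- "mapped"
  idx <- which(concordant)
  list(fragments = new_fragments(chrom = index$chrom, start = start[idx],
                                 end = end[idx], pair = idx),
       status = factor(status, levels = c("mapped", "ambiguous", "unmapped")))
}

#' Load fragment intervals from a BED or BEDPE file
#'
#' BED rows become fragments directly; BEDPE rows are collapsed to the
#' outer interval spanned by the two mates.  Invalid rows are rejected
#' with an error naming the offending line.
#'
#' @param path Path to a BED (>= 3 columns) or BEDPE (>= 6 columns,
#'   detected by paired chrom columns) file, 0-based half-open.
#' @param genome_length Optional; when given, fragments outside
#'   `[0, genome_length)` are rejected.
#' @return Fragment data.frame (`chrom`, `start`, `end`).
#' @export
load_fragments <- function(path, genome_length = NULL) {
  lines <- readLines(path)
  keep <- which(nzchar(lines) & !startsWith(lines, "#") &
                  !startsWith(lines, "track"))
  if (!length(keep)) return(new_fragments())
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  ncol1 <- length(fields[[1]])
  # BEDPE rows carry a second chrom in column 4 and integer mate
  # coordinates in columns 5-6 (a BED6 row has a strand there instead)
  is_bedpe <- ncol1 >= 6L &&
    suppressWarnings(!is.na(as.integer(fields[[1]][2])) &&
                       !is.na(as.integer(fields[[1]][3])) &&
                       is.na(as.integer(fields[[1]][4])) &&
                       !is.na(as.integer(fields[[1]][5])) &&
                       !is.na(as.integer(fields[[1]][6])))
  parse_row <- function(f, lineno) {
    if (is_bedpe) {
      if (length(f) < 6L)
        stop(sprintf("line %d: BEDPE row has fewer than 6 fields", lineno),
             call. = FALSE)
      if (f[1] != f[4])
        stop(sprintf("line %d: BEDPE mates on different sequences", lineno),
             call. = FALSE)
      s <- suppressWarnings(as.integer(c(f[2], f[5])))
      e <- suppressWarnings(as.integer(c(f[3], f[6])))
      if (any(is.na(s)) || any(is.na(e)))
        stop(sprintf("line %d: non-integer coordinates", lineno), call. = FALSE)
      c(chrom = f[1], start = min(s), end = max(e))
    } else {
      if (length(f) < 3L)
        stop(sprintf("line %d: BED row has fewer than 3 fields", lineno),
             call. = FALSE)
      s <- suppressWarnings(as.integer(f[2]))
      e <- suppressWarnings(as.integer(f[3]))
      if (is.na(s) || is.na(e))
        stop(sprintf("line %d: non-integer coordinates", lineno), call. = FALSE)
      c(chrom = f[1], start = s, end = e)
    }
  }
  rows <- mapply(parse_row, fields, keep, SIMPLIFY = FALSE)
  chrom <- vapply(rows, `[[`, character(1), "chrom")
  start <- as.integer(vapply(rows, `[[`, character(1), "start"))
  end <- as.integer(vapply(rows, `[[`, character(1), "end"))
  bad <- which(start >= end)
  if (length(bad))
    stop(sprintf("line %d: empty or inverted interval (start >= end)",
                 keep[bad[1]]), call. = FALSE)
  if (!is.null(genome_length)) {
    oob <- which(start < 0L | end > genome_length)
    if (length(oob))
      stop(sprintf("line %d: interval outside the reference", keep[oob[1]]),
           call. = FALSE)
  }
  new_fragments(chrom = chrom, start = start, end = end)
}
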