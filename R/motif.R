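# Degenerate-consensus scanning and position-frequency summaries of
# called regions.  De-novo motif discovery is delegated to external
# tools (regions are exported as FASTA); only IUPAC scanning and PWM
# summarization are implemented here.

#' Shipped consensus patterns
#'
#' Named IUPAC presets: the canonical binding-sequence consensus
#' (`ibs_known`, WATCARnnnnTTR), the per-condition consensus elements
#' (`consensus_0min` CAnnnnTTT, `consensus_10min` WWTCARSnnnTTA,
#' `consensus_20min` WWCARSnnnTT, `consensus_random` WAWCAACnnnTT),
#' and the transiently bound attL-proximal consensus (`ttca_like`,
#' TAAnnnnTTGATW).
#'
#' @return Named character vector of IUPAC patterns.
#' @export
motif_presets <- function() {
  c(ibs_known = "WATCARnnnnTTR",
    consensus_0min = "CAnnnnTTT",
    consensus_10min = "WWTCARSnnnTTA",
    consensus_20min = "WWCARSnnnTT",
    consensus_random = "WAWCAACnnnTT",
    ttca_like = "TAAnnnnTTGATW")
}

iupac_to_regex <- function(pattern) {
  codes <- strsplit(toupper(pattern), "")[[1]]
  bad <- setdiff(codes, names(IUPAC_CODES))
  if (length(bad))
    stop("illegal IUPAC code(s): ", paste(bad, collapse = ","), call. = FALSE)
  paste(vapply(codes, function(cc) {
    allowed <- IUPAC_CODES[[cc]]
    if (length(allowed) == 1L) allowed
    else paste0("[", paste(allowed, collapse = ""), "]")
  }, character(1)), collapse = "")
}

#' Scan a sequence for a degenerate IUPAC pattern
#'
#' Reports every position (overlapping hits included) where each
#' pattern code's allowed-base set contains the sequence base.  A
#' reference `N` matches nothing except a pattern `N`.  Minus-strand
#' hits are found by scanning the reverse complement and are reported
#' in plus-strand coordinates with the plus-strand window sequence.
#'
#' @param sequence DNA string over `A,C,G,T,N`.
#' @param pattern IUPAC pattern string.
#' @param both_strands Scan the minus strand too?
#' @return A data.frame: `position` (0-based start), `strand`,
#'   `matched_seq` (plus-strand window).
#' @export
#' @examples
#' iupac_scan("AATCAGAAAATTG", "WATCARnnnnTTR")
iupac_scan <- function(sequence, pattern, both_strands = TRUE) {
  sequence <- toupper(sequence)
  plen <- nchar(pattern)
  rex <- paste0("(?=", iupac_to_regex(pattern), ")")   # overlapping hits
  scan1 <- function(s) {
    m <- gregexpr(rex, s, perl = TRUE)[[1]]
    if (m[1] == -1L) integer() else as.integer(m) - 1L
  }
  pos_f <- scan1(sequence)
  hits <- data.frame(position = pos_f,
                     strand = rep("+", length(pos_f)),
                     stringsAsFactors = FALSE)
  if (both_strands) {
    rc <- revcomp(sequence)
    pos_rc <- scan1(rc)
    pos_m <- nchar(sequence) - pos_rc - plen
    hits <- rbind(hits, data.frame(position = pos_m,
                                   strand = rep("-", length(pos_m)),
                                   stringsAsFactors = FALSE))
  }
  hits <- hits[order(hits$position, hits$strand), , drop = FALSE]
  hits$matched_seq <- if (nrow(hits))
    substring(sequence, hits$position + 1L, hits$position + plen)
  else character()
  rownames(hits) <- NULL
  hits
}

#' Fraction of regions containing a consensus
#'
#' A region counts once no matter how many hits it contains; hits on
#' either strand count.
#'
#' @param regions Data.frame with `start`/`end` (0-based half-open).
#' @param genome DNA string.
#' @param pattern IUPAC pattern.
#' @return A list: `n_with_match`, `n_total`, `fraction`.
#' @export
consensus_fraction <- function(regions, genome, pattern) {
  if (!nrow(regions)) stop("empty region list", call. = FALSE)
  if (any(regions$start < 0) || any(regions$end > nchar(genome)))
    stop("region outside genome", call. = FALSE)
  has <- vapply(seq_len(nrow(regions)), function(k) {
    s <- substring(genome, regions$start[k] + 1L, regions$end[k])
    nrow(iupac_scan(s, pattern, both_strands = TRUE)) > 0L
  }, logical(1))
  list(n_with_match = sum(has), n_total = nrow(regions),
       fraction = sum(has) / nrow(regions))
}

#' Position-frequency summary of aligned sequences
#'
#' Column base frequencies with pseudocount smoothing, plus per-column
#' information content in bits against a uniform background:
#' `IC = 2 + sum f log2 f`.
#'
#' @param sequences Character vector (>= 2) of equal-length aligned
#'   DNA strings.
#' @param pseudocount Added to every base count per column before
#'   normalization.
#' @return A list of class `pwm`: `freq` (4 x L matrix, rows ACGT),
#'   `ic` (bits per column), `n_sequences`.
#' @export
build_pwm <- function(sequences, pseudocount = 0) {
  if (length(sequences) < 2L) stop("need >= 2 sequences", call. = FALSE)
  L <- unique(nchar(sequences))
  if (length(L) != 1L) stop("sequences must have equal length", call. = FALSE)
  mat <- do.call(rbind, strsplit(toupper(sequences), ""))
  freq <- vapply(seq_len(L), function(j) {
    counts <- table(factor(mat[, j], levels = BASES)) + pseudocount
    as.numeric(counts / sum(counts))
  }, numeric(4))
  rownames(freq) <- BASES
  ic <- apply(freq, 2, function(f) {
    nz <- f[f > 0]
    2 + sum(nz * log2(nz))
  })
  structure(list(freq = freq, ic = ic, n_sequences = length(sequences)),
            class = "pwm")
}

#' Export region sequences as FASTA
#'
#' One record per region; the header encodes the 1-based inclusive
#' coordinates (`chrom:101-180` for the internal `[100, 180)`).
#' Optional symmetric flanks are clipped at the genome ends.
#'
#' @param regions Data.frame with `chrom`, `start`, `end`.
#' @param genome DNA string.
#' @param file Output FASTA path.
#' @param flank Bases added on each side.
#' @return Invisibly, the file path.
#' @export
export_region_fasta <- function(regions, genome, file, flank = 0L) {
  L <- nchar(genome)
  s <- pmax(0L, regions$start - flank)
  e <- pmin(L, regions$end + flank)
  seqs <- Biostrings::DNAStringSet(substring(genome, s + 1L, e))
  names(seqs) <- sprintf("%s:%d-%d", regions$chrom, s + 1L, e)
  Biostrings::writeXStringSet(seqs, file)
  invisible(file)
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM over %d columns from %d sequences; total IC %.2f bits\n",
              ncol(x$freq), x$n_sequences, sum(x$ic)))
  invisible(x)
}
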