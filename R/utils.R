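#' @importFrom stats rbinom runif setNames
#' @importFrom utils read.table write.table head
NULL

# Internal helpers shared across modules.  Coordinates are 0-based
# half-open everywhere inside the package; conversion to the 1-based
# inclusive convention happens only in human-readable reports.

BASES <- c("A", "C", "G", "T")

# IUPAC degenerate nucleotide codes.  A reference 'N' matches only a
# pattern 'N', hence its presence in the N class and nowhere else.
IUPAC_CODES <- list(
  A = "A", C = "C", G = "G", T = "T",
  W = c("A", "T"), S = c("G", "C"),
  R = c("A", "G"), Y = c("C", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T", "N")
)

#' Reverse complement of a DNA string
#'
#' Plain-character convenience wrapper around
#' [Biostrings::reverseComplement()]; accepts and returns `character`.
#'
#' @param x A character vector of DNA strings over `A,C,G,T,N`.
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp("AACGT")
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

stop_if_not_scalar_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != trunc(x) || x < min)
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
}

# 0-based half-open [start, end) -> IRanges (1-based closed)
to_iranges <- function(start, end) IRanges::IRanges(start = start + 1L, end = end)

#' Format a half-open interval in the 1-based inclusive reporting style
#'
#' Internal coordinates are 0-based half-open; reports use the 1-based
#' inclusive convention with thousands separators, e.g. the interval
#' `[3925748, 3925842)` renders as `"3,925,749 to 3,925,842"`.
#'
#' @param start,end Integer vectors, 0-based half-open.
#' @return Character vector of formatted positions.
#' @export
#' @examples
#' format_position(3925748, 3925842)
format_position <- function(start, end) {
  stopifnot(all(start < end))
  paste0(formatC(start + 1, format = "d", big.mark = ","), " to ",
         formatC(end, format = "d", big.mark = ","))
}

# fragments are plain data.frames: chrom, start, end (0-based half-open)
validate_fragments <- function(fragments) {
  need <- c("chrom", "start", "end")
  if (!is.data.frame(fragments) || !all(need %in% names(fragments)))
    stop("fragments must be a data.frame with columns chrom, start, end",
         call. = FALSE)
  if (nrow(fragments) && any(fragments$start >= fragments$end))
    stop("fragments must satisfy start < end (0-based half-open)", call. = FALSE)
  invisible(fragments)
}

new_fragments <- function(chrom = character(), start = integer(),
                          end = integer(), ...) {
  df <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                   end = as.integer(end), ..., stringsAsFactors = FALSE)
  validate_fragments(df)
  df
}
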