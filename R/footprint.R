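# Core caller.  A protected region ("component") is a 70-110 bp
# interval sandwiched between positions where many fragment 5' starts
# (left edge) and 3' ends (right edge) pile up, with mean read depth
# above a library-size-scaled threshold.  Overlapping components are
# grouped into peaks.

#' Caller configuration
#'
#' @param ewf Minimum component width in bases.
#' @param ewt Maximum component width in bases.
#' @param base_threshold Depth threshold (reads) assigned to the
#'   reference library.
#' @param ref_mapped Mapped-fragment count of the reference library;
#'   thresholds for other libraries are scaled by their mapped-count
#'   ratio (see [scale_threshold()]).
#' @param end_support_min Minimum number of fragment ends piled exactly
#'   at a candidate edge position.
#' @param edge_bucket Edge tolerance (bases) used when deduplicating
#'   near-identical candidates: two candidates sharing both edges
#'   within `edge_bucket` bases are considered the same region.
#' @return A list of class `caller_config`.
#' @export
caller_config <- function(ewf = 70L, ewt = 110L, base_threshold = 10000L,
                          ref_mapped = NULL, end_support_min = 3L,
                          edge_bucket = 2L) {
  if (!(ewf > 0 && ewf <= ewt))
    stop("need 0 < ewf <= ewt", call. = FALSE)
  if (base_threshold <= 0) stop("`base_threshold` must be > 0", call. = FALSE)
  if (end_support_min < 1) stop("`end_support_min` must be >= 1", call. = FALSE)
  structure(list(ewf = as.integer(ewf), ewt = as.integer(ewt),
                 base_threshold = base_threshold,
                 ref_mapped = ref_mapped,
                 end_support_min = as.integer(end_support_min),
                 edge_bucket = as.integer(edge_bucket)),
            class = "caller_config")
}

#' Per-base depth and fragment-end profiles
#'
#' `depth[p]` counts fragments covering position `p`; `left_ends[s]`
#' and `right_ends[e - 1]` are incremented once per fragment `[s, e)`,
#' i.e. right ends are recorded at the last covered base.  Conservation
#' identities: the depth sums to the total fragment length, and both
#' end vectors sum to the fragment count.
#'
#' @param fragments Fragment data.frame (`chrom`, `start`, `end`),
#'   0-based half-open, all within `[0, genome_length)`.
#' @param genome_length Genome length in bases.
#' @return A list of class `fp_profiles`: `depth`, `left_ends`,
#'   `right_ends` (integer vectors indexed 1 + position), and
#'   `total_mapped`.
#' @export
compute_profiles <- function(fragments, genome_length) {
  validate_fragments(fragments)
  stop_if_not_scalar_count(genome_length, "genome_length")
  L <- as.integer(genome_length)
  if (nrow(fragments) && (any(fragments$start < 0) || any(fragments$end > L)))
    stop("fragment out of genome bounds", call. = FALSE)
  if (nrow(fragments)) {
    cov <- IRanges::coverage(to_iranges(fragments$start, fragments$end),
                             width = L)
    depth <- as.integer(cov)
    left_ends <- tabulate(fragments$start + 1L, nbins = L)
    right_ends <- tabulate(fragments$end, nbins = L)
  } else {
    depth <- left_ends <- right_ends <- integer(L)
  }
  structure(list(depth = depth, left_ends = left_ends,
                 right_ends = right_ends, total_mapped = nrow(fragments),
                 genome_length = L),
            class = "fp_profiles")
}

#' Scale the depth threshold to a library's mapped-read count
#'
#' The reference library is assigned `base_threshold`; any other
#' library gets `floor(base_threshold * sample_mapped / ref_mapped)`,
#' so thresholds track sequencing depth and calls stay comparable
#' across libraries.  Truncation (floor) is used, inferred from the
#' published threshold values this rule reproduces.
#'
#' @param base_threshold Threshold (reads) for the reference library.
#' @param ref_mapped Mapped count of the reference library.
#' @param sample_mapped Mapped count of the library being called.
#' @return Integer threshold.
#' @export
#' @examples
#' scale_threshold(10000, 15289849, 29977846)  # 19606
scale_threshold <- function(base_threshold, ref_mapped, sample_mapped) {
  for (nm in c("base_threshold", "ref_mapped", "sample_mapped")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0 ||
        v != trunc(v))
      stop(sprintf("`%s` must be a single positive integer", nm), call. = FALSE)
  }
  # products stay below 2^53, so double arithmetic is exact here
  as.integer(floor(as.numeric(base_threshold) * as.numeric(sample_mapped) /
                     as.numeric(ref_mapped)))
}

# candidate enumeration shared by the caller; returns data.frame of all
# (start, end) half-open windows whose width lies in [ewf, ewt], whose
# first and last positions carry enough fragment-end support, scored by
# mean depth
enumerate_candidates <- function(profiles, cfg) {
  L <- profiles$genome_length
  lefts <- which(profiles$left_ends >= cfg$end_support_min) - 1L   # 0-based i
  rights <- which(profiles$right_ends >= cfg$end_support_min) - 1L # 0-based j
  if (!length(lefts) || !length(rights))
    return(data.frame(start = integer(), end = integer(),
                      width = integer(), score = numeric()))
  is_right <- logical(L)
  is_right[rights + 1L] <- TRUE
  cum <- c(0, cumsum(as.numeric(profiles$depth)))
  out <- vector("list", cfg$ewt - cfg$ewf + 1L)
  for (w in cfg$ewf:cfg$ewt) {
    i <- lefts[lefts + w <= L]
    i <- i[is_right[i + w]]          # j = i + w - 1 has right support
    if (!length(i)) next
    score <- (cum[i + w + 1L] - cum[i + 1L]) / w
    out[[w - cfg$ewf + 1L]] <- data.frame(start = i, end = i + w,
                                          width = w, score = score)
  }
  cand <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(cand))
    return(data.frame(start = integer(), end = integer(),
                      width = integer(), score = numeric()))
  rownames(cand) <- NULL
  cand
}

#' Call protected-region components
#'
#' Candidates are all windows of width `ewf` to `ewt` whose first
#' position has `end_support_min` fragment 5' starts and whose last
#' position has `end_support_min` fragment 3' ends, scored by mean
#' depth over the window.  Candidates scoring at least `threshold` are
#' selected greedily in descending score order (ties: wider first, then
#' leftmost); a candidate is discarded only when both its edges fall
#' within `edge_bucket` bases of an already-selected component, so
#' genuinely distinct overlapping components are retained.
#'
#' @param profiles An `fp_profiles` object from [compute_profiles()].
#' @param threshold Depth threshold for this library (see
#'   [scale_threshold()]).
#' @param cfg A `caller_config`.
#' @param fragments Optional fragment data.frame used to attach
#'   `read_count` (fragments overlapping each component by >= 1 base).
#' @param chrom Sequence name for the output.
#' @return A data.frame of class `fp_components`: `component_id`,
#'   `chrom`, `start`, `end`, `width`, `avg_depth`, `read_count`,
#'   sorted by position.
#' @export
call_components <- function(profiles, threshold, cfg = caller_config(),
                            fragments = NULL, chrom = "chr") {
  stopifnot(inherits(profiles, "fp_profiles"), inherits(cfg, "caller_config"))
  if (threshold <= 0) stop("`threshold` must be > 0", call. = FALSE)
  if (profiles$genome_length < 1L) stop("empty genome", call. = FALSE)
  cand <- enumerate_candidates(profiles, cfg)
  cand <- cand[cand$score >= threshold, , drop = FALSE]
  sel <- greedy_select(cand, cfg$edge_bucket)
  sel <- sel[order(sel$start, sel$end), , drop = FALSE]
  comps <- data.frame(component_id = seq_len(nrow(sel)),
                      chrom = rep(chrom, nrow(sel)),
                      start = sel$start, end = sel$end, width = sel$width,
                      avg_depth = sel$score,
                      read_count = rep(NA_integer_, nrow(sel)),
                      stringsAsFactors = FALSE)
  if (!is.null(fragments) && nrow(comps)) {
    validate_fragments(fragments)
    comps$read_count <- IRanges::countOverlaps(
      to_iranges(comps$start, comps$end),
      to_iranges(fragments$start, fragments$end), minoverlap = 1L)
  }
  rownames(comps) <- NULL
  class(comps) <- c("fp_components", "data.frame")
  comps
}

# greedy deduplication: descending score, ties wider then leftmost;
# drop a candidate iff both edges lie within `bucket` bases of a
# previously selected candidate's edges
greedy_select <- function(cand, bucket) {
  if (!nrow(cand)) return(cand)
  ord <- order(-cand$score, -cand$width, cand$start)
  cand <- cand[ord, , drop = FALSE]
  keep_start <- integer(0)
  keep_end <- integer(0)
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    dup <- any(abs(cand$start[k] - keep_start) <= bucket &
                 abs(cand$end[k] - keep_end) <= bucket)
    if (!dup) {
      keep[k] <- TRUE
      keep_start <- c(keep_start, cand$start[k])
      keep_end <- c(keep_end, cand$end[k])
    }
  }
  cand[keep, , drop = FALSE]
}

#' Group components into peaks
#'
#' Peaks are the transitive closure of components under interval
#' overlap (at least one shared base; abutting half-open intervals do
#' not overlap).  Each peak spans its members.
#'
#' @param components An `fp_components` data.frame, sorted by position.
#' @return A list with `peaks` (data.frame: `peak_id`, `chrom`,
#'   `start`, `end`, `n_members`, `member_ids`) and `components` (the
#'   input with a `peak_id` column added).
#' @export
merge_peaks <- function(components) {
  if (!nrow(components)) {
    peaks <- data.frame(peak_id = integer(), chrom = character(),
                        start = integer(), end = integer(),
                        n_members = integer(), member_ids = character(),
                        stringsAsFactors = FALSE)
    components$peak_id <- integer(0)
    return(list(peaks = peaks, components = components))
  }
  ir <- to_iranges(components$start, components$end)
  # min.gapwidth = 0 merges overlapping ranges only, not abutting ones
  red <- IRanges::reduce(ir, min.gapwidth = 0L)
  hit <- IRanges::findOverlaps(ir, red)
  components$peak_id <- S4Vectors::subjectHits(hit)[order(S4Vectors::queryHits(hit))]
  peaks <- data.frame(peak_id = seq_along(red),
                      chrom = components$chrom[1],
                      start = BiocGenerics::start(red) - 1L,
                      end = BiocGenerics::end(red),
                      n_members = as.integer(table(factor(components$peak_id,
                                                          levels = seq_along(red)))),
                      member_ids = vapply(seq_along(red), function(p)
                        paste(components$component_id[components$peak_id == p],
                              collapse = ","), character(1)),
                      stringsAsFactors = FALSE)
  list(peaks = peaks, components = components)
}

#' Export called components and peaks
#'
#' Writes `components.bed` and `peaks.bed` (BED6, 0-based half-open)
#' and a human-readable `components.tsv` in which coordinates follow
#' the 1-based inclusive reporting convention (e.g. the internal
#' interval `[3925748, 3925842)` is reported as
#' `"3,925,749 to 3,925,842"`).
#'
#' @param components An `fp_components` data.frame (with `peak_id`,
#'   as returned by [merge_peaks()]; added as `NA` when absent).
#' @param peaks Peak data.frame from [merge_peaks()].
#' @param dir Output directory.
#' @return Invisibly, named vector of paths written.
#' @export
export_components <- function(components, peaks, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(components_bed = file.path(dir, "components.bed"),
             peaks_bed = file.path(dir, "peaks.bed"),
             tsv = file.path(dir, "components.tsv"))
  if (is.null(components$peak_id)) components$peak_id <- NA_integer_
  write_bed(new_fragments(chrom = components$chrom, start = components$start,
                          end = components$end,
                          name = sprintf("component_%d", components$component_id),
                          score = as.integer(pmin(1000, round(components$avg_depth))),
                          strand = rep(".", nrow(components))),
            paths[["components_bed"]])
  write_bed(new_fragments(chrom = peaks$chrom, start = peaks$start,
                          end = peaks$end,
                          name = sprintf("peak_%d", peaks$peak_id),
                          score = peaks$n_members,
                          strand = rep(".", nrow(peaks))),
            paths[["peaks_bed"]])
  tsv <- data.frame(component_id = components$component_id,
                    chrom = components$chrom,
                    genomic_positions = if (nrow(components))
                      format_position(components$start, components$end)
                    else character(),
                    width = components$width,
                    avg_depth = round(components$avg_depth, 1),
                    read_count = components$read_count,
                    peak_id = components$peak_id,
                    stringsAsFactors = FALSE)
  write.table(tsv, paths[["tsv"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}

#' @export
print.fp_components <- function(x, ...) {
  cat(sprintf("Protected-region components: %d called\n", nrow(x)))
  if (nrow(x)) print.data.frame(head(as.data.frame(x), 10), ...)
  invisible(x)
}
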