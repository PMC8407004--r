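# Cross-condition occupancy analysis: normalized read numbers per
# component, per-library threshold classification, ranking,
# timepoint-specificity labels, display scale factors, and the
# qPCR-style ratio arithmetic used alongside the sequencing assay.

#' Count fragments overlapping a component
#'
#' A fragment counts if it shares at least one base with the component
#' interval (both 0-based half-open).
#'
#' @param component Either a numeric `c(start, end)` pair or a one-row
#'   data.frame with `start`/`end` columns.
#' @param fragments Fragment data.frame.
#' @return Integer count.
#' @export
count_overlapping <- function(component, fragments) {
  validate_fragments(fragments)
  if (is.data.frame(component)) component <- c(component$start[1], component$end[1])
  stopifnot(length(component) == 2L, component[1] < component[2])
  if (!nrow(fragments)) return(0L)
  IRanges::countOverlaps(to_iranges(component[1], component[2]),
                         to_iranges(fragments$start, fragments$end),
                         minoverlap = 1L)
}

#' Normalized reads number
#'
#' A component's overlapping fragment count divided by the library's
#' total mapped count, making occupancy comparable across libraries of
#' different depth.
#'
#' @param read_count Fragments overlapping the component.
#' @param total_mapped Total mapped fragments in the library.
#' @return Proportion in `[0, 1]`.
#' @export
normalized_reads <- function(read_count, total_mapped) {
  if (any(total_mapped <= 0)) stop("`total_mapped` must be > 0", call. = FALSE)
  if (any(read_count < 0) || any(read_count > total_mapped))
    stop("need 0 <= read_count <= total_mapped", call. = FALSE)
  read_count / total_mapped
}

#' Classify a component's timepoint specificity
#'
#' Labels follow the above-threshold pattern across the four ordered
#' conditions (0 min, 10 min, 20 min, random): above at 0 min only is
#' pre-initiation-specific (replication-origin-like); above at 10 min
#' only is post-initiation-transient; above everywhere is constitutive;
#' anything else is sporadic.
#'
#' @param flags Logical vector of above-threshold calls, named or
#'   ordered as `c("0min", "10min", "20min", "random")`.
#' @return A list of class `specificity_call`: `label` and `flags`.
#' @export
classify_specificity <- function(flags) {
  conds <- c("0min", "10min", "20min", "random")
  if (!is.null(names(flags))) {
    if (!all(conds %in% names(flags)))
      stop("missing condition(s): ",
           paste(setdiff(conds, names(flags)), collapse = ","), call. = FALSE)
    flags <- flags[conds]
  }
  if (length(flags) != 4L || any(is.na(flags)))
    stop("need four non-missing condition flags", call. = FALSE)
  label <- if (flags[1] && !any(flags[2:4])) "pre-initiation-specific"
  else if (flags[2] && !any(flags[c(1, 3, 4)])) "post-initiation-transient"
  else if (all(flags)) "constitutive"
  else "sporadic"
  structure(list(label = label, flags = setNames(as.logical(flags), conds)),
            class = "specificity_call")
}

#' Rank components within one condition
#'
#' Descending by average depth; ties broken by normalized reads, then
#' by genomic position.  Rank 1 is the highest-binding region.
#'
#' @param table An `occupancy_table` (or data.frame with columns
#'   `avg_depth_<condition>`, `normalized_<condition>`, `start`).
#' @param condition Condition label.
#' @return The table rows reordered, with a `rank` column added.
#' @export
rank_components <- function(table, condition) {
  ad <- table[[paste0("avg_depth_", condition)]]
  nr <- table[[paste0("normalized_", condition)]]
  if (is.null(ad) || !nrow(table))
    stop("table has no rows for condition ", condition, call. = FALSE)
  ord <- order(-ad, -nr, table$start)
  out <- table[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Display scale factor between libraries
#'
#' Ratio of mapped counts used to expand a library's vertical plotting
#' scale so peak heights are directly comparable to the reference.
#' Full precision is returned; rounding is presentation-only.
#'
#' @param ref_mapped,sample_mapped Positive mapped counts.
#' @param digits Rounding applied by [format()]-style presentation;
#'   `NULL` returns the exact ratio.
#' @return Numeric ratio.
#' @export
#' @examples
#' round(display_scale(15289849, 29977846), 2)  # 1.96
display_scale <- function(ref_mapped, sample_mapped, digits = NULL) {
  if (ref_mapped <= 0 || sample_mapped <= 0)
    stop("mapped counts must be > 0", call. = FALSE)
  r <- sample_mapped / ref_mapped
  if (is.null(digits)) r else round(r, digits)
}

#' Affinity-purification yield
#'
#' Percent of input template recovered after purification.
#'
#' @param purified_qty,input_qty Relative template quantities
#'   (arbitrary units, > 0; `purified_qty` >= 0).
#' @return Percent.
#' @export
chap_yield <- function(purified_qty, input_qty) {
  if (any(input_qty <= 0)) stop("`input_qty` must be > 0", call. = FALSE)
  100 * purified_qty / input_qty
}

#' Locus copy ratio normalized to a reference timepoint
#'
#' `r(t) = (a(t) / b(t)) / (a(ref) / b(ref))`; the reference timepoint
#' is exactly 1.
#'
#' @param locus_a_qty,locus_b_qty Named numeric vectors of quantities
#'   per timepoint (> 0), sharing names.
#' @param reference_timepoint Name of the reference timepoint.
#' @return Named numeric vector of normalized ratios.
#' @export
copy_ratio <- function(locus_a_qty, locus_b_qty, reference_timepoint) {
  if (any(locus_a_qty <= 0) || any(locus_b_qty <= 0))
    stop("quantities must be > 0", call. = FALSE)
  if (!identical(names(locus_a_qty), names(locus_b_qty)))
    stop("timepoint names must match between loci", call. = FALSE)
  if (!(reference_timepoint %in% names(locus_a_qty)))
    stop("missing reference timepoint: ", reference_timepoint, call. = FALSE)
  raw <- locus_a_qty / locus_b_qty
  raw / raw[[reference_timepoint]]
}

# merge components called in different conditions into union rows when
# they overlap >= 50% reciprocally (single-linkage closure); returns a
# data.frame of union intervals plus each cluster's representative
# member (the member with the highest avg_depth in its own condition),
# whose width stays within the caller bounds
merge_condition_components <- function(comp_list, min_reciprocal = 0.5) {
  all_comp <- do.call(rbind, lapply(names(comp_list), function(cd) {
    x <- comp_list[[cd]]
    if (!nrow(x)) return(NULL)
    data.frame(condition = cd, chrom = x$chrom, start = x$start, end = x$end,
               avg_depth = x$avg_depth, stringsAsFactors = FALSE)
  }))
  if (is.null(all_comp) || !nrow(all_comp))
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      rep_start = integer(), rep_end = integer()))
  ir <- to_iranges(all_comp$start, all_comp$end)
  hit <- IRanges::findOverlaps(ir, ir)
  q <- S4Vectors::queryHits(hit); s <- S4Vectors::subjectHits(hit)
  ov <- IRanges::width(IRanges::pintersect(ir[q], ir[s]))
  wq <- IRanges::width(ir[q]); ws <- IRanges::width(ir[s])
  link <- ov >= min_reciprocal * wq & ov >= min_reciprocal * ws
  # union-find over reciprocal-overlap links
  parent <- seq_len(nrow(all_comp))
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (k in which(link)) {
    a <- find(q[k]); b <- find(s[k])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  grp <- vapply(seq_len(nrow(all_comp)), find, integer(1))
  agg <- lapply(split(seq_len(nrow(all_comp)), grp), function(ix) {
    best <- ix[which.max(all_comp$avg_depth[ix])]
    data.frame(chrom = all_comp$chrom[ix[1]],
               start = min(all_comp$start[ix]), end = max(all_comp$end[ix]),
               rep_start = all_comp$start[best], rep_end = all_comp$end[best],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the component x condition occupancy table
#'
#' Components called in the individual conditions are merged into union
#' rows when they overlap at least 50% reciprocally; for every union
#' row and condition the table holds the overlapping-fragment count,
#' the normalized reads number, the mean depth over the cluster's
#' representative member interval (`rep_start`/`rep_end`, the member
#' with the highest depth in its own condition, so the evaluation
#' window always respects the caller width bounds), the library's
#' scaled threshold, and the above-threshold flag (mean depth >=
#' threshold).  Rows below threshold in every condition are dropped.
#'
#' @param components_by_condition Named list of `fp_components`, one
#'   per condition.
#' @param fragments_by_condition Named list of fragment data.frames
#'   (same names).
#' @param genome_length Genome length in bases.
#' @param cfg A `caller_config`; `cfg$ref_mapped` may be `NULL`, in
#'   which case the mapped count of `ref_condition` is used.
#' @param ref_condition Condition whose library defines the base
#'   threshold.
#' @param min_reciprocal Reciprocal-overlap fraction for cross-condition
#'   matching.
#' @return A data.frame of class `occupancy_table` with columns `chrom`,
#'   `start`, `end` and per condition `read_count_*`, `normalized_*`,
#'   `avg_depth_*`, `threshold_*`, `above_*`.
#' @export
occupancy_table <- function(components_by_condition, fragments_by_condition,
                            genome_length, cfg = caller_config(),
                            ref_condition = "0min", min_reciprocal = 0.5) {
  conds <- names(components_by_condition)
  stopifnot(identical(sort(conds), sort(names(fragments_by_condition))),
            ref_condition %in% conds)
  union <- merge_condition_components(components_by_condition, min_reciprocal)
  totals <- vapply(fragments_by_condition, nrow, integer(1))
  ref_mapped <- if (is.null(cfg$ref_mapped)) totals[[ref_condition]] else cfg$ref_mapped
  tab <- union
  if (!nrow(tab)) {
    class(tab) <- c("occupancy_table", "data.frame")
    attr(tab, "conditions") <- conds
    return(tab)
  }
  any_above <- rep(FALSE, nrow(tab))
  tab_ir <- to_iranges(tab$start, tab$end)
  for (cd in conds) {
    fr <- fragments_by_condition[[cd]]
    thr <- scale_threshold(cfg$base_threshold, ref_mapped, totals[[cd]])
    cum <- c(0, cumsum(as.numeric(compute_profiles(fr, genome_length)$depth)))
    rc <- IRanges::countOverlaps(tab_ir, to_iranges(fr$start, fr$end),
                                 minoverlap = 1L)
    # mean depth over the cluster's representative member interval: its
    # width respects the caller bounds, so depth is not diluted by the
    # (possibly wider) union span
    ad <- (cum[tab$rep_end + 1L] - cum[tab$rep_start + 1L]) /
      (tab$rep_end - tab$rep_start)
    tab[[paste0("read_count_", cd)]] <- rc
    tab[[paste0("normalized_", cd)]] <- normalized_reads(rc, totals[[cd]])
    tab[[paste0("avg_depth_", cd)]] <- ad
    tab[[paste0("threshold_", cd)]] <- thr
    tab[[paste0("above_", cd)]] <- ad >= thr
    any_above <- any_above | ad >= thr
  }
  tab <- tab[any_above, , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("occupancy_table", "data.frame")
  attr(tab, "conditions") <- conds
  tab
}

#' Label every occupancy-table row
#'
#' Applies [classify_specificity()] to the above-threshold flags of
#' each row.
#'
#' @param table An `occupancy_table` with the four standard conditions.
#' @return The table with a `specificity` character column added.
#' @export
specificity_table <- function(table) {
  conds <- c("0min", "10min", "20min", "random")
  cols <- paste0("above_", conds)
  if (!all(cols %in% names(table)))
    stop("table lacks above-threshold flags for the four standard conditions",
         call. = FALSE)
  table$specificity <- vapply(seq_len(nrow(table)), function(k)
    classify_specificity(setNames(as.logical(table[k, cols]), conds))$label,
    character(1))
  table
}

#' @export
print.specificity_call <- function(x, ...) {
  cat(sprintf("specificity: %s  [%s]\n", x$label,
              paste(names(x$flags)[x$flags], collapse = ",")))
  invisible(x)
}
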