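# Independent brute-force oracles and small fixture builders used
# across the suite.  Oracles deliberately re-derive results from first
# principles (explicit enumeration / pairwise loops) and share no code
# with the implementation paths they check.

# enumerate every (i, j) window directly: width in [ewf, ewt], left
# fragment-start support at i, right fragment-end support at j, scored
# by mean depth over the window
oracle_candidates <- function(depth, left_ends, right_ends,
                              ewf, ewt, support) {
  L <- length(depth)
  rows <- list()
  for (i0 in 0:(L - 1L)) {
    if (left_ends[i0 + 1L] < support) next
    for (w in ewf:ewt) {
      j0 <- i0 + w - 1L
      if (j0 > L - 1L) break
      if (right_ends[j0 + 1L] < support) next
      rows[[length(rows) + 1L]] <-
        data.frame(start = i0, end = j0 + 1L, width = w,
                   score = mean(depth[(i0 + 1L):(j0 + 1L)]))
    }
  }
  if (!length(rows))
    return(data.frame(start = integer(), end = integer(),
                      width = integer(), score = numeric()))
  do.call(rbind, rows)
}

# independent greedy pass: descending score, ties wider then leftmost;
# drop iff both edges within `bucket` of an already kept window
oracle_greedy <- function(cand, bucket = 2L) {
  if (!nrow(cand)) return(cand)
  cand <- cand[order(-cand$score, -cand$width, cand$start), , drop = FALSE]
  kept <- cand[0, , drop = FALSE]
  for (k in seq_len(nrow(cand))) {
    dup <- FALSE
    if (nrow(kept))
      dup <- any(abs(cand$start[k] - kept$start) <= bucket &
                   abs(cand$end[k] - kept$end) <= bucket)
    if (!dup) kept <- rbind(kept, cand[k, ])
  }
  kept[order(kept$start, kept$end), , drop = FALSE]
}

# pairwise >= 1-base overlap count
oracle_overlap_count <- function(comp_start, comp_end, starts, ends) {
  sum(starts < comp_end & ends > comp_start)
}

# position-by-position IUPAC membership scan (plus strand only)
oracle_iupac_scan <- function(sequence, pattern) {
  classes <- list(A = "A", C = "C", G = "G", T = "T",
                  W = c("A", "T"), S = c("G", "C"), R = c("A", "G"),
                  Y = c("C", "T"), K = c("G", "T"), M = c("A", "C"),
                  B = c("C", "G", "T"), D = c("A", "G", "T"),
                  H = c("A", "C", "T"), V = c("A", "C", "G"),
                  N = c("A", "C", "G", "T", "N"))
  sch <- strsplit(toupper(sequence), "")[[1]]
  pch <- strsplit(toupper(pattern), "")[[1]]
  plen <- length(pch)
  hits <- integer()
  if (length(sch) < plen) return(hits)
  for (p0 in 0:(length(sch) - plen)) {
    ok <- TRUE
    for (k in seq_len(plen)) {
      if (!(sch[p0 + k] %in% classes[[pch[k]]])) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, p0)
  }
  hits
}

# a small planted-site instance used by several tests
make_planted_instance <- function(seed, genome_length = 6000L,
                                  occupancy = 1, depth_n = 500L,
                                  n_background = 0L) {
  g <- generate_genome(genome_length, 0.5, seed = seed)
  truth <- plant_sites(g, list(list(site_id = "s1", pattern = "WATCARnnnnTTR",
                                    position = genome_length %/% 2L,
                                    occupancy = c(cond = occupancy))),
                       seed = seed + 1L)
  frags <- simulate_fragments(truth, "cond", n_background, depth_n,
                              seed = seed + 2L)
  list(truth = truth, fragments = frags, genome_length = genome_length)
}

random_fragments <- function(n, genome_length, len_min = 70L, len_max = 110L) {
  len <- sample(len_min:len_max, n, replace = TRUE)
  start <- sample.int(genome_length - len_max, n, replace = TRUE) - 1L
  data.frame(chrom = "chr", start = start, end = start + len,
             stringsAsFactors = FALSE)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
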