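test_that("profiles count coverage and fragment ends positionally", {
  fr <- data.frame(chrom = "chr", start = 10L, end = 90L)
  p <- compute_profiles(fr, 200)
  expect_identical(p$depth[11:90], rep(1L, 80))
  expect_identical(sum(p$depth), 80L)
  expect_identical(p$left_ends[11], 1L)
  expect_identical(p$right_ends[90], 1L)
  expect_identical(sum(p$left_ends), 1L)

  p2 <- compute_profiles(rbind(fr, fr), 200)
  expect_identical(p2$depth[11:90], rep(2L, 80))

  expect_error(compute_profiles(data.frame(chrom = "c", start = 10L,
                                           end = 300L), 200),
               "out of genome bounds")
})

test_that("depth and end-count conservation identities hold", {
  set.seed(201)
  for (rep in 1:5) {
    fr <- random_fragments(300, 5000)
    p <- compute_profiles(fr, 5000)
    expect_identical(sum(p$depth), sum(fr$end - fr$start))
    expect_identical(sum(p$left_ends), nrow(fr))
    expect_identical(sum(p$right_ends), nrow(fr))
  }
})

test_that("scale_threshold floors the mapped-read-ratio product", {
  expect_identical(scale_threshold(10000, 15289849, 29977846), 19606L)
  expect_identical(scale_threshold(10000, 15289849, 17885459), 11697L)
  expect_identical(scale_threshold(7, 123457, 123457), 7L)
  # integer-typed inputs must not overflow the intermediate product
  expect_identical(scale_threshold(10000L, 15289849L, 19546737L), 12784L)
  expect_error(scale_threshold(0, 1, 1), "positive integer")
  expect_error(scale_threshold(10, -5, 1), "positive integer")
})

test_that("call_components matches the brute-force oracle", {
  set.seed(202)
  cfg <- caller_config(ewf = 70, ewt = 110, end_support_min = 2)
  for (rep in 1:12) {
    L <- sample(1200:2500, 1)
    fr <- random_fragments(sample(100:250, 1), L)
    p <- compute_profiles(fr, L)
    thr <- max(1, stats::quantile(p$depth, 0.8))
    cand <- gefseq:::enumerate_candidates(p, cfg)
    ocand <- oracle_candidates(p$depth, p$left_ends, p$right_ends,
                               70, 110, 2)
    o <- order(cand$start, cand$end); oo <- order(ocand$start, ocand$end)
    expect_equal(cand[o, c("start", "end", "width", "score")],
                 ocand[oo, ], ignore_attr = TRUE)

    got <- call_components(p, thr, cfg)
    want <- oracle_greedy(ocand[ocand$score >= thr, , drop = FALSE])
    expect_equal(got[, c("start", "end", "width")],
                 want[, c("start", "end", "width")], ignore_attr = TRUE)
    expect_equal(got$avg_depth, want$score, ignore_attr = TRUE)
  }
})

test_that("a planted site yields one component cluster containing the motif", {
  inst <- make_planted_instance(seed = 203, occupancy = 1, depth_n = 500)
  p <- compute_profiles(inst$fragments[c("chrom", "start", "end")],
                        inst$genome_length)
  comp <- call_components(p, 50, caller_config())
  expect_gt(nrow(comp), 0)
  mstart <- inst$truth$sites$position[1]
  mend <- mstart + inst$truth$sites$width[1]
  expect_true(any(comp$start <= mstart & comp$end >= mend))
  expect_true(all(comp$width >= 70 & comp$width <= 110))
  # every candidate built from protected-fragment edges contains the motif
  expect_true(all(comp$start <= mstart & comp$end >= mend))
})

test_that("raising the threshold only shrinks the component set", {
  inst <- make_planted_instance(seed = 204, occupancy = 0.7, depth_n = 300,
                                n_background = 500)
  p <- compute_profiles(inst$fragments[c("chrom", "start", "end")],
                        inst$genome_length)
  cfg <- caller_config()
  thresholds <- c(20, 60, 120, 200)
  sets <- lapply(thresholds, function(t)
    call_components(p, t, cfg)[c("start", "end")])
  for (k in seq_along(sets)[-1]) {
    key_hi <- paste(sets[[k]]$start, sets[[k]]$end)
    key_lo <- paste(sets[[k - 1]]$start, sets[[k - 1]]$end)
    expect_true(all(key_hi %in% key_lo))
  }
})

test_that("duplicating fragments doubles depth and preserves calls", {
  inst <- make_planted_instance(seed = 205, occupancy = 1, depth_n = 200)
  fr <- inst$fragments[c("chrom", "start", "end")]
  p1 <- compute_profiles(fr, inst$genome_length)
  p2 <- compute_profiles(rbind(fr, fr), inst$genome_length)
  expect_identical(p2$depth, 2L * p1$depth)
  # support floor of 1 so edge support (which also doubles) cannot gate
  cfg <- caller_config(end_support_min = 1)
  c1 <- call_components(p1, 40, cfg)
  c2 <- call_components(p2, 80, cfg)
  expect_identical(c2[c("start", "end")], c1[c("start", "end")])
  expect_equal(c2$avg_depth, 2 * c1$avg_depth)
})

test_that("background-only data yields no components at 5x mean depth", {
  set.seed(206)
  g <- generate_genome(100000, 0.5, seed = 206)
  tr <- plant_sites(g, list(), seed = 1)
  fr <- simulate_fragments(tr, "x", n_background = 20000,
                           enrichment_depth = 0, seed = 207)
  p <- compute_profiles(fr[c("chrom", "start", "end")], 100000)
  thr <- 5 * mean(p$depth)
  expect_identical(nrow(call_components(p, thr, caller_config())), 0L)
})

test_that("merge_peaks takes the transitive overlap closure", {
  comp <- data.frame(component_id = 1:2, chrom = "chr",
                     start = c(100L, 150L), end = c(180L, 240L),
                     width = c(80L, 90L), avg_depth = c(5, 4),
                     read_count = NA_integer_)
  class(comp) <- c("fp_components", "data.frame")
  mp <- merge_peaks(comp)
  expect_identical(nrow(mp$peaks), 1L)
  expect_identical(mp$peaks$start, 100L)
  expect_identical(mp$peaks$end, 240L)
  expect_identical(mp$peaks$n_members, 2L)

  # abutting half-open intervals share no base: two peaks
  comp$start <- c(100L, 180L); comp$end <- c(180L, 260L)
  mp2 <- merge_peaks(comp)
  expect_identical(nrow(mp2$peaks), 2L)

  expect_identical(nrow(merge_peaks(comp[0, ])$peaks), 0L)
})

test_that("two adjacent planted sites give one peak with two member clusters", {
  g <- generate_genome(6000, 0.5, seed = 210)
  tr <- plant_sites(g, list(
    list(site_id = "a", pattern = "WATCARnnnnTTR", position = 3000,
         occupancy = c(x = 1)),
    list(site_id = "b", pattern = "WATCARnnnnTTR", position = 3060,
         occupancy = c(x = 1))), seed = 211)
  fr <- simulate_fragments(tr, "x", 0, 400, seed = 212)
  p <- compute_profiles(fr[c("chrom", "start", "end")], 6000)
  comp <- call_components(p, 50, caller_config())
  mp <- merge_peaks(comp)
  big <- mp$peaks[which.max(mp$peaks$n_members), ]
  expect_gte(big$n_members, 2)
  # the prominent peak spans both motifs
  expect_lte(big$start, 3000)
  expect_gte(big$end, 3073)
})

test_that("export_components renders the 1-based reporting convention", {
  comp <- data.frame(component_id = 1L, chrom = "chr",
                     start = 3925748L, end = 3925842L, width = 94L,
                     avg_depth = 30601.5, read_count = 1000L,
                     peak_id = 1L)
  class(comp) <- c("fp_components", "data.frame")
  peaks <- data.frame(peak_id = 1L, chrom = "chr", start = 3925748L,
                      end = 3925842L, n_members = 1L, member_ids = "1")
  d <- withr::local_tempdir()
  paths <- export_components(comp, peaks, d)
  tsv <- read.delim(paths[["tsv"]])
  expect_identical(tsv$genomic_positions, "3,925,749 to 3,925,842")
  # BED round-trip preserves the half-open interval exactly
  back <- load_fragments(paths[["components_bed"]])
  expect_identical(back$start, 3925748L)
  expect_identical(back$end, 3925842L)

  # empty set: header-only files
  p0 <- export_components(comp[0, ], peaks[0, ], withr::local_tempdir())
  expect_identical(nrow(read.delim(p0[["tsv"]])), 0L)
})
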