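test_that("generate_genome honours length, composition and determinism", {
  g0 <- generate_genome(10000, 0.0, seed = 3)
  expect_identical(nchar(g0), 10000L)
  expect_true(grepl("^[AT]+$", g0))

  g <- generate_genome(100000, 0.5, seed = 4)
  gc <- lengths(regmatches(g, gregexpr("[GC]", g))) / nchar(g)
  # binomial bound: 3 sd of a Binomial(L, 0.5) proportion
  expect_lt(abs(gc - 0.5), 3 * sqrt(0.25 / 100000))

  expect_identical(generate_genome(500, 0.4, seed = 11),
                   generate_genome(500, 0.4, seed = 11))
  expect_error(generate_genome(0, 0.5, 1), "integer")
  expect_error(generate_genome(100, 1.5, 1), "\\[0, 1\\]")
})

test_that("plant_sites instantiates IUPAC patterns in place", {
  g <- generate_genome(2000, 0.5, seed = 5)
  tr <- plant_sites(g, list(list(site_id = "a", pattern = "WATCARnnnnTTR",
                                 position = 700, occupancy = c(x = 1))),
                    seed = 6)
  inserted <- substr(tr$genome, 701, 713)
  expect_identical(inserted, tr$sites$motif[1])
  expect_identical(oracle_iupac_scan(inserted, "WATCARnnnnTTR"), 0L)
  # genome unchanged elsewhere
  expect_identical(substr(tr$genome, 1, 700), substr(g, 1, 700))
  expect_identical(substr(tr$genome, 714, 2000), substr(g, 714, 2000))

  # no degenerate codes: planted sequence is the pattern itself
  tr2 <- plant_sites(g, list(list(pattern = "ACGT", position = 10,
                                  occupancy = c(x = 0.5))), seed = 1)
  expect_identical(substr(tr2$genome, 11, 14), "ACGT")

  # empty site list: identity
  tr3 <- plant_sites(g, list(), seed = 1)
  expect_identical(tr3$genome, g)

  expect_error(plant_sites(g, list(list(pattern = "AXT", position = 0,
                                        occupancy = c(x = 1))), 1),
               "illegal IUPAC")
  expect_error(plant_sites(g, list(
    list(pattern = "ACGTACGT", position = 100, occupancy = c(x = 1)),
    list(pattern = "ACGTACGT", position = 103, occupancy = c(x = 1))), 1),
    "overlapping")
})

test_that("simulate_fragments respects occupancy, containment and length law", {
  inst <- make_planted_instance(seed = 21, occupancy = 0, depth_n = 500)
  expect_identical(nrow(inst$fragments), 0L)

  inst <- make_planted_instance(seed = 22, occupancy = 1, depth_n = 500)
  fr <- inst$fragments
  expect_identical(nrow(fr), 500L)
  mstart <- inst$truth$sites$position[1]
  mend <- mstart + inst$truth$sites$width[1]
  expect_true(all(fr$start <= mstart & fr$end >= mend))
  expect_true(all(fr$end - fr$start >= 70 & fr$end - fr$start <= 110))

  expect_error(simulate_fragments(inst$truth, "nope", 0, 10), "unknown condition")
})

test_that("fragment lengths are uniform on 70..110", {
  g <- generate_genome(50000, 0.5, seed = 30)
  tr <- plant_sites(g, list(), seed = 1)
  fr <- simulate_fragments(tr, "any", n_background = 12000,
                           enrichment_depth = 0, seed = 31)
  len <- fr$end - fr$start
  p <- stats::chisq.test(table(factor(len, levels = 70:110)))$p.value
  expect_gt(p, 0.001)
})

test_that("fragments_to_reads pads short fragments with adapter", {
  adapter <- "AGATCGGAAGAGCACACGTCTGAACTCCAGTCA"
  g <- generate_genome(1000, 0.5, seed = 40)
  fr <- data.frame(chrom = "chr", start = c(100L, 300L), end = c(180L, 410L))
  rd <- fragments_to_reads(fr, g, read_length = 100, adapter_seq = adapter)

  # 80 bp fragment: 80 genomic + first 20 adapter bases
  frag1 <- substr(g, 101, 180)
  expect_identical(as.character(rd$r1[[1]]),
                   paste0(frag1, substr(adapter, 1, 20)))
  expect_identical(as.character(rd$r2[[1]]),
                   paste0(revcomp(frag1), substr(adapter, 1, 20)))

  # 110 bp fragment: pure genomic prefixes, no adapter
  frag2 <- substr(g, 301, 410)
  expect_identical(as.character(rd$r1[[2]]), substr(frag2, 1, 100))
  # read 2 genomic portion is the reverse complement of the fragment's
  # last read-covered bases
  expect_identical(as.character(rd$r2[[2]]),
                   revcomp(substr(frag2, 11, 110)))
  expect_identical(names(rd$r1), names(rd$r2))
})

test_that("a simulated library is byte-identical across runs of one seed", {
  cfg <- sim_config(genome_length = 5000L, background_fragments = 200L,
                    enrichment_depth = 50L, seed = 9L)
  build <- function(dir) {
    g <- generate_genome(cfg$genome_length, cfg$gc_fraction, seed = cfg$seed)
    tr <- plant_sites(g, list(list(pattern = "WATCARnnnnTTR", position = 2500,
                                   occupancy = c(c1 = 0.8))),
                      seed = cfg$seed + 1L)
    fr <- simulate_fragments(tr, "c1", cfg$background_fragments,
                             cfg$enrichment_depth, seed = cfg$seed + 2L)
    write_simulation(tr, fr, "c1", cfg, dir)
  }
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- build(d1); p2 <- build(d2)
  for (k in names(p1))
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]), label = k)
})
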