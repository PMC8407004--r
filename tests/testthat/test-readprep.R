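adapter <- "AGATCGGAAGAGCACACGTCTGAACTCCAGTCA"

test_that("trim_adapter finds the genomic/adapter boundary", {
  set.seed(101)
  genomic <- random_dna(80)
  read <- paste0(genomic, substr(adapter, 1, 20))
  tr <- trim_adapter(read, adapter)
  expect_s3_class(tr, "trim_result")
  expect_identical(tr$boundary, 80L)
  expect_identical(tr$kept_prefix, genomic)
  expect_true(tr$adapter_found)

  # no adapter: boundary = read length (choose a read whose tail cannot
  # alias the adapter head)
  clean <- gsub("A", "C", random_dna(50))
  tr2 <- trim_adapter(clean, adapter)
  expect_identical(tr2$boundary, nchar(clean))
  expect_false(tr2$adapter_found)

  # read that IS an adapter prefix: boundary 0, empty kept prefix
  tr3 <- trim_adapter(substr(adapter, 1, 30), adapter)
  expect_identical(tr3$boundary, 0L)
  expect_identical(tr3$kept_prefix, "")

  # short read-end overlap is trimmed when exact
  read4 <- paste0(gsub("A", "G", random_dna(98)), substr(adapter, 1, 2))
  expect_identical(trim_adapter(read4, adapter)$boundary, 98L)

  expect_error(trim_adapter("", adapter), "empty read")
  expect_error(trim_adapter("ACGT", ""), "empty adapter")
})

test_that("trim_adapter tolerates mismatches at long overlaps only", {
  genomic <- gsub("A", "T", random_dna(70))
  adp <- substr(adapter, 1, 30)
  mutated <- paste0(substr(adp, 1, 10), "A", substr(adp, 12, 30))  # 1 mm / 30
  expect_identical(trim_adapter(paste0(genomic, mutated), adapter)$boundary, 70L)
  # 5 bp overlap with a mismatch is not accepted
  tail5 <- paste0(substr(adapter, 1, 4), if (substr(adapter, 5, 5) == "C") "G" else "C")
  expect_identical(trim_adapter(paste0(genomic, tail5), adapter)$boundary, 75L)
})

test_that("trim_reads agrees with trim_adapter read by read", {
  set.seed(102)
  reads <- vapply(1:300, function(i) {
    b <- sample(0:100, 1)
    paste0(random_dna(b), substr(paste0(adapter, random_dna(100)), 1, 100 - b))
  }, character(1))
  batch <- trim_reads(reads, adapter)
  single <- vapply(reads, function(r) trim_adapter(r, adapter)$boundary,
                   integer(1), USE.NAMES = FALSE)
  expect_identical(batch$boundary, single)
  expect_identical(batch$adapter_found, single < nchar(reads))
})

test_that("trimming is idempotent when the kept prefix has no adapter-like tail", {
  set.seed(103)
  for (i in 1:50) {
    genomic <- random_dna(85)
    first <- trim_adapter(paste0(genomic, substr(adapter, 1, 15)), adapter)
    again <- trim_adapter(first$kept_prefix, adapter)
    if (!again$adapter_found)  # kept prefix may coincidentally end adapter-like
      expect_identical(again$kept_prefix, first$kept_prefix)
  }
})

test_that("map_read_pair recovers the fragment and enforces its contracts", {
  set.seed(104)
  g <- random_dna(20000)
  idx <- genome_index(g)
  s <- 5000L; e <- 5090L
  frag <- substr(g, s + 1, e)
  res <- map_read_pair(frag, revcomp(frag), idx)
  expect_identical(res$status, "mapped")
  expect_identical(res$fragment$start, s)
  expect_identical(res$fragment$end, e)
  # perfect-match contract: the fragment sequence equals the reference
  expect_identical(substr(g, res$fragment$start + 1, res$fragment$end), frag)

  # mates mapping with r2 upstream of r1 are discordant
  r1 <- substr(g, 6001, 6080)
  r2 <- revcomp(substr(g, 1001, 1080))
  expect_identical(map_read_pair(r1, r2, idx)$status, "unmapped")

  # repeated placement is ambiguous
  g2 <- paste0(frag, random_dna(500), frag)
  idx2 <- genome_index(g2)
  expect_identical(map_read_pair(frag, revcomp(frag), idx2)$status, "ambiguous")
})

test_that("trim+map round-trip recovers >= 99% of truth intervals exactly", {
  inst <- make_planted_instance(seed = 50, genome_length = 30000L,
                                occupancy = 0.8, depth_n = 200L,
                                n_background = 3000L)
  fr <- inst$fragments
  rd <- fragments_to_reads(fr, inst$truth$genome, 100, adapter)
  t1 <- trim_reads(rd$r1, adapter)
  t2 <- trim_reads(rd$r2, adapter)
  idx <- genome_index(inst$truth$genome)
  mp <- map_read_pairs(substr(as.character(rd$r1), 1, t1$boundary),
                       substr(as.character(rd$r2), 1, t2$boundary),
                       idx, max_len = 150)
  got <- mp$fragments
  exact <- sum(got$start == fr$start[got$pair] & got$end == fr$end[got$pair])
  expect_gte(exact / nrow(fr), 0.99)
  # batch mapper agrees with the per-pair mapper on a sample
  take <- seq(1, nrow(fr), by = 200)
  for (i in take) {
    one <- map_read_pair(substr(as.character(rd$r1[[i]]), 1, t1$boundary[i]),
                         substr(as.character(rd$r2[[i]]), 1, t2$boundary[i]),
                         idx, max_len = 150)
    expect_identical(one$status, as.character(mp$status[i]))
  }
})

test_that("load_fragments parses BED and BEDPE and rejects bad rows by line", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr\t100\t180\t.\t0\t+", "chr\t500\t610\t.\t0\t-"), bed)
  fr <- load_fragments(bed)
  expect_identical(fr$start, c(100L, 500L))
  expect_identical(fr$end - fr$start, c(80L, 110L))

  pe <- withr::local_tempfile(fileext = ".bedpe")
  writeLines("chr\t100\t150\tchr\t160\t200\tpair1\t0\t+\t-", pe)
  fr2 <- load_fragments(pe)
  expect_identical(fr2$start, 100L)
  expect_identical(fr2$end, 200L)

  bad <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr\t100\t180", "chr\t200\t200"), bad)
  expect_error(load_fragments(bad), "line 2")
})
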