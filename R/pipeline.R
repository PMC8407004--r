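# Pipeline driver: simulate -> trim -> map -> call -> compare -> scan,
# with per-stage count reconciliation and deterministic outputs under a
# fixed seed.

# the standard synthetic cell-cycle site layout: one origin-like site
# (high occupancy only before initiation), one transient site (high
# occupancy only 10 min after initiation), ten constitutive sites
demo_site_specs <- function(genome_length = 100000L) {
  gap <- genome_length %/% 14L
  const_pos <- gap * c(1:3, 5:8, 10:12)
  specs <- lapply(seq_along(const_pos), function(k)
    list(site_id = sprintf("const%02d", k), pattern = "WATCARnnnnTTR",
         position = const_pos[k], strand = "+",
         occupancy = c("0min" = 0.6, "10min" = 0.6, "20min" = 0.6,
                       "random" = 0.6)))
  c(specs,
    list(list(site_id = "oriC_like", pattern = "WATCARnnnnTTR",
              position = gap * 4L, strand = "+",
              occupancy = c("0min" = 0.9, "10min" = 0.05, "20min" = 0.05,
                            "random" = 0.2)),
         list(site_id = "ttcA_like", pattern = "TAAnnnnTTGATW",
              position = gap * 9L, strand = "+",
              occupancy = c("0min" = 0.05, "10min" = 0.8, "20min" = 0.05,
                            "random" = 0.2))))
}

#' Simulate and analyse the standard synthetic cell-cycle experiment
#'
#' Builds the default four-condition experiment (see
#' [default_pipeline_config()]), simulates fragments per condition
#' directly (no read step), calls components per condition with
#' library-size-scaled thresholds, and assembles the occupancy and
#' specificity tables.
#'
#' @param seed Integer seed controlling every random draw.
#' @param config A `pipeline_config`.
#' @return A list: `truth`, `fragments` (per condition), `components`
#'   (per condition), `thresholds`, `occupancy` (specificity-labelled
#'   `occupancy_table`).
#' @export
cell_cycle_experiment <- function(seed, config = pipeline_config(seed = seed)) {
  stopifnot(inherits(config, "pipeline_config"))
  genome <- generate_genome(config$genome_length, config$gc_fraction,
                            seed = seed)
  truth <- plant_sites(genome, demo_site_specs(config$genome_length),
                       seed = seed + 1L)
  ccfg <- caller_config(ewf = config$ewf, ewt = config$ewt,
                        base_threshold = config$base_threshold,
                        end_support_min = config$end_support_min)
  fragments <- components <- list()
  for (i in seq_along(config$conditions)) {
    cd <- config$conditions[i]
    fragments[[cd]] <- simulate_fragments(
      truth, cd, config$background_fragments, config$enrichment_depth,
      seed = seed + 100L * i,
      len_min = config$protected_len_min, len_max = config$protected_len_max)
  }
  totals <- vapply(fragments, nrow, integer(1))
  ref_mapped <- totals[[config$ref_condition]]
  thresholds <- vapply(config$conditions, function(cd)
    scale_threshold(config$base_threshold, ref_mapped, totals[[cd]]),
    integer(1))
  for (cd in config$conditions) {
    prof <- compute_profiles(fragments[[cd]][c("chrom", "start", "end")],
                             config$genome_length)
    components[[cd]] <- call_components(prof, thresholds[[cd]], ccfg,
                                        fragments = fragments[[cd]])
  }
  occ <- occupancy_table(components, lapply(fragments,
                                            function(f) f[c("chrom", "start", "end")]),
                         config$genome_length, ccfg,
                         ref_condition = config$ref_condition)
  if (all(c("0min", "10min", "20min", "random") %in% config$conditions))
    occ <- specificity_table(occ)
  list(truth = truth, fragments = fragments, components = components,
       thresholds = thresholds, occupancy = occ)
}

#' Run the full pipeline to an output directory
#'
#' End-to-end driver: per condition, simulate fragments and
#' adapter-padded paired reads, trim the reads, place the pairs back on
#' the reference, call components on the recovered fragments with a
#' library-size-scaled threshold, then build the cross-condition
#' occupancy/specificity tables and scan called regions for the
#' configured consensus.  All randomness derives from `config$seed`;
#' rerunning with the same config gives byte-identical outputs.
#'
#' @param config A `pipeline_config`; `seed` must be set.
#' @param out_dir Output directory.
#' @return Invisibly, a list with the run log, occupancy table and
#'   output paths.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.na(config$seed))
    stop("config error: `seed` is required for a pipeline run", call. = FALSE)
  seed <- as.integer(config$seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  genome <- generate_genome(config$genome_length, config$gc_fraction,
                            seed = seed)
  truth <- plant_sites(genome, demo_site_specs(config$genome_length),
                       seed = seed + 1L)
  idx <- genome_index(truth$genome)
  ccfg <- caller_config(ewf = config$ewf, ewt = config$ewt,
                        base_threshold = config$base_threshold,
                        end_support_min = config$end_support_min)
  log <- list()
  fragments <- components <- list()

  for (i in seq_along(config$conditions)) {
    cd <- config$conditions[i]
    cdir <- file.path(out_dir, cd)
    dir.create(cdir, showWarnings = FALSE)
    truth_frags <- simulate_fragments(
      truth, cd, config$background_fragments, config$enrichment_depth,
      seed = seed + 100L * i,
      len_min = config$protected_len_min, len_max = config$protected_len_max)
    scfg <- sim_config(genome_length = config$genome_length,
                       gc_fraction = config$gc_fraction,
                       read_length = config$read_length,
                       adapter_seq = config$adapter_seq,
                       protected_len_min = config$protected_len_min,
                       protected_len_max = config$protected_len_max,
                       background_fragments = config$background_fragments,
                       enrichment_depth = config$enrichment_depth,
                       seed = seed)
    write_simulation(truth, truth_frags, cd, scfg, cdir)

    reads <- fragments_to_reads(truth_frags, truth$genome,
                                config$read_length, config$adapter_seq)
    t1 <- trim_reads(reads$r1, config$adapter_seq, config$min_overlap,
                     config$max_mismatch_rate)
    t2 <- trim_reads(reads$r2, config$adapter_seq, config$min_overlap,
                     config$max_mismatch_rate)
    mapped <- map_read_pairs(substr(as.character(reads$r1), 1L, t1$boundary),
                             substr(as.character(reads$r2), 1L, t2$boundary),
                             idx, max_len = config$ewt + 40L)
    frags <- mapped$fragments[c("chrom", "start", "end")]
    st <- table(mapped$status)
    if (sum(st) != nrow(truth_frags))
      stop("stage `map` (", cd, "): pair counts do not reconcile",
           call. = FALSE)
    write_bed(frags, file.path(cdir, "fragments.bed"))
    fragments[[cd]] <- frags
    log[[cd]] <- data.frame(condition = cd, pairs_in = nrow(truth_frags),
                            mapped = as.integer(st[["mapped"]]),
                            ambiguous = as.integer(st[["ambiguous"]]),
                            unmapped = as.integer(st[["unmapped"]]))
  }

  totals <- vapply(fragments, nrow, integer(1))
  ref_mapped <- totals[[config$ref_condition]]
  for (cd in config$conditions) {
    cdir <- file.path(out_dir, cd)
    thr <- scale_threshold(config$base_threshold, ref_mapped, totals[[cd]])
    prof <- compute_profiles(fragments[[cd]], config$genome_length)
    comp <- call_components(prof, thr, ccfg, fragments = fragments[[cd]])
    mp <- merge_peaks(comp)
    components[[cd]] <- mp$components
    export_components(mp$components, mp$peaks, cdir)
    write_bedgraph(prof$depth, file.path(cdir, "depth.bedgraph"))
    write_bedgraph(prof$left_ends, file.path(cdir, "ends_left.bedgraph"))
    write_bedgraph(prof$right_ends, file.path(cdir, "ends_right.bedgraph"))
    log[[cd]]$threshold <- thr
    log[[cd]]$components <- nrow(comp)
  }

  occ <- occupancy_table(components, fragments, config$genome_length, ccfg,
                         ref_condition = config$ref_condition)
  if (all(c("0min", "10min", "20min", "random") %in% config$conditions))
    occ <- specificity_table(occ)
  occ_out <- as.data.frame(occ)
  if (nrow(occ_out))
    occ_out$genomic_positions <- format_position(occ_out$start, occ_out$end)
  write.table(occ_out, file.path(out_dir, "occupancy.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(occ_out$specificity))
    write.table(occ_out[, c("chrom", "start", "end", "specificity")],
                file.path(out_dir, "specificity.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)

  # consensus scan over union regions in the reference condition
  scan <- if (nrow(occ))
    consensus_fraction(occ, truth$genome, config$scan_pattern)
  else list(n_with_match = 0L, n_total = 0L, fraction = NA_real_)
  writeLines(sprintf("pattern\t%s\nn_with_match\t%d\nn_total\t%d\nfraction\t%g",
                     config$scan_pattern, scan$n_with_match, scan$n_total,
                     scan$fraction),
             file.path(out_dir, "consensus_scan.tsv"))
  export_region_fasta(occ, truth$genome, file.path(out_dir, "regions.fasta"))

  runlog <- do.call(rbind, log)
  rownames(runlog) <- NULL
  write.table(runlog, file.path(out_dir, "runlog.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_pipeline_config(config, file.path(out_dir, "config_echo.yaml"))
  invisible(list(log = runlog, occupancy = occ, truth = truth,
                 dir = out_dir))
}
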