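#' Run the full synthetic-mode analysis pipeline
#'
#' Executes every stage in order on simulated data with known truth:
#' simulate triplet sequences -> build triplets from pairwise alignment
#' statistics and call diagnostic sites -> simulate counts and paired
#' reads -> classify reads at diagnostic sites and allocate counts ->
#' classify control balance (ECT/UCT) -> partition stress responses and
#' categorize triplets -> extract trend signatures, scan motif-planted
#' promoters and predict TF targets. Writes every intermediate table as
#' TSV under `config$out_dir` (each file headed by the configuration
#' hash and seed) plus a plain-text summary report, and returns the
#' in-memory results invisibly. Rerunning with the same configuration
#' reproduces every output byte for byte.
#'
#' @param config a [pipeline_config()].
#' @param write_fastq also write the simulated reads as FASTQ (off by
#'   default; the classification consumes in-memory placements).
#' @return invisible list with all stage outputs and `summary`.
#' @export
run_pipeline <- function(config = pipeline_config(), write_fastq = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  sim_cfg <- config$sim
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  hdr <- c(paste0("config_hash: ", hash),
           paste0("rng_seed: ", sim_cfg$rng_seed))
  out_path <- function(f) file.path(config$out_dir, f)

  ## stage 1: sequences
  sim <- simulate_triplets(sim_cfg)
  write_fasta(sim$sequences, out_path("triplet_sequences.fasta"))
  write_tsv(sim$sites, out_path("truth_diagnostic_sites.tsv"), hdr)

  ## stage 2: triplet building from pairwise alignment evidence
  al <- pairwise_stats_from_families(sim)
  built <- cluster_triplets(al, sim$genes, config$evalue_max,
                            config$coverage_min, config$identity_min)
  trip <- built$triplets
  trip$triplet_id <- sub("_A$", "", trip$gene_A)
  write_tsv(trip, out_path("triplets.tsv"), hdr)
  write_tsv(built$rejections, out_path("triplet_rejections.tsv"), hdr)
  sites <- rbindlist(lapply(trip$triplet_id, function(id) {
    call_diagnostic_sites(setNames(
      sim$sequences[paste0(id, "_", SUBGENOMES)], SUBGENOMES), id)
  }))
  write_tsv(sites, out_path("diagnostic_sites.tsv"), hdr)

  ## stage 3: counts and reads
  cs <- simulate_counts(sim, sim_cfg)
  write_tsv(cs$counts, out_path("true_counts.tsv"), hdr)
  write_tsv(cs$truth, out_path("truth_triplets.tsv"), hdr)
  rs <- simulate_reads(sim, cs, sim_cfg)
  if (write_fastq) write_fastq(rs, out_path("reads"))

  ## stage 4: read classification and allocation
  obs <- read_site_observations(rs, sites, sim_cfg$read_length)
  asn <- classify_reads(rs$reads[, .(read_id, triplet_id, sample)], obs)
  ct <- homeolog_count_table(asn)
  grp_tab <- asn[, .N, by = group][order(match(group, GROUP_LEVELS))]
  write_tsv(ct$wide, out_path("homeolog_counts.tsv"), hdr)
  write_tsv(grp_tab, out_path("read_groups.tsv"), hdr)

  ## stage 5: control balance classification
  ctrl_samples <- paste0(sim_cfg$control, "_r", seq_len(sim_cfg$n_reps))
  bal <- balance_calls(ct$long, ctrl_samples, config$balance_p,
                       config$balance_ratio, method = config$balance_method)
  bal_sum <- summarize_balance(bal)
  write_tsv(bal, out_path("balance_calls.tsv"), hdr)

  ## stage 6: stress-response partitioning
  long <- copy(ct$long)
  long[, condition := sub("_r[0-9]+$", "", sample)]
  prof <- response_profiles(long, control = sim_cfg$control,
                            de_fc = config$de_fc, de_fdr = config$de_fdr,
                            partition_ratio = config$partition_ratio,
                            pseudocount = config$pseudocount)
  part_sum <- summarize_partitioning(bal, prof$triplets)
  cat_tab <- prof$triplets[, .N, by = category][order(-N)]
  write_tsv(prof$genes, out_path("response_genes.tsv"), hdr)
  write_tsv(prof$triplets, out_path("response_triplets.tsv"), hdr)

  ## stage 7: promoters, motif scan, trend matching, target prediction
  mot <- motif_stage(sim, cs, ct$long, config)
  write_tsv(mot$hits, out_path("motif_hits.tsv"), hdr)
  write_tsv(mot$signatures, out_path("trend_signatures.tsv"), hdr)
  write_tsv(mot$overlap$sizes, out_path("target_set_sizes.tsv"), hdr)

  summary <- list(
    config_hash = unname(hash),
    n_triplets_simulated = sim_cfg$n_triplets,
    n_triplets_built = nrow(trip),
    triplets_match_truth = setequal(trip$triplet_id,
                                    unique(sim$genes$triplet_id)),
    n_read_pairs = nrow(rs$reads),
    read_groups = grp_tab,
    balance = bal_sum,
    partitioning = part_sum,
    categories = cat_tab,
    target_sizes = mot$overlap$sizes,
    target_overlaps = mot$overlap$overlaps)
  writeLines(format_report(summary), out_path("report.txt"))
  invisible(c(list(sim = sim, counts = cs, reads = rs, assignments = asn,
                   count_table = ct, balance = bal, profiles = prof,
                   motifs = mot), list(summary = summary)))
}

# Pairwise alignment statistics for every within-family pair of the
# simulated genes (the desk-scale stand-in for an all-vs-all search;
# synthetic homeologs are equal length and ungapped, so the alignment is
# the identity and the e-value is reported as 0).
pairwise_stats_from_families <- function(sim) {
  ids <- unique(sim$genes$triplet_id)
  out <- vector("list", 3L * length(ids))
  k <- 0L
  for (id in ids) {
    g <- paste0(id, "_", SUBGENOMES)
    for (p in list(c(1, 2), c(1, 3), c(2, 3))) {
      k <- k + 1L
      out[[k]] <- compute_alignment_stats(
        sim$sequences[[g[p[1]]]], sim$sequences[[g[p[2]]]],
        query_id = g[p[1]], subject_id = g[p[2]])
    }
  }
  do.call(rbind, out)
}

motif_stage <- function(sim, cs, long, config) {
  sim_cfg <- sim$config
  set.seed(stage_seed(sim_cfg$rng_seed, "pipeline"))
  genes <- copy(sim$genes)
  genes <- merge(genes, cs$truth[, .(triplet_id, response_class)],
                 by = "triplet_id", sort = FALSE)
  plant_hse <- genes$response_class == "hs_hd" &
    runif(nrow(genes)) < sim_cfg$frac_hse
  plant_dre <- genes$response_class == "ds_hd" &
    runif(nrow(genes)) < sim_cfg$frac_dre
  seed0 <- stage_seed(sim_cfg$rng_seed, "promoters")
  sets <- list(
    simulate_promoters(sum(plant_hse), planted = hse_motifs()[1],
                       seed = seed0, gene_ids = genes$gene_id[plant_hse]),
    simulate_promoters(sum(plant_dre), planted = list(dre_motif()),
                       seed = seed0 + 1L,
                       gene_ids = genes$gene_id[plant_dre]),
    simulate_promoters(sum(!plant_hse & !plant_dre), seed = seed0 + 2L,
                       gene_ids = genes$gene_id[!plant_hse & !plant_dre]))
  promoters <- do.call(c, lapply(sets, `[[`, "promoters"))
  promoters <- promoters[genes$gene_id]
  truth <- rbindlist(lapply(sets, `[[`, "truth"))

  hits <- scan_promoters(promoters, c(hse_motifs(), list(dre_motif())),
                         revcomp = config$scan_revcomp)

  expr <- setDT(copy(as.data.frame(long)))
  expr[, condition := sub("_r[0-9]+$", "", sample)]
  expr <- expr[, .(expr = mean(count)), by = .(triplet_id, subgenome,
                                               condition)]
  expr[, gene_id := paste0(triplet_id, "_", subgenome)]
  sig <- expr[, {
    e <- setNames(expr, condition)
    ts <- trend_signature(e, control = sim_cfg$control,
                          lfc_threshold = config$trend_lfc,
                          pseudocount = config$pseudocount)
    list(group = ts$group)
  }, by = gene_id]

  hse_names <- vapply(hse_motifs(), `[[`, character(1), "name")
  targets <- list(
    `DREB-group1` = predict_targets(hits, sig, "DRE", "DS/HD-induced"),
    `HSF-group1` = predict_targets(hits, sig, hse_names, "DS/HD-induced"),
    `DREB-group2` = predict_targets(hits, sig, "DRE", "HS/HD-induced"),
    `HSF-group2` = predict_targets(hits, sig, hse_names, "HS/HD-induced"))
  list(promoters = promoters, planted = truth, hits = hits,
       signatures = sig, targets = targets,
       overlap = target_overlap(targets))
}

# Hash of the analysis configuration (excluding the output location,
# which has no bearing on the results).
config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(cfg, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

format_report <- function(s) {
  fmt_df <- function(df) utils::capture.output(print(as.data.frame(df),
                                                     row.names = FALSE))
  c(sprintf("triadpart pipeline report (config %s)", s$config_hash),
    "",
    sprintf("triplets simulated: %d; built from alignments: %d (truth match: %s)",
            s$n_triplets_simulated, s$n_triplets_built,
            s$triplets_match_truth),
    sprintf("read pairs classified: %d", s$n_read_pairs),
    "", "read groups:", fmt_df(s$read_groups),
    "", "control balance:", fmt_df(s$balance),
    "", "stress partitioning by stratum:", fmt_df(s$partitioning),
    "", "partition categories:", fmt_df(s$categories),
    "", "predicted TF target sets:", fmt_df(s$target_sizes),
    fmt_df(s$target_overlaps))
}
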