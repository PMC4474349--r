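#' Simulation configuration for the synthetic wheat-triad generator
#'
#' Bundles every tunable of the synthetic-data generator into one validated
#' list. Defaults emulate the study design the package targets: hexaploid
#' wheat seedlings under control (CK), drought (DS), heat (HS) and combined
#' (HD) stress sampled at 1 h and 6 h, two replicates each, sequenced as
#' 100 bp paired-end reads with ~200 bp inserts.
#'
#' @param n_triplets number of homeologous triplets to simulate.
#' @param gene_length length of each homeolog sequence (bp).
#' @param divergence_rate per-base probability that a given PAIR of
#'   subgenome copies differs at a site. Copies are derived from a shared
#'   ancestral sequence; the per-copy branch rate is solved so the pairwise
#'   expectation equals this value.
#' @param read_length read length in bp.
#' @param insert_size mean insert (fragment) size in bp.
#' @param insert_sd standard deviation of the insert size.
#' @param seq_error_rate per-base sequencing substitution error probability.
#' @param conditions ordered condition labels; must contain `control`.
#' @param control the control condition label.
#' @param n_reps replicates per condition.
#' @param depth_mean mean read-pair depth per homeolog per sample at
#'   baseline expression.
#' @param frac_uct fraction of triplets planted with unequal homeolog
#'   contribution (one copy's mean raised `uct_ratio`-fold).
#' @param uct_ratio generating max/min expression ratio for planted
#'   unequal-contribution triplets (must be >= 1.5 to satisfy the
#'   downstream ratio gate).
#' @param frac_partitioned fraction of triplets planted with a
#'   homeolog-partitioned stress response.
#' @param stress_fc shared stress fold change applied to every homeolog of
#'   a responsive triplet in its responsive conditions (>= 2 so the
#'   differential-expression gate is attainable).
#' @param response_mix named fractions partitioning triplets by which
#'   stress conditions they respond to: `none` (flat), `all` (every stress
#'   condition), `ds_hd` (drought and combined only), `hs_hd` (heat and
#'   combined only). Must sum to 1. The latter two emulate the
#'   drought/combined- and heat/combined-induced expression-trend groups.
#' @param partition_ratio extra fold change given to the divergent homeolog
#'   of a partitioned triplet, i.e. the planted fold-change ratio between
#'   homeologs (>= 2).
#' @param count_dist `"poisson"` (default) or `"nbinom"` for overdispersed
#'   counts with dispersion `1/nb_size`.
#' @param nb_size negative-binomial size parameter when
#'   `count_dist = "nbinom"`.
#' @param lib_factors optional per-sample library-size factors (recycled);
#'   default all 1.
#' @param frac_hse,frac_dre fractions of simulated promoters planted with
#'   an HSE / DRE motif instance.
#' @param rng_seed integer master seed; all stage seeds derive from it.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_triplets = 100,
                       gene_length = 1500,
                       divergence_rate = 0.02,
                       read_length = 100,
                       insert_size = 200,
                       insert_sd = 10,
                       seq_error_rate = 0.001,
                       conditions = c("CK", "DS-1h", "DS-6h", "HS-1h",
                                      "HS-6h", "HD-1h", "HD-6h"),
                       control = "CK",
                       n_reps = 2,
                       depth_mean = 300,
                       frac_uct = 0.5,
                       uct_ratio = 2,
                       frac_partitioned = 0.3,
                       stress_fc = 2,
                       response_mix = c(none = 0.25, all = 0.25,
                                        ds_hd = 0.25, hs_hd = 0.25),
                       partition_ratio = 4,
                       count_dist = c("poisson", "nbinom"),
                       nb_size = 20,
                       lib_factors = NULL,
                       frac_hse = 0.3,
                       frac_dre = 0.3,
                       rng_seed = 1L) {
  count_dist <- match.arg(count_dist)
  cfg <- list(n_triplets = as.integer(n_triplets),
              gene_length = as.integer(gene_length),
              divergence_rate = divergence_rate,
              read_length = as.integer(read_length),
              insert_size = as.integer(insert_size),
              insert_sd = insert_sd,
              seq_error_rate = seq_error_rate,
              conditions = conditions,
              control = control,
              n_reps = as.integer(n_reps),
              depth_mean = depth_mean,
              frac_uct = frac_uct,
              uct_ratio = uct_ratio,
              frac_partitioned = frac_partitioned,
              stress_fc = stress_fc,
              response_mix = response_mix,
              partition_ratio = partition_ratio,
              count_dist = count_dist,
              nb_size = nb_size,
              lib_factors = lib_factors,
              frac_hse = frac_hse,
              frac_dre = frac_dre,
              rng_seed = as.integer(rng_seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_triplets >= 0,
            cfg$gene_length > cfg$read_length,
            cfg$read_length > 0,
            cfg$n_reps >= 1,
            cfg$depth_mean > 0,
            cfg$uct_ratio >= 1.5,
            cfg$partition_ratio >= 2,
            cfg$stress_fc > 0,
            is.finite(cfg$rng_seed))
  rates <- c(cfg$divergence_rate, cfg$seq_error_rate,
             cfg$frac_uct, cfg$frac_partitioned, cfg$frac_hse, cfg$frac_dre)
  if (any(rates < 0 | rates > 1))
    stop("all rates and fractions must lie in [0, 1]")
  if (!setequal(names(cfg$response_mix), c("none", "all", "ds_hd", "hs_hd")) ||
      abs(sum(cfg$response_mix) - 1) > 1e-8 || any(cfg$response_mix < 0))
    stop("response_mix must be non-negative fractions named ",
         "none/all/ds_hd/hs_hd summing to 1")
  if (!cfg$control %in% cfg$conditions)
    stop("design must contain the control condition '", cfg$control, "'")
  if (cfg$insert_size < cfg$read_length)
    stop("insert_size must be >= read_length")
  invisible(cfg)
}

#' Pipeline configuration: every analysis threshold in one place
#'
#' Thresholds default to the operative values of the analysis: pairwise
#' alignment filters (e-value 1e-10, coverage 75 %, identity 90 %), the
#' unequal-contribution gates (exact-test p < 0.01, Exp_max/Exp_min >= 1.5),
#' the differential-expression gates (fold change >= 2, BH-FDR adjusted
#' p < 0.01), the homeolog partition gate (fold-change ratio >= 2), and the
#' trend threshold (|log2FC| >= 1).
#'
#' @param sim a [sim_config()] used when the pipeline runs in synthetic mode.
#' @param evalue_max,coverage_min,identity_min pairwise alignment filters.
#' @param balance_p,balance_ratio unequal-contribution gates.
#' @param balance_method exact-test construction, see [pairwise_bias_test()].
#' @param de_fc,de_fdr differential-expression gates (linear fold change and
#'   BH-adjusted p).
#' @param partition_ratio fold-change-ratio threshold calling a homeolog
#'   pair's responses partitioned.
#' @param trend_lfc |log2FC| threshold for the ternary up/flat/down trend.
#' @param pseudocount added to pooled counts before fold changes.
#' @param scan_revcomp also scan the reverse complement of the DRE motif.
#' @param out_dir where [run_pipeline()] writes its tables.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(n_triplets = 40,
                                             depth_mean = 100),
                            evalue_max = 1e-10,
                            coverage_min = 75,
                            identity_min = 90,
                            balance_p = 0.01,
                            balance_ratio = 1.5,
                            balance_method = c("binomial", "fisher2x2"),
                            de_fc = 2,
                            de_fdr = 0.01,
                            partition_ratio = 2,
                            trend_lfc = 1,
                            pseudocount = 0.5,
                            scan_revcomp = FALSE,
                            out_dir = "results") {
  balance_method <- match.arg(balance_method)
  stopifnot(evalue_max >= 0, coverage_min >= 0, coverage_min <= 100,
            identity_min >= 0, identity_min <= 100,
            balance_p > 0, balance_p <= 1, balance_ratio >= 1,
            de_fc >= 1, de_fdr > 0, de_fdr <= 1,
            partition_ratio >= 1, trend_lfc >= 0, pseudocount > 0)
  cfg <- list(sim = sim, evalue_max = evalue_max, coverage_min = coverage_min,
              identity_min = identity_min, balance_p = balance_p,
              balance_ratio = balance_ratio, balance_method = balance_method,
              de_fc = de_fc, de_fdr = de_fdr,
              partition_ratio = partition_ratio, trend_lfc = trend_lfc,
              pseudocount = pseudocount, scan_revcomp = scan_revcomp,
              out_dir = out_dir)
  class(cfg) <- "pipeline_config"
  cfg
}

# Deterministic per-stage seed derived from the master seed. Keeps every
# stage's stream independent of how many draws earlier stages consumed.
stage_seed <- function(seed, stage) {
  offs <- c(triplets = 11L, counts = 23L, reads = 37L, promoters = 53L,
            pipeline = 71L, acceptance = 89L)
  if (!stage %in% names(offs)) stop("unknown stage: ", stage)
  as.integer((as.double(seed) * 7919 + offs[[stage]]) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
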