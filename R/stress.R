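#' Counts-per-million normalization
#'
#' @param counts numeric vector/matrix of raw counts.
#' @param lib_sizes library size per sample (recycled over columns for a
#'   matrix); must be positive.
#' @return counts / lib_size * 1e6, same shape as the input.
#' @export
normalize_counts <- function(counts, lib_sizes) {
  if (any(lib_sizes <= 0)) stop("library sizes must be positive")
  if (is.matrix(counts)) {
    if (length(lib_sizes) == 1L) lib_sizes <- rep(lib_sizes, ncol(counts))
    sweep(counts, 2, lib_sizes, "/") * 1e6
  } else {
    counts / lib_sizes * 1e6
  }
}

#' Exact conditional differential-expression test for pooled counts
#'
#' Pools replicates within each arm and tests the pooled treatment count
#' `t` against `t + c` under the binomial null with success probability
#' `lib_treat / (lib_treat + lib_ctrl)` (the exact conditional
#' Poisson-ratio test), using the two-sided minimum-likelihood
#' construction. The fold change is computed on pseudocounted pooled
#' rates: `FC = ((t + pc)/lib_treat) / ((c + pc)/lib_ctrl)`. The test is
#' deliberately pluggable: any function with this signature can replace
#' it in [response_profiles()] (e.g. an overdispersed test).
#'
#' @param treat,ctrl per-replicate counts for the two arms.
#' @param lib_treat,lib_ctrl per-replicate library sizes (default 1 each).
#' @param pseudocount added to each pooled sum for the fold change.
#' @return list: log2FC, fc (linear), p (NA when both pooled sums are 0,
#'   in which case the gene is skipped).
#' @export
de_test <- function(treat, ctrl, lib_treat = NULL, lib_ctrl = NULL,
                    pseudocount = 0.5) {
  lib_treat <- lib_treat %||% rep(1, length(treat))
  lib_ctrl <- lib_ctrl %||% rep(1, length(ctrl))
  if (length(treat) < 1L || length(ctrl) < 1L)
    stop("each arm needs at least one replicate")
  if (any(c(lib_treat, lib_ctrl) <= 0)) stop("library sizes must be positive")
  t <- sum(treat)
  c <- sum(ctrl)
  lt <- sum(lib_treat)
  lc <- sum(lib_ctrl)
  fc <- ((t + pseudocount) / lt) / ((c + pseudocount) / lc)
  if (t + c == 0)
    return(list(log2FC = NA_real_, fc = NA_real_, p = NA_real_))
  p0 <- lt / (lt + lc)
  p <- exact_binom_p(round(t), round(t + c), p0)
  list(log2FC = log2(fc), fc = fc, p = p)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH false-discovery-rate adjustment with enforced
#' monotonicity, applied within one contrast. Rejects inputs outside
#' `[0, 1]` (NAs are propagated).
#'
#' @param p raw p-values.
#' @return adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Pairwise fold-change ratios and the partitioned flag
#'
#' Compares the stress responses of the three homeologs of one triplet in
#' one condition by the ratios of their (pseudocounted, linear) fold
#' changes. The condition is called partitioned when any pairwise ratio
#' is at least `ratio_cutoff` or at most its reciprocal.
#'
#' @param fc named numeric: linear fold changes of A, B and D.
#' @param ratio_cutoff fold-change-ratio threshold (default 2).
#' @return list: ratios (AB, AD, BD), partitioned (logical).
#' @export
response_partition <- function(fc, ratio_cutoff = 2) {
  stopifnot(all(SUBGENOMES %in% names(fc)), all(is.finite(unlist(fc))),
            all(unlist(fc) > 0))
  r <- c(AB = fc[["A"]] / fc[["B"]], AD = fc[["A"]] / fc[["D"]],
         BD = fc[["B"]] / fc[["D"]])
  list(ratios = r,
       partitioned = any(r >= ratio_cutoff | r <= 1 / ratio_cutoff))
}

#' Assign a partitioned triplet to one of 12 categories
#'
#' The scheme crosses the direction of the dominant deviation (up/down)
#' with the dominant homeolog subset ({A}, {B}, {D}, {A,B}, {A,D},
#' {B,D}): in the flagged condition with the largest maximum pairwise
#' fold-change ratio, the dominant subset is the first subset (singletons
#' first, then pairs, lexicographic) whose members' |log2FC| each exceed
#' every remaining homeolog's |log2FC| by at least 1 (2-fold on the
#' linear scale); the direction is the sign of the subset's mean log2FC.
#' Conditions are ranked by their maximum pairwise ratio with ties broken
#' by condition order. Returns `"NONE"` when no condition is flagged or
#' no subset dominates.
#'
#' @param lfc 3 x n_conditions matrix of log2 fold changes with rownames
#'   A, B, D.
#' @param flagged logical per condition: partitioned flag.
#' @param max_ratio numeric per condition: max of the pairwise ratios and
#'   their reciprocals (used for ranking).
#' @param margin dominance margin on the log2 scale (default 1).
#' @return category string, e.g. `"up-A"` or `"down-BD"`, or `"NONE"`.
#' @export
categorize_triplet <- function(lfc, flagged, max_ratio, margin = 1) {
  lfc <- as.matrix(lfc)
  stopifnot(setequal(rownames(lfc), SUBGENOMES),
            ncol(lfc) == length(flagged), length(flagged) == length(max_ratio))
  lfc <- lfc[SUBGENOMES, , drop = FALSE]
  if (!any(flagged, na.rm = TRUE)) return("NONE")
  cand <- which(flagged)
  best <- cand[which.max(max_ratio[cand])]
  v <- abs(lfc[, best])
  subsets <- list("A", "B", "D", c("A", "B"), c("A", "D"), c("B", "D"))
  for (s in subsets) {
    rest <- setdiff(SUBGENOMES, s)
    if (min(v[s]) >= max(v[rest]) + margin) {
      dir <- if (mean(lfc[s, best]) >= 0) "up" else "down"
      return(paste0(dir, "-", paste(s, collapse = "")))
    }
  }
  "NONE"
}

#' Per-homeolog differential expression and homeolog partitioning
#'
#' For every homeolog gene and stress condition, pools replicates and
#' applies the exact conditional test against the control with
#' per-contrast BH adjustment and the two differential-expression gates
#' (|FC| >= `de_fc`, adjusted p < `de_fdr`). Then, per triplet and
#' condition, computes the pairwise fold-change ratios between homeologs
#' and the partitioned flag, and assigns each triplet flagged in at least
#' one stress condition to one of the 12 partition categories.
#'
#' @param long long count table (triplet_id, subgenome, sample, condition,
#'   count); replicate structure is taken from the sample column.
#' @param control the control condition label.
#' @param lib_sizes named per-sample library sizes (default: per-sample
#'   totals of `long`).
#' @param de_fc,de_fdr differential-expression gates.
#' @param partition_ratio fold-change-ratio threshold.
#' @param pseudocount pseudocount for fold changes.
#' @param test a function with the signature of [de_test()].
#' @return list: `genes` (per homeolog x condition: log2FC, fc, p, padj,
#'   de), `conditions` (per triplet x condition: ratios, partitioned),
#'   `triplets` (per triplet: partitioned_any, any_homeolog_de, category).
#' @export
response_profiles <- function(long, control = "CK", lib_sizes = NULL,
                              de_fc = 2, de_fdr = 0.01,
                              partition_ratio = 2, pseudocount = 0.5,
                              test = de_test) {
  long <- setDT(copy(as.data.frame(long)))
  stopifnot(all(c("triplet_id", "subgenome", "sample", "condition",
                  "count") %in% names(long)))
  if (is.null(lib_sizes)) {
    ls <- long[, .(lib = sum(count)), by = sample]
    lib_sizes <- setNames(ls$lib, ls$sample)
    lib_sizes[lib_sizes == 0] <- 1
  }
  long[, lib := lib_sizes[sample]]
  conds <- setdiff(unique(long$condition), control)
  ctrl <- long[condition == control]
  genes <- list()
  for (cd in conds) {
    tr <- long[condition == cd]
    key <- c("triplet_id", "subgenome")
    trw <- tr[, .(t_counts = list(count), t_libs = list(lib)), by = key]
    ctw <- ctrl[, .(c_counts = list(count), c_libs = list(lib)), by = key]
    m <- merge(trw, ctw, by = key)
    res <- mapply(function(tc, tl, cc, cl)
      unlist(test(tc, cc, tl, cl, pseudocount = pseudocount)),
      m$t_counts, m$t_libs, m$c_counts, m$c_libs)
    g <- m[, .(triplet_id, subgenome)]
    g[, `:=`(condition = cd, log2FC = res["log2FC", ], fc = res["fc", ],
             p = res["p", ])]
    g[, padj := bh_adjust(p)]
    g[, de := !is.na(padj) & (fc >= de_fc | fc <= 1 / de_fc) & padj < de_fdr]
    genes[[cd]] <- g
  }
  genes <- rbindlist(genes)
  setorder(genes, triplet_id, condition, subgenome)

  per_cond <- genes[, {
    fcv <- setNames(fc, subgenome)
    if (anyNA(fcv) || length(fcv) != 3L) {
      list(ratio_AB = NA_real_, ratio_AD = NA_real_, ratio_BD = NA_real_,
           max_ratio = NA_real_, partitioned = NA)
    } else {
      rp <- response_partition(fcv, partition_ratio)
      r <- rp$ratios
      list(ratio_AB = r[["AB"]], ratio_AD = r[["AD"]], ratio_BD = r[["BD"]],
           max_ratio = max(r, 1 / r), partitioned = rp$partitioned)
    }
  }, by = .(triplet_id, condition)]

  triplets <- lapply(split(genes, by = "triplet_id"), function(g) {
    pc <- per_cond[triplet_id == g$triplet_id[1]]
    pc <- pc[match(conds, condition)]
    lfc <- dcast(g, subgenome ~ condition, value.var = "log2FC")
    m <- as.matrix(lfc[, conds, with = FALSE])
    rownames(m) <- lfc$subgenome
    flg <- pc$partitioned
    flg[is.na(flg)] <- FALSE
    cat <- categorize_triplet(m, flg, ifelse(is.na(pc$max_ratio), 0,
                                             pc$max_ratio))
    data.table(triplet_id = g$triplet_id[1],
               partitioned_any = any(flg),
               any_homeolog_de = any(g$de, na.rm = TRUE),
               category = cat)
  })
  triplets <- rbindlist(triplets)[order(triplet_id)]
  list(genes = genes[], conditions = per_cond[], triplets = triplets)
}

#' Stratified summary of homeolog partitioning
#'
#' Reports, within the ECT and UCT strata and overall, the fraction of
#' triplets whose stress responses are partitioned (any pairwise
#' fold-change ratio beyond threshold in at least one stress condition),
#' with percentages to one decimal.
#'
#' @param balance data.frame with triplet_id and label (ECT/UCT/UNTESTED).
#' @param partition data.frame with triplet_id and partitioned_any (e.g.
#'   `$triplets` from [response_profiles()]).
#' @return data.frame rows ECT, UCT and overall: n, n_partitioned,
#'   percent.
#' @export
summarize_partitioning <- function(balance, partition) {
  b <- as.data.frame(balance)
  p <- as.data.frame(partition)
  m <- merge(b[, c("triplet_id", "label")],
             p[, c("triplet_id", "partitioned_any")], by = "triplet_id")
  m <- m[m$label %in% c("ECT", "UCT"), , drop = FALSE]
  if (!nrow(m))
    return(data.frame(stratum = character(), n = integer(),
                      n_partitioned = integer(), percent = numeric()))
  row_for <- function(sel, name) {
    n <- sum(sel)
    np <- sum(m$partitioned_any[sel])
    data.frame(stratum = name, n = n, n_partitioned = np,
               percent = if (n > 0) round(100 * np / n, 1) else 0)
  }
  rbind(row_for(m$label == "ECT", "ECT"),
        row_for(m$label == "UCT", "UCT"),
        row_for(rep(TRUE, nrow(m)), "overall"))
}
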