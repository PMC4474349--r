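#' Exact two-sided test for unequal expression of two homeologs
#'
#' Tests whether `x` reads from one homeolog against `y` from another
#' deviate from the 1:1 expectation. The default construction conditions
#' on the total `n = x + y` and sums the binomial(n, 1/2) probabilities of
#' every outcome no more likely than the observed one (the minimum-
#' likelihood two-sided exact test; for the symmetric null this equals
#' doubling the smaller tail). An alternative reading of a two-count
#' "Fisher's exact test" — the 2x2 table `[[x, y], [round(n/2),
#' n - round(n/2)]]` — is available via `method = "fisher2x2"`.
#'
#' @param x,y non-negative counts (vectorized; fractional counts are
#'   rounded half-to-even first).
#' @param method `"binomial"` (default) or `"fisher2x2"`.
#' @return p-value(s) in `[0, 1]`; `NA` where `x + y == 0`.
#' @export
pairwise_bias_test <- function(x, y, method = c("binomial", "fisher2x2")) {
  method <- match.arg(method)
  x <- round(x)
  y <- round(y)
  if (any(c(x, y) < 0, na.rm = TRUE)) stop("counts must be non-negative")
  mapply(function(xi, yi) {
    if (is.na(xi) || is.na(yi)) return(NA_real_)
    n <- xi + yi
    if (n == 0) return(NA_real_)
    if (method == "binomial") {
      exact_binom_p(xi, n, 0.5)
    } else {
      half <- round(n / 2)
      stats::fisher.test(matrix(c(xi, yi, half, n - half), nrow = 2,
                                byrow = TRUE))$p.value
    }
  }, x, y)
}

# Two-sided exact binomial p-value: sum of dbinom(k, n, p0) over all k
# whose probability does not exceed that of the observed count (with the
# customary relative tolerance guarding ties against roundoff).
exact_binom_p <- function(x, n, p0) {
  d <- dbinom(0:n, n, p0)
  min(1, sum(d[d <= d[x + 1] * (1 + 1e-7)]))
}

#' Classify one triplet as ECT or UCT from its control counts
#'
#' A triplet is UCT (unequal contribution) iff in every control replicate
#' at least one of the three pairwise comparisons (A vs B, A vs D, B vs D)
#' is significant at `p_cutoff`, AND the ratio of the maximum to the
#' minimum normalized mean expression of the three homeologs is at least
#' `ratio_cutoff`. Otherwise ECT; UNTESTED when the triplet has no control
#' reads at all. Significance is assessed per replicate on rounded
#' allocated counts; the ratio gate uses the mean of the
#' library-size-normalized replicates.
#'
#' @param counts 3 x n_reps matrix of allocated control counts with
#'   rownames A, B, D.
#' @param p_cutoff significance cutoff per pairwise exact test.
#' @param ratio_cutoff Exp_max/Exp_min threshold.
#' @param lib_sizes per-replicate library sizes (default all equal).
#' @param method exact-test construction, see [pairwise_bias_test()].
#' @return list: label ("ECT"/"UCT"/"UNTESTED"), significant (logical:
#'   p-gate passed in every replicate), ratio, p (3 x n_reps matrix of
#'   pairwise p-values), expr (normalized mean per homeolog).
#' @export
classify_balance <- function(counts, p_cutoff = 0.01, ratio_cutoff = 1.5,
                             lib_sizes = NULL,
                             method = c("binomial", "fisher2x2")) {
  method <- match.arg(method)
  counts <- as.matrix(counts)
  if (nrow(counts) != 3L || is.null(rownames(counts)) ||
      !setequal(rownames(counts), SUBGENOMES))
    stop("counts must be a 3 x n_reps matrix with rownames A, B, D")
  if (ncol(counts) < 1L) stop("at least one control replicate is required")
  counts <- counts[SUBGENOMES, , drop = FALSE]
  lib_sizes <- lib_sizes %||% rep(1, ncol(counts))
  if (length(lib_sizes) != ncol(counts) || any(lib_sizes <= 0))
    stop("lib_sizes must be positive, one per replicate")
  pairs <- rbind(c("A", "B"), c("A", "D"), c("B", "D"))
  p <- matrix(NA_real_, nrow = 3, ncol = ncol(counts),
              dimnames = list(c("A_vs_B", "A_vs_D", "B_vs_D"), NULL))
  for (r in seq_len(ncol(counts)))
    for (k in 1:3)
      p[k, r] <- pairwise_bias_test(counts[pairs[k, 1], r],
                                    counts[pairs[k, 2], r], method = method)
  expr <- rowMeans(sweep(counts, 2, lib_sizes, "/") * 1e6)
  if (sum(counts) == 0)
    return(list(label = "UNTESTED", significant = NA, ratio = NA_real_,
                p = p, expr = expr))
  rep_sig <- apply(p, 2, function(col) any(col < p_cutoff, na.rm = TRUE) &&
                     !all(is.na(col)))
  significant <- all(rep_sig)
  ratio <- if (min(expr) > 0) max(expr) / min(expr) else
    if (max(expr) > 0) Inf else NA_real_
  label <- if (significant && !is.na(ratio) && ratio >= ratio_cutoff)
    "UCT" else "ECT"
  list(label = label, significant = significant, ratio = ratio, p = p,
       expr = expr)
}

#' Balance calls for every triplet in an allocated count table
#'
#' Applies [classify_balance()] to the control replicates of each triplet.
#'
#' @param long long allocated count table (triplet_id, subgenome, sample,
#'   count) as produced by [homeolog_count_table()] or
#'   [simulate_counts()].
#' @param control_samples character vector naming the control replicate
#'   samples, in replicate order.
#' @param lib_sizes named per-sample library sizes (default: total counts
#'   per sample in `long`).
#' @inheritParams classify_balance
#' @return data.table: triplet_id, label, significant, ratio, min_p per
#'   replicate.
#' @export
balance_calls <- function(long, control_samples, p_cutoff = 0.01,
                          ratio_cutoff = 1.5, lib_sizes = NULL,
                          method = c("binomial", "fisher2x2")) {
  method <- match.arg(method)
  long <- setDT(copy(as.data.frame(long)))
  ctrl <- long[sample %in% control_samples]
  if (!nrow(ctrl)) stop("no control samples found in the count table")
  if (is.null(lib_sizes)) {
    ls <- long[, .(lib = sum(count)), by = sample]
    lib_sizes <- setNames(ls$lib, ls$sample)
    lib_sizes[lib_sizes == 0] <- 1
  }
  wide <- dcast(ctrl, triplet_id + subgenome ~ sample, value.var = "count",
                fill = 0)
  out <- lapply(split(wide, by = "triplet_id"), function(w) {
    m <- as.matrix(w[, control_samples, with = FALSE])
    rownames(m) <- w$subgenome
    cb <- classify_balance(m[SUBGENOMES, , drop = FALSE], p_cutoff,
                           ratio_cutoff,
                           lib_sizes = unname(lib_sizes[control_samples]),
                           method = method)
    data.table(triplet_id = w$triplet_id[1], label = cb$label,
               significant = cb$significant, ratio = cb$ratio,
               min_p = min(cb$p, na.rm = !all(is.na(cb$p))))
  })
  rbindlist(out)[order(triplet_id)]
}

#' Summarize balance classification proportions
#'
#' Reports how many tested triplets pass the significance gate alone and
#' how many pass both gates (the UCT definition), with percentages to one
#' decimal place.
#'
#' @param calls data.frame with columns `label` and `significant` (e.g.
#'   from [balance_calls()]).
#' @return data.frame rows `significant_only` and `uct`: numerator,
#'   denominator, percent.
#' @export
summarize_balance <- function(calls) {
  calls <- as.data.frame(calls)
  if (!nrow(calls))
    return(data.frame(measure = character(), n = integer(),
                      n_tested = integer(), percent = numeric()))
  tested <- calls[calls$label != "UNTESTED", , drop = FALSE]
  n <- nrow(tested)
  n_sig <- sum(tested$significant, na.rm = TRUE)
  n_uct <- sum(tested$label == "UCT")
  data.frame(
    measure = c("significant_only", "uct"),
    n = c(n_sig, n_uct),
    n_tested = n,
    percent = if (n > 0) round(100 * c(n_sig, n_uct) / n, 1) else
      c(0, 0))
}
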