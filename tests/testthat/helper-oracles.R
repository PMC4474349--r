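# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: probabilities from explicit binomial
# coefficients, scanning by per-position loops or the PCRE engine, and
# rule re-implementations written from the definitions.

# Two-sided exact binomial p by literal enumeration: sum the probability
# of every outcome no more likely than the observed one.
oracle_exact_p <- function(x, n, p0 = 0.5) {
  k <- 0:n
  d <- choose(n, k) * p0^k * (1 - p0)^(n - k)
  min(1, sum(d[d <= d[x + 1] * (1 + 1e-7)]))
}

# Benjamini-Hochberg step-up: sort ascending, multiply by n/rank, enforce
# monotonicity from the largest down, cap at 1.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(1, adj)
  out
}

# Per-position degenerate-motif matcher (0-based offsets). N in the
# sequence matches nothing.
oracle_scan_loop <- function(sequence, pattern) {
  map <- list(A = "A", C = "C", G = "G", T = "T", R = c("A", "G"),
              Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
              K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
              D = c("A", "G", "T"), H = c("A", "C", "T"),
              V = c("A", "C", "G"), N = c("A", "C", "G", "T"))
  s <- strsplit(sequence, "")[[1]]
  pat <- strsplit(pattern, "")[[1]]
  m <- length(pat)
  hits <- integer(0)
  if (length(s) < m) return(hits)
  for (off in 0:(length(s) - m)) {
    ok <- TRUE
    for (j in seq_len(m)) {
      if (!s[off + j] %in% map[[pat[j]]]) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, off)
  }
  hits
}

# Same semantics through the PCRE engine (overlapping via lookahead).
oracle_scan_regex <- function(sequence, pattern) {
  map <- c(A = "A", C = "C", G = "G", T = "T", R = "[AG]", Y = "[CT]",
           S = "[CG]", W = "[AT]", K = "[GT]", M = "[AC]", B = "[CGT]",
           D = "[AGT]", H = "[ACT]", V = "[ACG]", N = "[ACGT]")
  rx <- paste0("(?=", paste(map[strsplit(pattern, "")[[1]]],
                            collapse = ""), ")")
  m <- gregexpr(rx, sequence, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m) - 1L
}

# Trend-group rule re-evaluated from its definition.
oracle_trend_group <- function(states) {
  fam <- sub("-.*$", "", names(states))
  up <- function(f) any(states[fam == f] == "up")
  quiet <- function(f) !any(states[fam == f] == "up")
  if (up("DS") && up("HD") && quiet("HS")) return("DS/HD-induced")
  if (up("HS") && up("HD") && quiet("DS")) return("HS/HD-induced")
  "other"
}

# Category rule re-evaluated exhaustively over all 12 candidate classes.
oracle_categorize <- function(lfc, flagged, max_ratio, margin = 1) {
  if (!any(flagged)) return("NONE")
  idx <- which(flagged)
  best <- idx[which.max(max_ratio[idx])]
  v <- abs(lfc[c("A", "B", "D"), best])
  for (s in list("A", "B", "D", c("A", "B"), c("A", "D"), c("B", "D"))) {
    r <- setdiff(c("A", "B", "D"), s)
    if (all(outer(v[s], v[r], function(a, b) a >= b + margin))) {
      return(paste0(if (mean(lfc[s, best]) >= 0) "up" else "down", "-",
                    paste(s, collapse = "")))
    }
  }
  "NONE"
}

# Connected components by breadth-first search over an edge list.
oracle_components <- function(vertices, from, to) {
  adj <- lapply(setNames(vector("list", length(vertices)), vertices),
                function(x) character(0))
  for (i in seq_along(from)) {
    adj[[from[i]]] <- c(adj[[from[i]]], to[i])
    adj[[to[i]]] <- c(adj[[to[i]]], from[i])
  }
  seen <- character(0)
  comps <- list()
  for (v in vertices) {
    if (v %in% seen) next
    queue <- v
    comp <- character(0)
    while (length(queue)) {
      u <- queue[1]
      queue <- queue[-1]
      if (u %in% comp) next
      comp <- c(comp, u)
      queue <- c(queue, setdiff(adj[[u]], comp))
    }
    seen <- c(seen, comp)
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps
}

tiny_sim <- function(n = 4, seed = 101, ...) {
  cfg <- sim_config(n_triplets = n, rng_seed = seed, ...)
  list(cfg = cfg, sim = simulate_triplets(cfg))
}
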