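#' @import data.table
#' @importFrom stats dbinom p.adjust rbinom rnbinom rnorm rpois runif fisher.test
#' @importFrom utils head tail
NULL

DNA <- c("A", "C", "G", "T")
SUBGENOMES <- c("A", "B", "D")

random_dna <- function(n, length) {
  m <- matrix(sample(DNA, n * length, replace = TRUE), nrow = n)
  apply(m, 1, paste, collapse = "")
}

# Branch substitution rate from a shared ancestor such that two derived
# copies differ per site with probability `pairwise`. Two copies differ
# when exactly one mutates, or both mutate to different targets:
# P(differ) = 2b(1-b) + (2/3)b^2 = 2b - (4/3)b^2.
branch_rate <- function(pairwise) {
  if (pairwise == 0) return(0)
  (2 - sqrt(4 - (16 / 3) * pairwise)) / (8 / 3)
}

mutate_bases <- function(bases, idx) {
  if (length(idx) == 0L) return(bases)
  orig <- bases[idx]
  shift <- sample.int(3L, length(idx), replace = TRUE)
  bases[idx] <- DNA[(match(orig, DNA) - 1L + shift) %% 4L + 1L]
  bases
}

#' Simulate homeologous triplet sequences with known diagnostic sites
#'
#' Each triplet consists of three equal-length sequences (subgenomes A, B
#' and D) derived from a shared ancestral sequence by i.i.d. per-site
#' substitutions, with no indels, so the column-wise alignment is the
#' identity. The per-branch substitution rate is solved so that any two
#' copies differ at a site with probability `config$divergence_rate`.
#' Every column where the three copies are not identical is a
#' subgenome-diagnostic site and is recorded in the truth table.
#'
#' @param config a [sim_config()].
#' @return list of class `triplet_sim` with elements `genes` (one row per
#'   gene: gene_id, triplet_id, subgenome, chromosome_group), `sequences`
#'   (named character vector), `sites` (truth diagnostic sites: triplet_id,
#'   pos0 0-based, allele_A/B/D, pattern) and `config`.
#' @export
simulate_triplets <- function(config) {
  validate_sim_config(config)
  set.seed(stage_seed(config$rng_seed, "triplets"))
  n <- config$n_triplets
  L <- config$gene_length
  b <- branch_rate(config$divergence_rate)
  if (config$divergence_rate == 0 && n > 0)
    warning("divergence_rate is 0: triplets have no diagnostic sites; ",
            "all reads will be ambiguous")
  ids <- sprintf("T%04d", seq_len(n))
  seqs <- character(0)
  sites <- vector("list", n)
  for (i in seq_len(n)) {
    anc <- sample(DNA, L, replace = TRUE)
    copies <- lapply(SUBGENOMES, function(s) {
      mutate_bases(anc, which(runif(L) < b))
    })
    names(copies) <- SUBGENOMES
    differ <- which(copies$A != copies$B | copies$A != copies$D |
                      copies$B != copies$D)
    if (length(differ)) {
      sites[[i]] <- data.table(
        triplet_id = ids[i],
        pos0 = differ - 1L,
        allele_A = copies$A[differ],
        allele_B = copies$B[differ],
        allele_D = copies$D[differ])
    }
    sq <- vapply(copies, paste, character(1), collapse = "")
    names(sq) <- paste0(ids[i], "_", SUBGENOMES)
    seqs <- c(seqs, sq)
  }
  sites <- if (n > 0) rbindlist(sites) else
    data.table(triplet_id = character(), pos0 = integer(),
               allele_A = character(), allele_B = character(),
               allele_D = character())
  if (nrow(sites))
    sites[, pattern := site_pattern(allele_A, allele_B, allele_D)]
  else sites[, pattern := character(0)]
  genes <- data.table(
    gene_id = if (n > 0) paste0(rep(ids, each = 3), "_", SUBGENOMES)
              else character(0),
    triplet_id = rep(ids, each = 3),
    subgenome = rep(SUBGENOMES, n),
    chromosome_group = rep(if (n > 0) (seq_len(n) - 1L) %% 7L + 1L
                           else integer(0), each = 3))
  structure(list(genes = genes, sequences = seqs, sites = sites,
                 config = config),
            class = "triplet_sim")
}

# Discrimination pattern of a diagnostic column: which partition of
# {A,B,D} the alleles induce ("A|BD", "B|AD", "D|AB", or "A|B|D").
site_pattern <- function(a, b, d) {
  out <- character(length(a))
  out[a == b & a != d] <- "D|AB"
  out[a == d & a != b] <- "B|AD"
  out[b == d & a != b] <- "A|BD"
  out[a != b & a != d & b != d] <- "A|B|D"
  out
}

#' Simulate per-homeolog count tables with planted bias and partitioning
#'
#' Draws raw per-homeolog, per-sample counts whose generating means encode
#' (i) unequal homeolog contribution in a planted fraction of triplets
#' (one homeolog's baseline raised `uct_ratio`-fold, so the generating
#' Exp_max/Exp_min equals `uct_ratio` >= 1.5) and (ii) homeolog-partitioned
#' stress responses in a planted fraction (every homeolog responds
#' `stress_fc`-fold to stress; the divergent homeolog of a partitioned
#' triplet responds `stress_fc * partition_ratio`-fold, so the generating
#' fold-change ratio equals `partition_ratio` >= 2).
#'
#' @param sim a `triplet_sim` from [simulate_triplets()].
#' @param config a [sim_config()]; defaults to the one inside `sim`.
#' @return list of class `count_sim`: `counts` (long table: triplet_id,
#'   subgenome, sample, condition, rep, count, lib_factor), `truth`
#'   (per-triplet: balance label, biased/divergent homeolog, partition
#'   flag), `means` (generating means per triplet x homeolog x condition)
#'   and `config`.
#' @export
simulate_counts <- function(sim, config = sim$config) {
  validate_sim_config(config)
  set.seed(stage_seed(config$rng_seed, "counts"))
  n <- config$n_triplets
  ids <- unique(sim$genes$triplet_id)
  stopifnot(length(ids) == n)
  conds <- config$conditions
  stress <- setdiff(conds, config$control)

  n_uct <- round(config$frac_uct * n)
  n_part <- round(config$frac_partitioned * n)
  uct_idx <- if (n_uct > 0) sort(sample.int(n, n_uct)) else integer(0)
  part_idx <- if (n_part > 0) sort(sample.int(n, n_part)) else integer(0)
  uct_sub <- rep(NA_character_, n)
  uct_sub[uct_idx] <- sample(SUBGENOMES, n_uct, replace = TRUE)
  part_sub <- rep(NA_character_, n)
  part_sub[part_idx] <- sample(SUBGENOMES, n_part, replace = TRUE)
  resp_class <- sample(names(config$response_mix), n, replace = TRUE,
                       prob = config$response_mix)

  truth <- data.table(
    triplet_id = ids,
    balance = ifelse(seq_len(n) %in% uct_idx, "UCT", "ECT"),
    biased_subgenome = uct_sub,
    partitioned = seq_len(n) %in% part_idx,
    divergent_subgenome = part_sub,
    response_class = resp_class)

  # generating means per triplet x subgenome x condition
  grid <- data.table(expand.grid(triplet_id = ids, subgenome = SUBGENOMES,
                                 condition = conds,
                                 stringsAsFactors = FALSE))
  grid <- merge(grid, truth, by = "triplet_id", sort = FALSE)
  grid[, rel := ifelse(!is.na(biased_subgenome) &
                         subgenome == biased_subgenome,
                       config$uct_ratio, 1)]
  is_stress <- grid$condition != config$control
  fam <- sub("-.*$", "", grid$condition)  # CK / DS / HS / HD
  responsive <- is_stress & (
    grid$response_class == "all" |
      (grid$response_class == "ds_hd" & fam %in% c("DS", "HD")) |
      (grid$response_class == "hs_hd" & fam %in% c("HS", "HD")))
  grid[, fc := ifelse(responsive, config$stress_fc, 1)]
  # partitioned triplets: the divergent homeolog's response exceeds its
  # siblings' by partition_ratio in every stress condition
  grid[, fc := ifelse(is_stress & partitioned &
                        subgenome == divergent_subgenome,
                      fc * config$partition_ratio, fc)]
  grid[, mu := config$depth_mean * rel * fc]

  samples <- data.table(
    condition = rep(conds, each = config$n_reps),
    rep = rep(seq_len(config$n_reps), length(conds)))
  samples[, sample := paste0(condition, "_r", rep)]
  lf <- config$lib_factors %||% 1
  samples[, lib_factor := rep_len(lf, nrow(samples))]

  counts <- merge(grid[, .(triplet_id, subgenome, condition, mu)], samples,
                  by = "condition", allow.cartesian = TRUE)
  counts[, mu_s := mu * lib_factor]
  counts[, count := if (config$count_dist == "poisson")
    rpois(.N, mu_s) else rnbinom(.N, mu = mu_s, size = config$nb_size)]
  setorder(counts, triplet_id, subgenome, condition, rep)
  structure(list(
    counts = counts[, .(triplet_id, subgenome, sample, condition, rep,
                        count, lib_factor)],
    truth = truth,
    means = grid[, .(triplet_id, subgenome, condition, mean = mu)],
    config = config), class = "count_sim")
}

#' Simulate paired-end reads with known homeolog of origin
#'
#' Fragments are drawn uniformly along the homeolog of origin with
#' normally distributed insert sizes (clamped to `[read_length,
#' gene_length]`); each mate is `read_length` bases, mate 2 reported as
#' the reverse complement of the fragment's 3' end; per-base substitution
#' errors are injected at `seq_error_rate`. The read budget of each
#' triplet x homeolog x sample cell is its simulated count, so read mass
#' is conserved by construction.
#'
#' @param sim a `triplet_sim`.
#' @param counts a `count_sim` (or a compatible long count table).
#' @param config a [sim_config()].
#' @param samples optional subset of sample names to generate reads for.
#' @return list of class `read_sim`: `reads` (read_id, triplet_id, origin,
#'   sample, start0, insert, seq1, seq2) and `config`.
#' @export
simulate_reads <- function(sim, counts, config = sim$config,
                           samples = NULL) {
  validate_sim_config(config)
  if (config$insert_size < config$read_length)
    stop("insert_size must be >= read_length")
  set.seed(stage_seed(config$rng_seed, "reads"))
  tab <- if (inherits(counts, "count_sim")) counts$counts else setDT(counts)
  if (!is.null(samples)) tab <- tab[sample %in% samples]
  tab <- tab[count > 0]
  L <- config$gene_length
  rl <- config$read_length

  reads <- tab[rep(seq_len(nrow(tab)), tab$count),
               .(triplet_id, origin = subgenome, sample)]
  n <- nrow(reads)
  if (n == 0L)
    return(structure(list(reads = data.table(
      read_id = character(), triplet_id = character(), origin = character(),
      sample = character(), start0 = integer(), insert = integer(),
      seq1 = character(), seq2 = character()), config = config),
      class = "read_sim"))
  reads[, read_id := sprintf("r%07d", seq_len(n))]
  ins <- as.integer(pmin(L, pmax(rl, round(rnorm(n, config$insert_size,
                                                 config$insert_sd)))))
  start0 <- as.integer(floor(runif(n) * (L - ins + 1)))
  reads[, `:=`(start0 = start0, insert = ins)]
  refseq <- sim$sequences[paste0(reads$triplet_id, "_", reads$origin)]
  frag <- substring(refseq, start0 + 1L, start0 + ins)
  seq1 <- substr(frag, 1L, rl)
  seq2 <- revcomp(substring(frag, ins - rl + 1L, ins))
  reads[, seq1 := inject_errors(seq1, rl, config$seq_error_rate)]
  reads[, seq2 := inject_errors(seq2, rl, config$seq_error_rate)]
  structure(list(reads = reads[], config = config), class = "read_sim")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Per-base substitution errors: number of errors per read is binomial,
# positions uniform, substituted base uniform over the other three.
inject_errors <- function(seqs, len, rate) {
  if (rate == 0 || length(seqs) == 0L) return(seqs)
  nerr <- rbinom(length(seqs), len, rate)
  hit <- which(nerr > 0L)
  for (i in hit) {
    pos <- sample.int(len, nerr[i])
    ch <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    ch[pos] <- mutate_bases(ch[pos], seq_along(pos))
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

#' Simulate promoter sequences with planted motif instances
#'
#' Background bases are i.i.d. uniform over A/C/G/T. Each planted instance
#' is a concrete realization of its IUPAC pattern (every degenerate symbol
#' drawn uniformly from its class) placed at a random offset such that no
#' two planted instances overlap; positions and identities are recorded in
#' the truth table.
#'
#' @param n_genes number of promoters.
#' @param length promoter length in bp (default 2000, i.e. a 2 kb upstream
#'   region).
#' @param planted list of [iupac_motif()] objects to plant.
#' @param counts planted instances per gene for each motif (recycled).
#' @param seed integer seed.
#' @param gene_ids optional promoter names.
#' @return list of class `promoter_sim`: `promoters` (named character
#'   vector), `truth` (gene_id, pos0, motif) and the call parameters.
#' @export
simulate_promoters <- function(n_genes, length = 2000, planted = list(),
                               counts = 1L, seed = 1L, gene_ids = NULL) {
  stopifnot(n_genes >= 0, length >= 1)
  counts <- rep_len(as.integer(counts), max(1L, base::length(planted)))
  widths <- vapply(planted, function(m) nchar(m$pattern), integer(1))
  if (base::length(planted) && sum(widths * counts) > length)
    stop("planted motif instances cannot fit in the promoter length")
  set.seed(as.integer(seed))
  ids <- gene_ids %||% sprintf("P%04d", seq_len(n_genes))
  stopifnot(base::length(ids) == n_genes)
  proms <- if (n_genes > 0) random_dna(n_genes, length) else character(0)
  names(proms) <- ids
  truth <- list()
  for (g in seq_len(n_genes)) {
    taken <- integer(0)
    for (k in seq_along(planted)) {
      m <- planted[[k]]
      w <- widths[k]
      for (j in seq_len(counts[k])) {
        pos <- place_nonoverlap(length, w, taken)
        if (is.na(pos))
          stop("could not place planted motifs without overlap; ",
               "reduce counts or motif sizes")
        taken <- c(taken, seq.int(pos, pos + w - 1L))
        inst <- realize_iupac(m$pattern)
        substr(proms[g], pos + 1L, pos + w) <- inst
        truth[[base::length(truth) + 1L]] <-
          data.table(gene_id = ids[g], pos0 = pos, motif = m$name)
      }
    }
  }
  truth <- if (base::length(truth)) rbindlist(truth) else
    data.table(gene_id = character(), pos0 = integer(), motif = character())
  structure(list(promoters = proms, truth = truth, length = length,
                 planted = planted, seed = as.integer(seed)),
            class = "promoter_sim")
}

place_nonoverlap <- function(L, w, taken, max_tries = 200L) {
  for (t in seq_len(max_tries)) {
    pos <- sample.int(L - w + 1L, 1L) - 1L
    if (!any(seq.int(pos, pos + w - 1L) %in% taken)) return(pos)
  }
  NA_integer_
}

# One concrete DNA realization of an IUPAC pattern (N drawn from ACGT).
realize_iupac <- function(pattern) {
  classes <- iupac_classes(pattern)
  paste(vapply(classes, function(cl) sample(cl, 1L), character(1)),
        collapse = "")
}
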