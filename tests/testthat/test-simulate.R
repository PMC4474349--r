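test_that("zero divergence gives identical homeologs, no sites, a warning", {
  cfg <- sim_config(n_triplets = 1, divergence_rate = 0, rng_seed = 1)
  expect_warning(sim <- simulate_triplets(cfg), "no diagnostic sites")
  expect_identical(unname(sim$sequences["T0001_A"]),
                   unname(sim$sequences["T0001_B"]))
  expect_identical(unname(sim$sequences["T0001_A"]),
                   unname(sim$sequences["T0001_D"]))
  expect_equal(nrow(sim$sites), 0L)
})

test_that("the generator is deterministic given the seed", {
  cfg <- sim_config(n_triplets = 3, rng_seed = 42)
  s1 <- simulate_triplets(cfg)
  s2 <- simulate_triplets(cfg)
  expect_identical(s1$sequences, s2$sequences)
  expect_identical(s1$sites, s2$sites)
  f1 <- tempfile(fileext = ".fasta")
  f2 <- tempfile(fileext = ".fasta")
  write_fasta(s1$sequences, f1)
  write_fasta(s2$sequences, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  c1 <- simulate_counts(s1)
  c2 <- simulate_counts(s2)
  expect_identical(c1$counts, c2$counts)
  r1 <- simulate_reads(s1, c1, samples = "CK_r1")
  r2 <- simulate_reads(s2, c2, samples = "CK_r1")
  expect_identical(r1$reads, r2$reads)
})

test_that("pairwise divergence matches the binomial expectation", {
  cfg <- sim_config(n_triplets = 100, gene_length = 1500,
                    divergence_rate = 0.02, rng_seed = 7)
  sim <- simulate_triplets(cfg)
  # direct column-by-column comparison, per pair, per triplet
  diffs <- sapply(unique(sim$genes$triplet_id), function(id) {
    ch <- lapply(c("A", "B", "D"), function(s)
      strsplit(sim$sequences[[paste0(id, "_", s)]], "")[[1]])
    c(sum(ch[[1]] != ch[[2]]), sum(ch[[1]] != ch[[3]]),
      sum(ch[[2]] != ch[[3]]))
  })
  expected <- 1500 * 0.02
  se <- sqrt(1500 * 0.02 * 0.98 / length(diffs))
  expect_lt(abs(mean(diffs) - expected), 3 * se)
  # truth sites are exactly the polymorphic columns
  id <- "T0001"
  ch <- lapply(c("A", "B", "D"), function(s)
    strsplit(sim$sequences[[paste0(id, "_", s)]], "")[[1]])
  poly <- which(ch[[1]] != ch[[2]] | ch[[1]] != ch[[3]] |
                  ch[[2]] != ch[[3]]) - 1L
  expect_identical(sim$sites[triplet_id == id, pos0], poly)
})

test_that("planted balance structure is encoded in the generating means", {
  cfg <- sim_config(n_triplets = 200, frac_uct = 1, uct_ratio = 2,
                    depth_mean = 300, frac_partitioned = 0, rng_seed = 9)
  sim <- simulate_triplets(sim_config(n_triplets = 200, rng_seed = 9))
  cs <- simulate_counts(sim, cfg)
  expect_true(all(cs$truth$balance == "UCT"))
  # empirical biased/unbiased count ratio within 10 % of 2 in control
  ck <- cs$counts[condition == "CK"]
  m <- merge(ck, cs$truth, by = "triplet_id")
  biased <- m[subgenome == biased_subgenome, mean(count)]
  unbiased <- m[subgenome != biased_subgenome, mean(count)]
  expect_lt(abs(biased / unbiased - 2), 0.2)
  # generating means respect the planted ratio exactly
  mm <- merge(cs$means, cs$truth, by = "triplet_id")
  ratios <- mm[condition == "CK",
               max(mean) / min(mean), by = triplet_id]$V1
  expect_true(all(abs(ratios - 2) < 1e-12))
})

test_that("frac_uct = 0 plants only equal-contribution triplets", {
  s <- tiny_sim(n = 10, seed = 2, frac_uct = 0)
  cs <- simulate_counts(s$sim, s$cfg)
  expect_true(all(cs$truth$balance == "ECT"))
  ck_means <- cs$means[condition == "CK"]
  expect_true(all(abs(ck_means$mean - s$cfg$depth_mean) < 1e-12))
})

test_that("partitioned truth flags follow the generating fold changes", {
  cfg <- sim_config(n_triplets = 20, frac_partitioned = 0.5,
                    partition_ratio = 4, rng_seed = 3)
  sim <- simulate_triplets(cfg)
  cs <- simulate_counts(sim, cfg)
  mm <- merge(cs$means, cs$truth, by = "triplet_id")
  ck <- mm[condition == "CK", .(triplet_id, subgenome, base = mean)]
  mm <- merge(mm[condition != "CK"], ck, by = c("triplet_id", "subgenome"))
  mm[, fc := mean / base]
  ratio <- mm[, max(fc) / min(fc), by = .(triplet_id, condition,
                                          partitioned)]
  expect_true(all(ratio[partitioned == TRUE, V1] >= 2))
  expect_true(all(ratio[partitioned == FALSE, abs(V1 - 1) < 1e-12]))
})

test_that("error-free reads match their homeolog of origin exactly", {
  s <- tiny_sim(n = 3, seed = 5, seq_error_rate = 0)
  cs <- simulate_counts(s$sim, s$cfg)
  rs <- simulate_reads(s$sim, cs, samples = "CK_r1")
  ref <- s$sim$sequences[paste0(rs$reads$triplet_id, "_", rs$reads$origin)]
  frag <- substring(ref, rs$reads$start0 + 1, rs$reads$start0 + rs$reads$insert)
  expect_true(all(startsWith(frag, rs$reads$seq1)))
  rc2 <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(rs$reads$seq2)))
  expect_true(all(endsWith(frag, rc2)))
})

test_that("read budgets are conserved per homeolog and sample", {
  s <- tiny_sim(n = 3, seed = 6)
  cs <- simulate_counts(s$sim, s$cfg)
  rs <- simulate_reads(s$sim, cs, samples = c("CK_r1", "HS-1h_r2"))
  emitted <- rs$reads[, .N, by = .(triplet_id, origin, sample)]
  budget <- cs$counts[sample %in% c("CK_r1", "HS-1h_r2") & count > 0,
                      .(triplet_id, origin = subgenome, sample, count)]
  m <- merge(emitted, budget, by = c("triplet_id", "origin", "sample"),
             all = TRUE)
  expect_true(all(m$N == m$count))
})

test_that("injected sequencing errors occur at the configured rate", {
  s <- tiny_sim(n = 2, seed = 8, seq_error_rate = 0.01, depth_mean = 200)
  cs <- simulate_counts(s$sim, s$cfg)
  rs <- simulate_reads(s$sim, cs, samples = "CK_r1")
  ref <- s$sim$sequences[paste0(rs$reads$triplet_id, "_", rs$reads$origin)]
  frag <- substring(ref, rs$reads$start0 + 1,
                    rs$reads$start0 + rs$reads$insert)
  true1 <- substr(frag, 1, s$cfg$read_length)
  mism <- sum(mapply(function(a, b)
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]),
    true1, rs$reads$seq1))
  n_bases <- nrow(rs$reads) * s$cfg$read_length
  expect_gt(n_bases, 10000)
  se <- sqrt(n_bases * 0.01 * 0.99)
  expect_lt(abs(mism - n_bases * 0.01), 3 * se)
})

test_that("insert sizes below the read length are rejected", {
  expect_error(sim_config(n_triplets = 1, insert_size = 50,
                          read_length = 100), "insert_size")
})

test_that("promoter planting records truth and rejects over-packing", {
  ps <- simulate_promoters(5, length = 300, planted = hse_motifs()[1],
                           counts = 2, seed = 4)
  expect_equal(nrow(ps$truth), 10L)
  expect_true(all(nchar(ps$promoters) == 300))
  # planted realizations literally match the pattern at the truth offsets
  for (i in seq_len(nrow(ps$truth))) {
    sub <- substr(ps$promoters[[ps$truth$gene_id[i]]],
                  ps$truth$pos0[i] + 1, ps$truth$pos0[i] + 8)
    expect_match(sub, "^GAA[ACGT][ACGT]TTC$")
  }
  expect_error(
    simulate_promoters(2, length = 20, planted = hse_motifs(), counts = 2),
    "fit")
})

test_that("planted motifs are all recovered by the scanner", {
  ps <- simulate_promoters(30, length = 2000,
                           planted = c(hse_motifs(), list(dre_motif())),
                           seed = 10)
  hits <- scan_promoters(ps$promoters, c(hse_motifs(), list(dre_motif())))
  found <- merge(as.data.frame(ps$truth), as.data.frame(hits),
                 by = c("gene_id", "pos0", "motif"))
  expect_equal(nrow(found), nrow(ps$truth))  # 100 % recall
})
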