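sites3 <- data.frame(
  pos0 = c(10L, 50L, 90L),
  allele_A = c("C", "G", "A"),
  allele_B = c("C", "T", "A"),
  allele_D = c("T", "G", "A"))

test_that("a read showing one discriminating allele gets specific support", {
  # site 10 discriminates D vs AB; the read shows the D allele there and
  # matches everything at site 50 (G: consistent with A and D)
  obs <- data.frame(mate = 1L, pos0 = c(10L, 50L), obs_base = c("T", "G"))
  res <- classify_read_pair(obs, sites3)
  expect_equal(res$support, "D")
  expect_equal(res$group, "D")
  # showing the shared allele at the D-site leaves two-way ambiguity
  obs2 <- data.frame(mate = 1L, pos0 = c(10L, 50L), obs_base = c("C", "G"))
  expect_equal(classify_read_pair(obs2, sites3)$support, "A")
  obs3 <- data.frame(mate = 1L, pos0 = 10L, obs_base = "C")
  expect_equal(classify_read_pair(obs3, sites3)$group, "AB")
})

test_that("reads overlapping no diagnostic site support all three", {
  res <- classify_read_pair(data.frame(mate = integer(), pos0 = integer(),
                                       obs_base = character()), sites3)
  expect_equal(res$support, "ABD")
  expect_equal(res$group, "ABD_nosite")
})

test_that("conflicts are split into within-mate and between-mate", {
  # one mate contradicts every homeolog at its own sites
  obs <- data.frame(mate = 1L, pos0 = c(10L, 50L), obs_base = c("T", "T"))
  res <- classify_read_pair(obs, sites3)
  expect_equal(res$group, "CONFLICT_within")
  expect_equal(res$support, "")
  # each mate is consistent alone (mate 1 -> A only, mate 2 -> B only)
  obs2 <- data.frame(mate = c(1L, 2L), pos0 = c(50L, 10L),
                     obs_base = c("G", "C"))
  # mate1 at 50 shows G (A or D), mate2 at 10 shows C (A or B): intersect A
  expect_equal(classify_read_pair(obs2, sites3)$support, "A")
  obs3 <- data.frame(mate = c(1L, 1L, 2L), pos0 = c(10L, 50L, 50L),
                     obs_base = c("C", "G", "T"))
  # mate1: C@10 (AB) + G@50 (AD) -> A; mate2: T@50 -> B; disjoint
  res3 <- classify_read_pair(obs3, sites3)
  expect_equal(res3$group, "CONFLICT_between")
})

test_that("proportional allocation reproduces the worked examples", {
  expect_equal(allocate_counts(6, 2, 0, n_AB = 4),
               data.frame(A = 9, B = 3, D = 0))
  expect_equal(allocate_counts(0, 0, 0, n_ABD = 9),
               data.frame(A = 3, B = 3, D = 3))
  expect_equal(allocate_counts(1, 1, 2, n_ABD = 4),
               data.frame(A = 2, B = 2, D = 4))
  # zero-denominator two-way fallback splits equally
  expect_equal(allocate_counts(0, 0, 5, n_AB = 4),
               data.frame(A = 2, B = 2, D = 5))
  expect_equal(allocate_counts(0, 0, 0), data.frame(A = 0, B = 0, D = 0))
  expect_error(allocate_counts(-1, 0, 0), "non-negative")
})

test_that("allocation conserves classified read mass", {
  set.seed(31)
  n <- 500
  g <- matrix(rpois(7 * n, lambda = sample(c(0, 1, 5, 50), 7 * n,
                                           replace = TRUE)), ncol = 7)
  al <- allocate_counts(g[, 1], g[, 2], g[, 3], g[, 4], g[, 5], g[, 6],
                        g[, 7])
  expect_true(all(abs(rowSums(al) - rowSums(g)) < 1e-9))
  expect_true(all(unlist(al) >= 0))
})

test_that("error-free synthetic reads always support their origin", {
  s <- tiny_sim(n = 4, seed = 33, seq_error_rate = 0)
  cs <- simulate_counts(s$sim, s$cfg)
  rs <- simulate_reads(s$sim, cs, samples = "CK_r1")
  obs <- read_site_observations(rs, s$sim$sites, s$cfg$read_length)
  asn <- classify_reads(rs$reads[, .(read_id, triplet_id, sample, origin)],
                        obs)
  expect_true(all(!grepl("CONFLICT", asn$group)))
  expect_true(all(mapply(grepl, asn$origin, asn$support)))
})

test_that("allocated counts recover true read budgets within 5 %", {
  cfg <- sim_config(n_triplets = 30, depth_mean = 250, seq_error_rate = 0,
                    rng_seed = 34)
  sim <- simulate_triplets(cfg)
  cs <- simulate_counts(sim, cfg)
  rs <- simulate_reads(sim, cs, samples = "CK_r1")
  obs <- read_site_observations(rs, sim$sites, cfg$read_length)
  asn <- classify_reads(rs$reads[, .(read_id, triplet_id, sample)], obs)
  ct <- homeolog_count_table(asn)
  truth <- cs$counts[sample == "CK_r1",
                     .(triplet_id, subgenome, truth = count)]
  m <- merge(ct$long, truth, by = c("triplet_id", "subgenome"))
  m[, ok := abs(count - truth) / pmax(truth, 1) <= 0.05]
  frac_ok <- m[, .(ok = all(ok)), by = triplet_id][, mean(ok)]
  expect_gte(frac_ok, 0.95)
  # conservation at table level
  w <- ct$wide
  classified <- w$n_A + w$n_B + w$n_D + w$n_AB + w$n_AD + w$n_BD + w$n_ABD
  expect_true(all(abs(w$alloc_A + w$alloc_B + w$alloc_D - classified) < 1e-9))
})

test_that("SAM placements reproduce truth-based classification", {
  s <- tiny_sim(n = 1, seed = 35, seq_error_rate = 0, gene_length = 300)
  sim <- s$sim
  site <- sim$sites[1]
  rl <- 50L
  start1 <- max(0L, site$pos0 - 10L)
  sq <- substr(sim$sequences[[paste0(site$triplet_id, "_A")]],
               start1 + 1, start1 + rl)
  # one single-end-style pair (mate flags 64/128) placed on all 3 homeologs
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           paste0("@SQ\tSN:", names(sim$sequences)[1:3], "\tLN:300"))
  mk <- function(ref, flag) paste("r1", flag, ref, start1 + 1, 42,
                                  paste0(rl, "M"), "*", 0, 0, sq,
                                  strrep("I", rl), sep = "\t")
  recs <- c(mk("T0001_A", 64), mk("T0001_B", 64), mk("T0001_D", 64))
  sam <- tempfile(fileext = ".sam")
  writeLines(c(hdr, recs), sam)
  pl <- read_placements_sam(sam, sim$sites)
  expect_equal(nrow(pl$pairs), 1L)
  asn <- classify_reads(pl$pairs, pl$obs)
  # the read carries the A allele at every overlapped site
  expect_true(grepl("A", asn$support))
  expect_false(grepl("CONFLICT", asn$group))
})
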