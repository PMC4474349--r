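test_that("alignment statistics follow the identity/coverage definitions", {
  s <- strrep("ACGT", 25)
  st <- compute_alignment_stats(s, s)
  expect_equal(st$identity_pct, 100)
  expect_equal(st$coverage_pct, 100)
  s2 <- s
  substr(s2, 10, 10) <- "A"  # one mismatch (ref has C there)
  st2 <- compute_alignment_stats(s, s2)
  expect_equal(st2$identity_pct, 99)
  expect_equal(st2$coverage_pct, 100)
  # symmetric in its arguments
  st3 <- compute_alignment_stats(s2, s)
  expect_equal(st2$identity_pct, st3$identity_pct)
  expect_equal(st2$coverage_pct, st3$coverage_pct)
  # empty alignment degenerates to zero
  st0 <- compute_alignment_stats("", "")
  expect_equal(st0$identity_pct, 0)
  expect_equal(st0$coverage_pct, 0)
})

test_that("pairs below the retention filters are excluded from clustering", {
  genes <- data.frame(gene_id = c("a_A", "b_B", "c_D"),
                      subgenome = c("A", "B", "D"),
                      chromosome_group = c(1L, 1L, 1L))
  base <- data.frame(query_id = c("a_A", "a_A", "b_B"),
                     subject_id = c("b_B", "c_D", "c_D"),
                     identity_pct = 95, coverage_pct = 90, e_value = 1e-30)
  expect_equal(nrow(cluster_triplets(base, genes)$triplets), 1L)
  for (spoil in list(c("identity_pct", 89.9), c("coverage_pct", 74.9),
                     c("e_value", 1e-9))) {
    al <- base
    al[1, spoil[1]] <- as.numeric(spoil[2])
    res <- cluster_triplets(al, genes)
    expect_equal(nrow(res$triplets), 0L)
  }
})

test_that("components without exactly one member per subgenome are rejected", {
  genes <- data.frame(
    gene_id = c("a1_A", "a2_A", "b_B", "d_D"),
    subgenome = c("A", "A", "B", "D"),
    chromosome_group = 1L)
  al <- expand.grid(query_id = genes$gene_id, subject_id = genes$gene_id,
                    stringsAsFactors = FALSE)
  al <- al[al$query_id != al$subject_id, ]
  al$identity_pct <- 95; al$coverage_pct <- 90; al$e_value <- 0
  res <- cluster_triplets(al, genes)
  expect_equal(nrow(res$triplets), 0L)
  expect_true(any(grepl("size 4", res$rejections$reason)))
})

test_that("disagreeing chromosome groups block a triplet", {
  genes <- data.frame(gene_id = c("a_A", "b_B", "c_D"),
                      subgenome = c("A", "B", "D"),
                      chromosome_group = c(1L, 2L, 1L))
  al <- data.frame(query_id = c("a_A", "a_A", "b_B"),
                   subject_id = c("b_B", "c_D", "c_D"),
                   identity_pct = 95, coverage_pct = 90, e_value = 0)
  res <- cluster_triplets(al, genes)
  expect_equal(nrow(res$triplets), 0L)
  expect_match(res$rejections$reason, "chromosome")
  # unknown group on one member disables the check
  genes$chromosome_group[2] <- NA
  expect_equal(nrow(cluster_triplets(al, genes)$triplets), 1L)
})

test_that("synthetic families plus decoys are recovered exactly", {
  s <- tiny_sim(n = 10, seed = 21)
  al <- triadpart:::pairwise_stats_from_families(s$sim)
  genes <- as.data.frame(s$sim$genes)
  decoys <- data.frame(gene_id = sprintf("DEC%02d_%s", 1:10,
                                         rep(c("A", "B", "D"), length.out = 10)),
                       triplet_id = NA,
                       subgenome = rep(c("A", "B", "D"), length.out = 10),
                       chromosome_group = NA_integer_)
  res <- cluster_triplets(al, rbind(genes, decoys))
  expect_equal(nrow(res$triplets), 10L)
  expect_setequal(sub("_A$", "", res$triplets$gene_A),
                  unique(genes$triplet_id))
  expect_equal(sum(res$rejections$reason == "singleton"), 10L)
  # cross-check the component structure against a BFS oracle
  comps <- oracle_components(c(genes$gene_id, decoys$gene_id),
                             al$query_id, al$subject_id)
  triples <- Filter(function(cp) length(cp) == 3, comps)
  expect_equal(length(triples), 10L)
})

test_that("diagnostic-site calling implements the column rules", {
  aln <- c(A = "CCCAC", B = "CCTAC", D = "TCGAC")
  st <- call_diagnostic_sites(aln, "t")
  # col 0: D differs; col 2: all distinct; cols 1,3,4 monomorphic
  expect_equal(st$pos0, c(0L, 2L))
  expect_equal(st$pattern, c("D|AB", "A|B|D"))
  # one-vs-two pattern naming covers each singleton
  expect_equal(call_diagnostic_sites(c(A = "C", B = "C", D = "T"))$pattern,
               "D|AB")
  expect_equal(call_diagnostic_sites(c(A = "C", B = "T", D = "C"))$pattern,
               "B|AD")
  # gap and N columns are skipped
  aln2 <- c(A = "C-AN", B = "CTAN", D = "CTAC")
  expect_equal(nrow(call_diagnostic_sites(aln2)), 0L)
})

test_that("called sites equal truth substitutions on synthetic triplets", {
  s <- tiny_sim(n = 5, seed = 22)
  for (id in unique(s$sim$genes$triplet_id)) {
    aln <- setNames(s$sim$sequences[paste0(id, "_", c("A", "B", "D"))],
                    c("A", "B", "D"))
    called <- call_diagnostic_sites(aln, id)
    truth <- s$sim$sites[triplet_id == id]
    expect_identical(called$pos0, truth$pos0)
    expect_identical(called$pattern, truth$pattern)
  }
})

test_that("unequal-length triplets get a merged progressive alignment", {
  seqs <- c(A = "ACGTACGTAC", B = "ACGTCGTAC", D = "ACGTACGTTAC")
  msa <- triplet_msa(seqs)
  expect_equal(length(unique(nchar(msa))), 1L)
  degap <- function(x) gsub("-", "", x)
  expect_identical(degap(msa[["A"]]), seqs[["A"]])
  expect_identical(degap(msa[["B"]]), seqs[["B"]])
  expect_identical(degap(msa[["D"]]), seqs[["D"]])
})

test_that("internal global alignment reproduces forced statistics", {
  x <- strrep("ACGT", 30)
  y <- x
  substr(y, 5, 5) <- "T"
  st <- align_pair_stats(x, y)
  expect_equal(st$identity_pct, 100 * 119 / 120)
  expect_equal(st$coverage_pct, 100)
})
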