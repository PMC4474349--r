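# Stage 5 — stress-response partitioning. Per homeolog and stress
# condition: exact conditional DE test vs control, BH adjustment per
# contrast, and the FC >= 2 / FDR < 0.01 gates. Per triplet: pairwise
# fold-change ratios between homeologs, the partitioned flag (any ratio
# >= 2 or <= 0.5), the 12-category assignment, and the ECT/UCT-stratified
# partitioning proportions.

source("analysis/00_config.R")

ct <- setDT(read_tsv(file.path(OUT, "homeolog_counts.tsv")))
long <- melt(ct, id.vars = c("triplet_id", "sample"),
             measure.vars = c("alloc_A", "alloc_B", "alloc_D"),
             variable.name = "subgenome", value.name = "count")
long[, subgenome := sub("^alloc_", "", as.character(subgenome))]
long[, condition := sub("_r[0-9]+$", "", sample)]

pr <- response_profiles(long, control = CFG$sim$control,
                        de_fc = CFG$de_fc, de_fdr = CFG$de_fdr,
                        partition_ratio = CFG$partition_ratio,
                        pseudocount = CFG$pseudocount)
bal <- read_tsv(file.path(OUT, "balance_calls.tsv"))
sm <- summarize_partitioning(bal, pr$triplets)

write_tsv(pr$genes, file.path(OUT, "response_genes.tsv"))
write_tsv(pr$conditions, file.path(OUT, "response_conditions.tsv"))
write_tsv(pr$triplets, file.path(OUT, "response_triplets.tsv"))
write_tsv(sm, file.path(OUT, "partitioning_summary.tsv"))

cat(sprintf("%d of %d homeolog x condition contrasts pass the DE gates\n",
            sum(pr$genes$de, na.rm = TRUE), nrow(pr$genes)))
cat("partitioning by balance stratum:\n"); print(sm)
cat("partition categories:\n")
print(pr$triplets[, .N, by = category][order(-N)])
truth <- setDT(read_tsv(file.path(OUT, "truth_triplets.tsv")))
m <- merge(pr$triplets, truth, by = "triplet_id")
cat(sprintf("partitioned flag: sensitivity %.2f, specificity %.2f vs truth\n",
            m[partitioned == TRUE, mean(partitioned_any)],
            m[partitioned == FALSE, mean(!partitioned_any)]))
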