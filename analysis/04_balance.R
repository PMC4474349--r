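# Stage 4 — control balance. Tests each triplet's homeolog counts in the
# control replicates pairwise (exact test, p < 0.01 in both replicates)
# and applies the Exp_max/Exp_min >= 1.5 ratio gate to call ECT vs UCT.
# Works from the allocated counts written by stage 3.

source("analysis/00_config.R")

ct <- setDT(read_tsv(file.path(OUT, "homeolog_counts.tsv")))
long <- melt(ct, id.vars = c("triplet_id", "sample"),
             measure.vars = c("alloc_A", "alloc_B", "alloc_D"),
             variable.name = "subgenome", value.name = "count")
long[, subgenome := sub("^alloc_", "", as.character(subgenome))]

bal <- balance_calls(long, control_samples, CFG$balance_p,
                     CFG$balance_ratio, method = CFG$balance_method)
sm <- summarize_balance(bal)
write_tsv(bal, file.path(OUT, "balance_calls.tsv"))
write_tsv(sm, file.path(OUT, "balance_summary.tsv"))

truth <- setDT(read_tsv(file.path(OUT, "truth_triplets.tsv")))
agree <- merge(bal, truth, by = "triplet_id")[, mean(label == balance)]
cat("balance summary (percent of tested triplets):\n"); print(sm)
cat(sprintf("agreement with planted truth labels: %.1f %%\n", 100 * agree))
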