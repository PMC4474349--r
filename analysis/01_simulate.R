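# Stage 1 — synthetic cohort. Simulates 60 homeologous triplets (1.5 kb,
# 2 % pairwise divergence), their per-sample counts over the 7-condition
# x 2-replicate stress design, and 100 bp paired-end reads for every
# sample, and writes the sequences plus all truth tables.

source("analysis/00_config.R")

sim <- sim_stage()
cs <- counts_stage(sim)
rs <- simulate_reads(sim, cs, CFG$sim)

write_fasta(sim$sequences, file.path(OUT, "triplet_sequences.fasta"))
write_toy_gff3(sim, file.path(OUT, "gene_models.gff3"))
write_tsv(sim$sites, file.path(OUT, "truth_diagnostic_sites.tsv"))
write_tsv(cs$counts, file.path(OUT, "true_counts.tsv"))
write_tsv(cs$truth, file.path(OUT, "truth_triplets.tsv"))

cat(sprintf(
  "simulated %d triplets (%d diagnostic sites, %.1f per triplet),\n",
  CFG$sim$n_triplets, nrow(sim$sites),
  nrow(sim$sites) / CFG$sim$n_triplets))
cat(sprintf("%d read pairs across %d samples; truth: %d UCT, %d partitioned\n",
            nrow(rs$reads), uniqueN(cs$counts$sample),
            sum(cs$truth$balance == "UCT"), sum(cs$truth$partitioned)))
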