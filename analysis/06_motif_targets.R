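# Stage 6 — HSF/DREB target prediction. Simulates 2 kb promoters with
# HSE instances planted in heat/combined-responsive genes and DRE
# instances in drought/combined-responsive genes, scans both degenerate
# elements, derives each gene's ternary expression-trend signature from
# the allocated counts, and predicts co-expressed targets as genes with
# a motif hit AND a matching trend group.

source("analysis/00_config.R")

sim <- sim_stage()
cs <- counts_stage(sim)
ct <- setDT(read_tsv(file.path(OUT, "homeolog_counts.tsv")))
long <- melt(ct, id.vars = c("triplet_id", "sample"),
             measure.vars = c("alloc_A", "alloc_B", "alloc_D"),
             variable.name = "subgenome", value.name = "count")
long[, subgenome := sub("^alloc_", "", as.character(subgenome))]

mot <- triadpart:::motif_stage(sim, cs, long, CFG)

write_tsv(mot$hits, file.path(OUT, "motif_hits.tsv"))
write_tsv(mot$planted, file.path(OUT, "planted_motifs.tsv"))
write_tsv(mot$signatures, file.path(OUT, "trend_signatures.tsv"))
write_tsv(mot$overlap$sizes, file.path(OUT, "target_set_sizes.tsv"))
write_tsv(mot$overlap$overlaps, file.path(OUT, "target_set_overlaps.tsv"))

cat(sprintf("scanned %d promoters: %d HSE hits, %d DRE hits (%d planted)\n",
            length(mot$promoters),
            sum(grepl("^HSE", mot$hits$motif)),
            sum(mot$hits$motif == "DRE"), nrow(mot$planted)))
cat("trend groups:\n")
print(setDT(mot$signatures)[, .N, by = group])
cat("predicted target sets:\n"); print(mot$overlap$sizes)
print(mot$overlap$overlaps)
planted_found <- merge(as.data.frame(mot$planted),
                       as.data.frame(mot$hits),
                       by = c("gene_id", "pos0", "motif"))
cat(sprintf("planted-motif recall: %.1f %%\n",
            100 * nrow(planted_found) / max(1, nrow(mot$planted))))
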