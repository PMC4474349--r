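# Shared configuration for the numbered analysis scripts. Each script is
# a thin driver over the triadpart package: it regenerates what it needs
# deterministically from this seed, states what it found, and writes its
# tables under results/analysis/.

library(triadpart)
library(data.table)

SEED <- as.integer(Sys.getenv("TRIADPART_SEED", "1"))
OUT <- "results/analysis"
dir.create(OUT, showWarnings = FALSE, recursive = TRUE)

CFG <- pipeline_config(
  sim = sim_config(n_triplets = 60, depth_mean = 150, rng_seed = SEED),
  out_dir = OUT)

# deterministic regeneration helpers shared by the stage scripts
sim_stage <- function() simulate_triplets(CFG$sim)
counts_stage <- function(sim) simulate_counts(sim, CFG$sim)
control_samples <- paste0(CFG$sim$control, "_r", seq_len(CFG$sim$n_reps))
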