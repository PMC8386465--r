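#!/usr/bin/env Rscript
# Simulate the study community: 50 species with a skewed number of genomes
# per species, 1-19 rrn copies per genome, realistic intragenomic variation,
# and five gene variants deliberately shared between species pairs (the
# situation that makes ASVs lump species).  Everything downstream (02-04)
# reads the files this script writes.

suppressPackageStartupMessages(library(rrnsplit))

MASTER_SEED <- 108L
OUT <- "results/community"

cfg <- synth_config(seed = MASTER_SEED)
community <- generate_community(cfg)
for (k in 1:5) {
  community <- inject_shared_variant(
    community,
    sprintf("Synthetica species%03d", 2 * k - 1),
    sprintf("Synthetica species%03d", 2 * k),
    seed = MASTER_SEED + k)
}

paths <- write_community(community, OUT)
gt <- community$ground_truth$genomes

message("Simulated community written to ", OUT)
message("  species:            ", length(unique(community$copies$species_key)))
message("  genomes:            ", nrow(gt))
message("  gene copies:        ", nrow(community$copies))
message("  copy-number range:  ", min(gt$copy_number), "-", max(gt$copy_number))
message("  genomes with >1 ASV: ", sum(gt$true_n_asvs > 1),
        " (max intragenomic distance ",
        round(max(gt$max_intragenomic_distance), 4), ")")
message("  shared variants injected: ",
        nrow(community$ground_truth$shared_asvs))
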