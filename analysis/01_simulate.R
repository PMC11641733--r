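#!/usr/bin/env Rscript
## Stage 1: generate the synthetic cohort with known ground truth and
## write the expression matrix, clinical table and truth record.
source("analysis/_config.R")

sim <- pipeline_simulate(cfg, out_dir)
lab <- derive_labels(sim$clinical)
cat(sprintf("simulated %d genes x %d samples -> %s\n",
            nrow(sim$expr), ncol(sim$expr), out_dir))
print(lab)
cat(sprintf("planted pairs: %s\n",
            paste(sim$truth$planted_pairs$gene_i, ">",
                  sim$truth$planted_pairs$gene_j, collapse = ", ")))
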