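## Shared configuration of the analysis run: the default simulation
## emulates the training cohort (47 samples, 36 responders / 11
## non-responders, ~2,000 genes, 3 planted informative pairs at flip
## probability 0.05, 50 lesion-correlated response genes at |r| = 0.6,
## a true non-responder/responder hazard ratio of 2 and 20% censoring).
suppressPackageStartupMessages(library(reogps))

cfg <- pipeline_config(sim = sim_config(seed = 20240101L), seed = 20240101L)
out_dir <- "results/pipeline"
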