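#!/usr/bin/env Rscript
## Stage 3: enumerate candidate gene pairs (at least one response gene),
## orient them by expression difference, and screen by the Wilcoxon
## rank-sum (p < 0.01) and one-sided exact binomial filters.
source("analysis/_config.R")

pt <- pipeline_screen_pairs(cfg, out_dir)
funnel <- attr(pt, "funnel")
cat(sprintf(paste0(
  "pair funnel: %d candidate pairs -> %d ED-oriented -> ",
  "%d past the rank-sum screen -> %d past the binomial filter ",
  "(null accuracy %.3f)\n"),
  funnel$n_pairs_total, funnel$n_ed_positive, funnel$n_wilcoxon_pass,
  funnel$n_binomial_pass, funnel$binomial_null_p))
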