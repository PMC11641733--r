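#!/usr/bin/env Rscript
## Stage 2: screen response genes by Spearman correlation with the
## lesion-size measure (p < 0.05 and |rho| > 0.3), and report the
## analytic power of that screen at this sample size.
source("analysis/_config.R")

rg <- pipeline_screen_genes(cfg, out_dir)
cat(sprintf("retained %d response genes of %d tested (%d constant genes skipped)\n",
            nrow(rg), attr(rg, "n_tested"), attr(rg, "n_skipped_constant")))
n <- attr(rg, "n_samples")
cat(sprintf("analytic power of the screen at n=%d, r=0.3: %.2f\n",
            n, power_spearman(n, 0.3, 0.05)))
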