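#!/usr/bin/env Rscript
## Stage 4: greedy forward selection of the gene-pair signature from the
## 20 top-accuracy seeds, then score every sample by majority vote.
source("analysis/_config.R")

sig <- pipeline_select(cfg, out_dir)
print(sig)
cat(sprintf("training accuracy (F-score): %.3f after %d greedy step(s) from seed rank %d\n",
            sig$provenance$f_score, length(sig$provenance$trajectory),
            sig$provenance$seed_rank))

scores <- pipeline_apply(cfg, out_dir)
cat("score distribution:\n")
print(table(scores$score))
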