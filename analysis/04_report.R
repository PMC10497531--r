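#!/usr/bin/env Rscript
# Stage 4: assemble the run report from the stage-3 outputs.

library(darkcore)

path <- assemble_report("results/subset_study")
cat("Report written to", path, "\n\n")
cat(readLines(path, n = 25), sep = "\n")
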