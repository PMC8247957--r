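#!/usr/bin/env Rscript
# Recompute the published velocity / climatic-debt worked examples from the
# bundled inputs and record the comparison table.

library(ctidebt)

wx <- verify_worked_examples()
print(wx)
dir.create("results", showWarnings = FALSE)
write.csv(wx, file.path("results", "worked_examples.csv"), row.names = FALSE)
stopifnot(all(wx$pass))
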