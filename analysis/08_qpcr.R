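#!/usr/bin/env Rscript
## Step 08 — qPCR validation statistics.
##
## Delta-Cq per sample (target minus reference assay, replicates averaged)
## and a Welch two-sided test between the groups. Lower delta-Cq = higher
## expression, so up-regulation in the case group appears as t < 0.

suppressPackageStartupMessages(library(mirmet))

out <- "results/analysis"
qt <- read.delim(file.path(out, "qpcr.tsv"))
d <- delta_cq(qt)
write.table(d, file.path(out, "qpcr_dcq.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
r <- compare_groups(d$dcq[d$group == "case"], d$dcq[d$group == "control"])
message(sprintf("Welch two-sided t-test on dCq: t = %.3f, df = %.2f, p = %.4f",
                r$t, r$df, r$p))
message(r$note)
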