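#!/usr/bin/env Rscript
## Step 02 — read-level QC and sample/study exclusion gates.
##
## Applies the filter cascade (base quality -> adapter trimming -> length ->
## complexity), classifies retained reads against the miRNA reference, and
## evaluates the gates: a sample fails when <25% of retained reads are
## 20-25 nt, >75% of input reads were discarded, or <10% of retained reads
## are miRNA; a study is excluded when >50% of its samples fail or
## contamination is detected.

suppressPackageStartupMessages(library(mirmet))

out <- "results/analysis"
ref <- read.delim(file.path(out, "reference.tsv"))
fq <- list.files(file.path(out, "fastq"), pattern = "\\.fastq$",
                 full.names = TRUE)

reports <- lapply(fq, function(f) {
  stem <- sub("\\.fastq$", "", f)
  other <- readLines(paste0(stem, ".other_refs.txt"))
  names(other) <- sprintf("otherRNA-%d", seq_along(other))
  qc_sample(f, ref, other_refs = other, sample_id = basename(stem))
})
names(reports) <- vapply(reports, `[[`, character(1), "sample_id")

tab <- qc_report_table(reports)
write.table(tab, file.path(out, "qc_report.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
message("sample QC: ", sum(tab$pass), "/", nrow(tab), " samples pass")

study_of <- sub("_s\\d+$", "", tab$sample_id)
verdicts <- do.call(rbind, lapply(unique(study_of), function(st) {
  v <- qc_study(reports[study_of == st], study_id = st)
  data.frame(study_id = v$study_id, n_samples = v$n_samples,
             n_failed = v$n_failed, contamination_flag = v$contamination_flag,
             include = v$include)
}))
write.table(verdicts, file.path(out, "study_verdicts.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
message("study gates: ", paste(sprintf("%s include=%s", verdicts$study_id,
                                       verdicts$include), collapse = "; "))

## retained reads feed step 03; persist them as plain text
for (r in reports) {
  write.table(r$retained,
              file.path(out, "fastq", paste0(r$sample_id, ".retained.tsv")),
              sep = "\t", row.names = FALSE, quote = FALSE)
}
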