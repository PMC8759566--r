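#!/usr/bin/env Rscript
## Step 03 — annotation merging, read counting, RPM.
##
## Near-identical mature sequences cross-map, so annotations are merged
## (union-find over the sequence-similarity relation) before counting; each
## QC-retained read increments exactly one merged group, ambiguous reads are
## dropped and tallied.

suppressPackageStartupMessages(library(mirmet))

out <- "results/analysis"
ref <- read.delim(file.path(out, "reference.tsv"))
qc_tab <- read.delim(file.path(out, "qc_report.tsv"))
verdicts <- read.delim(file.path(out, "study_verdicts.tsv"))

merged <- merge_annotations(ref)
write.table(
  data.frame(group_id = merged$group_id,
             members = vapply(merged$members, paste, character(1),
                              collapse = ","),
             representative_seq = merged$representative_seq,
             n_members = merged$n_members),
  file.path(out, "merged_annotations.tsv"), sep = "\t", row.names = FALSE,
  quote = FALSE)
message("merged ", nrow(ref), " annotations into ", nrow(merged), " groups")

keep_study <- verdicts$study_id[verdicts$include]
keep <- qc_tab$sample_id[qc_tab$pass &
                           sub("_s\\d+$", "", qc_tab$sample_id) %in%
                           keep_study]
counts <- sapply(keep, function(sid) {
  ret <- read.delim(file.path(out, "fastq", paste0(sid, ".retained.tsv")))
  res <- count_reads(ret$seq, merged)
  message(sprintf("  %s: %d assigned, %d ambiguous, %d unassigned", sid,
                  sum(res$counts), res$ambiguous, res$unassigned))
  res$counts
})
write.table(data.frame(group_id = merged$group_id, counts,
                       check.names = FALSE),
            file.path(out, "fastq_counts.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
r <- rpm_matrix(counts)
write.table(data.frame(group_id = merged$group_id, round(r, 2),
                       check.names = FALSE),
            file.path(out, "fastq_rpm.tsv"), sep = "\t", row.names = FALSE,
            quote = FALSE)
message("counted ", length(keep), " QC-passing samples from included studies")
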