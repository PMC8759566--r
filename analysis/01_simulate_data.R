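#!/usr/bin/env Rscript
## Step 01 — generate the synthetic study.
##
## Produces everything the downstream steps consume, with planted truth:
##   * a mature-miRNA reference (target + contaminant clades),
##   * per-sample FASTQ files for two small "studies" (one clean, one with a
##     failing sample mix) with sidecar read-category truth,
##   * a tissue count matrix over the seven-tissue panel (pCRC, nCR, mLi,
##     nLi, mLu, nLu, PM) with planted metastasis and normal-background
##     effects,
##   * a predicted miRNA-target interaction map and gene-set collection with
##     one planted suppressed set,
##   * a qPCR Cq table emulating the validation experiment (n = 11 + 11).

suppressPackageStartupMessages(library(mirmet))

seed <- 42
out <- "results/analysis"
dir.create(file.path(out, "fastq"), recursive = TRUE, showWarnings = FALSE)

## reference ------------------------------------------------------------------
ref <- generate_reference(12, 3, seed = seed, near_duplicates = 2)
write.table(ref, file.path(out, "reference.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
message("reference: ", sum(ref$clade_tag == "target"), " target + ",
        sum(ref$clade_tag == "contaminant"), " contaminant miRNAs ",
        "(incl. 2 near-duplicate annotations for merging)")

## read sets ------------------------------------------------------------------
studies <- list(
  studyA = list(
    s1 = c(mirna = 0.7, low_quality = 0.1, short = 0.1, other_rna = 0.1),
    s2 = c(mirna = 0.6, low_quality = 0.15, short = 0.15, other_rna = 0.1),
    s3 = c(mirna = 0.65, low_quality = 0.1, short = 0.15,
           low_complexity = 0.05, other_rna = 0.05)
  ),
  studyB = list(  # degraded study: most samples fail the discard gate
    s1 = c(mirna = 0.1, low_quality = 0.8, short = 0.1),
    s2 = c(mirna = 0.05, low_quality = 0.85, short = 0.1),
    s3 = c(mirna = 0.6, low_quality = 0.2, short = 0.2)
  )
)
k <- 0
for (study in names(studies)) {
  for (sample in names(studies[[study]])) {
    k <- k + 1
    sim <- simulate_reads(ref, studies[[study]][[sample]], 5000,
                          seed = seed + k)
    stem <- file.path(out, "fastq", paste0(study, "_", sample))
    write_fastq(sim$reads, paste0(stem, ".fastq"))
    write.table(sim$truth, paste0(stem, ".truth.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    writeLines(sim$other_refs, paste0(stem, ".other_refs.txt"))
  }
}
message("wrote ", k, " FASTQ files with sidecar truth under ",
        file.path(out, "fastq"))

## count matrix with planted effects ------------------------------------------
base <- default_design(n_mirna = 250, n_per_tissue = 10, seed = seed)
ct <- attr(base, "celltype_specific")$mirna
eligible <- setdiff(names(which(rowMeans(base$programs) > 200)), ct)
set.seed(seed)
pick <- sample(eligible, 30)
met <- rbind(
  data.frame(mirna = pick[1:5], tissue = "mLi", lfc = c(2, 1.5, 1, -1.5, -1)),
  data.frame(mirna = pick[6:10], tissue = "mLu", lfc = c(1.5, 1, 2, -1, -1.5)),
  data.frame(mirna = pick[11:14], tissue = "PM", lfc = c(1.5, 1, -1, -1.5)),
  data.frame(mirna = pick[1:2], tissue = c("mLu", "PM"), lfc = c(2, 1.5))
)
bg <- rbind(
  data.frame(mirna = pick[15:19], site = "Li", lfc = c(2, 1.5, -1.5, 1, -1)),
  data.frame(mirna = pick[20:24], site = "Lu", lfc = c(1.5, -1.5, 2, -1, 1))
)
design <- default_design(n_mirna = 250, n_per_tissue = 10,
                         met_effects = met, bg_effects = bg, seed = seed)
sim <- simulate_counts(design)
cm <- sim$counts
write.table(data.frame(mirna = rownames(cm$counts), cm$counts,
                       check.names = FALSE),
            file.path(out, "counts.tsv"), sep = "\t", row.names = FALSE,
            quote = FALSE)
write.table(cm$meta, file.path(out, "meta.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(sim$truth$met_de, file.path(out, "truth_met_de.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(sim$truth$bg_de, file.path(out, "truth_bg_de.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(sim$truth$celltype_specific,
            file.path(out, "truth_celltype.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
message("count matrix: ", nrow(cm$counts), " miRNAs x ", ncol(cm$counts),
        " samples; planted ", nrow(met), " metastasis and ", nrow(bg),
        " background effects")

## interactions and gene sets --------------------------------------------------
truth <- sim$truth
truth$met_de <- met[, c("mirna", "tissue", "lfc")]
names(truth$met_de) <- c("mirna", "site", "lfc")
truth$met_de$sign <- sign(truth$met_de$lfc)
truth$suppressed_gene_sets <- "set01"
gs <- simulate_interactions_and_sets(1000, generate_reference(250, 0,
                                                              seed = seed),
                                     truth, seed = seed + 100, n_sets = 50)
write.table(gs$interactions, file.path(out, "interactions.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
write_gmt(gs$sets, file.path(out, "genesets.gmt"))
message("interaction map: ", nrow(gs$interactions), " pairs; ",
        length(gs$sets), " gene sets (planted suppressed: set01)")

## qPCR ------------------------------------------------------------------------
qt <- simulate_qpcr(11, delta = -1, sd = 1, seed = seed)
write.table(qt, file.path(out, "qpcr.tsv"), sep = "\t", row.names = FALSE,
            quote = FALSE)
message("qPCR table: ", length(unique(qt$sample_id)),
        " samples, 2 assays x 2 replicates")
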