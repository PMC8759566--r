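#!/usr/bin/env Rscript
## Step 06 — cell-type-specific miRNAs.
##
## Filters the generator's cell-type-specific miRNAs at the >100 RPM gate,
## builds the z-score heatmap matrix (per-tissue mean z of RPM), runs a
## correlation PCA with loadings, and Welch-tests mean VST values between
## tissue groups for selected markers.

suppressPackageStartupMessages(library(mirmet))

out <- "results/analysis"
counts <- as.matrix(read.delim(file.path(out, "counts.tsv"), row.names = 1,
                               check.names = FALSE))
meta <- read.delim(file.path(out, "meta.tsv"))
cm <- mirna_counts(counts, meta)
labels <- read.delim(file.path(out, "truth_celltype.tsv"))

kept <- filter_celltype_mirnas(cm, labels)
message(nrow(kept), " of ", nrow(labels),
        " cell-type-specific miRNAs exceed 100 RPM in >=1 tissue")

r <- rpm_matrix(cm)[kept$mirna, , drop = FALSE]
z <- zscore_matrix(r)
hm <- tissue_mean_z(z, cm$meta$tissue)
write.table(data.frame(mirna = rownames(hm), celltype = kept$celltype,
                       round(hm, 3), check.names = FALSE),
            file.path(out, "celltype_heatmap.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)

s <- size_factors(cm)
disp <- estimate_dispersions(cm$counts, s,
                             cm$meta$tissue %in% c("pCRC", "mLi", "mLu",
                                                   "PM"))
v <- vst(cm$counts, s, disp)[kept$mirna, , drop = FALSE]
p <- pca_with_loadings(t(v))
write.table(data.frame(sample_id = rownames(p$scores),
                       tissue = cm$meta$tissue, round(p$scores[, 1:2], 4)),
            file.path(out, "celltype_pca_scores.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(data.frame(mirna = rownames(p$loadings),
                       round(p$loadings[, 1:2], 4)),
            file.path(out, "celltype_pca_loadings.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
message(sprintf("PCA: PC1 %.1f%%, PC2 %.1f%% of variance",
                100 * p$var_explained[1], 100 * p$var_explained[2]))

## Welch tests: each kept marker, its home tissues vs the rest
welch_rows <- do.call(rbind, lapply(seq_len(nrow(kept)), function(i) {
  m <- kept$mirna[i]
  home <- switch(kept$celltype[i],
                 hepatocyte = c("nLi", "mLi"),
                 pneumocyte = c("nLu", "mLu"),
                 epithelial = c("pCRC", "nCR", "mLi", "mLu", "PM"),
                 c("nCR", "nLi", "nLu"))
  g1 <- v[m, cm$meta$tissue %in% home]
  g2 <- v[m, !cm$meta$tissue %in% home]
  w <- welch_t(g1, g2)
  data.frame(mirna = m, celltype = kept$celltype[i],
             home = paste(home, collapse = ","),
             t = round(w$t, 3), df = round(w$df, 2),
             p = signif(w$p, 3))
}))
write.table(welch_rows, file.path(out, "celltype_welch.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
message("Welch home-vs-rest tests significant at 0.05 for ",
        sum(welch_rows$p < 0.05), "/", nrow(welch_rows), " markers")
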