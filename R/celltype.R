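## Analysis of cell-type-specific miRNAs: expression filter, z-score matrix
## for heatmaps, correlation PCA with loadings, and Welch tests. Cell-type
## markers (e.g. hepatocyte Mir-122_5p) let bulk tissue composition be read
## off the expression matrix: normal liver is dominated by hepatocyte
## markers, metastases carry a mixture of tumour-epithelial and organ
## signal.

#' Filter cell-type-specific miRNAs by expression
#'
#' Keeps labeled miRNAs whose per-tissue mean RPM strictly exceeds 100 in at
#' least one tissue.
#'
#' @param cm A [mirna_counts].
#' @param labels Named character vector or `data.frame(mirna, celltype)`
#'   mapping miRNAs to cell types.
#' @param rpm_threshold Expression floor (strict >).
#' @return `data.frame(mirna, celltype)` of retained miRNAs.
#' @export
filter_celltype_mirnas <- function(cm, labels, rpm_threshold = 100) {
  stopifnot(inherits(cm, "mirna_counts"))
  if (is.data.frame(labels)) {
    labels <- setNames(labels$celltype, labels$mirna)
  }
  present <- intersect(names(labels), rownames(cm$counts))
  if (length(present) == 0) {
    stop("no labeled miRNA present in the count matrix", call. = FALSE)
  }
  r <- rpm_matrix(cm)
  tissues <- unique(cm$meta$tissue)
  tissue_means <- sapply(tissues, function(t) {
    rowMeans(r[present, cm$meta$tissue == t, drop = FALSE])
  })
  keep <- apply(as.matrix(tissue_means), 1, max) > rpm_threshold
  data.frame(mirna = present[keep],
             celltype = unname(labels[present[keep]]),
             stringsAsFactors = FALSE)
}

#' Per-miRNA z-scores across samples
#'
#' `z_ij = (x_ij - mean_i) / sd_i` with the sample standard deviation
#' (denominator n - 1). Rows with zero standard deviation become all zeros
#' with a warning.
#'
#' @param x Numeric matrix (miRNAs x samples), typically RPM.
#' @return Matrix of z-scores, same shape.
#' @export
zscore_matrix <- function(x) {
  stopifnot(ncol(x) >= 2)
  m <- rowMeans(x)
  s <- apply(x, 1, sd)
  if (any(s == 0)) {
    warning("constant rows scaled to zero: ",
            paste(rownames(x)[s == 0], collapse = ", "))
  }
  z <- (x - m) / ifelse(s == 0, 1, s)
  z[s == 0, ] <- 0
  z
}

#' Per-tissue mean z-scores (heatmap columns)
#'
#' @param z Output of [zscore_matrix()].
#' @param tissue Tissue label per sample (column).
#' @return Matrix miRNAs x tissues of mean z-scores.
#' @export
tissue_mean_z <- function(z, tissue) {
  sapply(unique(tissue), function(t) {
    rowMeans(z[, tissue == t, drop = FALSE])
  })
}

#' Welch two-sided t-test
#'
#' Unequal-variance t-statistic with Welch-Satterthwaite degrees of freedom:
#' `t = (mean(x) - mean(y)) / sqrt(v1/n1 + v2/n2)`,
#' `df = (v1/n1 + v2/n2)^2 / ((v1/n1)^2/(n1-1) + (v2/n2)^2/(n2-1))`,
#' `p = 2 (1 - T_df(|t|))`.
#'
#' @param x,y Numeric vectors (each length >= 2, finite).
#' @return List of class `welch_result`: `t`, `df`, `p`, `mean_diff`.
#' @export
welch_t <- function(x, y) {
  stopifnot(length(x) >= 2, length(y) >= 2, all(is.finite(c(x, y))))
  n1 <- length(x); n2 <- length(y)
  v1 <- var(x); v2 <- var(y)
  md <- mean(x) - mean(y)
  if (v1 == 0 && v2 == 0) {
    if (md == 0) {
      return(structure(list(t = 0, df = n1 + n2 - 2, p = 1, mean_diff = 0),
                       class = "welch_result"))
    }
    warning("zero variance in both groups with unequal means")
    return(structure(list(t = sign(md) * Inf, df = n1 + n2 - 2, p = 0,
                          mean_diff = md), class = "welch_result"))
  }
  se2 <- v1 / n1 + v2 / n2
  t <- md / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(t), df)
  structure(list(t = t, df = df, p = p, mean_diff = md),
            class = "welch_result")
}

#' Correlation PCA with loadings
#'
#' Columns (miRNAs) are centered and scaled to unit variance before the
#' eigendecomposition, matching a correlation-circle presentation of the
#' loadings. Components are ordered by decreasing eigenvalue; each loading
#' vector is sign-fixed so its largest-magnitude entry is positive.
#'
#' @param x Numeric matrix, samples x miRNAs (e.g. VST values).
#' @param scale. Scale columns to unit variance (correlation PCA, default)
#'   or only center (covariance PCA).
#' @return List: `scores` (samples x PCs), `loadings` (miRNAs x PCs,
#'   orthonormal), `var_explained` (fractions summing to 1).
#' @export
pca_with_loadings <- function(x, scale. = TRUE) {
  if (nrow(x) < 3) stop("at least 3 samples required", call. = FALSE)
  stopifnot(ncol(x) >= 2)
  sds <- apply(x, 2, sd)
  if (scale. && any(sds == 0)) {
    warning("dropping zero-variance columns: ",
            paste(colnames(x)[sds == 0], collapse = ", "))
    x <- x[, sds > 0, drop = FALSE]
  }
  p <- prcomp(x, center = TRUE, scale. = scale.)
  flip <- apply(p$rotation, 2, function(v) {
    if (v[which.max(abs(v))] < 0) -1 else 1
  })
  loadings <- sweep(p$rotation, 2, flip, "*")
  scores <- sweep(p$x, 2, flip, "*")
  list(scores = scores, loadings = loadings,
       var_explained = p$sdev^2 / sum(p$sdev^2))
}

#' Load the packaged cell-type marker miRNA list
#'
#' A curated, editable list of cell-type-specific miRNAs (MirGeneDB
#' nomenclature) shipped under `extdata/`.
#'
#' @return `data.frame(mirna, celltype)`.
#' @export
celltype_marker_list <- function() {
  path <- system.file("extdata", "celltype_mirnas.tsv", package = "mirmet")
  utils::read.delim(path, stringsAsFactors = FALSE)
}
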