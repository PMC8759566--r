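## Visualization-ready outputs: UMAP embedding of the VST matrix (interfaced
## to uwot, not reimplemented), volcano tables and LFC confidence-interval
## tables.

#' UMAP embedding of samples
#'
#' Embeds samples (rows) of a VST matrix into two dimensions with
#' [uwot::umap()], single-threaded for determinism at a fixed seed. The
#' parameters and seed are recorded on the result.
#'
#' @param x Numeric matrix, samples x miRNAs (e.g. VST values).
#' @param n_neighbors,min_dist UMAP hyperparameters.
#' @param seed Integer seed.
#' @param annotations Optional `data.frame` (one row per sample) bound to
#'   the coordinates (e.g. tissue, study).
#' @return `data.frame(sample_id, umap1, umap2, ...)`, with attribute
#'   `params`.
#' @export
embed_umap <- function(x, n_neighbors = 15, min_dist = 0.1, seed = 1,
                       annotations = NULL) {
  if (nrow(x) < n_neighbors + 1) {
    stop("need at least n_neighbors + 1 samples", call. = FALSE)
  }
  set.seed(as.integer(seed))
  emb <- uwot::umap(x, n_neighbors = n_neighbors, min_dist = min_dist,
                    n_threads = 1, n_sgd_threads = 1)
  out <- data.frame(sample_id = if (!is.null(rownames(x))) rownames(x) else
    sprintf("sample_%d", seq_len(nrow(x))),
    umap1 = emb[, 1], umap2 = emb[, 2], stringsAsFactors = FALSE)
  if (!is.null(annotations)) out <- cbind(out, annotations)
  attr(out, "params") <- list(n_neighbors = n_neighbors,
                              min_dist = min_dist, seed = seed)
  out
}

#' Volcano-plot table
#'
#' @param de A `de_result` from [run_de()].
#' @return `data.frame(mirna, lfc, neg_log10_fdr, relevant)`; rows with `NA`
#'   p-values are excluded.
#' @export
volcano_table <- function(de) {
  d <- de[!is.na(de$p_value), , drop = FALSE]
  data.frame(mirna = d$mirna, lfc = d$lfc_shrunk,
             neg_log10_fdr = -log10(pmax(d$fdr, 1e-300)),
             relevant = d$relevant, stringsAsFactors = FALSE)
}

#' LFC table with 95% confidence intervals
#'
#' Normal-approximation intervals `lfc +- 1.96 se` around the MLE LFC.
#'
#' @param de A `de_result`.
#' @return `data.frame(mirna, lfc, se, ci_lo, ci_hi)`.
#' @export
lfc_ci_table <- function(de) {
  data.frame(mirna = de$mirna, lfc = de$lfc_mle, se = de$se,
             ci_lo = de$lfc_mle - 1.96 * de$se,
             ci_hi = de$lfc_mle + 1.96 * de$se,
             stringsAsFactors = FALSE)
}
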