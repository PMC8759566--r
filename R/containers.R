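#' miRNA count matrix with sample metadata
#'
#' Container tying an integer miRNA-by-sample count matrix to its sample
#' metadata (tissue and study labels). All downstream analyses
#' (normalization, differential expression, cell-type analysis) start here.
#'
#' @param counts Integer matrix, rows = miRNA annotations (named), columns =
#'   samples (named). Must be non-negative.
#' @param meta `data.frame` with columns `sample_id`, `tissue` and optionally
#'   `study`; one row per column of `counts`, matched by `sample_id`.
#' @return An object of class `mirna_counts`: a list with elements `counts`
#'   and `meta`.
#' @export
mirna_counts <- function(counts, meta) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have row (miRNA) and column (sample) names", call. = FALSE)
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  stopifnot(is.data.frame(meta), all(c("sample_id", "tissue") %in% names(meta)))
  if (!all(colnames(counts) %in% meta$sample_id)) {
    stop("every sample must have tissue metadata", call. = FALSE)
  }
  meta <- meta[match(colnames(counts), meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  if (is.null(meta$study)) meta$study <- "study1"
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, meta = meta), class = "mirna_counts")
}

#' @export
print.mirna_counts <- function(x, ...) {
  cat("mirna_counts: ", nrow(x$counts), " miRNAs x ", ncol(x$counts),
      " samples\n", sep = "")
  cat("tissues:", paste(sprintf("%s (%d)", names(table(x$meta$tissue)),
                                table(x$meta$tissue)), collapse = ", "), "\n")
  invisible(x)
}

#' Subset a count matrix by sample
#'
#' @param x A [mirna_counts] object.
#' @param samples Character vector of sample ids to keep.
#' @return A [mirna_counts] restricted to those samples.
#' @export
subset_samples <- function(x, samples) {
  stopifnot(inherits(x, "mirna_counts"), all(samples %in% colnames(x$counts)))
  mirna_counts(x$counts[, samples, drop = FALSE],
               x$meta[x$meta$sample_id %in% samples, , drop = FALSE])
}
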