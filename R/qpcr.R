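## qPCR validation statistics: delta-Cq against a reference miRNA and a
## Welch two-sided comparison between groups. Lower delta-Cq means higher
## target expression.

#' Per-sample delta-Cq
#'
#' For every sample, technical replicates are averaged within each assay and
#' the delta-Cq is the mean target Cq minus the mean reference Cq. Samples
#' missing either assay are dropped with a warning; a single available
#' replicate is used as-is with a warning.
#'
#' @param table `data.frame(sample_id, group, assay, replicate, cq)` with
#'   `assay` in `{"target", "reference"}`.
#' @return `data.frame(sample_id, group, dcq)`.
#' @export
delta_cq <- function(table) {
  stopifnot(all(c("sample_id", "group", "assay", "cq") %in% names(table)))
  if (any(table$cq <= 0)) stop("Cq values must be positive", call. = FALSE)
  out <- lapply(split(table, table$sample_id), function(d) {
    tg <- d$cq[d$assay == "target"]
    rf <- d$cq[d$assay == "reference"]
    if (length(tg) == 0 || length(rf) == 0) {
      warning("sample ", d$sample_id[1], " missing an assay; dropped")
      return(NULL)
    }
    if (length(tg) < 2 || length(rf) < 2) {
      warning("sample ", d$sample_id[1], " has a single replicate for ",
              "an assay; using it as-is")
    }
    data.frame(sample_id = d$sample_id[1], group = d$group[1],
               dcq = mean(tg) - mean(rf), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$group, out$sample_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Welch comparison of delta-Cq between groups
#'
#' Two-sided Welch t-test of case vs control delta-Cq values. Because
#' delta-Cq falls as expression rises, a negative t-statistic (case minus
#' control) indicates higher target expression in cases.
#'
#' @param dcq_case,dcq_control Numeric vectors of per-sample delta-Cq
#'   (each length >= 2).
#' @return A `welch_result` (see [welch_t()]) with an added `note` field on
#'   the direction convention.
#' @export
compare_groups <- function(dcq_case, dcq_control) {
  res <- welch_t(dcq_case, dcq_control)
  res$note <- "lower dCq = higher expression; t < 0 means case higher"
  res
}
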