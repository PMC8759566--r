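## miRNA-driven gene-set enrichment scoring.
##
## Up-regulated miRNAs suppress their target mRNAs, so each miRNA gets a
## signed significance score S_miRNA = -log10(FDR) * sign(LFC), each gene the
## sum of the scores of the miRNAs predicted to target it (S_mRNA), and each
## gene set a logistic regression of membership on S_mRNA: a positive slope
## means the set's genes are preferentially targeted by up-regulated miRNAs,
## i.e. the set is more suppressed. Inputs are first corrected for
## normal-tissue background expression.

#' Background-correct DE inputs for enrichment scoring
#'
#' For each miRNA with a significant (background FDR < `bg_fdr`) same-sign
#' background entry, the LFC is pulled towards 0 and the FDR towards 1 in
#' proportion to the relative background magnitude `r = min(1,
#' |LFC_bg|/|LFC|)`: `LFC' = LFC (1 - r)`, `FDR' = FDR + r (1 - FDR)`.
#' Absent, non-significant or opposite-sign background leaves the entry
#' unchanged; so does `LFC = 0` (r undefined, treated as 0).
#'
#' @param input `data.frame` with columns `mirna`, `lfc`, `fdr` and optional
#'   `lfc_bg`, `fdr_bg` (`NA` = no background entry).
#' @param bg_fdr Significance threshold for the background entry.
#' @return `input` with `lfc` and `fdr` corrected.
#' @export
background_correct <- function(input, bg_fdr = 0.05) {
  stopifnot(all(c("mirna", "lfc", "fdr") %in% names(input)))
  if (is.null(input$lfc_bg) || is.null(input$fdr_bg)) return(input)
  active <- !is.na(input$lfc_bg) & !is.na(input$fdr_bg) &
    input$fdr_bg < bg_fdr &
    sign(input$lfc_bg) == sign(input$lfc) &
    input$lfc != 0
  r <- ifelse(active, pmin(1, abs(input$lfc_bg) / abs(input$lfc)), 0)
  input$lfc <- input$lfc * (1 - r)
  input$fdr <- input$fdr + r * (1 - input$fdr)
  input
}

#' Signed miRNA significance score
#'
#' `S_miRNA = -log10(max(fdr, 1e-300)) * sign(lfc)`; `sign(0) = 0`.
#'
#' @param fdr FDR (or p) values in `[0, 1]`.
#' @param lfc Log2 fold changes.
#' @return Numeric scores, finite by construction.
#' @export
s_mirna <- function(fdr, lfc) {
  stopifnot(all(fdr >= 0 & fdr <= 1, na.rm = TRUE))
  -log10(pmax(fdr, 1e-300)) * sign(lfc)
}

#' Per-gene suppression score
#'
#' `S_mRNA[g]` is the sum of `S_miRNA` over the distinct miRNAs predicted to
#' target gene `g`; duplicate interaction rows count once. Interactions
#' naming miRNAs absent from `scores` are skipped with a warning. Genes with
#' no interactions are absent from the result (they score 0 in the
#' enrichment universe).
#'
#' @param scores Named numeric vector of S_miRNA scores.
#' @param interactions `data.frame(mirna_id, gene_id)`.
#' @return Named numeric vector over targeted genes.
#' @export
s_mrna <- function(scores, interactions) {
  inter <- unique(interactions[, c("mirna_id", "gene_id")])
  unknown <- setdiff(unique(inter$mirna_id), names(scores))
  if (length(unknown) > 0) {
    warning("skipping interactions for unknown miRNAs: ",
            paste(utils::head(unknown, 5), collapse = ", "),
            if (length(unknown) > 5) ", ...")
    inter <- inter[inter$mirna_id %in% names(scores), , drop = FALSE]
  }
  if (nrow(inter) == 0) return(setNames(numeric(0), character(0)))
  out <- tapply(scores[inter$mirna_id], inter$gene_id, sum)
  setNames(as.numeric(out), names(out))
}

## Plain IRLS logistic fit of y on a single covariate; returns slope, its
## Fisher-information SE and a Wald p. Used for gene-set scoring.
#' @keywords internal
#' @noRd
irls_logistic <- function(x, y, max_iter = 50, tol = 1e-8) {
  X <- cbind(1, x)
  beta <- c(log((mean(y) + 1e-6) / (1 - mean(y) + 1e-6)), 0)
  dev_old <- Inf
  separated <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- pmin(pmax(X %*% beta, -30), 30)
    p <- 1 / (1 + exp(-eta))
    w <- as.vector(p * (1 - p))
    if (all(w < 1e-10)) { separated <- TRUE; break }
    z <- eta + (y - p) / pmax(w, 1e-10)
    XtW <- t(X * w)
    beta_new <- tryCatch(solve(XtW %*% X, XtW %*% z),
                         error = function(e) NULL)
    if (is.null(beta_new)) { separated <- TRUE; break }
    beta <- as.vector(beta_new)
    d <- -2 * sum(y * log(pmax(p, 1e-12)) +
                    (1 - y) * log(pmax(1 - p, 1e-12)))
    if (abs(d - dev_old) / (abs(d) + 0.1) < tol) break
    dev_old <- d
  }
  if (abs(beta[2]) > 25) separated <- TRUE
  eta <- pmin(pmax(X %*% beta, -30), 30)
  p <- 1 / (1 + exp(-eta))
  w <- as.vector(p * (1 - p))
  info <- t(X * w) %*% X
  se <- tryCatch(sqrt(diag(solve(info)))[2], error = function(e) NA_real_)
  list(b0 = beta[1], b1 = beta[2], se_b1 = se, separated = separated)
}

#' Score one gene set by logistic regression
#'
#' Fits `logit P(g in set) = b0 + b1 * S_mRNA[g]` over the gene universe by
#' maximum likelihood and reports the slope, its SE (Fisher information) and
#' a two-sided Wald p. `b1 > 0` means membership increases with suppression
#' score: the set is "more suppressed".
#'
#' @param scores Named numeric vector of S_mRNA over the universe (genes
#'   absent get 0).
#' @param members Character vector of set member genes.
#' @param universe Character vector of all genes.
#' @return List of class `geneset_result`: `b1`, `se_b1`, `p`, `direction`,
#'   `n_members`, `separated`.
#' @export
geneset_logistic <- function(scores, members, universe) {
  k <- length(intersect(members, universe))
  if (k < 5 || k > length(universe) - 5) {
    stop("set overlap with universe must be in [5, |universe| - 5]",
         call. = FALSE)
  }
  x <- setNames(numeric(length(universe)), universe)
  x[intersect(names(scores), universe)] <-
    scores[intersect(names(scores), universe)]
  y <- as.numeric(universe %in% members)
  fit <- irls_logistic(as.vector(x), y)
  p <- if (fit$separated || !is.finite(fit$se_b1)) NA_real_ else
    2 * pnorm(-abs(fit$b1 / fit$se_b1))
  structure(list(b1 = fit$b1, se_b1 = fit$se_b1, p = p,
                 direction = if (fit$b1 > 0) "more_suppressed" else
                   "less_suppressed",
                 n_members = k, separated = fit$separated),
            class = "geneset_result")
}

#' Run the full enrichment analysis
#'
#' Background-corrects the DE input, computes S_miRNA and S_mRNA, scores
#' every testable set in every collection by logistic regression, and
#' BH-adjusts within each collection separately. The gene universe is the
#' union of all genes in the interaction map and all collection members;
#' genes without interactions score 0.
#'
#' @param input DE input for [background_correct()] (columns `mirna`, `lfc`,
#'   `fdr`, optional `lfc_bg`, `fdr_bg`).
#' @param interactions `data.frame(mirna_id, gene_id)`.
#' @param collections Named list of collections, each a named list of gene
#'   sets (as from [read_gmt()]); a single collection may be passed as a
#'   named list of character vectors.
#' @param bg_fdr Background significance threshold.
#' @return `data.frame(collection, set_id, b1, se, p, fdr, direction,
#'   n_members)`, one row per testable set.
#' @export
run_gsea <- function(input, interactions, collections, bg_fdr = 0.05) {
  if (!is.list(collections[[1]])) {
    collections <- list(collection = collections)
  }
  corrected <- background_correct(input, bg_fdr)
  sm <- setNames(s_mirna(corrected$fdr, corrected$lfc), corrected$mirna)
  sg <- s_mrna(sm, interactions)
  universe <- union(unique(interactions$gene_id),
                    unlist(lapply(collections, function(col)
                      unlist(col, use.names = FALSE))))
  if (length(universe) == 0) stop("empty gene universe", call. = FALSE)
  out <- do.call(rbind, lapply(names(collections), function(cname) {
    col <- collections[[cname]]
    testable <- names(col)[vapply(col, function(g) {
      k <- length(intersect(g, universe))
      k >= 5 && k <= length(universe) - 5
    }, logical(1))]
    if (length(testable) == 0) return(NULL)
    rows <- lapply(testable, function(sid) {
      r <- geneset_logistic(sg, col[[sid]], universe)
      data.frame(collection = cname, set_id = sid, b1 = r$b1,
                 se = r$se_b1, p = r$p, direction = r$direction,
                 n_members = r$n_members, stringsAsFactors = FALSE)
    })
    d <- do.call(rbind, rows)
    d$fdr <- bh_adjust(d$p)
    d
  }))
  rownames(out) <- NULL
  out[, c("collection", "set_id", "b1", "se", "p", "fdr", "direction",
          "n_members")]
}

#' Read a GMT gene-set file
#'
#' @param path Path to a GMT file (set id, description, member genes,
#'   tab-separated, one set per line).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write gene sets to GMT
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of per-set descriptions
#'   (defaults to the set ids).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = names(sets)) {
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
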