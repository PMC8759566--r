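## Negative-binomial Wald differential expression.
##
## The engine is a from-scratch NB GLM: median-of-ratios size factors,
## method-of-moments genewise dispersions moderated towards a fitted
## mean-dispersion trend alpha(mu) = a0 + a1/mu, a per-gene IRLS fit of
## log mu = log s_j + b0 + b1 * group with the dispersion held fixed, a Wald
## test of b1 = 0, empirical-Bayes shrinkage of the log2 fold change under a
## zero-centered normal prior, Benjamini-Hochberg correction, and a
## physiological-relevance filter (FDR < 0.05, |LFC| > 0.58, mean expression
## > 100 RPM in at least one group). Deliberate simplifications relative to
## full DE packages: no Cox-Reid dispersion adjustment, no independent
## filtering, no outlier replacement, two-group designs only.

#' Differential-expression configuration
#'
#' @param fdr_threshold Relevance gate on BH-adjusted p (strict <).
#' @param lfc_threshold Relevance gate on |log2 fold change| (strict >);
#'   0.58 is approximately 1.5-fold.
#' @param rpm_threshold Relevance gate on the larger group mean RPM
#'   (strict >).
#' @param use_shrunk Apply the relevance LFC gate to the shrunken LFC
#'   (`TRUE`, default) or the MLE.
#' @param trend_weight Weight of the trend (vs genewise) dispersion in the
#'   log-scale blend.
#' @param prior_var Optional fixed prior variance for LFC shrinkage
#'   (log2 scale); estimated from the data when `NULL`.
#' @param max_iter,tol IRLS iteration cap and relative deviance tolerance.
#' @return A list of class `de_config`.
#' @export
de_config <- function(fdr_threshold = 0.05, lfc_threshold = 0.58,
                      rpm_threshold = 100, use_shrunk = TRUE,
                      trend_weight = 0.5, prior_var = NULL,
                      max_iter = 100, tol = 1e-8) {
  structure(as.list(environment()), class = "de_config")
}

#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over genes with all-positive
#' counts of that sample's count divided by the gene's geometric mean across
#' samples; size factors are then rescaled to geometric mean 1.
#'
#' @param counts miRNA-by-sample count matrix (or [mirna_counts]).
#' @return Named positive numeric vector, one per sample, geometric mean 1.
#' @export
size_factors <- function(counts) {
  if (inherits(counts, "mirna_counts")) counts <- counts$counts
  stopifnot(ncol(counts) >= 2)
  pos <- rowSums(counts == 0) == 0
  if (!any(pos)) {
    stop("no gene with all-positive counts; consider a pseudo-reference",
         call. = FALSE)
  }
  lc <- log(counts[pos, , drop = FALSE])
  lgeo <- rowMeans(lc)
  s <- exp(apply(lc - lgeo, 2, median))
  s <- s / exp(mean(log(s)))
  s
}

#' Estimate dispersions with a mean-dispersion trend
#'
#' Genewise method-of-moments dispersions on size-factor-normalized counts,
#' using the pooled within-group variance so planted group effects do not
#' inflate them: `alpha_i = max((var_i - mu_i) / mu_i^2, 1e-8)`. A robust
#' least-squares trend `alpha_tr(mu) = a0 + a1/mu` is fitted over genes with
#' positive mean, and the final dispersion blends genewise and trend values
#' on the log scale with weight `trend_weight`.
#'
#' @param counts Count matrix (genes x samples).
#' @param s Size factors from [size_factors()].
#' @param group Two-level factor/character vector over samples.
#' @param config A [de_config()].
#' @return List of class `dispersion_model`: `alpha_gene`, `a0`, `a1`,
#'   `alpha_trend`, `alpha_final`, `mu`.
#' @export
estimate_dispersions <- function(counts, s, group, config = de_config()) {
  if (inherits(counts, "mirna_counts")) counts <- counts$counts
  group <- as.character(group)
  lv <- unique(group)
  if (any(table(group) < 2)) stop("each group needs >= 2 samples",
                                  call. = FALSE)
  yn <- sweep(counts, 2, s, "/")
  gm <- sapply(lv, function(g) rowMeans(yn[, group == g, drop = FALSE]))
  gv <- sapply(lv, function(g) {
    apply(yn[, group == g, drop = FALSE], 1, var)
  })
  ng <- as.vector(table(group)[lv])
  v_within <- as.vector(gv %*% (ng - 1)) / sum(ng - 1)
  mu <- rowMeans(gm)
  floor_a <- 1e-8
  alpha_gene <- pmax((v_within - mu) / mu^2, floor_a)
  alpha_gene[!is.finite(alpha_gene)] <- floor_a

  fit_idx <- which(mu > 0)
  a0 <- floor_a; a1 <- 0
  if (length(fit_idx) >= 10) {
    df <- data.frame(a = alpha_gene[fit_idx], im = 1 / mu[fit_idx])
    fit <- tryCatch(MASS::rlm(a ~ im, data = df, maxit = 50),
                    error = function(e) lm(a ~ im, data = df),
                    warning = function(w) lm(a ~ im, data = df))
    cf <- coef(fit)
    if (any(!is.finite(cf))) {
      a0 <- max(median(alpha_gene), floor_a)
      a1 <- 0
    } else {
      a0 <- max(cf[[1]], floor_a)
      a1 <- max(cf[[2]], 0)
    }
  } else {
    a0 <- max(median(alpha_gene), floor_a)
  }
  alpha_trend <- pmax(a0 + a1 / pmax(mu, 1e-8), floor_a)
  w <- config$trend_weight
  alpha_final <- exp(w * log(alpha_trend) + (1 - w) * log(alpha_gene))
  structure(list(alpha_gene = alpha_gene, a0 = a0, a1 = a1,
                 alpha_trend = alpha_trend, alpha_final = alpha_final,
                 mu = mu), class = "dispersion_model")
}

## Vectorized two-group NB IRLS with fixed dispersion and log(s) offsets.
## Design: log mu_ij = log s_j + b0_i + b1_i * x_j, x in {0, 1}.
#' @keywords internal
#' @noRd
nb_irls <- function(counts, s, alpha, x, max_iter = 100, tol = 1e-8) {
  y <- counts
  G <- nrow(y); n <- ncol(y)
  o <- matrix(log(s), G, n, byrow = TRUE)
  xm <- matrix(x, G, n, byrow = TRUE)
  yn <- sweep(y, 2, s, "/")
  m0 <- rowMeans(yn[, x == 0, drop = FALSE])
  m1 <- rowMeans(yn[, x == 1, drop = FALSE])
  pseudo <- 0.5 / n
  b0 <- log(pmax(m0, pseudo))
  b1 <- log(pmax(m1, pseudo)) - b0
  dev <- function(mu) {
    t1 <- ifelse(y > 0, y * log(y / mu), 0)
    t2 <- (y + 1 / alpha) * (log1p(alpha * y) - log1p(alpha * mu))
    2 * rowSums(t1 - t2)
  }
  dev_old <- rep(Inf, G)
  delta <- rep(Inf, G)
  A11 <- A12 <- det <- numeric(G)
  for (it in seq_len(max_iter)) {
    eta <- pmin(pmax(o + b0 + b1 * xm, -30), 30)
    mu <- exp(eta)
    w <- mu / (1 + alpha * mu)
    z <- (eta - o) + (y - mu) / mu
    A11 <- rowSums(w)
    A12 <- rowSums(w * xm)          # x is 0/1 so sum(w x^2) = sum(w x)
    b1v <- rowSums(w * z)
    b2v <- rowSums(w * xm * z)
    det <- A11 * A12 - A12^2
    b0 <- (A12 * b1v - A12 * b2v) / det
    b1 <- (A11 * b2v - A12 * b1v) / det
    d <- dev(exp(pmin(pmax(o + b0 + b1 * xm, -30), 30)))
    delta <- abs(d - dev_old) / (abs(d) + 0.1)
    dev_old <- d
    if (all(delta < tol)) break
  }
  converged <- delta < sqrt(tol) & is.finite(b1) & is.finite(det) & det > 0
  se1 <- sqrt(A11 / det)
  list(b0 = b0, b1 = b1, se1 = se1, converged = converged)
}

#' Per-gene NB Wald test between two groups
#'
#' Fits, for every gene, an NB GLM with log link, design intercept + group
#' indicator, offset `log(s_j)` and fixed dispersion, and tests the group
#' coefficient against 0 with a Wald z-test. Coefficients and standard
#' errors are reported on the log2 scale.
#'
#' @param counts Count matrix (genes x samples).
#' @param s Size factors.
#' @param disp A `dispersion_model` (or numeric vector of dispersions).
#' @param group Two-level vector over samples.
#' @param case,control The group levels to contrast; `lfc > 0` means higher
#'   in `case`.
#' @param config A [de_config()].
#' @return `data.frame(gene, lfc_mle, se, wald_z, p_value, converged)`.
#' @export
wald_test <- function(counts, s, disp, group, case, control,
                      config = de_config()) {
  if (inherits(counts, "mirna_counts")) counts <- counts$counts
  alpha <- if (inherits(disp, "dispersion_model")) disp$alpha_final else disp
  group <- as.character(group)
  stopifnot(all(group %in% c(case, control)),
            sum(group == case) >= 2, sum(group == control) >= 2)
  x <- as.numeric(group == case)
  fit <- nb_irls(counts, s, alpha, x,
                 max_iter = config$max_iter, tol = config$tol)
  lfc <- fit$b1 / log(2)
  se <- fit$se1 / log(2)
  z <- fit$b1 / fit$se1
  p <- 2 * pnorm(-abs(z))
  p[!fit$converged] <- NA_real_
  data.frame(gene = rownames(counts), lfc_mle = lfc, se = se, wald_z = z,
             p_value = p, converged = fit$converged,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Empirical-Bayes shrinkage of log2 fold changes
#'
#' Posterior mean under a zero-centered normal prior:
#' `lfc * v / (v + se^2)` with prior variance `v` estimated as
#' `max(mean(lfc^2) - mean(se^2), 0.0625)` unless supplied. Noisy estimates
#' (large SE) are pulled towards zero; precise ones are nearly unchanged.
#'
#' @param lfc,se MLE log2 fold changes and their standard errors.
#' @param prior_var Optional prior variance.
#' @return Numeric vector of shrunken LFCs.
#' @export
shrink_lfc <- function(lfc, se, prior_var = NULL) {
  if (is.null(prior_var)) {
    ok <- is.finite(lfc) & is.finite(se)
    prior_var <- max(mean(lfc[ok]^2) - mean(se[ok]^2), 0.0625)
  }
  lfc * prior_var / (prior_var + se^2)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up procedure: `q_(i) = min_{k >= i}(p_(k) * m / k)` capped at 1,
#' mapped back to input order. `NA` p-values are excluded from the
#' denominator and stay `NA`.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (`NA` allowed).
#' @return Adjusted values in input order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  q <- rep(NA_real_, length(p))
  idx <- which(!is.na(p))
  m <- length(idx)
  if (m == 0) return(q)
  pp <- p[idx]
  o <- order(pp)
  stepup <- rev(cummin(rev(pp[o] * m / seq_len(m))))
  q[idx[o]] <- pmin(stepup, 1)
  q
}

#' Variance-stabilizing transformation
#'
#' Closed-form VST for NB counts under the fitted dispersion trend
#' `alpha(mu) = a0 + a1/mu`, applied to size-factor-normalized counts `n`:
#' `log2((1 + a1 + 2 a0 n + 2 sqrt(a0 n (1 + a1 + a0 n))) / (4 a0))`.
#' Monotone increasing, approaching `log2(n)` for large counts. When
#' `a0 <= 0` the transform falls back to `log2(n + 1)` with a warning.
#'
#' @param counts Count matrix (genes x samples) or [mirna_counts].
#' @param s Size factors.
#' @param disp A `dispersion_model` (supplies `a0`, `a1`).
#' @return Transformed matrix, same shape as `counts`.
#' @export
vst <- function(counts, s, disp) {
  if (inherits(counts, "mirna_counts")) counts <- counts$counts
  n <- sweep(counts, 2, s, "/")
  a0 <- disp$a0; a1 <- disp$a1
  if (a0 <= 0) {
    warning("non-positive trend intercept; falling back to log2(n + 1)")
    return(log2(n + 1))
  }
  log2((1 + a1 + 2 * a0 * n + 2 * sqrt(a0 * n * (1 + a1 + a0 * n))) /
         (4 * a0))
}

#' Physiological-relevance filter
#'
#' A miRNA is relevant iff its FDR is strictly below the threshold, its
#' |LFC| strictly above 0.58 (about 1.5-fold), and the mean expression of at
#' least one compared group strictly above 100 RPM. All boundaries strict.
#'
#' @param fdr BH-adjusted p-values.
#' @param lfc Log2 fold changes (shrunken, by default convention).
#' @param rpm_case,rpm_control Per-group mean RPM.
#' @param config A [de_config()].
#' @return Logical vector (`NA` fdr counts as not relevant).
#' @export
relevance_filter <- function(fdr, lfc, rpm_case, rpm_control,
                             config = de_config()) {
  ok <- !is.na(fdr) & fdr < config$fdr_threshold &
    abs(lfc) > config$lfc_threshold &
    pmax(rpm_case, rpm_control) > config$rpm_threshold
  ok & !is.na(ok)
}

#' Run a full two-group differential-expression contrast
#'
#' Subsets the count matrix to the two tissues, drops genes with all-zero
#' counts across the selected samples, computes size factors, dispersions,
#' the Wald test, LFC shrinkage, BH correction, per-group mean RPM
#' (arithmetic mean of per-sample RPM over all miRNA-assigned reads) and the
#' relevance flag.
#'
#' @param cm A [mirna_counts].
#' @param case,control Tissue labels to contrast (`lfc > 0` = higher in
#'   `case`).
#' @param config A [de_config()].
#' @return A `data.frame` of class `de_result` with columns `mirna`,
#'   `mean_rpm_case`, `mean_rpm_control`, `lfc_mle`, `se`, `lfc_shrunk`,
#'   `wald_z`, `p_value`, `fdr`, `relevant`, `converged`; attributes `case`,
#'   `control` and `dispersion_model`.
#' @export
run_de <- function(cm, case, control, config = de_config()) {
  stopifnot(inherits(cm, "mirna_counts"))
  keep_s <- cm$meta$sample_id[cm$meta$tissue %in% c(case, control)]
  sub <- subset_samples(cm, keep_s)
  group <- sub$meta$tissue
  full_rpm <- rpm_matrix(sub$counts)
  rpm_case <- rowMeans(full_rpm[, group == case, drop = FALSE])
  rpm_control <- rowMeans(full_rpm[, group == control, drop = FALSE])

  nonzero <- rowSums(sub$counts) > 0
  counts <- sub$counts[nonzero, , drop = FALSE]
  s <- size_factors(counts)
  disp <- estimate_dispersions(counts, s, group, config)
  wt <- wald_test(counts, s, disp, group, case, control, config)
  wt$lfc_shrunk <- shrink_lfc(wt$lfc_mle, wt$se, config$prior_var)
  wt$fdr <- bh_adjust(wt$p_value)
  wt$mean_rpm_case <- rpm_case[nonzero]
  wt$mean_rpm_control <- rpm_control[nonzero]
  lfc_for_filter <- if (config$use_shrunk) wt$lfc_shrunk else wt$lfc_mle
  wt$relevant <- relevance_filter(wt$fdr, lfc_for_filter,
                                  wt$mean_rpm_case, wt$mean_rpm_control,
                                  config)
  out <- wt[, c("gene", "mean_rpm_case", "mean_rpm_control", "lfc_mle",
                "se", "lfc_shrunk", "wald_z", "p_value", "fdr", "relevant",
                "converged")]
  names(out)[1] <- "mirna"
  attr(out, "case") <- case
  attr(out, "control") <- control
  attr(out, "dispersion_model") <- disp
  attr(out, "size_factors") <- s
  class(out) <- c("de_result", class(out))
  out
}
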