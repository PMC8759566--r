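## Shared oracles and fixture builders. Oracles are deliberately naive and
## independent of the package's code paths.

## Brute-force BH step-up: q_(i) = min_{k >= i}(p_(k) m / k), capped at 1.
bf_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(p[o][i:m] * m / (i:m), 1)
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

## Brute-force connected components over a logical relation matrix.
bf_components <- function(rel) {
  n <- nrow(rel)
  reach <- rel | diag(TRUE, n)
  for (k in seq_len(n)) {
    reach <- reach | (reach %*% reach > 0)
  }
  comp <- integer(n)
  cid <- 0
  for (i in seq_len(n)) {
    if (comp[i] == 0) {
      cid <- cid + 1
      comp[reach[i, ]] <- cid
    }
  }
  comp
}

## Brute-force double-loop gene scoring.
bf_s_mrna <- function(scores, interactions) {
  inter <- unique(interactions[, c("mirna_id", "gene_id")])
  genes <- unique(inter$gene_id)
  out <- setNames(numeric(length(genes)), genes)
  for (g in genes) {
    for (m in inter$mirna_id[inter$gene_id == g]) {
      out[g] <- out[g] + scores[[m]]
    }
  }
  out
}

## Exhaustive-scan adapter trimming oracle: try every suffix position.
bf_trim <- function(seq, adapter, min_overlap = 6, rate = 0.1) {
  L <- nchar(seq)
  for (p in seq_len(L)) {
    ov <- min(nchar(adapter), L - p + 1)
    if (ov < min_overlap) next
    a <- strsplit(substr(adapter, 1, ov), "")[[1]]
    r <- strsplit(substr(seq, p, p + ov - 1), "")[[1]]
    if (sum(a != r) <= floor(rate * ov)) return(substr(seq, 1, p - 1))
  }
  seq
}

## Mean silhouette over a 2-D embedding with labels (euclidean).
simple_silhouette <- function(xy, labels) {
  d <- as.matrix(dist(xy))
  n <- nrow(xy)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(l) {
      mean(d[i, labels == l])
    }, numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

## Flat two-tissue design: one cell-type program (no composition signal), so
## planted effects are the only group differences.
make_flat_design <- function(baseline_rpm, tissues = c("pCRC", "mLi"),
                             n_per_tissue = 15, met_effects = NULL,
                             dispersion = 0.05, libsize = 1e6, seed = 1) {
  n_mirna <- length(baseline_rpm)
  mirnas <- sprintf("Mir-%d_5p", seq_len(n_mirna))
  programs <- matrix(baseline_rpm, n_mirna, 1,
                     dimnames = list(mirnas, "bulk"))
  mixing <- matrix(1, length(tissues), 1,
                   dimnames = list(tissues, "bulk"))
  simulation_design(
    tissues = data.frame(tissue = tissues, n = n_per_tissue),
    programs = programs, mixing = mixing, met_effects = met_effects,
    dispersion = dispersion, libsize_range = c(libsize, libsize),
    dirichlet_conc = Inf, seed = seed
  )
}

## Minimal DE-result table for background-filter unit tests.
make_de_table <- function(mirna, lfc, fdr, rpm_case = 500,
                          rpm_control = 500, case = "x", control = "y",
                          config = de_config()) {
  d <- data.frame(mirna = mirna, mean_rpm_case = rpm_case,
                  mean_rpm_control = rpm_control, lfc_mle = lfc, se = 0.1,
                  lfc_shrunk = lfc, wald_z = lfc / 0.1,
                  p_value = fdr, fdr = fdr, converged = TRUE,
                  stringsAsFactors = FALSE)
  d$relevant <- relevance_filter(d$fdr, d$lfc_shrunk, d$mean_rpm_case,
                                 d$mean_rpm_control, config)
  attr(d, "case") <- case
  attr(d, "control") <- control
  class(d) <- c("de_result", class(d))
  d
}

## Minimal QC report for study-gate tests.
make_report <- function(pass, contamination_frac = 0) {
  structure(list(pass = pass, contamination_frac = contamination_frac),
            class = "qc_report")
}

## Expected sample gates evaluated from a read-simulation sidecar truth.
gates_from_truth <- function(truth, config = qc_config()) {
  retained_cat <- c("mirna", "contaminant", "other_rna")
  ret <- truth[truth$category %in% retained_cat, , drop = FALSE]
  n_input <- nrow(truth)
  n_ret <- nrow(ret)
  frac_20_25 <- if (n_ret > 0) {
    mean(ret$insert_len >= 20 & ret$insert_len <= 25)
  } else 0
  frac_mirna <- if (n_ret > 0) {
    mean(ret$category %in% c("mirna", "contaminant"))
  } else 0
  discard_frac <- (n_input - n_ret) / n_input
  list(
    n_retained = n_ret,
    n_discarded = n_input - n_ret,
    frac_20_25 = frac_20_25,
    frac_mirna = frac_mirna,
    pass = frac_20_25 >= config$min_frac_20_25 &&
      discard_frac <= config$max_discard_frac &&
      frac_mirna >= config$min_mirna_frac
  )
}
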