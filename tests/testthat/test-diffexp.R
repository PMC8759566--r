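nb_matrix <- function(G, n, mu, alpha, seed, libs = rep(1, n)) {
  set.seed(seed)
  matrix(rnbinom(G * n, mu = outer(mu, libs), size = if (alpha > 0)
    1 / alpha else Inf), G, n,
    dimnames = list(paste0("g", seq_len(G)), paste0("s", seq_len(n))))
}

test_that("size factors satisfy closed-form identities", {
  m <- matrix(c(10, 20, 30, 10, 20, 30), 3, 2,
              dimnames = list(letters[1:3], c("x", "y")))
  expect_equal(unname(size_factors(m)), c(1, 1))

  m2 <- cbind(x = c(10, 20, 30), y = c(20, 40, 60))
  rownames(m2) <- letters[1:3]
  s <- size_factors(m2)
  expect_equal(unname(s), c(1 / sqrt(2), sqrt(2)))
  expect_equal(exp(mean(log(s))), 1, tolerance = 1e-12)

  # permutation equivariance
  m3 <- nb_matrix(50, 4, rep(500, 50), 0.1, seed = 1, libs = c(1, 2, 0.5, 1))
  m3 <- m3 + 1
  s3 <- size_factors(m3)
  expect_equal(unname(size_factors(m3[, c(3, 1, 4, 2)])),
               unname(s3[c(3, 1, 4, 2)]))

  expect_error(size_factors(matrix(c(0, 1, 1, 0), 2, 2,
                                   dimnames = list(c("a", "b"), c("x", "y")))),
               "all-positive")
})

test_that("dispersion estimation recovers Poisson and NB regimes", {
  m <- nb_matrix(300, 50, rep(500, 300), 0, seed = 2)
  s <- rep(1, 50)
  d <- estimate_dispersions(m, s, rep(c("A", "B"), each = 25))
  expect_lte(median(d$alpha_gene), 0.01)

  m2 <- nb_matrix(400, 30, exp(runif(400, log(100), log(2000))), 0.2,
                  seed = 3)
  d2 <- estimate_dispersions(m2, rep(1, 30), rep(c("A", "B"), each = 15))
  expect_gte(mean(d2$alpha_final >= 0.1 & d2$alpha_final <= 0.4), 0.9)

  m3 <- matrix(5L, 10, 6, dimnames = list(paste0("g", 1:10),
                                          paste0("s", 1:6)))
  d3 <- estimate_dispersions(m3, rep(1, 6), rep(c("A", "B"), each = 3))
  expect_true(all(d3$alpha_gene == 1e-8))
  expect_true(all(d3$alpha_final > 0))
})

test_that("group effects do not inflate within-group dispersion estimates", {
  mu <- rep(500, 200)
  m <- nb_matrix(200, 30, mu, 0.05, seed = 4)
  grp <- rep(c("A", "B"), each = 15)
  m[1:50, grp == "B"] <- nb_matrix(50, 15, mu[1:50] * 4, 0.05, seed = 5)
  d <- estimate_dispersions(m, rep(1, 30), grp)
  expect_lt(median(d$alpha_gene[1:50]), 0.15)
})

test_that("Wald test is exactly null on duplicated groups and calibrated under the null", {
  base <- nb_matrix(100, 10, exp(runif(100, log(100), log(1000))), 0.1,
                    seed = 6)
  m <- cbind(base, base)
  colnames(m) <- paste0("s", 1:20)
  grp <- rep(c("A", "B"), each = 10)
  s <- size_factors(m)
  disp <- estimate_dispersions(m, s, grp)
  wt <- wald_test(m, s, disp, grp, "B", "A")
  expect_lt(max(abs(wt$lfc_mle)), 1e-6)
  expect_gt(min(wt$p_value), 1 - 1e-6)

  m2 <- nb_matrix(800, 40, exp(runif(800, log(50), log(5000))), 0.1,
                  seed = 7, libs = runif(40, 0.7, 1.3))
  grp2 <- rep(c("A", "B"), each = 20)
  s2 <- size_factors(m2)
  wt2 <- wald_test(m2, s2, estimate_dispersions(m2, s2, grp2), grp2,
                   "B", "A")
  expect_gt(mean(wt2$p_value < 0.05, na.rm = TRUE), 0.02)
  expect_lt(mean(wt2$p_value < 0.05, na.rm = TRUE), 0.08)
})

test_that("planted fold changes are recovered without bias", {
  errs <- vapply(1:5, function(seed) {
    mu <- rep(500, 200)
    m <- nb_matrix(200, 30, mu, 0.05, seed = seed)
    grp <- rep(c("A", "B"), each = 15)
    m[1:40, grp == "B"] <- nb_matrix(40, 15, mu[1:40] * 4, 0.05,
                                     seed = seed + 100)
    s <- size_factors(m)
    wt <- wald_test(m, s, estimate_dispersions(m, s, grp), grp, "B", "A")
    mean(wt$lfc_mle[1:40])
  }, numeric(1))
  expect_true(mean(errs) > 1.8 && mean(errs) < 2.2)
})

test_that("LFC shrinkage has the stated limits and monotonicity", {
  expect_equal(shrink_lfc(2, 1e-9, prior_var = 0.25), 2, tolerance = 1e-6)
  expect_equal(shrink_lfc(2, 0.5, prior_var = 0.25), 1)  # se^2 == prior
  set.seed(8)
  lfc <- rnorm(100, 0, 1); se <- runif(100, 0.01, 1)
  sh <- shrink_lfc(lfc, se)
  expect_true(all(abs(sh) <= abs(lfc)))
  expect_true(all(sign(sh) == sign(lfc) | sh == 0))
})

test_that("BH adjustment equals the step-up formula and p.adjust", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  set.seed(9)
  for (i in 1:50) {
    p <- runif(sample(5:80, 1))^sample(1:3, 1)
    q <- bh_adjust(p)
    expect_equal(q, bf_bh(p))
    expect_equal(q, p.adjust(p, "BH"))
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
  p_na <- c(0.01, NA, 0.5)
  q_na <- bh_adjust(p_na)
  expect_true(is.na(q_na[2]))
  expect_equal(q_na[c(1, 3)], p.adjust(p_na[c(1, 3)], "BH"))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("VST is monotone, log2-asymptotic and variance-stabilizing", {
  disp <- structure(list(a0 = 0.05, a1 = 5), class = "dispersion_model")
  n <- matrix(seq(1, 1e4, length.out = 200), 1)
  v <- vst(n, 1, disp)
  expect_true(all(diff(v[1, ]) > 0))
  big <- vst(matrix(c(1e6, 1e7), 1), 1, disp)
  expect_lt(abs((big[2] - log2(1e7)) - (big[1] - log2(1e6))), 0.01)

  mu <- exp(seq(log(50), log(5000), length.out = 40))
  m <- nb_matrix(40, 200, mu, 0.05, seed = 10)
  s <- rep(1, 200)
  dm <- estimate_dispersions(m, s, rep(c("A", "B"), each = 100))
  vmat <- vst(m, s, dm)
  raw_var <- apply(m, 1, var)
  vst_var <- apply(vmat, 1, var)
  expect_gt(max(raw_var) / min(raw_var), 50)
  expect_lt(max(vst_var) / min(vst_var), 5)

  disp0 <- structure(list(a0 = 0, a1 = 1), class = "dispersion_model")
  expect_warning(v0 <- vst(matrix(3, 1), 1, disp0), "log2")
  expect_equal(v0[1], 2)
})

test_that("relevance filter applies all three strict gates", {
  expect_false(relevance_filter(0.01, 0.58, 500, 500))   # LFC not > 0.58
  expect_true(relevance_filter(0.01, 1.0, 50, 120))      # one tissue > 100
  expect_false(relevance_filter(0.06, 2.0, 1000, 1000))  # FDR gate
  expect_false(relevance_filter(0.01, 1.0, 100, 100))    # RPM not > 100
  expect_true(relevance_filter(0.01, -0.6, 500, 10))
  expect_false(relevance_filter(NA, 2, 500, 500))
})

test_that("run_de wires the stages together on planted data", {
  me <- data.frame(mirna = c("Mir-1_5p", "Mir-2_5p"), tissue = "mLi",
                   lfc = c(1.5, -1.5))
  d <- make_flat_design(baseline_rpm = rep(c(300, 1500), 30),
                        n_per_tissue = 12, met_effects = me,
                        dispersion = 0.05, seed = 11)
  sim <- simulate_counts(d)
  de <- run_de(sim$counts, "mLi", "pCRC")
  expect_s3_class(de, "de_result")
  expect_equal(attr(de, "case"), "mLi")
  hits <- de[de$mirna %in% me$mirna, ]
  expect_true(all(hits$relevant))
  expect_equal(sign(hits$lfc_shrunk[order(hits$mirna)]), c(1, -1))
  # BH floor invariant: fdr >= p everywhere
  expect_true(all(de$fdr >= de$p_value - 1e-12, na.rm = TRUE))
  others <- de[!de$mirna %in% me$mirna, ]
  expect_lt(mean(others$relevant), 0.05)
})
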