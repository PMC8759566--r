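test_that("background correction interpolates LFC to 0 and FDR to 1", {
  inp <- data.frame(mirna = "m1", lfc = 2, fdr = 0.01, lfc_bg = 1,
                    fdr_bg = 0.001)
  out <- background_correct(inp)
  expect_equal(out$lfc, 1)          # r = 0.5
  expect_equal(out$fdr, 0.505)

  # dominant background: LFC -> 0, FDR -> 1
  inp2 <- data.frame(mirna = "m1", lfc = 1, fdr = 0.01, lfc_bg = 3,
                     fdr_bg = 0.001)
  out2 <- background_correct(inp2)
  expect_equal(out2$lfc, 0)
  expect_equal(out2$fdr, 1)

  # absent, non-significant or opposite-sign background: identity
  inp3 <- data.frame(mirna = c("a", "b", "c"), lfc = c(2, 2, 2),
                     fdr = 0.01, lfc_bg = c(NA, 1, -1),
                     fdr_bg = c(NA, 0.2, 0.001))
  expect_equal(background_correct(inp3)$lfc, c(2, 2, 2))
  no_bg <- data.frame(mirna = "m", lfc = 1, fdr = 0.5)
  expect_identical(background_correct(no_bg), no_bg)
  # zero LFC with significant same-sign(0) background: unchanged
  inp4 <- data.frame(mirna = "m", lfc = 0, fdr = 0.5, lfc_bg = 0,
                     fdr_bg = 0.001)
  expect_equal(background_correct(inp4)$fdr, 0.5)
})

test_that("background correction never strengthens evidence", {
  set.seed(17)
  inp <- data.frame(mirna = sprintf("m%d", 1:200),
                    lfc = rnorm(200, 0, 1.5), fdr = runif(200),
                    lfc_bg = rnorm(200, 0, 1.5), fdr_bg = runif(200))
  out <- background_correct(inp)
  expect_true(all(abs(out$lfc) <= abs(inp$lfc) + 1e-12))
  expect_true(all(out$fdr >= inp$fdr - 1e-12))
})

test_that("miRNA scores follow -log10(fdr) * sign(lfc)", {
  expect_equal(s_mirna(0.01, 2), 2)
  expect_equal(s_mirna(1, -3), 0)
  expect_equal(s_mirna(0.001, -0.3), -3)
  expect_equal(s_mirna(0.5, 0), 0)    # sign(0) = 0
  expect_true(is.finite(s_mirna(0, 5)))
  expect_error(s_mirna(1.5, 1), "fdr")
})

test_that("gene scores sum distinct targeting miRNAs, matching brute force", {
  sc <- c(a = 2, b = 3, c = -1)
  inter <- data.frame(mirna_id = c("a", "b", "b"), gene_id = "g1")
  expect_equal(unname(s_mrna(sc, inter)["g1"]), 5)  # duplicate b counted once
  expect_false("g2" %in% names(s_mrna(sc, inter)))
  expect_warning(
    got <- s_mrna(sc, data.frame(mirna_id = c("a", "zz"),
                                 gene_id = c("g1", "g1"))), "unknown")
  expect_equal(unname(got["g1"]), 2)

  set.seed(18)
  mirnas <- sprintf("m%02d", 1:30)
  scores <- setNames(rnorm(30), mirnas)
  inter2 <- data.frame(
    mirna_id = sample(mirnas, 3000, replace = TRUE),
    gene_id = sample(sprintf("g%03d", 1:500), 3000, replace = TRUE))
  got2 <- s_mrna(scores, inter2)
  oracle <- bf_s_mrna(scores, inter2)
  expect_equal(got2[sort(names(got2))], oracle[sort(names(oracle))])
})

test_that("gene-set logistic slope matches glm and flips with score negation", {
  set.seed(19)
  uni <- sprintf("g%04d", 1:800)
  sg <- setNames(rnorm(800, 0, 3), uni)
  memb <- sample(uni, 40)
  sg[memb] <- sg[memb] + 3
  fit <- geneset_logistic(sg, memb, uni)
  ref <- glm(as.numeric(uni %in% memb) ~ sg[uni], family = binomial())
  expect_lt(abs(fit$b1 - unname(coef(ref)[2])), 1e-6)
  expect_equal(fit$direction, "more_suppressed")
  neg <- geneset_logistic(-sg, memb, uni)
  expect_lt(abs(neg$b1 + fit$b1), 1e-6)
  expect_equal(neg$direction, "less_suppressed")

  # planted +5 shift at |set| = 50, universe 1000: strong detection
  uni2 <- sprintf("h%04d", 1:1000)
  sg2 <- setNames(rnorm(1000, 0, 2), uni2)
  memb2 <- sample(uni2, 50)
  sg2[memb2] <- sg2[memb2] + 5
  fit2 <- geneset_logistic(sg2, memb2, uni2)
  expect_gt(fit2$b1, 0)
  expect_lt(fit2$p, 1e-3)

  expect_error(geneset_logistic(sg, uni[1:3], uni), "\\[5")
})

test_that("set-membership permutations yield calibrated null p-values", {
  set.seed(20)
  uni <- sprintf("g%04d", 1:600)
  sg <- setNames(rnorm(600, 0, 2), uni)
  pvals <- replicate(400, geneset_logistic(sg, sample(uni, 25), uni)$p)
  expect_gt(mean(pvals < 0.05), 0.02)
  expect_lt(mean(pvals < 0.05), 0.09)
})

test_that("run_gsea scores every testable set with per-collection BH", {
  ref <- generate_reference(20, 0, seed = 21)
  truth <- list(met_de = data.frame(mirna = sprintf("Mir-%d_5p", 1:4),
                                    site = "mLi", sign = 1),
                suppressed_gene_sets = "set01")
  sim <- simulate_interactions_and_sets(500, ref, truth, seed = 22,
                                        n_sets = 10)
  set.seed(23)
  input <- data.frame(mirna = ref$annotation_id, lfc = rnorm(20, 0, 0.3),
                      fdr = runif(20, 0.3, 1))
  input$lfc[1:4] <- 2; input$fdr[1:4] <- 1e-6
  res <- run_gsea(input, sim$interactions,
                  list(colA = sim$sets[1:5], colB = sim$sets[6:10]))
  expect_equal(nrow(res), 10)
  expect_setequal(unique(res$collection), c("colA", "colB"))
  for (cn in c("colA", "colB")) {
    sub <- res[res$collection == cn, ]
    expect_equal(sub$fdr, bh_adjust(sub$p))
  }
  expect_equal(res$set_id[which.min(res$fdr)], "set01")
  expect_equal(res$direction[res$set_id == "set01"], "more_suppressed")

  # all-null scores: no spurious confident calls
  input0 <- data.frame(mirna = ref$annotation_id, lfc = 0, fdr = 1)
  res0 <- run_gsea(input0, sim$interactions, sim$sets)
  expect_true(all(abs(res0$b1) < 1e-6))
  expect_equal(sum(res0$fdr < 0.05, na.rm = TRUE), 0)
})
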