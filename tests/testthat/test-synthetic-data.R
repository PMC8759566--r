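test_that("reference generation honours counts, clades and determinism", {
  ref <- generate_reference(5, 0, seed = 1)
  expect_equal(nrow(ref), 5)
  expect_true(all(ref$clade_tag == "target"))
  expect_identical(ref, generate_reference(5, 0, seed = 1))

  ref2 <- generate_reference(3, 2, seed = 7)
  expect_equal(sum(ref2$clade_tag == "contaminant"), 2)
  expect_false(anyDuplicated(ref2$annotation_id) > 0)
  expect_true(all(nchar(ref2$mature_seq) >= 18 & nchar(ref2$mature_seq) <= 25))
  expect_true(all(grepl("^[ACGT]+$", ref2$mature_seq)))

  expect_error(generate_reference(0, 0), "n_target")
})

test_that("generated sequences keep pairwise distance unless near-duplicates requested", {
  ref <- generate_reference(20, 5, seed = 11)
  n <- nrow(ref)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      d <- sum(strsplit(substr(ref$mature_seq[i], 1, 18), "")[[1]] !=
                 strsplit(substr(ref$mature_seq[j], 1, 18), "")[[1]])
      expect_gte(d, 3)
    }
  }
  refd <- generate_reference(5, 0, seed = 3, near_duplicates = 2)
  expect_equal(nrow(refd), 7)
  # the duplicate differs from its source at exactly one (terminal) position
  d <- mapply(function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]),
              refd$mature_seq[1:2], refd$mature_seq[6:7])
  expect_true(all(d == 1))
})

test_that("zero-effect Poisson counts differ across groups only by library scaling", {
  d <- make_flat_design(baseline_rpm = rep(c(200, 1000, 5000), each = 20),
                        n_per_tissue = 6, dispersion = 0, libsize = 1e6,
                        seed = 2)
  sim <- simulate_counts(d)
  m <- sim$counts$counts
  tis <- sim$counts$meta$tissue
  propA <- rowMeans(sweep(m[, tis == "pCRC"], 2, colSums(m[, tis == "pCRC"]), "/"))
  propB <- rowMeans(sweep(m[, tis == "mLi"], 2, colSums(m[, tis == "mLi"]), "/"))
  expect_lt(max(abs(log2(propA / propB))), 0.1)
  expect_equal(nrow(sim$truth$met_de), 0)
})

test_that("planted log2 effects are recovered by group-mean ratios", {
  ratios <- vapply(1:10, function(seed) {
    d <- make_flat_design(baseline_rpm = rep(1000, 50), n_per_tissue = 20,
                          met_effects = data.frame(mirna = "Mir-1_5p",
                                                   tissue = "mLi", lfc = 1),
                          dispersion = 0.01, seed = seed)
    sim <- simulate_counts(d)
    m <- sim$counts$counts
    tis <- sim$counts$meta$tissue
    norm <- sweep(m, 2, colSums(m), "/")
    log2(mean(norm["Mir-1_5p", tis == "mLi"]) /
           mean(norm["Mir-1_5p", tis == "pCRC"]))
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 1), 0.2)
  expect_true(all(abs(ratios - 1) < 0.3))
})

test_that("fixed library-size range pins column totals", {
  d <- make_flat_design(baseline_rpm = rep(2000, 500), n_per_tissue = 4,
                        dispersion = 0.001, libsize = 1e6, seed = 5)
  sim <- simulate_counts(d)
  expect_true(all(abs(colSums(sim$counts$counts) - 1e6) < 0.01 * 1e6))
})

test_that("truth tables record planted effects and invalid designs error", {
  me <- data.frame(mirna = c("Mir-2_5p", "Mir-3_5p"), tissue = "mLi",
                   lfc = c(1.5, -1))
  be <- data.frame(mirna = "Mir-4_5p", site = "Li", lfc = 2)
  d <- default_design(n_mirna = 50, n_per_tissue = 3, met_effects = me,
                      bg_effects = be, seed = 1)
  sim <- simulate_counts(d)
  expect_setequal(sim$truth$met_de$mirna, me$mirna)
  expect_equal(sim$truth$met_de$sign, c(1, -1))
  expect_equal(sim$truth$bg_de$mirna, "Mir-4_5p")
  expect_error(
    simulation_design(data.frame(tissue = character(0), n = integer(0)),
                      matrix(1, 2, 1, dimnames = list(c("a", "b"), "ct")),
                      matrix(1, 0, 1)),
    "empty tissue"
  )
  expect_error(default_design(n_mirna = 50, n_per_tissue = 1), "group sizes")
})

test_that("read simulation apportions categories exactly and deterministically", {
  ref <- generate_reference(6, 2, seed = 4)
  sim <- simulate_reads(ref, c(mirna = 1.0), 100, seed = 1)
  expect_equal(nrow(sim$reads), 100)
  expect_true(all(sim$truth$category == "mirna"))

  sim2 <- simulate_reads(ref, c(mirna = 0.5, short = 0.5), 10, seed = 1)
  expect_equal(as.vector(table(sim2$truth$category)[c("mirna", "short")]),
               c(5L, 5L))

  a <- simulate_reads(ref, c(mirna = 0.6, low_quality = 0.4), 50, seed = 9)
  b <- simulate_reads(ref, c(mirna = 0.6, low_quality = 0.4), 50, seed = 9)
  expect_identical(a, b)

  # largest-remainder rounding conserves the total for awkward fractions
  fr <- c(mirna = 1 / 3, short = 1 / 3, low_quality = 1 / 3)
  sim3 <- simulate_reads(ref, fr, 100, seed = 2)
  expect_equal(sum(table(sim3$truth$category)), 100)

  expect_error(simulate_reads(ref, c(mirna = 0.7, short = 0.2), 10),
               "sum to 1")
})

test_that("interaction generator enforces preconditions and round-trips GMT", {
  ref <- generate_reference(10, 0, seed = 2)
  truth_bad <- list(met_de = data.frame(mirna = "Mir-1_5p", site = "mLi",
                                        sign = -1),
                    suppressed_gene_sets = "set01")
  expect_error(simulate_interactions_and_sets(100, ref, truth_bad),
               "up-regulated")
  expect_error(
    simulate_interactions_and_sets(5, ref,
                                   list(met_de = data.frame(),
                                        suppressed_gene_sets = character(0))),
    "n_genes")

  truth <- list(met_de = data.frame(mirna = "Mir-1_5p", site = "mLi",
                                    sign = 1),
                suppressed_gene_sets = character(0))
  sim <- simulate_interactions_and_sets(200, ref, truth, seed = 3,
                                        n_sets = 5, set_size = 10)
  path <- tempfile(fileext = ".gmt")
  write_gmt(sim$sets, path)
  expect_identical(read_gmt(path), sim$sets)
})

test_that("without planted suppression, targeting is independent of set membership", {
  ref <- generate_reference(10, 0, seed = 2)
  truth <- list(met_de = empty <- data.frame(mirna = character(0),
                                             site = character(0),
                                             sign = numeric(0)),
                suppressed_gene_sets = character(0))
  ok <- vapply(1:20, function(seed) {
    sim <- simulate_interactions_and_sets(400, ref, truth, seed = seed,
                                          n_sets = 2, set_size = 50)
    deg <- table(factor(sim$interactions$gene_id, levels = sim$genes))
    memb <- sim$genes %in% sim$sets$set01
    tab <- table(memb, as.vector(deg) > median(deg))
    suppressWarnings(chisq.test(tab)$p.value) > 0.01
  }, logical(1))
  expect_gte(sum(ok), 18)
})

test_that("qPCR tables have two replicates per assay and honour preconditions", {
  qt <- simulate_qpcr(5, delta = -1, sd = 0.5, seed = 1)
  counts <- table(qt$sample_id, qt$assay)
  expect_true(all(counts == 2))
  expect_equal(length(unique(qt$sample_id)), 10)
  expect_error(simulate_qpcr(1, -1, 0.5), "n_per_group")
  expect_error(simulate_qpcr(5, -1, 0), "sd")
})
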