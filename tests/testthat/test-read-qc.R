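phred_str <- function(scores) intToUtf8(as.integer(scores) + 33L)

test_that("base-quality filter uses the strict <50% boundary", {
  # exactly half the bases above Phred 20: kept (not strictly below half)
  expect_true(filter_read_quality(phred_str(c(rep(30, 5), rep(2, 5)))))
  expect_false(filter_read_quality(phred_str(c(rep(30, 4), rep(2, 6)))))
  expect_true(filter_read_quality(phred_str(rep(40, 10))))
  expect_false(filter_read_quality(""))
  # Phred exactly 20 does not count as "above 20"
  expect_false(filter_read_quality(phred_str(rep(20, 10))))
})

test_that("adapter trimming removes the leftmost qualifying suffix", {
  adapter <- "TGGAATTCTCGGGTGCCAAGG"
  m <- "ACGTACGTACGTACGTACGTAC"  # 22 nt
  q <- strrep("I", nchar(m))
  qa <- strrep("I", nchar(m) + nchar(adapter))
  r <- trim_adapter(paste0(m, adapter), qa, adapter)
  expect_equal(r$seq, m)
  expect_equal(nchar(r$qual), nchar(m))

  r2 <- trim_adapter(m, q, adapter)
  expect_equal(r2$seq, m)

  # only the first 6 adapter bases present: still trimmed (minimum overlap)
  r3 <- trim_adapter(paste0(m, substr(adapter, 1, 6)),
                     strrep("I", nchar(m) + 6), adapter)
  expect_equal(r3$seq, m)

  expect_error(trim_adapter("ACGT", "IIII", "TGGAA"), "shorter")
})

test_that("adapter trimming matches the exhaustive-scan oracle on random reads", {
  set.seed(42)
  adapter <- "TGGAATTCTCGGGTGCCAAGG"
  for (i in 1:50) {
    insert <- paste(sample(c("A", "C", "G", "T"), sample(8:30, 1),
                           replace = TRUE), collapse = "")
    keep_adapter <- sample(0:nchar(adapter), 1)
    s <- paste0(insert, substr(adapter, 1, keep_adapter))
    got <- trim_adapter(s, strrep("I", nchar(s)), adapter)$seq
    expect_identical(got, bf_trim(s, adapter))
  }
})

test_that("length filter boundary is strict at 18 nt", {
  expect_false(filter_read_length(strrep("A", 17)))
  expect_true(filter_read_length(strrep("A", 18)))
  expect_true(filter_read_length(strrep("A", 25)))
})

test_that("low-complexity filter flags tandem repeats but keeps mature miRNAs", {
  expect_false(filter_low_complexity(strrep("A", 20)))
  expect_false(filter_low_complexity(strrep("AC", 9)))   # 18 nt di-repeat
  expect_false(filter_low_complexity(strrep("AGT", 7)))  # tri-repeat
  expect_true(filter_low_complexity("ACGTACGGTTCAAGCTAGCTA"))
  ref <- generate_reference(10, 0, seed = 8)
  expect_true(all(vapply(ref$mature_seq, filter_low_complexity, logical(1))))
})

test_that("read classification follows priority and tolerance rules", {
  ref <- generate_reference(5, 2, seed = 3)
  tgt <- ref$mature_seq[ref$clade_tag == "target"][1]
  con <- ref$mature_seq[ref$clade_tag == "contaminant"][1]
  expect_equal(classify_read(tgt, ref), "mirna_target")
  expect_equal(classify_read(con, ref), "mirna_contaminant")
  # one mismatch: still classified
  mut1 <- tgt
  substr(mut1, 3, 3) <- setdiff(c("A", "C", "G", "T"), substr(tgt, 3, 3))[1]
  expect_equal(classify_read(mut1, ref), "mirna_target")
  # two mismatches: unknown, confirmed against a brute-force Hamming scan
  mut2 <- mut1
  substr(mut2, 7, 7) <- setdiff(c("A", "C", "G", "T"), substr(tgt, 7, 7))[1]
  bf_min_dist <- min(vapply(ref$mature_seq, function(s) {
    n <- min(nchar(mut2), nchar(s))
    sum(strsplit(substr(mut2, 1, n), "")[[1]] !=
          strsplit(substr(s, 1, n), "")[[1]])
  }, numeric(1)))
  expect_gte(bf_min_dist, 2)
  expect_equal(classify_read(mut2, ref), "unknown")
  # length difference beyond 2 nt: unknown even with matching prefix
  expect_equal(classify_read(substr(tgt, 1, nchar(tgt) - 3), ref), "unknown")
})

test_that("sample QC reproduces generator truth and evaluates gates", {
  ref <- generate_reference(8, 2, seed = 5)
  sim <- simulate_reads(ref, c(mirna = 0.5, short = 0.5), 200, seed = 6)
  rep1 <- qc_sample(sim$reads, ref, adapter = sim$adapter,
                    other_refs = sim$other_refs)
  expect_equal(rep1$n_input, 200)
  expect_equal(rep1$n_discarded, 100)  # the short half
  expect_equal(rep1$category_tally[["mirna_target"]], 100)
  expect_true(rep1$pass)

  sim2 <- simulate_reads(ref, c(low_quality = 0.8, mirna = 0.2), 200,
                         seed = 7)
  rep2 <- qc_sample(sim2$reads, ref, adapter = sim2$adapter,
                    other_refs = sim2$other_refs)
  expect_false(rep2$pass)
  expect_true("discard_fraction" %in% rep2$fail_reasons)

  sim3 <- simulate_reads(ref, c(other_rna = 0.95, mirna = 0.05), 200,
                         seed = 8)
  rep3 <- qc_sample(sim3$reads, ref, adapter = sim3$adapter,
                    other_refs = sim3$other_refs)
  expect_false(rep3$pass)
  expect_true("mirna_fraction" %in% rep3$fail_reasons)
  expect_false("discard_fraction" %in% rep3$fail_reasons)
})

test_that("tallies are conserved on arbitrary category mixtures", {
  ref <- generate_reference(6, 2, seed = 9)
  for (seed in 1:5) {
    set.seed(seed)
    w <- runif(6)
    fr <- setNames(w / sum(w), c("mirna", "low_quality", "short",
                                 "low_complexity", "contaminant",
                                 "other_rna"))
    sim <- simulate_reads(ref, fr, 300, seed = seed)
    r <- qc_sample(sim$reads, ref, adapter = sim$adapter,
                   other_refs = sim$other_refs)
    expect_equal(r$n_input, r$n_retained + r$n_discarded)
    expect_equal(sum(r$category_tally), r$n_retained)
    g <- gates_from_truth(sim$truth)
    expect_equal(r$n_retained, g$n_retained)
    expect_equal(r$frac_20_25, g$frac_20_25)
    expect_equal(r$frac_mirna, g$frac_mirna)
    expect_equal(r$pass, g$pass)
  }
})

test_that("reads above 18 nt pre-trim but short post-trim are discarded", {
  ref <- generate_reference(3, 0, seed = 1)
  adapter <- "TGGAATTCTCGGGTGCCAAGG"
  s <- paste0("ACGTACGTACGT", adapter)  # 12 nt insert, 33 nt raw
  r <- qc_sample(data.frame(read_id = "r1", seq = s,
                            qual = strrep("I", nchar(s))),
                 ref, adapter = adapter)
  expect_equal(r$n_discarded, 1)
  expect_equal(r$n_retained, 0)
})

test_that("FASTQ round-trip preserves reads and misformatted input errors", {
  ref <- generate_reference(4, 0, seed = 2)
  sim <- simulate_reads(ref, c(mirna = 1), 20, seed = 3)
  path <- tempfile(fileext = ".fastq")
  write_fastq(sim$reads, path)
  back <- read_fastq(path)
  expect_equal(back, sim$reads)
  bad <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT"), bad)
  expect_error(read_fastq(bad), "FASTQ")
})

test_that("study gate uses the strict >50% failure boundary and contamination", {
  reports <- list(make_report(TRUE), make_report(TRUE),
                  make_report(FALSE), make_report(FALSE))
  v <- qc_study(reports)
  expect_true(v$include)  # 2/4 = 0.5, not > 0.5

  v2 <- qc_study(c(reports[1], reports[3:4], reports[3]))
  expect_false(v2$include)  # 3/4

  v3 <- qc_study(list(make_report(TRUE), make_report(TRUE, 0.4)))
  expect_false(v3$include)
  expect_true(v3$contamination_flag)

  expect_error(qc_study(list()), "empty")
})
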