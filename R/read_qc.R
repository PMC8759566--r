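## Read-level QC filters and sample-/study-level exclusion gates.
##
## Filter order is fixed: base quality -> adapter trimming -> length ->
## complexity. Gate boundaries are strict as stated: a read is discarded when
## strictly fewer than 50% of its bases exceed Phred 20; a sample fails when
## strictly fewer than 25% of retained reads are 20-25 nt, strictly more than
## 75% of input reads were discarded, or strictly fewer than 10% of retained
## reads classify as miRNA; a study is excluded when strictly more than 50%
## of its samples fail, or contamination exceeds the threshold.

#' QC configuration
#'
#' @param min_frac_q20 Minimum fraction of bases with Phred > 20 for a read
#'   to be kept (discard when strictly below).
#' @param min_length Minimum post-trimming read length (discard when strictly
#'   below).
#' @param complexity_threshold Discard when a single 1-3 nt motif, tandemly
#'   repeated, covers at least this fraction of the read.
#' @param min_overlap Minimum adapter-prefix overlap for trimming.
#' @param adapter_mismatch_rate Maximum mismatch rate within the overlap.
#' @param classify_max_mismatch Maximum mismatches (over the shorter length,
#'   5'-anchored) for read classification.
#' @param classify_max_len_diff Maximum 3' length difference for
#'   classification.
#' @param min_frac_20_25 Sample gate: minimum fraction of retained reads with
#'   length 20-25 nt.
#' @param max_discard_frac Sample gate: maximum fraction of input reads
#'   discarded.
#' @param min_mirna_frac Sample gate: minimum fraction of retained reads
#'   classified as miRNA (target or contaminant clade).
#' @param contamination_threshold Study gate: maximum fraction of classified
#'   miRNA reads from non-target clades in any sample.
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(min_frac_q20 = 0.5, min_length = 18,
                      complexity_threshold = 0.8, min_overlap = 6,
                      adapter_mismatch_rate = 0.1,
                      classify_max_mismatch = 1, classify_max_len_diff = 2,
                      min_frac_20_25 = 0.25, max_discard_frac = 0.75,
                      min_mirna_frac = 0.10, contamination_threshold = 0.10) {
  structure(as.list(environment()), class = "qc_config")
}

#' Base-quality read filter
#'
#' A read is kept iff at least half of its bases have Phred quality strictly
#' above 20 (discard iff the fraction is strictly below 0.5).
#'
#' @param qual Phred+33 quality string (one read).
#' @param config A [qc_config()].
#' @return `TRUE` to keep, `FALSE` to discard. Empty reads are discarded.
#' @export
filter_read_quality <- function(qual, config = qc_config()) {
  q <- phred_decode(qual)
  if (length(q) == 0L) return(FALSE)
  mean(q > 20) >= config$min_frac_q20
}

#' Trim the 3' adapter from a read
#'
#' Removes the read suffix starting at the leftmost position where a prefix
#' of the adapter aligns with at least `min_overlap` bases and at most
#' `adapter_mismatch_rate` mismatches (mismatch budget = floor(rate x
#' overlap)). If no position qualifies the read is returned unchanged. The
#' quality string is trimmed in lockstep.
#'
#' @param seq,qual Read sequence and Phred+33 quality string.
#' @param adapter Adapter sequence (length >= `min_overlap`).
#' @param config A [qc_config()].
#' @return List with trimmed `seq` and `qual`.
#' @export
trim_adapter <- function(seq, qual, adapter, config = qc_config()) {
  if (nchar(adapter) < config$min_overlap) {
    stop("adapter shorter than the minimum overlap (", config$min_overlap,
         ")", call. = FALSE)
  }
  L <- nchar(seq)
  a <- charToRaw(adapter)
  r <- charToRaw(seq)
  for (p in seq_len(L)) {
    ov <- min(length(a), L - p + 1L)
    if (ov < config$min_overlap) break
    mm <- sum(r[p:(p + ov - 1L)] != a[seq_len(ov)])
    if (mm <= floor(config$adapter_mismatch_rate * ov)) {
      return(list(seq = substr(seq, 1L, p - 1L),
                  qual = substr(qual, 1L, p - 1L)))
    }
  }
  list(seq = seq, qual = qual)
}

#' Post-trimming length filter
#'
#' @param seq Adapter-trimmed read sequence.
#' @param config A [qc_config()].
#' @return `TRUE` to keep (length >= 18 by default), `FALSE` to discard.
#' @export
filter_read_length <- function(seq, config = qc_config()) {
  nchar(seq) >= config$min_length
}

#' @keywords internal
#' @noRd
is_low_complexity <- function(seq, threshold = 0.8) {
  L <- nchar(seq)
  if (L == 0L) return(TRUE)
  for (k in 1:3) {
    if (L < 2L * k) next
    starts <- seq_len(L - k + 1L)
    motifs <- unique(substring(seq, starts, starts + k - 1L))
    for (m in motifs) {
      hits <- gregexpr(paste0("(?:", m, ")+"), seq, perl = TRUE)[[1]]
      if (hits[1] == -1) next
      if (max(attr(hits, "match.length")) / L >= threshold) return(TRUE)
    }
  }
  FALSE
}

#' Low-complexity read filter
#'
#' Discards reads in which a single 1-, 2- or 3-nt motif, tandemly repeated,
#' covers at least the configured fraction (default 80%) of the read — a
#' deterministic proxy for the repetitive-element artifact class.
#'
#' @param seq Trimmed read sequence.
#' @param config A [qc_config()].
#' @return `TRUE` to keep, `FALSE` to discard.
#' @export
filter_low_complexity <- function(seq, config = qc_config()) {
  !is_low_complexity(seq, config$complexity_threshold)
}

#' Classify retained reads against miRNA and other-RNA references
#'
#' A read is assigned the first class (priority `mirna_target` >
#' `mirna_contaminant` > `other_rna`) for which it matches some reference
#' sequence 5'-anchored with at most `classify_max_mismatch` mismatches over
#' the shorter length and at most `classify_max_len_diff` nt of 3' length
#' difference; otherwise `unknown`.
#'
#' @param seqs Character vector of trimmed, retained read sequences.
#' @param refs Reference table from [generate_reference()] (columns
#'   `annotation_id`, `mature_seq`, `clade_tag`).
#' @param other_refs Optional named character vector of non-miRNA reference
#'   sequences (rRNA/tRNA fragments etc.).
#' @param config A [qc_config()].
#' @return Character vector of categories, one per read.
#' @export
classify_read <- function(seqs, refs, other_refs = character(0),
                          config = qc_config()) {
  n <- length(seqs)
  out <- rep("unknown", n)
  if (n == 0L) return(out)
  match_ref <- function(ref_seqs) {
    hit <- rep(FALSE, n)
    lens <- nchar(seqs)
    for (rs in ref_seqs) {
      lr <- nchar(rs)
      cand <- which(!hit & abs(lens - lr) <= config$classify_max_len_diff)
      for (i in cand) {
        if (hamming_prefix(seqs[i], rs) <= config$classify_max_mismatch) {
          hit[i] <- TRUE
        }
      }
    }
    hit
  }
  tgt <- match_ref(refs$mature_seq[refs$clade_tag == "target"])
  out[tgt] <- "mirna_target"
  con <- match_ref(refs$mature_seq[refs$clade_tag == "contaminant"])
  out[out == "unknown" & con] <- "mirna_contaminant"
  if (length(other_refs) > 0) {
    oth <- match_ref(other_refs)
    out[out == "unknown" & oth] <- "other_rna"
  }
  out
}

#' Run sample-level QC
#'
#' Applies the quality, adapter-trimming, length and complexity filters in
#' that order, classifies the retained reads, and evaluates the three sample
#' gates: fraction of retained reads with length 20-25 nt (fail when < 25%),
#' fraction of input reads discarded (fail when > 75%), and fraction of
#' retained reads classified as miRNA (fail when < 10%).
#'
#' @param reads A read table (`data.frame` with `read_id`, `seq`, `qual`) or
#'   a path to a FASTQ file.
#' @param refs miRNA reference table.
#' @param adapter 3' adapter sequence.
#' @param other_refs Optional non-miRNA reference sequences for
#'   classification.
#' @param config A [qc_config()].
#' @param sample_id Sample label for the report.
#' @return A list of class `qc_report`: `sample_id`, `n_input`,
#'   `n_discarded`, `n_retained`, `frac_20_25`, `frac_mirna`,
#'   `category_tally`, `contamination_frac`, `pass`, `fail_reasons`, plus the
#'   retained trimmed reads (`retained`, a `data.frame` with `read_id`,
#'   `seq`, `qual`, `category`) for downstream counting.
#' @export
qc_sample <- function(reads, refs, adapter = DEFAULT_ADAPTER,
                      other_refs = character(0), config = qc_config(),
                      sample_id = "sample") {
  if (is.character(reads) && length(reads) == 1L) reads <- read_fastq(reads)
  stopifnot(is.data.frame(reads), all(c("read_id", "seq", "qual") %in%
                                        names(reads)))
  n_input <- nrow(reads)
  keep_q <- vapply(reads$qual, filter_read_quality, logical(1),
                   config = config, USE.NAMES = FALSE)
  kept <- reads[keep_q, , drop = FALSE]
  if (nrow(kept) > 0) {
    trimmed <- lapply(seq_len(nrow(kept)), function(i) {
      trim_adapter(kept$seq[i], kept$qual[i], adapter, config)
    })
    kept$seq <- vapply(trimmed, `[[`, character(1), "seq")
    kept$qual <- vapply(trimmed, `[[`, character(1), "qual")
  }
  keep_len <- vapply(kept$seq, filter_read_length, logical(1),
                     config = config, USE.NAMES = FALSE)
  kept <- kept[keep_len, , drop = FALSE]
  keep_cx <- vapply(kept$seq, filter_low_complexity, logical(1),
                    config = config, USE.NAMES = FALSE)
  kept <- kept[keep_cx, , drop = FALSE]

  n_retained <- nrow(kept)
  n_discarded <- n_input - n_retained
  categories <- classify_read(kept$seq, refs, other_refs, config)
  kept$category <- categories
  tally <- table(factor(categories, levels = c("mirna_target",
                                               "mirna_contaminant",
                                               "other_rna", "unknown")))
  n_mirna <- sum(tally[c("mirna_target", "mirna_contaminant")])
  frac_20_25 <- if (n_retained > 0) {
    mean(nchar(kept$seq) >= 20 & nchar(kept$seq) <= 25)
  } else 0
  frac_mirna <- if (n_retained > 0) n_mirna / n_retained else 0
  contamination_frac <- if (n_mirna > 0) {
    as.numeric(tally["mirna_contaminant"]) / n_mirna
  } else 0

  fail <- character(0)
  if (frac_20_25 < config$min_frac_20_25) fail <- c(fail, "length_fraction")
  if (n_input > 0 && n_discarded / n_input > config$max_discard_frac) {
    fail <- c(fail, "discard_fraction")
  }
  if (frac_mirna < config$min_mirna_frac) fail <- c(fail, "mirna_fraction")

  structure(list(
    sample_id = sample_id, n_input = n_input, n_discarded = n_discarded,
    n_retained = n_retained, frac_20_25 = frac_20_25,
    frac_mirna = frac_mirna,
    category_tally = setNames(as.integer(tally), names(tally)),
    contamination_frac = contamination_frac,
    pass = length(fail) == 0, fail_reasons = fail,
    retained = kept
  ), class = "qc_report")
}

#' Study-level QC verdict
#'
#' A study is excluded when strictly more than half of its samples failed
#' sample-level QC, or when any sample shows contamination (fraction of
#' classified miRNA reads from non-target clades) above the configured
#' threshold.
#'
#' @param reports List of [qc_sample()] reports from one study.
#' @param config A [qc_config()].
#' @param study_id Study label.
#' @return List of class `study_verdict`: `study_id`, `n_samples`,
#'   `n_failed`, `contamination_flag`, `include`.
#' @export
qc_study <- function(reports, config = qc_config(), study_id = "study") {
  if (length(reports) == 0) stop("empty report list", call. = FALSE)
  n <- length(reports)
  n_failed <- sum(!vapply(reports, `[[`, logical(1), "pass"))
  contam <- any(vapply(reports, `[[`, numeric(1), "contamination_frac") >
                  config$contamination_threshold)
  structure(list(
    study_id = study_id, n_samples = n, n_failed = n_failed,
    contamination_flag = contam,
    include = (n_failed / n <= 0.5) && !contam
  ), class = "study_verdict")
}

#' Flatten QC reports to a table
#'
#' @param reports List of [qc_sample()] reports.
#' @return One row per sample with the gate quantities and verdict.
#' @export
qc_report_table <- function(reports) {
  do.call(rbind, lapply(reports, function(r) {
    data.frame(sample_id = r$sample_id, n_input = r$n_input,
               n_discarded = r$n_discarded, n_retained = r$n_retained,
               frac_20_25 = r$frac_20_25, frac_mirna = r$frac_mirna,
               contamination_frac = r$contamination_frac, pass = r$pass,
               fail_reasons = paste(r$fail_reasons, collapse = ";"),
               stringsAsFactors = FALSE)
  }))
}
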