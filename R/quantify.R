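## Annotation merging and read counting.
##
## Mature miRNA genes with near-identical sequences cross-map, so they are
## merged into one annotation before counting: two annotations are related
## when their mature sequences differ by at most `max_mismatch` positions
## over the shorter length (5'-aligned) and by at most `max_len_diff` nt of
## 3' length difference (identical sequences and sub/superstrings with <= 2
## nt 3' difference are special cases of this relation). Connected components
## of the relation become merged groups.

#' Merge configuration
#'
#' @param max_mismatch Maximum Hamming distance over the shorter length.
#' @param max_len_diff Maximum 3' length difference.
#' @return A list of class `merge_config`.
#' @export
merge_config <- function(max_mismatch = 1, max_len_diff = 2) {
  structure(list(max_mismatch = max_mismatch, max_len_diff = max_len_diff),
            class = "merge_config")
}

#' Merge near-identical miRNA annotations
#'
#' Union-find over the sequence-similarity relation; each connected component
#' becomes one merged annotation whose `group_id` is its member ids sorted
#' lexicographically and joined by "/", and whose representative sequence is
#' the longest member sequence (ties broken by annotation id order).
#'
#' @param refs Reference table (`annotation_id`, `mature_seq`, unique ids).
#' @param config A [merge_config()].
#' @return `data.frame` with columns `group_id`, `members` (list column),
#'   `representative_seq`, `n_members`.
#' @export
merge_annotations <- function(refs, config = merge_config()) {
  if (anyDuplicated(refs$annotation_id)) {
    stop("duplicate annotation ids", call. = FALSE)
  }
  n <- nrow(refs)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  lens <- nchar(refs$mature_seq)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq((i + 1), n)) {
        if (abs(lens[i] - lens[j]) > config$max_len_diff) next
        if (hamming_prefix(refs$mature_seq[i], refs$mature_seq[j]) <=
            config$max_mismatch) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  groups <- split(seq_len(n), comp)
  out <- do.call(rbind, lapply(groups, function(idx) {
    ids <- sort(refs$annotation_id[idx])
    ord <- idx[order(-lens[idx], refs$annotation_id[idx])]
    data.frame(group_id = paste(ids, collapse = "/"),
               representative_seq = refs$mature_seq[ord[1]],
               n_members = length(idx), stringsAsFactors = FALSE)
  }))
  out$members <- lapply(groups, function(idx) sort(refs$annotation_id[idx]))
  out <- out[order(out$group_id), c("group_id", "members",
                                    "representative_seq", "n_members")]
  rownames(out) <- NULL
  out
}

#' Count retained reads against merged annotations
#'
#' Each read increments exactly one merged group when it matches exactly one
#' group's representative sequence under the classification tolerance
#' (5'-anchored, <= 1 mismatch over the shorter length, <= 2 nt 3' length
#' difference by default). Reads matching two or more groups are tallied as
#' `ambiguous` and dropped; reads matching none are tallied as `unassigned`.
#'
#' @param seqs Character vector of QC-retained, trimmed read sequences.
#' @param merged Output of [merge_annotations()].
#' @param config A [qc_config()] (supplies the match tolerance).
#' @return List with `counts` (named integer vector over group ids),
#'   `ambiguous` and `unassigned` tallies.
#' @export
count_reads <- function(seqs, merged, config = qc_config()) {
  if (nrow(merged) == 0) stop("empty merged reference", call. = FALSE)
  counts <- setNames(integer(nrow(merged)), merged$group_id)
  ambiguous <- 0L; unassigned <- 0L
  if (length(seqs) > 0) {
    lens <- nchar(seqs)
    rlens <- nchar(merged$representative_seq)
    for (i in seq_along(seqs)) {
      cand <- which(abs(lens[i] - rlens) <= config$classify_max_len_diff)
      hits <- cand[vapply(cand, function(g) {
        hamming_prefix(seqs[i], merged$representative_seq[g]) <=
          config$classify_max_mismatch
      }, logical(1))]
      if (length(hits) == 1L) {
        counts[hits] <- counts[hits] + 1L
      } else if (length(hits) >= 2L) {
        ambiguous <- ambiguous + 1L
      } else {
        unassigned <- unassigned + 1L
      }
    }
  }
  list(counts = counts, ambiguous = ambiguous, unassigned = unassigned)
}

#' Reads per million mapped miRNA reads
#'
#' @param counts Non-negative numeric vector (at least one nonzero entry).
#' @return `counts / sum(counts) * 1e6`.
#' @export
rpm <- function(counts) {
  if (all(counts == 0)) stop("all-zero count vector", call. = FALSE)
  counts / sum(counts) * 1e6
}

#' Per-sample RPM matrix
#'
#' @param counts miRNA-by-sample count matrix (or [mirna_counts]).
#' @return Matrix of the same shape with each column scaled to 1e6.
#' @export
rpm_matrix <- function(counts) {
  if (inherits(counts, "mirna_counts")) counts <- counts$counts
  apply(counts, 2, rpm)
}
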