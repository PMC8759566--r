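## Synthetic-data generators with planted truth.
##
## Every generator is a pure function of its arguments including `seed`, so
## downstream recovery tests are reproducible and read truth only from the
## returned truth tables, never from generator internals.

DEFAULT_ADAPTER <- "TGGAATTCTCGGGTGCCAAGG"

READ_CATEGORIES <- c("mirna", "low_quality", "short", "low_complexity",
                     "contaminant", "other_rna")

#' Generate a synthetic mature-miRNA reference
#'
#' Creates a set of mature miRNA reference records with unique annotation ids,
#' random mature sequences of 20-23 nt over ACGT, and clade tags separating
#' analysis targets (e.g. human) from contaminant clades (e.g. rodent spike-in
#' carry-over). Sequences are rejection-sampled so that any two records differ
#' at >= `min_hamming` positions over their first 18 nt, which makes read
#' classification and annotation merging behave predictably; near-duplicate
#' pairs for exercising annotation merging must be requested explicitly.
#'
#' @param n_target Number of target-clade miRNAs (>= 1).
#' @param n_contaminant Number of contaminant-clade miRNAs.
#' @param seed Integer seed.
#' @param min_hamming Minimum pairwise Hamming distance (over the first 18 nt)
#'   enforced between generated sequences.
#' @param near_duplicates Number of additional target records generated as
#'   single-mismatch 3'-variants of the first targets (annotation ids suffixed
#'   `-v`); these intentionally violate `min_hamming` so that
#'   [merge_annotations()] has something to merge.
#' @param celltype_labels Optional character vector (length `n_target`) of
#'   cell-type labels; default `"none"` for all.
#' @return `data.frame` with columns `annotation_id`, `mature_seq`,
#'   `clade_tag`, `celltype_label`.
#' @export
generate_reference <- function(n_target, n_contaminant = 0, seed = 1,
                               min_hamming = 3, near_duplicates = 0,
                               celltype_labels = NULL) {
  if (n_target < 1) stop("n_target must be >= 1", call. = FALSE)
  stopifnot(n_contaminant >= 0, near_duplicates >= 0,
            near_duplicates <= n_target)
  set.seed(as.integer(seed))
  n <- n_target + n_contaminant
  seqs <- character(0)
  while (length(seqs) < n) {
    cand <- random_seq(sample(20:23, 1))
    ok <- !is_low_complexity(cand) &&
      (length(seqs) == 0 ||
         all(vapply(seqs, function(s) {
           sum(charToRaw(substr(cand, 1, 18)) != charToRaw(substr(s, 1, 18)))
         }, integer(1)) >= min_hamming))
    if (ok) seqs <- c(seqs, cand)
  }
  ref <- data.frame(
    annotation_id = c(sprintf("Mir-%d_5p", seq_len(n_target)),
                      if (n_contaminant > 0)
                        sprintf("Xeno-Mir-%d_3p", seq_len(n_contaminant))),
    mature_seq = seqs,
    clade_tag = rep(c("target", "contaminant"), c(n_target, n_contaminant)),
    celltype_label = "none",
    stringsAsFactors = FALSE
  )
  if (!is.null(celltype_labels)) {
    stopifnot(length(celltype_labels) == n_target)
    ref$celltype_label[seq_len(n_target)] <- celltype_labels
  }
  if (near_duplicates > 0) {
    dup <- ref[seq_len(near_duplicates), , drop = FALSE]
    for (i in seq_len(near_duplicates)) {
      s <- dup$mature_seq[i]
      pos <- nchar(s)  # mutate the 3' terminal base: a 1-mismatch variant
      base <- substr(s, pos, pos)
      substr(s, pos, pos) <- sample(setdiff(c("A", "C", "G", "T"), base), 1)
      dup$mature_seq[i] <- s
      dup$annotation_id[i] <- paste0(dup$annotation_id[i], "-v")
    }
    ref <- rbind(ref, dup)
  }
  ref
}

## --- count simulation ------------------------------------------------------

#' Construct a simulation design for synthetic tissue count matrices
#'
#' A design bundles everything [simulate_counts()] needs: tissue group sizes,
#' per-cell-type expression programs, per-tissue cell-type mixing proportions,
#' planted metastasis and normal-background log2 effects, NB dispersions and
#' the library-size range.
#'
#' @param tissues `data.frame` with columns `tissue`, `n` (group sizes >= 2).
#' @param programs Numeric matrix, miRNAs x cell types, of baseline mean
#'   expression on the RPM scale (>= 0, rows named by miRNA).
#' @param mixing Numeric matrix, tissues x cell types; each row sums to 1.
#' @param met_effects `data.frame(mirna, tissue, lfc)` of planted
#'   metastasis-associated log2 effects, applied to that tissue only.
#' @param bg_effects `data.frame(mirna, site, lfc)` with `site` in
#'   `{"Li","Lu"}` of planted normal-background log2 effects; an effect for
#'   site Li is applied to nLi, mLi and PM samples (and Lu correspondingly),
#'   emulating tissue-composition signal that contaminates bulk metastasis
#'   samples and must be filtered out downstream.
#' @param dispersion NB dispersion alpha (variance = mu + alpha mu^2); scalar
#'   or per-miRNA vector; `0` degenerates to Poisson.
#' @param libsize_range Length-2 numeric, uniform range of per-sample totals.
#' @param dirichlet_conc Concentration of the per-sample Dirichlet mixing draw
#'   (larger = more homogeneous tissues; `Inf` = fixed proportions).
#' @param seed Integer seed.
#' @return A list of class `simulation_design`.
#' @export
simulation_design <- function(tissues, programs, mixing,
                              met_effects = NULL, bg_effects = NULL,
                              dispersion = 0.1,
                              libsize_range = c(5e5, 2e6),
                              dirichlet_conc = 200, seed = 1) {
  stopifnot(is.data.frame(tissues), all(c("tissue", "n") %in% names(tissues)))
  if (nrow(tissues) == 0) stop("empty tissue list", call. = FALSE)
  if (any(tissues$n < 2)) stop("all group sizes must be >= 2", call. = FALSE)
  programs <- as.matrix(programs)
  if (any(programs < 0)) stop("baseline means must be >= 0", call. = FALSE)
  mixing <- as.matrix(mixing)
  stopifnot(identical(sort(rownames(mixing)), sort(tissues$tissue)),
            ncol(mixing) == ncol(programs))
  if (any(abs(rowSums(mixing) - 1) > 1e-8)) {
    stop("mixing proportions per tissue must sum to 1", call. = FALSE)
  }
  if (any(dispersion < 0)) stop("dispersions must be >= 0", call. = FALSE)
  disp <- rep_len(dispersion, nrow(programs))
  names(disp) <- rownames(programs)
  structure(list(tissues = tissues, programs = programs, mixing = mixing,
                 met_effects = met_effects, bg_effects = bg_effects,
                 dispersion = disp, libsize_range = libsize_range,
                 dirichlet_conc = dirichlet_conc, seed = as.integer(seed)),
            class = "simulation_design")
}

#' Default study-like simulation design
#'
#' Builds a design emulating the tissue panel of the study: primary colorectal
#' cancer (pCRC), normal colorectum (nCR), liver and lung metastases with
#' adjacent normals (mLi/nLi, mLu/nLu) and peritoneal metastases (PM). Tissue
#' profiles are mixtures of five cell-type programs (epithelial, hepatocyte,
#' pneumocyte, immune, stromal), so cell-type-specific miRNAs differ across
#' tissues: normal liver is hepatocyte-dominated, normal lung
#' pneumocyte-dominated, and the tumour tissues epithelial-dominated.
#'
#' @param n_mirna Number of miRNAs (>= 20).
#' @param n_per_tissue Samples per tissue group.
#' @param frac_celltype Fraction of miRNAs made cell-type specific.
#' @param met_effects,bg_effects Planted effects, as in [simulation_design()].
#' @param dispersion,libsize_range,dirichlet_conc,seed As in
#'   [simulation_design()].
#' @return A `simulation_design` with a `celltype_specific` attribute
#'   (`data.frame(mirna, celltype)`).
#' @export
default_design <- function(n_mirna = 300, n_per_tissue = 12,
                           frac_celltype = 0.1,
                           met_effects = NULL, bg_effects = NULL,
                           dispersion = 0.1, libsize_range = c(5e5, 2e6),
                           dirichlet_conc = 200, seed = 1) {
  stopifnot(n_mirna >= 20)
  set.seed(derive_seed(seed, 11))
  celltypes <- c("epithelial", "hepatocyte", "pneumocyte", "immune", "stromal")
  mirnas <- sprintf("Mir-%d_5p", seq_len(n_mirna))
  # broad program: shared log-normal baseline with mild cell-type wobble
  base <- rlnorm(n_mirna, meanlog = log(800), sdlog = 1.4)
  programs <- matrix(base, n_mirna, length(celltypes),
                     dimnames = list(mirnas, celltypes))
  programs <- programs * matrix(rlnorm(length(programs), 0, 0.2),
                                n_mirna, length(celltypes))
  # cell-type-specific miRNAs: high in one program, near-zero elsewhere
  n_ct <- round(frac_celltype * n_mirna)
  ct_idx <- sample.int(n_mirna, n_ct)
  ct_assign <- sample(celltypes, n_ct, replace = TRUE)
  for (k in seq_len(n_ct)) {
    programs[ct_idx[k], ] <- 5
    programs[ct_idx[k], ct_assign[k]] <- rlnorm(1, log(8000), 0.5)
  }
  tissues <- data.frame(
    tissue = c("pCRC", "nCR", "mLi", "nLi", "mLu", "nLu", "PM"),
    n = n_per_tissue
  )
  mixing <- rbind(
    pCRC = c(0.55, 0.025, 0.025, 0.20, 0.20),
    nCR  = c(0.45, 0.025, 0.025, 0.25, 0.25),
    mLi  = c(0.45, 0.25, 0.01, 0.14, 0.15),
    nLi  = c(0.05, 0.70, 0.01, 0.14, 0.10),
    mLu  = c(0.45, 0.01, 0.25, 0.14, 0.15),
    nLu  = c(0.05, 0.01, 0.60, 0.19, 0.15),
    PM   = c(0.50, 0.01, 0.01, 0.23, 0.25)
  )
  colnames(mixing) <- celltypes
  d <- simulation_design(tissues, programs, mixing,
                         met_effects = met_effects, bg_effects = bg_effects,
                         dispersion = dispersion,
                         libsize_range = libsize_range,
                         dirichlet_conc = dirichlet_conc, seed = seed)
  attr(d, "celltype_specific") <- data.frame(
    mirna = mirnas[ct_idx], celltype = ct_assign, stringsAsFactors = FALSE)
  d
}

#' @keywords internal
#' @noRd
rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (all(g == 0)) g[which.max(alpha)] <- 1
  g / sum(g)
}

#' Simulate a miRNA count matrix with planted truth
#'
#' Draws, for each sample, cell-type mixing proportions from a Dirichlet
#' around its tissue's mixing vector, forms the expected expression profile as
#' the mixture of cell-type programs, multiplies in the planted log2 effects
#' for that tissue, rescales to a library size drawn uniformly from the
#' design's range, and draws NB counts (variance = mu + alpha mu^2).
#'
#' @param design A [simulation_design()].
#' @return A list with elements `counts` (a [mirna_counts]) and `truth`, a
#'   list with `met_de` (`data.frame(mirna, site, sign)`), `bg_de`
#'   (`data.frame(mirna, site, sign)` with site in `{"Li","Lu"}`),
#'   `celltype_specific` and `suppressed_gene_sets` (empty; filled by the
#'   caller before [simulate_interactions_and_sets()]).
#' @export
simulate_counts <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  set.seed(derive_seed(design$seed, 23))
  tis <- design$tissues
  P <- design$programs
  mirnas <- rownames(P)
  sample_tissue <- rep(tis$tissue, tis$n)
  sample_id <- unlist(lapply(seq_len(nrow(tis)), function(i) {
    sprintf("%s_%02d", tis$tissue[i], seq_len(tis$n[i]))
  }))
  n_s <- length(sample_id)

  # per-sample effect multipliers from planted effects
  eff <- matrix(1, nrow(P), n_s, dimnames = list(mirnas, sample_id))
  me <- design$met_effects
  if (!is.null(me) && nrow(me) > 0) {
    for (k in seq_len(nrow(me))) {
      j <- sample_tissue == me$tissue[k]
      eff[me$mirna[k], j] <- eff[me$mirna[k], j] * 2^me$lfc[k]
    }
  }
  be <- design$bg_effects
  if (!is.null(be) && nrow(be) > 0) {
    for (k in seq_len(nrow(be))) {
      affected <- c(paste0(c("n", "m"), be$site[k]), "PM")
      j <- sample_tissue %in% affected
      eff[be$mirna[k], j] <- eff[be$mirna[k], j] * 2^be$lfc[k]
    }
  }

  counts <- matrix(0L, nrow(P), n_s, dimnames = list(mirnas, sample_id))
  alpha <- design$dispersion
  for (j in seq_len(n_s)) {
    mix0 <- design$mixing[sample_tissue[j], ]
    w <- if (is.finite(design$dirichlet_conc)) {
      rdirichlet1(design$dirichlet_conc * mix0)
    } else mix0
    mu_raw <- as.vector(P %*% w) * eff[, j]
    L <- runif(1, design$libsize_range[1], design$libsize_range[2])
    mu <- mu_raw / sum(mu_raw) * L
    pois <- alpha <= 0
    y <- integer(nrow(P))
    if (any(pois)) y[pois] <- rpois(sum(pois), mu[pois])
    if (any(!pois)) {
      y[!pois] <- rnbinom(sum(!pois), mu = mu[!pois], size = 1 / alpha[!pois])
    }
    counts[, j] <- y
  }
  meta <- data.frame(sample_id = sample_id, tissue = sample_tissue,
                     study = "synthetic", stringsAsFactors = FALSE)
  truth <- list(
    met_de = if (is.null(me)) empty_effect_table() else
      data.frame(mirna = me$mirna, site = me$tissue, sign = sign(me$lfc),
                 stringsAsFactors = FALSE),
    bg_de = if (is.null(be)) empty_effect_table() else
      data.frame(mirna = be$mirna, site = be$site, sign = sign(be$lfc),
                 stringsAsFactors = FALSE),
    celltype_specific = attr(design, "celltype_specific"),
    suppressed_gene_sets = character(0)
  )
  list(counts = mirna_counts(counts, meta), truth = truth)
}

#' @keywords internal
#' @noRd
empty_effect_table <- function() {
  data.frame(mirna = character(0), site = character(0), sign = numeric(0),
             stringsAsFactors = FALSE)
}

## --- read simulation -------------------------------------------------------

#' @keywords internal
#' @noRd
high_qual <- function(len) phred_encode(sample(33:40, len, replace = TRUE))

#' Simulate a small-RNA-seq read population
#'
#' Generates `n_reads` reads split over six categories whose per-category
#' counts equal `round(fraction * n_reads)` under largest-remainder rounding,
#' exactly. Categories: `mirna` (a target mature sequence with up to 2 nt of
#' 3' truncation/extension, kept within 18-25 nt, plus the 3' adapter, high
#' quality), `low_quality` (>50% of bases at Phred <= 20), `short` (<18 nt
#' insert), `low_complexity` (mono-/di-nucleotide tandem repeats),
#' `contaminant` (mature sequences from contaminant-clade references) and
#' `other_rna` (fragments of a small set of non-miRNA reference sequences,
#' returned so the classifier can recognize them).
#'
#' @param ref Reference from [generate_reference()].
#' @param fractions Named numeric over (a subset of) the six categories,
#'   summing to 1 (+- 1e-9).
#' @param n_reads Number of reads (>= 1).
#' @param adapter 3' adapter sequence appended to every insert.
#' @param seed Integer seed.
#' @return List with `reads` (`data.frame(read_id, seq, qual)`), `truth`
#'   (`data.frame(read_id, category, insert_len)`; the sidecar truth table),
#'   `other_refs` (named character vector of non-miRNA reference sequences)
#'   and `adapter`.
#' @export
simulate_reads <- function(ref, fractions, n_reads,
                           adapter = DEFAULT_ADAPTER, seed = 1) {
  stopifnot(n_reads >= 1)
  if (!all(names(fractions) %in% READ_CATEGORIES)) {
    stop("unknown read category: ",
         paste(setdiff(names(fractions), READ_CATEGORIES), collapse = ", "),
         call. = FALSE)
  }
  fr <- setNames(numeric(length(READ_CATEGORIES)), READ_CATEGORIES)
  fr[names(fractions)] <- fractions
  if (abs(sum(fr) - 1) > 1e-9) {
    stop("category fractions must sum to 1", call. = FALSE)
  }
  set.seed(derive_seed(seed, 37))
  n_cat <- setNames(largest_remainder(fr, n_reads), READ_CATEGORIES)
  targets <- ref[ref$clade_tag == "target", , drop = FALSE]
  contams <- ref[ref$clade_tag == "contaminant", , drop = FALSE]
  if (n_cat["contaminant"] > 0 && nrow(contams) == 0) {
    stop("contaminant reads requested but reference has no contaminant clade",
         call. = FALSE)
  }

  # non-miRNA RNA references (tRNA/rRNA fragment stand-ins), kept away from
  # the miRNA references so classification is unambiguous
  other_refs <- character(0)
  while (length(other_refs) < 5) {
    cand <- random_seq(sample(20:24, 1))
    near <- any(vapply(ref$mature_seq, function(s) {
      abs(nchar(cand) - nchar(s)) <= 2 && hamming_prefix(cand, s) <= 1
    }, logical(1)))
    if (!near && !is_low_complexity(cand)) {
      other_refs <- c(other_refs, cand)
    }
  }
  names(other_refs) <- sprintf("otherRNA-%d", seq_along(other_refs))

  one_mirna_read <- function(pool) {
    i <- sample.int(nrow(pool), 1)
    m <- pool$mature_seq[i]
    len <- nchar(m)
    dmin <- max(-2L, 18L - len); dmax <- min(2L, 25L - len)
    d <- sample(seq(dmin, dmax), 1)
    insert <- if (d < 0) substr(m, 1, len + d) else if (d > 0)
      paste0(m, random_seq(d)) else m
    insert
  }
  make <- list(
    mirna = function() one_mirna_read(targets),
    contaminant = function() one_mirna_read(contams),
    short = function() random_seq(sample(10:17, 1)),
    low_complexity = function() {
      motif <- sample(c("A", "T", "G", "C", "AC", "AG", "CT", "GT"), 1)
      strtrim(strrep(motif, 30), sample(18:25, 1))
    },
    other_rna = function() other_refs[[sample.int(length(other_refs), 1)]],
    low_quality = function() random_seq(22)
  )

  cat_vec <- rep(READ_CATEGORIES, n_cat[READ_CATEGORIES])
  cat_vec <- sample(cat_vec)
  seqs <- character(n_reads); quals <- character(n_reads)
  insert_len <- integer(n_reads)
  for (i in seq_len(n_reads)) {
    insert <- make[[cat_vec[i]]]()
    insert_len[i] <- nchar(insert)
    s <- paste0(insert, adapter)
    if (cat_vec[i] == "low_quality") {
      L <- nchar(s)
      n_bad <- ceiling(runif(1, 0.55, 0.9) * L)
      q <- sample(30:40, L, replace = TRUE)
      q[sample.int(L, n_bad)] <- sample(2:15, n_bad, replace = TRUE)
      quals[i] <- phred_encode(q)
    } else {
      quals[i] <- high_qual(nchar(s))
    }
    seqs[i] <- s
  }
  ids <- sprintf("read_%06d", seq_len(n_reads))
  list(
    reads = data.frame(read_id = ids, seq = seqs, qual = quals,
                       stringsAsFactors = FALSE),
    truth = data.frame(read_id = ids, category = cat_vec,
                       insert_len = insert_len, stringsAsFactors = FALSE),
    other_refs = other_refs,
    adapter = adapter
  )
}

## --- interactions and gene sets --------------------------------------------

#' Simulate a miRNA-target interaction map and gene-set collection
#'
#' Builds a gene universe, random gene sets, and a predicted miRNA-to-mRNA
#' interaction table. Genes in sets listed in `truth$suppressed_gene_sets` are
#' preferentially targeted by the miRNAs planted as up-regulated in
#' `truth$met_de`, so that downstream enrichment scoring should flag those
#' sets as more suppressed; all other links are uniform at random.
#'
#' @param n_genes Universe size (>= 10).
#' @param ref Reference from [generate_reference()]; target-clade miRNAs form
#'   the interaction map's miRNA side.
#' @param truth Truth list from [simulate_counts()], with
#'   `suppressed_gene_sets` set to ids among `sprintf("set%02d", 1:n_sets)`.
#' @param seed Integer seed.
#' @param n_sets,set_size Number and size of gene sets.
#' @param targets_per_mirna Number of uniform targets per miRNA; the default
#'   (20% of the universe) mirrors the density of predicted-interaction maps,
#'   where each miRNA targets a sizeable fraction of all genes. Dense maps
#'   keep per-gene scores continuous rather than separable.
#' @param enrich_prob Probability that an up-regulated planted miRNA targets
#'   each member of a suppressed set.
#' @return List with `interactions` (`data.frame(mirna_id, gene_id)`), `sets`
#'   (named list of gene vectors) and `genes` (the universe).
#' @export
simulate_interactions_and_sets <- function(n_genes, ref, truth, seed = 1,
                                           n_sets = 50, set_size = 20,
                                           targets_per_mirna =
                                             round(0.2 * n_genes),
                                           enrich_prob = 0.8) {
  if (n_genes < 10) stop("n_genes must be >= 10", call. = FALSE)
  up <- unique(truth$met_de$mirna[truth$met_de$sign > 0])
  if (length(truth$suppressed_gene_sets) > 0 && length(up) == 0) {
    stop("suppressed gene sets planted but no up-regulated miRNA in truth",
         call. = FALSE)
  }
  set.seed(derive_seed(seed, 53))
  genes <- sprintf("g%04d", seq_len(n_genes))
  set_ids <- sprintf("set%02d", seq_len(n_sets))
  sets <- setNames(lapply(set_ids, function(s) sample(genes, set_size)),
                   set_ids)
  stopifnot(all(truth$suppressed_gene_sets %in% set_ids))
  mirnas <- ref$annotation_id[ref$clade_tag == "target"]
  inter <- do.call(rbind, lapply(mirnas, function(m) {
    tg <- sample(genes, min(targets_per_mirna, n_genes))
    data.frame(mirna_id = m, gene_id = tg, stringsAsFactors = FALSE)
  }))
  for (sid in truth$suppressed_gene_sets) {
    for (m in up) {
      hit <- sets[[sid]][runif(set_size) < enrich_prob]
      if (length(hit) > 0) {
        inter <- rbind(inter, data.frame(mirna_id = m, gene_id = hit,
                                         stringsAsFactors = FALSE))
      }
    }
  }
  inter <- unique(inter)
  rownames(inter) <- NULL
  list(interactions = inter, sets = sets, genes = genes)
}

## --- qPCR ------------------------------------------------------------------

#' Simulate a qPCR Cq table for a target and a reference assay
#'
#' Two groups (`case`, `control`) of `n_per_group` samples, each measured for
#' a `target` and a `reference` assay with 2 PCR replicates per assay. A
#' sample-level plate/input shift is shared between assays (it cancels in the
#' delta-Cq), sample-level biological noise with standard deviation `sd` acts
#' on the target assay, and the expected case-minus-control difference in
#' delta-Cq equals `delta` (negative delta = higher target expression in
#' cases).
#'
#' @param n_per_group Samples per group (>= 2).
#' @param delta Expected group difference in delta-Cq (cycles).
#' @param sd Sample-level standard deviation of the target signal (> 0).
#' @param seed Integer seed.
#' @param base_target,base_reference Baseline Cq levels.
#' @param replicate_sd Technical replicate standard deviation.
#' @return `data.frame(sample_id, group, assay, replicate, cq)`.
#' @export
simulate_qpcr <- function(n_per_group = 11, delta = -1, sd = 1, seed = 1,
                          base_target = 25, base_reference = 20,
                          replicate_sd = 0.1) {
  stopifnot(n_per_group >= 2)
  if (sd <= 0) stop("sd must be > 0", call. = FALSE)
  set.seed(derive_seed(seed, 71))
  rows <- list()
  for (grp in c("case", "control")) {
    for (i in seq_len(n_per_group)) {
      sid <- sprintf("%s_%02d", grp, i)
      shift <- rnorm(1, 0, 0.3)                     # cancels in dCq
      u <- rnorm(1, 0, sd)                          # biological noise
      t_level <- base_target + (grp == "case") * delta + u + shift
      r_level <- base_reference + shift
      for (r in 1:2) {
        rows[[length(rows) + 1]] <- data.frame(
          sample_id = sid, group = grp,
          assay = c("target", "reference"),
          replicate = r,
          cq = c(t_level, r_level) + rnorm(2, 0, replicate_sd),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
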