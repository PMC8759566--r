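## Normal-tissue background correction of site-specific DE calls.
##
## Sign-orientation convention, fixed throughout: positive = higher at the
## metastatic / normal-site organ. Foreground contrasts are run as
## (metastasis vs pCRC); background contrasts as (site-normal vs nCR) and
## (site-normal vs pCRC). "Differentially expressed in the same direction in
## the corresponding normal tissue" is then an equality of signs. For
## peritoneal metastases, where no adjacent normal tissue exists, the signed
## union of the liver and lung background sets is used.

#' Build a background-expression set for a metastatic site
#'
#' A miRNA enters the set with sign `s` when it passes the full relevance
#' filter with sign `s` in either of the two background contrasts
#' (site-normal vs nCR, site-normal vs pCRC). Conflicting signs across the
#' contrasts are both recorded. The combination rule is configurable via
#' `mode`.
#'
#' @param de_ncr `de_result` for the site-normal vs nCR contrast (case =
#'   site-normal tissue, so positive LFC = higher in the site-normal organ).
#' @param de_pcrc `de_result` for the site-normal vs pCRC contrast, same
#'   orientation.
#' @param site Metastatic site the set applies to (`"mLi"`, `"mLu"`).
#' @param mode Combination rule: `"union"` (default), `"ncr_only"`,
#'   `"pcrc_only"` or `"intersection"` (same-signed in both contrasts).
#' @param config A [de_config()] (relevance thresholds).
#' @return A `data.frame` of class `background_set` with columns `mirna`,
#'   `sign`, `provenance`; attribute `site`.
#' @export
build_background_set <- function(de_ncr, de_pcrc, site,
                                 mode = c("union", "ncr_only", "pcrc_only",
                                          "intersection"),
                                 config = de_config()) {
  mode <- match.arg(mode)
  for (de in list(de_ncr, de_pcrc)) {
    if (is.null(attr(de, "case"))) {
      stop("background DE tables must carry orientation metadata ",
           "(attributes 'case'/'control')", call. = FALSE)
    }
  }
  entries <- function(de, tag) {
    rel <- de[de$relevant, , drop = FALSE]
    if (nrow(rel) == 0) {
      return(data.frame(mirna = character(0), sign = numeric(0),
                        provenance = character(0), stringsAsFactors = FALSE))
    }
    lfc <- if (config$use_shrunk) rel$lfc_shrunk else rel$lfc_mle
    data.frame(mirna = rel$mirna, sign = sign(lfc), provenance = tag,
               stringsAsFactors = FALSE)
  }
  e_ncr <- entries(de_ncr, "nCR_vs_nSite")
  e_pcrc <- entries(de_pcrc, "pCRC_vs_nSite")
  bg <- switch(mode,
    union = rbind(e_ncr, e_pcrc),
    ncr_only = e_ncr,
    pcrc_only = e_pcrc,
    intersection = merge(e_ncr[, c("mirna", "sign")],
                         e_pcrc[, c("mirna", "sign")])
  )
  if (mode == "intersection" && nrow(bg) > 0) bg$provenance <- "both"
  if (nrow(bg) > 0) {
    key <- paste(bg$mirna, bg$sign)
    prov <- tapply(bg$provenance, key, function(x)
      paste(sort(unique(x)), collapse = "+"))
    bg <- bg[!duplicated(key), , drop = FALSE]
    bg$provenance <- as.character(prov[paste(bg$mirna, bg$sign)])
    bg <- bg[order(bg$mirna, bg$sign), , drop = FALSE]
  }
  rownames(bg) <- NULL
  attr(bg, "site") <- site
  class(bg) <- c("background_set", class(bg))
  bg
}

#' Suppress site-specific DE calls that mirror normal-tissue background
#'
#' A relevant call for a miRNA is suppressed when the background set for the
#' same site contains that miRNA with the same sign as the call's LFC;
#' opposite-sign background never suppresses. The final call requires
#' relevance before background and no suppression.
#'
#' @param calls `de_result` for the metastasis-vs-pCRC contrast of the same
#'   site as `bg`.
#' @param bg A [build_background_set()] (or [union_background()]) result.
#' @param site Site of the calls; must match `attr(bg, "site")`.
#' @param config A [de_config()].
#' @return `calls` with added columns `relevant_before_bg`,
#'   `suppressed_by_background`, `final_call`.
#' @export
apply_background_filter <- function(calls, bg, site, config = de_config()) {
  if (!identical(attr(bg, "site"), site)) {
    stop("background set is for site '", attr(bg, "site"),
         "', calls are for '", site, "'", call. = FALSE)
  }
  lfc <- if (config$use_shrunk) calls$lfc_shrunk else calls$lfc_mle
  key <- paste(calls$mirna, sign(lfc))
  bg_key <- paste(bg$mirna, bg$sign)
  calls$relevant_before_bg <- calls$relevant
  calls$suppressed_by_background <- key %in% bg_key
  calls$final_call <- calls$relevant_before_bg &
    !calls$suppressed_by_background
  attr(calls, "site") <- site
  calls
}

#' Signed union of two background sets (peritoneal metastases)
#'
#' No tumour-adjacent tissue exists for peritoneal metastases, so the union
#' of the liver and lung background sets is used: a miRNA suppresses a PM
#' call when either site's background matches the call's sign.
#'
#' @param bg_liver,bg_lung Background sets for mLi and mLu.
#' @return A `background_set` with `attr(site) == "PM"`.
#' @export
union_background <- function(bg_liver, bg_lung) {
  bg <- rbind(as.data.frame(bg_liver), as.data.frame(bg_lung))
  if (nrow(bg) > 0) {
    key <- paste(bg$mirna, bg$sign)
    prov <- tapply(bg$provenance, key, function(x)
      paste(sort(unique(x)), collapse = "+"))
    bg <- bg[!duplicated(key), , drop = FALSE]
    bg$provenance <- as.character(prov[paste(bg$mirna, bg$sign)])
    bg <- bg[order(bg$mirna, bg$sign), , drop = FALSE]
  }
  rownames(bg) <- NULL
  attr(bg, "site") <- "PM"
  class(bg) <- c("background_set", class(bg))
  bg
}

#' Summarize final calls across metastatic sites
#'
#' @param calls_by_site Named list (site -> output of
#'   [apply_background_filter()]).
#' @param config A [de_config()].
#' @return `data.frame(mirna, n_sites, sites, signs, mixed_sign)`, one row
#'   per miRNA with at least one final call, sorted by descending site count
#'   then miRNA id.
#' @export
multi_site_summary <- function(calls_by_site, config = de_config()) {
  if (length(calls_by_site) == 0) stop("at least one site required",
                                       call. = FALSE)
  rows <- do.call(rbind, lapply(names(calls_by_site), function(site) {
    x <- calls_by_site[[site]]
    x <- x[x$final_call, , drop = FALSE]
    if (nrow(x) == 0) return(NULL)
    lfc <- if (config$use_shrunk) x$lfc_shrunk else x$lfc_mle
    data.frame(mirna = x$mirna, site = site, sign = sign(lfc),
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows) || nrow(rows) == 0) {
    return(data.frame(mirna = character(0), n_sites = integer(0),
                      sites = character(0), signs = character(0),
                      mixed_sign = logical(0), stringsAsFactors = FALSE))
  }
  agg <- lapply(split(rows, rows$mirna), function(d) {
    d <- d[order(d$site), , drop = FALSE]
    data.frame(mirna = d$mirna[1], n_sites = nrow(d),
               sites = paste(d$site, collapse = ","),
               signs = paste(ifelse(d$sign > 0, "+", "-"), collapse = ","),
               mixed_sign = length(unique(d$sign)) > 1,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  out <- out[order(-out$n_sites, out$mirna), , drop = FALSE]
  rownames(out) <- NULL
  out
}
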