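#' Read a FASTQ file into a read table
#'
#' Reads a (Phred+33) FASTQ file and returns one row per read with the
#' sequence and quality string. Parsing is delegated to
#' [Biostrings::readQualityScaledDNAStringSet()].
#'
#' @param path Path to an uncompressed or gzipped FASTQ file.
#' @return A `data.frame` with columns `read_id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4 != 0) {
    stop("failed to parse FASTQ '", path, "': truncated record ",
         length(lines) %/% 4 + 1, call. = FALSE)
  }
  heads <- seq(1, length(lines), by = 4)
  bad <- which(!startsWith(lines[heads], "@") |
                 !startsWith(lines[heads + 2], "+") |
                 nchar(lines[heads + 1]) != nchar(lines[heads + 3]))
  if (length(bad) > 0) {
    stop("failed to parse FASTQ '", path, "': malformed record ", bad[1],
         call. = FALSE)
  }
  tryCatch({
    x <- withCallingHandlers(
      Biostrings::readQualityScaledDNAStringSet(path,
                                                quality.scoring = "phred"),
      warning = function(w) {
        if (grepl("metadata columns.*dropped", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      }
    )
    data.frame(
      read_id = names(x),
      seq = as.character(x),
      qual = as.character(Biostrings::quality(x)),
      row.names = NULL,
      stringsAsFactors = FALSE
    )
  }, error = function(e) stop("failed to parse FASTQ '", path, "': ",
                              conditionMessage(e), call. = FALSE))
}

#' Write a read table to FASTQ
#'
#' @param reads A `data.frame` with columns `read_id`, `seq`, `qual`
#'   (Phred+33 quality strings, same length as `seq`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("read_id", "seq", "qual") %in% names(reads)))
  if (any(nchar(reads$seq) != nchar(reads$qual))) {
    stop("sequence and quality strings must have equal lengths", call. = FALSE)
  }
  s <- Biostrings::DNAStringSet(reads$seq)
  q <- Biostrings::PhredQuality(reads$qual)
  x <- withCallingHandlers(
    Biostrings::QualityScaledDNAStringSet(s, q),
    warning = function(w) {
      if (grepl("metadata columns.*dropped", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  names(x) <- reads$read_id
  Biostrings::writeQualityScaledXStringSet(x, path)
  invisible(path)
}
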