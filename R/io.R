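#' Read a log2-ratio track from tab-delimited text
#'
#' Expects a header with at least `chrom`, `position`, `snp_id` and
#' `log2ratio`; extra columns (such as a simulation truth `true_cn`) are kept.
#' Rows are sorted by position on read. Malformed input — missing columns,
#' non-numeric ratios, duplicate positions within a chromosome — raises a
#' descriptive error naming the offending file lines.
#'
#' @param path Input file path.
#' @return A tibble track, ordered by position within chromosome.
#' @export
read_track <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  dat <- utils::read.delim(path, sep = "\t", colClasses = "character",
                           check.names = FALSE)
  required <- c("chrom", "position", "snp_id", "log2ratio")
  missing <- setdiff(required, names(dat))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  line_of <- function(rows) paste(rows + 1L, collapse = ", ") # +1 for header
  pos <- suppressWarnings(as.numeric(dat$position))
  bad <- which(!is.finite(pos))
  if (length(bad)) {
    stop("non-numeric position at line(s) ", line_of(bad), call. = FALSE)
  }
  lr <- suppressWarnings(as.numeric(dat$log2ratio))
  bad <- which(!is.finite(lr))
  if (length(bad)) {
    stop("non-numeric or missing log2ratio at line(s) ", line_of(bad),
         call. = FALSE)
  }
  dup <- which(duplicated(paste(dat$chrom, pos)))
  if (length(dup)) {
    stop("duplicate position at line(s) ", line_of(dup), call. = FALSE)
  }
  out <- tibble::as_tibble(dat)
  out$position <- as.integer(pos)
  out$log2ratio <- lr
  if ("true_cn" %in% names(out)) out$true_cn <- as.integer(out$true_cn)
  if ("cn_call" %in% names(out)) out$cn_call <- as.integer(out$cn_call)
  dplyr::arrange(out, .data$chrom, .data$position)
}

#' Write a track as tab-delimited text
#'
#' @param track A track tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path) {
  stopifnot(is.data.frame(track))
  readr::write_tsv(track, path)
  invisible(path)
}

#' Write calls and segments of a fit
#'
#' Writes the annotated per-SNP track (input columns, the seven averaged class
#' probabilities, and the integer call) as tab-delimited text and, optionally,
#' the called segments as a headerless BED-like file with 0-based half-open
#' genomic coordinates (`chrom`, `start`, `end`, `cn_call`, `n_snps`).
#'
#' @param fit A [cnv_fit()] object.
#' @param path Output path for the per-SNP table.
#' @param segments_path Optional output path for the BED-like segment file.
#' @return `path`, invisibly.
#' @export
write_calls <- function(fit, path, segments_path = NULL) {
  stopifnot(inherits(fit, "cnv_fit"))
  d <- tidy(fit)
  readr::write_tsv(d, path)
  if (!is.null(segments_path)) {
    segs <- segment_calls(d)
    bed <- tibble::tibble(
      chrom = segs$chrom,
      start = segs$pos_start - 1L, # BED: 0-based half-open
      end = segs$pos_end,
      cn_call = segs$cn_call,
      n_snps = segs$n_snps
    )
    readr::write_tsv(bed, segments_path, col_names = FALSE)
  }
  invisible(path)
}
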