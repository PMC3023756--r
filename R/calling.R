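#' Integer copy-number calls from averaged class probabilities
#'
#' Assigns each SNP to the class with the largest averaged posterior weight.
#' Exact ties are broken toward the diploid class (no aberration is called in
#' doubt), then toward the lowest class index. Calls are invariant to positive
#' rescaling of the rows.
#'
#' @param omega_bar Numeric matrix (`n x k_max`) of averaged per-SNP class
#'   probabilities.
#' @param classes Class table matching the columns of `omega_bar`.
#' @return Integer vector of copy-number calls (6 codes ">5").
#' @export
call_copy_numbers <- function(omega_bar, classes = cn_classes()) {
  omega_bar <- as.matrix(omega_bar)
  validate_classes(classes)
  stopifnot(ncol(omega_bar) == nrow(classes))
  if (any(omega_bar < 0) || any(!is.finite(omega_bar))) {
    stop("probabilities must be finite and non-negative", call. = FALSE)
  }
  if (any(rowSums(omega_bar) == 0)) {
    stop("malformed accumulation: a row of `omega_bar` is all zero", call. = FALSE)
  }
  dip <- which(classes$cn == 2)
  apply(omega_bar, 1, function(w) {
    cand <- which(w == max(w))
    j <- if (dip %in% cand) dip else min(cand)
    classes$cn[j]
  })
}

#' Collapse per-SNP calls into segments
#'
#' Maximal runs of a constant call become segments, reported as half-open
#' 0-based SNP-index ranges (`start`, `end`, so `end - start = n_snps`) with
#' genomic positions carried through when available.
#'
#' @param data A data frame with a `cn_call` column (e.g. from
#'   [tidy.cnv_fit()]), ordered by position; `chrom` and `position` are used
#'   when present. Alternatively a bare integer vector of calls.
#' @param calls Column name holding the calls (default `cn_call`).
#' @return A tibble with `chrom`, `start`, `end` (SNP indices, half-open),
#'   `cn_call`, `cn_label`, `n_snps` and, when positions are available,
#'   `pos_start` / `pos_end`.
#' @examples
#' segment_calls(c(2, 2, 3, 3, 3, 2))
#' @export
segment_calls <- function(data, calls = "cn_call") {
  if (!is.data.frame(data)) {
    data <- tibble::tibble(cn_call = as.integer(data))
    calls <- "cn_call"
  }
  stopifnot(calls %in% names(data))
  cc <- data[[calls]]
  r <- rle(cc)
  end <- cumsum(r$lengths)
  start <- end - r$lengths
  out <- tibble::tibble(
    chrom = if ("chrom" %in% names(data)) data$chrom[start + 1] else "chr1",
    start = start,
    end = end,
    cn_call = r$values,
    cn_label = ifelse(r$values >= 6, ">5", as.character(r$values)),
    n_snps = r$lengths
  )
  if ("position" %in% names(data)) {
    out$pos_start <- data$position[start + 1]
    out$pos_end <- data$position[end]
  }
  out
}

#' Expand a segment table back to per-SNP values
#'
#' Inverse of [segment_calls()] at the SNP level: repeats each segment's call
#' `n_snps` times. Also used to expand simulation patterns into truth vectors.
#'
#' @param segments A data frame with columns `cn` or `cn_call` and `n_snps`.
#' @return Integer vector of per-SNP values.
#' @export
expand_segments <- function(segments) {
  stopifnot(is.data.frame(segments), "n_snps" %in% names(segments))
  val <- if ("cn_call" %in% names(segments)) segments[["cn_call"]]
         else segments[["cn"]]
  if (is.null(val)) stop("need a `cn` or `cn_call` column", call. = FALSE)
  rep(as.integer(val), segments$n_snps)
}
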