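#' Expected log2-ratio of an integer copy number under normal-cell contamination
#'
#' Tumor samples are usually a mixture of aberrant tumor cells and diploid
#' normal cells. If a fraction `p` of cells is normal, a locus with `cn` copies
#' in the tumor produces an average intensity proportional to
#' `cn * (1 - p) + 2 * p` plus an additive background `b`, so the expected
#' log2-ratio against a diploid reference is
#' `log2((cn * (1 - p) + 2 * p + b) / (2 + b))`. Contamination shrinks every
#' aberrant mean toward 0; the diploid mean is 0 for any `p` and `b`.
#'
#' @param cn Integer copy number (>= 0), vectorized. The ">5" class is
#'   conventionally evaluated at `cn = 6`.
#' @param p Fraction of normal cells in `[0, 1]`.
#' @param b Non-negative background factor. The default 1.47 is calibrated by
#'   [calibrate_background()] from published component means (see
#'   [cnag_reference_means()]).
#' @return Numeric vector of expected log2-ratios.
#' @examples
#' theoretical_log2ratio(0:6)
#' theoretical_log2ratio(3, p = 0.2) # shrunk toward 0
#' @export
theoretical_log2ratio <- function(cn, p = 0, b = 1.47) {
  if (any(!is.finite(cn)) || any(cn < 0)) {
    stop("`cn` must be a non-negative copy number", call. = FALSE)
  }
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("`p` must lie in [0, 1]", call. = FALSE)
  }
  if (any(!is.finite(b)) || any(b < 0)) {
    stop("`b` must be non-negative", call. = FALSE)
  }
  log2((cn * (1 - p) + 2 * p + b) / (2 + b))
}

#' Reference component means for copy numbers 0-5 and >5
#'
#' Published mean log2-ratios of the seven copy-number components of an
#' uncontaminated sample, as reported for the CNAG signal model. These are the
#' calibration inputs for the background factor `b`; with `b = 1.47` the
#' signal model reproduces all seven values (the ">5" class at `cn = 6`).
#'
#' @return A tibble with columns `cn` (integer, 6 codes ">5"), `label` and
#'   `log2ratio`.
#' @export
cnag_reference_means <- function() {
  tibble::tibble(
    cn = c(0L, 1L, 2L, 3L, 4L, 5L, 6L),
    label = c("0", "1", "2", "3", "4", "5", ">5"),
    log2ratio = c(-1.24, -0.49, 0, 0.365, 0.657, 0.899, 1.106)
  )
}

#' Calibrate the background factor from observed component means
#'
#' Recovers the additive background `b` of the contamination signal model by
#' least squares: `b` minimizes the sum of squared differences between
#' `log2((cn + b) / (2 + b))` and the supplied uncontaminated component means.
#' The problem is one-dimensional and is solved by bracketed scalar
#' minimization on `interval`.
#'
#' @param target_means Data frame with columns `cn` and `log2ratio`: observed
#'   mean log2-ratios of components at known copy number, without
#'   contamination. At least one non-diploid row is required (the diploid mean
#'   is 0 for every `b` and carries no information).
#' @param interval Search bracket for `b`.
#' @return The calibrated scalar `b`.
#' @examples
#' calibrate_background(dplyr::filter(cnag_reference_means(), cn %in% c(1, 3, 4, 5)))
#' @export
calibrate_background <- function(target_means, interval = c(1e-6, 10)) {
  stopifnot(is.data.frame(target_means),
            all(c("cn", "log2ratio") %in% names(target_means)))
  cn <- target_means$cn
  obs <- target_means$log2ratio
  if (any(cn < 0)) stop("copy numbers must be non-negative", call. = FALSE)
  if (all(cn == 2)) {
    stop("`b` is unidentifiable from diploid means alone; supply at least one cn != 2",
         call. = FALSE)
  }
  ss <- function(b) sum((log2((cn + b) / (2 + b)) - obs)^2)
  optimize(ss, interval = interval, tol = 1e-10)$minimum
}

#' Copy-number classes: default uniform supports for the component means
#'
#' The mixture ties each component permanently to a copy-number class through
#' a uniform prior interval for its mean. The seven default intervals, for
#' copy numbers 0, 1, 2, 3, 4, 5 and >5, are pairwise disjoint, increase with
#' copy number, and each contains the theoretical class mean (the boundaries
#' sit closer to zero than the uncontaminated means for CN 1-5, anticipating
#' some normal-cell contamination; CN 0 and >5 are centered on the
#' uncontaminated means). The diploid interval is (-0.05, 0.05), symmetric
#' about the null log2-ratio 0.
#'
#' @param b Background factor used for the `theoretical_mean` column.
#' @return A tibble with columns `class` (1-based index), `cn` (integer, 6
#'   codes ">5"), `label`, `lower`, `upper` and `theoretical_mean`.
#' @examples
#' cn_classes()
#' @export
cn_classes <- function(b = 1.47) {
  cls <- tibble::tibble(
    class = 1:7,
    cn = c(0L, 1L, 2L, 3L, 4L, 5L, 6L),
    label = c("0", "1", "2", "3", "4", "5", ">5"),
    lower = c(-2, -0.6, -0.05, 0.15, 0.45, 0.75, 0.95),
    upper = c(-0.8, -0.25, 0.05, 0.4, 0.66, 0.9, 1.3)
  )
  cls$theoretical_mean <- theoretical_log2ratio(cls$cn, p = 0, b = b)
  validate_classes(cls)
  cls
}

#' Copy-number classes centered on contamination-shrunk means
#'
#' Builds class intervals centered at `theoretical_log2ratio(cn, p, b)` with
#' the given half-widths, for use when the normal-cell fraction `p` is known.
#' If the requested half-widths would make consecutive intervals overlap, all
#' half-widths are shrunk by a common factor until the intervals are disjoint.
#' The diploid interval is always centered at 0.
#'
#' @param p Normal-cell fraction in `[0, 1)`. At `p = 1` every class mean
#'   collapses to 0 and the classes are unidentifiable.
#' @param b Background factor.
#' @param half_widths Positive half-widths, one per class (recycled if scalar).
#' @return A tibble in the same shape as [cn_classes()].
#' @examples
#' cn_classes_contaminated(p = 0.2)
#' @export
cn_classes_contaminated <- function(p, b = 1.47, half_widths = 0.12) {
  if (!is.finite(p) || p < 0 || p >= 1) {
    stop("`p` must lie in [0, 1); at p = 1 all class means collapse to 0",
         call. = FALSE)
  }
  if (any(half_widths <= 0)) stop("half-widths must be positive", call. = FALSE)
  cn <- c(0L, 1L, 2L, 3L, 4L, 5L, 6L)
  hw <- rep_len(half_widths, length(cn))
  centers <- theoretical_log2ratio(cn, p = p, b = b)
  gaps <- diff(centers)
  wsum <- hw[-length(hw)] + hw[-1]
  shrink <- min(1, 0.995 * min(gaps / wsum))
  hw <- hw * shrink
  cls <- tibble::tibble(
    class = seq_along(cn),
    cn = cn,
    label = c("0", "1", "2", "3", "4", "5", ">5"),
    lower = centers - hw,
    upper = centers + hw,
    theoretical_mean = centers
  )
  validate_classes(cls)
  cls
}

validate_classes <- function(cls) {
  stopifnot(is.data.frame(cls),
            all(c("class", "cn", "lower", "upper") %in% names(cls)))
  if (any(cls$lower >= cls$upper)) {
    stop("each class interval must have lower < upper", call. = FALSE)
  }
  if (is.unsorted(cls$lower, strictly = TRUE) ||
      is.unsorted(cls$upper, strictly = TRUE)) {
    stop("class intervals must be strictly increasing with copy number", call. = FALSE)
  }
  if (any(cls$lower[-1] <= cls$upper[-nrow(cls)])) {
    stop("class intervals must be pairwise disjoint", call. = FALSE)
  }
  dip <- which(cls$cn == 2)
  if (length(dip) != 1 || cls$lower[dip] >= 0 || cls$upper[dip] <= 0) {
    stop("exactly one diploid class is required and its interval must contain 0",
         call. = FALSE)
  }
  invisible(cls)
}

#' Write a class table as tab-delimited text
#'
#' @param classes A class table from [cn_classes()] or
#'   [cn_classes_contaminated()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_classes <- function(classes, path) {
  validate_classes(classes)
  out <- dplyr::select(classes, "class", "cn", "label", "lower", "upper",
                       "theoretical_mean")
  readr::write_tsv(out, path)
  invisible(path)
}
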