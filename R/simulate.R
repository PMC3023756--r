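#' Benchmark copy-number segment patterns
#'
#' Two fixed patterns of true copy-number segments used throughout the
#' simulation study, each 245 SNPs long. Pattern "A" holds single-copy
#' aberrations (CN 1 and 3) of widths 5-40 between diploid stretches;
#' pattern "B" swaps in more extreme aberrations (CN 4 and a homozygous
#' deletion CN 0).
#'
#' @param id `"A"` or `"B"`.
#' @return A tibble with columns `cn` and `n_snps`, in chromosome order.
#' @examples
#' sum(cn_pattern("A")$n_snps) # 245
#' @export
cn_pattern <- function(id) {
  widths <- c(10L, 5L, 50L, 10L, 50L, 20L, 50L, 40L, 10L)
  cn <- switch(as.character(id),
    A = c(2L, 3L, 2L, 1L, 2L, 3L, 2L, 3L, 2L),
    B = c(2L, 4L, 2L, 3L, 2L, 0L, 2L, 3L, 2L),
    stop("unknown pattern id: ", id, call. = FALSE)
  )
  tibble::tibble(cn = cn, n_snps = widths)
}

#' The eight simulation scenarios
#'
#' The scenario grid crosses the two segment patterns with four noise /
#' contamination configurations: SD 0.05, 0.15, 0.2 without contamination and
#' SD 0.2 with 20% normal cells. `snr` is the expected log2-ratio of a
#' three-copy segment (at the scenario's contamination) divided by the SD, the
#' scale on which scenario difficulty is labelled (7.3, 2.4, 1.8, 1.5).
#'
#' @param b Background factor of the signal model.
#' @return A tibble with one row per scenario: `scenario`, `pattern`, `sd`,
#'   `p`, `b`, `snr`.
#' @export
scenario_grid <- function(b = 1.47) {
  grid <- tibble::tibble(
    scenario = 1:8,
    pattern = rep(c("A", "B"), each = 4),
    sd = rep(c(0.05, 0.15, 0.2, 0.2), 2),
    p = rep(c(0, 0, 0, 0.2), 2),
    b = b
  )
  grid$snr <- theoretical_log2ratio(3, grid$p, grid$b) / grid$sd
  grid
}

#' Simulate a log2-ratio track from a segment pattern
#'
#' Per-SNP log2-ratios are drawn independently as
#' `N(theoretical_log2ratio(cn_i, p, b), sd^2)` — the same SD for every
#' component — over the true copy-number profile of the pattern. Positions are
#' synthetic and equally spaced.
#'
#' @param pattern `"A"`, `"B"`, or a data frame with columns `cn`, `n_snps`.
#' @param sd Per-SNP noise standard deviation on the log2 scale (> 0).
#' @param p Normal-cell contamination fraction.
#' @param b Background factor.
#' @param seed Optional integer seed.
#' @param chrom,start,spacing Synthetic genomic coordinates.
#' @return A tibble track with columns `chrom`, `position`, `snp_id`,
#'   `log2ratio` and the simulation truth `true_cn`.
#' @examples
#' simulate_track("A", sd = 0.05, seed = 1)
#' @export
simulate_track <- function(pattern = "A", sd = 0.05, p = 0, b = 1.47,
                           seed = NULL, chrom = "chr1", start = 1e6,
                           spacing = 2500) {
  if (!is.data.frame(pattern)) pattern <- cn_pattern(pattern)
  stopifnot(sd > 0)
  if (!is.null(seed)) set.seed(seed)
  truth <- expand_segments(pattern)
  n <- length(truth)
  means <- theoretical_log2ratio(truth, p = p, b = b)
  tibble::tibble(
    chrom = chrom,
    position = as.integer(start + (seq_len(n) - 1) * spacing),
    snp_id = sprintf("SNP%05d", seq_len(n)),
    log2ratio = rnorm(n, mean = means, sd = sd),
    true_cn = truth
  )
}

#' Misclassification rate of an aberrant segment
#'
#' `P(call != j | true CN = j)` for `j != 2`: the fraction of truly aberrant
#' SNPs whose call differs from the truth. Defined only away from the diploid
#' class (a wrong diploid SNP is a false positive, not a misclassification).
#'
#' @param calls,truth Integer vectors of equal length, restricted to SNPs of
#'   one (pooled) aberrant segment.
#' @return Rate in `[0, 1]`.
#' @export
mc_rate <- function(calls, truth) {
  stopifnot(length(calls) == length(truth))
  if (any(truth == 2)) {
    stop("MC rate is defined for aberrant segments only (use fp_rate for CN = 2)",
         call. = FALSE)
  }
  mean(calls != truth)
}

#' False-negative rate of an aberrant segment
#'
#' `P(call = 2 | true CN != 2)`: the fraction of truly aberrant SNPs called
#' diploid. Always bounded above by the misclassification rate.
#'
#' @inheritParams mc_rate
#' @return Rate in `[0, 1]`.
#' @export
fn_rate <- function(calls, truth) {
  stopifnot(length(calls) == length(truth))
  if (any(truth == 2)) {
    stop("FN rate is defined for aberrant segments only", call. = FALSE)
  }
  mean(calls == 2)
}

#' False-positive rate over diploid SNPs
#'
#' `P(call != 2 | true CN = 2)`: the fraction of truly diploid SNPs called
#' aberrant. Pool the diploid SNPs of interest (e.g. across patterns and
#' replicates for matching noise configurations and segment widths) before
#' calling.
#'
#' @inheritParams mc_rate
#' @return Rate in `[0, 1]`.
#' @export
fp_rate <- function(calls, truth) {
  stopifnot(length(calls) == length(truth))
  keep <- truth == 2
  if (!any(keep)) stop("no diploid SNPs supplied", call. = FALSE)
  mean(calls[keep] != 2)
}

#' Per-segment error rates of one called track
#'
#' Splits the truth into maximal constant segments and reports, per segment,
#' the misclassification and false-negative rate (aberrant segments) or the
#' false-positive rate (diploid segments).
#'
#' @param data A data frame holding per-SNP calls and truth in chromosome
#'   order.
#' @param calls,truth Column names (defaults `cn_call`, `true_cn`).
#' @return A tibble with one row per true segment: `segment`, `cn`, `n_snps`,
#'   `mc`, `fn`, `fp` (rates not applying to a segment are `NA`).
#' @export
evaluate_calls <- function(data, calls = "cn_call", truth = "true_cn") {
  stopifnot(is.data.frame(data), calls %in% names(data), truth %in% names(data))
  cc <- data[[calls]]
  tt <- data[[truth]]
  r <- rle(tt)
  end <- cumsum(r$lengths)
  start <- end - r$lengths + 1
  purrr::map_dfr(seq_along(r$values), function(s) {
    i <- start[s]:end[s]
    dip <- r$values[s] == 2
    tibble::tibble(
      segment = s,
      cn = r$values[s],
      n_snps = r$lengths[s],
      mc = if (dip) NA_real_ else mc_rate(cc[i], tt[i]),
      fn = if (dip) NA_real_ else fn_rate(cc[i], tt[i]),
      fp = if (dip) fp_rate(cc[i], tt[i]) else NA_real_
    )
  })
}

#' Run the scaled-down simulation study
#'
#' Simulates replicate tracks for the requested scenarios, fits the sampler to
#' each, and aggregates per-segment misclassification and false-negative rates
#' plus false-positive rates pooled over the diploid segments of both patterns
#' by segment width (the diploid structure is shared between patterns, so the
#' pooled FP denominators cover twice the replicates).
#'
#' @param replicates Replicate tracks per scenario.
#' @param burnin,samples Chain size per replicate fit.
#' @param seed Base seed; replicate seeds are derived deterministically.
#' @param scenarios Scenario numbers (subset of 1:8).
#' @param prior A [prior_config()].
#' @return A list of class `cnv_rate_report` with tibbles `mc`, `fn`
#'   (scenario x aberrant segment) and `fp` (noise configuration x diploid
#'   segment width), rates in percent, plus the per-SNP call table `calls`.
#' @export
reproduce_tables <- function(replicates = 5, burnin = 2000, samples = 2000,
                             seed = 1, scenarios = 1:8,
                             prior = prior_config()) {
  stopifnot(all(scenarios %in% 1:8))
  grid <- scenario_grid()
  runs <- purrr::map_dfr(scenarios, function(sc) {
    spec <- grid[grid$scenario == sc, ]
    purrr::map_dfr(seq_len(replicates), function(r) {
      s <- seed + 8191L * sc + r
      trk <- simulate_track(spec$pattern, sd = spec$sd, p = spec$p, b = spec$b,
                            seed = s)
      fit <- cnv_fit(trk, prior = prior, burnin = burnin, samples = samples,
                     seed = s + 1L)
      dplyr::mutate(
        dplyr::select(tidy(fit), "cn_call"),
        true_cn = trk$true_cn,
        scenario = sc,
        pattern = spec$pattern,
        sd = spec$sd,
        p = spec$p,
        replicate = r,
        segment = rep(seq_len(nrow(cn_pattern(spec$pattern))),
                      cn_pattern(spec$pattern)$n_snps),
        n_snps = rep(cn_pattern(spec$pattern)$n_snps,
                     cn_pattern(spec$pattern)$n_snps)
      )
    })
  })
  aberr <- dplyr::filter(runs, .data$true_cn != 2)
  mc <- dplyr::summarise(
    dplyr::group_by(aberr, .data$scenario, .data$segment, .data$true_cn,
                    .data$n_snps),
    rate = 100 * mc_rate(.data$cn_call, .data$true_cn),
    .groups = "drop"
  )
  fn <- dplyr::summarise(
    dplyr::group_by(aberr, .data$scenario, .data$segment, .data$true_cn,
                    .data$n_snps),
    rate = 100 * fn_rate(.data$cn_call, .data$true_cn),
    .groups = "drop"
  )
  dip <- dplyr::filter(runs, .data$true_cn == 2)
  fp <- dplyr::summarise(
    dplyr::group_by(dip, .data$sd, .data$p, .data$n_snps),
    rate = 100 * fp_rate(.data$cn_call, .data$true_cn),
    n_replicates = dplyr::n_distinct(paste(.data$pattern, .data$replicate)),
    .groups = "drop"
  )
  structure(list(mc = mc, fn = fn, fp = fp, calls = tibble::as_tibble(runs),
                 replicates = replicates),
            class = "cnv_rate_report")
}

#' @export
print.cnv_rate_report <- function(x, ...) {
  cat("Simulation study rates (%) at", x$replicates, "replicates\n")
  cat("\nMisclassification (aberrant segments):\n")
  print(x$mc, n = Inf)
  cat("\nFalse negatives:\n")
  print(x$fn, n = Inf)
  cat("\nFalse positives (pooled diploid segments):\n")
  print(x$fp, n = Inf)
  invisible(x)
}

#' Write a rate report as tab-delimited tables
#'
#' @param report A [reproduce_tables()] result.
#' @param prefix Output path prefix; writes `<prefix>.mc.tsv`,
#'   `<prefix>.fn.tsv` and `<prefix>.fp.tsv`.
#' @return `prefix`, invisibly.
#' @export
write_rate_report <- function(report, prefix) {
  stopifnot(inherits(report, "cnv_rate_report"))
  readr::write_tsv(report$mc, paste0(prefix, ".mc.tsv"))
  readr::write_tsv(report$fn, paste0(prefix, ".fn.tsv"))
  readr::write_tsv(report$fp, paste0(prefix, ".fp.tsv"))
  invisible(prefix)
}
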