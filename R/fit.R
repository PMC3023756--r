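#' Fit the Bayesian spatial mixture copy-number model
#'
#' Runs the reversible-jump sampler on one chromosome's ordered log2-ratios.
#' Each iteration performs, in order: a birth/death move on the number of
#' active components, a sequential Metropolis-Hastings sweep over the field
#' values at every SNP (proposing from the exact Gaussian full conditionals,
#' so only the data term enters the acceptance ratio), a random-walk update of
#' the smoothing parameter `h` (truncated-normal proposal, adapted during
#' burn-in to an acceptance rate between 40% and 70% and frozen afterwards), a
#' Gibbs draw of the per-SNP allocations, and a draw of the component means
#' and variances in which each mean may migrate to the class interval with the
#' largest posterior mass; components landing in the same interval are merged
#' with allocation-count weights.
#'
#' After burn-in the per-SNP mixture weights over all `k_max` classes are
#' accumulated (zero for inactive classes) and averaged; the final call at
#' each SNP is the class with the largest averaged weight.
#'
#' @param track A data frame with a `log2ratio` column (and optionally
#'   `chrom`, `position`, `snp_id`, as from [read_track()] or
#'   [simulate_track()]), or a bare numeric vector of ordered log2-ratios.
#' @param prior A [prior_config()].
#' @param burnin,samples Iterations to discard / to average over.
#' @param seed Optional integer seed; fixing it makes the fit bit-reproducible.
#' @param sigma_h Initial random-walk scale for the `h` update.
#' @param adapt_every Burn-in adaptation window (iterations) for `sigma_h`.
#' @param k_warmup Initial burn-in iterations during which the birth/death
#'   move is held off, letting the fields sharpen around the starting
#'   components before any can be culled. Pure initialization policy: these
#'   iterations are discarded with the rest of burn-in and the post-burn-in
#'   kernel is unchanged.
#' @param prior_only If `TRUE`, the data likelihood is replaced by a constant
#'   so the chain targets the prior — used to validate the sampler.
#' @param store_mu If `TRUE`, keep the post-burn-in trace of component means.
#' @return An object of class `cnv_fit` with averaged weights `omega_bar`
#'   (`n x k_max`), integer calls, traces of `k` and `h`, acceptance
#'   diagnostics and the class table. See [tidy.cnv_fit()], [glance.cnv_fit()],
#'   [segment_calls()].
#' @examples
#' trk <- simulate_track("A", sd = 0.05, seed = 1)
#' fit <- cnv_fit(trk, burnin = 200, samples = 200, seed = 1)
#' glance(fit)
#' @export
cnv_fit <- function(track, prior = prior_config(), burnin = 5000,
                    samples = 5000, seed = NULL, sigma_h = 100,
                    adapt_every = 50, k_warmup = min(200, burnin %/% 2),
                    prior_only = FALSE, store_mu = FALSE) {
  track <- as_track(track)
  y <- track$log2ratio
  n <- length(y)
  if (n < 2) stop("at least 2 SNPs are required", call. = FALSE)
  if (any(!is.finite(y))) stop("log2-ratios must be finite", call. = FALSE)
  stopifnot(inherits(prior, "cnv_prior"), burnin >= 1, samples >= 1)
  if (!is.null(seed)) set.seed(seed)

  graph <- neighbor_graph(n, prior$nb)
  ctx <- build_ctx(y, prior, graph, prior_only)
  init <- init_state(ctx, prior)
  res <- cpp_run_chain(ctx, init, as.integer(burnin), as.integer(samples),
                       sigma_h, as.integer(adapt_every), store_mu,
                       as.integer(k_warmup))

  omega_bar <- res$omega_bar
  colnames(omega_bar) <- prior$classes$label
  calls <- call_copy_numbers(omega_bar, prior$classes)
  acc <- res$accept
  structure(
    list(
      track = track,
      classes = prior$classes,
      omega_bar = omega_bar,
      calls = calls,
      k_trace = res$k_trace,
      h_trace = res$h_trace,
      active_trace = res$active_trace,
      mu_trace = if (store_mu) res$mu_trace else NULL,
      accept = tibble::tibble(
        move = c("birth", "death", "field", "h"),
        proposed = c(acc$birth_proposed, acc$death_proposed,
                     acc$field_proposed, acc$h_proposed),
        accepted = c(acc$birth_accepted, acc$death_accepted,
                     acc$field_accepted, acc$h_accepted),
        rate = .data_rate(c(acc$birth_accepted, acc$death_accepted,
                            acc$field_accepted, acc$h_accepted),
                          c(acc$birth_proposed, acc$death_proposed,
                            acc$field_proposed, acc$h_proposed))
      ),
      n_merges = acc$merges,
      sigma_h = res$sigma_h,
      burnin = burnin,
      samples = samples,
      prior = prior,
      seed = seed,
      final_state = res$state
    ),
    class = "cnv_fit"
  )
}

.data_rate <- function(a, p) ifelse(p > 0, a / p, NA_real_)

as_track <- function(track) {
  if (is.numeric(track) && is.null(dim(track))) {
    track <- tibble::tibble(
      chrom = "chr1",
      position = seq_along(track),
      snp_id = sprintf("SNP%05d", seq_along(track)),
      log2ratio = as.numeric(track)
    )
  }
  stopifnot(is.data.frame(track), "log2ratio" %in% names(track))
  track <- tibble::as_tibble(track)
  if (!"position" %in% names(track)) track$position <- seq_len(nrow(track))
  if (!"chrom" %in% names(track)) track$chrom <- "chr1"
  if (!"snp_id" %in% names(track)) {
    track$snp_id <- sprintf("SNP%05d", seq_len(nrow(track)))
  }
  if (is.unsorted(track$position)) {
    track <- dplyr::arrange(track, .data$position)
  }
  track
}

build_ctx <- function(y, prior, graph, prior_only = FALSE) {
  list(
    n = length(y), kmax = prior$kmax, nb = graph$nb, y = y,
    lower = prior$classes$lower, upper = prior$classes$upper,
    eigenvalues = graph$eigenvalues, degree = graph$degree,
    poisson_mean = prior$poisson_mean, ig_shape = prior$ig_shape,
    ig_scale = prior$ig_scale, h_max = prior$h_max, phi = prior$phi,
    eigenvectors = graph$eigenvectors, prior_only = prior_only
  )
}

# Every class starts active, means at interval midpoints, sigma^2 = 0.04,
# x = 0, h = 10, z from one Gibbs allocation sweep. Starting saturated means
# burn-in only has to prune unneeded components through death moves (which mix
# well: a zero-weight component is cheap to remove) instead of discovering
# rare ones through births, whose prior-drawn field proposals rarely match the
# short segment that needs them.
init_state <- function(ctx, prior) {
  kmax <- prior$kmax
  cls <- prior$classes
  state <- list(
    active = rep(1L, kmax),
    mu = (cls$lower + cls$upper) / 2,
    sigma2 = rep(0.04, kmax),
    x = matrix(0, nrow = ctx$n, ncol = kmax),
    z = rep(1L, ctx$n),
    h = min(10, ctx$h_max / 2)
  )
  cpp_update_allocations(ctx, state)
}

#' @export
print.cnv_fit <- function(x, ...) {
  n <- nrow(x$omega_bar)
  segs <- segment_calls(tidy(x))
  cat("Bayesian spatial mixture copy-number fit\n")
  cat("  SNPs:", n, " classes:", nrow(x$classes),
      " burn-in:", x$burnin, " samples:", x$samples, "\n")
  kt <- table(x$k_trace[-seq_len(x$burnin)])
  cat("  posterior k mode:", names(kt)[which.max(kt)],
      " median h:", signif(median(x$h_trace[-seq_len(x$burnin)]), 4), "\n")
  cat("  segments called:", nrow(segs), "(",
      paste0(segs$cn_label, "(", segs$n_snps, ")", collapse = ", "), ")\n")
  invisible(x)
}

#' Tidy per-SNP results of a copy-number fit
#'
#' @param x A [cnv_fit()] object.
#' @param ... Unused.
#' @return A tibble with one row per SNP: the input track columns, the
#'   averaged class probabilities (`p_cn0` ... `p_cn_gt5`), the integer call
#'   `cn_call` (6 codes ">5") and its `cn_label`.
#' @export
tidy.cnv_fit <- function(x, ...) {
  probs <- tibble::as_tibble(x$omega_bar, .name_repair = "minimal")
  names(probs) <- paste0("p_cn", sub(">5", "_gt5", x$classes$label))
  dplyr::bind_cols(
    x$track,
    probs,
    tibble::tibble(
      cn_call = x$calls,
      cn_label = x$classes$label[match(x$calls, x$classes$cn)]
    )
  )
}

#' One-row summary of a copy-number fit
#'
#' @param x A [cnv_fit()] object.
#' @param ... Unused.
#' @return A tibble with chain diagnostics: posterior mode of `k`, median `h`,
#'   per-move acceptance rates, the final `sigma_h` and the segment count.
#' @export
glance.cnv_fit <- function(x, ...) {
  post <- seq(x$burnin + 1, x$burnin + x$samples)
  kt <- table(x$k_trace[post])
  acc <- setNames(x$accept$rate, x$accept$move)
  tibble::tibble(
    n_snp = nrow(x$omega_bar),
    k_max = nrow(x$classes),
    k_mode = as.integer(names(kt)[which.max(kt)]),
    h_median = median(x$h_trace[post]),
    accept_birth = acc[["birth"]],
    accept_death = acc[["death"]],
    accept_field = acc[["field"]],
    accept_h = acc[["h"]],
    sigma_h = x$sigma_h,
    n_segments = nrow(segment_calls(tidy(x)))
  )
}

#' Plot a copy-number fit along the chromosome
#'
#' Log2-ratios against genomic position, colored by the called copy-number
#' class, with the class's expected log2-ratio drawn through each segment.
#'
#' @param object A [cnv_fit()] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cnv_fit
#' @export
autoplot.cnv_fit <- function(object, ...) {
  d <- tidy(object)
  segs <- segment_calls(d)
  segs$mean_lr <- object$classes$theoretical_mean[
    match(segs$cn_call, object$classes$cn)]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$position, y = .data$log2ratio)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$cn_label), size = 0.8) +
    ggplot2::geom_segment(
      data = segs,
      ggplot2::aes(x = .data$pos_start, xend = .data$pos_end,
                   y = .data$mean_lr, yend = .data$mean_lr),
      linewidth = 0.8, colour = "black"
    ) +
    ggplot2::labs(x = "position", y = "log2 ratio", colour = "copy number") +
    ggplot2::theme_minimal()
}

#' @export
plot.cnv_fit <- function(x, ...) print(autoplot(x, ...))

#' Export chain diagnostics as a tab-delimited file
#'
#' Writes the per-iteration traces of `k` and `h` together with per-move
#' acceptance summaries.
#'
#' @param fit A [cnv_fit()] object.
#' @param path Output file path for the trace; acceptance rates are written to
#'   `paste0(path, ".accept")`.
#' @return `path`, invisibly.
#' @export
write_diagnostics <- function(fit, path) {
  stopifnot(inherits(fit, "cnv_fit"))
  tr <- tibble::tibble(
    iteration = seq_along(fit$k_trace),
    phase = rep(c("burnin", "sampling"), c(fit$burnin, fit$samples)),
    k = fit$k_trace,
    h = fit$h_trace
  )
  readr::write_tsv(tr, path)
  readr::write_tsv(dplyr::mutate(fit$accept, sigma_h_final = fit$sigma_h),
                   paste0(path, ".accept"))
  invisible(path)
}
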