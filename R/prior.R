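#' Prior configuration for the spatial mixture sampler
#'
#' Bundles every tunable prior and smoothing choice of the model. Defaults:
#' seven copy-number classes ([cn_classes()]), a truncated Poisson with mean 2
#' on the number of active components, an inverse-gamma prior on the component
#' variances centered on 0.2 with a vague spread (shape 2.1, scale 0.22), a
#' uniform prior on the smoothing parameter `h` over `(0, 1e6)`, softmax
#' temperature `phi = 0.01` and `nb = 4` smoothing neighbors on each side.
#'
#' @param classes Class table ([cn_classes()] or [cn_classes_contaminated()]);
#'   its row count sets `k_max`.
#' @param poisson_mean Mean of the truncated Poisson prior on `k`.
#' @param ig_shape,ig_scale Inverse-gamma hyperparameters for the component
#'   variances; the default pair has mean `ig_scale / (ig_shape - 1) = 0.2`.
#' @param h_max Upper bound of the uniform prior on `h`.
#' @param phi Softmax scaling factor (> 0).
#' @param nb Smoothing neighbors on each side (>= 1).
#' @return An object of class `cnv_prior`.
#' @examples
#' prior_config()
#' @export
prior_config <- function(classes = cn_classes(), poisson_mean = 2,
                         ig_shape = 2.1, ig_scale = 0.22,
                         h_max = 1e6, phi = 0.01, nb = 4) {
  validate_classes(classes)
  stopifnot(poisson_mean > 0, ig_shape > 0, ig_scale > 0,
            h_max > 0, phi > 0, nb >= 1)
  structure(
    list(classes = classes, kmax = nrow(classes), poisson_mean = poisson_mean,
         ig_shape = ig_shape, ig_scale = ig_scale, h_max = h_max,
         phi = phi, nb = as.integer(nb)),
    class = "cnv_prior"
  )
}

#' @export
print.cnv_prior <- function(x, ...) {
  cat("Spatial mixture prior: k_max =", x$kmax,
      ", k ~ TPoisson(", x$poisson_mean, "), sigma^2 ~ IG(",
      x$ig_shape, ",", x$ig_scale, "), h ~ U(0,", x$h_max,
      "), phi =", x$phi, ", nb =", x$nb, "\n")
  invisible(x)
}

#' Log prior mass of the number of components
#'
#' Poisson(`poisson_mean`) probability renormalized on `{1, ..., k_max}`.
#'
#' @param k Number of active components, in `1..k_max`.
#' @param prior A [prior_config()].
#' @return Log prior probability (vectorized over `k`).
#' @export
log_prior_k <- function(k, prior = prior_config()) {
  if (any(k < 1 | k > prior$kmax)) {
    stop("`k` must lie in 1..k_max", call. = FALSE)
  }
  dpois(k, prior$poisson_mean, log = TRUE) -
    log(sum(dpois(seq_len(prior$kmax), prior$poisson_mean)))
}

#' Birth probability of the trans-dimensional move
#'
#' The sampler proposes a birth (add a component) with probability `b_k` and a
#' death otherwise: `b_1 = 1`, `b_{k_max} = 0` and `b_k = 0.5` in between.
#'
#' @inheritParams log_prior_k
#' @return Birth probabilities (vectorized over `k`).
#' @export
birth_probability <- function(k, prior = prior_config()) {
  if (any(k < 1 | k > prior$kmax)) {
    stop("`k` must lie in 1..k_max", call. = FALSE)
  }
  ifelse(k == 1, 1, ifelse(k == prior$kmax, 0, 0.5))
}
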