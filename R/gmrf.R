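#' Window neighbor graph over ordered SNP positions
#'
#' SNPs `i` and `i'` are neighbors when `|i - i'| <= nb` (and `i != i'`), so
#' interior SNPs have `2 * nb` neighbors and SNPs near the chromosome ends
#' simply have fewer. The Gaussian Markov random field over a field column `x`
#' has precision `I + h * Q`, with `Q = D - A` the graph Laplacian (degree
#' matrix minus adjacency); its eigenvalues `g_1, ..., g_n` enter the
#' normalizing constant `c(h)` of the field density, so they are computed once
#' per chromosome and cached on the graph object.
#'
#' @param n Number of SNPs (>= 2).
#' @param nb Neighbors on each side (window half-width), `1 <= nb < n`.
#' @return An object of class `cnv_graph`: a list with `n`, `nb`, `degree`,
#'   `eigenvalues` (non-negative, at least one zero) and `eigenvectors` of `Q`.
#' @examples
#' g <- neighbor_graph(5, nb = 1)
#' g$degree
#' @export
neighbor_graph <- function(n, nb = 4) {
  if (length(n) != 1 || !is.finite(n) || n < 2) {
    stop("`n` must be an integer >= 2", call. = FALSE)
  }
  if (length(nb) != 1 || !is.finite(nb) || nb <= 0) {
    stop("`nb` must be a positive integer", call. = FALSE)
  }
  n <- as.integer(n)
  nb <- as.integer(min(nb, n - 1L))
  idx <- seq_len(n)
  A <- outer(idx, idx, function(i, j) as.numeric(abs(i - j) <= nb & i != j))
  deg <- as.integer(rowSums(A))
  Q <- diag(deg) - A
  e <- eigen(Q, symmetric = TRUE)
  structure(
    list(n = n, nb = nb, degree = deg,
         eigenvalues = pmax(e$values, 0),
         eigenvectors = e$vectors),
    class = "cnv_graph"
  )
}

#' @export
print.cnv_graph <- function(x, ...) {
  cat("SNP neighbor graph: n =", x$n, ", nb =", x$nb,
      "(window of", 2 * x$nb, "neighbors in the interior)\n")
  invisible(x)
}

neighbors_of <- function(i, graph) {
  setdiff(max(1L, i - graph$nb):min(graph$n, i + graph$nb), i)
}

#' Log-density of one Gaussian Markov random field column
#'
#' Evaluates `log c(h) - (1/2) * (h * sum_{i~i'} (x_i - x_{i'})^2 + sum_i x_i^2)`
#' where the pair sum runs over unordered neighbor pairs of `graph` and
#' `log c(h) = -(n/2) log(2 pi) + (1/2) sum_i log(1 + h g_i)`. This is the
#' density of `N(0, (I + h Q)^{-1})`; at `h = 0` it reduces to `n` iid standard
#' normals.
#'
#' @param x Numeric vector of field values, length `graph$n`.
#' @param h Non-negative smoothing parameter.
#' @param graph A [neighbor_graph()].
#' @return The log-density (scalar).
#' @export
gmrf_log_density <- function(x, h, graph) {
  stopifnot(inherits(graph, "cnv_graph"), length(x) == graph$n)
  if (!is.finite(h) || h < 0) stop("`h` must be non-negative", call. = FALSE)
  n <- graph$n
  pair_sum <- 0
  for (i in seq_len(n - 1)) {
    js <- (i + 1):min(n, i + graph$nb)
    pair_sum <- pair_sum + sum((x[i] - x[js])^2)
  }
  log_c <- -(n / 2) * log(2 * pi) + 0.5 * sum(log1p(h * graph$eigenvalues))
  log_c - 0.5 * (h * pair_sum + sum(x^2))
}

#' Full conditional of one field value given its neighbors
#'
#' Under the field prior with precision `I + h Q`, the conditional of `x_i`
#' given the rest is normal with mean `h * sum(neighbors) / (1 + h * n_i)` and
#' variance `1 / (1 + h * n_i)`, `n_i` the number of neighbors of SNP `i`.
#' This exact full conditional is the proposal used by the sampler's field
#' sweep, which is why the field prior cancels from its acceptance ratio.
#'
#' @param x Numeric field column, length `graph$n`.
#' @param i SNP index.
#' @param h Non-negative smoothing parameter.
#' @param graph A [neighbor_graph()].
#' @return A list with elements `mean` and `variance`.
#' @export
gmrf_conditional <- function(x, i, h, graph) {
  stopifnot(inherits(graph, "cnv_graph"), length(x) == graph$n,
            i >= 1, i <= graph$n)
  if (!is.finite(h) || h < 0) stop("`h` must be non-negative", call. = FALSE)
  ni <- graph$degree[i]
  list(mean = h * sum(x[neighbors_of(i, graph)]) / (1 + h * ni),
       variance = 1 / (1 + h * ni))
}

#' Mixture weights from field values (tempered softmax)
#'
#' Turns the `n x k` field matrix into spatially smooth mixture weights by
#' row-wise logistic transformation `w_ij = exp(x_ij / phi) / sum_l exp(x_il / phi)`.
#' Small `phi` sharpens the weights toward an indicator of the per-row maximum;
#' the transform is invariant to adding a constant to a row. Computed with
#' max-subtraction so large `x / phi` cannot overflow.
#'
#' @param x Numeric matrix (`n x k`) of field values; a vector is treated as a
#'   single row.
#' @param phi Positive scaling factor (default 0.01).
#' @return A matrix of weights with rows summing to 1.
#' @examples
#' field_weights(rbind(c(0, 0), c(0.01 * log(2), 0)))
#' @export
field_weights <- function(x, phi = 0.01) {
  if (!is.finite(phi) || phi <= 0) stop("`phi` must be positive", call. = FALSE)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  m <- apply(x, 1, max)
  w <- exp((x - m) / phi)
  w / rowSums(w)
}
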