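# Synthetic coupled-data generators. Defaults reproduce the two simulation
# designs used to study the factorization frameworks: an unstructured
# Gaussian-noise design for cross-validation behaviour, and a weighted
# low-rank design with per-block component weights for parameter recovery.

#' Simulate an unstructured Gaussian coupled dataset
#'
#' Every tensor and matrix entry is drawn i.i.d. from N(mean, sd^2); with
#' the default N(1, 1) and dims (40, 50, 30, 20) this is the pure-noise
#' design used to probe overfitting of the factorization under masked
#' cross-validation: the data carry no low-rank structure, so test error
#' should never drop below train error.
#'
#' @param dims length-4 sizes (n_samples, n_microbes, n_pathways,
#'   n_metabolites); default c(40, 50, 30, 20).
#' @param mean,sd entry distribution parameters; default N(1, 1).
#' @param seed optional RNG seed.
#' @return a \code{coupled_dataset}.
#' @export
simulate_noise_dataset <- function(dims = c(40, 50, 30, 20), mean = 1,
                                   sd = 1, seed = NULL) {
  if (length(dims) != 4L || any(dims < 1))
    stop("'dims' must be four positive sizes", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  tensor <- array(stats::rnorm(prod(dims[1:3]), mean, sd), dim = dims[1:3])
  mat <- matrix(stats::rnorm(dims[1] * dims[4], mean, sd), dims[1], dims[4])
  coupled_dataset(tensor, mat)
}

#' Simulate a weighted low-rank coupled dataset with known ground truth
#'
#' Factor matrices are drawn i.i.d. from N(factor_mean, factor_sd^2)
#' (default N(1, 1)) and the blocks built as
#' \deqn{T = \sum_r \lambda_r\, a_r \circ b_r \circ c_r, \quad
#'       M = \sum_r \sigma_r\, a_r \circ d_r,}
#' optionally plus i.i.d. Gaussian noise. The default weights
#' lambda = (1, 0.5, 1) and sigma = (1, 1, 0.5) make the blocks emphasize
#' different components, so the tensor and matrix do not share all latent
#' factors uniformly.
#'
#' @param dims length-4 sizes; default c(40, 50, 30, 20).
#' @param R number of components; must match the weight lengths.
#' @param lambda tensor-block component weights.
#' @param sigma matrix-block component weights.
#' @param factor_mean,factor_sd factor entry distribution; default N(1, 1).
#' @param noise_sd additive noise standard deviation (default 0: exact
#'   low-rank data).
#' @param seed optional RNG seed.
#' @return list with elements \code{data} (a \code{coupled_dataset}) and
#'   \code{truth} (factors, weights, noise level, seed, dims).
#' @export
simulate_weighted_dataset <- function(dims = c(40, 50, 30, 20), R = 3,
                                      lambda = c(1, 0.5, 1),
                                      sigma = c(1, 1, 0.5),
                                      factor_mean = 1, factor_sd = 1,
                                      noise_sd = 0, seed = NULL) {
  if (length(dims) != 4L || any(dims < 1))
    stop("'dims' must be four positive sizes", call. = FALSE)
  if (length(lambda) != R || length(sigma) != R)
    stop("'lambda' and 'sigma' must have length R", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  draw <- function(n) matrix(stats::rnorm(n * R, factor_mean, factor_sd),
                             n, R)
  a <- draw(dims[1]); b <- draw(dims[2]); c <- draw(dims[3])
  d <- draw(dims[4])
  tensor <- cp_reconstruct(a, b, c, lambda)
  mat <- matrix_reconstruct(a, d, sigma)
  if (noise_sd > 0) {
    tensor <- tensor + array(stats::rnorm(length(tensor), 0, noise_sd),
                             dim = dim(tensor))
    mat <- mat + matrix(stats::rnorm(length(mat), 0, noise_sd),
                        nrow(mat), ncol(mat))
  }
  truth <- list(a = a, b = b, c = c, d = d, lambda = lambda, sigma = sigma,
                noise_sd = noise_sd, seed = seed, dims = dims)
  list(data = coupled_dataset(tensor, mat), truth = truth)
}

#' Simulate a coupled dataset whose blocks share identical weights
#'
#' Same construction as [simulate_weighted_dataset()] with
#' lambda = sigma = \code{weights}: both blocks weight every component
#' identically, the regime in which a shared-factor model without block
#' weights is correctly specified.
#'
#' @param dims length-4 sizes; default c(40, 50, 30, 20).
#' @param weights common component weights, default c(1, 0.5, 1).
#' @param ... passed to [simulate_weighted_dataset()].
#' @param seed optional RNG seed.
#' @return as [simulate_weighted_dataset()].
#' @export
simulate_equal_weights_dataset <- function(dims = c(40, 50, 30, 20),
                                           weights = c(1, 0.5, 1),
                                           seed = NULL, ...) {
  simulate_weighted_dataset(dims = dims, R = length(weights),
                            lambda = weights, sigma = weights,
                            seed = seed, ...)
}
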