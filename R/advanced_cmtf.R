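# Advanced coupled factorization: per-component, per-block weights with an
# L1-type penalty on the weights and a column-centering penalty on the factor
# matrices, minimized jointly by a quasi-Newton (BFGS) solver.
#
#   f = ||T - That||^2 + ||M - Mhat||^2
#       + beta * sum_r sqrt(lambda_r^2 + eps) + beta * sum_r sqrt(sigma_r^2 + eps)
#       + (alpha/2) * sum over factor-matrix columns x of ||x - mean(x)||^2
#
# with That = sum_r lambda_r a_r o b_r o c_r and Mhat = sum_r sigma_r a_r o v_r.
# The smoothed L1 lets some components carry (near-)zero weight in one block,
# so tensor-specific and matrix-specific variation separate.

new_weighted_model <- function(a, b, c, v, lambda, sigma) {
  structure(list(a = a, b = b, c = c, v = v,
                 lambda = lambda, sigma = sigma, R = ncol(a),
                 objective_trace = numeric(0), converged = FALSE,
                 n_iter = 0L),
            class = c("cmtf_weighted_fit", "cmtf_fit"))
}

#' @export
reconstruct.cmtf_weighted_fit <- function(model) {
  list(tensor = cp_reconstruct(model$a, model$b, model$c, model$lambda),
       matrix = matrix_reconstruct(model$a, model$v, model$sigma))
}

center_cols <- function(m) sweep(m, 2, colMeans(m))

#' Objective of the weighted coupled factorization
#'
#' Squared reconstruction error of both blocks, plus a smoothed L1 penalty
#' \eqn{\beta \sum_r \sqrt{w_r^2 + \epsilon}} on each weight vector, plus a
#' column-centering penalty \eqn{(\alpha/2) \sum_x ||x - \bar x||^2} over all
#' columns of the four factor matrices.
#'
#' @param data a \code{coupled_dataset}.
#' @param model a \code{cmtf_weighted_fit} (fields a, b, c, v, lambda, sigma).
#' @param alpha column-penalty coefficient (>= 0).
#' @param beta weight-penalty coefficient (>= 0).
#' @param eps smoothing constant of the L1 term (> 0).
#' @return scalar objective value.
#' @export
advanced_objective <- function(data, model, alpha = 1, beta = 1,
                               eps = 1e-8) {
  stopifnot(alpha >= 0, beta >= 0, eps > 0)
  check_model_data(data, model)
  rec <- reconstruct(model)
  sum((data$tensor - rec$tensor)^2) + sum((data$matrix - rec$matrix)^2) +
    beta * sum(sqrt(model$lambda^2 + eps)) +
    beta * sum(sqrt(model$sigma^2 + eps)) +
    (alpha / 2) * (sum(center_cols(model$a)^2) +
                   sum(center_cols(model$b)^2) +
                   sum(center_cols(model$c)^2) +
                   sum(center_cols(model$v)^2))
}

#' Analytic gradient of the weighted objective
#'
#' Exact gradient of [advanced_objective()] with respect to the factor
#' matrices and both weight vectors; matches central finite differences on
#' small random instances. With E the tensor residual and F the matrix
#' residual (reconstruction minus data):
#' \deqn{\partial a = 2 E_{(1)} (c \odot b)\,diag(\lambda)
#'       + 2 F v\,diag(\sigma) + \alpha (a - \bar a)}
#' \deqn{\partial \lambda_r = 2\,E \times_1 a_r \times_2 b_r \times_3 c_r
#'       + \beta \lambda_r / \sqrt{\lambda_r^2 + \epsilon}}
#' and analogously for b, c, v and sigma.
#'
#' @inheritParams advanced_objective
#' @return list with gradients \code{a}, \code{b}, \code{c}, \code{v},
#'   \code{lambda}, \code{sigma}.
#' @export
advanced_gradient <- function(data, model, alpha = 1, beta = 1,
                              eps = 1e-8) {
  stopifnot(alpha >= 0, beta >= 0, eps > 0)
  check_model_data(data, model)
  a <- model$a; b <- model$b; c <- model$c; v <- model$v
  lambda <- model$lambda; sigma <- model$sigma
  rec <- reconstruct(model)
  Et <- rec$tensor - data$tensor
  Fm <- rec$matrix - data$matrix
  E1 <- matricize(Et, 1); E2 <- matricize(Et, 2); E3 <- matricize(Et, 3)
  kr_cb <- khatri_rao(c, b)
  E1kr <- E1 %*% kr_cb
  Fv <- Fm %*% v
  ga <- 2 * sweep(E1kr, 2, lambda, "*") + 2 * sweep(Fv, 2, sigma, "*") +
    alpha * center_cols(a)
  gb <- 2 * sweep(E2 %*% khatri_rao(c, a), 2, lambda, "*") +
    alpha * center_cols(b)
  gc <- 2 * sweep(E3 %*% khatri_rao(b, a), 2, lambda, "*") +
    alpha * center_cols(c)
  gv <- 2 * sweep(t(Fm) %*% a, 2, sigma, "*") + alpha * center_cols(v)
  glambda <- 2 * colSums(a * E1kr) + beta * lambda / sqrt(lambda^2 + eps)
  gsigma <- 2 * colSums(a * Fv) + beta * sigma / sqrt(sigma^2 + eps)
  list(a = ga, b = gb, c = gc, v = gv, lambda = glambda, sigma = gsigma)
}

pack_par <- function(model) {
  c(as.numeric(model$a), as.numeric(model$b), as.numeric(model$c),
    as.numeric(model$v), model$lambda, model$sigma)
}

unpack_par <- function(par, dims, R) {
  sizes <- c(dims[1] * R, dims[2] * R, dims[3] * R, dims[4] * R, R, R)
  ends <- cumsum(sizes)
  new_weighted_model(
    a = matrix(par[seq_len(ends[1])], dims[1], R),
    b = matrix(par[(ends[1] + 1):ends[2]], dims[2], R),
    c = matrix(par[(ends[2] + 1):ends[3]], dims[3], R),
    v = matrix(par[(ends[3] + 1):ends[4]], dims[4], R),
    lambda = par[(ends[4] + 1):ends[5]],
    sigma = par[(ends[5] + 1):ends[6]])
}

#' Fit the weighted coupled factorization by quasi-Newton optimization
#'
#' Minimizes [advanced_objective()] over all factor matrices and both weight
#' vectors jointly with BFGS, from seeded random starts (weights start at 1).
#' The best of \code{n_starts} restarts by final objective is returned.
#'
#' @param data a \code{coupled_dataset}.
#' @param R number of latent factors.
#' @param alpha,beta,eps penalty parameters, see [advanced_objective()].
#'   No values are prescribed for real data; the defaults alpha = 1,
#'   beta = 1 are starting points the user should tune.
#' @param max_iter BFGS iteration cap per start.
#' @param reltol relative objective tolerance of the optimizer.
#' @param seed RNG seed; restart k uses \code{seed + k - 1}.
#' @param n_starts number of seeded restarts (best kept).
#' @param init_model optional \code{cmtf_fit} or \code{cmtf_weighted_fit}
#'   used as a warm start (replaces the random restarts). A basic fit is
#'   lifted with unit weights.
#' @return a \code{cmtf_weighted_fit} with fields \code{a}, \code{b},
#'   \code{c}, \code{v}, \code{lambda}, \code{sigma},
#'   \code{objective_trace} (objective at each accepted iterate of the
#'   winning start), \code{converged}, \code{n_iter}.
#' @export
#' @examples
#' sim <- simulate_weighted_dataset(dims = c(10, 8, 6, 5), seed = 2)
#' fit <- fit_advanced(sim$data, R = 3, alpha = 0, beta = 0.1, seed = 2,
#'                     n_starts = 1, max_iter = 200)
#' block_weight_shares(fit)
fit_advanced <- function(data, R = 3, alpha = 1, beta = 1, eps = 1e-8,
                         max_iter = 500, reltol = 1e-10, seed = NULL,
                         n_starts = 3, init_model = NULL) {
  stopifnot(inherits(data, "coupled_dataset"))
  dims <- dim(data)
  if (R < 1) stop("'R' must be a positive integer", call. = FALSE)

  env <- new.env()
  fn <- function(par) {
    m <- unpack_par(par, dims, R)
    val <- advanced_objective(data, m, alpha = alpha, beta = beta, eps = eps)
    env$last_f <- val
    val
  }
  gr <- function(par) {
    m <- unpack_par(par, dims, R)
    env$trace <- c(env$trace, env$last_f)
    g <- advanced_gradient(data, m, alpha = alpha, beta = beta, eps = eps)
    c(as.numeric(g$a), as.numeric(g$b), as.numeric(g$c), as.numeric(g$v),
      g$lambda, g$sigma)
  }

  starts <- list()
  if (!is.null(init_model)) {
    m0 <- init_model
    if (!inherits(m0, "cmtf_weighted_fit")) {
      m0 <- new_weighted_model(m0$a, m0$b, m0$c, m0$d,
                               lambda = rep(1, R), sigma = rep(1, R))
    }
    check_model_data(data, m0)
    starts[[1]] <- pack_par(m0)
  } else {
    for (k in seq_len(n_starts)) {
      f0 <- init_factors(dims, R,
                         seed = if (is.null(seed)) NULL else seed + k - 1L)
      starts[[k]] <- pack_par(new_weighted_model(
        f0$a, f0$b, f0$c, f0$d, lambda = rep(1, R), sigma = rep(1, R)))
    }
  }

  best <- NULL
  for (p0 in starts) {
    env$trace <- numeric(0)
    env$last_f <- NA_real_
    res <- stats::optim(p0, fn, gr, method = "BFGS",
                        control = list(maxit = max_iter, reltol = reltol))
    res$trace <- env$trace
    if (is.null(best) || res$value < best$value) best <- res
  }

  model <- unpack_par(best$par, dims, R)
  model$objective_trace <- best$trace
  model$objective <- best$value
  model$converged <- best$convergence == 0
  model$n_iter <- as.integer(best$counts[["gradient"]])
  model$config <- list(R = R, alpha = alpha, beta = beta, eps = eps,
                       max_iter = max_iter, reltol = reltol, seed = seed,
                       n_starts = if (is.null(init_model)) n_starts else 0L)
  model <- finalize_components(model)
  attach_labels(model, data)
}

#' Per-component, per-block weight shares
#'
#' Normalizes the absolute component weights of both blocks to a common
#' total, quantifying how much each latent factor draws from the tensor
#' (microbiome) versus the matrix (metabolome) block:
#' \code{share(tensor, r) = |lambda_r| / (sum|lambda| + sum|sigma|)} and
#' analogously for the matrix block. All 2R shares sum to 1.
#'
#' @param model a fitted \code{cmtf_weighted_fit}.
#' @return matrix with R rows and columns \code{tensor}, \code{matrix}.
#' @export
block_weight_shares <- function(model) {
  stopifnot(inherits(model, "cmtf_weighted_fit"))
  total <- sum(abs(model$lambda)) + sum(abs(model$sigma))
  if (total == 0)
    stop("all component weights are zero; shares are undefined", call. = FALSE)
  out <- cbind(tensor = abs(model$lambda) / total,
               matrix = abs(model$sigma) / total)
  rownames(out) <- paste0("factor_", seq_len(model$R))
  out
}

#' Rescale factor columns to unit norm, absorbing scales into the weights
#'
#' Standard CP normalization: each column of a, b, c (and a, v) is scaled to
#' unit Euclidean norm and the accumulated scale is pushed into lambda
#' (tensor block) and sigma (matrix block). The reconstructions are
#' unchanged; the weights become comparable across components.
#'
#' @param model a \code{cmtf_weighted_fit}.
#' @return the normalized model.
#' @export
normalize_components <- function(model) {
  stopifnot(inherits(model, "cmtf_weighted_fit"))
  nrm <- function(m) apply(m, 2, function(x) sqrt(sum(x^2)))
  na <- nrm(model$a); nb <- nrm(model$b); nc <- nrm(model$c)
  nv <- nrm(model$v)
  safe <- function(n) ifelse(n > 0, n, 1)
  model$a <- sweep(model$a, 2, safe(na), "/")
  model$b <- sweep(model$b, 2, safe(nb), "/")
  model$c <- sweep(model$c, 2, safe(nc), "/")
  model$v <- sweep(model$v, 2, safe(nv), "/")
  model$lambda <- model$lambda * na * nb * nc
  model$sigma <- model$sigma * na * nv
  model
}

#' @export
print.cmtf_weighted_fit <- function(x, ...) {
  cat(sprintf("Weighted CMTF fit: R = %d, %d iteration(s), %s\n", x$R,
              x$n_iter, if (x$converged) "converged" else "not converged"))
  if (!is.null(x$objective))
    cat(sprintf("  objective: %.6g\n", x$objective))
  cat("  lambda:", format(x$lambda, digits = 4), "\n")
  cat("  sigma: ", format(x$sigma, digits = 4), "\n")
  invisible(x)
}
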