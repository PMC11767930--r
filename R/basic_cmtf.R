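# Basic coupled matrix-tensor factorization fitted by alternating least
# squares. The tensor T (sample x microbe x pathway) and matrix M (sample x
# metabolite) share the sample factor a:
#   T ~ sum_r a_r o b_r o c_r,   M ~ sum_r a_r o d_r.

#' Initialize factor matrices for a coupled factorization
#'
#' Draws seeded random factor matrices for the four modes.
#'
#' @param dims length-4 vector (n_samples, n_microbes, n_pathways,
#'   n_metabolites).
#' @param R number of latent factors (>= 1).
#' @param seed optional RNG seed for reproducibility.
#' @param init \code{"normal"} (i.i.d. standard normal, default) or
#'   \code{"uniform"} (U(0, 1)).
#' @return an unfitted object of class \code{cmtf_fit} with factor matrices
#'   \code{a}, \code{b}, \code{c}, \code{d}.
#' @export
init_factors <- function(dims, R, seed = NULL,
                         init = c("normal", "uniform")) {
  init <- match.arg(init)
  if (length(dims) != 4L || any(dims < 1))
    stop("'dims' must be four positive sizes", call. = FALSE)
  if (length(R) != 1L || R < 1)
    stop("'R' must be a positive integer", call. = FALSE)
  if (R > min(dims))
    warning("R exceeds the smallest mode size; the model is over-parameterized")
  if (!is.null(seed)) set.seed(seed)
  draw <- function(n) {
    repeat {
      m <- matrix(if (init == "normal") stats::rnorm(n * R)
                  else stats::runif(n * R), n, R)
      if (all(colSums(m != 0) > 0)) return(m)
    }
  }
  structure(
    list(a = draw(dims[1]), b = draw(dims[2]), c = draw(dims[3]),
         d = draw(dims[4]), R = as.integer(R), rmse_trace = numeric(0),
         converged = FALSE, n_iter = 0L),
    class = "cmtf_fit")
}

check_model_data <- function(data, model) {
  d <- dim(data)
  metab <- if (is.null(model$d)) model$v else model$d
  if (nrow(model$a) != d[1] || nrow(model$b) != d[2] ||
      nrow(model$c) != d[3] || nrow(metab) != d[4])
    stop("model factor shapes do not match the data", call. = FALSE)
  invisible(TRUE)
}

#' One alternating-least-squares sweep
#'
#' Updates the factor matrices once each, in the order a, b, c, d, by the
#' coupled normal equations
#' \deqn{a = [T_{(1)}\; M]\,[(c \odot b); d]\,(b^Tb * c^Tc + d^Td)^\dagger}
#' \deqn{b = T_{(2)} (c \odot a)(a^Ta * c^Tc)^\dagger,\quad
#'       c = T_{(3)} (b \odot a)(a^Ta * b^Tb)^\dagger,\quad
#'       d = M^T (a^\dagger)^T}
#' where \eqn{\odot} is the Khatri-Rao product, \eqn{*} the Hadamard product
#' and \eqn{\dagger} the Moore-Penrose pseudoinverse. Each update is the
#' exact least-squares minimizer for its block given the others, so the
#' combined squared error never increases.
#'
#' @param data a \code{coupled_dataset}.
#' @param model a \code{cmtf_fit} whose factor shapes match \code{data}.
#' @param coupled_sample_update when \code{TRUE} (default) the normal matrix
#'   of the sample update includes the metabolite term \eqn{d^Td} required by
#'   the joint objective; \code{FALSE} drops that term (a documented
#'   compatibility variant that is not the exact coupled minimizer).
#' @return the model with updated factor matrices.
#' @export
als_sweep <- function(data, model, coupled_sample_update = TRUE) {
  check_model_data(data, model)
  T1 <- matricize(data$tensor, 1)
  T2 <- matricize(data$tensor, 2)
  T3 <- matricize(data$tensor, 3)
  M <- data$matrix
  a <- model$a; b <- model$b; c <- model$c; d <- model$d

  G <- cbind(T1, M)
  K <- rbind(khatri_rao(c, b), d)
  N <- crossprod(b) * crossprod(c)
  if (coupled_sample_update) N <- N + crossprod(d)
  a <- G %*% K %*% MASS::ginv(N)

  b <- T2 %*% khatri_rao(c, a) %*% MASS::ginv(crossprod(a) * crossprod(c))
  c <- T3 %*% khatri_rao(b, a) %*% MASS::ginv(crossprod(a) * crossprod(b))
  d <- t(M) %*% t(MASS::ginv(a))

  dimnames(a) <- dimnames(b) <- dimnames(c) <- dimnames(d) <- NULL
  model$a <- a; model$b <- b; model$c <- c; model$d <- d
  model
}

#' Reconstruct both blocks from a fitted model
#'
#' @param model a \code{cmtf_fit} or \code{cmtf_weighted_fit}.
#' @return list with elements \code{tensor} and \code{matrix}.
#' @export
reconstruct <- function(model) UseMethod("reconstruct")

#' @export
reconstruct.cmtf_fit <- function(model) {
  list(tensor = cp_reconstruct(model$a, model$b, model$c),
       matrix = matrix_reconstruct(model$a, model$d))
}

#' Combined reconstruction error of a fitted model
#'
#' Per-entry RMSE, total SSE and relative squared error over the
#' concatenation of the tensor and matrix blocks.
#'
#' @param data a \code{coupled_dataset}.
#' @param model a fitted model.
#' @return list with \code{sse}, \code{rmse}, \code{rel_sq}.
#' @export
reconstruction_error <- function(data, model) {
  rec <- reconstruct(model)
  residual_norms(c(as.numeric(data$tensor), as.numeric(data$matrix)),
                 c(as.numeric(rec$tensor), as.numeric(rec$matrix)))
}

# Order components by explained variance (descending) and flip signs so each
# component's largest-magnitude sample loading is positive. Sign flips are
# applied to (a, b, d) jointly, which leaves both reconstructions unchanged.
finalize_components <- function(model) {
  ev <- explained_variance(model)
  ord <- order(ev, decreasing = TRUE)
  flip <- function(m, s) sweep(m, 2, s, "*")
  s <- vapply(seq_len(model$R), function(r) {
    col <- model$a[, r]
    v <- col[which.max(abs(col))]
    if (v < 0) -1 else 1
  }, numeric(1))
  model$a <- flip(model$a, s)[, ord, drop = FALSE]
  model$b <- flip(model$b, s)[, ord, drop = FALSE]
  model$c <- model$c[, ord, drop = FALSE]
  dn <- if (inherits(model, "cmtf_weighted_fit")) "v" else "d"
  model[[dn]] <- flip(model[[dn]], s)[, ord, drop = FALSE]
  if (!is.null(model$lambda)) model$lambda <- model$lambda[ord]
  if (!is.null(model$sigma)) model$sigma <- model$sigma[ord]
  model
}

attach_labels <- function(model, data) {
  fac <- paste0("factor_", seq_len(model$R))
  rownames(model$a) <- data$sample_ids
  rownames(model$b) <- data$microbe_ids
  rownames(model$c) <- data$pathway_ids
  dn <- if (inherits(model, "cmtf_weighted_fit")) "v" else "d"
  rownames(model[[dn]]) <- data$metabolite_ids
  for (f in c("a", "b", "c", dn)) colnames(model[[f]]) <- fac
  model
}

#' Fit the basic coupled factorization by alternating least squares
#'
#' Iterates [als_sweep()] from a seeded random start until the relative
#' change of the combined per-entry RMSE falls below \code{tol} or
#' \code{max_iter} sweeps are reached. An exactly-zero RMSE is treated as
#' converged (exact fit). After fitting, components are ordered by explained
#' variance and sign-fixed for reporting.
#'
#' @param data a \code{coupled_dataset}.
#' @param R number of latent factors.
#' @param tol relative-change stopping threshold on the RMSE (default 1e-6).
#' @param max_iter maximum number of sweeps.
#' @param seed RNG seed for the initialization.
#' @param init initialization distribution, see [init_factors()].
#' @param coupled_sample_update see [als_sweep()].
#' @return a fitted \code{cmtf_fit} with fields \code{a}, \code{b}, \code{c},
#'   \code{d}, \code{rmse_trace}, \code{converged}, \code{n_iter}.
#' @export
#' @examples
#' sim <- simulate_weighted_dataset(dims = c(12, 10, 8, 6), seed = 1)
#' fit <- fit_basic(sim$data, R = 3, seed = 1)
#' reconstruction_error(sim$data, fit)$rel_sq
fit_basic <- function(data, R, tol = 1e-6, max_iter = 500, seed = NULL,
                      init = "normal", coupled_sample_update = TRUE) {
  stopifnot(inherits(data, "coupled_dataset"))
  if (tol <= 0) stop("'tol' must be positive", call. = FALSE)
  if (max_iter < 1) stop("'max_iter' must be at least 1", call. = FALSE)
  model <- init_factors(dim(data), R, seed = seed, init = init)
  n_entries <- prod(dim(data$tensor)) + length(data$matrix)
  trace <- numeric(0)
  rmse_prev <- Inf
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    model <- als_sweep(data, model,
                       coupled_sample_update = coupled_sample_update)
    rmse <- reconstruction_error(data, model)$rmse
    trace <- c(trace, rmse)
    if (is.finite(rmse_prev)) {
      if (rmse_prev == 0 ||
          abs(rmse - rmse_prev) / rmse_prev <= tol) {
        converged <- TRUE
        break
      }
    }
    rmse_prev <- rmse
  }
  model$rmse_trace <- trace
  model$converged <- converged
  model$n_iter <- it
  model$config <- list(R = R, tol = tol, max_iter = max_iter, seed = seed,
                       init = init,
                       coupled_sample_update = coupled_sample_update)
  model <- finalize_components(model)
  attach_labels(model, data)
}

#' @export
print.cmtf_fit <- function(x, ...) {
  cat(sprintf("Basic CMTF fit: R = %d, %d sweep(s), %s\n", x$R, x$n_iter,
              if (x$converged) "converged" else "not converged"))
  if (length(x$rmse_trace))
    cat(sprintf("  final RMSE: %.6g\n", utils::tail(x$rmse_trace, 1)))
  invisible(x)
}
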