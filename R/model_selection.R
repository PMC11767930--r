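# Masked-entry cross-validation for choosing the number of latent factors.
# Held-out entries are zeroed before fitting (the zero-masking scheme; an
# optional EM-style imputation refit is available), and errors are weighted
# relative squared errors with block weights proportional to block size.

#' Draw a train/test mask pair for both blocks
#'
#' Each tensor and matrix entry is assigned independently to the test set
#' with probability \code{fraction}; mask value 1 marks a training entry.
#' Block weights \code{W_t}, \code{W_m} are set by the size ratio
#' \code{W_t = size(T) / (size(T) + size(M))}, so \code{W_t + W_m = 1}.
#'
#' @param dims length-4 vector (n_samples, n_microbes, n_pathways,
#'   n_metabolites), or a \code{coupled_dataset}.
#' @param fraction hold-out probability in (0, 1); default 0.2.
#' @param seed optional RNG seed.
#' @return object of class \code{mask_pair} with binary \code{omega_t},
#'   \code{omega_m} and weights \code{W_t}, \code{W_m}.
#' @export
make_mask_pair <- function(dims, fraction = 0.2, seed = NULL) {
  if (inherits(dims, "coupled_dataset")) dims <- dim(dims)
  if (length(dims) != 4L || any(dims < 1))
    stop("'dims' must be four positive sizes", call. = FALSE)
  if (length(fraction) != 1L || fraction <= 0 || fraction >= 1)
    stop("'fraction' must lie strictly between 0 and 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n_t <- prod(dims[1:3]); n_m <- dims[1] * dims[4]
  omega_t <- array(stats::rbinom(n_t, 1, 1 - fraction), dim = dims[1:3])
  omega_m <- matrix(stats::rbinom(n_m, 1, 1 - fraction), dims[1], dims[4])
  structure(list(omega_t = omega_t, omega_m = omega_m,
                 holdout_fraction = fraction, seed = seed,
                 W_t = n_t / (n_t + n_m), W_m = n_m / (n_t + n_m)),
            class = "mask_pair")
}

#' Masked cross-validation error
#'
#' The block-weighted relative squared error over the training
#' (\code{which = "train"}, mask entries 1) or test (\code{which = "test"},
#' mask entries 0) part of both blocks:
#' \deqn{W_t \frac{||\omega_t * (T - \hat T)||^2}{||\omega_t * T||^2}
#'     + W_m \frac{||\omega_m * (M - \hat M)||^2}{||\omega_m * M||^2}}
#' (a relative squared error, not a root mean square, despite serving as the
#' cross-validation "error" curve).
#'
#' @param data a \code{coupled_dataset} (the original, unmasked data).
#' @param model a fitted model.
#' @param mask a \code{mask_pair}.
#' @param which \code{"train"} or \code{"test"}.
#' @return scalar error.
#' @export
masked_error <- function(data, model, mask, which = c("train", "test")) {
  which <- match.arg(which)
  stopifnot(inherits(mask, "mask_pair"))
  rec <- reconstruct(model)
  wt <- if (which == "train") mask$omega_t else 1 - mask$omega_t
  wm <- if (which == "train") mask$omega_m else 1 - mask$omega_m
  rt <- residual_norms(data$tensor, rec$tensor, mask = wt)
  rm_ <- residual_norms(data$matrix, rec$matrix, mask = wm)
  mask$W_t * rt$rel_sq + mask$W_m * rm_$rel_sq
}

#' Fit the basic model on masked data
#'
#' Test entries are replaced by 0 (the zero-masking hold-out scheme) and the
#' basic factorization is fitted on the masked data; train and test errors
#' are then evaluated against the original data. With \code{impute = TRUE}
#' the held-out entries are iteratively replaced by the current
#' reconstruction and the model refitted (EM-style), which avoids treating
#' "missing" as "zero".
#'
#' @param data a \code{coupled_dataset}.
#' @param mask a \code{mask_pair}.
#' @param R number of latent factors.
#' @param ... passed to [fit_basic()].
#' @param impute logical; EM-style imputation refits (default off).
#' @param em_iter number of imputation rounds when \code{impute = TRUE}.
#' @return a fitted \code{cmtf_fit} with \code{train_error} and
#'   \code{test_error} fields.
#' @export
fit_masked <- function(data, mask, R, ..., impute = FALSE, em_iter = 10) {
  stopifnot(inherits(mask, "mask_pair"))
  masked <- coupled_dataset(data$tensor * mask$omega_t,
                            data$matrix * mask$omega_m,
                            sample_ids = data$sample_ids,
                            microbe_ids = data$microbe_ids,
                            pathway_ids = data$pathway_ids,
                            metabolite_ids = data$metabolite_ids,
                            groups = data$groups)
  model <- fit_basic(masked, R, ...)
  if (impute) {
    for (i in seq_len(em_iter)) {
      rec <- reconstruct(model)
      filled <- coupled_dataset(
        data$tensor * mask$omega_t + rec$tensor * (1 - mask$omega_t),
        data$matrix * mask$omega_m + rec$matrix * (1 - mask$omega_m),
        sample_ids = data$sample_ids, microbe_ids = data$microbe_ids,
        pathway_ids = data$pathway_ids,
        metabolite_ids = data$metabolite_ids, groups = data$groups)
      model <- fit_basic(filled, R, ...)
    }
  }
  model$train_error <- masked_error(data, model, mask, "train")
  no_test <- all(mask$omega_t == 1) && all(mask$omega_m == 1)
  model$test_error <- if (no_test) NA_real_
                      else masked_error(data, model, mask, "test")
  model
}

#' Cross-validate the number of latent factors
#'
#' Reserves a random fraction of the entries of both blocks as a test set
#' (one mask draw per replicate, shared across the whole rank grid so the
#' train errors are comparable across ranks), fits the basic model on the
#' masked data at each candidate rank and records the train and test
#' errors. Deterministic given \code{seed}; with \code{n_rep > 1} several
#' independent mask draws are made.
#'
#' @param data a \code{coupled_dataset}.
#' @param R_grid candidate ranks, default 1..10.
#' @param fraction hold-out fraction, default 0.2.
#' @param seed RNG seed driving all mask draws and initializations.
#' @param n_rep mask draws per rank (default 1).
#' @param ... passed to [fit_basic()] via [fit_masked()].
#' @return data frame of class \code{cmtf_cv} with columns \code{R},
#'   \code{rep}, \code{train_error}, \code{test_error}.
#' @export
cross_validate <- function(data, R_grid = 1:10, fraction = 0.2, seed = 1,
                           n_rep = 1, ...) {
  if (length(R_grid) == 0)
    stop("'R_grid' must be non-empty", call. = FALSE)
  set.seed(seed)
  mask_seeds <- sample.int(.Machine$integer.max %/% 2, n_rep)
  fit_seeds <- matrix(sample.int(.Machine$integer.max %/% 2,
                                 n_rep * length(R_grid)),
                      nrow = n_rep)
  rows <- list()
  for (rep in seq_len(n_rep)) {
    mask <- make_mask_pair(dim(data), fraction = fraction,
                           seed = mask_seeds[rep])
    for (j in seq_along(R_grid)) {
      fit <- fit_masked(data, mask, R = R_grid[j],
                        seed = fit_seeds[rep, j], ...)
      rows[[length(rows) + 1L]] <-
        data.frame(R = R_grid[j], rep = rep,
                   train_error = fit$train_error,
                   test_error = fit$test_error)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "fraction") <- fraction
  attr(out, "seed") <- seed
  class(out) <- c("cmtf_cv", "data.frame")
  out
}
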