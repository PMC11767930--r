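# Group-separation testing in latent-factor space and loading-based
# biomarker ranking.

#' Explained-variance share of each latent factor
#'
#' The squared Frobenius norm of component r's joint reconstruction (tensor
#' block plus matrix block) divided by the total squared norm of the full
#' reconstruction. For a rank-1 component the block norm factorizes into the
#' product of its vector norms (times the block weight). Shares sum to 1
#' exactly when the components are mutually orthogonal.
#'
#' @param model a fitted \code{cmtf_fit} or \code{cmtf_weighted_fit}.
#' @return numeric vector of length R.
#' @export
explained_variance <- function(model) {
  weighted <- inherits(model, "cmtf_weighted_fit")
  lambda <- if (weighted) model$lambda else rep(1, model$R)
  sigma <- if (weighted) model$sigma else rep(1, model$R)
  dmat <- if (weighted) model$v else model$d
  sq <- function(m) colSums(m^2)
  comp <- lambda^2 * sq(model$a) * sq(model$b) * sq(model$c) +
    sigma^2 * sq(model$a) * sq(dmat)
  rec <- reconstruct(model)
  total <- sum(rec$tensor^2) + sum(rec$matrix^2)
  if (total == 0)
    stop("model reconstruction is identically zero", call. = FALSE)
  unname(comp / total)
}

#' Sample scores on the two top-variance latent factors
#'
#' Projects samples onto the two latent factors with the largest
#' explained-variance share: the corresponding columns of the sample factor
#' matrix, in variance order.
#'
#' @param model a fitted model with R >= 2.
#' @return samples x 2 score matrix.
#' @export
project_top2 <- function(model) {
  if (model$R < 2)
    stop("at least two latent factors are required", call. = FALSE)
  ord <- order(explained_variance(model), decreasing = TRUE)[1:2]
  model$a[, ord, drop = FALSE]
}

#' Two-group separation test in a low-dimensional score space
#'
#' Squared Mahalanobis distance between the group centroids under the pooled
#' within-group covariance,
#' \deqn{D^2 = (\bar y - \bar x)^T S_{pooled}^{-1} (\bar y - \bar x),\quad
#'       S_{pooled} = \frac{(s_1 - 1) S_1 + (s_2 - 1) S_2}{s_1 + s_2 - 2},}
#' converted to the two-sample Hotelling F statistic
#' \deqn{f = \frac{s_1 + s_2 - n - 1}{n (s_1 + s_2 - 2)}
#'       \cdot \frac{s_1 s_2}{s_1 + s_2} \cdot D^2}
#' which under multivariate normality follows F(n, s1 + s2 - n - 1), with n
#' the score dimension (2 for the standard top-2 projection).
#'
#' @param scores numeric matrix, samples x n (typically [project_top2()]).
#' @param groups two-level factor or character vector of group labels, one
#'   per row of \code{scores}; each group needs at least 3 members.
#' @return object of class \code{separation_test} with fields \code{D2},
#'   \code{f}, \code{df}, \code{p.value}, \code{sizes}.
#' @export
mahalanobis_separation <- function(scores, groups) {
  scores <- as.matrix(scores)
  groups <- factor(groups)
  groups <- droplevels(groups)
  if (nlevels(groups) != 2)
    stop("exactly two groups are required", call. = FALSE)
  if (length(groups) != nrow(scores))
    stop("'groups' must have one label per score row", call. = FALSE)
  n <- ncol(scores)
  g1 <- scores[groups == levels(groups)[1], , drop = FALSE]
  g2 <- scores[groups == levels(groups)[2], , drop = FALSE]
  s1 <- nrow(g1); s2 <- nrow(g2)
  if (s1 < 3 || s2 < 3)
    stop("each group needs at least 3 samples", call. = FALSE)
  Sp <- ((s1 - 1) * stats::cov(g1) + (s2 - 1) * stats::cov(g2)) /
    (s1 + s2 - 2)
  diff <- colMeans(g1) - colMeans(g2)
  Sp_inv <- tryCatch(solve(Sp), error = function(e)
    stop("pooled covariance is singular; jitter the scores or inspect the factors for degeneracy",
         call. = FALSE))
  D2 <- as.numeric(t(diff) %*% Sp_inv %*% diff)
  df2 <- s1 + s2 - n - 1
  f <- (df2 / (n * (s1 + s2 - 2))) * (s1 * s2 / (s1 + s2)) * D2
  p <- stats::pf(f, n, df2, lower.tail = FALSE)
  structure(list(D2 = D2, f = f, df = c(df1 = n, df2 = df2), p.value = p,
                 sizes = c(s1 = s1, s2 = s2),
                 groups = levels(groups)),
            class = "separation_test")
}

#' @export
print.separation_test <- function(x, ...) {
  cat("Two-group separation in latent-factor space\n")
  cat(sprintf("  groups: %s (n = %d) vs %s (n = %d)\n",
              x$groups[1], x$sizes[1], x$groups[2], x$sizes[2]))
  cat(sprintf("  D^2 = %.4g, F(%d, %d) = %.4g, p = %.4g\n",
              x$D2, x$df[1], x$df[2], x$f, x$p.value))
  invisible(x)
}

#' Rank features of one mode by absolute loading on a latent factor
#'
#' Features with the largest absolute loadings on a factor are candidate
#' biomarkers; negative loadings indicate a negative association with the
#' factor. Ties in |loading| are broken by feature id (lexicographic).
#'
#' @param model a fitted model.
#' @param mode \code{"microbe"}, \code{"pathway"} or \code{"metabolite"}.
#' @param factor which latent factor (column), default 1.
#' @param k number of features to keep; defaults to all. Values above the
#'   feature count are truncated with a warning.
#' @return data frame of class \code{biomarker_ranking} with columns
#'   \code{feature}, \code{loading}, \code{rank}, \code{sign}.
#' @export
top_loadings <- function(model, mode = c("microbe", "pathway", "metabolite"),
                         factor = 1, k = NULL) {
  mode <- match.arg(mode)
  mat <- switch(mode, microbe = model$b, pathway = model$c,
                metabolite = if (inherits(model, "cmtf_weighted_fit"))
                  model$v else model$d)
  if (factor < 1 || factor > model$R)
    stop("'factor' out of range", call. = FALSE)
  loading <- mat[, factor]
  ids <- rownames(mat)
  if (is.null(ids)) ids <- paste0("feature_", seq_along(loading))
  ord <- order(-abs(loading), ids)
  n <- length(loading)
  if (is.null(k)) k <- n
  if (k < 1) stop("'k' must be at least 1", call. = FALSE)
  if (k > n) {
    warning(sprintf("k = %d exceeds the %d available features; truncated",
                    k, n))
    k <- n
  }
  sel <- ord[seq_len(k)]
  out <- data.frame(feature = ids[sel], loading = unname(loading[sel]),
                    rank = seq_len(k),
                    sign = ifelse(loading[sel] >= 0, 1L, -1L),
                    row.names = NULL)
  attr(out, "mode") <- mode
  attr(out, "factor") <- factor
  class(out) <- c("biomarker_ranking", "data.frame")
  out
}

#' Top-k hit ratio of a biomarker ranking
#'
#' Fraction of the k highest-|loading| features that belong to a validated
#' biomarker set.
#'
#' @param ranking a \code{biomarker_ranking} (from [top_loadings()]).
#' @param validated character vector of validated feature ids.
#' @param k cutoff; defaults to the ranking length.
#' @return ratio in [0, 1].
#' @export
top_k_hit_ratio <- function(ranking, validated, k = NULL) {
  if (is.null(k)) k <- nrow(ranking)
  if (k < 1 || k > nrow(ranking))
    stop("'k' must lie between 1 and the ranking length", call. = FALSE)
  if (length(validated) == 0) {
    warning("empty validated set; hit ratio is 0")
    return(0)
  }
  mean(ranking$feature[seq_len(k)] %in% validated)
}

#' Hit-ratio curve over k = 1..K
#'
#' @inheritParams top_k_hit_ratio
#' @param K largest cutoff; defaults to the ranking length.
#' @return data frame with columns \code{k} and \code{hit_ratio}.
#' @export
hit_ratio_curve <- function(ranking, validated, K = nrow(ranking)) {
  hits <- ranking$feature[seq_len(K)] %in% validated
  data.frame(k = seq_len(K), hit_ratio = cumsum(hits) / seq_len(K))
}
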