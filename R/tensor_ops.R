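# Dense 3-way tensor primitives used by both factorization frameworks.
# Unfolding follows the Kolda-Bader mode-n convention: rows index the chosen
# mode, columns enumerate the remaining modes with the lower-numbered one
# varying fastest.

check_tensor3 <- function(x, name = "tensor") {
  if (!is.array(x) || length(dim(x)) != 3L)
    stop(sprintf("'%s' must be a 3-way array", name), call. = FALSE)
  if (!all(is.finite(x)))
    stop(sprintf("'%s' contains non-finite entries", name), call. = FALSE)
  invisible(x)
}

#' Unfold a 3-way tensor along one mode
#'
#' Rearranges a 3-way array into a matrix whose rows index the chosen mode.
#' Columns enumerate the two remaining modes with the lower-numbered
#' remaining mode varying fastest (Kolda-Bader convention), so that
#' \code{fold(matricize(x, m), m, dim(x))} recovers \code{x} for every mode.
#'
#' @param x a 3-way numeric array.
#' @param mode integer in 1..3, the mode mapped to rows.
#' @return a matrix of dimension \code{dim(x)[mode]} by the product of the
#'   other two mode lengths.
#' @seealso [fold()]
#' @export
#' @examples
#' x <- array(1:24, dim = c(2, 3, 4))
#' dim(matricize(x, 2))  # 3 x 8
matricize <- function(x, mode) {
  if (!is.array(x) || length(dim(x)) != 3L)
    stop("'x' must be a 3-way array", call. = FALSE)
  if (length(mode) != 1L || !mode %in% 1:3)
    stop("'mode' must be 1, 2 or 3", call. = FALSE)
  perm <- c(mode, setdiff(1:3, mode))
  matrix(aperm(x, perm), nrow = dim(x)[mode])
}

#' Fold an unfolded matrix back into a 3-way tensor
#'
#' Exact inverse of [matricize()] under the same column-ordering convention.
#'
#' @param m matrix produced by (or shaped like the output of) [matricize()].
#' @param mode the mode that indexes the rows of \code{m}.
#' @param dims length-3 integer vector, the target tensor shape.
#' @return a 3-way array of dimension \code{dims}.
#' @export
fold <- function(m, mode, dims) {
  m <- as.matrix(m)
  if (length(mode) != 1L || !mode %in% 1:3)
    stop("'mode' must be 1, 2 or 3", call. = FALSE)
  if (length(dims) != 3L || any(dims < 1))
    stop("'dims' must be a length-3 vector of positive sizes", call. = FALSE)
  perm <- c(mode, setdiff(1:3, mode))
  if (nrow(m) != dims[mode] || ncol(m) != prod(dims[-mode]))
    stop(sprintf("matrix of dimension %d x %d is inconsistent with shape (%s) in mode %d",
                 nrow(m), ncol(m), paste(dims, collapse = ","), mode),
         call. = FALSE)
  aperm(array(m, dim = dims[perm]), match(1:3, perm))
}

#' Khatri-Rao (column-wise Kronecker) product
#'
#' Column \code{r} of the result is \code{kronecker(A[, r], B[, r])}, i.e.
#' the row index runs over (i, j) pairs with B's index varying fastest. This
#' matches the unfolding convention used by [matricize()], so
#' \code{matricize(cp_reconstruct(a, b, c), 1) == a \%*\% t(khatri_rao(c, b))}.
#'
#' @param A,B matrices with the same number of columns.
#' @return a matrix with \code{nrow(A) * nrow(B)} rows.
#' @export
khatri_rao <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (ncol(A) != ncol(B))
    stop("'A' and 'B' must have the same number of columns", call. = FALSE)
  I <- nrow(A); J <- nrow(B)
  A[rep(seq_len(I), each = J), , drop = FALSE] *
    B[rep(seq_len(J), times = I), , drop = FALSE]
}

#' Reconstruct a 3-way tensor from CP factor matrices
#'
#' Computes the rank-R tensor with entries
#' \code{sum_r w_r * a[i, r] * b[j, r] * c[k, r]}.
#'
#' @param a,b,c factor matrices with a common column count R.
#' @param weights optional length-R component weights; default all ones.
#' @return a 3-way array of dimension \code{c(nrow(a), nrow(b), nrow(c))}.
#' @export
cp_reconstruct <- function(a, b, c, weights = NULL) {
  a <- as.matrix(a); b <- as.matrix(b); c <- as.matrix(c)
  R <- ncol(a)
  if (ncol(b) != R || ncol(c) != R)
    stop("factor matrices must share the same number of columns", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, R)
  if (length(weights) != R)
    stop("'weights' must have one entry per component", call. = FALSE)
  aw <- sweep(a, 2, weights, "*")
  fold(aw %*% t(khatri_rao(c, b)), 1, c(nrow(a), nrow(b), nrow(c)))
}

#' Reconstruct the coupled matrix block from factor matrices
#'
#' Entry (s, v) is \code{sum_r w_r * a[s, r] * d[v, r]}, i.e.
#' \code{a \%*\% diag(w) \%*\% t(d)}.
#'
#' @param a,d factor matrices with a common column count R.
#' @param weights optional length-R component weights; default all ones.
#' @return a matrix of dimension \code{nrow(a)} by \code{nrow(d)}.
#' @export
matrix_reconstruct <- function(a, d, weights = NULL) {
  a <- as.matrix(a); d <- as.matrix(d)
  R <- ncol(a)
  if (ncol(d) != R)
    stop("factor matrices must share the same number of columns", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, R)
  if (length(weights) != R)
    stop("'weights' must have one entry per component", call. = FALSE)
  sweep(a, 2, weights, "*") %*% t(d)
}

#' Contract a 3-way tensor with one vector per mode
#'
#' Returns the scalar \code{sum_{ijk} x[i,j,k] * u[i] * v[j] * w[k]}, the
#' tensor-vector product in all three modes at once.
#'
#' @param x a 3-way array.
#' @param u,v,w vectors matching modes 1, 2 and 3 of \code{x}.
#' @return a scalar.
#' @export
tensor_vector_contract <- function(x, u, v, w) {
  if (!is.array(x) || length(dim(x)) != 3L)
    stop("'x' must be a 3-way array", call. = FALSE)
  d <- dim(x)
  if (length(u) != d[1] || length(v) != d[2] || length(w) != d[3])
    stop("vector lengths must match the tensor modes", call. = FALSE)
  as.numeric(crossprod(u, matricize(x, 1) %*% kronecker(w, v)))
}

#' Residual error summaries between data and a reconstruction
#'
#' Computes, over the (optionally masked) entries, the sum of squared
#' residuals, the per-entry root mean squared error and the squared residual
#' norm relative to the squared data norm.
#'
#' @param x observed array or matrix.
#' @param xhat reconstruction of the same shape.
#' @param mask optional binary array of the same shape; 1 marks entries that
#'   enter the sums.
#' @return a list with elements \code{sse}, \code{rmse} and \code{rel_sq}.
#' @export
residual_norms <- function(x, xhat, mask = NULL) {
  if (!identical(dim(x), dim(xhat)) && length(x) != length(xhat))
    stop("'x' and 'xhat' must have the same shape", call. = FALSE)
  x <- as.numeric(x); xhat <- as.numeric(xhat)
  if (is.null(mask)) {
    mask <- rep(1, length(x))
  } else {
    mask <- as.numeric(mask)
    if (length(mask) != length(x))
      stop("'mask' must have the same shape as 'x'", call. = FALSE)
    if (!all(mask %in% c(0, 1)))
      stop("'mask' must be binary", call. = FALSE)
  }
  n_used <- sum(mask)
  if (n_used == 0)
    stop("mask excludes every entry", call. = FALSE)
  sse <- sum(mask * (x - xhat)^2)
  denom <- sum(mask * x^2)
  if (denom == 0)
    stop("relative error undefined: masked data entries are all zero",
         call. = FALSE)
  list(sse = sse, rmse = sqrt(sse / n_used), rel_sq = sse / denom)
}
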