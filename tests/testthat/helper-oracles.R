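# Brute-force oracles, independent of the package's linear-algebra paths.

# Mode-n unfolding by explicit index enumeration (Kolda-Bader column order:
# lower-numbered remaining mode varies fastest).
oracle_matricize <- function(x, mode) {
  d <- dim(x)
  rest <- setdiff(1:3, mode)
  m <- matrix(0, d[mode], prod(d[rest]))
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    idx <- c(i, j, k)
    col <- idx[rest[1]] + (idx[rest[2]] - 1) * d[rest[1]]
    m[idx[mode], col] <- x[i, j, k]
  }
  m
}

oracle_khatri_rao <- function(A, B) {
  sapply(seq_len(ncol(A)), function(r) kronecker(A[, r], B[, r]))
}

oracle_cp <- function(a, b, c, w = rep(1, ncol(a))) {
  out <- array(0, dim = c(nrow(a), nrow(b), nrow(c)))
  for (r in seq_len(ncol(a)))
    for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b)))
      for (k in seq_len(nrow(c)))
        out[i, j, k] <- out[i, j, k] + w[r] * a[i, r] * b[j, r] * c[k, r]
  out
}

# Least-squares solve min ||Y - X beta|| via QR, used as the independent
# route for the ALS conditional updates.
oracle_ls <- function(X, Y) qr.coef(qr(X), Y)

# Central finite differences of a scalar function.
fd_gradient <- function(fn, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + h
    xm[i] <- xm[i] - h
    (fn(xp) - fn(xm)) / (2 * h)
  }, numeric(1))
}

random_coupled <- function(dims, seed = NULL, mean = 0, sd = 1) {
  if (!is.null(seed)) set.seed(seed)
  coupled_dataset(
    array(rnorm(prod(dims[1:3]), mean, sd), dim = dims[1:3]),
    matrix(rnorm(dims[1] * dims[4], mean, sd), dims[1], dims[4]))
}

random_weighted_model <- function(dims, R, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cmtfomics:::new_weighted_model(
    a = matrix(rnorm(dims[1] * R), dims[1], R),
    b = matrix(rnorm(dims[2] * R), dims[2], R),
    c = matrix(rnorm(dims[3] * R), dims[3], R),
    v = matrix(rnorm(dims[4] * R), dims[4], R),
    lambda = rnorm(R), sigma = rnorm(R))
}

# Factor congruence: product over the three tensor modes of the absolute
# cosine between matched fitted and true columns; components matched by the
# best of all permutations.
match_components <- function(fit, truth) {
  cosab <- function(x, y) abs(sum(x * y)) / sqrt(sum(x^2) * sum(y^2))
  R <- ncol(fit$a)
  perms <- as.matrix(expand.grid(rep(list(seq_len(R)), R)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == R), ,
                 drop = FALSE]
  best <- NULL
  for (i in seq_len(nrow(perms))) {
    p <- perms[i, ]
    cong <- vapply(seq_len(R), function(r) {
      cosab(fit$a[, r], truth$a[, p[r]]) *
        cosab(fit$b[, r], truth$b[, p[r]]) *
        cosab(fit$c[, r], truth$c[, p[r]])
    }, numeric(1))
    if (is.null(best) || mean(cong) > mean(best$congruence))
      best <- list(perm = p, congruence = cong)
  }
  best
}
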