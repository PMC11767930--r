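test_that("explained_variance reflects component norms", {
  one <- structure(list(a = matrix(1:3), b = matrix(1:2), c = matrix(1:2),
                        d = matrix(1:2), R = 1L), class = "cmtf_fit")
  expect_equal(explained_variance(one), 1)
  # two orthogonal equal-norm components share variance equally
  a <- cbind(c(1, 0, 0, 0), c(0, 1, 0, 0))
  b <- cbind(c(1, 0), c(0, 1)); cc <- cbind(c(1, 0), c(0, 1))
  d <- cbind(c(1, 0), c(0, 1))
  m <- structure(list(a = a, b = b, c = cc, d = d, R = 2L),
                 class = "cmtf_fit")
  expect_equal(explained_variance(m), c(0.5, 0.5))
  expect_equal(sum(explained_variance(m)), 1)
  zero <- structure(list(a = matrix(0, 2, 1), b = matrix(0, 2, 1),
                         c = matrix(0, 2, 1), d = matrix(0, 2, 1), R = 1L),
                    class = "cmtf_fit")
  expect_error(explained_variance(zero), "zero")
})

test_that("project_top2 picks the two top-variance factors in order", {
  # three orthogonal components with norms 1, 3, 2 in the tensor block
  a <- diag(3); b <- diag(3); cc <- diag(3); d <- matrix(0, 2, 3)
  b[, 2] <- b[, 2] * 3; b[, 3] <- b[, 3] * 2
  m <- structure(list(a = a, b = b, c = cc, d = d, R = 3L),
                 class = "cmtf_fit")
  sc <- project_top2(m)
  expect_equal(sc, a[, c(2, 3)])
  one <- structure(list(a = matrix(1, 3, 1), b = matrix(1, 2, 1),
                        c = matrix(1, 2, 1), d = matrix(1, 2, 1), R = 1L),
                   class = "cmtf_fit")
  expect_error(project_top2(one), "two latent factors")
})

test_that("mahalanobis_separation reproduces the hand-worked example", {
  g <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  scores <- rbind(g, sweep(g, 2, c(3, 0), "+"))
  res <- mahalanobis_separation(scores, rep(c("g1", "g2"), each = 4))
  expect_equal(res$D2, 27)
  expect_equal(res$f, 22.5)
  expect_equal(unname(res$df), c(2, 5))
  expect_equal(res$p.value, stats::pf(22.5, 2, 5, lower.tail = FALSE))
  # identical means
  res0 <- mahalanobis_separation(rbind(g, g), rep(c("a", "b"), each = 4))
  expect_equal(res0$D2, 0)
  expect_equal(res0$f, 0)
  expect_equal(res0$p.value, 1)
  expect_error(mahalanobis_separation(scores, rep("g1", 8)), "two groups")
  expect_error(mahalanobis_separation(scores[c(1, 2, 5:8), ],
                                      c("a", "a", "b", "b", "b", "b")),
               "at least 3")
})

test_that("separation agrees with an independent Hotelling-T2 route", {
  set.seed(99)
  for (i in 1:5) {
    s1 <- sample(5:12, 1); s2 <- sample(5:12, 1)
    x <- matrix(rnorm(2 * s1), s1, 2)
    y <- matrix(rnorm(2 * s2), s2, 2) + 0.8
    res <- mahalanobis_separation(rbind(x, y),
                                  c(rep("x", s1), rep("y", s2)))
    # oracle: stats::mahalanobis on the pooled covariance, then the
    # classical T2 -> F conversion
    Sp <- ((s1 - 1) * cov(x) + (s2 - 1) * cov(y)) / (s1 + s2 - 2)
    D2 <- unname(stats::mahalanobis(colMeans(x), colMeans(y), Sp))
    T2 <- (s1 * s2 / (s1 + s2)) * D2
    f <- T2 * (s1 + s2 - 2 - 1) / (2 * (s1 + s2 - 2))
    expect_equal(res$D2, D2, tolerance = 1e-10)
    expect_equal(res$f, f, tolerance = 1e-10)
  }
})

test_that("D2 is invariant under common affine maps of the scores", {
  set.seed(101)
  scores <- matrix(rnorm(40), 20, 2)
  grp <- rep(c("a", "b"), each = 10)
  A <- matrix(c(2, 1, -1, 3), 2, 2)
  shifted <- scores %*% A + matrix(c(5, -7), 20, 2, byrow = TRUE)
  expect_equal(mahalanobis_separation(scores, grp)$D2,
               mahalanobis_separation(shifted, grp)$D2, tolerance = 1e-10)
})

test_that("top_loadings ranks by absolute loading with deterministic ties", {
  b <- matrix(c(0.1, -0.9, 0.5), 3, 1,
              dimnames = list(c("f1", "f2", "f3"), NULL))
  m <- structure(list(a = matrix(0, 2, 1), b = b, c = matrix(0, 2, 1),
                      d = matrix(0, 2, 1), R = 1L), class = "cmtf_fit")
  rk <- top_loadings(m, "microbe", factor = 1, k = 2)
  expect_equal(rk$feature, c("f2", "f3"))
  expect_equal(rk$loading, c(-0.9, 0.5))
  expect_equal(rk$sign, c(-1L, 1L))
  full <- top_loadings(m, "microbe", factor = 1)
  expect_equal(full$feature, c("f2", "f3", "f1"))
  # tie at |0.5| broken lexicographically by id
  b2 <- matrix(c(-0.5, 0.5, 0.1), 3, 1,
               dimnames = list(c("zz", "aa", "mm"), NULL))
  m$b <- b2
  expect_equal(top_loadings(m, "microbe", k = 2)$feature, c("aa", "zz"))
  expect_warning(top_loadings(m, "microbe", k = 10), "truncated")
})

test_that("top_k_hit_ratio counts validated features among the top k", {
  rk <- data.frame(feature = paste0("f", 1:10),
                   loading = seq(1, 0.1, by = -0.1), rank = 1:10,
                   sign = 1L)
  class(rk) <- c("biomarker_ranking", "data.frame")
  expect_equal(top_k_hit_ratio(rk, paste0("f", 1:10), k = 5), 1)
  expect_equal(top_k_hit_ratio(rk, "none", k = 5), 0)
  expect_equal(top_k_hit_ratio(rk, c("f1", "f3", "f9"), k = 10), 0.3)
  expect_warning(r0 <- top_k_hit_ratio(rk, character(0), k = 5), "empty")
  expect_equal(r0, 0)
  # when all validated features outrank the rest, the curve never rises
  curve <- hit_ratio_curve(rk, paste0("f", 1:4))
  expect_true(all(diff(curve$hit_ratio) <= 1e-12))
})

test_that("the null distribution of the separation p-value is calibrated", {
  set.seed(424)
  p <- replicate(400, {
    sc <- matrix(rnorm(48), 24, 2)
    mahalanobis_separation(sc, rep(c("a", "b"), each = 12))$p.value
  })
  # quick sanity bound; the full 2000-draw calibration runs in the
  # acceptance suite
  expect_gt(mean(p < 0.05), 0.02)
  expect_lt(mean(p < 0.05), 0.09)
})
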