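make_profile <- function(pathway, taxon, sample, abundance) {
  data.frame(pathway = pathway, taxon = taxon, sample = sample,
             abundance = abundance, stringsAsFactors = FALSE)
}

test_that("logstack scaling log-transforms totals and scales contributions", {
  p1 <- make_profile("P1", "t1", "s1", 9)
  expect_equal(logstack_scale(p1)$abundance, 1)  # log10(1 + 9)
  p2 <- make_profile("P1", c("t1", "t2"), "s1", c(45, 45))
  expect_equal(logstack_scale(p2)$abundance,
               rep(0.5 * log10(91), 2), tolerance = 1e-12)
  p0 <- make_profile("P1", c("t1", "t2"), "s1", c(0, 0))
  expect_equal(logstack_scale(p0)$abundance, c(0, 0))
  p3 <- make_profile("P1", "t1", "s1", 99)
  expect_equal(logstack_scale(p3, base = exp(1))$abundance, log(100))
  bad <- make_profile("P1", "t1", "s1", -1)
  expect_error(logstack_scale(bad), "non-negative")
})

test_that("logstack preserves within-cell proportions and sums to log total", {
  set.seed(31)
  prof <- make_profile(
    pathway = rep(c("P1", "P2"), each = 6),
    taxon = rep(paste0("t", 1:3), 4),
    sample = rep(rep(c("s1", "s2"), each = 3), 2),
    abundance = rexp(12, rate = 0.1))
  scaled <- logstack_scale(prof)
  cell <- interaction(prof$pathway, prof$sample)
  for (cl in levels(cell)) {
    y <- prof$abundance[cell == cl]
    z <- scaled$abundance[cell == cl]
    expect_equal(z[1] / z[2], y[1] / y[2], tolerance = 1e-12)
    expect_equal(sum(z), log10(1 + sum(y)), tolerance = 1e-12)
  }
})

test_that("clr transform centers each sample row", {
  expect_equal(clr_transform(matrix(1, 1, 4)), matrix(0, 1, 4))
  out <- clr_transform(matrix(c(1, 10, 100), 1))
  expect_equal(as.numeric(out), c(-log(10), 0, log(10)), tolerance = 1e-12)
  set.seed(17)
  m <- matrix(rexp(60), 6, 10)
  m[sample(60, 8)] <- 0
  cl <- clr_transform(m)
  expect_true(all(abs(rowSums(cl)) < 1e-9))
  expect_error(clr_transform(matrix(c(-1, 2), 1)), "non-negative")
  expect_error(clr_transform(m, pseudo = 0), "pseudo")
})

test_that("collapse_to_subjects averages sample rows per subject", {
  m <- rbind(sA1 = c(1, 2), sA2 = c(3, 6), sB1 = c(2, 2))
  colnames(m) <- c("f1", "f2")
  map <- c(sA1 = "A", sA2 = "A", sB1 = "B")
  out <- collapse_to_subjects(m, map)
  expect_equal(out["A", ], c(f1 = 2, f2 = 4))
  expect_equal(out["B", ], c(f1 = 2, f2 = 2))
  # three samples averaging to 3
  m3 <- matrix(c(1, 2, 6), 3, 1, dimnames = list(paste0("s", 1:3), "f"))
  expect_equal(unname(collapse_to_subjects(m3, c(s1 = "x", s2 = "x",
                                                 s3 = "x"))[1, 1]), 3)
  # identity mapping is identity up to ordering
  id_map <- c(sB1 = "sB1", sA1 = "sA1", sA2 = "sA2")
  out_id <- collapse_to_subjects(m, id_map)
  expect_equal(out_id[rownames(m), ], m)
  expect_error(collapse_to_subjects(m, c(sA1 = "A")), "sA2")
})

test_that("collapse_to_subjects works blockwise on coupled datasets", {
  set.seed(41)
  cd <- coupled_dataset(array(rnorm(4 * 3 * 2), dim = c(4, 3, 2)),
                        matrix(rnorm(8), 4, 2),
                        sample_ids = c("s1", "s2", "s3", "s4"),
                        groups = c("g1", "g1", "g2", "g2"))
  map <- c(s1 = "subjA", s2 = "subjA", s3 = "subjB", s4 = "subjB")
  out <- collapse_to_subjects(cd, map)
  expect_equal(out$sample_ids, c("subjA", "subjB"))
  expect_equal(out$tensor[1, , ], (cd$tensor[1, , ] + cd$tensor[2, , ]) / 2)
  expect_equal(unname(out$matrix[2, ]),
               unname(colMeans(cd$matrix[3:4, ])))
  expect_equal(out$groups, c("g1", "g2"))
  bad_map <- c(s1 = "A", s2 = "B", s3 = "B", s4 = "B")
  expect_error(collapse_to_subjects(cd, bad_map), "conflicting group")
})

test_that("assemble_coupled builds the tensor with zero fill and inner join", {
  prof <- make_profile(
    pathway = c("P1", "P1", "P2", "P2", "P1"),
    taxon = c("tA", "tB", "tA", "tB", "tA"),
    sample = c("s1", "s1", "s2", "s3", "s3"),
    abundance = c(2, 1, 4, 5, 3))
  metab <- matrix(1:6, 3, 2,
                  dimnames = list(c("s1", "s2", "s3"), c("m1", "m2")))
  cd <- assemble_coupled(prof, metab, quiet = TRUE)
  expect_equal(dim(cd$tensor), c(3, 2, 2))
  expect_equal(dim(cd$matrix), c(3, 2))
  expect_equal(cd$tensor["s1", "tA", "P1"], 2)
  expect_equal(cd$tensor["s1", "tA", "P2"], 0)  # absent triple -> 0
  # sample present only in one block is dropped
  metab2 <- rbind(metab, s9 = c(7, 8))
  expect_message(cd2 <- assemble_coupled(prof, metab2), "s9")
  expect_equal(cd2$sample_ids, c("s1", "s2", "s3"))
  # empty intersection errors
  metab3 <- matrix(1:2, 1, 2, dimnames = list("sX", c("m1", "m2")))
  expect_error(assemble_coupled(prof, metab3, quiet = TRUE), "share no")
  # duplicate metabolite ids error
  metab4 <- matrix(1:6, 3, 2,
                   dimnames = list(c("s1", "s2", "s3"), c("m1", "m1")))
  expect_error(assemble_coupled(prof, metab4, quiet = TRUE), "duplicate")
})

test_that("assemble_coupled collapses to subjects and attaches groups", {
  prof <- make_profile(
    pathway = rep("P1", 4), taxon = rep("tA", 4),
    sample = c("s1", "s2", "s3", "s4"), abundance = c(1, 3, 5, 7))
  metab <- matrix(c(2, 4, 6, 8), 4, 1,
                  dimnames = list(paste0("s", 1:4), "m1"))
  meta <- data.frame(sample = paste0("s", 1:4),
                     subject = c("A", "A", "B", "B"),
                     group = c("ctl", "ctl", "case", "case"))
  cd <- assemble_coupled(prof, metab, metadata = meta, quiet = TRUE)
  expect_equal(cd$sample_ids, c("A", "B"))
  expect_equal(unname(cd$tensor[, 1, 1]), c(2, 6))
  expect_equal(unname(cd$matrix[, 1]), c(3, 7))
  expect_equal(cd$groups, c("ctl", "case"))
})
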