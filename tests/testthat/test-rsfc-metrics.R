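nets2 <- list(A = c("r1", "r2", "r3"), B = c("r4", "r5"))

make_ts <- function(mat, missing = character(0)) {
  list(data = mat, missing_rois = missing)
}

test_that("fisher z is atanh with clipping and odd symmetry", {
  expect_equal(fisher_z(0), 0)
  expect_equal(round(fisher_z(0.4621), 4), 0.5)
  r <- seq(-0.9, 0.9, by = 0.1)
  expect_equal(fisher_z(-r), -fisher_z(r))
  expect_true(is.finite(fisher_z(1)))
  expect_equal(fisher_z(1), atanh(1 - 1e-7))
  expect_error(fisher_z(1.2), ">")
})

test_that("ROI correlation matrix is symmetric with unit diagonal and propagates missingness", {
  set.seed(1)
  m <- matrix(rnorm(50 * 4), 50, 4,
              dimnames = list(NULL, c("r1", "r2", "r3", "r4")))
  m[, 2] <- 2 * m[, 1]          # perfect linear relation
  cm <- roi_correlation_matrix(m)
  expect_equal(dim(cm$r_values), c(4, 4))
  expect_equal(unname(diag(cm$r_values)), rep(1, 4))
  expect_equal(cm$r_values, t(cm$r_values))
  expect_equal(unname(cm$r_values["r1", "r2"]), 1)
  expect_equal(cm$z_values[!cm$missing_mask],
               fisher_z(cm$r_values[!cm$missing_mask]))

  m2 <- m
  m2[, 3] <- NA                 # missing ROI
  cm2 <- roi_correlation_matrix(m2)
  expect_true(all(cm2$missing_mask["r3", ]))
  expect_true(all(is.na(cm2$r_values["r3", ])))
  # missingness monotonicity: untouched pairs unchanged
  keep <- c("r1", "r2", "r4")
  expect_equal(cm2$r_values[keep, keep], cm$r_values[keep, keep])

  m3 <- m
  m3[, 4] <- 7                  # constant ROI -> undefined correlations
  expect_true(all(roi_correlation_matrix(m3)$missing_mask["r4", ]))
  expect_error(roi_correlation_matrix(m[1:2, ]), "at least 3")
})

test_that("within-network strength equals the brute-force pair enumeration oracle", {
  # direct arithmetic example: pair z values {0.2, 0.4, 0.9} -> mean 0.5
  z <- matrix(NA, 3, 3, dimnames = list(c("r1", "r2", "r3"),
                                        c("r1", "r2", "r3")))
  r <- tanh(c(0.2, 0.4, 0.9))
  m <- diag(3)
  m[1, 2] <- m[2, 1] <- r[1]
  m[1, 3] <- m[3, 1] <- r[2]
  m[2, 3] <- m[3, 2] <- r[3]
  dimnames(m) <- dimnames(z)
  # build a series with exactly this correlation structure via its Cholesky
  set.seed(2)
  base <- qr.Q(qr(scale(matrix(rnorm(200 * 3), 200, 3), scale = FALSE)))
  # centered orthonormal columns, so the sample correlation is exactly m
  series <- base %*% chol(m)
  colnames(series) <- c("r1", "r2", "r3")
  cm <- roi_correlation_matrix(series)
  expect_equal(within_network_strength(cm, list(N = c("r1", "r2", "r3")), "N"),
               mean(c(0.2, 0.4, 0.9)), tolerance = 1e-6)

  # random 6-ROI network vs explicit loop over all 15 pairs
  set.seed(3)
  labs <- paste0("r", 1:6)
  x <- matrix(rnorm(100 * 6), 100, 6, dimnames = list(NULL, labs))
  cmr <- roi_correlation_matrix(x)
  oracle <- local({
    tot <- 0; k <- 0
    for (i in 1:5) for (j in (i + 1):6) {
      tot <- tot + atanh(cor(x[, i], x[, j])); k <- k + 1
    }
    tot / k
  })
  expect_equal(within_network_strength(cmr, list(N = labs), "N"), oracle,
               tolerance = 1e-10)
  expect_equal(k <- 15, 15)

  # a missing ROI restricts the mean to the remaining pairs
  x2 <- x
  x2[, 6] <- NA
  cm2 <- roi_correlation_matrix(x2)
  oracle5 <- local({
    tot <- 0; k <- 0
    for (i in 1:4) for (j in (i + 1):5) {
      tot <- tot + atanh(cor(x[, i], x[, j])); k <- k + 1
    }
    tot / k
  })
  expect_equal(within_network_strength(cm2, list(N = labs), "N"), oracle5)
  # fewer than 2 usable ROIs -> missing marker
  x3 <- x
  x3[, 2:6] <- NA
  expect_true(is.na(within_network_strength(roi_correlation_matrix(x3),
                                            list(N = labs), "N")))
})

test_that("network mask series averages raw member series", {
  m <- cbind(r1 = c(1, 2, 3), r2 = c(3, 2, 1), r3 = c(2, 2, 2),
             r4 = c(0, 1, 0), r5 = c(1, 0, 1))
  expect_equal(network_mask_series(m, nets2, "A"), c(2, 2, 2))
  expect_equal(network_mask_series(m, list(S = "r4"), "S"), c(0, 1, 0))
  # anticorrelated equal-amplitude members cancel
  anti <- cbind(r1 = sin(1:50), r2 = -sin(1:50), r3 = 0)
  expect_equal(var(network_mask_series(anti, nets2, "A")), 0)
  # missing member drops out of the divisor
  ts <- make_ts(m, missing = "r2")
  expect_equal(network_mask_series(ts, nets2, "A"),
               rowMeans(m[, c("r1", "r3")]))
  ts_all <- make_ts(m, missing = c("r4", "r5"))
  expect_null(network_mask_series(ts_all, nets2, "B"))
})

test_that("between-network matrix is 4x4 with 6 unique pairs and respects independence", {
  set.seed(4)
  nets4 <- split(paste0("r", 1:8), rep(c("A", "B", "C", "D"), each = 2))
  x <- matrix(rnorm(3000 * 8), 3000, 8, dimnames = list(NULL, paste0("r", 1:8)))
  bm <- between_network_matrix(x, nets4)
  expect_equal(dim(bm$z_values), c(4, 4))
  off <- bm$z_values[upper.tri(bm$z_values)]
  expect_equal(length(off), 6)
  expect_true(all(abs(off) < 0.08))  # independent signals -> near zero
  # duplicated network signals -> z at the clipping ceiling
  x2 <- x
  x2[, nets4$B] <- x[, nets4$A]
  bm2 <- between_network_matrix(x2, nets4)
  expect_equal(unname(bm2$z_values["A", "B"]), atanh(1 - 1e-7))
})

test_that("dominant-node amplification moves between-network but not within-network metrics", {
  # network A: one node sharing the B signal, one independent node; when the
  # independent node dominates in amplitude, the A mask decouples from B,
  # while correlation-based within-network strength is scale-invariant
  set.seed(5)
  n <- 500
  shared <- rnorm(n)
  x <- cbind(a1 = shared + 0.3 * rnorm(n),
             a2 = rnorm(n),
             b1 = shared + 0.3 * rnorm(n),
             b2 = shared + 0.3 * rnorm(n))
  nets <- list(A = c("a1", "a2"), B = c("b1", "b2"))
  w1 <- within_network_strength(roi_correlation_matrix(x), nets, "A")
  b1 <- between_network_matrix(x, nets)$z_values["A", "B"]
  x2 <- x
  x2[, "a2"] <- x[, "a2"] * 8    # amplify the independent node
  w2 <- within_network_strength(roi_correlation_matrix(x2), nets, "A")
  b2 <- between_network_matrix(x2, nets)$z_values["A", "B"]
  expect_equal(w1, w2, tolerance = 1e-10)   # correlations are scale-free
  expect_lt(abs(b2), abs(b1) - 0.2)         # mask averaging is not
})

test_that("full-size metric table has 4 within and 6 between entries", {
  cfg <- cohort_config(n_per_group = 1, n_behavioral_extra = 0,
                       n_volumes = 60, motion_spike_rate = 0, seed = 2)
  ts <- simulate_bold(list(subject_id = "s1"), cfg, "BL")
  tab <- connectivity_metrics(ts, cfg$networks)
  expect_equal(table(tab$class)[["within"]], 4)
  expect_equal(table(tab$class)[["between"]], 6)
  expect_equal(ncol(roi_correlation_matrix(ts$data)$r_values), 26)
})
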