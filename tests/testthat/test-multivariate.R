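test_that("PCA matches the SVD oracle and is deterministic up to fixed signs", {
  set.seed(21)
  m <- matrix(rexp(20 * 8, 0.2), 20, 8,
              dimnames = list(paste0("a", 1:20), paste0("s", 1:8)))
  g <- setNames(rep(c("W", "P"), each = 4), paste0("s", 1:8))
  ptab <- peak_table(m, g)
  fit <- pca_fit(ptab, n_components = 7)

  # full-rank reconstruction reproduces the scaled matrix
  recon <- fit$scores %*% t(fit$loadings)
  expect_lt(max(abs(recon - fit$X)), 1e-10)

  # explained fractions valid and non-increasing
  expect_true(all(fit$explained >= 0 & fit$explained <= 1))
  expect_true(all(diff(fit$explained) <= 1e-12))

  # oracle: direct SVD gives identical singular values
  sv <- svd(fit$X)
  expect_equal(fit$explained, (sv$d^2 / sum(sv$d^2))[1:7], tolerance = 1e-12)

  # duplicated sample gives identical score rows
  m2 <- cbind(m, s9 = m[, "s1"])
  g2 <- c(g, s9 = "P")
  fit2 <- pca_fit(peak_table(m2, g2), n_components = 3)
  expect_equal(fit2$scores[1, ], fit2$scores[9, ], tolerance = 1e-10)
})

test_that("rank-1 data loads entirely on the first component", {
  base <- c(1, 2, 3, 4, 5, 6)
  m <- rbind(a1 = 1 + base, a2 = 3 + 2 * base, a3 = 10 - base)
  colnames(m) <- paste0("s", 1:6)
  g <- setNames(rep(c("W", "P"), each = 3), colnames(m))
  fit <- pca_fit(peak_table(m, g), n_components = 2)
  expect_equal(fit$explained[1], 1, tolerance = 1e-12)

  # constant analyte is excluded under autoscaling with a warning
  m2 <- rbind(m, flat = rep(2, 6))
  expect_warning(fitc <- pca_fit(peak_table(m2, g), 2), "constant")
  expect_equal(nrow(fitc$loadings), 3L)
})

test_that("PLS-DA separates planted groups, normalizes VIP and bounds Q2 by R2", {
  set.seed(5)
  n <- 16
  g <- setNames(rep(c("A", "B"), each = n), paste0("s", 1:(2 * n)))
  m <- matrix(rexp(2 * 2 * n), 2, 2 * n,
              dimnames = list(c("marker", "noise"), names(g)))
  m["marker", 1:n] <- runif(n, 10, 11)       # disjoint intensity ranges
  m["marker", (n + 1):(2 * n)] <- runif(n, 1, 2)
  fit <- plsda_fit(peak_table(m, g), n_components = 1)
  expect_equal(names(which.max(fit$vip)), "marker")
  expect_gt(fit$q2, 0.9)
  expect_lte(fit$q2, fit$r2y)
  expect_equal(mean(fit$vip^2), 1, tolerance = 1e-8)

  # one-group design is degenerate
  g1 <- setNames(rep("A", 2 * n), names(g))
  expect_error(plsda_fit(peak_table(m, g1)), "two groups")
})

test_that("a 5-SD informative analyte tops the VIP ranking in >=95% of runs", {
  hits <- 0L
  for (i in 1:100) {
    set.seed(i)
    g <- setNames(rep(c("A", "B"), each = 8), paste0("s", 1:16))
    m <- matrix(exp(rnorm(51 * 16, sd = 0.3)), 51, 16,
                dimnames = list(c("signal", paste0("n", 1:50)), names(g)))
    m["signal", 1:8] <- m["signal", 1:8] * exp(5 * 0.3)  # 5 SD shift (log)
    fit <- plsda_fit(peak_table(m, g), n_components = 1)
    if (names(which.max(fit$vip)) == "signal") hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("our PLS-DA agrees with an independent reference implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(8)
  g <- setNames(rep(c("A", "B"), each = 8), paste0("s", 1:16))
  m <- matrix(rexp(25 * 16), 25, 16,
              dimnames = list(paste0("a", 1:25), names(g)))
  m[1, 1:8] <- m[1, 1:8] + 4
  fit <- plsda_fit(peak_table(m, g), n_components = 1)
  ref <- mixOmics::plsda(scale(t(m)), factor(g), ncomp = 1)
  ref_vip <- mixOmics::vip(ref)[, 1]
  expect_equal(unname(fit$vip), unname(ref_vip[names(fit$vip)]),
               tolerance = 1e-8)
  expect_equal(abs(cor(fit$scores[, 1], ref$variates$X[, 1])), 1,
               tolerance = 1e-8)
})

test_that("permutation validation is seeded, bounded below, and detects separation", {
  set.seed(13)
  g <- setNames(rep(c("A", "B"), each = 8), paste0("s", 1:16))
  m <- matrix(rexp(5 * 16), 5, 16, dimnames = list(paste0("a", 1:5), names(g)))
  m[1, 1:8] <- m[1, 1:8] + 20
  fit <- plsda_fit(peak_table(m, g), n_components = 1)
  v1 <- permutation_validate(fit, n_perm = 49, seed = 99)
  v2 <- permutation_validate(fit, n_perm = 49, seed = 99)
  expect_identical(v1$p_value, v2$p_value)
  # strong separation beats every permutation
  expect_equal(v1$p_value, 1 / 50)
  expect_warning(permutation_validate(fit, n_perm = 10, seed = 1), "coarse")
})

test_that("on pure noise the median Q2 is non-positive", {
  q2s <- vapply(1:40, function(i) {
    set.seed(i + 500)
    g <- setNames(rep(c("A", "B"), each = 8), paste0("s", 1:16))
    m <- matrix(rexp(20 * 16), 20, 16,
                dimnames = list(paste0("a", 1:20), names(g)))
    plsda_fit(peak_table(m, g), n_components = 1)$q2
  }, numeric(1))
  expect_lte(median(q2s), 0)
})
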