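random_pls_problem <- function(seed, n = 24, p = 6, collinear = FALSE) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("v", 1:p)))
  if (collinear) X[, p] <- X[, 1] + rnorm(n, sd = 0.05)
  b <- rnorm(p)
  y <- as.numeric(X %*% b) + rnorm(n, sd = 0.5)
  list(X = X, y = y)
}

test_that("a single-component fit on its own predictor is exact", {
  set.seed(1)
  x <- matrix(rnorm(20), 20, 1, dimnames = list(NULL, "v"))
  y <- as.numeric(x)
  fit <- pls_vip(x, y, ncomp = 1)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(unname(coef(fit)["v"]), 1, tolerance = 1e-10)
})

test_that("full-component PLS reproduces OLS and orthogonal scores", {
  for (s in 1:10) {
    pr <- random_pls_problem(s)
    fit <- pls_vip(pr$X, pr$y, ncomp = ncol(pr$X))
    ols <- coef(lm(pr$y ~ pr$X))
    expect_equal(unname(coef(fit)), unname(ols), tolerance = 1e-8)
    g <- crossprod(fit$scores)
    expect_lt(max(abs(g[upper.tri(g)])), 1e-10)
    expect_equal(predict(fit, pr$X), fitted(fit), tolerance = 1e-12)
    expect_equal(residuals(fit), pr$y - fitted(fit), tolerance = 1e-12)
  }
})

test_that("VIP identities hold on every fitted model", {
  for (s in 1:10) {
    pr <- random_pls_problem(s)
    for (a in c(1, 3, ncol(pr$X))) {
      fit <- pls_vip(pr$X, pr$y, ncomp = a)
      v <- strataAGB::vip(fit)
      expect_equal(sum(v^2), ncol(pr$X), tolerance = 1e-8)
      if (a == 1) {
        w <- fit$weights[, 1]
        expect_equal(unname(v),
                     sqrt(ncol(pr$X)) * abs(w) / sqrt(sum(w^2)),
                     tolerance = 1e-10)
      }
    }
  }
})

test_that("VIP matches the mixOmics reference implementation", {
  skip_if_not_installed("mixOmics")
  pr <- random_pls_problem(42, n = 20, p = 10)
  fit <- pls_vip(pr$X, pr$y, ncomp = 3)
  mf <- mixOmics::pls(pr$X, pr$y, ncomp = 3, mode = "regression",
                      scale = TRUE)
  mv <- mixOmics::vip(mf)
  expect_equal(unname(strataAGB::vip(fit)), unname(mv[, 3]),
               tolerance = 1e-10)
})

test_that("permuting predictor columns permutes VIPs identically", {
  pr <- random_pls_problem(7)
  fit <- pls_vip(pr$X, pr$y, ncomp = 3)
  perm <- sample(ncol(pr$X))
  fit2 <- pls_vip(pr$X[, perm], pr$y, ncomp = 3)
  expect_equal(strataAGB::vip(fit2), strataAGB::vip(fit)[perm],
               tolerance = 1e-10)
})

test_that("component count is bounded by rank and sample size", {
  pr <- random_pls_problem(3, n = 12, p = 5)
  Xr <- cbind(pr$X, dup = pr$X[, 1])  # rank 5, p = 6
  expect_error(pls_vip(Xr, pr$y, ncomp = 6), "rank")
  expect_error(pls_vip(pr$X[1:4, ], pr$y[1:4], ncomp = 4), "rank")
  Xz <- pr$X; Xz[, 2] <- 1
  expect_error(pls_vip(Xz, pr$y, ncomp = 2), "v2")
})

test_that("formula interface matches the default method", {
  pr <- random_pls_problem(11, p = 4)
  d <- data.frame(y = pr$y, pr$X)
  f1 <- pls_vip(y ~ v1 + v2 + v3 + v4, data = d, ncomp = 2)
  f2 <- pls_vip(pr$X, pr$y, ncomp = 2)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-12)
  expect_equal(strataAGB::vip(f1), strataAGB::vip(f2), tolerance = 1e-12)
})

test_that("VIP bands follow the stated half-open intervals", {
  cl <- classify_vip(c(psr = 1.084, a = 0.9, b = 0.8, c = 1.0, d = 0.2))
  expect_equal(cl$band[cl$predictor == "psr"], "major")
  expect_equal(cl$band[cl$predictor == "a"], "medium")
  expect_equal(cl$band[cl$predictor == "b"], "negligible")
  expect_equal(cl$band[cl$predictor == "c"], "medium")
  expect_true(all(cl$boundary[cl$predictor %in% c("b", "c")]))
  expect_false(any(cl$boundary[cl$predictor %in% c("psr", "a", "d")]))
  expect_equal(cl$vip, sort(cl$vip, decreasing = TRUE))
})

test_that("cross-validated RMSEP is deterministic under its seed", {
  pr <- random_pls_problem(5)
  cv1 <- cv_rmsep(pr$X, pr$y, ncomp_max = 4, seed = 99)
  cv2 <- cv_rmsep(pr$X, pr$y, ncomp_max = 4, seed = 99)
  expect_identical(cv1, cv2)
  cv3 <- cv_rmsep(pr$X, pr$y, ncomp_max = 4, seed = 100)
  expect_false(identical(cv1$rmsep, cv3$rmsep))
})

test_that("shaving finds an informative predictor among noise", {
  hits <- 0L
  for (s in 1:10) {
    set.seed(s)
    n <- 30
    X <- matrix(rnorm(n * 8), n, 8,
                dimnames = list(NULL, paste0("v", 1:8)))
    y <- 2 * X[, 3] + rnorm(n, sd = 0.3)
    sh <- shave_pls(X, y, seed = s)
    expect_gte(length(sh$selected), 1L)
    if ("v3" %in% sh$selected) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("shaving never empties the predictor set and is deterministic", {
  pr <- random_pls_problem(13, n = 30, p = 6)
  sh <- shave_pls(pr$X, pr$y, step_fraction = 0.99, seed = 1)
  expect_gte(length(sh$selected), 1L)

  sh1 <- shave_pls(pr$X, pr$y, seed = 21)
  sh2 <- shave_pls(pr$X, pr$y, seed = 21)
  expect_identical(sh1$selected, sh2$selected)
  expect_equal(strataAGB::vip(sh1), strataAGB::vip(sh2), tolerance = 0)

  # reporting is idempotent: refitting the selected subset reproduces
  # the reported final VIPs
  refit <- pls_vip(pr$X[, sh1$selected, drop = FALSE], pr$y,
                   ncomp = sh1$model$ncomp)
  expect_equal(strataAGB::vip(refit), strataAGB::vip(sh1),
               tolerance = 1e-12)
})
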