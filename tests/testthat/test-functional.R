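test_that("community-weighted means are abundance-weighted raw traits", {
  tr <- data.frame(species = c("A", "B"), SLA = c(8, 4))
  ab <- one_plot_ab(c(0.25, 0.75), c("A", "B"))
  expect_equal(as.numeric(cwm(ab, tr)), 5)

  mono <- one_plot_ab(1, "A")
  expect_equal(as.numeric(cwm(mono, tr[1, ])), 8)

  ab2 <- one_plot_ab(c(0.5, 0.5), c("A", "C"))
  expect_error(cwm(ab2, tr), "C")
})

test_that("functional space standardizes each trait over the pool", {
  tr <- data.frame(species = letters[1:6], SLA = rnorm(6, 15, 3),
                   LN = rnorm(6, 20, 4))
  z <- functional_space(tr)
  expect_equal(unname(colMeans(z)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(z, 2, sd)), c(1, 1), tolerance = 1e-12)
  tr$LN <- 7
  expect_error(functional_space(tr), "constant")
})

test_that("FDis matches hand values and is an isometry invariant", {
  z <- matrix(c(0, 2), 2, 1, dimnames = list(c("A", "B"), "t"))
  ab <- one_plot_ab(c(0.5, 0.5), c("A", "B"))
  expect_equal(as.numeric(fdis(ab, z)), 1)  # centroid 1, both at distance 1

  expect_equal(as.numeric(fdis(one_plot_ab(1, "A"), z[1, , drop = FALSE])),
               0)  # monoculture

  # translation and rotation leave FDis unchanged
  set.seed(4)
  zz <- matrix(rnorm(12), 6, 2, dimnames = list(letters[1:6], c("x", "y")))
  w <- rgamma(6, 1); w <- w / sum(w)
  ab6 <- one_plot_ab(w, letters[1:6])
  th <- 0.7
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  zz2 <- sweep(zz %*% rot, 2, c(3, -1), "+")
  dimnames(zz2) <- dimnames(zz)
  expect_equal(fdis(ab6, zz), fdis(ab6, zz2), tolerance = 1e-12)
})

test_that("FRic is the pool-relative hull volume with degenerate flagging", {
  sq <- matrix(c(0, 0, 1, 0, 0, 1, 1, 1), 4, 2, byrow = TRUE,
               dimnames = list(c("A", "B", "C", "D"), c("x", "y")))
  ab_all <- one_plot_ab(rep(0.25, 4), rownames(sq))
  expect_equal(as.numeric(fric(ab_all, sq)), 1)

  ab_tri <- one_plot_ab(c(1 / 3, 1 / 3, 1 / 3, 0), rownames(sq))
  expect_equal(as.numeric(fric(ab_tri, sq)), 0.5)

  # abundance beyond presence is ignored
  ab_skew <- one_plot_ab(c(0.97, 0.01, 0.01, 0.01), rownames(sq))
  expect_equal(as.numeric(fric(ab_skew, sq)), 1)

  # fewer points than d + 1: flagged zero
  ab_pair <- one_plot_ab(c(0.5, 0.5, 0, 0), rownames(sq))
  fr <- fric(ab_pair, sq)
  expect_equal(as.numeric(fr), 0)
  expect_true(attr(fr, "degenerate")[["p1"]])
})

test_that("FRic never decreases when a species is added", {
  set.seed(9)
  z <- matrix(rnorm(30), 10, 3,
              dimnames = list(paste0("s", 1:10), c("a", "b", "c")))
  for (rep in 1:10) {
    base <- sort(sample(10, sample(4:8, 1)))
    extra <- sample(setdiff(1:10, base), 1)
    w1 <- w2 <- rep(0, 10)
    w1[base] <- 1 / length(base)
    w2[c(base, extra)] <- 1 / (length(base) + 1)
    ab <- rbind(p1 = w1, p2 = w2)
    colnames(ab) <- rownames(z)
    fr <- fric(ab, z)
    expect_gte(fr[["p2"]], fr[["p1"]] - 1e-8)
  }
})

test_that("FDis and FRic are invariant to raw trait units", {
  set.seed(11)
  tr <- data.frame(species = paste0("s", 1:8),
                   SLA = exp(rnorm(8, 2.7, 0.3)), LN = exp(rnorm(8, 3, 0.2)),
                   LP = exp(rnorm(8, 0.4, 0.3)))
  w <- rgamma(8, 1); w <- w / sum(w)
  ab <- one_plot_ab(w, tr$species)
  tr2 <- tr
  tr2$SLA <- tr$SLA * 100; tr2$LN <- tr$LN / 7; tr2$LP <- tr$LP * 0.001
  z1 <- functional_space(tr); z2 <- functional_space(tr2)
  expect_equal(fdis(ab, z1), fdis(ab, z2), tolerance = 1e-10)
  expect_equal(as.numeric(fric(ab, z1)), as.numeric(fric(ab, z2)),
               tolerance = 1e-8)
})

test_that("FDiv matches the hand-computed log-variance case", {
  # A = {1/2, 1/2}, C = {e, e^3}: ln xbar = 2, V = 1, score = 2/pi atan(5)
  tr <- data.frame(species = c("A", "B"), t1 = c(exp(1), exp(3)))
  ab <- one_plot_ab(c(0.5, 0.5), c("A", "B"))
  expect_equal(as.numeric(fdiv(ab, tr)), 0.874334083621998,
               tolerance = 1e-12)

  # all species identical -> 0; huge spread -> approaches 1
  tr0 <- data.frame(species = c("A", "B"), t1 = c(3, 3))
  expect_equal(as.numeric(fdiv(ab, tr0)), 0)
  trbig <- data.frame(species = c("A", "B"), t1 = c(1e-8, 1e8))
  expect_gt(as.numeric(fdiv(ab, trbig)), 0.999)

  trneg <- data.frame(species = c("A", "B"), t1 = c(-1, 2))
  expect_error(fdiv(ab, trneg), "positive")
})

test_that("metrics equal brute-force oracles on random communities", {
  for (s in 1:30) {
    com <- random_community(s)
    ab <- one_plot_ab(com$w, com$species)
    trait_cols <- setdiff(names(com$traits), "species")
    x <- as.matrix(com$traits[, trait_cols, drop = FALSE])
    rownames(x) <- com$species
    z <- functional_space(com$traits)

    for (tc in seq_along(trait_cols))
      expect_equal(as.numeric(cwm(ab, com$traits)[, tc]),
                   oracle_cwm(com$w, x[, tc]), tolerance = 1e-10)
    expect_equal(as.numeric(fdis(ab, z)), oracle_fdis(com$w, z),
                 tolerance = 1e-10)
    expect_equal(as.numeric(fdiv(ab, com$traits)),
                 oracle_fdiv(com$w, x), tolerance = 1e-10)
  }
})

test_that("hull volumes agree with the independent 3-D oracle", {
  for (s in 1:10) {
    set.seed(100 + s)
    x <- matrix(rnorm(3 * sample(6:12, 1)), ncol = 3)
    expect_equal(convhull_volume(x), oracle_hull3d(x)$volume,
                 tolerance = 1e-8)
  }
})
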