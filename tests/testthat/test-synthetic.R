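small_config <- function(...) {
  sim_config(n_plots = 8, n_species_pool = 20,
             stems_per_plot = c(overstory = 18, understory = 40),
             beta = list(overstory = c(CWM_SLA = 1), understory = NULL),
             ...)
}

test_that("Yule simulator produces reproducible binary ultrametric trees", {
  phy <- simulate_phylogeny(2, seed = 1)
  expect_equal(length(phy$tip.label), 2L)
  d <- patristic_matrix(phy)
  expect_equal(d[1, 2], d[2, 1])
  expect_gt(d[1, 2], 0)

  t1 <- simulate_phylogeny(15, seed = 42)
  t2 <- simulate_phylogeny(15, seed = 42)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  t3 <- simulate_phylogeny(15, seed = 43)
  expect_false(identical(ape::write.tree(t1), ape::write.tree(t3)))

  expect_true(ape::is.binary(t1))
  expect_true(ape::is.ultrametric(t1, tol = 1e-8))
  expect_error(simulate_phylogeny(1), ">= 2")
})

test_that("lineage counts follow the Yule expectation", {
  b <- 1
  n_rep <- 300
  counts <- sapply(seq_len(n_rep), function(s) {
    phy <- simulate_phylogeny(25, birth_rate = b, seed = 5000 + s)
    st <- attr(phy, "split_times")
    c(n1 = 1 + sum(st <= 1), n2 = 1 + sum(st <= 2))
  })
  # E[N(t)] = exp(b t); sd(N(t)) = sqrt(exp(2bt) - exp(bt))
  for (t in 1:2) {
    m <- mean(counts[t, ])
    expv <- exp(b * t)
    se <- sqrt(exp(2 * b * t) - exp(b * t)) / sqrt(n_rep)
    expect_lt(abs(m - expv), 4 * se + 0.05 * expv)
  }
})

test_that("trait signal blends Brownian and independent components", {
  phy <- simulate_phylogeny(8, seed = 77)
  V <- ape::vcv.phylo(phy)
  tbar <- mean(diag(V))
  sigma2 <- 0.3

  expect_equal(simulate_traits(phy, sigma2 = 0, seed = 1)$SLA,
               rep(15, 8))  # degenerate: all at the median

  t1 <- simulate_traits(phy, sigma2, 0.5, seed = 9)
  t2 <- simulate_traits(phy, sigma2, 0.5, seed = 9)
  expect_identical(t1, t2)

  # lambda = 0: tip covariance vanishes off-diagonal
  n_rep <- 300
  z0 <- sapply(seq_len(n_rep), function(s)
    log(simulate_traits(phy, sigma2, lambda = 0, seed = s,
                        means = c(x = 1))$x))
  c0 <- tcrossprod(z0 - rowMeans(z0)) / (n_rep - 1)
  off0 <- c0[upper.tri(c0)]
  expect_lt(max(abs(off0)), 0.25 * sigma2 * tbar)
  expect_equal(mean(diag(c0)), sigma2 * tbar, tolerance = 0.2)

  # lambda = 1: tip covariance proportional to shared branch length
  z1 <- sapply(seq_len(n_rep), function(s)
    log(simulate_traits(phy, sigma2, lambda = 1, seed = 10000 + s,
                        means = c(x = 1))$x))
  c1 <- tcrossprod(z1 - rowMeans(z1)) / (n_rep - 1)
  fit <- lm(as.vector(c1) ~ 0 + as.vector(V))
  expect_equal(unname(coef(fit)), sigma2, tolerance = 0.2)
  expect_gt(cor(as.vector(c1), as.vector(V)), 0.9)
})

test_that("community generator is deterministic and satisfies invariants", {
  cfg <- small_config()
  s1 <- simulate_community(cfg, seed = 3)
  s2 <- simulate_community(cfg, seed = 3)
  expect_identical(as.data.frame(s1$inventory), as.data.frame(s2$inventory))
  expect_identical(s1$environment, s2$environment)
  expect_identical(s1$traits, s2$traits)

  inv <- s1$inventory
  expect_true(all(inv$dbh >= 1))
  expect_true(all(inv$dbh <= 100))
  expect_true(all(inv$height > 0))
  expect_true(all(nchar(inv$species) > 0))
  st <- split_strata(inv, cfg$stratum_threshold)
  expect_true(all(st$understory$dbh < 9))
  expect_true(all(st$overstory$dbh >= 9))
  expect_equal(length(unique(inv$plot_id)), cfg$n_plots)

  # traits strictly positive, one row per pool species
  expect_true(all(as.matrix(s1$traits[, -1]) > 0))
  expect_equal(nrow(s1$traits), cfg$n_species_pool)
})

test_that("ground-truth stem AGB reconciles exactly with the allometry module", {
  cfg <- small_config()
  sim <- simulate_community(cfg, seed = 11)
  gt <- sim$ground_truth

  # per-stem values match stem_agb on the final inventory
  expect_equal(gt$stems$agb_kg,
               stem_agb(gt$stems$dbh, gt$stems$height, gt$stems$species,
                        cfg$allometry), tolerance = 1e-12)

  # per-plot sums match plot_agb per stratum exactly
  sa <- stratum_agb(sim$inventory, cfg$allometry, cfg$stratum_threshold)
  for (stn in c("overstory", "understory")) {
    g <- gt$plots[gt$plots$stratum == stn, ]
    a <- sa[sa$stratum == stn, ]
    expect_equal(g$realized_agb[match(a$plot_id, g$plot_id)], a$agb,
                 tolerance = 1e-10)
  }

  # stratum without planted effect keeps its base stems untouched
  g_u <- gt$plots[gt$plots$stratum == "understory", ]
  expect_equal(g_u$realized_agb, g_u$base_agb, tolerance = 1e-12)
  expect_true(all(is.na(g_u$target_agb)))
})

test_that("planted effects steer plot AGB toward the linear model", {
  cfg <- small_config(noise_frac = 0.1)
  sim <- simulate_community(cfg, seed = 21)
  st <- split_strata(sim$inventory, cfg$stratum_threshold)
  ab <- abundance_matrix(st$overstory)
  tr <- sim$traits
  x <- cwm(ab, tr[normalize_species(tr$species) %in%
                    normalize_species(colnames(ab)), ], "SLA")
  agb <- plot_agb(st$overstory, cfg$allometry)
  m <- merge(agb, data.frame(plot_id = rownames(ab), sla = as.numeric(x)),
             by = "plot_id")
  expect_gt(cor(m$agb, m$sla), 0.6)
})

test_that("dataset writer emits files the readers accept", {
  dir <- withr::local_tempdir()
  sim <- simulate_dataset(small_config(), seed = 2, dir = dir)
  inv <- read_inventory(file.path(dir, "inventory.csv"))
  expect_equal(nrow(inv), nrow(sim$inventory))
  expect_equal(inv$dbh, sim$inventory$dbh, tolerance = 1e-10)
  tr <- read_traits(file.path(dir, "traits.csv"))
  expect_equal(nrow(tr), nrow(sim$traits))
  phy <- read_phylogeny(file.path(dir, "phylogeny.nwk"))
  expect_setequal(phy$tip.label, sim$phylogeny$tip.label)
  env <- read_environment(file.path(dir, "environment.csv"))
  expect_equal(nrow(env), nrow(sim$environment))
  gt <- utils::read.csv(file.path(dir, "ground_truth_plots.csv"))
  expect_true(all(c("base_agb", "target_agb", "realized_agb") %in%
                    names(gt)))
})
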