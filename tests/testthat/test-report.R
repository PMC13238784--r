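test_that("bivariate OLS matches closed forms and lm", {
  set.seed(1)
  x <- rnorm(30)
  y <- 2 * x
  f <- bivariate_fit(x, y)
  expect_equal(f$slope, 2, tolerance = 1e-12)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)
  expect_lt(f$p_value, 1e-12)

  # orthogonalized response: slope and R2 collapse to zero
  y2 <- rnorm(30)
  xc <- x - mean(x)
  y2c <- y2 - mean(y2)
  y2o <- y2c - xc * sum(xc * y2c) / sum(xc * xc)
  f2 <- bivariate_fit(x, y2o)
  expect_equal(f2$slope, 0, tolerance = 1e-10)
  expect_equal(f2$r_squared, 0, tolerance = 1e-10)

  for (s in 1:20) {
    set.seed(s)
    n <- sample(10:40, 1)
    xx <- rnorm(n); yy <- 0.5 * xx + rnorm(n)
    ff <- bivariate_fit(xx, yy)
    lmf <- summary(lm(yy ~ xx))
    expect_equal(ff$slope, unname(coef(lmf)["xx", "Estimate"]),
                 tolerance = 1e-10)
    expect_equal(ff$r_squared, lmf$r.squared, tolerance = 1e-10)
    expect_equal(ff$p_value, unname(coef(lmf)["xx", "Pr(>|t|)"]),
                 tolerance = 1e-10)
    expect_equal(ff$n, n)
  }

  expect_error(bivariate_fit(rep(1, 10), rnorm(10)), "zero-variance")
  expect_error(bivariate_fit(1:2, 1:2), "3 observations")
})

test_that("diversity profile assembles both strata with full columns", {
  cfg <- sim_config(n_plots = 6, n_species_pool = 18,
                    stems_per_plot = c(overstory = 20, understory = 45),
                    beta = list(overstory = NULL, understory = NULL))
  sim <- simulate_community(cfg, seed = 5)
  prof <- diversity_profile(sim$inventory, sim$traits, sim$phylogeny,
                            cfg$allometry)
  expect_setequal(unique(prof$stratum), c("overstory", "understory"))
  expect_true(all(c("agb", "CWM_SLA", "CWM_LC", "FDis", "FRic", "FDiv",
                    "MPD", "MNTD", "PSV", "PSR") %in% names(prof)))
  expect_true(all(prof$agb >= 0))
  expect_true(all(prof$n_species <= prof$n_stems))
  # PSR = n * PSV wherever defined
  ok <- !is.na(prof$PSV)
  expect_equal(prof$PSR[ok], prof$n_species[ok] * prof$PSV[ok],
               tolerance = 1e-10)
})

test_that("diversity profile aborts on species name mismatches", {
  cfg <- sim_config(n_plots = 4, n_species_pool = 12,
                    stems_per_plot = c(overstory = 15, understory = 30),
                    beta = list(overstory = NULL, understory = NULL))
  sim <- simulate_community(cfg, seed = 6)
  bad_traits <- sim$traits[-1, ]
  present <- sim$traits$species[1] %in% sim$inventory$species
  if (present)
    expect_error(
      diversity_profile(sim$inventory, bad_traits, sim$phylogeny),
      sim$traits$species[1])
})

test_that("pipeline runs end to end, deterministically, with full schema", {
  cfg <- sim_config(n_plots = 12, n_species_pool = 25,
                    stems_per_plot = c(overstory = 25, understory = 60),
                    beta = list(overstory = c(CWM_SLA = 1),
                                understory = NULL))
  r1 <- suppressMessages(run_pipeline(cfg, seed = 9))
  r2 <- suppressMessages(run_pipeline(cfg, seed = 9))
  expect_identical(r1$profile, r2$profile)
  expect_identical(r1$vip, r2$vip)
  expect_identical(r1$bivariate, r2$bivariate)

  expect_setequal(names(r1$pls), c("overstory", "understory"))
  cols <- strataAGB:::predictor_columns()
  expect_length(cols, 15L)
  for (stn in names(r1$predictors))
    expect_true(all(cols %in% names(r1$predictors[[stn]])))
  expect_true(all(c("stratum", "predictor", "vip", "band", "boundary")
                  %in% names(r1$vip)))
  expect_true(all(c("stratum", "predictor", "slope", "r_squared",
                    "p_value", "n") %in% names(r1$bivariate)))
  # bivariate fits cover exactly the shaved-in predictors per stratum
  for (stn in names(r1$pls))
    expect_setequal(r1$bivariate$predictor[r1$bivariate$stratum == stn],
                    r1$pls[[stn]]$selected)
  expect_equal(r1$manifest$seed, 9)
  expect_true(nzchar(r1$manifest$config_hash))
})

test_that("pipeline report tables round-trip byte-identically to disk", {
  cfg <- sim_config(n_plots = 10, n_species_pool = 20,
                    stems_per_plot = c(overstory = 20, understory = 50),
                    beta = list(overstory = NULL, understory = NULL))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  suppressMessages(run_pipeline(cfg, seed = 4, out_dir = d1))
  suppressMessages(run_pipeline(cfg, seed = 4, out_dir = d2))
  for (f in c("diversity_profile.csv", "env_scores.csv", "vip_table.csv",
              "bivariate_fits.csv", "stratum_agb_summary.csv")) {
    expect_true(file.exists(file.path(d1, f)))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
})

test_that("pipeline consumes file-based configs written by the generator", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(n_plots = 10, n_species_pool = 20,
                    stems_per_plot = c(overstory = 20, understory = 50),
                    beta = list(overstory = NULL, understory = NULL))
  simulate_dataset(cfg, seed = 8, dir = dir)
  file_cfg <- list(inventory = file.path(dir, "inventory.csv"),
                   traits = file.path(dir, "traits.csv"),
                   phylogeny = file.path(dir, "phylogeny.nwk"),
                   environment = file.path(dir, "environment.csv"),
                   allometry = file.path(dir, "allometry.csv"),
                   stratum_threshold = 9,
                   pls = list(seed = 8))
  rep <- suppressMessages(run_pipeline(file_cfg))
  expect_setequal(unique(rep$profile$stratum),
                  c("overstory", "understory"))
  expect_equal(length(unique(rep$profile$plot_id)), 10L)
})
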