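#' Configuration for the synthetic community generator
#'
#' Bundles every tunable of [simulate_community()] with defaults emulating
#' the study design the package targets: 30 plots of 20 m x 20 m along a
#' 2450-2650 m elevation gradient, a 60-species pool sampled independently
#' by the two strata (observed richness near 48 overstory / 44 understory
#' species), stems of DBH 1-100 cm split at 9 cm, five lognormal leaf
#' traits with tunable phylogenetic signal, and planted predictor-AGB
#' effects that make the true biomass drivers known.
#'
#' @param n_plots number of plots.
#' @param plot_area plot area, m^2.
#' @param n_species_pool species-pool size (>= 4; the trait hull needs at
#'   least traits + 1 points).
#' @param stratum_threshold DBH split, cm.
#' @param birth_rate Yule speciation rate for the pool phylogeny.
#' @param trait_sigma2 Brownian rate of log traits per unit branch length.
#' @param trait_lambda phylogenetic signal blend in [0, 1]: 1 = pure
#'   Brownian motion on the tree, 0 = independent noise of matched scale.
#' @param trait_means median trait values (SLA mm^2/mg, others mg/g).
#' @param concentration Dirichlet concentration of per-plot species weights
#'   around the pool-level relative abundances (smaller = patchier plots).
#' @param base_abund_sdlog lognormal sd of pool-level species commonness.
#' @param stems_per_plot expected stems per plot by stratum.
#' @param dbh per-stratum truncated-lognormal DBH parameters
#'   (`meanlog`, `sdlog`, `min`, `max`; cm).
#' @param height height model `H = h1 * D^h2 * exp(eps)`,
#'   `eps ~ N(0, h_sdlog^2)` (m).
#' @param allometry an [allometric_model()].
#' @param beta named planted effect vectors per stratum (names are
#'   predictor columns, e.g. `CWM_SLA`, `MPD`); `NULL` for no planted
#'   effect in a stratum.
#' @param noise_frac sd of the planted-model noise as a fraction of the
#'   planted signal sd.
#' @param agb_cv coefficient of variation imposed on plot AGB around its
#'   base mean by the planted model.
#' @param basis abundance basis, see [abundance_matrix()].
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_plots = 30,
                       plot_area = 400,
                       n_species_pool = 60,
                       stratum_threshold = 9,
                       birth_rate = 1,
                       trait_sigma2 = 0.02,
                       trait_lambda = 0.5,
                       trait_means = c(SLA = 15, LN = 20, LP = 1.5,
                                       LK = 8, LC = 450),
                       concentration = 15,
                       base_abund_sdlog = 1.5,
                       stems_per_plot = c(overstory = 35, understory = 130),
                       dbh = list(
                         overstory = c(meanlog = log(20), sdlog = 0.6,
                                       min = 9, max = 100),
                         understory = c(meanlog = log(4.3), sdlog = 0.55,
                                        min = 1, max = 9)),
                       height = c(h1 = 2, h2 = 0.6, h_sdlog = 0.1),
                       allometry = default_allometry(),
                       beta = list(overstory = c(CWM_SLA = 1, MPD = 1),
                                   understory = NULL),
                       noise_frac = 0.25,
                       agb_cv = 0.35,
                       basis = "stem_count") {
  cfg <- list(n_plots = n_plots, plot_area = plot_area,
              n_species_pool = n_species_pool,
              stratum_threshold = stratum_threshold,
              birth_rate = birth_rate, trait_sigma2 = trait_sigma2,
              trait_lambda = trait_lambda, trait_means = trait_means,
              concentration = concentration,
              base_abund_sdlog = base_abund_sdlog,
              stems_per_plot = stems_per_plot, dbh = dbh, height = height,
              allometry = allometry, beta = beta, noise_frac = noise_frac,
              agb_cv = agb_cv, basis = basis)
  stopifnot(n_plots >= 1, plot_area > 0, n_species_pool >= 4,
            birth_rate > 0, trait_sigma2 >= 0,
            trait_lambda >= 0, trait_lambda <= 1,
            concentration > 0, noise_frac >= 0, agb_cv > 0,
            all(trait_means > 0))
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a Yule (pure-birth) phylogeny
#'
#' Starts from a single lineage at time zero; with k extant lineages the
#' next split occurs after an Exp(k * birth_rate) wait and splits a
#' uniformly chosen lineage. Simulation stops at `n_species` tips, which
#' are extended to one further exponential wait so the tree is ultrametric.
#' The absolute split times (from time zero) are attached as attribute
#' `"split_times"` so lineage-through-time behaviour can be checked against
#' the Yule expectation `E[N(t)] = exp(birth_rate * t)`.
#'
#' @param n_species number of tips (>= 2).
#' @param birth_rate speciation rate per lineage per unit time.
#' @param seed optional seed (global RNG state is restored afterwards).
#' @return an ultrametric [ape::phylo] tree with tips `sp01`, `sp02`, ...
#' @export
simulate_phylogeny <- function(n_species, birth_rate = 1, seed = NULL) {
  if (n_species < 2) stop("n_species must be >= 2", call. = FALSE)
  with_seed(seed, {
    nsp <- as.integer(n_species)
    split_times <- cumsum(rexp(nsp - 1L, rate = birth_rate * seq_len(nsp - 1L)))
    t_end <- split_times[nsp - 1L] + rexp(1L, rate = birth_rate * nsp)

    # node bookkeeping: children and birth times; node 1 is the stem lineage
    n_nodes <- 2L * nsp - 1L
    child1 <- child2 <- integer(n_nodes)
    birth <- numeric(n_nodes)
    split_at <- rep(NA_real_, n_nodes)
    birth[1L] <- 0
    active <- 1L
    nxt <- 2L
    for (i in seq_len(nsp - 1L)) {
      v <- active[sample.int(length(active), 1L)]
      split_at[v] <- split_times[i]
      child1[v] <- nxt; child2[v] <- nxt + 1L
      birth[nxt] <- birth[nxt + 1L] <- split_times[i]
      active <- c(setdiff(active, v), nxt, nxt + 1L)
      nxt <- nxt + 2L
    }
    tip_counter <- 0L
    fmt <- paste0("sp%0", max(2L, nchar(nsp)), "d")
    nwk <- function(v) {
      len <- (if (is.na(split_at[v])) t_end else split_at[v]) - birth[v]
      if (child1[v] == 0L) {
        tip_counter <<- tip_counter + 1L
        paste0(sprintf(fmt, tip_counter), ":", format(len, digits = 15))
      } else {
        paste0("(", nwk(child1[v]), ",", nwk(child2[v]), "):",
               format(len, digits = 15))
      }
    }
    phy <- ape::read.tree(text = paste0(nwk(1L), ";"))
    attr(phy, "split_times") <- split_times
    phy
  })
}

#' Simulate species traits with tunable phylogenetic signal
#'
#' Each log trait is a blend `sqrt(lambda) * BM + sqrt(1 - lambda) * eps`
#' of a Brownian-motion realization on the tree (rate `sigma2`) and
#' independent normal noise of matched marginal scale
#' (`sd = sqrt(sigma2 * mean depth)`), exponentiated around the configured
#' median so traits are strictly positive (lognormal). `lambda = 1` gives
#' tip covariance proportional to shared branch length; `lambda = 0` gives
#' independent tips; `sigma2 = 0` collapses every species to the median.
#'
#' @param phy an [ape::phylo] tree.
#' @param sigma2 Brownian rate on the log scale.
#' @param lambda signal blend in [0, 1].
#' @param seed optional seed.
#' @param means named median trait values.
#' @return trait table: `species` plus one column per trait.
#' @export
simulate_traits <- function(phy, sigma2 = 0.02, lambda = 0.5, seed = NULL,
                            means = c(SLA = 15, LN = 20, LP = 1.5,
                                      LK = 8, LC = 450)) {
  stopifnot(lambda >= 0, lambda <= 1, sigma2 >= 0, all(means > 0))
  with_seed(seed, {
    n <- length(phy$tip.label)
    V <- ape::vcv.phylo(phy)
    tbar <- mean(diag(V))
    L <- if (sigma2 > 0)
      t(chol(V + diag(1e-10 * tbar, n))) else NULL
    out <- data.frame(species = phy$tip.label, stringsAsFactors = FALSE)
    for (tr in names(means)) {
      z <- if (sigma2 == 0) rep(0, n) else {
        bm <- sqrt(sigma2) * as.numeric(L %*% rnorm(n))
        eps <- rnorm(n, 0, sqrt(sigma2 * tbar))
        sqrt(lambda) * bm + sqrt(1 - lambda) * eps
      }
      out[[tr]] <- means[[tr]] * exp(z)
    }
    out
  })
}

# truncated lognormal DBH draw
rdbh <- function(n, par) {
  lo <- stats::plnorm(par[["min"]], par[["meanlog"]], par[["sdlog"]])
  hi <- stats::plnorm(par[["max"]], par[["meanlog"]], par[["sdlog"]])
  qlnorm(runif(n, lo, hi), par[["meanlog"]], par[["sdlog"]])
}

#' Simulate a plot-by-environment table
#'
#' Topography is drawn uniformly over the study design's ranges (elevation
#' 2450-2650 m, slope 5-35 deg, aspect 0-360 deg). Edaphic variables load
#' on two latent factors — fertility (SOM, TN, TP, TK, AN, AK) and acidity
#' (pH inversely; AP, AB) — plus independent noise, giving the correlated
#' structure a soil PCA can compress.
#'
#' @param n_plots number of plots.
#' @param plot_ids plot identifiers.
#' @param seed optional seed.
#' @return data.frame with `plot_id`, `elevation`, `slope`, `aspect`,
#'   `pH`, `SOM`, `TN`, `TP`, `TK`, `AN`, `AP`, `AK`, `AB`.
#' @export
simulate_environment <- function(n_plots,
                                 plot_ids = sprintf("plot%02d",
                                                    seq_len(n_plots)),
                                 seed = NULL) {
  with_seed(seed, {
    n <- n_plots
    f1 <- rnorm(n); f2 <- rnorm(n)
    mk <- function(mu, sd, l1, l2 = 0) {
      res <- sqrt(max(0, 1 - l1^2 - l2^2))
      pmax(mu + sd * (l1 * f1 + l2 * f2 + rnorm(n, 0, res)), mu * 0.05)
    }
    data.frame(
      plot_id = plot_ids,
      elevation = runif(n, 2450, 2650),
      slope = runif(n, 5, 35),
      aspect = runif(n, 0, 360),
      pH = mk(4.55, 0.18, 0, -0.7),
      SOM = mk(80, 20, 0.8),
      TN = mk(4, 1, 0.8),
      TP = mk(0.8, 0.2, 0.6),
      TK = mk(15, 4, 0.5),
      AN = mk(0.30, 0.08, 0.7),
      AP = mk(0.02, 0.008, 0.3, 0.5),
      AK = mk(0.15, 0.05, 0.7),
      AB = mk(0.001, 0.0004, 0.2, 0.6),
      stringsAsFactors = FALSE
    )
  })
}

# Assemble the per-plot predictor columns for one stratum. `only` limits
# computation to the column families actually requested.
predictor_frame <- function(inv, traits, phy, env_scores = NULL,
                            basis = "stem_count", only = NULL) {
  want <- function(cols) is.null(only) || any(cols %in% only)
  trait_cols <- setdiff(names(traits), "species")
  out <- NULL
  add <- function(df) if (is.null(out)) df else
    merge(out, df, by = "plot_id", sort = FALSE)
  ab <- abundance_matrix(inv, basis)
  pool_traits <- traits[normalize_species(traits$species) %in%
                          normalize_species(colnames(ab)), , drop = FALSE]
  if (want(paste0("CWM_", trait_cols))) {
    out <- add(data.frame(plot_id = rownames(ab),
                          cwm(ab, pool_traits, trait_cols),
                          stringsAsFactors = FALSE))
  }
  if (want(c("FDis", "FRic", "FDiv"))) {
    fs <- functional_space(pool_traits, trait_cols)
    fdis_v <- if (want("FDis")) fdis(ab, fs) else NULL
    fric_v <- if (want("FRic")) as.numeric(fric(ab, fs)) else NULL
    fdiv_v <- if (want("FDiv")) fdiv(ab, pool_traits, trait_cols) else NULL
    df <- data.frame(plot_id = rownames(ab), stringsAsFactors = FALSE)
    if (!is.null(fdis_v)) df$FDis <- fdis_v
    if (!is.null(fric_v)) df$FRic <- fric_v
    if (!is.null(fdiv_v)) df$FDiv <- fdiv_v
    out <- add(df)
  }
  if (want(c("MPD", "MNTD", "PSV", "PSR", "n_species"))) {
    pp <- phylo_profile(inv, phy, basis)
    out <- add(pp)
  }
  if (!is.null(env_scores) && want(setdiff(names(env_scores), "plot_id"))) {
    out <- add(env_scores)
  }
  out
}

#' Simulate a stratified forest community with planted AGB drivers
#'
#' End-to-end generator: Yule pool phylogeny, lognormal traits with
#' phylogenetic signal, per-plot species abundances (Dirichlet around
#' lognormal pool commonness, drawn independently per stratum), stem DBH
#' from stratum-specific truncated lognormals, heights from a power-law
#' model, per-stem AGB from the configured allometry — then, for each
#' stratum with a planted effect vector, plot AGB is steered toward the
#' linear model `AGB = mean + cv * (X beta + noise)` by rescaling stem
#' counts (stems are resampled from the plot's own stem pool until the
#' target biomass is reached, preserving composition), so the true drivers
#' of AGB are known exactly.
#'
#' @param config a [sim_config()].
#' @param seed optional seed; the whole simulation is deterministic given
#'   it.
#' @return list with `inventory` ([plot_inventory()]), `environment`,
#'   `traits`, `phylogeny`, and `ground_truth` (list: `stems` — the exact
#'   final stem table with per-stem AGB in kg; `plots` — per plot/stratum
#'   base, target and realized AGB with the planted signal and noise;
#'   `beta`, `predictors`).
#' @export
simulate_community <- function(config = sim_config(), seed = NULL) {
  cfg <- config
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(seed, {
    phy <- simulate_phylogeny(cfg$n_species_pool, cfg$birth_rate)
    traits <- simulate_traits(phy, cfg$trait_sigma2, cfg$trait_lambda,
                              means = cfg$trait_means)
    plot_ids <- sprintf("plot%02d", seq_len(cfg$n_plots))
    env <- simulate_environment(cfg$n_plots, plot_ids)
    nsp <- cfg$n_species_pool
    strata <- c("overstory", "understory")

    stems_by_stratum <- list()
    for (st in strata) {
      base_w <- rlnorm(nsp, 0, cfg$base_abund_sdlog)
      base_w <- base_w / sum(base_w)
      # Dirichlet mass: total concentration governs plot-to-plot
      # compositional turnover; base_w sets which species are common
      alpha <- cfg$concentration * base_w
      rows <- list()
      for (p in seq_len(cfg$n_plots)) {
        g <- rgamma(nsp, shape = alpha)
        if (all(g == 0)) g[sample.int(nsp, 1L)] <- 1
        w <- g / sum(g)
        n_stems <- max(5L, rpois(1L, cfg$stems_per_plot[[st]]))
        counts <- as.integer(rmultinom(1L, n_stems, w))
        idx <- rep(seq_len(nsp), counts)
        dbh <- rdbh(length(idx), cfg$dbh[[st]])
        height <- cfg$height[["h1"]] * dbh^cfg$height[["h2"]] *
          exp(rnorm(length(idx), 0, cfg$height[["h_sdlog"]]))
        rows[[p]] <- data.frame(plot_id = plot_ids[p],
                                species = phy$tip.label[idx],
                                dbh = dbh, height = pmax(height, 0.1),
                                stringsAsFactors = FALSE)
      }
      stems_by_stratum[[st]] <- do.call(rbind, rows)
    }

    gt_plots <- list(); gt_pred <- list()
    for (st in strata) {
      stems <- stems_by_stratum[[st]]
      stems$agb_kg <- stem_agb(stems$dbh, stems$height, stems$species,
                               cfg$allometry)
      beta <- cfg$beta[[st]]
      base_agb <- tapply(stems$agb_kg, factor(stems$plot_id, plot_ids),
                         sum, default = 0) / 1000 * 10000 / cfg$plot_area
      if (is.null(beta) || length(beta) == 0L) {
        stems_by_stratum[[st]] <- stems
        gt_plots[[st]] <- data.frame(
          plot_id = plot_ids, stratum = st,
          base_agb = as.numeric(base_agb),
          target_agb = NA_real_, realized_agb = as.numeric(base_agb),
          signal = NA_real_, noise = NA_real_,
          stringsAsFactors = FALSE)
        next
      }
      mbar <- mean(base_agb)
      e <- NULL
      stems2 <- stems
      # One fixed random stem order per plot: the retained stem set is then
      # a deterministic, nested function of the target biomass, which lets
      # the fixed-point iteration below converge.
      plot_rows <- lapply(plot_ids, function(pid)
        which(stems$plot_id == pid))
      plot_ord <- lapply(plot_rows, function(rw) rw[sample.int(length(rw))])
      # Fixed-point iteration: the planted relation must hold between plot
      # AGB and the predictor values recomputed from the FINAL inventory,
      # so re-derive the target from the current composition and resample
      # again from the original stem pool until the two are consistent.
      # Targets are damped (averaged with the previous round) to suppress
      # 2-cycles where a plot alternates between two retained stem sets.
      prev_target <- NULL
      for (iter in seq_len(20L)) {
        inv_cur <- plot_inventory(stems2[, c("plot_id", "species", "dbh",
                                             "height")], cfg$plot_area)
        pred <- predictor_frame(inv_cur, traits, phy, basis = cfg$basis,
                                only = names(beta))
        miss <- setdiff(names(beta), names(pred))
        if (length(miss))
          stop("planted effect on unknown predictor(s): ",
               paste(miss, collapse = ", "), call. = FALSE)
        pred <- pred[match(plot_ids, pred$plot_id), , drop = FALSE]
        X <- as.matrix(pred[, names(beta), drop = FALSE])
        if (anyNA(X)) {
          if (iter == 1L)
            stop("planted predictors undefined for some plots ",
                 "(fewer than 2 species?)", call. = FALSE)
          break  # degenerate plot after rescaling: keep previous round
        }
        s <- as.numeric(scale(X) %*% beta)
        if (is.null(e))  # noise drawn once, reused across iterations
          e <- rnorm(cfg$n_plots, 0, cfg$noise_frac * sd(s))
        g <- s + e
        target <- mbar * (1 + cfg$agb_cv * g / sd(g))
        floored <- target < 0.05 * mbar
        if (mean(floored) > 0.1)
          stop("infeasible planted effects: >10% of plots require ",
               "non-positive AGB", call. = FALSE)
        target[floored] <- 0.05 * mbar
        if (!is.null(prev_target)) {
          if (max(abs(target - prev_target) / mbar) < 0.01) {
            target <- prev_target  # converged: keep the realized state
            break
          }
          target <- (target + prev_target) / 2
        }
        prev_target <- target
        target_kg <- target * cfg$plot_area / 10000 * 1000

        new_rows <- list()
        for (p in seq_len(cfg$n_plots)) {
          ord <- plot_ord[[p]]
          csum <- cumsum(stems$agb_kg[ord])
          n_full <- 0L
          tk <- target_kg[p]
          while (tk > csum[length(csum)]) {  # whole-pool replications
            n_full <- n_full + 1L
            tk <- tk - csum[length(csum)]
          }
          n_part <- which(csum >= tk)[1L]
          if (is.na(n_part)) n_part <- length(ord)
          # round to the nearer prefix so realized AGB tracks the target
          if (n_part > 1L && tk - csum[n_part - 1L] < csum[n_part] - tk)
            n_part <- n_part - 1L
          take <- c(rep(ord, n_full), ord[seq_len(n_part)])
          new_rows[[p]] <- stems[take, , drop = FALSE]
        }
        stems2 <- do.call(rbind, new_rows)
        rownames(stems2) <- NULL
      }
      stems_by_stratum[[st]] <- stems2
      realized <- tapply(stems2$agb_kg, factor(stems2$plot_id, plot_ids),
                         sum, default = 0) / 1000 * 10000 / cfg$plot_area
      gt_plots[[st]] <- data.frame(
        plot_id = plot_ids, stratum = st,
        base_agb = as.numeric(base_agb), target_agb = target,
        realized_agb = as.numeric(realized), signal = s, noise = e,
        stringsAsFactors = FALSE)
      gt_pred[[st]] <- cbind(stratum = st, pred)
    }

    stems_all <- do.call(rbind, lapply(strata, function(st)
      cbind(stratum = st, stems_by_stratum[[st]])))
    rownames(stems_all) <- NULL
    inv <- plot_inventory(stems_all[, c("plot_id", "species", "dbh",
                                        "height")], cfg$plot_area)
    list(inventory = inv,
         environment = env,
         traits = traits,
         phylogeny = phy,
         ground_truth = list(
           stems = stems_all,
           plots = do.call(rbind, gt_plots),
           beta = cfg$beta,
           predictors = if (length(gt_pred))
             do.call(rbind, gt_pred) else NULL),
         config = cfg)
  })
}

#' Simulate a dataset and optionally write it to disk
#'
#' Runs [simulate_community()] and, when `dir` is given, writes every file
#' the readers in this package consume: `inventory.csv`, `traits.csv`,
#' `environment.csv`, `phylogeny.nwk`, `allometry.csv`, plus
#' `ground_truth_stems.csv` and `ground_truth_plots.csv`.
#'
#' @inheritParams simulate_community
#' @param dir output directory (created if needed); `NULL` skips writing.
#' @return the [simulate_community()] result, invisibly when writing.
#' @export
simulate_dataset <- function(config = sim_config(), seed = 1, dir = NULL) {
  sim <- simulate_community(config, seed)
  if (is.null(dir)) return(sim)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, f) write.table(df, file.path(dir, f), sep = ",",
                                    row.names = FALSE, quote = FALSE)
  wr(as.data.frame(sim$inventory), "inventory.csv")
  wr(sim$traits, "traits.csv")
  wr(sim$environment, "environment.csv")
  ape::write.tree(sim$phylogeny, file.path(dir, "phylogeny.nwk"))
  wr(as.data.frame(sim$config$allometry), "allometry.csv")
  wr(sim$ground_truth$stems, "ground_truth_stems.csv")
  wr(sim$ground_truth$plots, "ground_truth_plots.csv")
  invisible(sim)
}
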