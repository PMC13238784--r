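#' Bivariate OLS fit of AGB on one predictor
#'
#' Ordinary least squares of `y` on `x`: slope, intercept, R-squared (the
#' squared Pearson correlation) and the two-sided p-value of the slope from
#' the t statistic with n - 2 degrees of freedom.
#'
#' @param x predictor vector.
#' @param y response vector.
#' @return one-row data.frame: `slope`, `intercept`, `r_squared`,
#'   `p_value`, `n`.
#' @export
bivariate_fit <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("bivariate fit needs at least 3 observations",
                   call. = FALSE)
  if (sd(x) == 0) stop("zero-variance predictor", call. = FALSE)
  r <- cor(x, y)
  slope <- r * sd(y) / sd(x)
  intercept <- mean(y) - slope * mean(x)
  r2 <- r^2
  tstat <- r * sqrt((n - 2) / max(1 - r2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  data.frame(slope = slope, intercept = intercept, r_squared = r2,
             p_value = p, n = n)
}

#' Per-plot, per-stratum diversity and AGB profile
#'
#' Splits the inventory at the stratum threshold and assembles, for each
#' stratum, plot AGB (Mg/ha), community-weighted means, functional
#' diversity (FDis, FRic, FDiv) and phylogenetic diversity (MPD, MNTD,
#' PSV, PSR).
#'
#' @param inventory a [plot_inventory()].
#' @param traits trait table covering the inventory's species.
#' @param phylogeny phylogeny covering the inventory's species.
#' @param model an [allometric_model()].
#' @param threshold stratum DBH threshold (cm).
#' @param basis abundance basis, see [abundance_matrix()].
#' @return data.frame keyed by `plot_id`, `stratum` with columns `agb`,
#'   `n_stems`, `n_species`, `CWM_*`, `FDis`, `FRic`, `FDiv`,
#'   `FRic_degenerate`, `MPD`, `MNTD`, `PSV`, `PSR`.
#' @export
diversity_profile <- function(inventory, traits, phylogeny,
                              model = default_allometry(), threshold = 9,
                              basis = "stem_count") {
  rep <- match_names(inventory, traits, phylogeny)
  if (!rep$ok)
    stop("species name mismatch; missing from traits: ",
         paste(rep$missing_from_traits, collapse = ", "),
         "; missing from tree: ",
         paste(rep$missing_from_tree, collapse = ", "), call. = FALSE)
  st <- split_strata(inventory, threshold)
  out <- list()
  for (nm in names(st)) {
    inv <- st[[nm]]
    if (nrow(inv) == 0L) next
    agb <- plot_agb(inv, model)
    fp <- functional_profile(inv, traits, basis)
    pp <- phylo_profile(inv, phylogeny, basis)
    pp$n_species <- NULL  # already in the AGB table
    m <- merge(merge(agb, fp, by = "plot_id", sort = FALSE),
               pp, by = "plot_id", sort = FALSE)
    out[[nm]] <- cbind(stratum = nm, m)
  }
  res <- do.call(rbind, out)
  res <- res[, c("plot_id", "stratum",
                 setdiff(names(res), c("plot_id", "stratum")))]
  rownames(res) <- NULL
  res
}

# predictor column set used for the PLS candidate matrix
predictor_columns <- function(trait_cols = c("SLA", "LN", "LP", "LK", "LC")) {
  c(paste0("CWM_", trait_cols), "FDis", "FRic", "FDiv",
    "MPD", "MNTD", "PSR", "Soil_PC1", "Soil_PC2", "Topo_PC1", "Topo_PC2")
}

#' Run the full diversity-to-AGB analysis pipeline
#'
#' Orchestrates every stage: input loading (or synthetic generation),
#' species-name reconciliation, per-stratum AGB, functional and
#' phylogenetic diversity profiles, environmental PCA, PLS regression of
#' AGB on the candidate predictor matrix with backward shaving and VIP
#' classification, and bivariate OLS fits of AGB on each predictor
#' surviving shaving. Deterministic given `seed`.
#'
#' Inputs come either from a configuration (list or YAML path with keys
#' `inventory`, `traits`, `phylogeny`, `environment`, optional `allometry`,
#' `stratum_threshold`, `basis`, `pls` settings) or from the synthetic
#' generator when `config` is `NULL` or a [sim_config()].
#'
#' @param config `NULL` (synthetic defaults), a [sim_config()], a YAML file
#'   path, or a list of file paths/settings.
#' @param seed seed for the synthetic generator and PLS fold assignment.
#' @param out_dir optional directory; when given, every report table is
#'   written there as CSV.
#' @param cv_folds,step_fraction,ncomp_max shaving settings (see
#'   [shave_pls()]); overridden by `config$pls` when present.
#' @return list of class `agb_report`: `profile` (diversity profile),
#'   `env` ([env_pca()] result), `predictors` (per-stratum matrices),
#'   `pls` (per-stratum [shave_pls()] objects), `vip` (stacked VIP table),
#'   `bivariate` (stacked OLS table), `agb` (stratum AGB summary),
#'   `manifest`, and for synthetic runs `simulation` (the generator
#'   output).
#' @export
run_pipeline <- function(config = NULL, seed = 1, out_dir = NULL,
                         cv_folds = 10, step_fraction = 0.2,
                         ncomp_max = 5) {
  if (is.character(config)) config <- read_config(config)
  sim <- NULL
  if (is.null(config) || inherits(config, "sim_config")) {
    cfg <- if (is.null(config)) sim_config() else config
    message("stage simulate: generating synthetic community (seed ", seed,
            ")")
    sim <- simulate_community(cfg, seed)
    inventory <- sim$inventory
    traits <- sim$traits
    phylogeny <- sim$phylogeny
    environment <- sim$environment
    model <- cfg$allometry
    threshold <- cfg$stratum_threshold
    basis <- cfg$basis
  } else {
    stopifnot(is.list(config))
    for (k in c("inventory", "traits", "phylogeny", "environment"))
      if (is.null(config[[k]]))
        stop("config is missing input '", k, "'", call. = FALSE)
    inventory <- read_inventory(config$inventory,
                                plot_area = config$plot_area %||% 400)
    traits <- read_traits(config$traits)
    phylogeny <- read_phylogeny(config$phylogeny)
    environment <- read_environment(config$environment)
    model <- if (is.null(config$allometry)) default_allometry()
             else read_allometry(config$allometry)
    threshold <- config$stratum_threshold %||% 9
    basis <- config$basis %||% "stem_count"
    if (!is.null(config$pls)) {
      cv_folds <- config$pls$cv_folds %||% cv_folds
      step_fraction <- config$pls$step_fraction %||% step_fraction
      ncomp_max <- config$pls$ncomp_max %||% ncomp_max
      seed <- config$pls$seed %||% seed
    }
  }

  rep <- match_names(inventory, traits, phylogeny)
  if (!rep$ok)
    stop("stage match_names: species unmatched; missing from traits: ",
         paste(rep$missing_from_traits, collapse = ", "),
         "; missing from tree: ",
         paste(rep$missing_from_tree, collapse = ", "), call. = FALSE)
  message("stage match_names: ", length(unique(inventory$species)),
          " species reconciled across ", nrow(inventory), " stems")

  profile <- diversity_profile(inventory, traits, phylogeny, model,
                               threshold, basis)
  message("stage diversity: profile of ", nrow(profile),
          " plot x stratum rows")

  env <- env_pca(environment)
  message("stage environment_pca: topographic PC1 ",
          sprintf("%.2f%%", 100 * env$topo$var_explained[1]),
          ", soil PC1 ",
          sprintf("%.2f%%", 100 * env$soil$var_explained[1]))

  trait_cols <- setdiff(names(traits), "species")
  cols <- predictor_columns(trait_cols)
  predictors <- list(); pls <- list(); vip_tabs <- list(); biv <- list()
  for (stn in unique(profile$stratum)) {
    pf <- profile[profile$stratum == stn, , drop = FALSE]
    m <- merge(pf, env$scores, by = "plot_id", sort = FALSE)
    keep <- stats::complete.cases(m[, c(cols, "agb")])
    if (any(!keep))
      message("stage pls (", stn, "): dropping ", sum(!keep),
              " plot(s) with undefined metrics")
    m <- m[keep, , drop = FALSE]
    X <- as.matrix(m[, cols]); rownames(X) <- m$plot_id
    y <- m$agb
    predictors[[stn]] <- data.frame(plot_id = m$plot_id, agb = y, X,
                                    stringsAsFactors = FALSE)
    sh <- shave_pls(X, y, cv_folds = cv_folds,
                    step_fraction = step_fraction,
                    ncomp_max = ncomp_max, seed = seed)
    pls[[stn]] <- sh
    vip_tabs[[stn]] <- cbind(stratum = stn, sh$vip_table)
    bt <- do.call(rbind, lapply(sh$selected, function(v)
      cbind(predictor = v, bivariate_fit(X[, v], y))))
    biv[[stn]] <- cbind(stratum = stn, bt)
    message("stage pls (", stn, "): ", length(sh$selected),
            " informative predictor(s) retained")
  }

  st <- split_strata(inventory, threshold)
  agb_summary <- do.call(rbind, lapply(split(profile, profile$stratum),
    function(d) data.frame(stratum = d$stratum[1], n_plots = nrow(d),
                           mean_agb = mean(d$agb), sd_agb = sd(d$agb),
                           n_species = length(unique(
                             st[[d$stratum[1]]]$species)),
                           stringsAsFactors = FALSE)))
  rownames(agb_summary) <- NULL

  cfg_for_hash <- if (is.null(sim)) config else sim$config
  tf <- tempfile(); on.exit(unlink(tf), add = TRUE)
  saveRDS(cfg_for_hash, tf)
  manifest <- list(
    package_version = as.character(utils::packageVersion("strataAGB")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = seed,
    config_hash = unname(tools::md5sum(tf)),
    stratum_threshold = threshold,
    basis = basis,
    pls = list(cv_folds = cv_folds, step_fraction = step_fraction,
               ncomp_max = ncomp_max),
    note = paste("bivariate p-values are reported unadjusted;",
                 "no multiplicity correction is applied")
  )

  out <- list(profile = profile, env = env, predictors = predictors,
              pls = pls,
              vip = { v <- do.call(rbind, vip_tabs); rownames(v) <- NULL; v },
              bivariate = { b <- do.call(rbind, biv); rownames(b) <- NULL; b },
              agb = agb_summary, manifest = manifest, simulation = sim)
  class(out) <- "agb_report"

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(df, f) write.table(df, file.path(out_dir, f), sep = ",",
                                      row.names = FALSE, quote = FALSE)
    wr(out$profile, "diversity_profile.csv")
    wr(out$env$scores, "env_scores.csv")
    wr(out$vip, "vip_table.csv")
    wr(out$bivariate, "bivariate_fits.csv")
    wr(out$agb, "stratum_agb_summary.csv")
    for (stn in names(out$predictors))
      wr(out$predictors[[stn]], paste0("predictors_", stn, ".csv"))
    writeLines(yaml::as.yaml(manifest), file.path(out_dir, "manifest.yaml"))
    message("report written to ", out_dir)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.agb_report <- function(x, ...) {
  cat("Diversity-AGB pipeline report\n")
  cat("  stratum AGB (Mg/ha):\n")
  print(x$agb, row.names = FALSE)
  cat("  PCA: topo PC1/2 ",
      paste0(sprintf("%.2f%%", 100 * x$env$topo$var_explained),
             collapse = "/"),
      "; soil PC1/2 ",
      paste0(sprintf("%.2f%%", 100 * x$env$soil$var_explained),
             collapse = "/"), "\n", sep = "")
  for (stn in names(x$pls)) {
    cat("  ", stn, ": informative predictors: ",
        paste(x$pls[[stn]]$selected, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
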