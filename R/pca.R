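#' Correlation-matrix PCA of a plot-by-variable table
#'
#' Standardizes each variable (zero mean, unit variance) and decomposes with
#' [stats::prcomp()]. Eigenvector signs are fixed so each component's
#' largest-magnitude loading is positive, making reports reproducible.
#' Constant variables are an error (they carry no information and break the
#' standardization).
#'
#' @param x numeric matrix or data.frame (plots x variables).
#' @param n_keep number of components to report (default 2).
#' @return list of class `pca_scores`: `scores` (n x n_keep), `loadings`
#'   (p x n_keep), `var_explained` (fraction per kept component),
#'   `var_explained_all`, `sdev`.
#' @export
run_pca <- function(x, n_keep = 2) {
  x <- as.matrix(x)
  if (nrow(x) < 3L) stop("PCA needs at least 3 plots", call. = FALSE)
  cst <- apply(x, 2, function(v) sd(v) == 0 || !all(is.finite(v)))
  if (any(cst))
    stop("constant or non-finite variable(s): ",
         paste(colnames(x)[cst], collapse = ", "), call. = FALSE)
  pc <- prcomp(x, center = TRUE, scale. = TRUE)
  n_keep <- min(n_keep, ncol(pc$rotation))
  # sign convention
  for (k in seq_len(ncol(pc$rotation))) {
    j <- which.max(abs(pc$rotation[, k]))
    if (pc$rotation[j, k] < 0) {
      pc$rotation[, k] <- -pc$rotation[, k]
      pc$x[, k] <- -pc$x[, k]
    }
  }
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  out <- list(scores = pc$x[, seq_len(n_keep), drop = FALSE],
              loadings = pc$rotation[, seq_len(n_keep), drop = FALSE],
              var_explained = ve[seq_len(n_keep)],
              var_explained_all = ve,
              sdev = pc$sdev)
  class(out) <- "pca_scores"
  out
}

#' @export
print.pca_scores <- function(x, ...) {
  k <- length(x$var_explained)
  cat("PCA:", nrow(x$scores), "plots,", nrow(x$loadings), "variables;",
      "first", k, "component(s) explain",
      paste0(sprintf("%.2f%%", 100 * x$var_explained), collapse = " + "),
      "\n")
  invisible(x)
}

#' Topographic and edaphic PCA scores
#'
#' Runs two separate correlation-matrix PCAs — one on the topographic
#' variables (`elevation`, `slope`, `aspect`), one on the edaphic variables
#' (everything else) — and returns plot scores `Topo_PC1/2` and
#' `Soil_PC1/2`. Aspect is circular (degrees), so by default it enters as
#' the pair `sin(aspect)`, `cos(aspect)`; set `aspect = "raw"` to use the
#' raw degrees instead.
#'
#' @param env environment table from [read_environment()] (or compatible
#'   data.frame with `plot_id`).
#' @param n_keep components kept per PCA (default 2).
#' @param aspect `"sincos"` (default) or `"raw"`.
#' @param topo_vars names of the topographic variables.
#' @return list of class `env_pca`: `scores` (data.frame `plot_id`,
#'   `Topo_PC1..`, `Soil_PC1..`), `topo` and `soil` ([run_pca()] objects).
#' @export
env_pca <- function(env, n_keep = 2, aspect = c("sincos", "raw"),
                    topo_vars = c("elevation", "slope", "aspect")) {
  aspect <- match.arg(aspect)
  stopifnot("plot_id" %in% names(env))
  vars <- setdiff(names(env), "plot_id")
  topo_present <- intersect(topo_vars, vars)
  soil_vars <- setdiff(vars, topo_vars)
  if (length(topo_present) < 2L || length(soil_vars) < 2L)
    stop("need at least 2 topographic and 2 edaphic variables",
         call. = FALSE)
  topo <- env[, topo_present, drop = FALSE]
  if ("aspect" %in% names(topo) && aspect == "sincos") {
    rad <- topo$aspect * pi / 180
    topo$aspect_sin <- sin(rad)
    topo$aspect_cos <- cos(rad)
    topo$aspect <- NULL
  }
  p_topo <- run_pca(topo, n_keep)
  p_soil <- run_pca(env[, soil_vars, drop = FALSE], n_keep)
  sc <- data.frame(plot_id = as.character(env$plot_id),
                   p_topo$scores, p_soil$scores,
                   stringsAsFactors = FALSE)
  names(sc) <- c("plot_id",
                 paste0("Topo_PC", seq_len(ncol(p_topo$scores))),
                 paste0("Soil_PC", seq_len(ncol(p_soil$scores))))
  rownames(sc) <- NULL
  out <- list(scores = sc, topo = p_topo, soil = p_soil)
  class(out) <- "env_pca"
  out
}

#' @export
print.env_pca <- function(x, ...) {
  cat("Environment PCA\n  topographic: ")
  print(x$topo)
  cat("  edaphic:     ")
  print(x$soil)
  invisible(x)
}
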