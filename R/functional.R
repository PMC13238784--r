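#' Standardized functional trait space
#'
#' Z-scores each trait over the supplied species pool (mean 0, sd 1), the
#' reference frame in which functional dispersion and richness are computed
#' so that no trait dominates by unit choice. Community-weighted means, by
#' contrast, are always reported on the raw trait scale.
#'
#' @param traits trait table (see [read_traits()]).
#' @param trait_cols trait columns to use (default all but `species`).
#' @return numeric matrix (species x traits) of standardized values, with
#'   `"center"` and `"scale"` attributes; rownames are species names.
#' @export
functional_space <- function(traits, trait_cols = NULL) {
  if (is.null(trait_cols)) trait_cols <- setdiff(names(traits), "species")
  x <- as.matrix(traits[, trait_cols, drop = FALSE])
  rownames(x) <- traits$species
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  if (any(scl == 0))
    stop("trait(s) constant across the species pool: ",
         paste(trait_cols[scl == 0], collapse = ", "), call. = FALSE)
  z <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  attr(z, "center") <- ctr
  attr(z, "scale") <- scl
  z
}

# Align a species x trait matrix (or trait table) to the columns of an
# abundance matrix, matching on normalized names; errors name the culprits.
align_species <- function(ab, mat, what = "trait table") {
  key_ab <- normalize_species(colnames(ab))
  key_m <- normalize_species(rownames(mat))
  ix <- match(key_ab, key_m)
  if (anyNA(ix))
    stop("species missing from ", what, ": ",
         paste(colnames(ab)[is.na(ix)], collapse = ", "), call. = FALSE)
  mat[ix, , drop = FALSE]
}

#' Community-weighted mean traits
#'
#' CWM of each trait per plot: the abundance-weighted mean trait value
#' `sum_i w_i * trait_i` on the raw (unstandardized) trait scale.
#'
#' @param ab abundance matrix from [abundance_matrix()].
#' @param traits trait table with a `species` column.
#' @param trait_cols trait columns (default all but `species`).
#' @return numeric matrix (plots x traits) with columns `CWM_<trait>`.
#' @export
cwm <- function(ab, traits, trait_cols = NULL) {
  if (is.null(trait_cols)) trait_cols <- setdiff(names(traits), "species")
  x <- as.matrix(traits[, trait_cols, drop = FALSE])
  rownames(x) <- traits$species
  x <- align_species(ab, x)
  out <- ab %*% x
  colnames(out) <- paste0("CWM_", trait_cols)
  out
}

#' Functional dispersion (FDis)
#'
#' Abundance-weighted mean Euclidean distance of each species to the
#' community-weighted centroid in standardized trait space:
#' `FDis = sum_i w_i * ||x_i - c||` with `c = sum_i w_i x_i`.
#' A monoculture has FDis 0.
#'
#' @param ab abundance matrix from [abundance_matrix()].
#' @param fspace standardized trait space from [functional_space()].
#' @return named numeric vector of FDis per plot.
#' @export
fdis <- function(ab, fspace) {
  z <- align_species(ab, fspace, "trait space")
  out <- numeric(nrow(ab))
  for (p in seq_len(nrow(ab))) {
    w <- ab[p, ]
    cen <- colSums(w * z)
    d <- sqrt(rowSums(sweep(z, 2, cen)^2))
    out[p] <- sum(w * d)
  }
  names(out) <- rownames(ab)
  out
}

#' Convex-hull volume of a point set
#'
#' Volume of the convex hull of `n` points in `d` dimensions (`d` up to 6),
#' by exact facet enumeration (general-position algorithm with duplicate
#' removal and a deterministic tiny jitter retried on detected degeneracy).
#' Returns 0 with attribute `degenerate = TRUE` when the points do not span
#' `d` dimensions.
#'
#' @param x numeric matrix (points x dimensions).
#' @return hull volume (length, area, volume... by dimension).
#' @export
convhull_volume <- function(x) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  x <- x[!duplicated(round(x, 12L)), , drop = FALSE]
  d <- ncol(x)
  if (d == 1L) {
    v <- if (nrow(x) >= 2L) max(x) - min(x) else 0
    return(v)
  }
  flag_degenerate <- function(v) { attr(v, "degenerate") <- TRUE; v }
  if (nrow(x) < d + 1L) return(flag_degenerate(0))
  if (qr(sweep(x, 2, colMeans(x)))$rank < d) return(flag_degenerate(0))
  v <- hull_volume_cpp(x)
  jit <- 1e-9 * max(apply(x, 2, function(c) diff(range(c))))
  k <- 0L
  while (v < 0 && k < 4L) {
    k <- k + 1L
    # deterministic, data-independent perturbation; no RNG state touched
    pert <- sin(seq_len(length(x)) * 1.61803398874989)
    v <- hull_volume_cpp(x + jit * 10^(k - 1) * pert)
  }
  if (v < 0)
    stop("convex hull degenerate beyond jitter tolerance", call. = FALSE)
  v
}

#' Functional richness (FRic)
#'
#' Presence-based convex-hull volume of the community in standardized trait
#' space, normalized by the hull volume of the stratum species pool, so that
#' FRic lies in [0, 1] and equals 1 when a community spans the pool's entire
#' trait space. Communities with fewer than `d + 1` species (`d` = number of
#' traits) or with degenerate (affinely dependent) coordinates get FRic 0
#' and are flagged.
#'
#' @inheritParams fdis
#' @param pool species names defining the reference pool (default: all
#'   species in `fspace`).
#' @return named numeric vector of FRic per plot with a logical
#'   `"degenerate"` attribute marking flagged plots.
#' @export
fric <- function(ab, fspace, pool = rownames(fspace)) {
  z <- align_species(ab, fspace, "trait space")
  zpool <- fspace[normalize_species(rownames(fspace)) %in%
                    normalize_species(pool), , drop = FALSE]
  vpool <- convhull_volume(zpool)
  if (isTRUE(attr(vpool, "degenerate")) || vpool == 0)
    stop("species pool does not span the trait space; FRic undefined",
         call. = FALSE)
  out <- numeric(nrow(ab))
  degen <- logical(nrow(ab))
  for (p in seq_len(nrow(ab))) {
    pts <- z[ab[p, ] > 0, , drop = FALSE]
    v <- convhull_volume(pts)
    degen[p] <- isTRUE(attr(v, "degenerate"))
    out[p] <- as.numeric(v) / vpool
  }
  names(out) <- names(degen) <- rownames(ab)
  attr(out, "degenerate") <- degen
  out
}

#' Functional divergence of log trait values (FDiv)
#'
#' For each trait, the abundance-weighted variance of log trait values,
#' `V = sum_i A_i (ln C_i - ln xbar)^2` with
#' `ln xbar = sum_i A_i ln C_i`, is mapped to [0, 1) by
#' `(2/pi) * atan(5 V)`; FDiv is the mean of the per-trait scores. All
#' species sharing a trait value gives 0; extreme spread approaches 1.
#' Raw traits must be strictly positive.
#'
#' @inheritParams cwm
#' @return named numeric vector of FDiv per plot.
#' @export
fdiv <- function(ab, traits, trait_cols = NULL) {
  if (is.null(trait_cols)) trait_cols <- setdiff(names(traits), "species")
  x <- as.matrix(traits[, trait_cols, drop = FALSE])
  rownames(x) <- traits$species
  if (any(x <= 0))
    stop("FDiv requires strictly positive trait values", call. = FALSE)
  lx <- log(align_species(ab, x))
  out <- numeric(nrow(ab))
  for (p in seq_len(nrow(ab))) {
    w <- ab[p, ]
    lbar <- colSums(w * lx)
    v <- colSums(w * sweep(lx, 2, lbar)^2)
    out[p] <- mean(2 / pi * atan(5 * v))
  }
  names(out) <- rownames(ab)
  out
}

#' Per-plot functional diversity profile for one stratum
#'
#' Assembles CWMs (raw scale), FDis, FRic and FDiv from a stratum inventory
#' and a trait table.
#'
#' @param inv stratum [plot_inventory()].
#' @param traits trait table.
#' @param basis abundance basis, see [abundance_matrix()].
#' @param trait_cols trait columns (default all but `species`).
#' @return data.frame: `plot_id`, `CWM_*`, `FDis`, `FRic`, `FDiv`,
#'   `FRic_degenerate`.
#' @export
functional_profile <- function(inv, traits, basis = "stem_count",
                               trait_cols = NULL) {
  ab <- abundance_matrix(inv, basis)
  if (is.null(trait_cols)) trait_cols <- setdiff(names(traits), "species")
  pool_traits <- traits[normalize_species(traits$species) %in%
                          normalize_species(colnames(ab)), , drop = FALSE]
  fs <- functional_space(pool_traits, trait_cols)
  fr <- fric(ab, fs)
  out <- data.frame(plot_id = rownames(ab),
                    cwm(ab, pool_traits, trait_cols),
                    FDis = fdis(ab, fs),
                    FRic = as.numeric(fr),
                    FDiv = fdiv(ab, pool_traits, trait_cols),
                    FRic_degenerate = attr(fr, "degenerate"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
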