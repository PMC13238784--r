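#' Patristic (cophenetic) distance matrix
#'
#' Tip-to-tip path lengths `d(s_i, s_j)`: the sum of branch lengths along
#' the unique path joining two tips.
#'
#' @param phy an [ape::phylo] tree with branch lengths.
#' @return symmetric numeric matrix with zero diagonal, dimnames = tips.
#' @export
patristic_matrix <- function(phy) {
  if (is.null(phy$edge.length))
    stop("phylogeny has no branch lengths", call. = FALSE)
  ape::cophenetic.phylo(phy)
}

# Match community species to rows of a species x species matrix.
match_tips <- function(species, m) {
  ix <- match(normalize_species(species), normalize_species(rownames(m)))
  if (anyNA(ix))
    stop("species missing from phylogeny: ",
         paste(species[is.na(ix)], collapse = ", "), call. = FALSE)
  ix
}

#' Mean pairwise phylogenetic distance (MPD)
#'
#' Presence-based mean of patristic distances over all unordered species
#' pairs of a community: `2/(n(n-1)) * sum_{i<j} d(s_i, s_j)`. Undefined
#' (NA) for communities of fewer than two species.
#'
#' @param species community species names.
#' @param pd patristic matrix from [patristic_matrix()].
#' @return MPD (numeric scalar; NA if n < 2).
#' @export
mpd_comm <- function(species, pd) {
  species <- unique(species)
  n <- length(species)
  if (n < 2L) return(NA_real_)
  ix <- match_tips(species, pd)
  d <- pd[ix, ix]
  sum(d[upper.tri(d)]) * 2 / (n * (n - 1))
}

#' Mean nearest taxon distance (MNTD)
#'
#' Mean over community species of the patristic distance to the nearest
#' other community member: `1/n * sum_i min_{j != i} d(s_i, s_j)`.
#'
#' @inheritParams mpd_comm
#' @return MNTD (numeric scalar; NA if n < 2).
#' @export
mntd_comm <- function(species, pd) {
  species <- unique(species)
  n <- length(species)
  if (n < 2L) return(NA_real_)
  ix <- match_tips(species, pd)
  d <- pd[ix, ix]
  diag(d) <- Inf
  mean(apply(d, 1, min))
}

#' Phylogenetic correlation matrix of a set of tips
#'
#' Entry (i, j) is the shared root-to-MRCA path length of tips i and j
#' divided by the geometric mean of their root-to-tip depths. On an
#' ultrametric tree this is the usual Helmus-style correlation (shared depth
#' over total depth); the geometric-mean normalization extends it to
#' non-ultrametric trees while keeping a unit diagonal and entries in
#' [0, 1] for nonnegative branch lengths.
#'
#' @param phy an [ape::phylo] tree.
#' @param species tip subset (default all tips).
#' @return correlation matrix with unit diagonal.
#' @export
phylo_correlation <- function(phy, species = phy$tip.label) {
  v <- ape::vcv.phylo(phy)  # shared branch length from root
  ix <- match_tips(unique(species), v)
  v <- v[ix, ix, drop = FALSE]
  dep <- diag(v)
  if (any(dep <= 0))
    stop("zero root-to-tip depth; cannot normalize phylogenetic covariance",
         call. = FALSE)
  v / sqrt(outer(dep, dep))
}

#' Phylogenetic species variability and richness (PSV, PSR)
#'
#' PSV is 1 minus the mean off-diagonal phylogenetic correlation among the
#' community's tips: `PSV = (n * tr(C) - sum(C)) / (n (n - 1))`. It ranges
#' 0-1; values near 1 mean the species are phylogenetically unrelated (a
#' star phylogeny gives exactly 1). PSR = n * PSV is species richness
#' discounted by relatedness.
#'
#' @param phy an [ape::phylo] rooted tree.
#' @param species community species names.
#' @return list with `psv`, `psr`, `n` (NA metrics if n < 2).
#' @export
psv_psr <- function(phy, species) {
  species <- unique(species)
  n <- length(species)
  if (n < 2L) return(list(psv = NA_real_, psr = NA_real_, n = n))
  C <- phylo_correlation(phy, species)
  psv <- (n * sum(diag(C)) - sum(C)) / (n * (n - 1))
  list(psv = psv, psr = n * psv, n = n)
}

#' Per-plot phylogenetic diversity profile for one stratum
#'
#' Species richness, MPD, MNTD, PSV and PSR per plot, computed on the
#' stratum's tree (the supplied tree pruned to the stratum's observed
#' species; patristic distances and shared depths are unaffected by
#' pruning).
#'
#' @param inv stratum [plot_inventory()].
#' @param phy phylogeny covering the inventory's species.
#' @param basis abundance basis used only to tabulate presence (metrics are
#'   presence-based as defined).
#' @return data.frame: `plot_id`, `n_species`, `MPD`, `MNTD`, `PSV`, `PSR`.
#' @export
phylo_profile <- function(inv, phy, basis = "stem_count") {
  ab <- abundance_matrix(inv, basis)
  keep <- phy$tip.label[normalize_species(phy$tip.label) %in%
                          normalize_species(colnames(ab))]
  if (length(keep) < length(unique(colnames(ab))))
    stop("species missing from phylogeny: ",
         paste(setdiff(normalize_species(colnames(ab)),
                       normalize_species(phy$tip.label)), collapse = ", "),
         call. = FALSE)
  sub <- if (length(keep) < length(phy$tip.label))
    ape::keep.tip(phy, keep) else phy
  pd <- patristic_matrix(sub)
  plots <- rownames(ab)
  out <- data.frame(plot_id = plots, n_species = NA_integer_,
                    MPD = NA_real_, MNTD = NA_real_,
                    PSV = NA_real_, PSR = NA_real_,
                    stringsAsFactors = FALSE)
  for (p in seq_along(plots)) {
    sp <- colnames(ab)[ab[p, ] > 0]
    out$n_species[p] <- length(sp)
    if (length(sp) >= 2L) {
      out$MPD[p] <- mpd_comm(sp, pd)
      out$MNTD[p] <- mntd_comm(sp, pd)
      ps <- psv_psr(sub, sp)
      out$PSV[p] <- ps$psv
      out$PSR[p] <- ps$psr
    }
  }
  out
}
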