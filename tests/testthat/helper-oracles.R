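# Independent brute-force oracles, written straight from the defining
# formulas with plain loops. They deliberately share no code with the
# package implementations they check.

oracle_cwm <- function(w, trait) {
  s <- 0
  for (i in seq_along(w)) s <- s + w[i] * trait[i]
  unname(s)
}

oracle_fdis <- function(w, z) {
  # z: species x traits (already standardized); w: relative abundances
  cen <- rep(0, ncol(z))
  for (i in seq_along(w)) cen <- cen + w[i] * z[i, ]
  s <- 0
  for (i in seq_along(w)) s <- s + w[i] * sqrt(sum((z[i, ] - cen)^2))
  s
}

oracle_fdiv <- function(w, traits) {
  # traits: species x traits, raw positive values
  scores <- numeric(ncol(traits))
  for (t in seq_len(ncol(traits))) {
    lx <- log(traits[, t])
    lbar <- 0
    for (i in seq_along(w)) lbar <- lbar + w[i] * lx[i]
    v <- 0
    for (i in seq_along(w)) v <- v + w[i] * (lx[i] - lbar)^2
    scores[t] <- 2 / pi * atan(5 * v)
  }
  mean(scores)
}

oracle_mpd <- function(d) {
  n <- nrow(d)
  s <- 0
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) s <- s + d[i, j]
  2 * s / (n * (n - 1))
}

oracle_mntd <- function(d) {
  n <- nrow(d)
  s <- 0
  for (i in seq_len(n)) {
    m <- Inf
    for (j in seq_len(n)) if (j != i && d[i, j] < m) m <- d[i, j]
    s <- s + m
  }
  s / n
}

# patristic distances as shortest paths on the tree graph
oracle_patristic_igraph <- function(phy) {
  g <- igraph::graph_from_edgelist(apply(phy$edge, 2, as.character))
  igraph::E(g)$weight <- phy$edge.length
  n <- length(phy$tip.label)
  d <- igraph::distances(g, v = as.character(seq_len(n)),
                         to = as.character(seq_len(n)), mode = "all")
  dimnames(d) <- list(phy$tip.label, phy$tip.label)
  d
}

# 3-D convex hull by brute-force facet enumeration in plain R (independent
# of the compiled implementation): returns facet half-space representation
# and the enclosed volume via signed tetrahedra against the centroid.
oracle_hull3d <- function(x) {
  stopifnot(ncol(x) == 3)
  n <- nrow(x)
  cen <- colMeans(x)
  facets <- list()
  vol <- 0
  for (i in seq_len(n - 2)) for (j in seq(i + 1, n - 1)) for (k in seq(j + 1, n)) {
    nrm <- c(
      (x[j, 2] - x[i, 2]) * (x[k, 3] - x[i, 3]) -
        (x[j, 3] - x[i, 3]) * (x[k, 2] - x[i, 2]),
      (x[j, 3] - x[i, 3]) * (x[k, 1] - x[i, 1]) -
        (x[j, 1] - x[i, 1]) * (x[k, 3] - x[i, 3]),
      (x[j, 1] - x[i, 1]) * (x[k, 2] - x[i, 2]) -
        (x[j, 2] - x[i, 2]) * (x[k, 1] - x[i, 1]))
    if (sqrt(sum(nrm^2)) < 1e-12) next
    off <- sum(nrm * x[i, ])
    side <- x %*% nrm - off
    if (all(side <= 1e-9 * max(abs(side)))) {
    } else if (all(side >= -1e-9 * max(abs(side)))) {
      nrm <- -nrm; off <- -off
    } else next
    facets[[length(facets) + 1]] <- list(normal = nrm, offset = off)
    v <- abs(det(rbind(x[j, ] - x[i, ], x[k, ] - x[i, ], cen - x[i, ]))) / 6
    vol <- vol + v
  }
  list(volume = vol, facets = facets)
}

# rejection-sampling volume estimate using the oracle facets for membership
oracle_hull3d_mc <- function(x, n_samples = 2e5, seed = 1) {
  h <- oracle_hull3d(x)
  lo <- apply(x, 2, min); hi <- apply(x, 2, max)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  pts <- cbind(runif(n_samples, lo[1], hi[1]),
               runif(n_samples, lo[2], hi[2]),
               runif(n_samples, lo[3], hi[3]))
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  inside <- rep(TRUE, n_samples)
  for (f in h$facets) {
    s <- pts %*% f$normal - f$offset
    inside <- inside & (s <= 1e-9 * max(1, abs(f$offset)))
  }
  prod(hi - lo) * mean(inside)
}

# random small community in a random trait space (fixtures for the
# metric-oracle suite); built on ape::rtree, a code path independent of the
# package's own Yule generator
random_community <- function(seed, max_species = 15, max_traits = 5) {
  set.seed(seed)
  n_sp <- sample(3:max_species, 1)
  n_tr <- sample(2:max_traits, 1)
  species <- paste0("t", seq_len(n_sp))
  traits <- data.frame(species = species)
  for (t in seq_len(n_tr))
    traits[[paste0("tr", t)]] <- exp(rnorm(n_sp, 0, 0.8))
  w <- rgamma(n_sp, 1)
  w <- w / sum(w)
  phy <- ape::rtree(n_sp, tip.label = species)
  list(species = species, traits = traits, w = w, phy = phy,
       n_sp = n_sp, n_tr = n_tr)
}

# abundance matrix with a single plot row, for metric calls
one_plot_ab <- function(w, species) {
  m <- matrix(w, 1, length(w), dimnames = list("p1", species))
  m
}

# run code under a temporary seed, restoring global RNG state
with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  force(code)
}
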