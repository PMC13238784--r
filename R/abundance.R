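#' Plot-by-species relative abundance matrix
#'
#' Builds the community matrix feeding all diversity metrics. Relative
#' abundance of species i in a plot is its share of the plot total, measured
#' either as stem count (default) or basal area (`pi * (dbh/2)^2` summed
#' over stems). Rows sum to 1; species never observed are excluded; empty
#' plots are dropped with a warning.
#'
#' @param inv a [plot_inventory()] (typically one stratum).
#' @param basis `"stem_count"` (default) or `"basal_area"`.
#' @return numeric matrix (plots x species) of relative abundances with a
#'   `"counts"` attribute holding the raw per-plot measure and a `"basis"`
#'   attribute.
#' @export
abundance_matrix <- function(inv, basis = c("stem_count", "basal_area")) {
  basis <- match.arg(basis)
  stopifnot(inherits(inv, "plot_inventory"))
  if (nrow(inv) == 0L)
    stop("empty inventory: no stems to tabulate", call. = FALSE)
  measure <- switch(basis,
                    stem_count = rep(1, nrow(inv)),
                    basal_area = pi * (inv$dbh / 2)^2)
  plots <- unique(inv$plot_id)
  species <- sort(unique(inv$species))
  m <- matrix(0, length(plots), length(species),
              dimnames = list(plots, species))
  agg <- tapply(measure, list(factor(inv$plot_id, plots),
                              factor(inv$species, species)), sum)
  agg[is.na(agg)] <- 0
  m[] <- agg
  tot <- rowSums(m)
  if (any(tot == 0)) {
    warning("dropping empty plot(s): ",
            paste(plots[tot == 0], collapse = ", "), call. = FALSE)
    m <- m[tot > 0, , drop = FALSE]
    tot <- tot[tot > 0]
  }
  w <- m / tot
  attr(w, "counts") <- m
  attr(w, "basis") <- basis
  w
}
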