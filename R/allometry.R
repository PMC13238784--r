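#' Allometric biomass model
#'
#' A table of power-law allometric equations predicting per-stem aboveground
#' biomass (kg) from DBH `D` (cm) and height `H` (m). Two equation forms are
#' supported per entry:
#' \describe{
#'   \item{`compound` (default)}{`W = a * (D^2 * H)^b` — the exponent spans
#'     the compound size term, matching the general stand equation.}
#'   \item{`split`}{`W = a * D^2 * H^b` — the exponent applies to height
#'     only.}
#' }
#' The entry with species `*` (or `general`) is the fallback for species
#' without their own equation. Coefficient units assume `W` in kg per stem;
#' plot totals are reported in Mg/ha by [plot_agb()].
#'
#' @param table data.frame with columns `species`, `a`, `b` and optionally
#'   `form` (`"compound"`/`"split"`, recycled if length 1).
#' @return object of class `allometric_model`.
#' @seealso [default_allometry()], [stem_agb()]
#' @export
allometric_model <- function(table) {
  stopifnot(is.data.frame(table))
  need <- c("species", "a", "b")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("allometric table missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  tb <- data.frame(species = as.character(table$species),
                   a = as.numeric(table$a), b = as.numeric(table$b),
                   form = if (is.null(table$form)) "compound"
                          else as.character(table$form),
                   stringsAsFactors = FALSE)
  if (any(!is.finite(tb$a)) || any(tb$a <= 0))
    stop("allometric coefficient a must be positive", call. = FALSE)
  if (any(!is.finite(tb$b)) || any(tb$b <= 0))
    stop("allometric exponent b must be positive", call. = FALSE)
  bad <- !tb$form %in% c("compound", "split")
  if (any(bad))
    stop("unknown allometric form(s): ",
         paste(unique(tb$form[bad]), collapse = ", "), call. = FALSE)
  tb$species[tolower(tb$species) == "general"] <- "*"
  key <- ifelse(tb$species == "*", "*", normalize_species(tb$species))
  if (anyDuplicated(key))
    stop("duplicate species in allometric table", call. = FALSE)
  attr(tb, "key") <- key
  class(tb) <- c("allometric_model", "data.frame")
  tb
}

#' Default allometric coefficients
#'
#' Ships the *Castanopsis wattii* equation (`a = 0.03086`, `b = 0.9696`)
#' plus a placeholder general broadleaf model (`a = 0.0509`, `b = 0.93`,
#' compound form, kg per stem). The general entry is a documented stand-in:
#' supply locally fitted coefficients for real inventories.
#'
#' @return an [allometric_model()].
#' @export
default_allometry <- function() {
  allometric_model(data.frame(
    species = c("Castanopsis wattii", "*"),
    a = c(0.03086, 0.0509),
    b = c(0.9696, 0.93),
    form = "compound",
    stringsAsFactors = FALSE
  ))
}

#' Per-stem aboveground biomass
#'
#' Evaluates the allometric equation for each stem, resolving each species
#' to its own coefficients where present and to the general (`*`) entry
#' otherwise. Vectorized over stems.
#'
#' @param dbh DBH in cm (or a [plot_inventory()], in which case `height`
#'   and `species` are taken from it).
#' @param height height in m.
#' @param species species names.
#' @param model an [allometric_model()].
#' @return numeric vector of stem biomass in kg.
#' @export
#' @examples
#' m <- default_allometry()
#' stem_agb(30, 20, "Castanopsis wattii", m)
stem_agb <- function(dbh, height = NULL, species = NULL,
                     model = default_allometry()) {
  if (inherits(dbh, "plot_inventory")) {
    inv <- dbh
    dbh <- inv$dbh; height <- inv$height; species <- inv$species
  }
  stopifnot(length(dbh) == length(height), length(dbh) == length(species))
  key <- attr(model, "key")
  gi <- match("*", key)
  ix <- match(normalize_species(species), key)
  if (anyNA(ix)) {
    if (is.na(gi))
      stop("no general allometric model and no coefficients for species: ",
           paste(unique(species[is.na(ix)]), collapse = ", "), call. = FALSE)
    ix[is.na(ix)] <- gi
  }
  a <- model$a[ix]; b <- model$b[ix]; form <- model$form[ix]
  w <- ifelse(form == "compound",
              a * (dbh^2 * height)^b,
              a * dbh^2 * height^b)
  as.numeric(w)
}

#' Split an inventory into overstory and understory strata
#'
#' Stems with DBH >= `threshold` form the overstory; the rest the
#' understory. The partition is exhaustive and disjoint.
#'
#' @param inv a [plot_inventory()].
#' @param threshold stratum DBH threshold in cm (default 9).
#' @return named list of two `plot_inventory` objects: `overstory`,
#'   `understory`.
#' @export
split_strata <- function(inv, threshold = 9) {
  stopifnot(inherits(inv, "plot_inventory"))
  if (threshold <= 1)
    stop("stratum threshold must exceed the 1-cm census minimum",
         call. = FALSE)
  area <- attr(inv, "plot_area")
  up <- inv$dbh >= threshold
  mk <- function(keep) {
    out <- as.data.frame(inv)[keep, , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "plot_area") <- area
    class(out) <- c("plot_inventory", "data.frame")
    out
  }
  list(overstory = mk(up), understory = mk(!up))
}

#' Plot-level aboveground biomass (Mg/ha)
#'
#' Sums [stem_agb()] (kg) within each plot and converts to Mg/ha:
#' `sum(kg) / 1000 * 10000 / plot_area`. For a 400 m^2 plot the scale
#' factor is 25.
#'
#' @param inv a [plot_inventory()] (typically one stratum from
#'   [split_strata()]).
#' @param model an [allometric_model()].
#' @param plot_area plot area in m^2; defaults to the inventory attribute.
#' @param plot_ids optional plot ids to report (plots absent from `inv` get
#'   AGB 0); defaults to the plots present.
#' @return data.frame with `plot_id`, `agb` (Mg/ha), `n_stems`, `n_species`.
#' @export
plot_agb <- function(inv, model = default_allometry(), plot_area = NULL,
                     plot_ids = NULL) {
  stopifnot(inherits(inv, "plot_inventory"))
  if (is.null(plot_area)) plot_area <- attr(inv, "plot_area")
  if (is.null(plot_ids)) plot_ids <- unique(inv$plot_id)
  w <- if (nrow(inv)) stem_agb(inv, model = model) else numeric(0)
  f <- factor(inv$plot_id, levels = plot_ids)
  agb_kg <- tapply(w, f, sum, default = 0)
  n_stems <- tapply(rep(1L, nrow(inv)), f, sum, default = 0L)
  n_species <- vapply(split(inv$species, f),
                      function(s) length(unique(s)), integer(1))
  out <- data.frame(plot_id = plot_ids,
                    agb = as.numeric(agb_kg) / 1000 * 10000 / plot_area,
                    n_stems = as.integer(n_stems),
                    n_species = as.integer(n_species),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Per-stratum plot AGB
#'
#' Convenience wrapper: splits at `threshold` and returns the stacked
#' per-plot AGB table for both strata. Every plot present in the full
#' inventory appears in both strata (AGB 0 where a stratum is empty), so
#' stratum AGBs always sum to the whole-plot AGB.
#'
#' @inheritParams split_strata
#' @inheritParams plot_agb
#' @return data.frame with `plot_id`, `stratum`, `agb`, `n_stems`,
#'   `n_species`.
#' @export
stratum_agb <- function(inv, model = default_allometry(), threshold = 9) {
  st <- split_strata(inv, threshold)
  ids <- unique(inv$plot_id)
  out <- rbind(
    cbind(stratum = "overstory",
          plot_agb(st$overstory, model, plot_ids = ids)),
    cbind(stratum = "understory",
          plot_agb(st$understory, model, plot_ids = ids))
  )
  out <- out[, c("plot_id", "stratum", "agb", "n_stems", "n_species")]
  rownames(out) <- NULL
  out
}
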