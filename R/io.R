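#' Normalize species names for matching
#'
#' Trims leading/trailing whitespace, collapses internal runs of whitespace
#' or underscores (the Newick convention for spaces) to a single space, and
#' lower-cases. Matching across inventory, trait table and phylogeny is done
#' on the normalized form; original names are preserved for display. The
#' normalization is idempotent and no fuzzy matching is attempted: taxonomic
#' errors must be fixed explicitly in the data.
#'
#' @param x character vector of species names.
#' @return character vector of normalized names.
#' @export
#' @examples
#' normalize_species(c("  Castanopsis   wattii ", "Castanopsis_wattii"))
normalize_species <- function(x) {
  x <- gsub("[_[:space:]]+", " ", as.character(x))
  tolower(trimws(x))
}

# Detect delimiter from the header line: whichever of tab/comma splits it
# into more fields wins.
detect_delim <- function(path) {
  header <- readLines(path, n = 1L, warn = FALSE)
  n_tab <- length(strsplit(header, "\t", fixed = TRUE)[[1L]])
  n_com <- length(strsplit(header, ",", fixed = TRUE)[[1L]])
  if (n_tab >= n_com) "\t" else ","
}

read_delim_auto <- function(path, delim = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(delim)) delim <- detect_delim(path)
  read.delim(path, sep = delim, header = TRUE, check.names = FALSE,
             stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

# Resolve required columns case-insensitively, allowing a few synonyms.
resolve_columns <- function(df, wanted, path) {
  nm <- tolower(names(df))
  out <- integer(length(wanted))
  for (i in seq_along(wanted)) {
    hit <- which(nm %in% wanted[[i]])
    if (length(hit) == 0L)
      stop("format error in '", path, "': missing column matching {",
           paste(wanted[[i]], collapse = ", "), "}", call. = FALSE)
    out[i] <- hit[1L]
  }
  out
}

#' Construct and validate a plot inventory
#'
#' A plot inventory is a `data.frame` with columns `plot_id`, `species`,
#' `dbh` (cm) and `height` (m), one row per living stem, carrying the plot
#' area (m^2) as an attribute. Census rules are enforced: DBH >= 1 cm,
#' height > 0, non-empty species names.
#'
#' @param records data.frame with columns `plot_id`, `species`, `dbh`,
#'   `height`.
#' @param plot_area plot area in m^2 (default 400, a 20 m x 20 m plot).
#' @return object of class `plot_inventory` (a data.frame).
#' @export
plot_inventory <- function(records, plot_area = 400) {
  stopifnot(is.data.frame(records))
  need <- c("plot_id", "species", "dbh", "height")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("inventory is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!is.numeric(plot_area) || length(plot_area) != 1L || plot_area <= 0)
    stop("plot_area must be a single positive number", call. = FALSE)
  inv <- records[, need]
  inv$plot_id <- as.character(inv$plot_id)
  inv$species <- as.character(inv$species)
  inv$dbh <- as.numeric(inv$dbh)
  inv$height <- as.numeric(inv$height)

  bad <- which(!is.finite(inv$dbh) | inv$dbh < 1)
  if (length(bad))
    stop("validation error: dbh < 1 cm (census threshold) or non-finite in row(s): ",
         paste(utils::head(bad, 10L), collapse = ", "), call. = FALSE)
  bad <- which(!is.finite(inv$height) | inv$height <= 0)
  if (length(bad))
    stop("validation error: non-positive height in row(s): ",
         paste(utils::head(bad, 10L), collapse = ", "), call. = FALSE)
  bad <- which(is.na(inv$species) | trimws(inv$species) == "")
  if (length(bad))
    stop("validation error: empty species name in row(s): ",
         paste(utils::head(bad, 10L), collapse = ", "), call. = FALSE)

  rownames(inv) <- NULL
  attr(inv, "plot_area") <- plot_area
  class(inv) <- c("plot_inventory", "data.frame")
  inv
}

#' Read a stem inventory from a delimited file
#'
#' Expects a UTF-8 text file with a header naming plot, species, DBH and
#' height columns (case-insensitive; `plot`/`plot_id`, `species`,
#' `dbh`, `height` are recognized). The delimiter is auto-detected from
#' comma/tab unless given.
#'
#' @param path file path.
#' @param delim field delimiter; `NULL` (default) auto-detects.
#' @inheritParams plot_inventory
#' @return a validated [plot_inventory()].
#' @export
read_inventory <- function(path, delim = NULL, plot_area = 400) {
  df <- read_delim_auto(path, delim)
  ix <- resolve_columns(df, list(c("plot_id", "plot"), "species",
                                 c("dbh", "dbh_cm"), c("height", "height_m")),
                        path)
  out <- df[, ix]
  names(out) <- c("plot_id", "species", "dbh", "height")
  plot_inventory(out, plot_area = plot_area)
}

#' Write a stem inventory to a delimited file
#' @param inv a [plot_inventory()].
#' @param path output path.
#' @param delim field delimiter (default comma).
#' @return `path`, invisibly.
#' @export
write_inventory <- function(inv, path, delim = ",") {
  write.table(as.data.frame(inv), path, sep = delim, row.names = FALSE,
              quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a species-by-trait table
#'
#' One row per species with the five leaf traits used throughout: `SLA`
#' (mm^2/mg), `LN`, `LP`, `LK`, `LC` (mg/g). All trait values must be finite
#' and strictly positive (the divergence index takes logarithms).
#'
#' @inheritParams read_inventory
#' @param trait_cols trait column names to require.
#' @return data.frame with `species` plus trait columns.
#' @export
read_traits <- function(path, delim = NULL,
                        trait_cols = c("SLA", "LN", "LP", "LK", "LC")) {
  df <- read_delim_auto(path, delim)
  ix <- resolve_columns(df, c(list("species"), as.list(tolower(trait_cols))),
                        path)
  out <- df[, ix]
  names(out) <- c("species", trait_cols)
  out$species <- as.character(out$species)
  validate_traits(out, trait_cols)
}

validate_traits <- function(tr, trait_cols = setdiff(names(tr), "species")) {
  key <- normalize_species(tr$species)
  if (anyDuplicated(key))
    stop("duplicate species in trait table: ",
         paste(unique(tr$species[duplicated(key)]), collapse = ", "),
         call. = FALSE)
  for (tc in trait_cols) {
    v <- as.numeric(tr[[tc]])
    if (any(!is.finite(v)))
      stop("trait '", tc, "' has non-finite values", call. = FALSE)
    if (any(v <= 0))
      stop("trait '", tc, "' must be strictly positive (log transform); ",
           "offending species: ",
           paste(tr$species[v <= 0], collapse = ", "), call. = FALSE)
    tr[[tc]] <- v
  }
  rownames(tr) <- NULL
  tr
}

#' Read a plot-by-environment table
#'
#' Topographic (`elevation` m, `slope` deg, `aspect` deg) and edaphic
#' (`pH`, `SOM`, `TN`, `TP`, `TK`, `AN`, `AP`, `AK`, `AB`; g/kg except pH)
#' variables, one row per plot. Missing cells are an error: imputation is
#' out of scope and must happen upstream.
#'
#' @inheritParams read_inventory
#' @return data.frame with `plot_id` first.
#' @export
read_environment <- function(path, delim = NULL) {
  df <- read_delim_auto(path, delim)
  ix <- resolve_columns(df, list(c("plot_id", "plot")), path)
  names(df)[ix] <- "plot_id"
  df$plot_id <- as.character(df$plot_id)
  if (anyDuplicated(df$plot_id))
    stop("duplicate plot_id in environment table", call. = FALSE)
  num <- setdiff(names(df), "plot_id")
  for (v in num) {
    df[[v]] <- as.numeric(df[[v]])
    if (any(is.na(df[[v]])))
      stop("environment variable '", v, "' has missing values", call. = FALSE)
  }
  df[, c("plot_id", num)]
}

#' Read an allometric coefficient table
#'
#' Columns: `species`, `a`, `b`, optional `form`. The row with species `*`
#' (or `general`) is the fallback model for unmatched species. See
#' [allometric_model()] for the equation forms.
#'
#' @inheritParams read_inventory
#' @return an [allometric_model()].
#' @export
read_allometry <- function(path, delim = NULL) {
  df <- read_delim_auto(path, delim)
  ix <- resolve_columns(df, list("species", "a", "b"), path)
  out <- df[, ix]
  names(out) <- c("species", "a", "b")
  out$form <- if ("form" %in% tolower(names(df)))
    as.character(df[[which(tolower(names(df)) == "form")[1L]]])
  else "compound"
  allometric_model(out)
}

#' Read a phylogeny from a Newick file
#'
#' Wraps [ape::read.tree()]. The tree must be single and rooted with branch
#' lengths; missing branch lengths are an error by default because every
#' phylogenetic metric here depends on them.
#'
#' @param path Newick file path.
#' @param missing_bl `"error"` (default) or `"zero"` to replace absent
#'   branch lengths with 0.
#' @return an [ape::phylo] object.
#' @export
read_phylogeny <- function(path, missing_bl = c("error", "zero")) {
  missing_bl <- match.arg(missing_bl)
  phy <- tryCatch(ape::read.tree(path),
                  error = function(e) stop("Newick parse error in '", path,
                                           "': ", conditionMessage(e),
                                           call. = FALSE))
  if (is.null(phy)) stop("Newick parse error in '", path, "'", call. = FALSE)
  if (inherits(phy, "multiPhylo")) {
    if (length(phy) != 1L)
      stop("expected a single tree in '", path, "'", call. = FALSE)
    phy <- phy[[1L]]
  }
  if (is.null(phy$edge.length)) {
    if (missing_bl == "error")
      stop("phylogeny in '", path, "' has no branch lengths", call. = FALSE)
    phy$edge.length <- rep(0, nrow(phy$edge))
  }
  if (anyNA(phy$edge.length)) {
    if (missing_bl == "error")
      stop("phylogeny in '", path, "' has missing branch lengths",
           call. = FALSE)
    phy$edge.length[is.na(phy$edge.length)] <- 0
  }
  if (any(phy$edge.length < 0))
    stop("phylogeny in '", path, "' has negative branch lengths",
         call. = FALSE)
  phy
}

#' Reconcile species names across inventory, traits and phylogeny
#'
#' Matching uses [normalize_species()]. With `drop = FALSE` (default) the
#' result is a report only; downstream functions refuse to proceed on any
#' mismatch. With `drop = TRUE`, unmatched inventory species are removed
#' from all three structures consistently, with a warning.
#'
#' @param inventory a [plot_inventory()].
#' @param traits a trait table (see [read_traits()]).
#' @param phylogeny an [ape::phylo] tree whose tips are species names.
#' @param drop drop unmatched species instead of only reporting.
#' @return list of class `name_report` with elements `missing_from_traits`,
#'   `missing_from_tree`, `ok`, and (when `drop = TRUE`) the pruned
#'   `inventory`, `traits`, `phylogeny`.
#' @export
match_names <- function(inventory, traits, phylogeny, drop = FALSE) {
  inv_key <- normalize_species(inventory$species)
  tr_key <- normalize_species(traits$species)
  tip_key <- normalize_species(phylogeny$tip.label)
  sp <- unique(inventory$species)
  sp_key <- normalize_species(sp)
  rep <- list(
    missing_from_traits = sp[!(sp_key %in% tr_key)],
    missing_from_tree = sp[!(sp_key %in% tip_key)]
  )
  rep$ok <- length(rep$missing_from_traits) == 0L &&
    length(rep$missing_from_tree) == 0L
  if (drop && !rep$ok) {
    bad_key <- normalize_species(
      unique(c(rep$missing_from_traits, rep$missing_from_tree)))
    warning("dropping ", length(bad_key),
            " species unmatched across inputs: ",
            paste(utils::head(unique(c(rep$missing_from_traits,
                                       rep$missing_from_tree)), 10L),
                  collapse = ", "), call. = FALSE)
    keep <- !(inv_key %in% bad_key)
    inv2 <- inventory[keep, , drop = FALSE]
    rep$inventory <- plot_inventory(inv2, attr(inventory, "plot_area"))
    keep_key <- unique(normalize_species(rep$inventory$species))
    rep$traits <- traits[tr_key %in% keep_key, , drop = FALSE]
    rep$phylogeny <- ape::keep.tip(phylogeny,
                                   phylogeny$tip.label[tip_key %in% keep_key])
  } else if (drop) {
    rep$inventory <- inventory
    rep$traits <- traits
    rep$phylogeny <- phylogeny
  }
  class(rep) <- "name_report"
  rep
}

#' @export
print.name_report <- function(x, ...) {
  cat("Species name reconciliation\n")
  cat("  missing from trait table:", length(x$missing_from_traits), "\n")
  if (length(x$missing_from_traits))
    cat("   ", paste(x$missing_from_traits, collapse = ", "), "\n")
  cat("  missing from phylogeny:  ", length(x$missing_from_tree), "\n")
  if (length(x$missing_from_tree))
    cat("   ", paste(x$missing_from_tree, collapse = ", "), "\n")
  cat(if (isTRUE(x$ok)) "  all names matched\n" else
    "  MISMATCH: fix names or rerun with drop = TRUE\n")
  invisible(x)
}

#' Read a pipeline configuration file
#'
#' YAML key-value file naming input paths and analysis settings (stratum
#' threshold, abundance basis, PLS settings, seed). See the package vignette
#' for the full key list.
#'
#' @param path YAML file path.
#' @return named list.
#' @export
read_config <- function(path) {
  yaml::read_yaml(path)
}
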