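## Point-level witness-tree records: parsing, standardization, cleaning.
##
## The canonical in-memory representation is a `pls_points` object: a list
## with a per-corner table (`points`) and a per-tree table (`trees`) joined
## on `point_id`. Corners with no trees ("no tree" posts) are retained with
## zero rows in `trees`; they are required downstream as occupancy
## denominators.

#' Standardized taxon vocabulary
#'
#' The 20 genus-level (or near-genus) groups plus "Other hardwood" used
#' throughout the pipeline, and the non-tree sentinel labels.
#'
#' @return Character vector of standardized taxon labels.
#' @export
pls_taxa <- function() {
  c("Ash", "Basswood", "Beech", "Birch", "Black gum/sweet gum",
    "Cedar/juniper", "Cherry", "Dogwood", "Elm", "Fir", "Hemlock",
    "Hickory", "Ironwood", "Maple", "Oak", "Pine",
    "Poplar/tulip poplar", "Spruce", "Tamarack", "Walnut",
    "Other hardwood")
}

#' @rdname pls_taxa
#' @export
pls_sentinels <- function() c("No tree", "Water", "Unknown")

#' Cleaning and parsing configuration
#'
#' Holds the unit dialect of the input file and the individually
#' toggleable cleaning rules. Two dialects are supported and must be
#' declared explicitly (no autodetection): `"historical"` (dbh in inches,
#' distances in links) and `"metric"` (cm and m). Distance units can be
#' overridden separately, e.g. `dist_unit = "chains"`.
#'
#' Rules (each toggleable, each with an exclusion-reason code):
#' \describe{
#'   \item{missing_dbh}{drop corners where any tree has a missing
#'     diameter (required for unbiased biomass/basal-area estimation).}
#'   \item{min_distance}{drop corners where any effective distance is
#'     below `min_distance` m (guards the plotless estimator against
#'     division blow-up).}
#' }
#' Additional rules may be registered as named predicate functions taking
#' a `pls_points` object and returning the point ids to drop.
#'
#' @param dialect `"historical"` or `"metric"`.
#' @param dist_unit distance unit; defaults to the dialect's unit
#'   (`"links"` or `"m"`); `"chains"` also accepted.
#' @param dbh_unit diameter unit; defaults to the dialect's unit.
#' @param drop_missing_dbh logical; enable the missing-dbh rule.
#' @param drop_min_distance logical; enable the minimum-distance rule.
#' @param min_distance minimum usable effective distance, m.
#' @param extra_rules named list of `function(points) -> point ids`.
#' @return An object of class `cleaning_config`.
#' @export
cleaning_config <- function(dialect = c("historical", "metric"),
                            dist_unit = NULL, dbh_unit = NULL,
                            drop_missing_dbh = TRUE,
                            drop_min_distance = TRUE,
                            min_distance = 0.001,
                            extra_rules = list()) {
  dialect <- match.arg(dialect)
  if (is.null(dist_unit))
    dist_unit <- if (dialect == "historical") "links" else "m"
  if (is.null(dbh_unit))
    dbh_unit <- if (dialect == "historical") "in" else "cm"
  dist_unit <- match.arg(dist_unit, c("links", "chains", "m"))
  dbh_unit <- match.arg(dbh_unit, c("in", "cm"))
  stopifnot(is.numeric(min_distance), min_distance >= 0)
  if (length(extra_rules) && is.null(names(extra_rules)))
    stop("extra_rules must be a named list")
  structure(list(dialect = dialect, dist_unit = dist_unit,
                 dbh_unit = dbh_unit,
                 drop_missing_dbh = isTRUE(drop_missing_dbh),
                 drop_min_distance = isTRUE(drop_min_distance),
                 min_distance = min_distance,
                 extra_rules = extra_rules),
            class = "cleaning_config")
}

required_point_cols <- function() c("point_id", "x", "y", "zone",
                                    "corner_type", "era")

dist_to_m <- function(x, unit) {
  switch(unit, links = links_to_m(x), chains = chains_to_m(x), m = x)
}
dbh_to_cm <- function(x, unit) switch(unit, "in" = in_to_cm(x), cm = x)

#' Effective point-to-tree distance
#'
#' The distance used by the plotless density estimator: the
#' surveyor-recorded distance plus one-half the tree diameter (surveyors
#' measured to the tree face, the estimator wants the center). With dbh
#' in cm and distance in m this is `dist + dbh / 200`. Trees with a
#' missing diameter keep the recorded distance and are flagged via the
#' `"flagged"` attribute.
#'
#' @param dist_recorded recorded distance, m.
#' @param dbh diameter at breast height, cm (may be `NA`).
#' @return Numeric vector of effective distances, m, with a logical
#'   `"flagged"` attribute marking missing-dbh entries.
#' @export
effective_distance <- function(dist_recorded, dbh) {
  if (any(dist_recorded < 0, na.rm = TRUE))
    stop("negative recorded distance")
  flagged <- is.na(dbh) & !is.na(dist_recorded)
  out <- dist_recorded + ifelse(is.na(dbh), 0, dbh) / 200
  attr(out, "flagged") <- flagged
  out
}

new_pls_points <- function(points, trees, rejected = NULL) {
  structure(list(points = points, trees = trees,
                 rejected = rejected), class = "pls_points")
}

#' @export
print.pls_points <- function(x, ...) {
  cat("<pls_points> ", nrow(x$points), " survey corners, ",
      nrow(x$trees), " witness trees\n", sep = "")
  if (!is.null(x$rejected) && nrow(x$rejected))
    cat("  ", nrow(x$rejected), " rejected input rows\n", sep = "")
  invisible(x)
}

#' Number of corners
#' @param x a `pls_points` object.
#' @return Integer count of survey corners.
#' @export
n_points <- function(x) nrow(x$points)

#' Parse a point-record table into the canonical representation
#'
#' Reads the wide survey-corner CSV schema: one row per corner with
#' columns `point_id, x, y, zone, corner_type, era` and per-tree columns
#' `taxon_1..taxon_4, dbh_1..dbh_4, dist_1..dist_4, az_1..az_4` (trailing
#' tree slots may be absent). Empty or "no tree" slots yield corners with
#' fewer (possibly zero) trees. All distances are converted to m and
#' diameters to cm according to the declared unit dialect, and effective
#' distances are computed.
#'
#' @param file path to the CSV file, or a data frame already in the wide
#'   schema.
#' @param config a [cleaning_config()] declaring the unit dialect.
#' @return A `pls_points` object. Rows failing schema validation are
#'   dropped and recorded in the `rejected` component with a reason.
#' @export
parse_points <- function(file, config = cleaning_config("metric")) {
  stopifnot(inherits(config, "cleaning_config"))
  raw <- if (is.data.frame(file)) file else
    read.csv(file, stringsAsFactors = FALSE)
  miss <- setdiff(required_point_cols(), names(raw))
  if (length(miss))
    stop("malformed header: missing column(s) ",
         paste(miss, collapse = ", "))

  raw$x <- suppressWarnings(as.numeric(raw$x))
  raw$y <- suppressWarnings(as.numeric(raw$y))
  bad_coord <- !is.finite(raw$x) | !is.finite(raw$y)
  bad_id <- is.na(raw$point_id) | duplicated(raw$point_id)
  keep <- !(bad_coord | bad_id)
  rejected <- data.frame(
    row = which(!keep),
    reason = ifelse(bad_coord[!keep], "bad_coordinates", "bad_point_id"),
    stringsAsFactors = FALSE)
  raw <- raw[keep, , drop = FALSE]

  slots <- grep("^taxon_[1-4]$", names(raw), value = TRUE)
  nslot <- length(slots)
  trees_list <- vector("list", max(nslot, 1))
  if (nslot > 0) {
    for (j in seq_len(nslot)) {
      tx <- as.character(raw[[paste0("taxon_", j)]])
      dbh <- suppressWarnings(as.numeric(
        if (paste0("dbh_", j) %in% names(raw)) raw[[paste0("dbh_", j)]]
        else NA))
      dst <- suppressWarnings(as.numeric(
        if (paste0("dist_", j) %in% names(raw)) raw[[paste0("dist_", j)]]
        else NA))
      az <- suppressWarnings(as.numeric(
        if (paste0("az_", j) %in% names(raw)) raw[[paste0("az_", j)]]
        else NA))
      present <- !is.na(tx) & nzchar(trimws(tx)) &
        !tolower(trimws(tx)) %in% c("no tree", "none", "na")
      trees_list[[j]] <- data.frame(
        point_id = raw$point_id[present], tree_no = j,
        taxon_raw = trimws(tx[present]), dbh = dbh[present],
        dist_recorded = dst[present], azimuth = az[present],
        stringsAsFactors = FALSE)
    }
  }
  trees <- do.call(rbind, trees_list)
  if (is.null(trees))
    trees <- data.frame(point_id = character(), tree_no = integer(),
                        taxon_raw = character(), dbh = numeric(),
                        dist_recorded = numeric(), azimuth = numeric(),
                        stringsAsFactors = FALSE)

  trees$dbh <- dbh_to_cm(trees$dbh, config$dbh_unit)
  trees$dist_recorded <- dist_to_m(trees$dist_recorded, config$dist_unit)
  ed <- effective_distance(trees$dist_recorded, trees$dbh)
  trees$dist_effective <- as.numeric(ed)
  trees$flag_missing_dbh <- is.na(trees$dbh)
  trees$taxon_std <- NA_character_
  trees <- trees[order(trees$point_id, trees$tree_no), , drop = FALSE]
  rownames(trees) <- NULL

  counts <- table(trees$point_id)
  points <- data.frame(
    point_id = raw$point_id, x = raw$x, y = raw$y,
    zone = as.character(raw$zone),
    corner_type = as.character(raw$corner_type),
    era = as.character(raw$era),
    n_trees = as.integer(counts[match(raw$point_id, names(counts))]),
    stringsAsFactors = FALSE)
  points$n_trees[is.na(points$n_trees)] <- 0L
  if (any(points$n_trees > 4))
    stop("more than 4 trees at a corner")
  new_pls_points(points, trees, rejected)
}

#' Load a taxon-translation table
#'
#' @param file CSV with columns `vernacular` and `taxon_std`, or a data
#'   frame with those columns.
#' @return A `taxon_table` object (validated data frame).
#' @export
read_taxon_table <- function(file) {
  tab <- if (is.data.frame(file)) file else
    read.csv(file, stringsAsFactors = FALSE)
  stopifnot(all(c("vernacular", "taxon_std") %in% names(tab)))
  ok <- tab$taxon_std %in% c(pls_taxa(), pls_sentinels())
  if (!all(ok))
    stop("taxon_std outside the closed vocabulary: ",
         paste(unique(tab$taxon_std[!ok]), collapse = ", "))
  tab$key <- tolower(trimws(tab$vernacular))
  if (anyDuplicated(tab$key))
    stop("duplicate vernacular entries after normalization")
  class(tab) <- c("taxon_table", "data.frame")
  tab
}

#' Standardize surveyor taxon names
#'
#' Maps raw vernacular names to the standardized vocabulary by
#' case/whitespace-normalized lookup; unmatched names become `"Unknown"`
#' and are tallied.
#'
#' @param x a `pls_points` object.
#' @param table a [read_taxon_table()] table.
#' @return `x` with `trees$taxon_std` filled; the unmatched-name tally is
#'   attached as attribute `"unmatched"` (named integer vector).
#' @export
standardize_taxa <- function(x, table) {
  stopifnot(inherits(x, "pls_points"), inherits(table, "taxon_table"))
  key <- tolower(trimws(x$trees$taxon_raw))
  idx <- match(key, table$key)
  std <- table$taxon_std[idx]
  already <- is.na(idx) & x$trees$taxon_raw %in% c(pls_taxa(), pls_sentinels())
  std[already] <- x$trees$taxon_raw[already]
  unmatched <- is.na(std)
  std[unmatched] <- "Unknown"
  x$trees$taxon_std <- std
  tally <- table(key[unmatched])
  attr(x, "unmatched") <- setNames(as.integer(tally), names(tally))
  x
}

#' Apply cleaning rules
#'
#' Removes corners violating any enabled rule and returns both the kept
#' corners and an exclusion ledger partitioning removals by rule code.
#' Rules are evaluated in registration order; a corner is charged to the
#' first rule that removes it. The operation is idempotent and conserves
#' corners: `kept + excluded = input`.
#'
#' @param x a `pls_points` object (taxa standardized or not).
#' @param config a [cleaning_config()].
#' @return A list with `kept` (a `pls_points`) and `ledger` (data frame
#'   `point_id`, `rule`).
#' @export
apply_cleaning <- function(x, config) {
  stopifnot(inherits(x, "pls_points"), inherits(config, "cleaning_config"))
  ledger <- data.frame(point_id = character(), rule = character(),
                       stringsAsFactors = FALSE)
  dropped <- character()
  note <- function(ids, rule) {
    ids <- setdiff(ids, dropped)
    if (length(ids)) {
      ledger <<- rbind(ledger, data.frame(point_id = ids, rule = rule,
                                          stringsAsFactors = FALSE))
      dropped <<- c(dropped, ids)
    }
  }
  if (config$drop_missing_dbh) {
    bad <- unique(x$trees$point_id[x$trees$flag_missing_dbh])
    note(bad, "missing_dbh")
  }
  if (config$drop_min_distance) {
    bad <- unique(x$trees$point_id[
      !is.na(x$trees$dist_effective) &
        x$trees$dist_effective < config$min_distance])
    note(bad, "min_distance")
  }
  for (nm in names(config$extra_rules))
    note(config$extra_rules[[nm]](x), nm)

  keep <- !(x$points$point_id %in% dropped)
  kept <- new_pls_points(x$points[keep, , drop = FALSE],
                         x$trees[!(x$trees$point_id %in% dropped), ,
                                 drop = FALSE],
                         x$rejected)
  rownames(kept$points) <- rownames(kept$trees) <- NULL
  list(kept = kept, ledger = ledger)
}

#' Write an exclusion ledger
#' @param ledger data frame from [apply_cleaning()].
#' @param file output CSV path.
#' @return `file`, invisibly.
#' @export
write_exclusion_ledger <- function(ledger, file) {
  write.csv(ledger, file, row.names = FALSE)
  invisible(file)
}
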