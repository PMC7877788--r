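## Per-corner plotless density, tree biomass/basal area, and point-level
## products (totals and per-taxon).

#' Load a correction-factor table
#'
#' Correction factors are exogenous inputs keyed by survey zone, corner
#' type, and instruction era: `f_design` rescales the raw Morisita
#' estimate for changes in survey design (number and placement of trees
#' recorded), and `f_size` converts the raw density (no size threshold)
#' to the density of trees >= 20.32 cm (8 in) dbh. The table shipped in
#' `inst/extdata` is illustrative only, not the study values.
#'
#' @param file CSV (or data frame) with columns `zone, corner_type, era,
#'   f_design, f_size`.
#' @return A `correction_table` object.
#' @export
read_correction_table <- function(file) {
  tab <- if (is.data.frame(file)) file else
    read.csv(file, stringsAsFactors = FALSE)
  need <- c("zone", "corner_type", "era", "f_design", "f_size")
  stopifnot(all(need %in% names(tab)))
  if (any(!is.finite(tab$f_design)) || any(tab$f_design <= 0) ||
      any(!is.finite(tab$f_size)) || any(tab$f_size <= 0))
    stop("correction factors must be finite and > 0")
  tab$key <- paste(tab$zone, tab$corner_type, tab$era, sep = "\r")
  if (anyDuplicated(tab$key)) stop("duplicate (zone, corner_type, era) keys")
  class(tab) <- c("correction_table", "data.frame")
  tab
}

#' Look up correction factors
#' @param table a [read_correction_table()] table.
#' @param zone,corner_type,era character vectors (recycled to a common
#'   length).
#' @return Data frame with `f_design` and `f_size`; a missing key is an
#'   error (lookup must be total over the configured domain).
#' @export
lookup_correction <- function(table, zone, corner_type, era) {
  stopifnot(inherits(table, "correction_table"))
  key <- paste(zone, corner_type, era, sep = "\r")
  idx <- match(key, table$key)
  if (anyNA(idx))
    stop("no correction factors for: ",
         paste(unique(gsub("\r", "/", key[is.na(idx)])), collapse = "; "))
  data.frame(f_design = table$f_design[idx], f_size = table$f_size[idx])
}

#' Load an allometry table
#'
#' Coefficients of the regression of log biomass (kg) on log dbh (cm),
#' one row per standardized taxon (several taxa may share coefficients).
#' The shipped example table is illustrative, not the study assignments.
#'
#' @param file CSV (or data frame) with columns `taxon_std, b0, b1`.
#' @return An `allometry_table` object.
#' @export
read_allometry_table <- function(file) {
  tab <- if (is.data.frame(file)) file else
    read.csv(file, stringsAsFactors = FALSE)
  stopifnot(all(c("taxon_std", "b0", "b1") %in% names(tab)))
  if (any(tab$b1 <= 0)) stop("allometric slope b1 must be > 0")
  if (anyDuplicated(tab$taxon_std)) stop("duplicate taxon_std rows")
  class(tab) <- c("allometry_table", "data.frame")
  tab
}

#' Morisita plotless density estimator
#'
#' Estimates stem density at a survey corner from the effective
#' distances to the nearest tree in each of `m` sectors (two opposite
#' semicircles at the standard two-tree corner; quadrants at 3- and
#' 4-tree corners):
#' \deqn{\hat\lambda = f_{design} \, 10^4 \, \frac{m(m-1)}{\pi \sum_i r_i^2}}
#' in stems/ha with distances in m. For a one-tree corner the
#' sector-count factor degenerates and density is identifiable only
#' through an explicit design correction, so `f_design` must be supplied:
#' \eqn{\hat\lambda = f 10^4 / (\pi r^2)}.
#'
#' @param distances effective distances, m; one per sector (length 1-4).
#' @param f_design design correction factor (> 0); defaults to 1 except
#'   for one-tree corners, where it is required.
#' @return Raw stem density, stems/ha (no size threshold).
#' @export
morisita_density <- function(distances, f_design = 1) {
  m <- length(distances)
  if (m < 1 || m > 4) stop("need 1 to 4 sector distances")
  if (any(!is.finite(distances)) || any(distances <= 0))
    stop("all distances must be finite and > 0")
  if (m == 1 && missing(f_design))
    stop("one-tree corner: density is not identifiable without f_design")
  if (!is.finite(f_design) || f_design <= 0) stop("f_design must be > 0")
  mult <- if (m == 1) 1 else m * (m - 1)
  f_design * 1e4 * mult / (pi * sum(distances^2))
}

#' Apply the size-threshold correction
#'
#' Scales a raw density (all recorded trees, no meaningful diameter
#' threshold) to the density of trees >= 20.32 cm (8 in) dbh.
#'
#' @param density_raw raw stems/ha (>= 0).
#' @param f_size size-correction factor (> 0).
#' @return Corrected stems/ha.
#' @export
correct_density_threshold <- function(density_raw, f_size) {
  if (any(density_raw < 0, na.rm = TRUE)) stop("density_raw must be >= 0")
  if (any(!is.finite(f_size)) || any(f_size <= 0))
    stop("f_size must be > 0")
  density_raw * f_size
}

#' Individual-tree aboveground biomass from dbh
#'
#' Allometric scaling `exp(b0 + b1 * log(dbh))`, biomass in kg, dbh in
#' cm. Missing dbh propagates to a missing result.
#'
#' @param dbh diameter at breast height, cm (> 0).
#' @param b0,b1 intercept and slope of the log-log regression.
#' @return Biomass, kg.
#' @export
tree_biomass <- function(dbh, b0, b1) {
  if (any(dbh[!is.na(dbh)] <= 0)) stop("dbh must be > 0")
  exp(b0 + b1 * log(dbh))
}

#' Individual-tree basal area from dbh
#'
#' Cross-sectional area at breast height: `pi * (dbh/200)^2` m^2 with
#' dbh in cm.
#'
#' @param dbh diameter at breast height, cm (>= 0).
#' @return Basal area, m^2.
#' @export
tree_basal_area <- function(dbh) {
  if (any(dbh[!is.na(dbh)] < 0)) stop("dbh must be >= 0")
  pi * (dbh / 200)^2
}

#' Point-level products: density, basal area, biomass, per taxon
#'
#' For a corner with `n` trees and raw density `d`, each per-tree value
#' (biomass kg, basal area m^2, or the constant 1 for stem counts)
#' contributes `d / n` times its value, assigned to the tree's taxon;
#' the point total is the sum over trees. With two trees this is
#' one-half the stem density times each tree's value. Biomass is
#' converted kg/ha -> Mg/ha. Per-taxon values sum to the total exactly
#' by construction. Deliberately uses the *raw* (uncorrected) density:
#' all recorded trees enter, with no size threshold.
#'
#' @param trees data frame with columns `taxon_std`, `dbh` (cm) for the
#'   corner's trees (0 rows for a treeless corner).
#' @param density_raw raw stems/ha at this corner.
#' @param allometry an [read_allometry_table()] table.
#' @return List with `total` (named vector: density, basal_area,
#'   biomass) and `by_taxon` (data frame taxon, density, basal_area,
#'   biomass).
#' @export
point_products <- function(trees, density_raw, allometry) {
  stopifnot(inherits(allometry, "allometry_table"))
  if (nrow(trees) == 0) {
    return(list(total = c(density = 0, basal_area = 0, biomass = 0),
                by_taxon = data.frame(taxon = character(),
                                      density = numeric(),
                                      basal_area = numeric(),
                                      biomass = numeric())))
  }
  if (anyNA(trees$dbh)) stop("missing dbh; exclude the point upstream")
  n <- nrow(trees)
  idx <- match(trees$taxon_std, allometry$taxon_std)
  if (anyNA(idx))
    stop("no allometry for taxon: ",
         paste(unique(trees$taxon_std[is.na(idx)]), collapse = ", "))
  bm_kg <- tree_biomass(trees$dbh, allometry$b0[idx], allometry$b1[idx])
  ba <- tree_basal_area(trees$dbh)
  per_tree <- data.frame(taxon = trees$taxon_std,
                         density = density_raw / n,
                         basal_area = density_raw / n * ba,
                         biomass = density_raw / n * bm_kg / 1000)
  agg <- aggregate(per_tree[c("density", "basal_area", "biomass")],
                   by = list(taxon = per_tree$taxon), FUN = sum)
  list(total = c(density = sum(per_tree$density),
                 basal_area = sum(per_tree$basal_area),
                 biomass = sum(per_tree$biomass)),
       by_taxon = agg)
}

#' Point-level estimates for a whole survey dataset
#'
#' Runs the per-corner chain: look up correction factors, estimate raw
#' density from effective distances (nearest tree per sector), apply the
#' size-threshold correction, and compute basal-area and biomass
#' products from the raw density. Corners whose density cannot be
#' estimated (e.g. a one-tree corner) get `NA` with a reason; treeless
#' corners get zeros.
#'
#' @param x a cleaned, standardized `pls_points` object.
#' @param correction a [read_correction_table()] table.
#' @param allometry an [read_allometry_table()] table.
#' @return List with `totals` (data frame: point_id, x, y, n_trees,
#'   density_raw, density_corrected, basal_area, biomass, reason) and
#'   `by_taxon` (long data frame: point_id, taxon, density, basal_area,
#'   biomass).
#' @export
point_estimates <- function(x, correction, allometry) {
  stopifnot(inherits(x, "pls_points"))
  pts <- x$points
  fac <- lookup_correction(correction, pts$zone, pts$corner_type, pts$era)
  tr_split <- split(x$trees, factor(x$trees$point_id,
                                    levels = pts$point_id))
  out <- data.frame(point_id = pts$point_id, x = pts$x, y = pts$y,
                    n_trees = pts$n_trees,
                    density_raw = NA_real_, density_corrected = NA_real_,
                    basal_area = NA_real_, biomass = NA_real_,
                    reason = NA_character_, stringsAsFactors = FALSE)
  taxon_rows <- vector("list", nrow(pts))
  for (i in seq_len(nrow(pts))) {
    tr <- tr_split[[i]]
    if (nrow(tr) == 0) {
      out[i, c("density_raw", "density_corrected",
               "basal_area", "biomass")] <- 0
      next
    }
    d <- tryCatch(morisita_density(tr$dist_effective, fac$f_design[i]),
                  error = function(e) e)
    if (inherits(d, "error")) {
      out$reason[i] <- conditionMessage(d)
      next
    }
    out$density_raw[i] <- d
    out$density_corrected[i] <- correct_density_threshold(d, fac$f_size[i])
    pp <- point_products(tr, d, allometry)
    out$basal_area[i] <- pp$total[["basal_area"]]
    out$biomass[i] <- pp$total[["biomass"]]
    if (nrow(pp$by_taxon)) {
      pp$by_taxon$point_id <- pts$point_id[i]
      taxon_rows[[i]] <- pp$by_taxon
    }
  }
  by_taxon <- do.call(rbind, taxon_rows)
  if (is.null(by_taxon))
    by_taxon <- data.frame(taxon = character(), density = numeric(),
                           basal_area = numeric(), biomass = numeric(),
                           point_id = character())
  list(totals = out,
       by_taxon = by_taxon[c("point_id", "taxon", "density",
                             "basal_area", "biomass")])
}
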