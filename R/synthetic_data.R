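## Synthetic-data generators at the two levels the pipeline consumes:
## (a) tree level -- a marked spatial Poisson process sampled by the
## survey-corner protocol (nearest tree per sector); (b) cell level --
## gridded occupancy/potential surfaces with binomial / log-normal
## observation noise. Ground truth is always returned alongside the
## generated data so recovery tests can score against it.

#' Simulate a marked Poisson forest
#'
#' Homogeneous Poisson process of tree locations with i.i.d. marks:
#' dbh from a left-truncated log-normal (surveyors rarely recorded very
#' small stems) and taxon from a fixed mixture.
#'
#' @param lambda stem density, stems/ha.
#' @param extent domain `c(xmin, xmax, ymin, ymax)`, m.
#' @param dbh_meanlog,dbh_sdlog log-normal dbh parameters (cm scale).
#' @param dbh_min left-truncation point, cm.
#' @param taxon_probs named probability vector over taxa (sums to 1).
#' @param seed integer seed.
#' @return Data frame `x, y, dbh, taxon` with the simulation settings in
#'   attribute `"sim"`.
#' @export
simulate_forest <- function(lambda = 200,
                            extent = c(0, 2000, 0, 2000),
                            dbh_meanlog = log(25), dbh_sdlog = 0.45,
                            dbh_min = 10,
                            taxon_probs = c(Oak = 0.35, Maple = 0.2,
                                            Pine = 0.15, Beech = 0.1,
                                            Birch = 0.1, Hemlock = 0.1),
                            seed = 1) {
  stopifnot(lambda >= 0, length(extent) == 4,
            extent[2] > extent[1], extent[4] > extent[3],
            abs(sum(taxon_probs) - 1) < 1e-8)
  set.seed(seed)
  area_ha <- (extent[2] - extent[1]) * (extent[4] - extent[3]) / 1e4
  n <- rpois(1, lambda * area_ha)
  if (n == 0) {
    out <- data.frame(x = numeric(), y = numeric(), dbh = numeric(),
                      taxon = character())
  } else {
    # inverse-cdf sampling of the truncated log-normal
    p0 <- stats::plnorm(dbh_min, dbh_meanlog, dbh_sdlog)
    dbh <- qlnorm(p0 + runif(n) * (1 - p0), dbh_meanlog, dbh_sdlog)
    out <- data.frame(
      x = runif(n, extent[1], extent[2]),
      y = runif(n, extent[3], extent[4]),
      dbh = dbh,
      taxon = sample(names(taxon_probs), n, replace = TRUE,
                     prob = taxon_probs))
  }
  attr(out, "sim") <- list(lambda = lambda, extent = extent,
                           dbh_meanlog = dbh_meanlog,
                           dbh_sdlog = dbh_sdlog, dbh_min = dbh_min,
                           taxon_probs = taxon_probs, seed = seed)
  out
}

#' Sample a forest by the survey-corner protocol
#'
#' Places corners on a regular lattice and records, at each corner, the
#' nearest tree in each sector: two opposite semicircles (east/west;
#' the default, matching the density estimator's two-sector form) or
#' four quadrants. Recorded distances are tree-face distances
#' (center distance minus dbh/200, floored at 0) so that the pipeline's
#' effective-distance rule reconstructs the exact center distance.
#' Corners are placed at least `spacing / 2` from the domain edge, and
#' the per-corner search is restricted to a window of `1.5 * spacing`,
#' which is effectively exhaustive whenever mean nearest-tree distances
#' are small relative to the spacing.
#'
#' @param trees data frame from [simulate_forest()].
#' @param spacing lattice spacing, m (default 805, the half-mile survey
#'   spacing).
#' @param protocol `"two-sector"` (default) or `"four-quadrant"`.
#' @param empty_sector `"keep"` (default: corner recorded with fewer
#'   trees) or `"drop"` (corner omitted).
#' @param zone,corner_type,era codes stamped on every corner (single
#'   values).
#' @return Wide survey-corner data frame in the [parse_points()] CSV
#'   schema (metric dialect).
#' @export
sample_corners <- function(trees, spacing = 805,
                           protocol = c("two-sector", "four-quadrant"),
                           empty_sector = c("keep", "drop"),
                           zone = "Z1", corner_type = "section",
                           era = "e1") {
  protocol <- match.arg(protocol)
  empty_sector <- match.arg(empty_sector)
  sim <- attr(trees, "sim")
  extent <- if (!is.null(sim)) sim$extent else
    c(min(trees$x), max(trees$x), min(trees$y), max(trees$y))
  cx <- seq(extent[1] + spacing / 2, extent[2] - spacing / 2 + 1e-9,
            by = spacing)
  cy <- seq(extent[3] + spacing / 2, extent[4] - spacing / 2 + 1e-9,
            by = spacing)
  if (!length(cx) || !length(cy)) stop("extent too small for spacing")
  corners <- expand.grid(cxi = seq_along(cx), cyi = seq_along(cy))
  corners$x <- cx[corners$cxi]; corners$y <- cy[corners$cyi]
  corners$corner_id <- seq_len(nrow(corners))

  n_sector <- if (protocol == "two-sector") 2L else 4L
  best_d <- matrix(Inf, nrow(corners), n_sector)
  best_t <- matrix(NA_integer_, nrow(corners), n_sector)
  if (nrow(trees)) {
    # nearest lattice index per tree, then candidate corners in a
    # 3x3 neighborhood (search window 1.5 * spacing)
    ti <- pmin(pmax(round((trees$x - cx[1]) / spacing), 0),
               length(cx) - 1)
    tj <- pmin(pmax(round((trees$y - cy[1]) / spacing), 0),
               length(cy) - 1)
    for (di in -1:1) for (dj in -1:1) {
      ci <- ti + di; cj <- tj + dj
      ok <- ci >= 0 & ci < length(cx) & cj >= 0 & cj < length(cy)
      if (!any(ok)) next
      cid <- cj[ok] * length(cx) + ci[ok] + 1L
      dx <- trees$x[ok] - corners$x[cid]
      dy <- trees$y[ok] - corners$y[cid]
      d <- sqrt(dx^2 + dy^2)
      inwin <- d <= 1.5 * spacing
      sector <- if (protocol == "two-sector") ifelse(dx >= 0, 1L, 2L)
        else 1L + (dx < 0) + 2L * (dy < 0)
      idx <- which(ok)[inwin]
      cid <- cid[inwin]; d <- d[inwin]; sector <- sector[inwin]
      o <- order(cid, sector, d)
      grp <- paste(cid[o], sector[o])
      first <- !duplicated(grp)
      sel <- o[first]
      pos <- cbind(cid[sel], sector[sel])
      better <- d[sel] < best_d[pos]
      pos <- pos[better, , drop = FALSE]
      best_d[pos] <- d[sel][better]
      best_t[pos] <- idx[sel][better]
    }
  }

  out <- data.frame(point_id = sprintf("c%05d", corners$corner_id),
                    x = corners$x, y = corners$y,
                    zone = zone, corner_type = corner_type, era = era,
                    stringsAsFactors = FALSE)
  for (s in seq_len(n_sector)) {
    j <- best_t[, s]
    has <- is.finite(best_d[, s])
    dbh <- ifelse(has, trees$dbh[j], NA_real_)
    out[[paste0("taxon_", s)]] <- ifelse(has, trees$taxon[j], "No tree")
    out[[paste0("dbh_", s)]] <- dbh
    out[[paste0("dist_", s)]] <-
      ifelse(has, pmax(0, best_d[, s] - dbh / 200), NA_real_)
    out[[paste0("az_", s)]] <-
      ifelse(has, (atan2(trees$x[j] - corners$x,
                         trees$y[j] - corners$y) * 180 / pi) %% 360,
             NA_real_)
  }
  if (empty_sector == "drop") {
    full <- rowSums(is.finite(best_d)) == n_sector
    out <- out[full, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Default synthetic occupancy surface
#'
#' Logistic transform of a sum of Gaussian bumps over the unit square:
#' smooth, bounded away from 0 and 1, with closed-form truth.
#'
#' @param u,v coordinates scaled to `[0, 1]`.
#' @return Occupancy probabilities in (0, 1).
#' @export
default_theta_surface <- function(u, v) {
  g <- function(u0, v0, s) exp(-((u - u0)^2 + (v - v0)^2) / (2 * s^2))
  plogis(-0.6 + 2.2 * g(0.35, 0.6, 0.25) + 1.8 * g(0.75, 0.25, 0.2))
}

#' Default synthetic log-potential surface
#'
#' Affine map of Gaussian bumps; `exp` of the surface spans roughly
#' 18-135 Mg/ha, a realistic conditional-biomass range.
#'
#' @param u,v coordinates scaled to `[0, 1]`.
#' @return Log-scale potential values.
#' @export
default_m_surface <- function(u, v) {
  g <- function(u0, v0, s) exp(-((u - u0)^2 + (v - v0)^2) / (2 * s^2))
  log(45) + 1.1 * g(0.3, 0.3, 0.3) - 0.9 * g(0.8, 0.7, 0.25)
}

#' Simulate gridded cell data from the two-stage generative model
#'
#' The exact sampling counterpart of the smoothing model's likelihoods:
#' `n_p ~ Binomial(N, theta*(s))` and, where `n_p > 0`,
#' `log Ybar_p ~ Normal(m*(s), sigma2 / n_p)`. Truth surfaces are
#' returned alongside the data.
#'
#' @param grid a [grid_spec()] (default 30 x 30 cells of 8 km).
#' @param theta_fun,m_fun truth surfaces as functions of scaled
#'   coordinates `(u, v)` in `[0, 1]`.
#' @param sigma2 observation log-variance per occupied corner
#'   (default 0.25).
#' @param N corners per cell (default 70, a fully surveyed cell);
#'   scalar or per-cell vector.
#' @param seed integer seed.
#' @return Data frame `cell_id, x, y, N, n_p, Ybar_p, obs` plus truth
#'   columns `theta_true, m_true, b_true`; `obs = (n_p / N) * Ybar_p`
#'   (0 where unoccupied) is the raw cell mean the model is judged
#'   against.
#' @export
simulate_cells <- function(grid = grid_spec(0, 0, 8000, 30, 30),
                           theta_fun = default_theta_surface,
                           m_fun = default_m_surface,
                           sigma2 = 0.25, N = 70, seed = 1) {
  stopifnot(inherits(grid, "grid_spec"), sigma2 >= 0, all(N >= 1))
  cells <- cell_centers(grid)
  u <- (cells$x - grid$x0) / (grid$nx * grid$cell_size)
  v <- (cells$y - grid$y0) / (grid$ny * grid$cell_size)
  cells$theta_true <- theta_fun(u, v)
  cells$m_true <- m_fun(u, v)
  cells$b_true <- cells$theta_true * exp(cells$m_true)
  cells$N <- as.integer(rep(N, length.out = nrow(cells)))
  set.seed(seed)
  cells$n_p <- rbinom(nrow(cells), cells$N, cells$theta_true)
  cells$Ybar_p <- NA_real_
  occ <- cells$n_p > 0
  cells$Ybar_p[occ] <- exp(rnorm(sum(occ), cells$m_true[occ],
                                 sqrt(sigma2 / cells$n_p[occ])))
  cells$obs <- ifelse(occ, (cells$n_p / cells$N) * cells$Ybar_p, 0)
  attr(cells, "sim") <- list(grid = grid, sigma2 = sigma2, seed = seed)
  cells
}

#' Bundled miniature fixtures
#'
#' Deterministic small datasets with precomputed expected outputs, built
#' in code (no stored binaries). Registry:
#' \describe{
#'   \item{cleaning10}{10 survey corners in the wide CSV schema, exactly
#'     3 with a missing dbh; expected: 7 kept under default cleaning.}
#'   \item{grid3x3}{a 3 x 3 grid with 4 points per cell and known
#'     per-cell aggregates.}
#'   \item{tables}{illustrative taxon-translation, correction and
#'     allometry tables (as shipped in `inst/extdata`).}
#' }
#'
#' @param name registry key.
#' @return List with `data` and `expected` components.
#' @export
make_fixture <- function(name) {
  switch(name,
    cleaning10 = {
      pts <- data.frame(
        point_id = sprintf("p%02d", 1:10),
        x = seq(100, 1000, by = 100), y = rep(500, 10),
        zone = "Z1", corner_type = "section", era = "e1",
        taxon_1 = c("Oak", "Oak", "Maple", "Pine", "Oak",
                    "Hemlock", "Oak", "Beech", "Birch", "Oak"),
        dbh_1 = c(30, NA, 25, 40, 22, 35, NA, 28, 31, 26),
        dist_1 = c(5, 6, 7, 4, 9, 6, 5, 8, 7, 6),
        az_1 = 45,
        taxon_2 = c("Maple", "Pine", "Oak", "Oak", "Maple",
                    "Oak", "Pine", "Oak", "Oak", "Maple"),
        dbh_2 = c(20, 25, 30, 35, 24, NA, 27, 33, 29, 21),
        dist_2 = c(4, 5, 6, 7, 8, 5, 6, 4, 5, 7),
        az_2 = 225, stringsAsFactors = FALSE)
      list(data = pts, expected = list(n_kept = 7,
           excluded = c("p02", "p06", "p07")))
    },
    grid3x3 = {
      grid <- grid_spec(0, 0, cell_size = 100, nx = 3, ny = 3)
      set.seed(42)
      pts <- expand.grid(ix = 0:2, iy = 0:2, j = 1:4)
      pts$x <- pts$ix * 100 + 20 + 15 * pts$j
      pts$y <- pts$iy * 100 + 10 + 18 * pts$j
      pts$value <- c(0, 0, 10, 30)[pts$j] * (1 + pts$ix + 3 * pts$iy)
      list(data = list(grid = grid, points = pts),
           expected = list(N = 4, n_p = 2,
                           cell_mean_rule = "(n_p/N)*Ybar_p"))
    },
    tables = {
      list(data = list(
        taxon = read_taxon_table(example_path("taxon_translation_example.csv")),
        correction = read_correction_table(example_path("correction_factors_example.csv")),
        allometry = read_allometry_table(example_path("allometry_example.csv"))),
        expected = list())
    },
    stop("unknown fixture: ", name))
}

example_path <- function(file) {
  p <- system.file("extdata", file, package = "plsforest")
  if (!nzchar(p)) stop("example file not found: ", file)
  p
}
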