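## Assignment of survey corners to grid cells and raw cell-level
## aggregates. Cells are half-open intervals [x0 + i*h, x0 + (i+1)*h) so
## every in-extent coordinate maps to exactly one cell.

#' Grid specification
#'
#' @param x0,y0 grid origin (lower-left corner of cell (0,0)), m, in the
#'   working equal-area projection.
#' @param cell_size cell edge length, m (default 8000, the 8-km product
#'   grid).
#' @param nx,ny cell counts in x and y.
#' @param crs optional free-text projection tag (carried as metadata;
#'   no geodesy is performed).
#' @return A `grid_spec` object.
#' @export
grid_spec <- function(x0, y0, cell_size = 8000, nx, ny, crs = NULL) {
  stopifnot(is.finite(x0), is.finite(y0), cell_size > 0,
            nx >= 1, ny >= 1)
  structure(list(x0 = x0, y0 = y0, cell_size = cell_size,
                 nx = as.integer(nx), ny = as.integer(ny), crs = crs),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat("<grid_spec> ", x$nx, "x", x$ny, " cells of ", x$cell_size,
      " m, origin (", x$x0, ", ", x$y0, ")\n", sep = "")
  invisible(x)
}

#' Cell centers of a grid
#' @param grid a [grid_spec()].
#' @return Data frame `cell_id, ix, iy, x, y` for all `nx * ny` cells;
#'   `cell_id = iy * nx + ix + 1` with 0-based indices.
#' @export
cell_centers <- function(grid) {
  ix <- rep(seq_len(grid$nx) - 1L, times = grid$ny)
  iy <- rep(seq_len(grid$ny) - 1L, each = grid$nx)
  data.frame(cell_id = iy * grid$nx + ix + 1L, ix = ix, iy = iy,
             x = grid$x0 + (ix + 0.5) * grid$cell_size,
             y = grid$y0 + (iy + 0.5) * grid$cell_size)
}

#' Assign points to grid cells
#'
#' Half-open convention: a point exactly on a cell boundary belongs to
#' the cell whose lower edge it sits on. Out-of-extent points map to
#' `NA` and are reported via the `"dropped"` attribute.
#'
#' @param x,y projected coordinates, m.
#' @param grid a [grid_spec()].
#' @return Integer vector of cell ids (NA = out of extent) with
#'   attribute `"dropped"` (indices of dropped points).
#' @export
assign_cells <- function(x, y, grid) {
  stopifnot(inherits(grid, "grid_spec"), length(x) == length(y))
  ix <- floor((x - grid$x0) / grid$cell_size)
  iy <- floor((y - grid$y0) / grid$cell_size)
  ok <- ix >= 0 & ix < grid$nx & iy >= 0 & iy < grid$ny
  id <- ifelse(ok, iy * grid$nx + ix + 1L, NA_integer_)
  dropped <- which(!ok)
  if (length(dropped))
    warning(length(dropped), " point(s) outside the grid extent dropped")
  structure(as.integer(id), dropped = dropped)
}

#' Raw cell-level aggregates for one variable
#'
#' For each grid cell computes: `N` (number of corners), `n_p` (corners
#' occupied by the taxon, i.e. with at least one tree of the taxon),
#' `Ybar_p` (mean of the point values over occupied corners only),
#' `cell_mean` (arithmetic mean over *all* corners, zeros included) and
#' `zero_prop` (fraction of unoccupied corners). The decomposition
#' `cell_mean = (n_p / N) * Ybar_p` holds to machine precision by
#' construction. Cells with no corners are retained with `N = 0` and
#' missing aggregates; they are prediction targets for the smoothing
#' model.
#'
#' @param cell_id cell assignment per point (NAs dropped).
#' @param value non-negative point-level values (0 where unoccupied).
#' @param grid a [grid_spec()].
#' @param occupied logical per point; default `value > 0`.
#' @return Data frame, one row per grid cell: `cell_id, x, y, N, n_p,
#'   Ybar_p, cell_mean, zero_prop`.
#' @export
aggregate_cells <- function(cell_id, value, grid, occupied = NULL) {
  stopifnot(inherits(grid, "grid_spec"), length(cell_id) == length(value))
  if (is.null(occupied)) occupied <- value > 0
  keep <- !is.na(cell_id) & !is.na(value)
  cell_id <- cell_id[keep]; value <- value[keep]
  occupied <- occupied[keep]
  cells <- cell_centers(grid)
  f <- factor(cell_id, levels = cells$cell_id)
  N <- as.integer(tabulate(f, nbins = nrow(cells)))
  # rowsum only returns groups that occur; re-expand to the full grid
  occ_sum <- rowsum(as.numeric(occupied), f)
  val_sum <- rowsum(value, f)
  n_p <- integer(nrow(cells))
  n_p[match(rownames(occ_sum), cells$cell_id)] <- as.integer(occ_sum[, 1])
  tot <- numeric(nrow(cells))
  tot[match(rownames(val_sum), cells$cell_id)] <- val_sum[, 1]
  cells$N <- N
  cells$n_p <- n_p
  cells$Ybar_p <- ifelse(n_p > 0, tot / n_p, NA_real_)
  cells$cell_mean <- ifelse(N > 0, tot / N, NA_real_)
  cells$zero_prop <- ifelse(N > 0, 1 - n_p / N, NA_real_)
  cells[c("cell_id", "x", "y", "N", "n_p", "Ybar_p", "cell_mean",
          "zero_prop")]
}

#' Gridded raw product for totals and all taxa
#'
#' Convenience wrapper running [assign_cells()] and [aggregate_cells()]
#' for total density (corrected), basal area, and biomass, and for each
#' taxon's biomass/basal area/density from the long per-taxon table.
#'
#' @param est output of [point_estimates()].
#' @param grid a [grid_spec()].
#' @param variables which totals to grid.
#' @return Named list of aggregate data frames: `total$<variable>` and
#'   `taxon$<taxon>$<variable>`.
#' @export
grid_aggregate <- function(est, grid,
                           variables = c("density_corrected",
                                         "basal_area", "biomass")) {
  tot <- est$totals
  usable <- !is.na(tot$density_raw)
  cid <- assign_cells(tot$x[usable], tot$y[usable], grid)
  tot <- tot[usable, , drop = FALSE]
  out <- list(total = list(), taxon = list())
  for (v in variables) {
    out$total[[v]] <- aggregate_cells(cid, tot[[v]], grid,
                                      occupied = tot$n_trees > 0)
  }
  bt <- est$by_taxon
  bt <- bt[bt$point_id %in% tot$point_id, , drop = FALSE]
  for (tax in sort(unique(bt$taxon))) {
    sub <- bt[bt$taxon == tax, , drop = FALSE]
    m <- match(tot$point_id, sub$point_id)
    out$taxon[[tax]] <- list()
    for (v in c("density", "basal_area", "biomass")) {
      val <- ifelse(is.na(m), 0, sub[[v]][m])
      out$taxon[[tax]][[v]] <-
        aggregate_cells(cid, val, grid, occupied = !is.na(m))
    }
  }
  out
}

#' Write a gridded product to CSV
#' @param cells aggregate data frame from [aggregate_cells()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_gridded_csv <- function(cells, file) {
  write.csv(cells, file, row.names = FALSE)
  invisible(file)
}
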