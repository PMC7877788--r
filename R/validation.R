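## 10-fold cross-validation protocol: weighted absolute error with
## truncation, data-level predictive draws, prediction-interval coverage
## on well-sampled cells, and interval-sharpness summaries.

#' Cross-validation configuration
#'
#' @param n_folds number of folds (default 10).
#' @param seed integer seed for fold assignment and predictive draws.
#' @param cap truncation cap for absolute error, in the variable's units
#'   (default 600, the Mg/ha biomass cap; caps for density and basal
#'   area are user choices).
#' @param level prediction-interval level (default 0.90).
#' @param min_points minimum corners per cell for coverage eligibility
#'   (default 60).
#' @param n_draws predictive draws per cell (default 250).
#' @return A `cv_config` object.
#' @export
cv_config <- function(n_folds = 10, seed = 1, cap = 600, level = 0.90,
                      min_points = 60, n_draws = 250) {
  stopifnot(n_folds >= 2, level > 0, level < 1, cap > 0,
            min_points >= 0, n_draws >= 2)
  structure(list(n_folds = n_folds, seed = as.integer(seed), cap = cap,
                 level = level, min_points = min_points,
                 n_draws = n_draws), class = "cv_config")
}

#' Random k-fold split
#'
#' Randomly partitions `n` cells into `n_folds` folds whose sizes differ
#' by at most one; reproducible given `seed`.
#'
#' @param n number of cells (>= `n_folds`).
#' @param n_folds number of folds.
#' @param seed integer seed.
#' @return Integer fold labels of length `n`.
#' @export
kfold_split <- function(n, n_folds = 10, seed = 1) {
  stopifnot(n >= n_folds)
  set.seed(seed)
  sample(rep(seq_len(n_folds), length.out = n))
}

#' Truncated weighted absolute error
#'
#' Mean absolute error between predictions and held-out raw values,
#' weighted by the number of survey corners in each held-out cell, with
#' both predictions and observations truncated at `cap` so extreme
#' values do not dominate the assessment:
#' `sum(w * |min(pred, cap) - min(obs, cap)|) / sum(w)`.
#'
#' @param pred,obs aligned numeric vectors.
#' @param w non-negative weights (corner counts).
#' @param cap truncation cap (same units as `pred`/`obs`); `Inf`
#'   recovers the untruncated error.
#' @return Weighted MAE (units of `pred`), or `NA` if all weights are 0.
#' @export
weighted_abs_error <- function(pred, obs, w, cap = 600) {
  stopifnot(length(pred) == length(obs), length(obs) == length(w),
            all(w >= 0, na.rm = TRUE))
  keep <- !is.na(pred) & !is.na(obs) & !is.na(w)
  pred <- pred[keep]; obs <- obs[keep]; w <- w[keep]
  if (sum(w) == 0) {
    warning("all weights zero")
    return(NA_real_)
  }
  sum(w * abs(pmin(pred, cap) - pmin(obs, cap))) / sum(w)
}

#' Data-level predictive draws
#'
#' Converts process-level draws into draws of the observable raw cell
#' value, so that interval coverage can be judged against data. For each
#' draw `d` and cell: draw `n_d ~ Binomial(N, theta_d)`; if `n_d = 0`
#' the data draw is 0; otherwise the data draw is `(n_d / N) * exp(m_d +
#' e_d)` with `e_d ~ Normal(0, sigma2 / n_d)` (the exponential is
#' dropped for an original-scale potential model). The binomial draw and
#' the residual noise make this a prediction for the raw observation
#' rather than the latent field.
#'
#' @param theta_draws `n_cells x D` occupancy draws (probabilities).
#' @param m_draws `n_cells x D` potential draws (link scale).
#' @param sigma2 residual variance of the potential model (per occupied
#'   corner).
#' @param N corners per cell (length `n_cells`).
#' @param seed integer seed.
#' @param scale potential-model scale tag.
#' @return `n_cells x D` matrix of data-level draws.
#' @export
predictive_draws <- function(theta_draws, m_draws, sigma2, N, seed = 1,
                             scale = "log") {
  stopifnot(all(dim(theta_draws) == dim(m_draws)),
            nrow(theta_draws) == length(N), sigma2 >= 0)
  nc <- nrow(theta_draws); D <- ncol(theta_draws)
  set.seed(seed)
  Nmat <- rep(N, times = D)
  nd <- rbinom(nc * D, size = Nmat, prob = pmin(1, as.vector(theta_draws)))
  e <- numeric(nc * D)
  pos <- nd > 0
  e[pos] <- rnorm(sum(pos), 0, sqrt(sigma2 / nd[pos]))
  mvec <- as.vector(m_draws)
  val <- if (identical(scale, "original")) mvec + e else exp(mvec + e)
  out <- (nd / Nmat) * val
  out[!pos] <- 0
  matrix(out, nc, D)
}

#' Prediction-interval coverage and sharpness
#'
#' Builds central intervals from the empirical quantiles of the data
#' draws (linear interpolation; the 5th and 95th percentiles at the
#' default 90% level) and reports the fraction of eligible cells (at
#' least `min_points` corners) whose observation falls inside, plus the
#' median interval length and median log-length as sharpness summaries.
#'
#' @param draws `n_cells x D` matrix from [predictive_draws()].
#' @param obs observed raw cell values (length `n_cells`).
#' @param N corners per cell.
#' @param level interval level (default 0.90).
#' @param min_points eligibility threshold on `N` (default 60).
#' @return List: `coverage`, `n_eligible`, `median_length`,
#'   `median_log_length`, and the per-cell bounds.
#' @export
pi_coverage <- function(draws, obs, N, level = 0.90, min_points = 60) {
  stopifnot(nrow(draws) == length(obs), length(obs) == length(N))
  eligible <- !is.na(obs) & N >= min_points
  if (!any(eligible)) {
    warning("no eligible cells")
    return(list(coverage = NA_real_, n_eligible = 0L,
                median_length = NA_real_, median_log_length = NA_real_,
                lower = rep(NA_real_, length(obs)),
                upper = rep(NA_real_, length(obs))))
  }
  alpha <- (1 - level) / 2
  lo <- apply(draws, 1, quantile, probs = alpha, names = FALSE)
  hi <- apply(draws, 1, quantile, probs = 1 - alpha, names = FALSE)
  inside <- obs >= lo & obs <= hi
  len <- (hi - lo)[eligible]
  list(coverage = mean(inside[eligible]),
       n_eligible = sum(eligible),
       median_length = median(len),
       median_log_length = median(log(len)),
       lower = lo, upper = hi)
}

#' Cross-validated model assessment over a grid of basis dimensions
#'
#' Implements the model-selection protocol: randomly split the grid
#' cells into `n_folds` folds; for each fold and each maximum basis
#' dimension `k`, fit the occupancy and potential models on the
#' remaining cells, predict the held-out cells, draw `n_draws`
#' data-level predictive values per held-out cell, and accumulate (a)
#' absolute error of the point prediction `b = theta * exp(m)` against
#' the held-out raw cell mean, weighted by the held-out cell's corner
#' count and truncated at `cap`, and (b) interval coverage and sharpness
#' on cells with at least `min_points` corners.
#'
#' @param cells data frame with `cell_id, x, y, N, n_p, Ybar_p` (raw
#'   aggregates; the observation is `(n_p / N) * Ybar_p`, zero where
#'   unoccupied).
#' @param k_grid integer vector of maximum basis dimensions to compare.
#' @param config a [cv_config()].
#' @param scale potential-model scale (`"log"` default, `"original"`
#'   for the scale comparison).
#' @param method,engine passed to the fitting functions.
#' @return A `cv_result` data frame: one row per `k` with `wmae`,
#'   `coverage`, `n_eligible`, `median_length`, `median_log_length`;
#'   fold labels in attribute `"folds"`.
#' @export
cv_smoothing <- function(cells, k_grid = c(100, 250, 500),
                         config = cv_config(), scale = "log",
                         method = "GCV.Cp", engine = "gam") {
  stopifnot(inherits(config, "cv_config"))
  obs_cells <- cells[cells$N > 0, , drop = FALSE]
  folds <- kfold_split(nrow(obs_cells), config$n_folds, config$seed)
  obs_val <- ifelse(obs_cells$n_p > 0,
                    (obs_cells$n_p / obs_cells$N) * obs_cells$Ybar_p, 0)
  res <- list()
  for (k in k_grid) {
    pred_b <- rep(NA_real_, nrow(obs_cells))
    draws_all <- matrix(NA_real_, nrow(obs_cells), config$n_draws)
    for (f in seq_len(config$n_folds)) {
      test <- folds == f
      train <- obs_cells[!test, , drop = FALSE]
      occ <- fit_occupancy(train, k = k, method = method,
                           engine = engine)
      pot <- fit_potential(train, k = k, scale = scale, method = method,
                           engine = engine)
      held <- obs_cells[test, , drop = FALSE]
      # predict held-out cells from the training fits
      Xo <- predict(occ$model, newdata = held, type = "lpmatrix")
      Xp <- predict(pot$model, newdata = held, type = "lpmatrix")
      seed_f <- config$seed * 1000L + f
      th_d <- plogis(Xo %*% t(draw_coefficients(occ, config$n_draws,
                                                seed = seed_f)))
      m_d <- Xp %*% t(draw_coefficients(pot, config$n_draws,
                                        seed = seed_f + 500L))
      theta_hat <- plogis(as.numeric(Xo %*% occ$beta))
      m_hat <- as.numeric(Xp %*% pot$beta)
      pred_b[test] <- if (identical(scale, "original"))
        theta_hat * m_hat else theta_hat * exp(m_hat)
      draws_all[test, ] <- predictive_draws(
        th_d, m_d, pot$sig2, held$N, seed = seed_f + 900L,
        scale = scale)
    }
    wmae <- weighted_abs_error(pred_b, obs_val, obs_cells$N,
                               cap = config$cap)
    cov <- pi_coverage(draws_all, obs_val, obs_cells$N,
                       level = config$level,
                       min_points = config$min_points)
    res[[as.character(k)]] <- data.frame(
      k = k, wmae = wmae, coverage = cov$coverage,
      n_eligible = cov$n_eligible, median_length = cov$median_length,
      median_log_length = cov$median_log_length)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "folds") <- folds
  class(out) <- c("cv_result", "data.frame")
  out
}
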