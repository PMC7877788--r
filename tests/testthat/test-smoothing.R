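test_that("basis construction caps k, is deterministic, spans constants", {
  cells <- small_cells()
  b <- build_basis(cells[c("x", "y")], k = 25)
  expect_s3_class(b, "spline_basis")
  expect_lte(b$k_effective, 25)
  expect_lte(build_basis(cells[c("x", "y")], k = 4)$k_effective, 4)
  # deterministic given coordinates and k
  b2 <- build_basis(cells[c("x", "y")], k = 25)
  expect_identical(b$X, b2$X)
  # penalties are symmetric PSD
  for (S in b$S) {
    expect_equal(S, t(S))
    expect_gte(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values),
               -1e-8)
  }
  # constants lie in the penalty nullspace: after constraint absorption
  # the constant is the unpenalized intercept, so the full design
  # [1, X] reproduces constants with zero penalty
  expect_equal(qr(cbind(1, b$X))$rank, ncol(b$X) + 1)
  expect_error(build_basis(cells[1:5, c("x", "y")], 16), "at least 10")
  expect_error(build_basis(cells[c("x", "y")], 3), ">= 4")
  expect_warning(build_basis(small_cells(4, 3)[c("x", "y")], k = 100),
                 "capped")
})

test_that("full-rank basis at cell centers on a 20x20 grid", {
  cells <- cell_centers(grid_spec(0, 0, 1000, 20, 20))
  b <- build_basis(cells[c("x", "y")], k = 25)
  expect_equal(qr(b$X)$rank, ncol(b$X))
})

test_that("occupancy fit recovers pooled, saturated and smooth truths", {
  # intercept-only: pooled proportion
  cells <- data.frame(cell_id = 1:2, x = c(0, 1), y = 0,
                      N = c(10L, 10L), n_p = c(3L, 7L))
  fit <- fit_occupancy(cells, k = NULL)
  expect_equal(unname(plogis(fit$fitted_link)), c(0.5, 0.5),
               tolerance = 1e-8)
  # saturation: n_p = N everywhere drives theta to 1
  cells$n_p <- cells$N
  fit1 <- suppressWarnings(fit_occupancy(cells, k = NULL))
  expect_gt(min(plogis(fit1$fitted_link)), 0.999)
  # degenerate all-zero fit is flagged
  cells$n_p <- 0L
  expect_warning(fit0 <- fit_occupancy(cells, k = NULL), "degenerate")
  expect_lt(max(plogis(fit0$fitted_link)), 1e-3)
  # smooth logistic-bump truth on a 30x30 grid, N = 70 per cell
  sim <- simulate_cells(seed = 31)
  fit2 <- fit_occupancy(sim, k = 250)
  expect_gte(cor(plogis(fit2$fitted_link), sim$theta_true), 0.9)
  expect_true(all(plogis(fit2$fitted_link) > 0 &
                    plogis(fit2$fitted_link) < 1))
})

test_that("occupancy fit predicts cells excluded from the likelihood", {
  sim <- simulate_cells(seed = 32)
  sim$N[1:30] <- 0L; sim$n_p[1:30] <- 0L
  fit <- fit_occupancy(sim, k = 100)
  expect_equal(length(fit$fitted_link), nrow(sim))
  expect_true(all(is.finite(fit$fitted_link)))
})

test_that("potential fit matches constant data and the PWLS closed form", {
  # constant data: m = log(c), zero residual variance
  cells <- data.frame(cell_id = 1:12, x = rep(1:4, 3), y = rep(1:3, each = 4),
                      n_p = c(3L, 8L, 5L, 9L, 2L, 7L, 4L, 6L, 3L, 5L, 8L, 2L),
                      Ybar_p = 50)
  fit <- fit_potential(cells, k = NULL)
  expect_equal(unname(fit$fitted_link), rep(log(50), 12), tolerance = 1e-10)
  expect_lt(fit$sig2, 1e-10)
  # closed-form penalized weighted least squares at fixed sp
  sim <- small_cells()
  sp_fix <- 0.5
  pot <- fit_potential(sim, k = 16, sp = sp_fix)
  X <- predict(pot$model, newdata = pot$model$model, type = "lpmatrix")
  obs <- sim[sim$n_p >= 1 & !is.na(sim$Ybar_p), ]
  beta_cf <- solve(t(X) %*% (obs$n_p * X) + total_penalty(pot$model, sp_fix),
                   t(X) %*% (obs$n_p * log(obs$Ybar_p)))
  expect_lt(max(abs(beta_cf - pot$beta)), 1e-8)
})

test_that("binomial fit solves the penalized IRLS fixed point", {
  sim <- small_cells()
  sp_fix <- 1
  occ <- fit_occupancy(sim, k = 16, sp = sp_fix)
  X <- predict(occ$model, newdata = occ$model$model, type = "lpmatrix")
  obs <- sim[sim$N > 0, ]
  eta <- as.numeric(X %*% occ$beta)
  mu <- plogis(eta)
  W <- obs$N * mu * (1 - mu)
  z <- eta + (obs$n_p / obs$N - mu) / (mu * (1 - mu))
  beta_new <- solve(t(X) %*% (W * X) + total_penalty(occ$model, sp_fix),
                    t(X) %*% (W * z))
  expect_lt(max(abs(beta_new - occ$beta)), 1e-6)
})

test_that("weight scaling by a constant leaves point estimates unchanged", {
  # rescaling all weights reparameterizes the smoothing parameter
  # (sp -> sp / 70); the selected fit and the per-corner residual
  # variance are unchanged up to optimizer tolerance
  sim <- small_cells()
  a <- fit_potential(sim, k = 16)
  b <- fit_potential(sim, k = 16, scale_weights = 70)
  expect_equal(a$fitted_link, b$fitted_link, tolerance = 1e-4)
  expect_equal(a$sig2, b$sig2, tolerance = 1e-4)
  expect_equal(unname(a$sp / b$sp), 70, tolerance = 0.01)
})

test_that("potential-surface recovery improves with points per cell", {
  rmse <- sapply(c(35, 70, 140), function(N) {
    sim <- simulate_cells(N = N, seed = 77)
    fit <- fit_potential(sim, k = 250)
    sqrt(mean((fit$fitted_link - sim$m_true)^2))
  })
  expect_true(all(diff(rmse) < 0))
})

test_that("field prediction is the occupancy-weighted potential", {
  sim <- small_cells()
  occ <- fit_occupancy(sim, k = 16)
  pot <- fit_potential(sim, k = 16)
  fld <- predict_fields(occ, pot)
  expect_equal(fld$b, fld$theta * exp(fld$m))
  expect_true(all(fld$b >= 0))
  expect_true(all(fld$theta > 0 & fld$theta < 1))
  # mismatched grids refuse to combine
  pot2 <- fit_potential(sim[1:40, ], k = 16)
  expect_error(predict_fields(occ, pot2), "same grid")
})

test_that("end-to-end field recovery on the synthetic truth", {
  sim <- simulate_cells(seed = 41)
  fld <- predict_fields(fit_occupancy(sim, k = 250),
                        fit_potential(sim, k = 250))
  sel <- sim$b_true > 10
  mare <- mean(abs(fld$b[sel] - sim$b_true[sel]) / sim$b_true[sel])
  expect_lt(mare, 0.15)
})

test_that("coefficient draws reproduce the posterior covariance", {
  sim <- small_cells()
  fit <- fit_potential(sim, k = 16)
  d <- draw_coefficients(fit, n_draws = 250, seed = 5)
  expect_equal(dim(d), c(250, length(fit$beta)))
  # reproducibility
  expect_identical(d, draw_coefficients(fit, n_draws = 250, seed = 5))
  # large-sample empirical covariance matches Vb in relative Frobenius norm
  big <- draw_coefficients(fit, n_draws = 1e5, seed = 6)
  emp <- stats::cov(big)
  relF <- norm(emp - fit$Vb, "F") / norm(fit$Vb, "F")
  expect_lt(relF, 0.05)
  # degenerate covariance: all draws collapse to the point estimate
  fit0 <- fit
  fit0$Vb <- matrix(0, length(fit$beta), length(fit$beta))
  d0 <- draw_coefficients(fit0, n_draws = 10, seed = 7)
  expect_equal(d0, matrix(rep(fit$beta, each = 10), nrow = 10),
               ignore_attr = TRUE)
})

test_that("draw adjustment rules clamp anomalous occupancy draws", {
  theta_hat <- c(0.01, 0.5, 0.9995)
  theta_d <- matrix(c(0.06, 0.04,   # cell 1: one draw beyond 5x
                      0.6, 0.4,     # cell 2: untouched
                      0.2, 0.99),   # cell 3
                    nrow = 3, byrow = TRUE)
  m_d <- matrix(log(100), 3, 2)
  # taxon rule: draws above five times the point estimate snap to it
  cube <- combine_and_adjust(theta_d, m_d, theta_hat, total = FALSE)
  expect_equal(cube$theta[1, ], c(0.01, 0.04))
  expect_equal(cube$theta[2, ], c(0.6, 0.4))
  expect_equal(cube$b, cube$theta * exp(cube$m))
  # total rule: cells with point estimate > 0.999 get theta = 1 draws
  cube2 <- combine_and_adjust(theta_d, m_d, theta_hat, total = TRUE)
  expect_equal(cube2$theta[3, ], c(1, 1))
  expect_equal(cube2$theta[1, ], theta_d[1, ])
  expect_error(combine_and_adjust(theta_d[1:2, ], m_d, theta_hat),
               "mismatched")
})

test_that("increasing the smoothing parameter decreases effective df", {
  sim <- small_cells()
  edfs <- sapply(c(0.01, 1, 100, 1e4), function(s)
    fit_potential(sim, k = 16, sp = s)$edf)
  expect_true(all(diff(edfs) < 0))
})

test_that("log-scale smoothing underestimates heavy-tailed raw means", {
  # documented downward bias of the geometric-mean-like log-scale fit:
  # on log-normal data the smoothed total sits below the raw mean
  sim <- simulate_cells(sigma2 = 0.8, seed = 55)
  fld <- predict_fields(fit_occupancy(sim, k = 100),
                        fit_potential(sim, k = 100))
  expect_lt(mean(fld$b), mean(sim$obs))
})

test_that("delta-method variance diagnostic is reported, not fitted", {
  sim <- small_cells()
  pot <- fit_potential(sim, k = 16)
  diag <- potential_variance_diagnostic(pot, sim)
  expect_equal(nrow(diag), sum(sim$n_p >= 1))
  expect_true(all(diag$var_model > 0))
  expect_true(all(is.finite(diag$ratio)))
})
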