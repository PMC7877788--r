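test_that("Morisita estimator matches closed forms and scales in f", {
  expect_equal(morisita_density(c(10, 10)), 1e4 / (100 * pi),
               tolerance = 1e-12)
  expect_equal(morisita_density(c(10, 10), f_design = 0.8),
               0.8 * 1e4 / (100 * pi), tolerance = 1e-12)
  # general m-sector form
  r <- c(8, 11, 14)
  expect_equal(morisita_density(r), 1e4 * 3 * 2 / (pi * sum(r^2)))
  expect_error(morisita_density(c(10, 0)), "> 0")
  expect_error(morisita_density(numeric(0)), "1 to 4")
  expect_error(morisita_density(5), "not identifiable")
  expect_equal(morisita_density(5, f_design = 0.6),
               0.6 * 1e4 / (pi * 25))
})

test_that("Morisita estimator is strictly decreasing in each distance", {
  base <- c(6, 9)
  for (i in 1:2) {
    r2 <- base; r2[i] <- r2[i] + 0.5
    expect_lt(morisita_density(r2), morisita_density(base))
  }
})

test_that("pooled Morisita mean over simulated corners recovers intensity", {
  # marked Poisson forest at 200 stems/ha sampled by the two-sector
  # corner protocol; the pooled mean over ~2000 corners should sit
  # within 5% of truth
  forest <- simulate_forest(lambda = 200, extent = c(0, 4600, 0, 4600),
                            seed = 7)
  corners <- sample_corners(forest, spacing = 100)
  expect_gte(nrow(corners), 2000)
  pts <- standardize_taxa(parse_points(corners, cleaning_config("metric")),
                          example_tables()$taxon)
  est <- point_estimates(pts, unit_correction(),
                         example_tables()$allometry)
  pooled <- mean(est$totals$density_raw, na.rm = TRUE)
  expect_lt(abs(pooled - 200) / 200, 0.05)
})

test_that("size-threshold correction is a guarded multiplication", {
  expect_equal(correct_density_threshold(100, 0.9), 90)
  expect_equal(correct_density_threshold(0, 0.5), 0)
  expect_error(correct_density_threshold(-1, 0.9), ">= 0")
  expect_error(correct_density_threshold(10, 0), "> 0")
})

test_that("size correction estimated from the diameter distribution works", {
  # forest whose dbh distribution puts a known mass above the 20.32 cm
  # threshold: f_size estimated from the distribution, corrected density
  # approximately f_size * raw
  forest <- simulate_forest(lambda = 300, extent = c(0, 2000, 0, 2000),
                            dbh_meanlog = log(28), dbh_sdlog = 0.4,
                            dbh_min = 10, seed = 21)
  f_size <- mean(forest$dbh >= 20.32)
  corners <- sample_corners(forest, spacing = 100)
  pts <- standardize_taxa(parse_points(corners, cleaning_config("metric")),
                          example_tables()$taxon)
  est <- point_estimates(
    pts,
    read_correction_table(data.frame(zone = "Z1",
                                     corner_type = "section", era = "e1",
                                     f_design = 1, f_size = f_size)),
    example_tables()$allometry)
  ratio <- mean(est$totals$density_corrected, na.rm = TRUE) /
    mean(est$totals$density_raw, na.rm = TRUE)
  expect_equal(ratio, f_size, tolerance = 1e-10)
})

test_that("tree biomass follows the log-log allometry", {
  expect_equal(tree_biomass(1, -2, 2.5), exp(-2))
  expect_equal(tree_biomass(20, -2, 2.5), exp(-2 + 2.5 * log(20)))
  expect_equal(round(tree_biomass(20, -2, 2.5), 2), 242.1)
  # monotone in dbh for b1 > 0
  d <- seq(5, 80, by = 5)
  expect_true(all(diff(tree_biomass(d, -2.3, 2.4)) > 0))
  expect_true(is.na(tree_biomass(NA, -2, 2.5)))
})

test_that("basal area is the breast-height disc area", {
  expect_equal(tree_basal_area(30), pi * 0.15^2)
  expect_equal(tree_basal_area(0), 0)
  expect_equal(tree_basal_area(40) / tree_basal_area(20), 4)
})

test_that("point products follow the density-times-tree-value rule", {
  allo <- read_allometry_table(data.frame(
    taxon_std = c("Oak", "Maple"), b0 = c(-2, -2), b1 = c(2.5, 2.5)))
  d <- 1e4 / (100 * pi)  # 31.831 stems/ha
  trees <- data.frame(taxon_std = c("Oak", "Oak"), dbh = c(20, 20))
  pp <- point_products(trees, d, allo)
  expect_equal(pp$total[["biomass"]], d * tree_biomass(20, -2, 2.5) / 1000,
               tolerance = 1e-12)
  expect_equal(round(pp$total[["biomass"]], 3), 7.706)
  expect_equal(pp$by_taxon$taxon, "Oak")
  # two taxa, equal biomass: each taxon gets half
  trees2 <- data.frame(taxon_std = c("Oak", "Maple"), dbh = c(20, 20))
  pp2 <- point_products(trees2, d, allo)
  expect_equal(pp2$by_taxon$biomass, rep(pp2$total[["biomass"]] / 2, 2))
  # zero-tree point
  pp0 <- point_products(trees[0, ], d, allo)
  expect_equal(unname(pp0$total), c(0, 0, 0))
  # missing dbh must have been excluded upstream
  expect_error(point_products(data.frame(taxon_std = "Oak", dbh = NA),
                              d, allo), "missing dbh")
})

test_that("per-taxon values sum to totals and are order-invariant", {
  tabs <- example_tables()
  forest <- simulate_forest(lambda = 250, extent = c(0, 1500, 0, 1500),
                            seed = 5)
  corners <- sample_corners(forest, spacing = 150)
  pts <- standardize_taxa(parse_points(corners, cleaning_config("metric")),
                          tabs$taxon)
  est <- point_estimates(pts, unit_correction(), tabs$allometry)
  for (v in c("density", "basal_area", "biomass")) {
    s <- rowsum(est$by_taxon[[v]], est$by_taxon$point_id)
    m <- match(rownames(s), est$totals$point_id)
    tot <- est$totals[[if (v == "density") "density_raw" else v]][m]
    expect_equal(as.numeric(s), tot, tolerance = 1e-12)
  }
  # permuting tree order at a point leaves products unchanged
  allo <- tabs$allometry
  trees <- data.frame(taxon_std = c("Oak", "Pine", "Maple"),
                      dbh = c(22, 35, 28))
  a <- point_products(trees, 120, allo)
  b <- point_products(trees[c(3, 1, 2), ], 120, allo)
  expect_equal(a$total, b$total)
  expect_equal(a$by_taxon[order(a$by_taxon$taxon), ],
               b$by_taxon[order(b$by_taxon$taxon), ],
               ignore_attr = TRUE)
})

test_that("correction lookup is total and errors on missing keys", {
  tabs <- example_tables()
  f <- lookup_correction(tabs$correction, "Z1", "section", "e1")
  expect_equal(f$f_design, 1.0)
  expect_error(lookup_correction(tabs$correction, "Z9", "section", "e1"),
               "no correction factors")
  expect_error(read_correction_table(data.frame(
    zone = "a", corner_type = "b", era = "c", f_design = -1,
    f_size = 1)), "> 0")
})
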