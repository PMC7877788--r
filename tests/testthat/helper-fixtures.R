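# Shared fixture builders for the test suite. Everything is generated in
# code; nothing is read from disk except the shipped example tables.

example_tables <- function() {
  list(
    taxon = read_taxon_table(
      system.file("extdata", "taxon_translation_example.csv",
                  package = "plsforest")),
    correction = read_correction_table(
      system.file("extdata", "correction_factors_example.csv",
                  package = "plsforest")),
    allometry = read_allometry_table(
      system.file("extdata", "allometry_example.csv",
                  package = "plsforest")))
}

unit_correction <- function() {
  read_correction_table(data.frame(
    zone = "Z1", corner_type = "section", era = "e1",
    f_design = 1, f_size = 1, stringsAsFactors = FALSE))
}

# one small simulated cell dataset reused across smoothing tests
small_cells <- function(nx = 10, ny = 5, seed = 9) {
  simulate_cells(grid = grid_spec(0, 0, 8000, nx, ny), seed = seed)
}

# total penalty matrix of a fitted single-smooth gam at given sp values
total_penalty <- function(model, sp) {
  sm <- model$smooth[[1]]
  p <- length(coef(model))
  S <- matrix(0, p, p)
  idx <- sm$first.para:sm$last.para
  for (j in seq_along(sm$S))
    S[idx, idx] <- S[idx, idx] + sp[j] * sm$S[[j]]
  S
}
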