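# Shared fixtures for the test suite; everything is generated in code.

default_grid <- function() seq(950, 1801, by = 0.5)

# small synthetic population for fast tests
tiny_population <- function(n_cells = 4, seed = 1, ...) {
  sample_population(synthetic_config(n_cells = n_cells, seed = seed, ...))
}

# composition-by-size spec with zero inter-cell chemistry variance:
# identical means in every class, degenerate Dirichlet
flat_composition_by_size <- function() {
  m <- default_composition_by_size()$mid$mean
  list(small = list(mean = m, concentration = Inf),
       mid = list(mean = m, concentration = Inf),
       large = list(mean = m, concentration = Inf))
}

# brute-force sliding quadratic-fit second derivative at interior points;
# independent oracle for the Savitzky-Golay output
sliding_quadratic_d2 <- function(y, grid, window = 35) {
  h <- (window - 1) %/% 2
  n <- length(y)
  vapply((h + 1):(n - h), function(i) {
    idx <- (i - h):(i + h)
    t <- grid[idx] - grid[i]
    fit <- lm.fit(cbind(1, t, t^2), y[idx])
    2 * fit$coefficients[3]
  }, numeric(1))
}

# a hand-built in-memory mask
make_mask <- function(pixels, res_x = 0.1, res_y = 0.1) {
  structure(list(pixels = pixels, res_x = res_x, res_y = res_y),
            class = "optir_mask")
}
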