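test_that("Pearson distance has the documented analytic values", {
  a <- c(1, 2, 3, 5, 4)
  expect_equal(pearson_distance(a, a), 0)
  expect_equal(pearson_distance(a, 2 * a + 3), 0)       # affine invariance
  expect_equal(pearson_distance(1:3, 3:1), 2)           # anticorrelation
  expect_error(pearson_distance(1:3, 1:4), "equal length")
  expect_error(pearson_distance(1:2, 1:2), "at least 3")
  expect_error(pearson_distance(1:5, rep(1, 5)), "constant")
})

test_that("Pearson distances stay in [0, 2] and are affine-invariant", {
  set.seed(11)
  for (i in 1:20) {
    a <- rnorm(50)
    b <- rnorm(50)
    d <- pearson_distance(a, b)
    expect_gte(d, 0)
    expect_lte(d, 2)
    expect_equal(pearson_distance(3 * a + 1, b), d, tolerance = 1e-12)
  }
})

test_that("cell centroid is the pointwise mean of the cell's spectra", {
  g <- seq(1, 10, 0.5)
  set.seed(12)
  m <- matrix(rnorm(6 * length(g)), nrow = 6)
  cell <- new_cell_record("c1", m)
  cen <- cell_centroid(cell, g)
  # direct summation oracle
  oracle <- apply(m, 2, function(col) sum(col) / 6)
  expect_equal(cen$intensity, oracle)
  # six identical spectra -> that spectrum
  same <- new_cell_record("c2", matrix(rep(m[1, ], 6), nrow = 6, byrow = TRUE))
  expect_equal(cell_centroid(same, g)$intensity, m[1, ])
  # x and -x -> zero vector
  pm <- new_cell_record("c3", rbind(m[1, ], -m[1, ]))
  expect_equal(cell_centroid(pm, g)$intensity, rep(0, length(g)))
})

test_that("population centroid averages spectra, not cell centroids", {
  g <- seq(1, 5, 0.5)
  set.seed(13)
  a <- matrix(rnorm(2 * length(g)), nrow = 2)
  b <- matrix(rnorm(3 * length(g)), nrow = 3)  # unbalanced design
  pop <- new_population(g, list(new_cell_record("a", a),
                                new_cell_record("b", b)))
  pc <- population_centroid(pop)
  expect_equal(pc$intensity, colMeans(rbind(a, b)))
  mean_of_centroids <- (colMeans(a) + colMeans(b)) / 2
  expect_false(isTRUE(all.equal(pc$intensity, mean_of_centroids)))
  # balanced design: the two coincide
  pop_b <- new_population(g, list(new_cell_record("a", a),
                                  new_cell_record("b", b[1:2, ])))
  pc_b <- population_centroid(pop_b)
  expect_equal(pc_b$intensity, (colMeans(a) + colMeans(b[1:2, ])) / 2)
})

test_that("intra-cell variability is zero for identical spectra, positive otherwise", {
  g <- seq(1, 20, 0.5)
  base <- sin(g)
  same <- new_cell_record("s", matrix(rep(base, 6), nrow = 6, byrow = TRUE))
  expect_equal(intra_cell_variability(same, g), 0)
  set.seed(14)
  pert <- t(vapply(1:6, function(i) base + rnorm(length(g), sd = 0.1),
                   numeric(length(g))))
  expect_gt(intra_cell_variability(new_cell_record("p", pert), g), 0)
  one <- new_cell_record("o", matrix(base, nrow = 1))
  expect_error(intra_cell_variability(one, g), ">= 2 spectra")
})

test_that("inter-cell variability is zero when a cell matches the population", {
  pop <- tiny_population(n_cells = 5, seed = 15)
  pre <- preprocess_dataset(pop)
  pc <- population_centroid(pre)
  # a synthetic cell whose centroid IS the population centroid
  ghost <- new_cell_record("ghost",
                           rbind(pc$intensity + 1e-3, pc$intensity - 1e-3))
  expect_equal(inter_cell_variability(ghost, pc, pre$grid), 0,
               tolerance = 1e-9)
  v <- variability_table(pre)
  expect_true(all(v$intra >= 0 & v$intra <= 2))
  expect_true(all(v$inter >= 0 & v$inter <= 2))
})

test_that("IQR outlier flags match the linear-interpolation quartile convention", {
  expect_equal(iqr_outliers(rep(1, 5)), rep(FALSE, 5))
  # hand-computed, type-7 quartiles: Q1 = 2, Q3 = 2.75, fences 0.875 / 3.875
  x <- c(1, 2, 2, 2, 3, 50)
  expect_equal(iqr_outliers(x), c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE))
  # symmetric data without extremes
  expect_equal(sum(iqr_outliers(c(1, 2, 3, 4, 5, 6, 7))), 0L)
  expect_error(iqr_outliers(1:3), "at least 4")
})

test_that("variability regression recovers exact and degenerate relations", {
  rec <- data.frame(cell_id = letters[1:5], region = "r",
                    inter = c(0.1, 0.2, 0.3, 0.4, 0.5),
                    intra = c(0.1, 0.2, 0.3, 0.4, 0.5),
                    intra_outlier = FALSE, inter_outlier = FALSE)
  fit <- variability_regression(rec)
  expect_equal(fit$slope, 1)
  expect_equal(fit$intercept, 0, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$n_points, 5L)
  expect_error(variability_regression(rec[1:2, ]), "at least 3")
})

test_that("intra independent of inter gives r_squared near zero", {
  set.seed(16)
  n <- 2000
  rec <- data.frame(cell_id = as.character(1:n), region = "r",
                    inter = runif(n), intra = runif(n),
                    intra_outlier = FALSE, inter_outlier = FALSE)
  expect_lt(variability_regression(rec)$r_squared, 0.01)
})

test_that("excluding an injected high-leverage outlier changes r_squared", {
  set.seed(17)
  n <- 30
  inter <- runif(n, 0.01, 0.05)
  intra <- 0.03 + rnorm(n, sd = 0.005)
  inter[n] <- 0.5
  intra[n] <- 0.5  # one high-leverage point
  rec <- data.frame(cell_id = as.character(1:n), region = "r",
                    inter = inter, intra = intra,
                    intra_outlier = iqr_outliers(intra),
                    inter_outlier = iqr_outliers(inter))
  with_o <- variability_regression(rec, exclude_outliers = FALSE)
  without_o <- variability_regression(rec, exclude_outliers = TRUE)
  expect_lt(without_o$n_points, with_o$n_points)
  expect_gt(abs(with_o$r_squared - without_o$r_squared), 0.1)
  expect_true(0 <= without_o$r_squared && without_o$r_squared <= 1)
})

test_that("cross-region correlation has its analytic fixed points", {
  pop <- tiny_population(n_cells = 6, seed = 18)
  # identical regions -> rho = 1
  same <- cross_region_correlation(pop, c(1350, 1780), c(1350, 1780))
  expect_equal(same$rho, 1)
  x <- cross_region_correlation(pop)
  expect_gte(x$rho, -1)
  expect_lte(x$rho, 1)
  expect_equal(x$n_cells, 6L)
  # matches a brute-force rank-then-correlate oracle
  oracle <- cor(rank(x$dist_a), rank(x$dist_b))
  expect_equal(x$rho, oracle, tolerance = 1e-12)
  # euclidean metric is exposed as the alternative
  xe <- cross_region_correlation(pop, metric = "euclidean")
  expect_true(is.finite(xe$rho))
})
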