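test_that("PCA explains ~100% on rank-1 data and sums to 100% at full rank", {
  g <- seq(1350, 1780, 0.5)
  base <- sin(g / 40)
  set.seed(20)
  cells <- lapply(1:5, function(i) {
    scale <- matrix(runif(4, 0.5, 2), ncol = 1)   # rank-1: scaled copies
    new_cell_record(paste0("c", i), scale %*% rbind(base))
  })
  pop <- new_population(g, cells, mode = "derivative")
  p1 <- pca_spectra(pop, n_components = 3)
  expect_gt(p1$explained_variance_pct[1], 99.999)
  # full-rank explained variances: non-increasing, non-negative, sum 100
  pop2 <- tiny_population(n_cells = 4, seed = 21)
  pre <- preprocess_dataset(pop2)
  pf <- pca_spectra(pre)
  ev <- pf$explained_variance_pct
  expect_true(all(diff(ev) <= 1e-9))
  expect_true(all(ev >= 0))
  expect_equal(sum(ev), 100, tolerance = 1e-9)
  expect_error(pca_spectra(pre, n_components = 1000), "exceeds")
})

test_that("PCA reconstruction recovers the centred data at full rank", {
  pop <- tiny_population(n_cells = 3, seed = 22)
  pre <- preprocess_dataset(pop)
  p <- pca_spectra(pre)
  x <- spectra_matrix(pre)$intensities
  centred <- sweep(x, 2, p$center)
  recon <- p$scores %*% t(p$loadings)
  expect_equal(recon, unname(centred), tolerance = 1e-8,
               ignore_attr = TRUE)
  # loadings unit-norm, sign fixed so the largest element is positive
  expect_equal(unname(sqrt(colSums(p$loadings^2))),
               rep(1, ncol(p$loadings)), tolerance = 1e-9)
  for (j in seq_len(ncol(p$loadings))) {
    i <- which.max(abs(p$loadings[, j]))
    expect_gt(p$loadings[i, j], 0)
  }
})

test_that("PC1 loading weights the TAG and protein carbonyl/amide bands", {
  pop <- sample_population(synthetic_config(seed = 23))
  pre <- preprocess_dataset(pop)
  p <- pca_spectra(pre, n_components = 2)
  l1 <- abs(p$loadings[, 1])
  at <- function(w) l1[which.min(abs(p$grid - w))]
  # the two key bands sit in the top decile of loading magnitude
  thr <- quantile(l1, 0.9)
  expect_gt(at(1748), thr)
  expect_gt(at(1659), thr)
})

test_that("band_ratio applies the offset to both terms", {
  expect_equal(band_ratio(0.25, 0.05), 5)
  expect_equal(band_ratio(-0.02, -0.001, offset = -0.1), -0.12 / -0.101)
  expect_equal(band_ratio(0.37, 0.37, offset = -0.1), 1)
  expect_error(band_ratio(1, 0.1, offset = -0.1), "zero")
  # invariant to common positive scaling at zero offset
  expect_equal(band_ratio(0.3 * 7, 0.1 * 7), band_ratio(0.3, 0.1))
})

test_that("ratio_table emits one tagged record per spectrum in each mode", {
  pop <- sample_population(synthetic_config(seed = 24))
  rs <- ratio_table(pop, "sparse")
  expect_equal(nrow(rs), 240L)
  expect_true(all(rs$mode == "sparse"))
  expect_true(all(rs$offset == 0))
  pre <- preprocess_dataset(pop)
  rb <- ratio_table(pre, "broadband")
  expect_equal(nrow(rb), 240L)
  expect_true(all(rb$offset == -0.1))
  expect_true(all(is.finite(rb$r_tag_ffa)))
  # mode contracts
  expect_error(ratio_table(pop, "broadband"), "preprocessed")
  expect_error(ratio_table(pre, "sparse"), "raw")
})

test_that("a pure-protein spectrum has near-zero lipid ratios in sparse mode", {
  s <- render_spectrum(composition(protein = 1), grid = default_grid())
  sp <- sparse_intensities(s)
  expect_lt(abs(band_ratio(sp["TAG", "raw_intensity"],
                           sp["protein", "raw_intensity"])), 0.1)
  expect_lt(abs(band_ratio(sp["FFA", "raw_intensity"],
                           sp["protein", "raw_intensity"])), 0.1)
})

test_that("per-cell TAG/FFA ratio ranks agree between modes", {
  run <- run_pipeline(synthetic_config(seed = 26), outdir = NULL)
  cm <- compare_modes(run)
  expect_gt(cm$rho, 0)
  expect_lt(cm$p_value, 0.01)
})

test_that("Shapiro-Wilk gate behaves on Gaussian, bimodal and constant input", {
  set.seed(27)
  gauss <- shapiro_wilk_test(rnorm(500))
  expect_gt(gauss$p_value, 0.001)
  expect_true(gauss$statistic > 0 && gauss$statistic <= 1)
  bimodal <- shapiro_wilk_test(c(rnorm(150, -6), rnorm(150, 6)))
  expect_lt(bimodal$p_value, 0.001)
  expect_error(shapiro_wilk_test(rep(1, 10)), "constant")
  expect_error(shapiro_wilk_test(c(1, 2)), "n >= 3")
})

test_that("Kruskal-Wallis matches the hand-computed no-ties example", {
  r <- kruskal_wallis_test(1:9, rep(c("a", "b", "c"), each = 3))
  expect_equal(r$statistic, 7.2)
  expect_equal(r$group_sizes, c(3L, 3L, 3L))
  # all-tied input: H = 0 by the tie convention
  tied <- kruskal_wallis_test(rep(5, 9), rep(c("a", "b", "c"), each = 3))
  expect_equal(tied$statistic, 0)
  expect_equal(tied$p_value, 1)
  expect_error(kruskal_wallis_test(1:5, rep("a", 5)), ">= 2 groups")
  expect_error(
    kruskal_wallis_test(1:4, factor(c("a", "a", "b", "b"),
                                    levels = c("a", "b", "c"))),
    "empty group")
  expect_error(kruskal_wallis_test(1:5, c("a", "b")), "equal length")
})

test_that("Kruskal-Wallis is invariant under strictly monotone transforms", {
  set.seed(28)
  x <- rnorm(60)
  g <- rep(c("a", "b", "c"), 20)
  h0 <- kruskal_wallis_test(x, g)$statistic
  expect_equal(kruskal_wallis_test(exp(x), g)$statistic, h0)
  expect_equal(kruskal_wallis_test(x^3, g)$statistic, h0)
})

test_that("size_group_comparison reports gate, test and medians", {
  pop <- sample_population(synthetic_config(seed = 29))
  rs <- ratio_table(pop, "sparse")
  g <- size_group_comparison(rs)
  expect_s3_class(g$shapiro, "group_test")
  expect_s3_class(g$kruskal, "group_test")
  expect_equal(sum(g$n), 240L)
  expect_equal(length(g$medians), length(g$size_classes))
  one_class <- rs[rs$size_class == rs$size_class[1], ]
  expect_error(size_group_comparison(one_class), "at least 2")
})
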