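#' Pearson distance between two intensity vectors
#'
#' The package's spectral dissimilarity: 1 minus the sample Pearson
#' correlation coefficient, in \[0, 2\]. 0 means identical spectral shape
#' (up to positive affine transformation), 2 perfect anticorrelation.
#'
#' @param a,b Numeric vectors of equal length >= 3; neither constant.
#' @return The Pearson distance.
#' @export
#' @examples
#' pearson_distance(1:5, 2 * (1:5) + 3)  # 0
pearson_distance <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length")
  if (length(a) < 3L) stop("need at least 3 points for a Pearson distance")
  if (sd(a) == 0 || sd(b) == 0) {
    stop("Pearson distance undefined for a constant vector")
  }
  1 - cor(a, b)
}

#' Cell centroid spectrum
#'
#' Pointwise arithmetic mean of one cell's point spectra on the shared
#' grid; the cell's average spectrum.
#'
#' @param cell A `cell_record`.
#' @param grid The population grid the cell lives on.
#' @return An `optir_spectrum`.
#' @export
cell_centroid <- function(cell, grid) {
  if (ncol(cell$intensities) != length(grid)) {
    stop("cell ", cell$cell_id, " is not on the supplied grid")
  }
  new_spectrum(grid, colMeans(cell$intensities), cell_id = cell$cell_id,
               point_id = NA_integer_)
}

#' Population centroid spectrum
#'
#' Pointwise mean over all individual spectra in the dataset (not over
#' cell centroids; with unequal point counts per cell the two differ).
#'
#' @param pop An `optir_population` with at least one spectrum.
#' @return An `optir_spectrum`.
#' @export
population_centroid <- function(pop) {
  if (n_spectra(pop) == 0L) stop("population contains no spectra")
  m <- spectra_matrix(pop)$intensities
  new_spectrum(pop$grid, colMeans(m))
}

#' Intra-cell variability
#'
#' Mean Pearson distance (1-PCC) from each of a cell's point spectra to
#' the cell centroid: the cell's internal chemical heterogeneity, driven
#' in oleaginous yeasts by distinct lipid-body and cytoplasm domains.
#'
#' @param cell A `cell_record` with >= 2 spectra.
#' @param grid The population grid.
#' @return The mean 1-PCC value.
#' @export
intra_cell_variability <- function(cell, grid) {
  if (nrow(cell$intensities) < 2L) {
    stop("cell ", cell$cell_id, " needs >= 2 spectra for intra variability")
  }
  centroid <- cell_centroid(cell, grid)$intensity
  mean(apply(cell$intensities, 1L, pearson_distance, b = centroid))
}

#' Inter-cell variability
#'
#' Pearson distance (1-PCC) between a cell centroid and the population
#' centroid: how far the cell's average chemistry sits from the population
#' average.
#'
#' @param cell A `cell_record`.
#' @param pop_centroid The population centroid spectrum
#'   ([population_centroid()]).
#' @param grid The population grid.
#' @return The 1-PCC value.
#' @export
inter_cell_variability <- function(cell, pop_centroid, grid) {
  pearson_distance(cell_centroid(cell, grid)$intensity,
                   pop_centroid$intensity)
}

#' Flag outliers by the 1.5 x IQR rule
#'
#' Values below Q1 - 1.5 IQR or above Q3 + 1.5 IQR are flagged. Quartiles
#' use the linear-interpolation convention (`stats::quantile` type 7).
#'
#' @param values Numeric vector, length >= 4.
#' @return Logical vector of flags.
#' @export
iqr_outliers <- function(values) {
  if (length(values) < 4L) {
    stop("need at least 4 values to apply the IQR outlier rule")
  }
  q <- quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  values < q[1] - 1.5 * iqr | values > q[2] + 1.5 * iqr
}

#' Per-cell variability table
#'
#' Computes intra- and inter-cell 1-PCC variability for every cell of a
#' preprocessed dataset and flags outliers in each statistic by the
#' 1.5 x IQR rule.
#'
#' @param pop A preprocessed `optir_population`.
#' @return Data frame with `cell_id`, `region`, `intra`, `inter`,
#'   `intra_outlier`, `inter_outlier`.
#' @export
#' @examples
#' pop <- sample_population(synthetic_config(n_cells = 6, seed = 2))
#' v <- variability_table(preprocess_dataset(pop))
variability_table <- function(pop) {
  pc <- population_centroid(pop)
  df <- data.frame(
    cell_id = vapply(pop$cells, function(x) x$cell_id, character(1)),
    region = pop$region,
    intra = vapply(pop$cells, intra_cell_variability, numeric(1),
                   grid = pop$grid),
    inter = vapply(pop$cells, inter_cell_variability, numeric(1),
                   pop_centroid = pc, grid = pop$grid),
    stringsAsFactors = FALSE
  )
  df$intra_outlier <- iqr_outliers(df$intra)
  df$inter_outlier <- iqr_outliers(df$inter)
  df
}

#' Regression of intra-cell on inter-cell variability
#'
#' Ordinary least squares with intra-cell variability as response and
#' inter-cell variability as predictor, one point per cell; R^2 is the
#' squared Pearson correlation of the two variables. With
#' `exclude_outliers`, cells flagged in either statistic are dropped
#' first.
#'
#' @param records A [variability_table()] data frame.
#' @param exclude_outliers Drop cells flagged in `intra_outlier` or
#'   `inter_outlier`.
#' @return A list: `slope`, `intercept`, `r_squared`, `n_points`,
#'   `outliers_excluded`.
#' @export
variability_regression <- function(records, exclude_outliers = FALSE) {
  df <- records
  if (exclude_outliers) {
    df <- df[!(df$intra_outlier | df$inter_outlier), , drop = FALSE]
  }
  if (nrow(df) < 3L) {
    stop("need at least 3 cells for the variability regression (have ",
         nrow(df), ")")
  }
  fit <- lm(intra ~ inter, data = df)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = cor(df$intra, df$inter)^2, n_points = nrow(df),
       outliers_excluded = exclude_outliers)
}

#' Spearman correlation of per-cell distances between two spectral regions
#'
#' Each region is preprocessed independently; for every cell one distance
#' from its centroid to the population centroid is computed under the
#' chosen metric (Pearson distance, or Euclidean distance between the
#' centroid spectra), and the Spearman rank correlation between the two
#' per-cell distance vectors is returned. This quantifies whether cells
#' that are chemically atypical in one region (e.g. lipids/proteins,
#' 1780-1350 cm^-1) are also atypical in the other (carbohydrates,
#' 1200-1000 cm^-1).
#'
#' @param pop A raw `optir_population`.
#' @param region_a,region_b Analysis intervals `c(low, high)`, cm^-1.
#' @param metric `"pearson_distance"` (default) or `"euclidean"`.
#' @param config Base [preprocess_config()]; its region is overridden.
#' @return A list: `rho`, `n_cells`, `metric`, and the two per-cell
#'   distance vectors.
#' @export
cross_region_correlation <- function(pop, region_a = c(1350, 1780),
                                     region_b = c(1000, 1200),
                                     metric = c("pearson_distance",
                                                "euclidean"),
                                     config = preprocess_config()) {
  metric <- match.arg(metric)
  dist_one <- function(region) {
    cfg <- config
    cfg$region <- as.numeric(region)
    pre <- preprocess_dataset(pop, cfg)
    pc <- population_centroid(pre)
    vapply(pre$cells, function(cell) {
      cen <- cell_centroid(cell, pre$grid)$intensity
      if (metric == "pearson_distance") {
        pearson_distance(cen, pc$intensity)
      } else {
        sqrt(sum((cen - pc$intensity)^2))
      }
    }, numeric(1))
  }
  da <- dist_one(region_a)
  db <- dist_one(region_b)
  if (length(da) < 3L) {
    stop("need at least 3 cells for a cross-region correlation")
  }
  list(rho = cor(da, db, method = "spearman"), n_cells = length(da),
       metric = metric, dist_a = da, dist_b = db)
}
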