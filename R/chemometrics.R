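#' PCA of preprocessed spectra
#'
#' Mean-centred principal component analysis of all individual
#' preprocessed spectra (not cell centroids). Loadings are unit-norm and
#' sign-fixed so each loading's largest-magnitude element is positive;
#' scores are flipped consistently, so projecting scores back through the
#' loadings recovers the centred data.
#'
#' @param pop A preprocessed `optir_population`.
#' @param n_components Number of components to keep (default
#'   `min(n_spectra, grid length)`, the full rank).
#' @return A list of class `pca_result`: `scores` (n_spectra x k),
#'   `loadings` (grid length x k), `explained_variance_pct` (length k,
#'   percentages of total variance), `center`, `grid`, `cell_id`,
#'   `point_id`, `size_class`.
#' @export
pca_spectra <- function(pop, n_components = NULL) {
  sm <- spectra_matrix(pop)
  x <- sm$intensities
  full <- min(nrow(x) - 1L, ncol(x))
  if (is.null(n_components)) n_components <- full
  if (n_components > full) {
    stop("n_components (", n_components, ") exceeds the data rank bound (",
         full, ")")
  }
  p <- prcomp(x, center = TRUE, scale. = FALSE)
  ev_all <- 100 * p$sdev^2 / sum(p$sdev^2)
  k <- n_components
  load <- p$rotation[, seq_len(k), drop = FALSE]
  scores <- p$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {  # sign convention
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  cls <- setNames(vapply(pop$cells, function(c) c$size_class, character(1)),
                  vapply(pop$cells, function(c) c$cell_id, character(1)))
  structure(list(scores = scores, loadings = load,
                 explained_variance_pct = ev_all[seq_len(k)],
                 center = p$center, grid = pop$grid,
                 cell_id = sm$cell_id, point_id = sm$point_id,
                 size_class = unname(cls[sm$cell_id])),
            class = "pca_result")
}

#' Offset band ratio
#'
#' Ratio of two band intensities with a common offset added to numerator
#' and denominator before division. For second-derivative broadband data
#' the offset (-0.1 by default in [ratio_table()]) shifts all values away
#' from zero so ratios are well defined; for sparse-mode raw intensities
#' no offset is used.
#'
#' @param numerator,denominator Band intensities.
#' @param offset Offset added to both values (default 0).
#' @return `(numerator + offset) / (denominator + offset)`.
#' @export
#' @examples
#' band_ratio(0.25, 0.05)           # 5
#' band_ratio(-0.02, -0.001, -0.1)  # 1.18812...
band_ratio <- function(numerator, denominator, offset = 0) {
  den <- denominator + offset
  if (any(den == 0)) stop("shifted denominator is zero; ratio undefined")
  (numerator + offset) / den
}

#' Per-spectrum band-ratio table
#'
#' Builds, for every spectrum, the three chemistry proxy ratios from the
#' carbonyl/amide intensities: `r_tag_ffa` = i(1748)/i(1714) (TAG-to-FFA
#' balance), `r_tag_prot` = i(1748)/i(1659) (TAG content) and
#' `r_ffa_prot` = i(1714)/i(1659) (FFA content).
#'
#' Two acquisition modes are supported. `"broadband"` reads the
#' intensities from preprocessed (second-derivative, vector-normalized)
#' spectra and applies an offset of -0.1 to both ratio terms; derivative
#' values are used as they are (negative at absorbance peaks).
#' `"sparse"` emulates four-wavenumber acquisition on raw spectra:
#' intensities at 1748, 1714 and 1659 cm^-1 baseline-referenced against
#' 1800 cm^-1 ([sparse_intensities()]), with no offset.
#'
#' @param pop An `optir_population`: preprocessed for broadband mode
#'   (region covering 1659-1748 cm^-1), raw (grid covering 1800 cm^-1) for
#'   sparse mode.
#' @param mode `"broadband"` or `"sparse"`.
#' @param offset Ratio offset; defaults to -0.1 for broadband, 0 for
#'   sparse.
#' @return Data frame with one row per spectrum: `cell_id`, `point_id`,
#'   `size_class`, the three intensities `i_1748`, `i_1714`, `i_1659`,
#'   the three ratios, `mode` and `offset`.
#' @export
ratio_table <- function(pop, mode = c("broadband", "sparse"),
                        offset = NULL) {
  mode <- match.arg(mode)
  if (mode == "broadband") {
    if (pop$mode != "derivative") {
      stop("broadband mode requires a preprocessed (derivative) dataset")
    }
    if (is.null(offset)) offset <- -0.1
    value_at <- function(spec, w) intensity_at(spec, w)$value
  } else {
    if (pop$mode != "raw") {
      stop("sparse mode requires a raw dataset covering 1800 cm-1")
    }
    if (is.null(offset)) offset <- 0
    value_at <- function(spec, w) {
      intensity_at(spec, w)$value - intensity_at(spec, sparse_reference)$value
    }
  }
  rows <- lapply(pop$cells, function(cell) {
    do.call(rbind, lapply(seq_along(cell$point_ids), function(j) {
      spec <- new_spectrum(pop$grid, cell$intensities[j, ],
                           cell_id = cell$cell_id,
                           point_id = cell$point_ids[j], mode = pop$mode)
      i1748 <- value_at(spec, 1748)
      i1714 <- value_at(spec, 1714)
      i1659 <- value_at(spec, 1659)
      data.frame(cell_id = cell$cell_id, point_id = cell$point_ids[j],
                 size_class = cell$size_class,
                 i_1748 = i1748, i_1714 = i1714, i_1659 = i1659,
                 r_tag_ffa = band_ratio(i1748, i1714, offset),
                 r_tag_prot = band_ratio(i1748, i1659, offset),
                 r_ffa_prot = band_ratio(i1714, i1659, offset),
                 mode = mode, offset = offset, stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Shapiro-Wilk normality gate
#'
#' Thin wrapper around the standard Shapiro-Wilk test, used as the
#' normality gate before choosing the rank-based Kruskal-Wallis test over
#' ANOVA.
#'
#' @param values Numeric vector, 3 <= n <= 5000, not all equal.
#' @return A list of class `group_test`: `statistic` (W), `p_value`,
#'   `n`, `method`.
#' @export
shapiro_wilk_test <- function(values) {
  if (length(values) < 3L) stop("Shapiro-Wilk test needs n >= 3")
  if (sd(values) == 0) {
    stop("Shapiro-Wilk test undefined for constant input")
  }
  t <- shapiro.test(values)
  structure(list(statistic = unname(t$statistic),
                 p_value = t$p.value, n = length(values),
                 method = "shapiro_wilk"),
            class = "group_test")
}

#' Kruskal-Wallis rank test across groups
#'
#' Rank-based k-group location test (the nonparametric alternative to
#' one-way ANOVA), with the standard tie correction and a chi-square
#' p-value on k - 1 degrees of freedom. An all-tied input returns H = 0.
#'
#' @param values Numeric vector.
#' @param groups Group labels, same length; >= 2 nonempty groups.
#' @return A list of class `group_test`: `statistic` (H), `p_value`,
#'   `group_sizes`, `tie_corrected`, `method`.
#' @export
#' @examples
#' kruskal_wallis_test(1:9, rep(c("a", "b", "c"), each = 3))$statistic  # 7.2
kruskal_wallis_test <- function(values, groups) {
  if (length(values) != length(groups)) {
    stop("values and groups must have equal length")
  }
  g <- if (is.factor(groups)) groups else factor(groups)
  sizes <- table(g)
  if (nlevels(g) < 2L) stop("Kruskal-Wallis test needs >= 2 groups")
  if (any(sizes == 0L)) {
    stop("empty group(s): ",
         paste(names(sizes)[sizes == 0L], collapse = ", "))
  }
  if (sd(values) == 0) {  # fully tied: tie correction degenerates; H = 0
    return(structure(list(statistic = 0, p_value = 1,
                          group_sizes = as.integer(sizes),
                          tie_corrected = TRUE,
                          method = "kruskal_wallis"),
                     class = "group_test"))
  }
  t <- kruskal.test(values, g)
  structure(list(statistic = unname(t$statistic), p_value = t$p.value,
                 group_sizes = as.integer(sizes),
                 tie_corrected = anyDuplicated(values) > 0L,
                 method = "kruskal_wallis"),
            class = "group_test")
}

#' Size-stratified comparison of the TAG-to-FFA ratio
#'
#' Runs the Shapiro-Wilk normality gate on the per-spectrum
#' 1748/1714 cm^-1 ratio values, then the Kruskal-Wallis test of the ratio
#' across the small/mid/large size classes, and reports per-class medians
#' and sizes.
#'
#' @param records A [ratio_table()] data frame with >= 2 size classes.
#' @param variable Ratio column to compare (default `"r_tag_ffa"`).
#' @return A list: `shapiro` and `kruskal` (`group_test` objects),
#'   `medians` and `n` per size class, `variable`, `mode`.
#' @export
size_group_comparison <- function(records, variable = "r_tag_ffa") {
  cls <- factor(records$size_class, levels = c("small", "mid", "large"))
  cls <- droplevels(cls)
  if (nlevels(cls) < 2L) {
    stop("need at least 2 size classes for a group comparison")
  }
  x <- records[[variable]]
  list(shapiro = shapiro_wilk_test(x),
       kruskal = kruskal_wallis_test(x, cls),
       medians = tapply(x, cls, median),
       n = as.integer(table(cls)),
       size_classes = levels(cls),
       variable = variable,
       mode = unique(records$mode))
}
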