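#' Full analysis pipeline
#'
#' Drives all stages in order: simulate (or load) a population, compute
#' cell areas and size classes, preprocess both analysis regions, compute
#' the per-cell variability statistics with and without outliers, the
#' cross-region Spearman correlation, the fingerprint-region PCA, and the
#' size-stratified band-ratio chemistry in broadband and sparse modes.
#' All result tables are written as plain CSV/JSON under `outdir`.
#'
#' @param synthetic A [synthetic_config()], or `NULL` together with
#'   `spectra_path` to analyse measured spectra.
#' @param spectra_path Path to a long-format spectra CSV (alternative
#'   input source; exactly one of `synthetic` / `spectra_path`).
#' @param preprocess Base [preprocess_config()]; its region is overridden
#'   per analysis region.
#' @param region_fingerprint,region_carbohydrate The two analysis regions.
#' @param metric Distance metric for the cross-region correlation.
#' @param outdir Output directory, created if needed; `NULL` skips file
#'   output.
#' @param seed Master seed; overrides the synthetic config seed so one
#'   argument reproduces the whole run.
#' @param verbose Print one line per stage.
#' @return A `run_summary` list: counts, per-region variability and
#'   regression summaries, cross-region correlation, PCA explained
#'   variances, group tests per mode, medians per size class, config
#'   echo; plus the underlying tables in `$tables`.
#' @export
#' @examples
#' \donttest{
#' res <- run_pipeline(synthetic_config(seed = 1), outdir = NULL)
#' res$counts
#' }
run_pipeline <- function(synthetic = synthetic_config(),
                         spectra_path = NULL,
                         preprocess = preprocess_config(),
                         region_fingerprint = c(1350, 1780),
                         region_carbohydrate = c(1000, 1200),
                         metric = "pearson_distance",
                         outdir = NULL, seed = NULL, verbose = FALSE) {
  if (is.null(synthetic) == is.null(spectra_path)) {
    stop("exactly one input source required: synthetic config or spectra_path")
  }
  say <- function(...) if (verbose) message(sprintf(...))

  if (!is.null(spectra_path)) {
    if (!file.exists(spectra_path)) {
      stop("input spectra file not found: ", spectra_path)
    }
    pop <- read_spectra_table(spectra_path)
    seed <- if (is.null(seed)) 0L else as.integer(seed)
  } else {
    if (!is.null(seed)) synthetic$seed <- as.integer(seed)
    seed <- synthetic$seed
    pop <- sample_population(synthetic)
  }
  say("population: %d cells, %d spectra", n_cells(pop), n_spectra(pop))

  areas <- area_table(pop)
  size_split <- table(factor(areas$size_class,
                             levels = c("small", "mid", "large")))

  pre_regions <- lapply(
    list(fingerprint = region_fingerprint,
         carbohydrate = region_carbohydrate),
    function(region) {
      cfg <- preprocess
      cfg$region <- as.numeric(region)
      preprocess_dataset(pop, cfg)
    })
  say("preprocessed %d + %d points",
      length(pre_regions$fingerprint$grid),
      length(pre_regions$carbohydrate$grid))

  variability <- lapply(pre_regions, variability_table)
  regressions <- lapply(variability, function(v) {
    list(with_outliers = variability_regression(v, FALSE),
         without_outliers = variability_regression(v, TRUE))
  })
  xreg <- cross_region_correlation(pop, region_fingerprint,
                                   region_carbohydrate, metric = metric,
                                   config = preprocess)
  say("cross-region Spearman rho = %.3f", xreg$rho)

  pca <- pca_spectra(pre_regions$fingerprint,
                     n_components = min(10L, n_spectra(pop) - 1L,
                                        length(pre_regions$fingerprint$grid)))

  ratios <- list(
    broadband = ratio_table(pre_regions$fingerprint, "broadband"),
    sparse = ratio_table(pop, "sparse")
  )
  # size-stratified tests need size classes, i.e. masks (or the simulator)
  have_sizes <- !all(is.na(areas$size_class))
  group_tests <- if (have_sizes) {
    lapply(ratios, size_group_comparison)
  } else {
    say("no size classes available; skipping size-group tests")
    NULL
  }
  if (have_sizes) {
    say("Kruskal-Wallis H: broadband %.2f, sparse %.2f",
        group_tests$broadband$kruskal$statistic,
        group_tests$sparse$kruskal$statistic)
  }

  summary <- list(
    counts = list(cells = n_cells(pop), spectra = n_spectra(pop),
                  per_size_class = as.list(setNames(as.integer(size_split),
                                                    names(size_split)))),
    variability = lapply(variability, function(v) {
      list(region = v$region[1],
           median_intra = median(v$intra), median_inter = median(v$inter),
           n_intra_outliers = sum(v$intra_outlier),
           n_inter_outliers = sum(v$inter_outlier))
    }),
    regressions = regressions,
    cross_region = list(rho = xreg$rho, metric = xreg$metric,
                        n_cells = xreg$n_cells),
    pca_explained_variance_pct = pca$explained_variance_pct,
    group_tests = if (is.null(group_tests)) NULL else
      lapply(group_tests, function(g) {
        list(shapiro_w = g$shapiro$statistic, shapiro_p = g$shapiro$p_value,
             kruskal_h = g$kruskal$statistic, kruskal_p = g$kruskal$p_value,
             medians = as.list(g$medians), n = g$n, mode = g$mode)
      }),
    seed = seed,
    config = if (is.null(spectra_path)) {
      # strip S3 classes (composition etc.) so the echo serializes to JSON
      rapply(unclass(synthetic), unclass, how = "replace")
    } else {
      list(spectra_path = spectra_path)
    },
    version = as.character(utils::packageVersion("optirpop")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )

  result <- structure(
    list(summary = summary,
         tables = list(areas = areas,
                       variability = variability,
                       ratios = ratios,
                       pca = pca),
         population = pop),
    class = "optir_run")

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_spectra_table(pop, file.path(outdir, "spectra.csv"))
    write.csv(areas, file.path(outdir, "areas.csv"), row.names = FALSE)
    for (r in names(variability)) {
      write.csv(variability[[r]],
                file.path(outdir, paste0("variability_", r, ".csv")),
                row.names = FALSE)
    }
    for (m in names(ratios)) {
      write.csv(ratios[[m]],
                file.path(outdir, paste0("ratios_", m, ".csv")),
                row.names = FALSE)
    }
    write.csv(data.frame(wavenumber_cm1 = pca$grid, pca$loadings),
              file.path(outdir, "pca_loadings.csv"), row.names = FALSE)
    write.csv(data.frame(cell_id = pca$cell_id, point_id = pca$point_id,
                         size_class = pca$size_class, pca$scores),
              file.path(outdir, "pca_scores.csv"), row.names = FALSE)
    jsonlite::write_json(summary, file.path(outdir, "run_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    say("results written to %s", outdir)
  }
  result
}

#' Concordance of broadband and sparse acquisition modes
#'
#' Compares the size-chemistry analysis between the preprocessed broadband
#' spectra and the sparse four-wavenumber simulation: Spearman rank
#' correlation (with test) of per-cell mean TAG-to-FFA ratios between the
#' two modes, and agreement of the Kruskal-Wallis significance decision at
#' the chosen level.
#'
#' @param run An `optir_run` from [run_pipeline()] containing both modes.
#' @param alpha Significance level for the decision agreement (default
#'   0.001).
#' @return A list: `rho`, `p_value`, `n_cells`, per-mode Kruskal-Wallis
#'   p-values, `significant` decisions and `decisions_agree`.
#' @export
compare_modes <- function(run, alpha = 0.001) {
  ratios <- run$tables$ratios
  if (is.null(ratios$broadband) || is.null(ratios$sparse)) {
    stop("run does not contain both acquisition modes")
  }
  per_cell <- function(df) {
    tapply(df$r_tag_ffa, df$cell_id, mean)
  }
  a <- per_cell(ratios$broadband)
  b <- per_cell(ratios$sparse)
  b <- b[names(a)]
  ct <- suppressWarnings(cor.test(a, b, method = "spearman"))
  p_bb <- run$summary$group_tests$broadband$kruskal_p
  p_sp <- run$summary$group_tests$sparse$kruskal_p
  sig <- c(broadband = p_bb < alpha, sparse = p_sp < alpha)
  list(rho = unname(ct$estimate), p_value = ct$p.value,
       n_cells = length(a),
       kruskal_p = c(broadband = p_bb, sparse = p_sp),
       significant = sig, alpha = alpha,
       decisions_agree = sig[["broadband"]] == sig[["sparse"]])
}
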