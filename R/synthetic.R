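#' Configuration for the synthetic O-PTIR population generator
#'
#' Encodes the acquisition design (40 cells, six single-point spectra per
#' cell on a 3x2 grid, fingerprint range 1801-950 cm^-1 at 0.5 cm^-1
#' resolution) together with the generative assumptions: a lognormal cell
#' area distribution, size-class-conditional Dirichlet compositions (small
#' cells protein-rich, mid-size cells FFA-rich, large cells TAG-rich), a
#' two-endmember lipid-body/cytoplasm mixing model for intra-cell
#' heterogeneity, a small random quadratic baseline drift, and additive
#' Gaussian noise.
#'
#' @param n_cells Number of cells (default 40).
#' @param points_per_cell Point spectra per cell (default 6, a 3x2 grid).
#' @param grid_start,grid_end,grid_step Wavenumber grid, cm^-1 (defaults
#'   950, 1801, 0.5; stored ascending).
#' @param size_distribution List `meanlog`, `sdlog` for the lognormal cell
#'   area (um^2). Defaults place roughly 20/67/13 % of mass in the
#'   small/mid/large bins.
#' @param composition_by_size Named list (`small`, `mid`, `large`), each
#'   with a `mean` composition and Dirichlet `concentration`
#'   (`Inf` = no inter-cell composition variance).
#' @param domain_mixing List `mean` (population mean lipid-body fraction),
#'   `mean_kappa` (Beta concentration of per-cell means; `Inf` = all cells
#'   share `mean`) and `point_kappa` (Beta concentration of per-point
#'   lipid-body fractions around the cell mean; smaller = more intra-cell
#'   variability).
#' @param noise_sd Additive Gaussian noise sd (absorbance-like units).
#' @param baseline List of ranges (`intercept`, `slope`, `quad`) for the
#'   per-spectrum quadratic drift coefficients, drawn uniformly; the
#'   polynomial is evaluated on the grid rescaled to \[-1, 1\].
#' @param mask_res Microns per pixel of generated masks (isotropic).
#' @param seed Master seed; all stochastic draws derive from it.
#'
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(
    n_cells = 40L,
    points_per_cell = 6L,
    grid_start = 950, grid_end = 1801, grid_step = 0.5,
    size_distribution = list(meanlog = 2.09, sdlog = 0.35),
    composition_by_size = default_composition_by_size(),
    domain_mixing = list(mean = 1 / 3, mean_kappa = 8, point_kappa = 12),
    noise_sd = 0.005,
    baseline = list(intercept = c(-0.03, 0.03), slope = c(-0.02, 0.02),
                    quad = c(-0.01, 0.01)),
    mask_res = 0.1,
    seed = 1L) {
  cfg <- list(n_cells = as.integer(n_cells),
              points_per_cell = as.integer(points_per_cell),
              grid_start = grid_start, grid_end = grid_end,
              grid_step = grid_step,
              size_distribution = size_distribution,
              composition_by_size = composition_by_size,
              domain_mixing = domain_mixing,
              noise_sd = noise_sd, baseline = baseline,
              mask_res = mask_res, seed = as.integer(seed))
  class(cfg) <- "synthetic_config"
  validate_synthetic_config(cfg)
}

validate_synthetic_config <- function(cfg) {
  if (is.na(cfg$n_cells) || cfg$n_cells < 1L) {
    stop("invalid config field n_cells: must be >= 1")
  }
  if (is.na(cfg$points_per_cell) || cfg$points_per_cell < 1L) {
    stop("invalid config field points_per_cell: must be >= 1")
  }
  if (cfg$grid_step <= 0) stop("invalid config field grid_step: must be > 0")
  if (cfg$grid_start >= cfg$grid_end) {
    stop("invalid config field grid_start/grid_end: need grid_start < grid_end")
  }
  if (cfg$noise_sd < 0) stop("invalid config field noise_sd: must be >= 0")
  for (f in c("meanlog", "sdlog")) {
    if (is.null(cfg$size_distribution[[f]])) {
      stop("invalid config field size_distribution: missing ", f)
    }
  }
  for (cls in c("small", "mid", "large")) {
    e <- cfg$composition_by_size[[cls]]
    if (is.null(e)) stop("invalid config field composition_by_size: missing ", cls)
    validate_composition(e$mean)
    if (is.null(e$concentration) || e$concentration <= 0) {
      stop("invalid config field composition_by_size$", cls,
           ": concentration must be > 0")
    }
  }
  dm <- cfg$domain_mixing
  if (is.null(dm$mean) || dm$mean <= 0 || dm$mean >= 1) {
    stop("invalid config field domain_mixing: mean must lie in (0, 1)")
  }
  if (is.null(dm$mean_kappa) || dm$mean_kappa <= 0 ||
      is.null(dm$point_kappa) || dm$point_kappa <= 0) {
    stop("invalid config field domain_mixing: kappa values must be > 0")
  }
  if (cfg$mask_res <= 0) stop("invalid config field mask_res: must be > 0")
  cfg
}

#' Default size-class composition means
#'
#' Mean component fractions conditional on the three size classes, encoding
#' the qualitative size-dependent chemistry the pipeline is designed to
#' detect: small cells protein-dominant with small lipid bodies; mid-size
#' cells with more FFA than TAG; large cells with more TAG than FFA. The
#' numeric values are declared generator defaults, not measured fractions.
#'
#' @return Named list of `mean` composition + Dirichlet `concentration`
#'   per size class.
#' @export
default_composition_by_size <- function() {
  list(
    small = list(mean = composition(TAG = 0.10, FFA = 0.12, protein = 0.45,
                                    carbohydrate = 0.25, phosphate = 0.08),
                 concentration = 150),
    mid = list(mean = composition(TAG = 0.15, FFA = 0.30, protein = 0.25,
                                  carbohydrate = 0.22, phosphate = 0.08),
               concentration = 150),
    large = list(mean = composition(TAG = 0.40, FFA = 0.12, protein = 0.18,
                                    carbohydrate = 0.22, phosphate = 0.08),
                 concentration = 150)
  )
}

# Dirichlet draw around a mean with given concentration; Inf -> the mean
rdirichlet1 <- function(mean, concentration) {
  if (!is.finite(concentration)) return(mean)
  g <- rgamma(length(mean), shape = mean * concentration, rate = 1)
  if (sum(g) == 0) return(mean)
  out <- g / sum(g)
  names(out) <- names(mean)
  out
}

# Beta draw with given mean and concentration kappa; Inf -> the mean
rbeta_mk <- function(n, mean, kappa) {
  if (!is.finite(kappa)) return(rep(mean, n))
  rbeta(n, shape1 = mean * kappa, shape2 = (1 - mean) * kappa)
}

#' Render one synthetic O-PTIR spectrum
#'
#' Forward model: intensity = sum over components of
#' fraction x (sum of band profiles) + quadratic baseline + Gaussian noise.
#'
#' @param composition A [composition()] vector.
#' @param library A band library (see [default_band_library()]).
#' @param grid Uniform, strictly increasing wavenumber grid, cm^-1.
#' @param baseline_coeffs Numeric length 3: intercept, slope and quadratic
#'   coefficient of the drift polynomial on the grid rescaled to \[-1, 1\].
#' @param noise_sd Additive Gaussian noise sd.
#' @param seed Optional seed making the noise draw reproducible.
#'
#' @return An `optir_spectrum` in raw mode.
#' @export
#' @examples
#' s <- render_spectrum(composition(TAG = 1), default_band_library(),
#'                      seq(950, 1801, 0.5))
render_spectrum <- function(composition, library = default_band_library(),
                            grid, baseline_coeffs = c(0, 0, 0),
                            noise_sd = 0, seed = NULL) {
  assert_uniform_grid(grid)
  validate_composition(composition)
  profiles <- component_profiles(library, grid)
  draw <- function() {
    y <- as.numeric(profiles %*% composition[.components])
    y <- y + baseline_poly(grid, baseline_coeffs)
    if (noise_sd > 0) y <- y + rnorm(length(grid), sd = noise_sd)
    y
  }
  y <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  new_spectrum(grid, y, mode = "raw")
}

baseline_poly <- function(grid, coeffs) {
  t <- 2 * (grid - min(grid)) / (max(grid) - min(grid)) - 1
  coeffs[1] + coeffs[2] * t + coeffs[3] * t^2
}

# lipid-body and cytoplasm endmembers for a cell composition; mixing at the
# cell's mean lipid-body fraction reproduces the cell composition (up to
# clipping at zero for strongly protein-dominated cells)
cell_endmembers <- function(comp, mix_mean) {
  lipid <- comp[["TAG"]] + comp[["FFA"]]
  if (lipid > 0.05) {
    lb <- c(TAG = 0.95 * comp[["TAG"]] / lipid,
            FFA = 0.95 * comp[["FFA"]] / lipid,
            protein = 0.02, carbohydrate = 0.02, phosphate = 0.01)
  } else {
    lb <- c(TAG = 0.475, FFA = 0.475, protein = 0.02,
            carbohydrate = 0.02, phosphate = 0.01)
  }
  cyt <- (comp[.components] - mix_mean * lb) / (1 - mix_mean)
  cyt <- pmax(cyt, 0)
  cyt <- cyt / sum(cyt)
  list(lipid_body = lb, cytoplasm = cyt)
}

# render all point spectra of one cell in the current RNG stream
render_cell_points <- function(comp, mix_mean, profiles, grid, cfg) {
  p <- cfg$points_per_cell
  m <- rbeta_mk(p, mix_mean, cfg$domain_mixing$point_kappa)
  em <- cell_endmembers(comp, mix_mean)
  out <- matrix(0, nrow = p, ncol = length(grid))
  for (j in seq_len(p)) {
    cj <- m[j] * em$lipid_body + (1 - m[j]) * em$cytoplasm
    y <- as.numeric(profiles %*% cj[.components])
    bl <- c(runif(1, cfg$baseline$intercept[1], cfg$baseline$intercept[2]),
            runif(1, cfg$baseline$slope[1], cfg$baseline$slope[2]),
            runif(1, cfg$baseline$quad[1], cfg$baseline$quad[2]))
    y <- y + baseline_poly(grid, bl)
    if (cfg$noise_sd > 0) y <- y + rnorm(length(grid), sd = cfg$noise_sd)
    out[j, ] <- y
  }
  list(intensities = out, mixing = m)
}

# build a binary disk mask whose pixel count is exactly n_px
disk_mask <- function(n_px, res) {
  r <- sqrt(n_px / pi)
  side <- max(3L, as.integer(ceiling(2 * r)) + 4L)
  cx <- (side + 1) / 2
  d2 <- outer(seq_len(side), seq_len(side),
              function(i, j) (i - cx)^2 + (j - cx)^2)
  ord <- order(d2)
  px <- matrix(0L, side, side)
  px[ord[seq_len(n_px)]] <- 1L
  structure(list(pixels = px, res_x = res, res_y = res),
            class = "optir_mask")
}

#' Simulate a synthetic yeast population
#'
#' Draws cell areas from the configured lognormal, builds a disk
#' segmentation mask per cell matching the sampled area, classifies cells
#' by area, draws a composition per cell conditional on its size class,
#' and renders the configured number of point spectra per cell as
#' two-endmember mixtures of a nearly pure lipid-body spectrum and a
#' cytoplasm spectrum, with per-point mixing fractions, baseline drift and
#' noise. Fully reproducible under the config seed.
#'
#' @param config A [synthetic_config()].
#' @param library Band library; defaults to [default_band_library()].
#' @return An `optir_population` with provenance (config, seed, ground
#'   truth compositions and mixing fractions).
#' @export
#' @examples
#' pop <- sample_population(synthetic_config(n_cells = 4, seed = 7))
#' n_spectra(pop)
sample_population <- function(config = synthetic_config(),
                              library = default_band_library()) {
  config <- validate_synthetic_config(config)
  grid <- seq(config$grid_start, config$grid_end, by = config$grid_step)
  profiles <- component_profiles(library, grid)
  dm <- config$domain_mixing
  cells <- withr::with_seed(config$seed, {
    areas_target <- rlnorm(config$n_cells,
                           meanlog = config$size_distribution$meanlog,
                           sdlog = config$size_distribution$sdlog)
    lapply(seq_len(config$n_cells), function(i) {
      n_px <- max(1L, as.integer(round(areas_target[i] / config$mask_res^2)))
      mask <- disk_mask(n_px, config$mask_res)
      area <- mask_area(mask)
      cls <- classify_size(area)
      spec <- config$composition_by_size[[cls]]
      comp <- rdirichlet1(spec$mean, spec$concentration)
      mix_mean <- rbeta_mk(1, dm$mean, dm$mean_kappa)
      rc <- render_cell_points(comp, mix_mean, profiles, grid, config)
      cell <- new_cell_record(sprintf("cell_%02d", i), rc$intensities,
                              mask = mask, area = area, size_class = cls)
      cell$composition <- comp
      cell$mixing <- rc$mixing
      cell$mix_mean <- mix_mean
      cell
    })
  })
  new_population(grid, cells, mode = "raw",
                 provenance = list(generator = "sample_population",
                                   config = config, seed = config$seed,
                                   outlier_cells = character(0)))
}

#' Inject compositional outlier cells into a synthetic population
#'
#' Replaces the composition of `n` randomly chosen cells with one displaced
#' towards a near-pure TAG extreme and re-renders their spectra, producing
#' cells whose centroids sit far from the population centroid. Used as a
#' fixture for outlier-detection behaviour of the inter-cell variability
#' statistics.
#'
#' @param pop A synthetic `optir_population` from [sample_population()].
#' @param n Number of cells to displace; must be <= number of cells.
#' @param severity In \[0, 1\]: 0 leaves compositions unchanged, 1 replaces
#'   them with the extreme composition.
#' @param seed Seed for the cell choice and re-rendering.
#' @param library Band library used for re-rendering.
#' @return The modified population; displaced cell ids are recorded in
#'   `provenance$outlier_cells`.
#' @export
inject_outlier_cells <- function(pop, n, severity = 0.9, seed = 1L,
                                 library = default_band_library()) {
  if (n > n_cells(pop)) {
    stop("cannot inject ", n, " outliers into ", n_cells(pop), " cells")
  }
  if (n == 0L) return(pop)
  cfg <- pop$provenance$config
  if (is.null(cfg)) stop("population lacks generator config in provenance")
  extreme <- composition(TAG = 0.85, FFA = 0.02, protein = 0.03,
                         carbohydrate = 0.07, phosphate = 0.03)
  profiles <- component_profiles(library, pop$grid)
  dm <- cfg$domain_mixing
  pop$cells <- withr::with_seed(seed, {
    chosen <- sample(n_cells(pop), n)
    cells <- pop$cells
    for (i in chosen) {
      old <- cells[[i]]$composition
      comp <- (1 - severity) * old[.components] +
        severity * extreme[.components]
      comp <- comp / sum(comp)
      mix_mean <- rbeta_mk(1, dm$mean, dm$mean_kappa)
      rc <- render_cell_points(comp, mix_mean, profiles, pop$grid, cfg)
      cells[[i]]$intensities <- rc$intensities
      cells[[i]]$composition <- comp
      cells[[i]]$mixing <- rc$mixing
      cells[[i]]$mix_mean <- mix_mean
      cells[[i]]$injected_outlier <- TRUE
    }
    attr(cells, "chosen") <- chosen
    cells
  })
  chosen <- attr(pop$cells, "chosen")
  attr(pop$cells, "chosen") <- NULL
  pop$provenance$outlier_cells <-
    vapply(pop$cells[chosen], function(x) x$cell_id, character(1))
  pop
}
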