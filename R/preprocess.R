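#' Preprocessing configuration
#'
#' Parameters of the Savitzky-Golay second-derivative preprocessing chain:
#' derivative first, then truncation to an analysis region, then vector
#' normalization.
#'
#' @param sg_window Savitzky-Golay window size in grid points; odd and
#'   larger than `sg_polyorder` (default 35).
#' @param sg_polyorder Polynomial order of the local fit (default 2).
#' @param sg_derivorder Derivative order (default 2).
#' @param region Closed analysis interval `c(low, high)` in cm^-1. The two
#'   presets used throughout are the lipid/protein fingerprint region
#'   `c(1350, 1780)` and the carbohydrate region `c(1000, 1200)`.
#' @param normalize Apply Euclidean vector normalization (default TRUE).
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(sg_window = 35L, sg_polyorder = 2L,
                              sg_derivorder = 2L, region = c(1350, 1780),
                              normalize = TRUE) {
  sg_window <- as.integer(sg_window)
  if (sg_window %% 2L == 0L || sg_window <= sg_polyorder) {
    stop("sg_window must be odd and greater than sg_polyorder")
  }
  if (length(region) != 2L || region[1] >= region[2]) {
    stop("region must be c(low, high) with low < high")
  }
  structure(list(sg_window = sg_window, sg_polyorder = as.integer(sg_polyorder),
                 sg_derivorder = as.integer(sg_derivorder),
                 region = as.numeric(region), normalize = isTRUE(normalize)),
            class = "preprocess_config")
}

# core SG derivative on an intensity matrix (rows = spectra); returns d^m/dnu^m
sg_derivative_matrix <- function(m, step, window, polyorder, derivorder) {
  if (ncol(m) < window) {
    stop("grid length (", ncol(m), ") shorter than SG window (", window, ")")
  }
  t(apply(m, 1L, function(x) {
    signal::sgolayfilt(x, p = polyorder, n = window, m = derivorder,
                       ts = step)
  }))
}

#' Savitzky-Golay derivative of a spectrum
#'
#' Computes the second derivative (by default) of the intensity with
#' respect to wavenumber by local least-squares polynomial fitting. The
#' output grid is unchanged; values are reported per (cm^-1)^derivorder.
#' The `(sg_window - 1) / 2` points at each end come from one-sided fits
#' and are flagged in `meta$sg_edge_points`; both default analysis regions
#' exclude them on the default acquisition grid.
#'
#' @param spectrum An `optir_spectrum` on a uniform grid.
#' @param config A [preprocess_config()].
#' @return An `optir_spectrum` with `mode = "derivative"`.
#' @export
#' @examples
#' g <- seq(950, 1801, 0.5)
#' s <- new_spectrum(g, (g - 1500)^2)
#' d <- savitzky_golay_derivative(s)
#' d$intensity[500]  # 2, the exact second derivative
savitzky_golay_derivative <- function(spectrum, config = preprocess_config()) {
  step <- assert_uniform_grid(spectrum$wavenumber)
  if (length(spectrum$wavenumber) < config$sg_window) {
    stop("grid length (", length(spectrum$wavenumber),
         ") shorter than SG window (", config$sg_window, ")")
  }
  y <- signal::sgolayfilt(spectrum$intensity, p = config$sg_polyorder,
                          n = config$sg_window, m = config$sg_derivorder,
                          ts = step)
  out <- new_spectrum(spectrum$wavenumber, y,
                      cell_id = spectrum$meta$cell_id,
                      point_id = spectrum$meta$point_id,
                      mode = "derivative", region = spectrum$meta$region)
  out$meta$sg_edge_points <- (config$sg_window - 1L) %/% 2L
  out
}

#' Truncate a spectrum to an analysis region
#'
#' Keeps grid points with `low <= wavenumber <= high` (both endpoints
#' inclusive); no interpolation or reordering.
#'
#' @param spectrum An `optir_spectrum`.
#' @param region Numeric `c(low, high)`, cm^-1.
#' @return The truncated `optir_spectrum`, with a region label attached.
#' @export
truncate_region <- function(spectrum, region) {
  keep <- spectrum$wavenumber >= region[1] - 1e-9 &
    spectrum$wavenumber <= region[2] + 1e-9
  if (!any(keep)) {
    stop("region [", region[1], ", ", region[2],
         "] contains no grid points")
  }
  out <- new_spectrum(spectrum$wavenumber[keep], spectrum$intensity[keep],
                      cell_id = spectrum$meta$cell_id,
                      point_id = spectrum$meta$point_id,
                      mode = spectrum$meta$mode,
                      region = sprintf("%g-%g", region[1], region[2]))
  out
}

#' Vector (Euclidean) normalization
#'
#' Scales the intensity vector to unit Euclidean norm, removing overall
#' intensity-scale effects; direction is preserved.
#'
#' @param spectrum An `optir_spectrum` with at least one nonzero intensity.
#' @return The normalized `optir_spectrum`.
#' @export
vector_normalize <- function(spectrum) {
  nrm <- sqrt(sum(spectrum$intensity^2))
  if (nrm == 0) {
    stop("cannot vector-normalize an all-zero spectrum (",
         spectrum$meta$cell_id, "/", spectrum$meta$point_id, ")")
  }
  spectrum$intensity <- spectrum$intensity / nrm
  spectrum
}

#' Preprocess every spectrum of a population
#'
#' Applies, in this order, the Savitzky-Golay second derivative, region
#' truncation, and (optionally) vector normalization to every spectrum of
#' the dataset.
#'
#' @param pop A raw `optir_population`.
#' @param config A [preprocess_config()].
#' @return A derivative-mode `optir_population` on the truncated grid.
#' @export
#' @examples
#' pop <- sample_population(synthetic_config(n_cells = 2, seed = 1))
#' pre <- preprocess_dataset(pop, preprocess_config(region = c(1350, 1780)))
preprocess_dataset <- function(pop, config = preprocess_config()) {
  step <- assert_uniform_grid(pop$grid)
  keep <- pop$grid >= config$region[1] - 1e-9 &
    pop$grid <= config$region[2] + 1e-9
  if (!any(keep)) {
    stop("region [", config$region[1], ", ", config$region[2],
         "] contains no grid points")
  }
  cells <- lapply(pop$cells, function(cell) {
    d <- tryCatch(
      sg_derivative_matrix(cell$intensities, step, config$sg_window,
                           config$sg_polyorder, config$sg_derivorder),
      error = function(e) stop("cell ", cell$cell_id, ": ",
                               conditionMessage(e), call. = FALSE))
    d <- d[, keep, drop = FALSE]
    if (config$normalize) {
      nrm <- sqrt(rowSums(d^2))
      # relative threshold: a constant input leaves only floating-point
      # residue in the derivative, which must not be normalized into noise
      floor_nrm <- 1e-10 * sqrt(rowSums(cell$intensities^2))
      if (any(nrm <= floor_nrm)) {
        stop("cell ", cell$cell_id,
             ": all-zero derivative spectrum cannot be normalized")
      }
      d <- d / nrm
    }
    cell$intensities <- d
    cell
  })
  new_population(pop$grid[keep], cells, mode = "derivative",
                 region = sprintf("%g-%g", config$region[1],
                                  config$region[2]),
                 provenance = c(pop$provenance,
                                list(preprocess = unclass(config))))
}

#' Intensity at the grid point nearest a target wavenumber
#'
#' No interpolation: the value at the nearest grid point is returned (the
#' 0.5 cm^-1 acquisition grid makes interpolation error negligible). Ties
#' are broken towards the lower wavenumber. Targets farther than one grid
#' step from any grid point are rejected.
#'
#' @param spectrum An `optir_spectrum`.
#' @param target Target wavenumber, cm^-1.
#' @return A list with `value`, `wavenumber` (the resolved grid point) and
#'   `target`.
#' @export
intensity_at <- function(spectrum, target) {
  d <- abs(spectrum$wavenumber - target)
  i <- which.min(d)  # first minimum = lower wavenumber on ties
  step <- spectrum$wavenumber[2] - spectrum$wavenumber[1]
  if (d[i] > step + 1e-9) {
    stop("target wavenumber ", target,
         " lies more than one grid step outside the grid")
  }
  list(value = spectrum$intensity[i], wavenumber = spectrum$wavenumber[i],
       target = target)
}

# wavenumbers of the sparse acquisition design
sparse_wavenumbers <- c(protein = 1659, FFA = 1714, TAG = 1748)
sparse_reference <- 1800

#' Sparse four-wavenumber intensities
#'
#' Emulates sparse-wavenumber acquisition: intensities are read at 1659
#' (protein), 1714 (FFA) and 1748 cm^-1 (TAG), and baseline-referenced by
#' subtracting the intensity at 1800 cm^-1, a wavenumber in the silent
#' spectral region with no significant biological absorbance.
#'
#' @param spectrum An `optir_spectrum` whose grid covers 1659-1800 cm^-1.
#' @return A data frame with one row per target wavenumber: `target`,
#'   `wavenumber` (resolved grid point), `raw_intensity` (baseline
#'   referenced), and the spectrum `mode`.
#' @export
sparse_intensities <- function(spectrum) {
  rng <- range(spectrum$wavenumber)
  if (rng[1] > min(sparse_wavenumbers) || rng[2] < sparse_reference) {
    stop("grid must cover ", min(sparse_wavenumbers), "-", sparse_reference,
         " cm-1 for sparse intensities")
  }
  ref <- intensity_at(spectrum, sparse_reference)
  rows <- lapply(sparse_wavenumbers, function(w) {
    v <- intensity_at(spectrum, w)
    data.frame(target = w, wavenumber = v$wavenumber,
               raw_intensity = v$value - ref$value,
               mode = spectrum$meta$mode, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- names(sparse_wavenumbers)
  out
}
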