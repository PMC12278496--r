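#' Construct a single point spectrum
#'
#' The atomic data object of the package: one wavenumber grid (ascending,
#' uniform, cm^-1) plus one intensity vector, with acquisition metadata.
#'
#' @param wavenumber Numeric vector of wavenumbers in cm^-1, strictly
#'   increasing.
#' @param intensity Numeric vector of intensities (arbitrary units), same
#'   length as `wavenumber`, all finite.
#' @param cell_id,point_id Identifiers carried through the pipeline.
#' @param mode `"raw"` for as-acquired spectra, `"derivative"` after
#'   Savitzky-Golay second-derivative preprocessing.
#' @param region Optional region label (e.g. `"1350-1780"`).
#'
#' @return An object of class `optir_spectrum`: a list with elements
#'   `wavenumber`, `intensity` and `meta`.
#' @export
#' @examples
#' s <- new_spectrum(seq(1000, 1100, 0.5), rnorm(201))
new_spectrum <- function(wavenumber, intensity, cell_id = NA_character_,
                         point_id = NA_integer_, mode = "raw",
                         region = NA_character_) {
  wavenumber <- as.numeric(wavenumber)
  intensity <- as.numeric(intensity)
  if (length(wavenumber) != length(intensity)) {
    stop("wavenumber and intensity must have equal length (",
         length(wavenumber), " vs ", length(intensity), ")")
  }
  if (length(wavenumber) < 2L || any(diff(wavenumber) <= 0)) {
    stop("wavenumber grid must be strictly increasing with >= 2 points")
  }
  if (!all(is.finite(intensity))) {
    stop("non-finite intensity values in spectrum ",
         cell_id, "/", point_id)
  }
  structure(
    list(wavenumber = wavenumber, intensity = intensity,
         meta = list(cell_id = cell_id, point_id = point_id,
                     mode = mode, region = region)),
    class = "optir_spectrum"
  )
}

#' @export
print.optir_spectrum <- function(x, ...) {
  cat(sprintf("<optir_spectrum> %s/%s [%s] %d points, %.1f-%.1f cm-1\n",
              x$meta$cell_id, x$meta$point_id, x$meta$mode,
              length(x$wavenumber), min(x$wavenumber), max(x$wavenumber)))
  invisible(x)
}

# grid uniformity check used by several stages; rel_tol on spacing spread
assert_uniform_grid <- function(wavenumber, rel_tol = 1e-6) {
  d <- diff(wavenumber)
  if (any(d <= 0)) stop("wavenumber grid must be strictly increasing")
  step <- d[1L]
  if (max(abs(d - step)) > rel_tol * step) {
    stop("wavenumber grid is not uniform (spacing varies by more than ",
         "relative tolerance ", rel_tol, ")")
  }
  step
}

#' Construct a cell record
#'
#' Bundles one cell's point spectra (rows of an intensity matrix on the
#' population grid), its segmentation mask, cross-section area and size
#' class.
#'
#' @param cell_id Cell identifier.
#' @param intensities Numeric matrix, one row per measurement point, one
#'   column per grid wavenumber.
#' @param point_ids Identifiers for the rows; defaults to 1..n.
#' @param mask Optional `optir_mask` (see [read_mask()]).
#' @param area Cross-section area in um^2 (from [mask_area()] when a mask
#'   is present).
#' @param size_class One of `"small"`, `"mid"`, `"large"`
#'   (see [classify_size()]).
#'
#' @return An object of class `cell_record`.
#' @export
new_cell_record <- function(cell_id, intensities, point_ids = NULL,
                            mask = NULL, area = NA_real_,
                            size_class = NA_character_) {
  intensities <- as.matrix(intensities)
  if (is.null(point_ids)) point_ids <- seq_len(nrow(intensities))
  if (length(point_ids) != nrow(intensities)) {
    stop("point_ids length must match number of spectra in cell ", cell_id)
  }
  structure(
    list(cell_id = as.character(cell_id), intensities = intensities,
         point_ids = point_ids, mask = mask, area = area,
         size_class = size_class),
    class = "cell_record"
  )
}

#' Construct a population dataset
#'
#' The collection of [new_cell_record()] objects sharing one wavenumber
#' grid, plus provenance (generator config and seed, or source path).
#'
#' @param grid Shared ascending wavenumber grid, cm^-1.
#' @param cells List of `cell_record` objects; every intensity matrix must
#'   have `length(grid)` columns and cell ids must be unique.
#' @param mode `"raw"` or `"derivative"`.
#' @param region Optional region label after truncation.
#' @param provenance List recording how the dataset was produced.
#'
#' @return An object of class `optir_population`.
#' @export
new_population <- function(grid, cells, mode = "raw",
                           region = NA_character_, provenance = list()) {
  grid <- as.numeric(grid)
  if (any(diff(grid) <= 0)) stop("population grid must be strictly increasing")
  ids <- vapply(cells, function(x) x$cell_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate cell ids: ", paste(unique(ids[duplicated(ids)]),
                                       collapse = ", "))
  }
  ok <- vapply(cells, function(x) ncol(x$intensities) == length(grid),
               logical(1))
  if (!all(ok)) {
    stop("cells not on the shared grid: ", paste(ids[!ok], collapse = ", "))
  }
  structure(
    list(grid = grid, cells = cells, mode = mode, region = region,
         provenance = provenance),
    class = "optir_population"
  )
}

#' @export
print.optir_population <- function(x, ...) {
  cat(sprintf(
    "<optir_population> %d cells, %d spectra [%s], grid %.1f-%.1f cm-1 (%d pts)\n",
    n_cells(x), n_spectra(x), x$mode, min(x$grid), max(x$grid),
    length(x$grid)))
  invisible(x)
}

#' Count cells / spectra in a population
#' @param pop An `optir_population`.
#' @return Integer count.
#' @export
n_cells <- function(pop) length(pop$cells)

#' @rdname n_cells
#' @export
n_spectra <- function(pop) {
  sum(vapply(pop$cells, function(x) nrow(x$intensities), integer(1)))
}

#' Stack all spectra of a population into one matrix
#'
#' @param pop An `optir_population`.
#' @return A list with `intensities` (n_spectra x n_grid matrix), and
#'   `cell_id` / `point_id` vectors indexing its rows.
#' @export
spectra_matrix <- function(pop) {
  mats <- lapply(pop$cells, function(x) x$intensities)
  m <- do.call(rbind, mats)
  list(
    intensities = m,
    cell_id = rep(vapply(pop$cells, function(x) x$cell_id, character(1)),
                  vapply(pop$cells, function(x) nrow(x$intensities),
                         integer(1))),
    point_id = unlist(lapply(pop$cells, function(x) x$point_ids),
                      use.names = FALSE)
  )
}

#' Extract one spectrum from a population
#'
#' @param pop An `optir_population`.
#' @param cell_id Cell identifier.
#' @param point_id Point identifier within the cell.
#' @return An `optir_spectrum`.
#' @export
get_spectrum <- function(pop, cell_id, point_id) {
  idx <- match(as.character(cell_id),
               vapply(pop$cells, function(x) x$cell_id, character(1)))
  if (is.na(idx)) stop("unknown cell id: ", cell_id)
  cell <- pop$cells[[idx]]
  p <- match(point_id, cell$point_ids)
  if (is.na(p)) stop("unknown point id ", point_id, " in cell ", cell_id)
  new_spectrum(pop$grid, cell$intensities[p, ], cell_id = cell$cell_id,
               point_id = point_id, mode = pop$mode, region = pop$region)
}
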