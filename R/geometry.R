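#' Cell cross-section area from a segmentation mask
#'
#' Area is the count of nonzero mask pixels multiplied by the spatial
#' resolution in X and Y (micrometers per pixel).
#'
#' @param mask An `optir_mask`: list with `pixels` (binary matrix) and
#'   `res_x`, `res_y` in um/px.
#' @return Area in um^2.
#' @export
#' @examples
#' m <- structure(list(pixels = matrix(1, 10, 10), res_x = 0.1, res_y = 0.1),
#'                class = "optir_mask")
#' mask_area(m)  # 1 um^2
mask_area <- function(mask) {
  n_px <- sum(mask$pixels != 0)
  if (n_px == 0L) stop("mask has no nonzero pixels; area undefined")
  n_px * mask$res_x * mask$res_y
}

#' Assign the three-bin size class from a cell area
#'
#' Cells with cross-section area below 6 um^2 are small, within 6-12 um^2
#' mid-size, and above 12 um^2 large. The boundaries 6 and 12 um^2 belong
#' to the mid class.
#'
#' @param area Cell area in um^2; must be > 0. Vectorised.
#' @return Character vector: `"small"`, `"mid"` or `"large"`.
#' @export
#' @examples
#' classify_size(c(5.99, 6, 12, 12.01))
classify_size <- function(area) {
  if (any(area <= 0)) stop("area must be > 0")
  ifelse(area < 6, "small", ifelse(area <= 12, "mid", "large"))
}

#' Per-cell area table
#'
#' @param pop An `optir_population` whose cells carry masks or areas.
#' @return Data frame with `cell_id`, `area_um2`, `size_class`.
#' @export
area_table <- function(pop) {
  data.frame(
    cell_id = vapply(pop$cells, function(x) x$cell_id, character(1)),
    area_um2 = vapply(pop$cells, function(x) x$area, numeric(1)),
    size_class = vapply(pop$cells, function(x) x$size_class, character(1)),
    stringsAsFactors = FALSE
  )
}
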