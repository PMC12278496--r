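#' Read a long-format spectra table
#'
#' The canonical on-disk format is a tidy CSV with columns `cell_id`,
#' `point_id`, `wavenumber_cm1`, `intensity`; one complete wavenumber grid
#' per (cell_id, point_id) pair. Rows may appear in any order; the reader
#' canonicalises to cells sorted by id, points sorted by id, wavenumbers
#' ascending, so shuffled files yield identical datasets.
#'
#' @param path Path to the CSV file.
#' @return An `optir_population` (masks and areas absent).
#' @export
read_spectra_table <- function(path) {
  if (!file.exists(path)) stop("spectra table not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  needed <- c("cell_id", "point_id", "wavenumber_cm1", "intensity")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("spectra table is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  if (nrow(df) == 0L) {
    return(new_population(grid = c(0, 1), cells = list(),
                          provenance = list(source = path)))
  }
  bad <- which(!is.finite(df$intensity))
  if (length(bad)) {
    stop("non-finite intensity at row(s): ",
         paste(head(bad, 5L), collapse = ", "))
  }
  key <- interaction(df$cell_id, df$point_id, drop = TRUE, sep = "/")
  grids <- split(df$wavenumber_cm1, key)
  grids <- lapply(grids, sort)
  ref <- grids[[1L]]
  same <- vapply(grids, function(g) {
    length(g) == length(ref) && all(g == ref)
  }, logical(1))
  if (!all(same)) {
    stop("inconsistent wavenumber grids for spectra: ",
         paste(names(grids)[!same], collapse = ", "))
  }
  if (any(duplicated(ref))) {
    stop("duplicated wavenumbers within a spectrum in ", path)
  }
  cells <- lapply(sort(unique(df$cell_id)), function(cid) {
    sub <- df[df$cell_id == cid, ]
    pids <- sort(unique(sub$point_id))
    m <- t(vapply(pids, function(pid) {
      s <- sub[sub$point_id == pid, ]
      s$intensity[order(s$wavenumber_cm1)]
    }, numeric(length(ref))))
    new_cell_record(cid, m, point_ids = pids)
  })
  new_population(ref, cells, mode = "raw",
                 provenance = list(source = path))
}

#' Write a population as a long-format spectra table
#'
#' Inverse of [read_spectra_table()]; intensities are written with 17
#' significant digits so the round trip is exact in double precision.
#'
#' @param pop An `optir_population`.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_spectra_table <- function(pop, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("cell_id,point_id,wavenumber_cm1,intensity", con)
  for (cell in pop$cells) {
    for (j in seq_along(cell$point_ids)) {
      lines <- sprintf("%s,%s,%s,%s",
                       cell$cell_id, cell$point_ids[j],
                       formatC(pop$grid, digits = 17, format = "g"),
                       formatC(cell$intensities[j, ], digits = 17,
                               format = "g"))
      writeLines(lines, con)
    }
  }
  invisible(path)
}

#' Read a segmentation mask (8-bit PNG + JSON sidecar)
#'
#' Any nonzero pixel belongs to the cell; the sidecar supplies the spatial
#' resolution as `{"res_x_um_per_px": rx, "res_y_um_per_px": ry}`.
#'
#' @param path_png Path to the grayscale PNG mask.
#' @param path_sidecar Path to the JSON sidecar; defaults to the PNG path
#'   with a `.json` extension.
#' @return An `optir_mask`: list with binary `pixels`, `res_x`, `res_y`.
#' @export
read_mask <- function(path_png,
                      path_sidecar = sub("\\.png$", ".json", path_png)) {
  if (!file.exists(path_png)) stop("mask PNG not found: ", path_png)
  if (!file.exists(path_sidecar)) {
    stop("mask sidecar not found: ", path_sidecar)
  }
  meta <- jsonlite::read_json(path_sidecar)
  rx <- meta$res_x_um_per_px
  ry <- meta$res_y_um_per_px
  if (is.null(rx) || is.null(ry) || rx <= 0 || ry <= 0) {
    stop("sidecar must provide positive res_x_um_per_px and res_y_um_per_px")
  }
  img <- png::readPNG(path_png)
  if (length(dim(img)) == 3L) img <- img[, , 1L]  # collapse channels
  structure(list(pixels = (img != 0) * 1L,
                 res_x = as.numeric(rx), res_y = as.numeric(ry)),
            class = "optir_mask")
}

#' Write a segmentation mask (8-bit PNG + JSON sidecar)
#'
#' @param mask An `optir_mask`.
#' @param path_png Output PNG path; sidecar written alongside with a
#'   `.json` extension.
#' @return The PNG path, invisibly.
#' @export
write_mask <- function(mask, path_png) {
  png::writePNG((mask$pixels != 0) * 1, path_png)
  jsonlite::write_json(
    list(res_x_um_per_px = mask$res_x, res_y_um_per_px = mask$res_y),
    sub("\\.png$", ".json", path_png), auto_unbox = TRUE, digits = NA)
  invisible(path_png)
}
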