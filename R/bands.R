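#' Spectral band descriptors and the default yeast band library
#'
#' The synthetic generator builds spectra as linear mixtures of component
#' spectra, each component being a sum of vibrational bands. A band is a
#' peak profile parameterised by centre (cm^-1), full width at half maximum
#' (cm^-1), peak amplitude and line shape (gaussian, lorentzian, or a
#' pseudo-Voigt mixture with weight `eta` on the Lorentzian part).
#'
#' @param center Band centre, cm^-1.
#' @param fwhm Full width at half maximum, cm^-1; must be > 0.
#' @param amplitude Peak height in absorbance-like units; must be >= 0.
#' @param shape One of `"gaussian"`, `"lorentzian"`, `"pseudo_voigt"`.
#' @param eta Lorentzian weight for `pseudo_voigt`, in \[0, 1\].
#' @return A one-row data frame describing the band.
#' @export
#' @examples
#' band(1748, 20, 1.0)
band <- function(center, fwhm, amplitude, shape = "pseudo_voigt",
                 eta = 0.5) {
  shape <- match.arg(shape, c("gaussian", "lorentzian", "pseudo_voigt"))
  if (fwhm <= 0) stop("band fwhm must be > 0")
  if (amplitude < 0) stop("band amplitude must be >= 0")
  if (shape == "pseudo_voigt" && (eta < 0 || eta > 1)) {
    stop("pseudo_voigt eta must lie in [0, 1]")
  }
  data.frame(center = center, fwhm = fwhm, amplitude = amplitude,
             shape = shape, eta = eta, stringsAsFactors = FALSE)
}

# component names used everywhere in the generator
.components <- c("TAG", "FFA", "protein", "carbohydrate", "phosphate")

#' Default band library for oleaginous yeast O-PTIR spectra
#'
#' Band positions follow the assignments for lipid-accumulating yeast
#' biomass in the 1801-950 cm^-1 fingerprint region: the TAG ester carbonyl
#' at 1748 cm^-1 with CH deformations at 1463/1377 cm^-1; the FFA
#' carboxylic-acid carbonyl at 1714 cm^-1 with the C-OH deformation at
#' 1413 cm^-1; protein Amide I (1659 cm^-1) and Amide II (1547 cm^-1);
#' cell-wall carbohydrate C-O/C-C modes confined to 1200-1000 cm^-1; and a
#' phosphate P=O stretch near 1245 cm^-1. No component has a band inside
#' the silent window around 1800 cm^-1, which downstream analyses use as a
#' baseline reference.
#'
#' @return A named list (one entry per component: TAG, FFA, protein,
#'   carbohydrate, phosphate), each a data frame of [band()] rows.
#' @export
#' @examples
#' lib <- default_band_library()
#' lib$TAG
default_band_library <- function() {
  list(
    TAG = rbind(
      band(1748, 20, 1.00),
      band(1463, 18, 0.30),
      band(1377, 16, 0.35)
    ),
    FFA = rbind(
      band(1714, 22, 1.00),
      band(1463, 18, 0.20),
      band(1413, 16, 0.30)
    ),
    protein = rbind(
      band(1659, 24, 1.00),
      band(1547, 24, 0.65),
      band(1453, 20, 0.15)
    ),
    carbohydrate = rbind(
      band(1150, 40, 0.55),
      band(1078, 40, 1.00),
      band(1032, 40, 0.70)
    ),
    phosphate = rbind(
      band(1245, 28, 0.60),
      band(1085, 35, 0.40)
    )
  )
}

# validate a band library: components, invariants, silent window
validate_band_library <- function(library) {
  if (!all(.components %in% names(library))) {
    stop("band library must contain components: ",
         paste(.components, collapse = ", "))
  }
  for (comp in names(library)) {
    b <- library[[comp]]
    if (any(b$fwhm <= 0) || any(b$amplitude < 0)) {
      stop("invalid band parameters for component ", comp)
    }
    if (any(b$center >= 1790 & b$center <= 1810)) {
      stop("component ", comp,
           " has a band centre inside the silent window 1790-1810 cm-1")
    }
  }
  invisible(library)
}

#' Construct a composition vector
#'
#' Fractions of the five modelled components (TAG, FFA, protein,
#' carbohydrate, phosphate); non-negative and summing to 1.
#'
#' @param TAG,FFA,protein,carbohydrate,phosphate Component fractions.
#' @return A named numeric vector of class `composition`.
#' @export
#' @examples
#' composition(TAG = 0.4, FFA = 0.12, protein = 0.18,
#'             carbohydrate = 0.22, phosphate = 0.08)
composition <- function(TAG = 0, FFA = 0, protein = 0, carbohydrate = 0,
                        phosphate = 0) {
  x <- c(TAG = TAG, FFA = FFA, protein = protein,
         carbohydrate = carbohydrate, phosphate = phosphate)
  validate_composition(x)
  structure(x, class = "composition")
}

validate_composition <- function(x) {
  if (!all(.components %in% names(x))) {
    stop("composition must name components: ",
         paste(.components, collapse = ", "))
  }
  if (any(x < 0)) stop("composition fractions must be non-negative")
  if (abs(sum(x) - 1) > 1e-9) {
    stop("composition fractions must sum to 1 (got ", sum(x), ")")
  }
  invisible(x)
}

# peak-normalized line profiles; amplitude is the peak height
band_profile <- function(b, grid) {
  u <- (grid - b$center) / b$fwhm
  gauss <- exp(-4 * log(2) * u^2)
  loren <- 1 / (1 + 4 * u^2)
  prof <- switch(b$shape,
                 gaussian = gauss,
                 lorentzian = loren,
                 pseudo_voigt = b$eta * loren + (1 - b$eta) * gauss)
  b$amplitude * prof
}

# n_grid x n_components matrix of pure-component spectra
component_profiles <- function(library, grid) {
  validate_band_library(library)
  sapply(.components, function(comp) {
    b <- library[[comp]]
    if (nrow(b) == 0L) return(numeric(length(grid)))
    rowSums(sapply(seq_len(nrow(b)), function(i) band_profile(b[i, ], grid)))
  })
}
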