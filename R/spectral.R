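#' Wavelength grid
#'
#' A regular wavelength grid on which all spectra in a modelling session live.
#' The default (300--700 nm at 1 nm, 401 points) covers the visible range used
#' for shallow-water fish visual modelling.
#'
#' @param start,stop grid limits in nm (`start < stop`).
#' @param step grid spacing in nm (> 0).
#' @return An object of class `wl_grid`.
#' @examples
#' g <- wl_grid()
#' length(wavelengths(g))  # 401
#' @export
wl_grid <- function(start = 300, stop = 700, step = 1) {
  if (!(is.numeric(start) && is.numeric(stop) && is.numeric(step))) {
    stop("wavelength grid limits must be numeric")
  }
  if (start >= stop) stop("grid start must be below stop")
  if (step <= 0) stop("grid step must be positive")
  structure(list(start = start, stop = stop, step = step), class = "wl_grid")
}

#' @rdname wl_grid
#' @param grid a `wl_grid`.
#' @export
wavelengths <- function(grid) {
  stopifnot(inherits(grid, "wl_grid"))
  seq(grid$start, grid$stop, by = grid$step)
}

#' @export
print.wl_grid <- function(x, ...) {
  cat(sprintf("wavelength grid: %g-%g nm, step %g nm (%d points)\n",
              x$start, x$stop, x$step, length(wavelengths(x))))
  invisible(x)
}

grids_equal <- function(a, b) {
  isTRUE(all.equal(unclass(a)[c("start", "stop", "step")],
                   unclass(b)[c("start", "stop", "step")]))
}

#' Spectrum object
#'
#' A spectrum is a non-negative function sampled on a [wl_grid()]: a surface
#' reflectance (values in \[0, 1\]), an illuminant (relative spectral power),
#' or a receptor sensitivity.
#'
#' @param values numeric vector, one value per grid point, all >= 0.
#' @param grid a [wl_grid()].
#' @param kind one of `"reflectance"`, `"illuminant"`, `"sensitivity"`.
#' @param name optional label.
#' @return An object of class `camo_spectrum`.
#' @export
make_spectrum <- function(values, grid = wl_grid(),
                          kind = c("reflectance", "illuminant", "sensitivity"),
                          name = "") {
  kind <- match.arg(kind)
  stopifnot(inherits(grid, "wl_grid"))
  wl <- wavelengths(grid)
  if (length(values) != length(wl)) {
    stop(sprintf("spectrum has %d values but the grid has %d points",
                 length(values), length(wl)))
  }
  if (anyNA(values) || any(values < 0)) stop("spectrum values must be non-negative")
  if (kind == "reflectance" && any(values > 1 + 1e-9)) {
    stop("reflectance values must not exceed 1")
  }
  structure(list(grid = grid, values = as.numeric(values), kind = kind, name = name),
            class = "camo_spectrum")
}

#' @export
print.camo_spectrum <- function(x, ...) {
  cat(sprintf("%s spectrum%s on %g-%g nm (max %.4g)\n", x$kind,
              if (nzchar(x$name)) paste0(" '", x$name, "'") else "",
              x$grid$start, x$grid$stop, max(x$values)))
  invisible(x)
}

#' Visual pigment sensitivity template
#'
#' Builds a visual pigment absorbance curve from its peak wavelength using the
#' Govardovskii et al. (2000) A1 alpha-band template, the standard nomogram for
#' fish visual pigments. The beta (ultraviolet shoulder) band is off by
#' default; it is negligible above ~430 nm for the peaks used here.
#'
#' @param lambda_max peak wavelength in nm (330--600 supported).
#' @param grid a [wl_grid()].
#' @param beta_band if `TRUE`, add the beta-band shoulder and renormalise to a
#'   unit peak.
#' @return A sensitivity `camo_spectrum` with its maximum within one grid step
#'   of `lambda_max` and a peak value within 2\% of 1.
#' @references Govardovskii VI, Fyhrquist N, Reuter T, Kuzmin DG, Donner K
#'   (2000). In search of the visual pigment template. Visual Neuroscience 17,
#'   509-528.
#' @export
pigment_template <- function(lambda_max, grid = wl_grid(), beta_band = FALSE) {
  if (!is.numeric(lambda_max) || length(lambda_max) != 1 || is.na(lambda_max)) {
    stop("lambda_max must be a single number")
  }
  if (lambda_max < 330 || lambda_max > 600) {
    stop("lambda_max outside the supported 330-600 nm range")
  }
  wl <- wavelengths(grid)
  x <- lambda_max / wl
  A <- 69.7; B <- 28; b <- 0.922; C <- -14.9; cc <- 1.104; D <- 0.674
  a <- 0.8795 + 0.0459 * exp(-(lambda_max - 300)^2 / 11940)
  alpha <- 1 / (exp(A * (a - x)) + exp(B * (b - x)) + exp(C * (cc - x)) + D)
  s <- alpha
  if (beta_band) {
    lmb <- 189 + 0.315 * lambda_max
    bb <- -40.5 + 0.195 * lambda_max
    beta <- 0.26 * exp(-((wl - lmb) / bb)^2)
    s <- alpha + beta
    s <- s / max(s)
  }
  make_spectrum(pmin(s, 1.5), grid, kind = "sensitivity",
                name = sprintf("pigment %g nm", lambda_max))
}

#' Observer visual systems
#'
#' Constructs the visual system of one of the study observers: the dichromatic
#' scorpionfish *Scorpaena porcus* (cones peaking at 455 and 530 nm, 1:1 cone
#' ratio, luminance carried by the long-wavelength cone) or the trichromatic
#' prey fish *Tripterygion delaisi* (468, 517, 530 nm, cone ratio 0.25:1:1,
#' luminance defined as the mean catch of the two longer-wavelength cones).
#' Both use a Weber fraction of 0.05 anchored on the most abundant cone class.
#' *S. maderensis* vision is not described; the *S. porcus* preset stands in
#' for scorpionfish generally.
#'
#' @param preset `"scorpaena_porcus"` or `"tripterygion_delaisi"`.
#' @return An object of class `visual_system` with fields `name`, `peaks`
#'   (nm, ascending), `abundances`, `weber_fraction` and `luminance_def`
#'   (receptor indices averaged for the luminance channel).
#' @export
visual_system <- function(preset = c("scorpaena_porcus", "tripterygion_delaisi")) {
  if (length(preset) != 1 || !preset %in% c("scorpaena_porcus", "tripterygion_delaisi")) {
    stop("unknown visual system preset: ", paste(preset, collapse = ", "))
  }
  vs <- switch(preset,
    scorpaena_porcus = list(
      name = "scorpaena_porcus",
      peaks = c(455, 530),
      abundances = c(1, 1),
      weber_fraction = 0.05,
      luminance_def = 2L
    ),
    tripterygion_delaisi = list(
      name = "tripterygion_delaisi",
      peaks = c(468, 517, 530),
      abundances = c(0.25, 1, 1),
      weber_fraction = 0.05,
      luminance_def = c(2L, 3L)
    )
  )
  validate_visual_system(structure(vs, class = "visual_system"))
}

validate_visual_system <- function(vs) {
  stopifnot(inherits(vs, "visual_system"))
  if (is.unsorted(vs$peaks, strictly = TRUE)) stop("receptor peaks must be strictly ascending")
  if (length(vs$abundances) != length(vs$peaks)) stop("abundances must match receptor count")
  if (any(vs$abundances <= 0)) stop("abundances must be positive")
  if (vs$weber_fraction <= 0) stop("Weber fraction must be positive")
  if (any(vs$luminance_def < 1 | vs$luminance_def > length(vs$peaks))) {
    stop("luminance definition indexes a receptor that does not exist")
  }
  vs
}

#' @export
print.visual_system <- function(x, ...) {
  cat(sprintf("visual system '%s': %d receptors at %s nm, ratio %s, Weber %.3g\n",
              x$name, length(x$peaks), paste(x$peaks, collapse = "/"),
              paste(x$abundances, collapse = ":"), x$weber_fraction))
  invisible(x)
}

#' @rdname visual_system
#' @param vs a `visual_system`.
#' @param grid a [wl_grid()].
#' @param beta_band passed to [pigment_template()].
#' @return `receptor_sensitivities()`: a list of sensitivity spectra, one per
#'   receptor.
#' @export
receptor_sensitivities <- function(vs, grid = wl_grid(), beta_band = FALSE) {
  lapply(vs$peaks, pigment_template, grid = grid, beta_band = beta_band)
}

#' Load an illuminant spectrum
#'
#' Loads an illuminant either from a built-in tabulation or from a two-column
#' CSV file (`wavelength_nm,value`, ascending wavelengths), resamples it to the
#' working grid by linear interpolation, and normalises it to a unit maximum.
#' The package ships the CIE D65 standard daylight tabulation (the illuminant
#' of the behavioural experiment) and a synthetic depth-attenuated blue-green
#' example emulating light at a few metres depth.
#'
#' @param source `"d65"`, `"depth6m_synthetic"`, or a path to a spectrum CSV.
#' @param grid a [wl_grid()].
#' @return An illuminant `camo_spectrum` with maximum value 1.
#' @export
load_illuminant <- function(source = "d65", grid = wl_grid()) {
  builtin <- c(d65 = "illuminant_d65.csv",
               depth6m_synthetic = "illuminant_depth6m_synthetic.csv")
  path <- if (source %in% names(builtin)) {
    system.file("extdata", builtin[[source]], package = "camochoice", mustWork = TRUE)
  } else if (file.exists(source)) {
    source
  } else {
    stop("unknown illuminant source: ", source)
  }
  tab <- utils::read.csv(path)
  if (ncol(tab) < 2) stop("spectrum file must have two columns (wavelength_nm,value)")
  spectrum_from_table(tab[[1]], tab[[2]], grid, kind = "illuminant",
                      name = source, normalise = TRUE)
}

#' Resample a tabulated spectrum onto a grid
#'
#' @param wl,values tabulated wavelengths (nm, ascending) and values.
#' @param grid target [wl_grid()].
#' @param kind spectrum kind, see [make_spectrum()].
#' @param name label.
#' @param normalise divide by the maximum (used for illuminants).
#' @export
spectrum_from_table <- function(wl, values, grid = wl_grid(),
                                kind = "reflectance", name = "",
                                normalise = FALSE) {
  if (is.unsorted(wl)) stop("tabulated wavelengths must be ascending")
  target <- wavelengths(grid)
  if (min(wl) > min(target) || max(wl) < max(target)) {
    stop(sprintf("spectrum covers %g-%g nm but the grid needs %g-%g nm",
                 min(wl), max(wl), min(target), max(target)))
  }
  v <- stats::approx(wl, values, xout = target)$y
  if (normalise) {
    m <- max(v)
    if (m <= 0) stop("cannot normalise a spectrum with non-positive maximum")
    v <- v / m
  }
  make_spectrum(v, grid, kind = kind, name = name)
}
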