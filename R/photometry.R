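#' Cone catch object
#'
#' Per-receptor quantum catches for one stimulus or region of interest, plus
#' the derived luminance-channel value under the observer's luminance
#' definition (a single long-wavelength cone for the scorpionfish observer,
#' the mean of the two longer-wavelength cones for the triplefin observer).
#'
#' @param catches positive numeric vector, one quantum catch per receptor.
#' @param observer a [visual_system()].
#' @param label stimulus label.
#' @return An object of class `cone_catch` with fields `catches`, `luminance`,
#'   `observer` (the preset name) and `label`.
#' @export
cone_catch <- function(catches, observer, label = "") {
  stopifnot(inherits(observer, "visual_system"))
  catches <- as.numeric(catches)
  if (length(catches) != length(observer$peaks)) {
    stop(sprintf("%d catches supplied for a %d-receptor observer",
                 length(catches), length(observer$peaks)))
  }
  if (anyNA(catches) || any(catches < 0)) stop("quantum catches must be non-negative")
  structure(list(catches = catches,
                 luminance = luminance_from_catches(catches, observer),
                 observer = observer$name, label = label),
            class = "cone_catch")
}

#' @export
print.cone_catch <- function(x, ...) {
  cat(sprintf("cone catch%s [%s]: Q = %s, L = %.4g\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              x$observer, paste(signif(x$catches, 4), collapse = ", "),
              x$luminance))
  invisible(x)
}

luminance_from_catches <- function(catches, observer) {
  idx <- observer$luminance_def
  if (any(idx < 1 | idx > length(catches))) {
    stop("luminance definition indexes a receptor that does not exist")
  }
  mean(catches[idx])
}

#' Luminance channel of a cone catch
#'
#' @param catch a [cone_catch()].
#' @param observer the [visual_system()] whose luminance definition applies.
#' @return The luminance-channel value: a single receptor's catch, or the
#'   arithmetic mean of the named receptors.
#' @export
luminance <- function(catch, observer) {
  stopifnot(inherits(catch, "cone_catch"), inherits(observer, "visual_system"))
  if (length(catch$catches) != length(observer$peaks)) {
    stop("catch does not match the observer's receptor count")
  }
  luminance_from_catches(catch$catches, observer)
}

#' Quantum catch of a reflectance under an illuminant
#'
#' Computes per-receptor quantum catches
#' \deqn{Q_i = \sum_\lambda R(\lambda)\, I(\lambda)\, S_i(\lambda)\, \Delta\lambda}
#' for an observer, together with its luminance channel. This is the direct
#' spectral route; image data goes through [normalize_to_standard()] and
#' [fit_channel_to_cone_map()] instead.
#'
#' @param reflectance a reflectance `camo_spectrum`.
#' @param illuminant an illuminant `camo_spectrum` on the same grid.
#' @param observer a [visual_system()].
#' @param sensitivities optional precomputed [receptor_sensitivities()] (saves
#'   rebuilding templates in tight loops).
#' @param label stimulus label.
#' @return A [cone_catch()].
#' @export
quantum_catch <- function(reflectance, illuminant, observer,
                          sensitivities = NULL, label = "") {
  stopifnot(inherits(reflectance, "camo_spectrum"),
            inherits(illuminant, "camo_spectrum"),
            inherits(observer, "visual_system"))
  if (!grids_equal(reflectance$grid, illuminant$grid)) {
    stop("reflectance and illuminant are on different wavelength grids")
  }
  if (is.null(sensitivities)) {
    sensitivities <- receptor_sensitivities(observer, reflectance$grid)
  }
  dl <- reflectance$grid$step
  q <- vapply(sensitivities, function(s) {
    if (!grids_equal(s$grid, reflectance$grid)) {
      stop("sensitivity spectrum is on a different wavelength grid")
    }
    sum(reflectance$values * illuminant$values * s$values) * dl
  }, numeric(1))
  cone_catch(q, observer, label = label)
}

#' ROI measurement record
#'
#' One region-of-interest measurement from a calibrated photo: per-channel
#' mean values over the masked pixels.
#'
#' @param photo_id photo identifier.
#' @param label substrate type or patch name.
#' @param channel_means positive per-channel means.
#' @param n_pixels number of pixels averaged (>= 1).
#' @export
roi_measurement <- function(photo_id, label, channel_means, n_pixels = 1L) {
  channel_means <- as.numeric(channel_means)
  if (anyNA(channel_means) || any(channel_means <= 0)) {
    stop("channel means must be positive")
  }
  if (n_pixels < 1) stop("an ROI must contain at least one pixel")
  structure(list(photo_id = as.character(photo_id), label = as.character(label),
                 channel_means = channel_means, n_pixels = as.integer(n_pixels)),
            class = "roi_measurement")
}

#' Grey standard
#'
#' A grey standard of known nominal reflectance photographed with the scene,
#' used for von Kries style normalisation. Two standards (e.g. 12\% and 72\%)
#' enable a two-point linear calibration.
#'
#' @param nominal_reflectance fraction in (0, 1), e.g. 0.09.
#' @param measured_values positive per-channel measured values.
#' @export
grey_standard <- function(nominal_reflectance, measured_values) {
  if (nominal_reflectance <= 0 || nominal_reflectance >= 1) {
    stop("nominal reflectance must lie strictly between 0 and 1")
  }
  measured_values <- as.numeric(measured_values)
  if (anyNA(measured_values) || any(measured_values <= 0)) {
    stop("grey standard measurements must be positive")
  }
  structure(list(nominal_reflectance = nominal_reflectance,
                 measured_values = measured_values),
            class = "grey_standard")
}

#' Normalise an ROI measurement with grey standards
#'
#' With a single standard, each channel is rescaled by the ratio rule
#' `value * nominal / standard`, mapping the standard onto its nominal
#' reflectance (grey-standard normalisation). With two standards a two-point
#' linear fit through both is used per channel, absorbing any additive offset.
#'
#' @param measurement an [roi_measurement()].
#' @param standard a [grey_standard()], or a list of two for the two-point fit.
#' @return An [roi_measurement()] whose channel values are reflectance
#'   estimates.
#' @export
normalize_to_standard <- function(measurement, standard) {
  stopifnot(inherits(measurement, "roi_measurement"))
  standards <- if (inherits(standard, "grey_standard")) list(standard) else standard
  if (!all(vapply(standards, inherits, logical(1), "grey_standard"))) {
    stop("standard must be a grey_standard or a list of grey_standards")
  }
  k <- length(measurement$channel_means)
  for (s in standards) {
    if (length(s$measured_values) != k) {
      stop("grey standard channel count does not match the measurement")
    }
  }
  refl <- if (length(standards) == 1) {
    s <- standards[[1]]
    measurement$channel_means / s$measured_values * s$nominal_reflectance
  } else if (length(standards) == 2) {
    s1 <- standards[[1]]; s2 <- standards[[2]]
    if (abs(s1$nominal_reflectance - s2$nominal_reflectance) < 1e-12) {
      stop("two-point calibration needs standards of different reflectance")
    }
    vapply(seq_len(k), function(ch) {
      slope <- (s2$nominal_reflectance - s1$nominal_reflectance) /
        (s2$measured_values[ch] - s1$measured_values[ch])
      s1$nominal_reflectance + slope * (measurement$channel_means[ch] - s1$measured_values[ch])
    }, numeric(1))
  } else {
    stop("at most two grey standards are supported")
  }
  if (any(refl <= 0)) stop("normalisation produced non-positive reflectance estimates")
  roi_measurement(measurement$photo_id, measurement$label, refl, measurement$n_pixels)
}

#' Mean channel values over a masked region
#'
#' @param image numeric array: `height x width` (one channel) or
#'   `height x width x channels`, linear-encoded.
#' @param mask logical (or 0/1) matrix of the same height/width; `TRUE` pixels
#'   belong to the ROI.
#' @param photo_id,label metadata for the returned record.
#' @return An [roi_measurement()] with per-channel arithmetic means and the
#'   pixel count.
#' @export
roi_mean <- function(image, mask, photo_id = "", label = "") {
  if (is.matrix(image)) image <- array(image, dim = c(dim(image), 1L))
  if (length(dim(image)) != 3) stop("image must be a matrix or a 3-d channel stack")
  mask <- mask != 0
  if (!identical(dim(mask), dim(image)[1:2])) {
    stop("mask dimensions do not match the image")
  }
  n <- sum(mask)
  if (n == 0) stop("ROI mask is empty")
  means <- vapply(seq_len(dim(image)[3]),
                  function(ch) mean(image[, , ch][mask]), numeric(1))
  roi_measurement(photo_id, label, means, n)
}

#' Fit a linear camera-channel to cone-catch map
#'
#' Trains a least-squares linear transform from camera-channel catches to
#' observer cone catches over a library of training reflectances, emulating
#' the standard multispectral-image calibration step. Camera catches and
#' observer catches of each training spectrum are computed with
#' [quantum_catch()] under the same illuminant; the map is the ordinary
#' least-squares solution (no intercept; both sides are linear in
#' reflectance).
#'
#' @param training_reflectances list of >= 10 reflectance spectra spanning the
#'   achievable gamut.
#' @param camera_sensitivities list of camera channel sensitivity spectra.
#' @param observer a [visual_system()].
#' @param illuminant an illuminant `camo_spectrum`.
#' @return An object of class `channel_map` with the transform matrix `M`
#'   (receptors x channels), the training root-mean-square relative error
#'   `rmsre`, and the ingredients needed by [apply_channel_map()].
#' @export
fit_channel_to_cone_map <- function(training_reflectances, camera_sensitivities,
                                    observer, illuminant) {
  if (length(training_reflectances) < 10) {
    stop("need at least 10 training spectra to condition the channel map")
  }
  obs_sens <- receptor_sensitivities(observer, illuminant$grid)
  cam_catch <- function(r) {
    vapply(camera_sensitivities,
           function(s) sum(r$values * illuminant$values * s$values) * r$grid$step,
           numeric(1))
  }
  X <- t(vapply(training_reflectances, cam_catch,
                numeric(length(camera_sensitivities))))
  Y <- t(vapply(training_reflectances,
                function(r) quantum_catch(r, illuminant, observer, obs_sens)$catches,
                numeric(length(obs_sens))))
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    stop("training set is rank-deficient: camera catches do not span the channels")
  }
  M <- t(qr.coef(qrx, Y))            # receptors x channels
  pred <- X %*% t(M)
  rel <- (pred - Y) / pmax(Y, .Machine$double.eps)
  structure(list(M = M, rmsre = sqrt(mean(rel^2)), observer = observer,
                 camera_sensitivities = camera_sensitivities,
                 illuminant_name = illuminant$name),
            class = "channel_map")
}

#' @rdname fit_channel_to_cone_map
#' @param map a fitted `channel_map`.
#' @param channel_values camera-channel catch values (e.g. normalised ROI
#'   channel means scaled by the camera's response to the illuminant), one per
#'   camera channel.
#' @param label stimulus label.
#' @return `apply_channel_map()`: a [cone_catch()] for the map's observer.
#' @export
apply_channel_map <- function(map, channel_values, label = "") {
  stopifnot(inherits(map, "channel_map"))
  if (length(channel_values) != ncol(map$M)) {
    stop("channel value count does not match the fitted map")
  }
  cone_catch(pmax(drop(map$M %*% channel_values), 0), map$observer, label = label)
}

#' Read a linear-encoded image file
#'
#' Reads a 16-bit TIFF or PNG as a linear channel stack in \[0, 1\]. No gamma
#' decoding is applied: inputs are declared linear.
#'
#' @param path image file (.tif/.tiff/.png).
#' @return Numeric array `height x width x channels`.
#' @export
read_linear_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) stop("package 'tiff' is required")
    tiff::readTIFF(path)
  } else if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE)) stop("package 'png' is required")
    png::readPNG(path)
  } else {
    stop("unsupported image format: ", ext)
  }
  if (is.matrix(img)) img <- array(img, dim = c(dim(img), 1L))
  img
}
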