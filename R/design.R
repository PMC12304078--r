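#' Grey scale for background design
#'
#' An ordered set of printed grey patches with their luminance (observer
#' quantum catch) under experimental light.
#'
#' @param labels patch labels.
#' @param luminances positive luminances, one per patch.
#' @param source free-text provenance note.
#' @return A `grey_scale` data-frame-like object ordered by luminance.
#' @export
grey_scale <- function(labels, luminances, source = "") {
  if (length(labels) != length(luminances)) stop("labels and luminances differ in length")
  if (length(labels) == 0) stop("grey scale is empty")
  if (any(luminances <= 0)) stop("luminances must be positive")
  o <- order(luminances)
  structure(data.frame(label = as.character(labels)[o],
                       luminance = as.numeric(luminances)[o],
                       stringsAsFactors = FALSE),
            source = source, class = c("grey_scale", "data.frame"))
}

#' Select the medium background grey
#'
#' Chooses the grey patch with the smallest absolute Weber contrast to the
#' medium-grey adapted fish body luminance (the study achieved |contrast|
#' 0.03 on its printed scale). Ties are broken toward the darker patch.
#'
#' @param fish_lum_medium_adapted body luminance of medium-adapted fish (> 0).
#' @param greys a [grey_scale()].
#' @return One-row data frame: `label`, `luminance`, `achieved_contrast`.
#' @export
select_medium <- function(fish_lum_medium_adapted, greys) {
  stopifnot(inherits(greys, "grey_scale"))
  if (fish_lum_medium_adapted <= 0) stop("fish luminance must be positive")
  w <- weber_contrast(greys$luminance, fish_lum_medium_adapted)
  # greys are sorted ascending, so which.min on |w| lands on the darker tie
  i <- which.min(abs(w))
  data.frame(label = greys$label[i], luminance = greys$luminance[i],
             achieved_contrast = w[i], stringsAsFactors = FALSE)
}

#' Select the light and dark background greys
#'
#' Chooses the light background as the patch whose Weber contrast against the
#' light-adapted fish is closest to `+target`, and the dark background as the
#' patch whose contrast against the dark-adapted fish is closest to
#' `-target` (the study used |contrast| 0.33): the light background is
#' lighter than the light-adapted fish, the dark one darker than the
#' dark-adapted fish.
#'
#' @param fish_lum_light_adapted,fish_lum_dark_adapted adapted body
#'   luminances (> 0).
#' @param greys a [grey_scale()].
#' @param target absolute Weber contrast target (default 0.33).
#' @return Two-row data frame (`role` = light/dark) with `label`, `luminance`
#'   and `achieved_contrast`.
#' @export
select_extremes <- function(fish_lum_light_adapted, fish_lum_dark_adapted,
                            greys, target = 0.33) {
  stopifnot(inherits(greys, "grey_scale"))
  if (fish_lum_light_adapted <= 0 || fish_lum_dark_adapted <= 0) {
    stop("fish luminances must be positive")
  }
  w_light <- weber_contrast(greys$luminance, fish_lum_light_adapted)
  w_dark <- weber_contrast(greys$luminance, fish_lum_dark_adapted)
  i_light <- which.min(abs(w_light - target))
  i_dark <- which.min(abs(w_dark + target))
  data.frame(role = c("light", "dark"),
             label = greys$label[c(i_light, i_dark)],
             luminance = greys$luminance[c(i_light, i_dark)],
             achieved_contrast = c(w_light[i_light], w_dark[i_dark]),
             stringsAsFactors = FALSE)
}

#' Starting-zone luminance
#'
#' Luminance of the central starting zone (and acclimation cylinder):
#' intermediate between the two experimental backgrounds of a treatment,
#' taken as the geometric mean (log-spaced, matching the logarithmic
#' luminance coding of the contrast model).
#'
#' @param bg_a_lum,bg_b_lum background luminances (> 0).
#' @return Positive luminance, strictly between the inputs when they differ.
#' @export
starting_zone <- function(bg_a_lum, bg_b_lum) {
  if (any(c(bg_a_lum, bg_b_lum) <= 0)) stop("background luminances must be positive")
  sqrt(bg_a_lum * bg_b_lum)
}

#' Full background design
#'
#' Runs the background-selection procedure: medium grey by minimal |Weber
#' contrast| to the medium-adapted fish, light/dark greys at the +-`target`
#' contrast to the light-/dark-adapted fish, plus the per-treatment
#' starting-zone luminances.
#'
#' @param fish_lums named vector `c(light = , medium = , dark = )` of adapted
#'   body luminances.
#' @param greys a [grey_scale()].
#' @param target extreme-contrast target (default 0.33).
#' @return An object of class `background_design`: `patches` (three-row data
#'   frame), `starting_zones` (per treatment), `target`.
#' @export
design_backgrounds <- function(fish_lums, greys, target = 0.33) {
  stopifnot(all(c("light", "medium", "dark") %in% names(fish_lums)))
  med <- select_medium(fish_lums[["medium"]], greys)
  ext <- select_extremes(fish_lums[["light"]], fish_lums[["dark"]], greys, target)
  patches <- data.frame(
    role = c("dark", "medium", "light"),
    label = c(ext$label[ext$role == "dark"], med$label, ext$label[ext$role == "light"]),
    luminance = c(ext$luminance[ext$role == "dark"], med$luminance,
                  ext$luminance[ext$role == "light"]),
    achieved_contrast = c(ext$achieved_contrast[ext$role == "dark"],
                          med$achieved_contrast,
                          ext$achieved_contrast[ext$role == "light"]),
    stringsAsFactors = FALSE)
  if (!(patches$luminance[1] < patches$luminance[2] &&
        patches$luminance[2] < patches$luminance[3])) {
    stop("design violated dark < medium < light luminance ordering")
  }
  lum <- stats::setNames(patches$luminance, patches$role)
  zones <- c(dark_light = starting_zone(lum["dark"], lum["light"]),
             medium_light = starting_zone(lum["medium"], lum["light"]),
             medium_dark = starting_zone(lum["medium"], lum["dark"]))
  names(zones) <- c("dark_light", "medium_light", "medium_dark")
  structure(list(patches = patches, starting_zones = zones, target = target),
            class = "background_design")
}

#' @export
print.background_design <- function(x, ...) {
  cat("background design (Weber target", x$target, ")\n")
  print(x$patches)
  cat("starting zones:\n")
  print(signif(x$starting_zones, 4))
  invisible(x)
}
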