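#' Achromatic contrast of a bar against its chosen background
#'
#' Mean over the background sample set of the achromatic JND between the bar
#' and each sample (eight 1 cm^2 samples per background in the study design).
#' Averaging per-sample JNDs, rather than contrasting against the pooled mean
#' sample, is the default; set `pool_samples = TRUE` for the alternative.
#'
#' @param bar_luminance luminance-channel catch of the bar (> 0).
#' @param sample_luminances luminances of the background samples (> 0);
#'   expected length 8 unless `n_samples` is overridden.
#' @param observer a [visual_system()] (the prey observer in the study).
#' @param n_samples required sample count (default 8; set `NA` to skip the
#'   check in reduced debug fixtures).
#' @param pool_samples contrast against the mean sample luminance instead of
#'   averaging per-sample contrasts.
#' @return Non-negative mean achromatic contrast in JND.
#' @export
bar_background_contrast <- function(bar_luminance, sample_luminances, observer,
                                    n_samples = 8, pool_samples = FALSE) {
  stopifnot(inherits(observer, "visual_system"))
  if (!is.na(n_samples) && length(sample_luminances) != n_samples) {
    stop(sprintf("expected %d background samples, got %d",
                 n_samples, length(sample_luminances)))
  }
  if (bar_luminance <= 0 || any(sample_luminances <= 0)) {
    stop("luminances must be positive")
  }
  jnd <- abs(log(bar_luminance / sample_luminances)) / observer$weber_fraction
  if (pool_samples) {
    abs(log(bar_luminance / mean(sample_luminances))) / observer$weber_fraction
  } else {
    mean(jnd)
  }
}

#' Internal pattern contrast
#'
#' Achromatic JND between the dark and light bar of one individual's pattern:
#' the estimate of disruptive internal contrast. Symmetric in bar order.
#'
#' @param dark_bar_luminance,light_bar_luminance luminance-channel catches of
#'   the two bars (> 0).
#' @param observer a [visual_system()].
#' @return Non-negative achromatic contrast in JND.
#' @export
internal_contrast <- function(dark_bar_luminance, light_bar_luminance, observer) {
  stopifnot(inherits(observer, "visual_system"))
  if (dark_bar_luminance <= 0 || light_bar_luminance <= 0) {
    stop("bar luminances must be positive")
  }
  abs(log(dark_bar_luminance / light_bar_luminance)) / observer$weber_fraction
}

#' Assemble the pattern analysis dataset
#'
#' Stage 4 data preparation: joins bar measurements to the chosen background
#' of each fish x treatment (from the choice records), drops cases where the
#' light background was chosen (rare in the study and excluded from its
#' models), and computes the three response variables -- luminance channel
#' cone catches per bar, achromatic contrast of each bar against the chosen
#' background, and internal pattern contrast per individual.
#'
#' @param bars data frame with columns `fish_id`, `species`, `treatment`,
#'   `bar` (`dark_bar`/`light_bar`) and `luminance` (prey-observer
#'   luminance-channel catch), one row per fish x treatment x bar.
#' @param samples named list of background sample luminance vectors (8 per
#'   background), names `dark`, `medium`, `light`.
#' @param choices choice records from [score_choices()] supplying
#'   `first_settled` per fish x treatment.
#' @param observer the prey [visual_system()].
#' @return List of two data frames: `bar_level` (rows = retained cases x 2
#'   bars; columns add `background`, `bg_contrast`) and `fish_level` (rows =
#'   retained cases; column `internal_contrast`).
#' @export
pattern_dataset <- function(bars, samples, choices, observer) {
  need <- c("fish_id", "species", "treatment", "bar", "luminance")
  if (!all(need %in% names(bars))) {
    stop("bars must have columns: ", paste(need, collapse = ", "))
  }
  if (!all(c("fish_id", "treatment", "first_settled") %in% names(choices))) {
    stop("choices must come from score_choices()")
  }
  key <- function(d) paste(d$fish_id, d$treatment, sep = "\r")
  settled <- choices[!is.na(choices$first_settled), , drop = FALSE]
  chosen <- stats::setNames(settled$first_settled, key(settled))
  bars$background <- chosen[key(bars)]
  if (anyNA(bars$background)) {
    miss <- unique(key(bars)[is.na(bars$background)])
    stop("no settled choice for ", length(miss), " bar measurement key(s)")
  }
  bars <- bars[bars$background != "light", , drop = FALSE]
  if (!nrow(bars)) stop("no cases left after dropping light-background choices")
  for (bg in unique(bars$background)) {
    if (!bg %in% names(samples)) stop("no sample set for background '", bg, "'")
    if (length(samples[[bg]]) != 8) {
      stop("background '", bg, "' needs exactly 8 samples")
    }
  }
  bars$bg_contrast <- vapply(seq_len(nrow(bars)), function(i) {
    bar_background_contrast(bars$luminance[i], samples[[bars$background[i]]],
                            observer)
  }, numeric(1))

  wide <- merge(
    bars[bars$bar == "dark_bar", c("fish_id", "species", "treatment",
                                   "background", "luminance")],
    bars[bars$bar == "light_bar", c("fish_id", "treatment", "luminance")],
    by = c("fish_id", "treatment"), suffixes = c("_dark", "_light"))
  if (nrow(wide) * 2 != nrow(bars)) {
    stop("each retained fish x treatment case needs exactly one dark and one light bar")
  }
  wide$internal_contrast <- mapply(internal_contrast, wide$luminance_dark,
                                   wide$luminance_light,
                                   MoreArgs = list(observer = observer))
  rownames(bars) <- rownames(wide) <- NULL
  list(bar_level = bars, fish_level = wide)
}

#' Pattern contrast models and response ratios
#'
#' Fits the three Gamma (log link) mixed models of the pattern stage --
#' luminance channel cone catches and achromatic background contrast (species
#' x bar x chosen background fixed effects) and internal pattern contrast
#' (species x chosen background) -- each with fish ID as a random intercept,
#' and extracts the response-ratio effect sizes: per species, each bar metric
#' on the medium vs. the dark chosen background; and between species on each
#' background (for internal contrast). Ratios whose 95\% compatibility
#' interval excludes one are flagged.
#'
#' @param dataset a [pattern_dataset()] result.
#' @param n_draws posterior draws (default 10,000).
#' @param seed integer seed.
#' @return List with `fits` (named `camo_glmm` list), `summaries` (predicted
#'   medians per cell) and `ratios` (data frame of response ratios with CIs
#'   and `excludes_one` flags).
#' @export
pattern_models <- function(dataset, n_draws = 10000, seed = 1) {
  bl <- dataset$bar_level
  fl <- dataset$fish_level
  bl$species <- factor(bl$species); bl$bar <- factor(bl$bar)
  bl$background <- factor(bl$background, levels = c("dark", "medium"))
  fl$species <- factor(fl$species)
  fl$background <- factor(fl$background, levels = c("dark", "medium"))

  fits <- list(); summaries <- list(); ratios <- list()
  bar_specs <- list(luminance = "luminance", bg_contrast = "bg_contrast")
  for (nm in names(bar_specs)) {
    spec <- glmm_spec(bar_specs[[nm]], "gamma_log",
                      ~ species * bar * background, random_group = "fish_id")
    fit <- fit_glmm(bl, spec)
    draws <- posterior_draws(fit, n = n_draws, seed = seed)
    lv <- expand.grid(species = levels(bl$species), bar = levels(bl$bar),
                      background = levels(bl$background),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    summaries[[nm]] <- predict_levels(fit, draws, lv)
    for (sp in levels(bl$species)) {
      for (br in levels(bl$bar)) {
        rr <- response_ratio(
          fit, draws,
          data.frame(species = sp, bar = br, background = "medium"),
          data.frame(species = sp, bar = br, background = "dark"))
        ratios[[length(ratios) + 1]] <- cbind(
          data.frame(response = nm, contrast = "medium_vs_dark",
                     species = sp, bar = br, background = NA), rr)
      }
    }
    fits[[nm]] <- fit
  }

  spec <- glmm_spec("internal_contrast", "gamma_log", ~ species * background,
                    random_group = "fish_id")
  fit <- fit_glmm(fl, spec)
  draws <- posterior_draws(fit, n = n_draws, seed = seed)
  lv <- expand.grid(species = levels(fl$species),
                    background = levels(fl$background),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  summaries$internal_contrast <- predict_levels(fit, draws, lv)
  for (sp in levels(fl$species)) {
    rr <- response_ratio(fit, draws,
                         data.frame(species = sp, background = "medium"),
                         data.frame(species = sp, background = "dark"))
    ratios[[length(ratios) + 1]] <- cbind(
      data.frame(response = "internal_contrast", contrast = "medium_vs_dark",
                 species = sp, bar = NA, background = NA), rr)
  }
  sps <- levels(fl$species)
  if (length(sps) == 2) {
    for (bg in levels(fl$background)) {
      rr <- response_ratio(fit, draws,
                           data.frame(species = sps[2], background = bg),
                           data.frame(species = sps[1], background = bg))
      ratios[[length(ratios) + 1]] <- cbind(
        data.frame(response = "internal_contrast",
                   contrast = paste0(sps[2], "_vs_", sps[1]),
                   species = NA, bar = NA, background = bg), rr)
    }
  }
  fits$internal_contrast <- fit
  ratio_tab <- do.call(rbind, ratios)
  rownames(ratio_tab) <- NULL
  list(fits = fits, summaries = summaries, ratios = ratio_tab)
}
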