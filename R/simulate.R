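with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

default_substrate_params <- function() {
  # per type: flat base reflectance + 1-2 Gaussian spectral bumps
  # (centre nm, width nm, amplitude); brightness separation between types
  # exceeds the photo-to-photo jitter so between-type achromatic contrast
  # dominates within-type contrast
  list(
    rubble_sand = list(base = 0.18, bumps = list(c(600, 80, 0.18))),
    seagrass_leaves = list(base = 0.06, bumps = list(c(550, 40, 0.10), c(680, 30, 0.03))),
    turf_algae = list(base = 0.03, bumps = list(c(560, 50, 0.04))),
    red_sponge = list(base = 0.04, bumps = list(c(620, 35, 0.18))),
    yellow_algae = list(base = 0.05, bumps = list(c(580, 45, 0.16), c(500, 30, 0.04))),
    seagrass_stems = list(base = 0.025, bumps = list(c(570, 60, 0.03)))
  )
}

default_species_params <- function() {
  # medium-adapted bar luminances (prey-observer catch units) and the
  # gain with which each bar tracks the chosen background on the log scale;
  # maderensis shifts both bars and keeps a wide, background-independent
  # internal contrast, porcus shifts mainly its dark bar
  list(
    maderensis = list(bar_lum = c(dark_bar = 0.045, light_bar = 0.175),
                      gain = c(dark_bar = 0.45, light_bar = 0.45)),
    porcus = list(bar_lum = c(dark_bar = 0.08, light_bar = 0.115),
                  gain = c(dark_bar = 0.35, light_bar = 0))
  )
}

#' Simulation configuration
#'
#' Bundles every parameter of the synthetic-data generators. The defaults
#' reproduce the study's structure: six substrate types with 12/9/9/3/5/5
#' photos, 23 *S. maderensis* and 27 *S. porcus* of which five *S. porcus*
#' never settle, three binary choice treatments with expected-success
#' probabilities 0.9 (dark-light), 0.8 (medium-light) and 0.15 (medium-dark),
#' and stop-and-go movement bouts in the ethograms.
#'
#' @param seed integer seed; every generator is deterministic given
#'   (seed, config).
#' @param photo_census named photo counts per substrate type.
#' @param substrate_params per-type spectral parameters (base + bumps), see
#'   source for the shipped defaults.
#' @param brightness_log_sd,chroma_log_sd between-photo lognormal jitter of
#'   overall brightness and of bump amplitudes.
#' @param n_fish named fish counts per species.
#' @param never_settlers named counts of fish per species that never settle
#'   in any treatment (study: five *S. porcus*).
#' @param choice_probabilities named per-treatment probabilities of the
#'   expected-success outcome (same for both species).
#' @param species_params per-species bar luminances and background-response
#'   gains.
#' @param indiv_log_sd,trial_log_sd lognormal SD of individual bar-luminance
#'   variation and of per-trial measurement noise.
#' @param fish_adapted_lums body luminance of light-/medium-/dark-adapted
#'   fish used by the background design stage (synthetic stand-ins for the
#'   study's prior colour-change measurements).
#' @param n_grey_patches,grey_range grey-scale size and luminance range.
#' @param illuminant illuminant source for the substrate library (see
#'   [load_illuminant()]).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       photo_census = c(rubble_sand = 12, seagrass_leaves = 9,
                                        turf_algae = 9, red_sponge = 3,
                                        yellow_algae = 5, seagrass_stems = 5),
                       substrate_params = default_substrate_params(),
                       brightness_log_sd = 0.25, chroma_log_sd = 0.15,
                       n_fish = c(maderensis = 23, porcus = 27),
                       never_settlers = c(maderensis = 0, porcus = 5),
                       choice_probabilities = c(dark_light = 0.9,
                                                medium_light = 0.8,
                                                medium_dark = 0.15),
                       species_params = default_species_params(),
                       indiv_log_sd = 0.10, trial_log_sd = 0.05,
                       fish_adapted_lums = c(light = 0.20, medium = 0.12,
                                             dark = 0.07),
                       n_grey_patches = 64, grey_range = c(0.02, 0.6),
                       illuminant = "depth6m_synthetic") {
  if (any(photo_census < 1)) stop("photo census counts must be >= 1")
  if (!all(names(photo_census) %in% names(substrate_params))) {
    stop("every censused substrate type needs spectral parameters")
  }
  if (any(choice_probabilities < 0 | choice_probabilities > 1)) {
    stop("choice probabilities must lie in [0, 1]")
  }
  if (!all(TREATMENTS %in% names(choice_probabilities))) {
    stop("choice probabilities needed for: ", paste(TREATMENTS, collapse = ", "))
  }
  if (any(n_fish < 1)) stop("fish counts must be >= 1")
  if (any(never_settlers < 0) || any(never_settlers > n_fish[names(never_settlers)])) {
    stop("never-settler counts must lie between 0 and the species' fish count")
  }
  if (any(c(brightness_log_sd, chroma_log_sd, indiv_log_sd, trial_log_sd) < 0)) {
    stop("jitter SDs must be non-negative")
  }
  structure(list(seed = as.integer(seed), photo_census = photo_census,
                 substrate_params = substrate_params,
                 brightness_log_sd = brightness_log_sd,
                 chroma_log_sd = chroma_log_sd, n_fish = n_fish,
                 never_settlers = never_settlers,
                 choice_probabilities = choice_probabilities,
                 species_params = species_params,
                 indiv_log_sd = indiv_log_sd, trial_log_sd = trial_log_sd,
                 fish_adapted_lums = fish_adapted_lums,
                 n_grey_patches = n_grey_patches, grey_range = grey_range,
                 illuminant = illuminant),
            class = "sim_config")
}

gaussian_bump <- function(wl, centre, width, amp) {
  amp * exp(-((wl - centre)^2) / (2 * width^2))
}

#' Generate a synthetic substrate photo library
#'
#' Builds per-type mean reflectance spectra from a flat base plus Gaussian
#' spectral bumps, jitters each photo multiplicatively (lognormal brightness
#' plus independent lognormal bump-amplitude jitter, giving both achromatic
#' and chromatic photo-to-photo variation) and converts every photo to
#' scorpionfish cone catches through the direct spectral route.
#'
#' @param config a [sim_config()].
#' @param grid a [wl_grid()].
#' @return List: `photos` (data frame `photo_id`, `substrate`, `Q1`, `Q2`
#'   for the scorpionfish observer), `spectra` (list of reflectance spectra),
#'   `observer`.
#' @export
gen_substrate_library <- function(config, grid = wl_grid()) {
  stopifnot(inherits(config, "sim_config"))
  observer <- visual_system("scorpaena_porcus")
  illum <- load_illuminant(config$illuminant, grid)
  sens <- receptor_sensitivities(observer, grid)
  wl <- wavelengths(grid)
  with_seed(config$seed, {
    rows <- list(); spectra <- list()
    for (type in names(config$photo_census)) {
      pars <- config$substrate_params[[type]]
      for (i in seq_len(config$photo_census[[type]])) {
        bf <- exp(stats::rnorm(1, 0, config$brightness_log_sd))
        v <- rep(pars$base, length(wl))
        for (bump in pars$bumps) {
          aj <- exp(stats::rnorm(1, 0, config$chroma_log_sd))
          v <- v + gaussian_bump(wl, bump[1], bump[2], bump[3] * aj)
        }
        v <- pmin(v * bf, 1)
        id <- sprintf("%s_%02d", type, i)
        sp <- make_spectrum(v, grid, "reflectance", name = id)
        cc <- quantum_catch(sp, illum, observer, sens, label = id)
        spectra[[id]] <- sp
        rows[[id]] <- data.frame(photo_id = id, substrate = type,
                                 Q1 = cc$catches[1], Q2 = cc$catches[2],
                                 stringsAsFactors = FALSE)
      }
    }
    photos <- do.call(rbind, rows)
    rownames(photos) <- NULL
    list(photos = photos, spectra = spectra, observer = observer)
  })
}

#' Generate a grey scale
#'
#' `n` patches with log-spaced luminances spanning `range` (constant ratio
#' between adjacent patches), labelled `g01 ... gNN` from dark to light.
#'
#' @param n_patches number of patches (>= 2).
#' @param range luminance range `c(min, max)`.
#' @return A [grey_scale()].
#' @export
gen_greyscale <- function(n_patches = 64, range = c(0.02, 0.6)) {
  if (n_patches < 2) stop("a grey scale needs at least 2 patches")
  if (any(range <= 0) || range[1] >= range[2]) stop("invalid luminance range")
  lum <- exp(seq(log(range[1]), log(range[2]), length.out = n_patches))
  grey_scale(sprintf("g%02d", seq_len(n_patches)), lum, source = "synthetic")
}

#' Generate a synthetic fish population
#'
#' Draws per-fish baseline dark- and light-bar luminances (lognormal
#' individual variation around the species means) and exposes the adaptation
#' rule: on a background of luminance L, a bar's expected log-luminance is
#' the convex combination `(1 - gain) * log(baseline) + gain * log(L)`, so
#' gain 0 leaves bars independent of the background and gain 1 moves them
#' fully onto it.
#'
#' @param config a [sim_config()].
#' @return List: `fish` (data frame `fish_id`, `species`, baseline
#'   `dark_bar`/`light_bar` luminances), and `adapted_luminance(fish_row,
#'   bar, background_lum)` closure applying the gain rule (without trial
#'   noise).
#' @export
gen_fish_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 1L, {
    rows <- list()
    for (sp in names(config$n_fish)) {
      pars <- config$species_params[[sp]]
      for (i in seq_len(config$n_fish[[sp]])) {
        rows[[length(rows) + 1]] <- data.frame(
          fish_id = sprintf("%s_%02d", sp, i), species = sp,
          dark_bar = pars$bar_lum[["dark_bar"]] *
            exp(stats::rnorm(1, 0, config$indiv_log_sd)),
          light_bar = pars$bar_lum[["light_bar"]] *
            exp(stats::rnorm(1, 0, config$indiv_log_sd)),
          stringsAsFactors = FALSE)
      }
    }
    fish <- do.call(rbind, rows)
  })
  # keep light bar above dark bar per fish (swap the rare crossed draws)
  crossed <- fish$light_bar <= fish$dark_bar
  if (any(crossed)) {
    tmp <- fish$dark_bar[crossed]
    fish$dark_bar[crossed] <- fish$light_bar[crossed]
    fish$light_bar[crossed] <- tmp
  }
  adapted <- function(fish_row, bar, background_lum) {
    pars <- config$species_params[[fish_row$species]]
    g <- pars$gain[[bar]]
    exp((1 - g) * log(fish_row[[bar]]) + g * log(background_lum))
  }
  list(fish = fish, adapted_luminance = adapted)
}

sim_trial_events <- function(fish_id, species, treatment, intended,
                             never_settler) {
  bgs <- treatment_backgrounds(treatment)
  ev <- list(); t <- 0
  add <- function(state, dur) {
    ev[[length(ev) + 1]] <<- data.frame(
      fish_id = fish_id, species = species, treatment = treatment,
      state = state, start_s = t, duration_s = dur, stringsAsFactors = FALSE)
    t <<- t + dur
  }
  add("moving", stats::runif(1, 5, 25))
  for (k in seq_len(sample(1:3, 1))) {        # stop-and-go decoys (< 5 s)
    add(sample(bgs, 1), stats::runif(1, 1, 4.5))
    add("moving", stats::runif(1, 4, 15))
  }
  if (stats::runif(1) < 0.5) {                # a settled-but-not-chosen bout
    add(sample(bgs, 1), stats::runif(1, 5, 50))
    add("moving", stats::runif(1, 4, 15))
  }
  if (never_settler) {
    add(sample(bgs, 1), stats::runif(1, 5, 45))
    add("moving", stats::runif(1, 10, 30))
  } else {
    add(intended, stats::runif(1, 60, 180))
  }
  do.call(rbind, ev)
}

#' Generate a synthetic choice experiment
#'
#' For every fish x treatment, draws the intended first-settled background
#' (the expected background with the treatment's success probability) and
#' realises it as a 10-minute ethogram event stream containing stop-and-go
#' decoy pauses (< 5 s), optional settled-but-abandoned bouts (< 60 s) and,
#' for settling fish, one qualifying bout of at least 60 s on the intended
#' background. Never-settling fish (a fixed count per species) produce no
#' qualifying bout in any treatment. Scoring the events with the behaviour
#' rules reproduces the intended choices exactly.
#'
#' @param config a [sim_config()].
#' @return List: `events` (ethogram data frame), `intended` (data frame
#'   `fish_id`, `species`, `treatment`, `intended` background, `success`),
#'   `never_settlers` (fish IDs).
#' @export
gen_choice_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  expected <- c(dark_light = "dark", medium_light = "medium",
                medium_dark = "medium")
  with_seed(config$seed + 2L, {
    ev_all <- list(); intend <- list(); never <- character()
    for (sp in names(config$n_fish)) {
      ids <- sprintf("%s_%02d", sp, seq_len(config$n_fish[[sp]]))
      ns <- config$never_settlers[[sp]]
      if (!is.null(ns) && ns > 0) never <- c(never, sample(ids, ns))
      for (id in ids) {
        for (tr in TREATMENTS) {
          p <- config$choice_probabilities[[tr]]
          succ <- stats::rbinom(1, 1, p)
          bgs <- treatment_backgrounds(tr)
          intended <- if (succ == 1) expected[[tr]] else setdiff(bgs, expected[[tr]])
          ev_all[[length(ev_all) + 1]] <-
            sim_trial_events(id, sp, tr, intended, id %in% never)
          intend[[length(intend) + 1]] <- data.frame(
            fish_id = id, species = sp, treatment = tr,
            intended = if (id %in% never) NA_character_ else intended,
            success = if (id %in% never) NA_integer_ else succ,
            stringsAsFactors = FALSE)
        }
      }
    }
    events <- do.call(rbind, ev_all)
    rownames(events) <- NULL
    list(events = events, intended = do.call(rbind, intend),
         never_settlers = never)
  })
}

#' Generate bar measurements after the choice trials
#'
#' Applies the adaptation rule of [gen_fish_population()] to the background
#' each fish actually chose in each treatment (from the scored choices),
#' adds per-trial lognormal measurement noise, and returns prey-observer
#' luminance-channel catches per fish x treatment x bar.
#'
#' @param config a [sim_config()].
#' @param population a [gen_fish_population()] result.
#' @param choices choice records from [score_choices()] (settled trials
#'   only are used).
#' @param background_lums named luminances of the experimental backgrounds
#'   (`dark`, `medium`, `light`), e.g. from [design_backgrounds()].
#' @return Data frame: `fish_id`, `species`, `treatment`, `bar`,
#'   `luminance`.
#' @export
gen_bar_measurements <- function(config, population, choices, background_lums) {
  stopifnot(inherits(config, "sim_config"))
  settled <- choices[!is.na(choices$first_settled), , drop = FALSE]
  with_seed(config$seed + 3L, {
    rows <- list()
    for (i in seq_len(nrow(settled))) {
      fr <- population$fish[population$fish$fish_id == settled$fish_id[i], ]
      if (!nrow(fr)) stop("choice record for unknown fish ", settled$fish_id[i])
      bg <- settled$first_settled[i]
      for (bar in c("dark_bar", "light_bar")) {
        lum <- population$adapted_luminance(fr, bar, background_lums[[bg]]) *
          exp(stats::rnorm(1, 0, config$trial_log_sd))
        rows[[length(rows) + 1]] <- data.frame(
          fish_id = fr$fish_id, species = fr$species,
          treatment = settled$treatment[i], bar = bar, luminance = lum,
          stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Generate background sample luminances
#'
#' Eight 1 cm^2 samples per experimental background: the design luminance
#' with small lognormal print/measurement jitter.
#'
#' @param config a [sim_config()].
#' @param background_lums named background luminances (`dark`, `medium`,
#'   `light`).
#' @param n_samples samples per background (default 8).
#' @param jitter_log_sd lognormal jitter SD (default 0.03).
#' @return Named list of luminance vectors.
#' @export
gen_background_samples <- function(config, background_lums, n_samples = 8,
                                   jitter_log_sd = 0.03) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 4L, {
    out <- lapply(background_lums, function(L) {
      L * exp(stats::rnorm(n_samples, 0, jitter_log_sd))
    })
    names(out) <- names(background_lums)
    out
  })
}
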