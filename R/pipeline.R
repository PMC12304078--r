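pipeline_input <- function(dir, file) {
  path <- file.path(dir, file)
  if (!file.exists(path)) {
    stop(structure(class = c("camochoice_missing_input", "error", "condition"),
                   list(message = paste0("missing pipeline input: ", path),
                        call = sys.call(-1))))
  }
  path
}

write_pipeline_csv <- function(x, dir, file) {
  utils::write.csv(x, file.path(dir, file), row.names = FALSE)
  file
}

#' Run the analysis pipeline
#'
#' Orchestrates the four analysis stages and the simulator over a directory
#' of CSV artefacts:
#' \describe{
#'   \item{simulate}{writes the full synthetic fixture set: substrate photo
#'     catches, grey scale, ethogram events, bar measurements and background
#'     samples.}
#'   \item{substrate-contrast}{pairwise substrate JNDs and the two Gamma
#'     contrast models.}
#'   \item{design}{background grey selection by Weber contrast and
#'     starting-zone luminances.}
#'   \item{choice}{ethogram scoring and the binomial choice model.}
#'   \item{pattern}{bar luminances, background and internal contrasts, and
#'     the three Gamma pattern models with response ratios.}
#'   \item{all}{everything above, in order.}
#' }
#' Every run writes a `manifest_<stage>.json` recording the seed, parameters
#' and outputs; outputs are byte-identical under an identical seed and
#' config.
#'
#' @param stage one of `simulate`, `substrate-contrast`, `design`, `choice`,
#'   `pattern`, `all`.
#' @param dir directory for inputs and outputs.
#' @param config a [sim_config()]; its seed drives the simulator, model
#'   posteriors use `seed`.
#' @param n_draws posterior draws for all models (>= 1000).
#' @param seed seed for posterior simulation.
#' @return (Invisibly) a named list of the stage results.
#' @export
run_pipeline <- function(stage = c("all", "simulate", "substrate-contrast",
                                   "design", "choice", "pattern"),
                         dir, config = sim_config(), n_draws = 10000,
                         seed = 1) {
  stage <- match.arg(stage)
  if (n_draws < 1000) stop("n_draws below 1000 gives unstable compatibility intervals")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  stages <- if (stage == "all") {
    c("simulate", "substrate-contrast", "design", "choice", "pattern")
  } else stage
  results <- list()
  for (st in stages) {
    outputs <- character()
    res <- switch(st,
      simulate = {
        lib <- gen_substrate_library(config)
        greys <- gen_greyscale(config$n_grey_patches, config$grey_range)
        pop <- gen_fish_population(config)
        expt <- gen_choice_experiment(config)
        choices <- score_choices(expt$events)
        design <- design_backgrounds(config$fish_adapted_lums, greys)
        bg_lums <- stats::setNames(design$patches$luminance, design$patches$role)
        bars <- gen_bar_measurements(config, pop, choices, bg_lums)
        samples <- gen_background_samples(config, bg_lums)
        sample_tab <- do.call(rbind, lapply(names(samples), function(bg) {
          data.frame(background = bg, sample = seq_along(samples[[bg]]),
                     luminance = samples[[bg]])
        }))
        outputs <- c(
          write_pipeline_csv(lib$photos, dir, "substrate_photos.csv"),
          write_pipeline_csv(as.data.frame(greys), dir, "greyscale.csv"),
          write_pipeline_csv(expt$events, dir, "events.csv"),
          write_pipeline_csv(bars, dir, "bar_measurements.csv"),
          write_pipeline_csv(sample_tab, dir, "background_samples.csv"))
        list(photos = lib$photos, greys = greys, events = expt$events,
             bars = bars, samples = samples)
      },
      `substrate-contrast` = {
        photos <- utils::read.csv(pipeline_input(dir, "substrate_photos.csv"))
        observer <- visual_system("scorpaena_porcus")
        tab <- pairwise_contrasts(photos, observer)
        mods <- substrate_models(tab, n_draws = n_draws, seed = seed)
        post <- do.call(rbind, lapply(names(mods$summaries), function(r) {
          cbind(response = r, mods$summaries[[r]])
        }))
        outputs <- c(
          write_pipeline_csv(tab, dir, "substrate_comparisons.csv"),
          write_pipeline_csv(post, dir, "substrate_posterior.csv"))
        list(table = tab, models = mods)
      },
      design = {
        gtab <- utils::read.csv(pipeline_input(dir, "greyscale.csv"))
        greys <- grey_scale(gtab$label, gtab$luminance)
        design <- design_backgrounds(config$fish_adapted_lums, greys)
        path <- file.path(dir, "background_design.json")
        jsonlite::write_json(
          list(patches = design$patches,
               starting_zones = as.list(design$starting_zones),
               target = design$target),
          path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
        outputs <- "background_design.json"
        design
      },
      choice = {
        events <- utils::read.csv(pipeline_input(dir, "events.csv"))
        choices <- score_choices(events)
        ana <- choice_analysis(choices, n_draws = n_draws, seed = seed)
        outputs <- c(
          write_pipeline_csv(choices, dir, "choices.csv"),
          write_pipeline_csv(ana$summary, dir, "choice_posterior.csv"))
        list(choices = choices, analysis = ana)
      },
      pattern = {
        bars <- utils::read.csv(pipeline_input(dir, "bar_measurements.csv"))
        sample_tab <- utils::read.csv(pipeline_input(dir, "background_samples.csv"))
        choices <- utils::read.csv(pipeline_input(dir, "choices.csv"))
        samples <- split(sample_tab$luminance, sample_tab$background)
        observer <- visual_system("tripterygion_delaisi")
        ds <- pattern_dataset(bars, samples, choices, observer)
        mods <- pattern_models(ds, n_draws = n_draws, seed = seed)
        outputs <- c(
          write_pipeline_csv(ds$bar_level, dir, "pattern_bar_level.csv"),
          write_pipeline_csv(ds$fish_level, dir, "pattern_fish_level.csv"),
          write_pipeline_csv(mods$ratios, dir, "pattern_ratios.csv"))
        list(dataset = ds, models = mods)
      })
    manifest <- list(
      stage = st, seed_config = config$seed, seed_posterior = seed,
      n_draws = n_draws,
      package = as.character(utils::packageVersion("camochoice")),
      parameters = list(photo_census = as.list(config$photo_census),
                        n_fish = as.list(config$n_fish),
                        never_settlers = as.list(config$never_settlers),
                        choice_probabilities = as.list(config$choice_probabilities),
                        fish_adapted_lums = as.list(config$fish_adapted_lums)),
      outputs = outputs)
    jsonlite::write_json(manifest, file.path(dir, paste0("manifest_", st, ".json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    results[[st]] <- res
  }
  invisible(results)
}
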