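test_that("the substrate library reproduces the study census deterministically", {
  cfg <- sim_config(seed = 5)
  lib <- gen_substrate_library(cfg)
  expect_equal(nrow(lib$photos), 43)
  expect_equal(unname(table(lib$photos$substrate)[names(cfg$photo_census)]),
               unname(cfg$photo_census), ignore_attr = TRUE)
  lib2 <- gen_substrate_library(sim_config(seed = 5))
  expect_identical(lib$photos, lib2$photos)
  expect_false(identical(lib$photos,
                         gen_substrate_library(sim_config(seed = 6))$photos))
  expect_true(all(lib$photos$Q1 > 0 & lib$photos$Q2 > 0))
})

test_that("zero jitter collapses within-type variation to zero JND", {
  cfg <- sim_config(seed = 1, brightness_log_sd = 0, chroma_log_sd = 0,
                    photo_census = c(rubble_sand = 3, turf_algae = 3))
  lib <- gen_substrate_library(cfg)
  tab <- pairwise_contrasts(lib$photos, porcus())
  within <- tab[tab$type == "within", ]
  expect_true(all(within$chromatic_jnd < 1e-9))
  expect_true(all(within$achromatic_jnd < 1e-9))
  between <- tab[tab$type == "between", ]
  expect_true(all(between$achromatic_jnd > 1))
})

test_that("between-type achromatic contrast exceeds within-type on average", {
  lib <- gen_substrate_library(sim_config(seed = 8))
  tab <- pairwise_contrasts(lib$photos, porcus())
  expect_gt(mean(tab$achromatic_jnd[tab$type == "between"]),
            mean(tab$achromatic_jnd[tab$type == "within"]))
})

test_that("grey scales are log-spaced with dense Weber coverage", {
  two <- gen_greyscale(2, c(0.1, 0.4))
  expect_equal(two$luminance, c(0.1, 0.4))
  g <- gen_greyscale(20, c(0.02, 0.6))
  ratios <- g$luminance[-1] / g$luminance[-20]
  expect_equal(max(ratios) - min(ratios), 0, tolerance = 1e-12)
  # with >= 60 patches any interior target has a patch within Weber 0.05
  g64 <- gen_greyscale(64, c(0.02, 0.6))
  set.seed(12)
  for (target in runif(25, 0.025, 0.55)) {
    w <- abs(weber_contrast(g64$luminance, target))
    expect_lt(min(w), 0.05)
  }
  expect_error(gen_greyscale(1), "at least 2")
})

test_that("fish population applies the background gain rule exactly", {
  cfg0 <- sim_config(seed = 2, species_params = list(
    maderensis = list(bar_lum = c(dark_bar = 0.05, light_bar = 0.15),
                      gain = c(dark_bar = 0, light_bar = 0)),
    porcus = list(bar_lum = c(dark_bar = 0.08, light_bar = 0.12),
                  gain = c(dark_bar = 1, light_bar = 1))))
  pop <- gen_fish_population(cfg0)
  f_mad <- pop$fish[pop$fish$species == "maderensis", ][1, ]
  # gain 0: luminance ignores the background
  expect_equal(pop$adapted_luminance(f_mad, "dark_bar", 0.05),
               pop$adapted_luminance(f_mad, "dark_bar", 0.5))
  # gain 1: luminance moves fully onto the background
  f_por <- pop$fish[pop$fish$species == "porcus", ][1, ]
  expect_equal(pop$adapted_luminance(f_por, "light_bar", 0.33), 0.33)
  # light bar stays above dark bar for every fish
  pop_def <- gen_fish_population(sim_config(seed = 3))
  expect_true(all(pop_def$fish$light_bar > pop_def$fish$dark_bar))
  expect_equal(nrow(pop_def$fish), 50)
})

test_that("default species parameters separate internal contrast by species", {
  cfg <- sim_config(seed = 4)
  pop <- gen_fish_population(cfg)
  ic <- function(sp, bg) {
    rows <- pop$fish[pop$fish$species == sp, ]
    mean(vapply(seq_len(nrow(rows)), function(i) {
      ld <- pop$adapted_luminance(rows[i, ], "dark_bar", bg)
      ll <- pop$adapted_luminance(rows[i, ], "light_bar", bg)
      abs(log(ld / ll)) / 0.05
    }, numeric(1)))
  }
  for (bg in c(0.047, 0.12)) expect_gt(ic("maderensis", bg), ic("porcus", bg))
  # porcus reduces internal contrast on the medium (brighter) background
  expect_lt(ic("porcus", 0.12), ic("porcus", 0.047))
})

test_that("scoring the generated ethograms reproduces the intended choices", {
  cfg <- sim_config(seed = 21)
  expt <- gen_choice_experiment(cfg)
  choices <- score_choices(expt$events)
  merged <- merge(choices, expt$intended, by = c("fish_id", "species", "treatment"))
  expect_equal(nrow(merged), sum(cfg$n_fish) * 3)
  settled <- !is.na(merged$intended)
  expect_identical(merged$first_settled[settled], merged$intended[settled])
  expect_identical(merged$success.x[settled], merged$success.y[settled])
  expect_true(all(is.na(merged$first_settled[!settled])))
  # the study's five porcus never-settlers
  expect_equal(length(expt$never_settlers), 5)
  expect_true(all(grepl("^porcus", expt$never_settlers)))
  expect_identical(gen_choice_experiment(sim_config(seed = 21))$events,
                   expt$events)
})

test_that("degenerate choice probabilities drive the expected outcomes", {
  cfg1 <- sim_config(seed = 9, n_fish = c(maderensis = 15, porcus = 15),
                     never_settlers = c(maderensis = 0, porcus = 0),
                     choice_probabilities = c(dark_light = 1, medium_light = 1,
                                              medium_dark = 1))
  choices <- score_choices(gen_choice_experiment(cfg1)$events)
  res <- choice_analysis(choices, n_draws = 1000, seed = 1)
  expect_true(all(res$summary$median > 0.5))
  expect_true(all(res$summary$non_random))

  cfg2 <- sim_config(seed = 9, never_settlers = c(maderensis = 23, porcus = 27))
  ch2 <- score_choices(gen_choice_experiment(cfg2)$events)
  expect_error(choice_analysis(ch2), "no settled choices")
})

test_that("config validation rejects out-of-range parameters", {
  expect_error(sim_config(choice_probabilities = c(dark_light = 1.2,
                                                   medium_light = 0.8,
                                                   medium_dark = 0.1)),
               "\\[0, 1\\]")
  expect_error(sim_config(never_settlers = c(maderensis = 0, porcus = 30)),
               "between 0")
  expect_error(sim_config(photo_census = c(rubble_sand = 0)), ">= 1")
  expect_error(sim_config(brightness_log_sd = -1), "non-negative")
})
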