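ev <- function(state, start, dur) {
  data.frame(state = state, start_s = start, duration_s = dur)
}

test_that("settled bouts apply the 5-second stop-and-go rule", {
  # a single 4 s pause is stop-and-go, not settling
  e1 <- ev(c("moving", "dark"), c(0, 10), c(10, 4))
  expect_equal(settled_bouts(e1, backgrounds = c("dark", "light")),
               c(dark = 0, light = 0))
  # the 5 s boundary is included, bouts sum per background
  e2 <- ev(c("dark", "moving", "dark"), c(0, 5, 20), c(5, 15, 10))
  expect_equal(settled_bouts(e2, backgrounds = c("dark", "light")),
               c(dark = 15, light = 0))
  # no events at all
  expect_equal(settled_bouts(ev(character(0), numeric(0), numeric(0)),
                             backgrounds = c("dark", "light")),
               c(dark = 0, light = 0))
  # overlapping events are a recording error
  e3 <- ev(c("dark", "light"), c(0, 3), c(10, 5))
  expect_error(settled_bouts(e3), "overlapping")
})

test_that("first settled requires one uninterrupted minute", {
  e1 <- ev(c("dark", "moving", "light"), c(0, 30, 40), c(30, 10, 70))
  expect_equal(first_settled(e1), "light")
  # earliest qualifying bout wins even if a later one is longer
  e2 <- ev(c("dark", "moving", "light"), c(100, 160, 300), c(60, 140, 200))
  expect_equal(first_settled(e2), "dark")
  # never settling a full minute
  e3 <- ev(c("dark", "light", "dark"), c(0, 100, 200), c(59, 45, 30))
  expect_true(is.na(first_settled(e3)))
})

test_that("success coding matches the expectation table cell for cell", {
  expect_equal(encode_success("dark", "dark_light"), 1L)
  expect_equal(encode_success("light", "dark_light"), 0L)
  expect_equal(encode_success("medium", "medium_light"), 1L)
  expect_equal(encode_success("light", "medium_light"), 0L)
  expect_equal(encode_success("medium", "medium_dark"), 1L)
  expect_equal(encode_success("dark", "medium_dark"), 0L)
  expect_error(encode_success("medium", "dark_light"), "not part")
  expect_error(encode_success("dark", "no_such"), "unknown treatment")
  # the coding is a bijection background -> {0, 1} within each treatment
  for (tr in c("dark_light", "medium_light", "medium_dark")) {
    bgs <- strsplit(tr, "_")[[1]]
    codes <- vapply(bgs, encode_success, integer(1), treatment = tr)
    expect_setequal(codes, c(0L, 1L))
  }
})

test_that("scored choices are consistent with the bout durations", {
  events <- rbind(
    cbind(fish_id = "f1", species = "porcus", treatment = "dark_light",
          ev(c("moving", "dark", "moving", "light"), c(0, 10, 80, 95),
             c(10, 70, 15, 30))),
    cbind(fish_id = "f2", species = "porcus", treatment = "dark_light",
          ev(c("moving", "light"), c(0, 20), c(20, 3))))
  ch <- score_choices(events)
  f1 <- ch[ch$fish_id == "f1", ]
  expect_equal(f1$first_settled, "dark")
  expect_equal(f1$success, 1L)
  expect_gte(f1$dur_dark, 60)
  expect_equal(f1$dur_light, 30)
  f2 <- ch[ch$fish_id == "f2", ]
  expect_true(is.na(f2$first_settled))
  expect_true(is.na(f2$success))
  expect_equal(f2$dur_light, 0)
})

test_that("degenerate all-expected choices yield non-random cells above 0.5", {
  records <- expand.grid(fish_id = sprintf("f%02d", 1:40),
                         treatment = c("dark_light", "medium_light", "medium_dark"),
                         stringsAsFactors = FALSE)
  records$species <- ifelse(as.integer(sub("f", "", records$fish_id)) <= 20,
                            "maderensis", "porcus")
  records$first_settled <- c(dark_light = "dark", medium_light = "medium",
                             medium_dark = "medium")[records$treatment]
  records$success <- 1L
  res <- choice_analysis(records, n_draws = 2000, seed = 1)
  expect_true(res$ridge_applied)
  expect_true(all(res$summary$median > 0.5))
  expect_true(all(res$summary$non_random))
  expect_equal(length(res$excluded_fish), 0)
})

test_that("never-settling fish are excluded and empty cells are not estimable", {
  set.seed(31)
  records <- expand.grid(fish_id = sprintf("f%02d", 1:30),
                         treatment = c("dark_light", "medium_light", "medium_dark"),
                         stringsAsFactors = FALSE)
  records$species <- ifelse(as.integer(sub("f", "", records$fish_id)) <= 15,
                            "maderensis", "porcus")
  records$success <- rbinom(nrow(records), 1, 0.7)
  records$first_settled <- "dark"
  never <- records$fish_id %in% c("f01", "f02")
  records$success[never] <- NA
  records$first_settled[never] <- NA
  res <- choice_analysis(records, n_draws = 1000, seed = 1)
  expect_setequal(res$excluded_fish, c("f01", "f02"))
  expect_true(all(res$summary$n[res$summary$species == "maderensis"] == 13))

  empty <- records
  empty$success[empty$species == "porcus" & empty$treatment == "medium_dark"] <- NA
  expect_error(choice_analysis(empty), "not estimable")
})

test_that("estimates are equivariant under species relabelling", {
  set.seed(77)
  records <- expand.grid(fish_id = sprintf("f%02d", 1:44),
                         treatment = c("dark_light", "medium_light", "medium_dark"),
                         stringsAsFactors = FALSE)
  records$species <- ifelse(as.integer(sub("f", "", records$fish_id)) <= 22,
                            "maderensis", "porcus")
  p <- ifelse(records$species == "maderensis", 0.85, 0.6)
  records$success <- rbinom(nrow(records), 1, p)
  records$first_settled <- "dark"
  res1 <- choice_analysis(records, n_draws = 4000, seed = 5)
  swapped <- records
  swapped$species <- ifelse(records$species == "maderensis", "porcus", "maderensis")
  res2 <- choice_analysis(swapped, n_draws = 4000, seed = 5)
  m1 <- res1$summary[order(res1$summary$species, res1$summary$treatment), ]
  m2 <- res2$summary[order(res2$summary$species, res2$summary$treatment), ]
  # medians for maderensis in res1 match porcus in res2 and vice versa
  expect_equal(m1$median[m1$species == "maderensis"],
               m2$median[m2$species == "porcus"], tolerance = 0.02)
  expect_equal(m1$median[m1$species == "porcus"],
               m2$median[m2$species == "maderensis"], tolerance = 0.02)
})
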