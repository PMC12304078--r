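TREATMENTS <- c("dark_light", "medium_light", "medium_dark")
SPECIES <- c("maderensis", "porcus")

treatment_backgrounds <- function(treatment) {
  switch(treatment,
         dark_light = c("dark", "light"),
         medium_light = c("medium", "light"),
         medium_dark = c("medium", "dark"),
         stop("unknown treatment: ", treatment))
}

check_events <- function(events) {
  need <- c("state", "start_s", "duration_s")
  if (!all(need %in% names(events))) {
    stop("events need columns: ", paste(need, collapse = ", "))
  }
  if (any(events$duration_s <= 0)) stop("event durations must be positive")
  o <- order(events$start_s)
  ev <- events[o, , drop = FALSE]
  if (nrow(ev) > 1) {
    ends <- ev$start_s[-nrow(ev)] + ev$duration_s[-nrow(ev)]
    if (any(ev$start_s[-1] < ends - 1e-9)) stop("overlapping events in the trial")
  }
  ev
}

#' Settled durations per background
#'
#' Sums the stationary bout durations per background for one trial, keeping
#' only bouts of at least `min_bout_s` seconds: shorter "stop-and-go" pauses,
#' where a fish pauses for a few seconds but moves on, do not count as
#' settling. Bouts whose `state` is `"moving"` never count.
#'
#' @param events data frame for one fish x treatment trial with columns
#'   `state` (background label or `"moving"`), `start_s`, `duration_s`;
#'   events must not overlap.
#' @param backgrounds background labels to report (defaults to the settled
#'   states present).
#' @param min_bout_s minimum settled bout duration (default 5 s).
#' @return Named numeric vector of settled seconds per background.
#' @export
settled_bouts <- function(events, backgrounds = NULL, min_bout_s = 5) {
  ev <- check_events(events)
  ev <- ev[ev$state != "moving" & ev$duration_s >= min_bout_s, , drop = FALSE]
  if (is.null(backgrounds)) backgrounds <- sort(unique(ev$state))
  out <- stats::setNames(numeric(length(backgrounds)), backgrounds)
  if (nrow(ev)) {
    sums <- tapply(ev$duration_s, ev$state, sum)
    out[intersect(names(sums), backgrounds)] <-
      sums[intersect(names(sums), backgrounds)]
  }
  out
}

#' First settled background
#'
#' The choice variable of the experiment: the background of the earliest
#' stationary bout lasting at least `min_settle_s` (1 minute in the study);
#' `NA` if the fish never settles that long.
#'
#' @inheritParams settled_bouts
#' @param min_settle_s minimum duration for a bout to count as settling
#'   (default 60 s).
#' @return Background label, or `NA_character_` if the fish never settled.
#' @export
first_settled <- function(events, min_settle_s = 60) {
  ev <- check_events(events)
  ev <- ev[ev$state != "moving" & ev$duration_s >= min_settle_s, , drop = FALSE]
  if (!nrow(ev)) return(NA_character_)
  ev$state[which.min(ev$start_s)]
}

#' Encode a choice as success or failure
#'
#' The hypothesis-driven success coding of first-settled choices: the
#' expected background scores 1, the opposite background 0. The expectations
#' are dark in dark-light, medium in medium-light and medium in medium-dark
#' (background-matching prediction).
#'
#' @param choice background label chosen.
#' @param treatment one of `dark_light`, `medium_light`, `medium_dark`.
#' @return 1 (expected) or 0 (unexpected).
#' @export
encode_success <- function(choice, treatment) {
  expected <- c(dark_light = "dark", medium_light = "medium", medium_dark = "medium")
  if (!treatment %in% names(expected)) stop("unknown treatment: ", treatment)
  bgs <- treatment_backgrounds(treatment)
  if (!choice %in% bgs) {
    stop("background '", choice, "' is not part of treatment '", treatment, "'")
  }
  as.integer(choice == expected[[treatment]])
}

#' Score an ethogram table into choice records
#'
#' Applies the bout rules to a full event table: settled durations (>= 5 s
#' bouts), the first-settled background (>= 60 s), and the success coding,
#' per fish x treatment.
#'
#' @param events data frame with columns `fish_id`, `species`, `treatment`,
#'   `state`, `start_s`, `duration_s`.
#' @param min_bout_s,min_settle_s bout thresholds, see [settled_bouts()] and
#'   [first_settled()].
#' @return Data frame of choice records: `fish_id`, `species`, `treatment`,
#'   `first_settled` (`NA` if never settled), `success` (`NA` if never
#'   settled), and `dur_<background>` settled-duration columns.
#' @export
score_choices <- function(events, min_bout_s = 5, min_settle_s = 60) {
  need <- c("fish_id", "species", "treatment", "state", "start_s", "duration_s")
  if (!all(need %in% names(events))) {
    stop("event table needs columns: ", paste(need, collapse = ", "))
  }
  keys <- unique(events[, c("fish_id", "species", "treatment")])
  keys <- keys[order(keys$fish_id, keys$treatment), , drop = FALSE]
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    ev <- events[events$fish_id == keys$fish_id[i] &
                 events$treatment == keys$treatment[i], , drop = FALSE]
    bgs <- treatment_backgrounds(keys$treatment[i])
    dur <- settled_bouts(ev, backgrounds = bgs, min_bout_s = min_bout_s)
    fs <- first_settled(ev, min_settle_s = min_settle_s)
    succ <- if (is.na(fs)) NA_integer_ else encode_success(fs, keys$treatment[i])
    out <- data.frame(fish_id = keys$fish_id[i], species = keys$species[i],
                      treatment = keys$treatment[i], first_settled = fs,
                      success = succ, stringsAsFactors = FALSE)
    out[paste0("dur_", names(dur))] <- as.list(dur)
    out
  })
  res <- do.call(rbind, lapply(rows, function(r) {
    for (cn in c("dur_dark", "dur_medium", "dur_light")) {
      if (!cn %in% names(r)) r[[cn]] <- 0
    }
    r[c("fish_id", "species", "treatment", "first_settled", "success",
        "dur_dark", "dur_medium", "dur_light")]
  }))
  rownames(res) <- NULL
  res
}

#' Binomial choice analysis
#'
#' Stage 3 model: binomial (logit) mixed model of first-settled success with
#' species, treatment and their interaction as fixed effects and fish ID as a
#' random intercept. Fish that never settled in any treatment are excluded
#' before fitting; trials without a settled choice are dropped. Per species x
#' treatment cell, the median proportion of expected choices and its 95\%
#' compatibility interval are simulated from the posterior; cells whose CI
#' excludes the random-choice threshold 0.5 are flagged non-random. Complete
#' separation (e.g. a cell of all successes) is stabilised by a weak
#' Gaussian ridge penalty on the coefficients (variance 4, i.e. SD 2 on the
#' logit scale), applied only when detected; a looser prior leaves the Wald
#' compatibility intervals of separated cells uninformatively wide.
#'
#' @param records choice records from [score_choices()].
#' @param n_draws posterior draws (default 10,000).
#' @param seed integer seed for the posterior simulation.
#' @return List: `fit` (`camo_glmm`), `summary` (per species x treatment
#'   median, CI, `non_random` flag, n), `excluded_fish` (never-settlers),
#'   `ridge_applied`.
#' @export
choice_analysis <- function(records, n_draws = 10000, seed = 1) {
  need <- c("fish_id", "species", "treatment", "success")
  if (!all(need %in% names(records))) stop("not a choice record table")
  settled_any <- tapply(!is.na(records$success), records$fish_id, any)
  never <- names(settled_any)[!settled_any]
  dat <- records[!records$fish_id %in% never & !is.na(records$success), , drop = FALSE]
  if (!nrow(dat)) stop("no settled choices left after exclusions")
  dat$species <- factor(dat$species)
  dat$treatment <- factor(dat$treatment, levels = TREATMENTS)
  dat$treatment <- droplevels(dat$treatment)
  cells <- table(dat$species, dat$treatment)
  if (any(cells == 0)) {
    stop("species x treatment cell(s) with no settled choices: model not estimable")
  }
  spec <- glmm_spec("success", "binomial_logit", ~ species * treatment,
                    random_group = "fish_id")
  fit <- tryCatch(fit_glmm(dat, spec), error = function(e) NULL)
  ridge_applied <- FALSE
  if (is.null(fit) || detect_separation(fit)) {
    fit <- fit_glmm(dat, spec, ridge_var = 4)
    ridge_applied <- TRUE
  }
  lv <- expand.grid(species = levels(dat$species),
                    treatment = levels(dat$treatment),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  draws <- posterior_draws(fit, n = n_draws, seed = seed)
  sm <- predict_levels(fit, draws, lv)
  sm$non_random <- sm$ci_low > 0.5 | sm$ci_high < 0.5
  sm$n <- mapply(function(s, tr) sum(dat$species == s & dat$treatment == tr),
                 sm$species, sm$treatment)
  list(fit = fit, summary = sm, excluded_fish = never,
       ridge_applied = ridge_applied)
}
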