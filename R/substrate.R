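#' Pairwise substrate contrasts
#'
#' Stage 1 of the pipeline: every photo's average cone catch is contrasted
#' against every photo of every other substrate type (between-type rows, all
#' n_A x n_B cross pairs) and against every other photo of its own type
#' (within-type rows, all n(n-1)/2 unordered distinct pairs; a photo is never
#' compared with itself). With six substrate types this yields 21 comparison
#' categories.
#'
#' @param photos data frame with columns `photo_id`, `substrate`, and one
#'   `Q<i>` column per receptor of `observer` (per-photo average catches).
#' @param observer a [visual_system()] (the scorpionfish preset in the study
#'   design).
#' @param substrate_levels optional character vector fixing the set of valid
#'   substrate labels; photos with labels outside it raise an error.
#' @return Data frame of class `comparison_table`: `comparison` (unordered
#'   pair label `"a:b"`), `photo_a`, `photo_b`, `chromatic_jnd`,
#'   `achromatic_jnd`, `type` (`between`/`within`).
#' @export
pairwise_contrasts <- function(photos, observer, substrate_levels = NULL) {
  stopifnot(inherits(observer, "visual_system"))
  k <- length(observer$peaks)
  qcols <- paste0("Q", seq_len(k))
  need <- c("photo_id", "substrate", qcols)
  if (!all(need %in% names(photos))) {
    stop("photos must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(photos$photo_id)) stop("one record per photo required")
  if (!is.null(substrate_levels)) {
    bad <- setdiff(unique(photos$substrate), substrate_levels)
    if (length(bad)) stop("unknown substrate label(s): ", paste(bad, collapse = ", "))
  }
  Q <- as.matrix(photos[, qcols])
  if (any(Q <= 0)) stop("all photo catches must be positive")
  noise <- receptor_noise(observer)
  types <- sort(unique(as.character(photos$substrate)))
  idx_by_type <- split(seq_len(nrow(photos)), as.character(photos$substrate))

  rows <- list()
  for (i in seq_along(types)) {
    for (j in i:length(types)) {
      ta <- types[i]; tb <- types[j]
      if (i == j) {
        ids <- idx_by_type[[ta]]
        if (length(ids) < 2) {
          stop("within-type comparison for '", ta, "' needs at least 2 photos")
        }
        pr <- utils::combn(ids, 2)
        ia <- pr[1, ]; ib <- pr[2, ]
      } else {
        g <- expand.grid(a = idx_by_type[[ta]], b = idx_by_type[[tb]])
        ia <- g$a; ib <- g$b
      }
      df <- log(Q[ia, , drop = FALSE]) - log(Q[ib, , drop = FALSE])
      w <- 1 / noise$e^2
      dfc <- df - drop(df %*% w) / sum(w)
      chrom <- sqrt(drop(dfc^2 %*% w))
      la <- Q[ia, , drop = FALSE][, observer$luminance_def, drop = FALSE]
      lb <- Q[ib, , drop = FALSE][, observer$luminance_def, drop = FALSE]
      achro <- abs(log(rowMeans(la)) - log(rowMeans(lb))) / observer$weber_fraction
      rows[[length(rows) + 1]] <- data.frame(
        comparison = paste(ta, tb, sep = ":"),
        photo_a = photos$photo_id[ia], photo_b = photos$photo_id[ib],
        chromatic_jnd = chrom, achromatic_jnd = achro,
        type = if (i == j) "within" else "between",
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("comparison_table", class(out))
  out
}

#' Substrate contrast models
#'
#' Fits the two Gamma (log link) mixed models of the substrate stage: one for
#' achromatic and one for chromatic contrast, with the substrate comparison
#' as fixed effect and the first photo of each pair as the random intercept
#' group. Per-comparison predicted medians and 95\% compatibility intervals
#' are simulated from the posterior and annotated with their JND detection
#' class.
#'
#' @param table a [pairwise_contrasts()] result.
#' @param n_draws posterior draws (default 10,000).
#' @param seed integer seed for the posterior simulation.
#' @return List with `fits` (named list of `camo_glmm`) and `summaries`
#'   (named list of data frames: per-comparison median, CI and
#'   `jnd_class` of the median).
#' @export
substrate_models <- function(table, n_draws = 10000, seed = 1) {
  need <- c("comparison", "photo_a", "chromatic_jnd", "achromatic_jnd")
  if (!all(need %in% names(table))) stop("not a pairwise contrast table")
  counts <- table(table$comparison)
  if (any(counts == 0)) stop("every comparison label needs at least one row")
  dat <- data.frame(comparison = factor(table$comparison),
                    photo_a = factor(table$photo_a),
                    chromatic = table$chromatic_jnd,
                    achromatic = table$achromatic_jnd)
  lv <- data.frame(comparison = factor(levels(dat$comparison),
                                       levels = levels(dat$comparison)))
  fits <- list(); summaries <- list()
  for (resp in c("achromatic", "chromatic")) {
    spec <- glmm_spec(resp, "gamma_log", ~comparison, random_group = "photo_a")
    fit <- fit_glmm(dat, spec)
    draws <- posterior_draws(fit, n = n_draws, seed = seed)
    sm <- predict_levels(fit, draws, lv)
    sm$jnd_class <- classify_jnd(sm$median)
    fits[[resp]] <- fit
    summaries[[resp]] <- sm
  }
  list(fits = fits, summaries = summaries)
}
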