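#' Hierarchical bootstrap for nested data
#'
#' Resampling with replacement at each nesting level -- mice, then
#' recordings within each sampled mouse, then observations within each
#' sampled recording -- respecting the non-independence of repeated
#' measures. For a two-condition comparison the statistic is the
#' difference of condition means per resample (each condition resampled
#' within its own hierarchy); the one-sided p-value is the proportion of
#' resamples whose statistic contradicts the observed direction, floored
#' at `1/n_resamples`.
#'
#' @param data data.frame with columns `value`, `mouse`, `recording`,
#'   and optionally `condition` (two levels).
#' @param statistic optional function mapping a resampled value vector
#'   (single-condition case) to a scalar; default is the mean.
#' @param n_resamples number of bootstrap resamples.
#' @param seed integer seed; fixed seed gives identical results.
#' @param depth 3 resamples observations within recordings as well; 2
#'   resamples only mice and recordings.
#' @param direction `"auto"` takes the tested direction from the
#'   observed statistic's sign (exploratory use; effectively two-sided,
#'   with correspondingly doubled error rate). A confirmatory one-sided
#'   test declares `"greater"` or `"less"` up front; the p-value is then
#'   the proportion of resamples at or below (resp. at or above) zero.
#' @return a `bootstrap_result`: `distribution`, `observed`, `p_value`,
#'   `direction`, `n_resamples`, `seed`.
#' @export
hierarchical_bootstrap <- function(data, statistic = mean,
                                   n_resamples = 1000, seed = 1L,
                                   depth = 3,
                                   direction = c("auto", "greater", "less")) {
  direction <- match.arg(direction)
  if (!all(c("value", "mouse", "recording") %in% names(data))) {
    stop("`data` needs columns value, mouse, recording")
  }
  set.seed(seed)
  two_cond <- "condition" %in% names(data) &&
    length(unique(data$condition)) == 2L
  build_tree <- function(df) {
    mice <- split(df, df$mouse, drop = TRUE)
    lapply(mice, function(m) {
      lapply(split(m$value, m$recording, drop = TRUE), as.numeric)
    })
  }
  resample_tree <- function(tree) {
    nm <- length(tree)
    picked <- tree[sample.int(nm, nm, replace = TRUE)]
    unlist(lapply(picked, function(m) {
      nr <- length(m)
      recs <- m[sample.int(nr, nr, replace = TRUE)]
      if (depth >= 3) {
        lapply(recs, function(v) v[sample.int(length(v), length(v),
                                              replace = TRUE)])
      } else {
        recs
      }
    }), use.names = FALSE)
  }
  if (two_cond) {
    levels_ <- sort(unique(as.character(data$condition)))
    tree1 <- build_tree(data[data$condition == levels_[1], ])
    tree2 <- build_tree(data[data$condition == levels_[2], ])
    if (length(tree1) < 2L || length(tree2) < 2L) {
      warning("single mouse in a condition: degenerates toward a flat bootstrap")
    }
    observed <- mean(data$value[data$condition == levels_[2]]) -
      mean(data$value[data$condition == levels_[1]])
    dist <- vapply(seq_len(n_resamples), function(i) {
      mean(resample_tree(tree2)) - mean(resample_tree(tree1))
    }, numeric(1))
  } else {
    tree <- build_tree(data)
    if (length(tree) < 2L) {
      warning("single mouse: degenerates toward a flat bootstrap")
    }
    observed <- statistic(data$value)
    dist <- vapply(seq_len(n_resamples), function(i) {
      statistic(resample_tree(tree))
    }, numeric(1))
  }
  if (direction == "auto") {
    direction <- if (observed >= 0) "greater" else "less"
  }
  contra <- if (direction == "greater") mean(dist <= 0) else mean(dist >= 0)
  p <- max(contra, 1 / n_resamples)
  structure(list(distribution = dist, observed = observed, p_value = p,
                 direction = direction, n_resamples = n_resamples,
                 seed = seed),
            class = "bootstrap_result")
}

#' Paired bootstrap treatment-effect test
#'
#' Per-recording paired differences (treatment minus baseline) in the
#' treatment arm are resampled with replacement `n_resamples` (10^4)
#' times; each resample's mean difference is compared against the
#' extremes of the observed control (saline) arm differences. The
#' one-sided p-value is the proportion of resampled treatment
#' differences that fail to exceed the relevant saline extreme -- less
#' than the maximum when the observed effect is an increase, greater
#' than the minimum when it is a decrease -- floored at
#' `1/n_resamples`.
#'
#' @param baseline,treatment paired per-recording values, treatment arm.
#' @param saline_baseline,saline_treatment paired per-recording values,
#'   control arm (>= 2 recordings).
#' @param n_resamples number of resamples.
#' @param seed integer seed.
#' @return a `bootstrap_result` with the resampled mean-difference
#'   distribution and the saline bounds in `bounds`.
#' @export
paired_bootstrap_effect <- function(baseline, treatment,
                                    saline_baseline, saline_treatment,
                                    n_resamples = 1e4, seed = 1L) {
  if (length(baseline) != length(treatment)) {
    stop("treatment arm is not paired (unequal lengths)")
  }
  if (length(saline_baseline) != length(saline_treatment)) {
    stop("saline arm is not paired (unequal lengths)")
  }
  if (length(saline_baseline) < 2L) stop("saline arm needs >= 2 recordings")
  set.seed(seed)
  d_treat <- treatment - baseline
  d_sal <- saline_treatment - saline_baseline
  bounds <- range(d_sal)
  n <- length(d_treat)
  dist <- vapply(seq_len(n_resamples), function(i) {
    mean(d_treat[sample.int(n, n, replace = TRUE)])
  }, numeric(1))
  increase <- mean(d_treat) >= mean(d_sal)
  inside <- if (increase) mean(dist <= bounds[2]) else mean(dist >= bounds[1])
  p <- max(inside, 1 / n_resamples)
  structure(list(distribution = dist, observed = mean(d_treat),
                 bounds = bounds, p_value = p,
                 direction = if (increase) "greater" else "less",
                 n_resamples = n_resamples, seed = seed),
            class = "bootstrap_result")
}

#' Simulate a null cohort of nested observations
#'
#' Generates a two-condition hierarchical dataset with no condition
#' effect: each mouse draws a random effect, each recording within it
#' another, and observations add residual noise. Used to study the
#' calibration (type-I error) of [hierarchical_bootstrap()]. The default
#' variance components make recording-to-recording variability the
#' dominant cluster term, the typical situation for repeated imaging
#' sessions where day-to-day state changes outweigh animal identity.
#'
#' @param n_mice,n_recordings,n_obs cohort shape per condition.
#' @param mouse_sd,recording_sd,obs_sd standard deviations of the random
#'   effects at each level.
#' @return data.frame with columns `value`, `mouse`, `recording`,
#'   `condition` (levels `"a"`, `"b"`).
#' @export
simulate_null_cohort <- function(n_mice = 5, n_recordings = 4, n_obs = 20,
                                 mouse_sd = 0.5, recording_sd = 1,
                                 obs_sd = 1) {
  arm <- function(cond) {
    do.call(rbind, lapply(seq_len(n_mice), function(m) {
      mu_m <- rnorm(1, 0, mouse_sd)
      do.call(rbind, lapply(seq_len(n_recordings), function(r) {
        data.frame(value = mu_m + rnorm(1, 0, recording_sd) +
                     rnorm(n_obs, 0, obs_sd),
                   mouse = paste0(cond, m),
                   recording = paste0(cond, m, "_", r),
                   condition = cond)
      }))
    }))
  }
  rbind(arm("a"), arm("b"))
}

#' Shuffled-onset null distribution
#'
#' Draws `n_events` uniform random onsets (keeping `edge_s` clear of the
#' recording edges, typically the analysis half-window) `n_shuffles`
#' times and applies the supplied analysis to each draw, returning the
#' outputs as the null distribution for event-locked statistics.
#' Circular shifting of the real onsets is available as an alternative.
#'
#' @param duration_s recording length in seconds.
#' @param n_events events per draw (or, for `method = "circular"`, the
#'   real onset times to shift).
#' @param n_shuffles number of null draws.
#' @param analysis function mapping a vector of onset times (seconds) to
#'   a scalar or vector.
#' @param edge_s margin excluded at both edges, seconds.
#' @param method `"uniform"` or `"circular"`.
#' @param seed integer seed.
#' @return list of analysis outputs, one per draw (simplified to a
#'   vector when each output is scalar).
#' @export
shuffled_event_null <- function(duration_s, n_events, n_shuffles,
                                analysis, edge_s = 0,
                                method = c("uniform", "circular"),
                                seed = 1L) {
  method <- match.arg(method)
  if (2 * edge_s >= duration_s) stop("analysis window longer than the recording")
  set.seed(seed)
  out <- vector("list", n_shuffles)
  for (i in seq_len(n_shuffles)) {
    times <- if (method == "uniform") {
      sort(runif(if (length(n_events) > 1L) length(n_events) else n_events,
                 edge_s, duration_s - edge_s))
    } else {
      if (length(n_events) < 2L) stop("circular method needs the real onsets")
      shifted <- (n_events + runif(1, 0, duration_s)) %% duration_s
      shifted <- sort(shifted)
      shifted[shifted > edge_s & shifted < duration_s - edge_s]
    }
    out[[i]] <- analysis(times)
  }
  if (all(vapply(out, length, integer(1)) == 1L)) unlist(out) else out
}
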