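#' Sum-to-zero +/-1 contrast codes for the study factors
#'
#' Adds the numeric contrast columns used consistently by the data
#' generators and the models: `group_c` (ASD = +1, COMP = -1), `dyad_type_c`
#' (mixed = +1, non-autistic = -1), `ips_c` (high = +1, low = -1) and, when
#' an `aoi` column is present, the two sum-coded columns `aoi1` (head = 1,
#' body = -1) and `aoi2` (hand = 1, body = -1). Under this coding a
#' two-level factor's marginal condition difference equals twice its
#' coefficient (e.g. a dyad-type coefficient of -3.87 means mixed dyads are
#' rated 7.74 points lower than non-autistic dyads).
#'
#' @param df data.frame with any of the columns `group`, `dyad_type`, `ips`
#'   (or `condition`), `aoi`.
#' @return `df` with contrast columns appended.
#' @export
contrast_codes <- function(df) {
  if ("group" %in% names(df)) {
    df$group_c <- ifelse(df$group == "ASD", 1, -1)
  }
  if ("dyad_type" %in% names(df)) {
    df$dyad_type_c <- ifelse(df$dyad_type == "mixed", 1, -1)
  }
  ips_col <- intersect(c("ips", "condition"), names(df))[1]
  if (!is.na(ips_col)) {
    df$ips_c <- ifelse(df[[ips_col]] == "high", 1, -1)
  }
  if ("aoi" %in% names(df)) {
    df$aoi1 <- ifelse(df$aoi == "head", 1, ifelse(df$aoi == "body", -1, 0))
    df$aoi2 <- ifelse(df$aoi == "hand", 1, ifelse(df$aoi == "body", -1, 0))
  }
  df
}

#' Default set of eight synthetic dyads
#'
#' Four mixed and four non-autistic dyads with identical coupling (the study
#' design manipulates synchrony within dyads via segment selection, and the
#' selected stimulus set is balanced in synchrony across dyad types).
#'
#' @param n_frames frames per dyad video (default 7500 = 5 min at 25 fps).
#' @param fps frame rate.
#' @param coupling latent lagged correlation of every dyad.
#' @param lag_frames coupling lag in frames.
#' @param noise_sd measurement-noise SD.
#' @param seed base seed; dyad i uses `seed + i`.
#' @return list of 8 [dyad_spec()]s.
#' @export
default_dyads <- function(n_frames = 7500, fps = 25, coupling = 0.5,
                          lag_frames = 12, noise_sd = 0.2, seed = 100) {
  types <- rep(c("mixed", "non-autistic"), each = 4)
  lapply(seq_along(types), function(i) {
    dyad_spec(dyad_id = sprintf("d%02d", i), dyad_type = types[i],
              n_frames = n_frames, fps = fps, coupling = coupling,
              lag_frames = lag_frames, noise_sd = noise_sd, seed = seed + i)
  })
}

#' Study design for the mixed 2 x 2 x 2 experiment
#'
#' Describes the generative model for observer data: a between-subjects
#' factor (observer group: ASD vs COMP) crossed with two within-subject
#' factors (dyad type: mixed vs non-autistic; movement synchrony: high vs
#' low), with Gaussian participant and dyad random intercepts. Effects are
#' coefficients on the sum-to-zero +/-1 codes of [contrast_codes()]; the
#' defaults use the rating-model point estimates of the study this package
#' models as generative truth (dyad type -3.87, synchrony 0.83).
#'
#' @param n_observers_per_group observers per group (paper: 27 ASD, 36 COMP;
#'   generation allows unequal via a length-2 vector c(ASD, COMP)).
#' @param dyads list of [dyad_spec()]s (default [default_dyads()]).
#' @param grand_mean grand mean rating on the 0-100 scale.
#' @param effects named coefficients on contrast codes; names use the
#'   columns of [contrast_codes()], e.g. `dyad_type_c`, `ips_c`, `group_c`,
#'   `"dyad_type_c:ips_c"`.
#' @param sd_participant,sd_dyad random-intercept SDs.
#' @param sigma trial-level residual SD.
#' @param n_trials_per_cell stimulus segments per dyad x condition (default
#'   4, giving 64 trials).
#' @param miss_prob probability that a trial's rating is missed (no response
#'   within the 4-s window).
#' @param seed integer master seed.
#' @return object of class `study_design`.
#' @export
study_design <- function(n_observers_per_group = c(27, 36),
                         dyads = default_dyads(),
                         grand_mean = 55,
                         effects = c(dyad_type_c = -3.87, ips_c = 0.83,
                                     group_c = 1.07,
                                     "dyad_type_c:ips_c" = -0.06,
                                     "group_c:dyad_type_c" = 0.24),
                         sd_participant = 8, sd_dyad = 4, sigma = 10,
                         n_trials_per_cell = 4, miss_prob = 0.06, seed = 1) {
  if (length(n_observers_per_group) == 1) {
    n_observers_per_group <- rep(n_observers_per_group, 2)
  }
  stopifnot(all(n_observers_per_group >= 0), sd_participant >= 0, sd_dyad >= 0,
            sigma >= 0, miss_prob >= 0, miss_prob <= 1)
  structure(
    list(n_observers_per_group = n_observers_per_group, groups = c("ASD", "COMP"),
         dyads = dyads, conditions = c("high", "low"), grand_mean = grand_mean,
         effects = effects, sd_participant = sd_participant, sd_dyad = sd_dyad,
         sigma = sigma, n_trials_per_cell = n_trials_per_cell,
         miss_prob = miss_prob, seed = as.integer(seed)),
    class = "study_design"
  )
}

design_grid <- function(design) {
  obs <- data.frame(
    participant_id = sprintf("s%03d", seq_len(sum(design$n_observers_per_group))),
    group = rep(design$groups, design$n_observers_per_group)
  )
  dy <- data.frame(
    dyad_id = vapply(design$dyads, `[[`, character(1), "dyad_id"),
    dyad_type = vapply(design$dyads, `[[`, character(1), "dyad_type")
  )
  grid <- merge(merge(obs, dy), data.frame(condition = design$conditions))
  grid[order(grid$participant_id, grid$dyad_id, grid$condition), ]
}

effect_sum <- function(df, effects) {
  if (length(effects) == 0) return(rep(0, nrow(df)))
  out <- rep(0, nrow(df))
  for (nm in names(effects)) {
    cols <- strsplit(nm, ":", fixed = TRUE)[[1]]
    if (!all(cols %in% names(df))) {
      stop(sprintf("unknown effect term '%s' (no contrast column '%s')",
                   nm, setdiff(cols, names(df))[1]), call. = FALSE)
    }
    code <- Reduce(`*`, df[cols])
    out <- out + effects[[nm]] * code
  }
  out
}

#' Generate a trial-level rating table from a study design
#'
#' Each trial's rating on the 0-100 scale is
#' `grand mean + sum(effects x codes) + participant intercept +
#' dyad intercept + Gaussian noise`, clipped to [0, 100]. Trials whose
#' simulated response falls outside the 4-s response window (probability
#' `miss_prob`) have a missing rating.
#'
#' @param design a [study_design()].
#' @return data.frame with one row per trial: `participant_id`, `group`,
#'   `dyad_id`, `dyad_type`, `condition`, `trial`, `block`, `rating` (NA if
#'   missed), `response_time`.
#' @export
gen_ratings <- function(design) {
  stopifnot(inherits(design, "study_design"))
  set.seed(design$seed)
  grid <- design_grid(design)
  trials <- merge(grid, data.frame(trial = seq_len(design$n_trials_per_cell)))
  trials <- trials[order(trials$participant_id, trials$dyad_id, trials$condition, trials$trial), ]
  rownames(trials) <- NULL
  trials <- contrast_codes(trials)
  pids <- unique(trials$participant_id)
  dids <- unique(trials$dyad_id)
  b_p <- stats::setNames(stats::rnorm(length(pids), 0, design$sd_participant), pids)
  b_d <- stats::setNames(stats::rnorm(length(dids), 0, design$sd_dyad), dids)
  mu <- design$grand_mean + effect_sum(trials, design$effects) +
    b_p[trials$participant_id] + b_d[trials$dyad_id]
  rating <- pmin(100, pmax(0, mu + stats::rnorm(nrow(trials), 0, design$sigma)))
  missed <- stats::runif(nrow(trials)) < design$miss_prob
  rating[missed] <- NA
  rt <- ifelse(missed, 4 + stats::rexp(nrow(trials), 2), stats::runif(nrow(trials), 0.6, 3.8))
  trials$block <- ifelse(trials$trial <= design$n_trials_per_cell / 2, 1L, 2L)
  trials$rating <- rating
  trials$response_time <- rt
  attr(trials, "truth") <- list(b_participant = b_p, b_dyad = b_d)
  trials
}

#' Generate an aggregated dwell-time table from a study design
#'
#' Produces per observer x dyad x condition x AOI dwell percentages from a
#' Gaussian linear predictor with per-AOI base levels and a group x AOI
#' interaction, clipped to [0, 100]. `aoi_effects` are on the percent scale
#' and named as group differences per AOI: `"group:head" = 10` means the
#' COMP group dwells 10 percentage points longer on heads than the ASD group
#' (i.e. an ASD - COMP difference of -10). The body percentage is kept at
#' least as large as head and hand, matching the nested-AOI classification
#' rule of the measurement pipeline.
#'
#' @param design a [study_design()].
#' @param aoi_effects named group-difference effects per AOI (percent).
#' @param base named per-AOI mean percentages.
#' @param sigma_dwell residual SD (percent).
#' @return data.frame: `participant_id`, `group`, `dyad_id`, `dyad_type`,
#'   `condition`, `aoi`, `dwell_pct`.
#' @export
gen_dwell_table <- function(design, aoi_effects = c("group:head" = 10.0),
                            base = c(head = 45, hand = 20, body = 80),
                            sigma_dwell = 8) {
  stopifnot(inherits(design, "study_design"))
  set.seed(design$seed + 1L)
  grid <- design_grid(design)
  tab <- merge(grid, data.frame(aoi = c("head", "hand", "body")))
  tab <- tab[order(tab$participant_id, tab$dyad_id, tab$condition, tab$aoi), ]
  rownames(tab) <- NULL
  tab <- contrast_codes(tab)
  pids <- unique(tab$participant_id)
  dids <- unique(tab$dyad_id)
  b_p <- stats::setNames(stats::rnorm(length(pids), 0, design$sd_participant), pids)
  b_d <- stats::setNames(stats::rnorm(length(dids), 0, design$sd_dyad), dids)
  mu <- base[tab$aoi] + b_p[tab$participant_id] + b_d[tab$dyad_id]
  for (nm in names(aoi_effects)) {
    parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2 || parts[1] != "group" || !(parts[2] %in% names(base))) {
      stop(sprintf("gen_dwell_table: effect '%s' must look like 'group:<aoi>'", nm), call. = FALSE)
    }
    sel <- tab$aoi == parts[2]
    # COMP (group_c = -1) higher by aoi_effects/2, ASD lower by aoi_effects/2
    mu[sel] <- mu[sel] - tab$group_c[sel] * aoi_effects[[nm]] / 2
  }
  val <- pmin(100, pmax(0, mu + stats::rnorm(nrow(tab), 0, sigma_dwell)))
  tab$dwell_pct <- val
  wide_max <- stats::ave(val, tab$participant_id, tab$dyad_id, tab$condition, FUN = max)
  tab$dwell_pct[tab$aoi == "body"] <- wide_max[tab$aoi == "body"]
  tab
}
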