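## Study-shaped synthetic observations from known ground-truth mechanisms.
## The clinical observations the model was built against exist only as
## published figures, so recovery experiments run against data generated by
## the model itself under a known mechanism set.

#' Specification for a synthetic observation set
#'
#' @param truth List of ground-truth [mechanism()]s (default: the refined
#'   calibration preset).
#' @param noise_cv Fractional (coefficient-of-variation) observation noise;
#'   multiplicative, applied per measurement.
#' @param seed Integer seed; generation is deterministic given the seed.
#' @param studies Subset of `c("rabelink", "bohm", "vml588")`.
#' @param n_subjects Named vector of per-study subject counts (the reported
#'   SE scales with `1/sqrt(n)`).
#' @return A list of class `et_synthetic_spec`.
#' @export
synthetic_spec <- function(truth = mechanism_preset("refined"),
                           noise_cv = 0.03, seed = 1L,
                           studies = c("rabelink", "bohm", "vml588"),
                           n_subjects = c(rabelink = 6, bohm = 6,
                                          vml588 = 9)) {
  if (length(studies) == 0) stop("studies must be non-empty")
  studies <- match.arg(studies, several.ok = TRUE)
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  check_mechanisms(truth)
  structure(list(truth = truth, noise_cv = noise_cv, seed = as.integer(seed),
                 studies = studies, n_subjects = n_subjects),
            class = "et_synthetic_spec")
}

## Empty observation rows for a protocol's measurement schedule.
schedule_rows <- function(study, arm, prot, n) {
  rows <- list()
  for (v in names(prot$sample_times)) {
    tt <- prot$sample_times[[v]]
    rows[[length(rows) + 1L]] <- data.frame(
      study = study, arm = arm, variable = v, time = tt,
      t_start = NA_real_, value = NA_real_, se = NA_real_, n = n)
  }
  for (v in names(prot$bins)) {
    b <- prot$bins[[v]]
    rows[[length(rows) + 1L]] <- data.frame(
      study = study, arm = arm, variable = v, time = b[, 2],
      t_start = b[, 1], value = NA_real_, se = NA_real_, n = n)
  }
  do.call(rbind, rows)
}

#' Generate a synthetic observation table
#'
#' Simulates each selected study protocol under the ground-truth mechanism
#' set, samples the model outputs at the protocols' measurement times and
#' collection bins, corrupts them with multiplicative Gaussian noise of the
#' given CV, and reports `se = cv * value / sqrt(n)`. With `noise_cv = 0`
#' the values equal the deterministic simulation exactly and `se` is left
#' missing.
#'
#' @param spec An [synthetic_spec()].
#' @param config An `et_config`.
#' @return An [observation_table()].
#' @examples
#' \donttest{
#' obs <- generate_observations(synthetic_spec(studies = "bohm", seed = 7))
#' head(obs)
#' }
#' @export
generate_observations <- function(spec, config = et_config()) {
  rows <- list()
  for (study in spec$studies) {
    for (arm in study_arms(study)) {
      prot <- protocol_for(study, arm)
      rows[[length(rows) + 1L]] <-
        schedule_rows(study, arm, prot, unname(spec$n_subjects[study]))
    }
  }
  obs <- do.call(rbind, rows)
  pred <- predict_observations(obs, spec$truth, config)
  if (spec$noise_cv > 0) {
    ## Each reported value is the mean over n subject replicates, each
    ## carrying multiplicative noise of the given CV; the emitted SE
    ## (cv * value / sqrt(n)) is then the actual sampling error of that
    ## mean.
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv())
    set.seed(spec$seed)
    eps <- vapply(seq_len(nrow(obs)), function(r)
      mean(rnorm(obs$n[r], sd = spec$noise_cv)), 0)
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    obs$value <- pred$pred * (1 + eps)
    obs$se <- spec$noise_cv * abs(obs$value) / sqrt(obs$n)
  } else {
    obs$value <- pred$pred
    obs$se <- NA_real_
  }
  observation_table(obs)
}
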