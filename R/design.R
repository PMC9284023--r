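#' Cross-over tissue-cage trial design
#'
#' Describes the sampling design: each animal carries one cage of every listed
#' length on each side of the neck, receives an IV bolus at time zero in each
#' of two cross-over periods, and in exactly one period carrageenan is
#' injected into all cages of one (randomised) side two hours before dosing.
#' Plasma and every cage are sampled at the listed times.
#'
#' @param n_sheep Number of animals (default 7).
#' @param cage_lengths_cm Cage lengths, each implanted on both sides
#'   (default 3, 6, 10, 14, 18 cm, i.e. 10 cages per animal).
#' @param n_periods Number of cross-over periods (default 2).
#' @param sampling_times_h Sampling times relative to the dose (h); the -1 h
#'   sample is pre-dose.
#' @param dose_mg_per_kg IV bolus dose (default 4 mg/kg).
#' @param carrageenan_period Which period carries carrageenan (default 2).
#' @param carrageenan_side_by_sheep Character vector (`"left"`/`"right"`), one
#'   per sheep; `NULL` means assign at simulation time from the seed.
#' @param missing_rate Fraction of cage records dropped completely at random
#'   (default 0).
#' @return Object of class `"trial_design"`.
#' @export
trial_design <- function(n_sheep = 7,
                         cage_lengths_cm = c(3, 6, 10, 14, 18),
                         n_periods = 2,
                         sampling_times_h = c(-1, 0.5, 1, 2, 3, 4, 5, 6, 8, 12, 24, 36, 48, 72),
                         dose_mg_per_kg = 4,
                         carrageenan_period = 2,
                         carrageenan_side_by_sheep = NULL,
                         missing_rate = 0) {
  stopifnot(n_sheep >= 1, length(cage_lengths_cm) >= 1, all(cage_lengths_cm > 0),
            n_periods >= 1, length(sampling_times_h) >= 1)
  if (is.unsorted(sampling_times_h, strictly = TRUE))
    stop("sampling times must be strictly increasing", call. = FALSE)
  if (!(carrageenan_period %in% seq_len(n_periods)))
    stop("carrageenan_period must identify exactly one of the periods", call. = FALSE)
  if (!is.null(carrageenan_side_by_sheep)) {
    if (length(carrageenan_side_by_sheep) != n_sheep ||
        !all(carrageenan_side_by_sheep %in% c("left", "right")))
      stop("carrageenan_side_by_sheep must be one of 'left'/'right' per sheep", call. = FALSE)
  }
  stopifnot(missing_rate >= 0, missing_rate < 1)
  structure(list(n_sheep = n_sheep, cage_lengths_cm = cage_lengths_cm,
                 n_periods = n_periods, sampling_times_h = sampling_times_h,
                 dose_mg_per_kg = dose_mg_per_kg,
                 carrageenan_period = carrageenan_period,
                 carrageenan_side_by_sheep = carrageenan_side_by_sheep,
                 missing_rate = missing_rate),
            class = "trial_design")
}

#' Default cross-over design with randomised carrageenan sides
#'
#' The study design with all defaults: 7 sheep, 10 cages each (5 lengths
#' duplicated left/right), two periods, 14 sampling times, 4 mg/kg dose, and
#' the carrageenan side drawn per sheep from the seeded generator.
#'
#' @param seed Optional integer seed for the side randomisation.
#' @return A [trial_design()].
#' @export
make_default_design <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- trial_design()
  d$carrageenan_side_by_sheep <- sample(c("left", "right"), d$n_sheep, replace = TRUE)
  d
}

#' @export
print.trial_design <- function(x, ...) {
  cat(sprintf("Cross-over tissue-cage trial: %d sheep, %d periods, %g mg/kg IV\n",
              x$n_sheep, x$n_periods, x$dose_mg_per_kg))
  cat(sprintf("  cages per sheep: %s cm, duplicated left/right\n",
              paste(x$cage_lengths_cm, collapse = "/")))
  cat(sprintf("  sampling (h): %s\n", paste(x$sampling_times_h, collapse = ", ")))
  cat(sprintf("  carrageenan in period %d, side %s; missing rate %g\n",
              x$carrageenan_period,
              if (is.null(x$carrageenan_side_by_sheep)) "randomised at simulation"
              else paste(x$carrageenan_side_by_sheep, collapse = "/"),
              x$missing_rate))
  invisible(x)
}
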