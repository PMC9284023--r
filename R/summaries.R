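# Non-compartmental peak summaries and estimated-marginal-mean contrasts.

#' Observed peak concentration per cage series
#'
#' For every cage series (sheep x period x side x length) extracts the maximum
#' observed concentration (Cmax) and its time (Tmax) from the post-dose
#' records; ties in Cmax break to the earliest attaining time.
#'
#' @param records Trial data frame; only post-dose cage records are used.
#' @return Data frame with one row per cage series: `sheep_id`, `period`,
#'   `side`, `length_cm`, `carr_cage`, `tmax_h`, `cmax_ug_ml`.
#' @export
observed_peaks <- function(records) {
  cg <- records[records$matrix == "cage" & !records$below_dose_time, , drop = FALSE]
  if (nrow(cg) == 0) stop("no post-dose cage records", call. = FALSE)
  key <- paste(cg$sheep_id, cg$period, cg$side, cg$length_cm)
  split_rows <- split(seq_len(nrow(cg)), key)
  rows <- lapply(split_rows, function(idx) {
    s <- cg[idx, , drop = FALSE]
    s <- s[order(s$time_h), , drop = FALSE]
    imax <- which.max(s$conc_ug_ml)  # first maximum: earliest time wins ties
    data.frame(sheep_id = s$sheep_id[1], period = s$period[1], side = s$side[1],
               length_cm = s$length_cm[1], carr_cage = any(s$carr_cage),
               tmax_h = s$time_h[imax], cmax_ug_ml = s$conc_ug_ml[imax])
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$sheep_id, out$period, out$side, out$length_cm), ]
  rownames(out) <- NULL
  out
}

#' Peak summaries by cage size
#'
#' Count, median, minimum and maximum of Tmax and Cmax per cage length, with
#' the cage SA/V for reference. Medians use the midpoint convention for even
#' counts (`stats::median`).
#'
#' @param peaks Output of [observed_peaks()].
#' @param ... Passed to [cage_spec()] for the SA/V column.
#' @return Data frame with one row per cage length.
#' @export
summarize_peaks <- function(peaks, ...) {
  if (nrow(peaks) == 0) stop("no peaks to summarise", call. = FALSE)
  lens <- sort(unique(peaks$length_cm))
  rows <- lapply(lens, function(L) {
    s <- peaks[peaks$length_cm == L, ]
    data.frame(length_cm = L,
               sav_per_cm = surface_to_volume(cage_spec(L, ...)),
               count = nrow(s),
               tmax_median = stats::median(s$tmax_h),
               tmax_min = min(s$tmax_h), tmax_max = max(s$tmax_h),
               cmax_median = stats::median(s$cmax_ug_ml),
               cmax_min = min(s$cmax_ug_ml), cmax_max = max(s$cmax_ug_ml))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pairwise estimated-marginal-mean contrasts between cage sizes
#'
#' Fits `response ~ factor(length)` with a random sheep intercept (or plain
#' fixed effects with `random_sheep = FALSE`) and returns all pairwise
#' differences of estimated marginal means with Wald confidence intervals and
#' p-values. No multiplicity adjustment by default; `adjust = "holm"` is
#' available.
#'
#' @param peaks Output of [observed_peaks()].
#' @param response `"cmax"` or `"tmax"`.
#' @param random_sheep Include a random per-sheep intercept (default TRUE).
#' @param adjust Multiplicity adjustment passed to emmeans (default "none").
#' @return Data frame with columns `contrast`, `estimate`, `ci_low`,
#'   `ci_high`, `p_value`.
#' @export
emm_contrasts <- function(peaks, response = c("cmax", "tmax"),
                          random_sheep = TRUE, adjust = "none") {
  response <- match.arg(response)
  peaks$resp <- if (response == "cmax") peaks$cmax_ug_ml else peaks$tmax_h
  peaks$len_f <- factor(peaks$length_cm)
  cnt <- table(peaks$len_f)
  if (any(cnt < 2)) {
    warning("dropping cage-size group(s) with fewer than 2 observations: ",
            paste(names(cnt)[cnt < 2], collapse = ", "), call. = FALSE)
    peaks <- droplevels(peaks[peaks$len_f %in% names(cnt)[cnt >= 2], ])
  }
  if (nlevels(peaks$len_f) < 2)
    stop("need at least 2 cage-size groups", call. = FALSE)
  if (random_sheep) {
    fit <- nlme::lme(resp ~ len_f, random = ~ 1 | sheep_id, data = peaks,
                     method = "REML")
  } else {
    fit <- stats::lm(resp ~ len_f, data = peaks)
  }
  emm <- emmeans::emmeans(fit, "len_f")
  ct <- summary(emmeans::contrast(emm, method = "pairwise", adjust = adjust),
                infer = c(TRUE, TRUE))
  out <- data.frame(contrast = gsub("len_f", "", as.character(ct$contrast)),
                    estimate = ct$estimate,
                    ci_low = ct$lower.CL, ci_high = ct$upper.CL,
                    p_value = ct$p.value)
  rownames(out) <- NULL
  out
}
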