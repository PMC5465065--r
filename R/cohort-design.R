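#' Experimental timeline marks
#'
#' Describes the session layout of an acute convulsant experiment: a control
#' (pre-injection) recording, the convulsant injection, a short
#' post-injection stabilization window that is excluded from analysis, and
#' the session end. Defaults follow the standard protocol: 10 min of control
#' recording, a 90 s stabilization window after injection, and a 60 min
#' session.
#'
#' @param control_start start of the control window, seconds (default 0).
#' @param injection_time convulsant application time, seconds (default 600).
#' @param stabilization_end end of the excluded post-injection window,
#'   seconds (default `injection_time + 90`).
#' @param session_end end of the recording, seconds (default 3600).
#' @return an object of class `zf_marks`.
#' @export
#' @examples
#' timeline_marks()
timeline_marks <- function(control_start = 0, injection_time = 600,
                           stabilization_end = injection_time + 90,
                           session_end = 3600) {
  m <- list(control_start = control_start, injection_time = injection_time,
            stabilization_end = stabilization_end, session_end = session_end)
  if (!(control_start < injection_time && injection_time < stabilization_end &&
        stabilization_end <= session_end)) {
    stop("timeline must satisfy control_start < injection_time < ",
         "stabilization_end <= session_end", call. = FALSE)
  }
  structure(m, class = "zf_marks")
}

#' @export
print.zf_marks <- function(x, ...) {
  cat(sprintf(
    "<zf_marks> control [%g, %g) s | injection %g s | analysis [%g, %g] s\n",
    x$control_start, x$injection_time, x$injection_time,
    x$stabilization_end, x$session_end))
  invisible(x)
}

#' Per-animal generative profile
#'
#' Bundles the distributions that govern one simulated animal: how many
#' epileptiform events it has in a session, how long they last, how long
#' after the injection the first one occurs, which channel they start on,
#' and whether the animal responds at all. Event counts are Poisson
#' truncated at >= 1 for responders; durations and latencies are log-normal
#' (right-skewed, strictly positive), parameterized by their means and a
#' coefficient of variation.
#'
#' @param sex `"male"` or `"female"`.
#' @param responder if `FALSE`, the animal never seizes (zero events).
#' @param count_mean mean number of events per session (truncated-Poisson
#'   mean for responders).
#' @param duration_mean,duration_cv mean (s) and coefficient of variation of
#'   the per-event duration distribution.
#' @param latency_mean,latency_cv mean (s, from injection) and CV of the
#'   latency to the first event.
#' @param onset_probs length-4 probability vector over onset channels;
#'   must sum to 1.
#' @param p_theta probability an event is a 5-7 Hz theta discharge (the
#'   remainder are 2-3 Hz spike-wave complexes).
#' @param p_focal probability an event stays focal (single channel); other
#'   events generalize to all channels with per-channel onset delays.
#' @param se_prob probability the animal is forced to have one
#'   status-epilepticus-like event (> 300 s).
#' @param id optional animal identifier.
#' @return an object of class `zf_profile`.
#' @export
animal_profile <- function(sex = c("male", "female"), responder = TRUE,
                           count_mean = if (sex == "male") 6.50 else 3.38,
                           duration_mean = if (sex == "male") 79 else 88,
                           duration_cv = 0.5,
                           latency_mean = if (sex == "male") 269 else 462,
                           latency_cv = 0.5,
                           onset_probs = default_onset_probs(sex),
                           p_theta = 0.7, p_focal = 0.3,
                           se_prob = 0, id = NA_character_) {
  sex <- match.arg(sex)
  if (length(onset_probs) != 4L || any(onset_probs < 0) ||
      abs(sum(onset_probs) - 1) > 1e-9) {
    stop("`onset_probs` must be 4 non-negative probabilities summing to 1",
         call. = FALSE)
  }
  for (nm in c("count_mean", "duration_mean", "latency_mean")) {
    stopifnot_scalar_pos(get(nm), nm)
  }
  structure(list(sex = sex, responder = isTRUE(responder),
                 count_mean = count_mean,
                 duration_mean = duration_mean, duration_cv = duration_cv,
                 latency_mean = latency_mean, latency_cv = latency_cv,
                 onset_probs = onset_probs, p_theta = p_theta,
                 p_focal = p_focal, se_prob = se_prob, id = id),
            class = "zf_profile")
}

#' Default onset-channel probabilities by sex
#'
#' Anterior (telencephalic) onset dominates in this seizure model: 39% of
#' events start on the left telencephalon (channel 2) and 32% on the right
#' (channel 1) in both sexes. The posterior remainder is lateralized by sex:
#' males favour the right posterior channel (19%, channel 4), females the
#' left (24%, channel 3).
#'
#' @param sex `"male"` or `"female"`.
#' @return length-4 probability vector (channels 1-4).
#' @export
default_onset_probs <- function(sex = c("male", "female")) {
  sex <- match.arg(sex)
  if (sex == "male") c(0.32, 0.39, 0.10, 0.19) else c(0.32, 0.39, 0.24, 0.05)
}

#' @export
print.zf_profile <- function(x, ...) {
  cat(sprintf("<zf_profile> %s%s | events ~%.2f | dur ~%.0f s | lat ~%.0f s\n",
              x$sex, if (x$responder) "" else " (non-responder)",
              x$count_mean, x$duration_mean, x$latency_mean))
  invisible(x)
}

#' Cohort configuration
#'
#' Specifies how many animals of each sex and responder status to simulate,
#' together with the timeline and sampling rate shared by all recordings.
#' Per-sex distribution parameters can be overridden through `male_args` /
#' `female_args`, which are forwarded to [animal_profile()].
#'
#' @param n_male,n_female number of animals per sex.
#' @param n_nonresponder_male,n_nonresponder_female how many of each sex
#'   never seize.
#' @param marks a [timeline_marks()] object.
#' @param fs sampling rate, Hz.
#' @param male_args,female_args named lists of overrides for
#'   [animal_profile()].
#' @return an object of class `zf_cohort_config`.
#' @export
cohort_config <- function(n_male, n_female,
                          n_nonresponder_male = 0, n_nonresponder_female = 0,
                          marks = timeline_marks(), fs = 500,
                          male_args = list(), female_args = list()) {
  counts <- c(n_male, n_female, n_nonresponder_male, n_nonresponder_female)
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts))) {
    stop("animal counts must be non-negative integers", call. = FALSE)
  }
  if (n_nonresponder_male > n_male || n_nonresponder_female > n_female) {
    stop("non-responder counts cannot exceed per-sex totals", call. = FALSE)
  }
  structure(list(n_male = n_male, n_female = n_female,
                 n_nonresponder_male = n_nonresponder_male,
                 n_nonresponder_female = n_nonresponder_female,
                 marks = marks, fs = fs,
                 male_args = male_args, female_args = female_args),
            class = "zf_cohort_config")
}

#' Named cohort presets
#'
#' Two presets mirror the reference PTZ experiment this package models:
#' `"ptz17"` is the full 17-animal cohort (8 male / 9 female) with three
#' non-responders (1 male, 2 female); `"ptz14"` is its 14 seizing animals
#' only (7 male / 7 female). Both use the sex-specific event-count, duration
#' and latency means of that experiment (6.50 vs 3.38 events, 79 vs 88 s,
#' 269 vs 462 s).
#'
#' @param name `"ptz17"` or `"ptz14"`.
#' @param fs sampling rate, Hz.
#' @param marks a [timeline_marks()] object.
#' @return a [cohort_config()] object.
#' @export
cohort_preset <- function(name = c("ptz17", "ptz14"), fs = 500,
                          marks = timeline_marks()) {
  name <- match.arg(name)
  switch(name,
    ptz17 = cohort_config(8, 9, 1, 2, marks = marks, fs = fs),
    ptz14 = cohort_config(7, 7, 0, 0, marks = marks, fs = fs))
}
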