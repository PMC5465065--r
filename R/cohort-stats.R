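#' Per-animal seizure metrics
#'
#' Summarizes one animal's detected events: event count (events of at least
#' 5 s, post-stabilization), count of long events (> 2 min), mean duration,
#' latency from the injection to the first event, and whether any event was
#' status-epilepticus-like.
#'
#' @param events detected-event data.frame for one animal (already
#'   filtered to >= 5 s by the detector).
#' @param marks the recording's [timeline_marks()].
#' @param animal_id,sex subject metadata carried into the output row.
#' @return one-row data.frame with columns animal_id, sex, n_events,
#'   n_long_events, mean_duration_s, latency_first_s (NA when no events),
#'   has_se.
#' @export
per_animal_metrics <- function(events, marks, animal_id = NA_character_,
                               sex = NA_character_) {
  stopifnot(inherits(marks, "zf_marks"))
  if (!is.null(events$animal_id) &&
      length(unique(events$animal_id)) > 1L) {
    stop("events from multiple animals passed to per_animal_metrics()",
         call. = FALSE)
  }
  n <- nrow(events)
  data.frame(
    animal_id = animal_id, sex = sex, n_events = n,
    n_long_events = if (n) sum(events$duration_s > 120) else 0L,
    mean_duration_s = if (n) mean(events$duration_s) else NA_real_,
    latency_first_s = if (n) min(events$onset_s) - marks$injection_time
                      else NA_real_,
    has_se = if (n) any(events$is_se) else FALSE,
    stringsAsFactors = FALSE)
}

#' Two-group comparison of a per-animal metric
#'
#' Classical pooled-variance (Student) two-sample t-test of one metric
#' between groups, two-sided; with 7 animals per group the degrees of
#' freedom are n1 + n2 - 2 = 12. Pooled rather than Welch to match the
#' conventional reporting of equal-variance df in this literature.
#'
#' @param metrics data.frame of [per_animal_metrics()] rows.
#' @param metric name of the metric column to compare.
#' @param group_field name of the grouping column (default `"sex"`).
#' @return object of class `zf_group_comparison`: list with `statistic`,
#'   `df`, `p_value`, `means` (named), `ns` (named), `metric`.
#' @export
#' @examples
#' m <- data.frame(sex = rep(c("male", "female"), each = 3),
#'                 n_events = c(7, 6, 8, 3, 4, 2))
#' group_compare(m, "n_events")
group_compare <- function(metrics, metric, group_field = "sex") {
  g <- factor(metrics[[group_field]])
  v <- metrics[[metric]]
  keep <- !is.na(v) & !is.na(g)
  g <- droplevels(g[keep]); v <- v[keep]
  if (nlevels(g) != 2L) {
    stop("`group_field` must define exactly two groups with data",
         call. = FALSE)
  }
  ns <- table(g)
  if (any(ns < 2L)) {
    stop("each group needs at least 2 animals with a defined metric",
         call. = FALSE)
  }
  tt <- stats::t.test(v ~ g, var.equal = TRUE)
  means <- tapply(v, g, mean)
  structure(list(statistic = unname(tt$statistic),
                 df = unname(tt$parameter), p_value = tt$p.value,
                 means = means, ns = as.integer(ns),
                 groups = levels(g), metric = metric),
            class = "zf_group_comparison")
}

#' @export
print.zf_group_comparison <- function(x, ...) {
  cat(sprintf("<zf_group_comparison> %s: t(%d) = %.3f, p = %.4f\n",
              x$metric, x$df, x$statistic, x$p_value))
  cat(sprintf("  %s: mean %.3f (n=%d) | %s: mean %.3f (n=%d)\n",
              x$groups[1], x$means[1], x$ns[1],
              x$groups[2], x$means[2], x$ns[2]))
  invisible(x)
}

#' Cohort-level summary
#'
#' Per-sex and overall means of event count, duration and latency, together
#' with status-epilepticus and non-responder tallies. Following the
#' convention of this experimental literature, means are computed over
#' seizing animals only; animals without any detected event are counted as
#' non-responders and reported separately.
#'
#' @param metrics data.frame of [per_animal_metrics()] rows, one per
#'   animal.
#' @return list of class `zf_cohort_summary` with elements `by_sex`
#'   (data.frame), `overall` (one-row data.frame), `n_nonresponders`,
#'   `n_se_animals`, `n_animals`.
#' @export
cohort_summary <- function(metrics) {
  if (!nrow(metrics)) stop("no animals in `metrics`", call. = FALSE)
  seizing <- metrics[metrics$n_events > 0, , drop = FALSE]
  smry <- function(d) {
    data.frame(n_animals = nrow(d),
               mean_count = mean(d$n_events),
               sd_count = stats::sd(d$n_events),
               mean_duration_s = mean(d$mean_duration_s, na.rm = TRUE),
               mean_latency_s = mean(d$latency_first_s, na.rm = TRUE))
  }
  by_sex <- do.call(rbind, lapply(split(seizing, seizing$sex), smry))
  by_sex <- cbind(sex = rownames(by_sex), by_sex)
  rownames(by_sex) <- NULL
  structure(list(by_sex = by_sex, overall = smry(seizing),
                 n_nonresponders = sum(metrics$n_events == 0),
                 n_se_animals = sum(metrics$has_se),
                 n_animals = nrow(metrics)),
            class = "zf_cohort_summary")
}

#' @export
print.zf_cohort_summary <- function(x, ...) {
  cat(sprintf("<zf_cohort_summary> %d animals (%d non-responders, %d with SE-like events)\n",
              x$n_animals, x$n_nonresponders, x$n_se_animals))
  cat(sprintf("  overall (seizing only): %.2f events/animal, mean duration %.1f s, mean latency %.1f s\n",
              x$overall$mean_count, x$overall$mean_duration_s,
              x$overall$mean_latency_s))
  for (i in seq_len(nrow(x$by_sex))) {
    r <- x$by_sex[i, ]
    cat(sprintf("  %s: n=%d, %.2f events, duration %.1f s, latency %.1f s\n",
                r$sex, r$n_animals, r$mean_count, r$mean_duration_s,
                r$mean_latency_s))
  }
  invisible(x)
}
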