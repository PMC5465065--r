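marks_std <- timeline_marks(0, 600, 690, 3600)

mk_events <- function(onsets, durations, se = NULL) {
  data.frame(onset_s = onsets, duration_s = durations,
             is_se = if (is.null(se)) durations > 300 else se)
}

test_that("per-animal metrics compute counts, durations and latency", {
  ev <- mk_events(600 + 300 + c(0, 400, 900), c(10, 20, 30))
  m <- per_animal_metrics(ev, marks_std, animal_id = "A1", sex = "male")
  expect_identical(m$n_events, 3L)
  expect_equal(m$mean_duration_s, 20)
  expect_equal(m$latency_first_s, 300)
  expect_identical(m$n_long_events, 0L)
  expect_false(m$has_se)
})

test_that("zero-event animals report missing latency", {
  m <- per_animal_metrics(mk_events(numeric(0), numeric(0)), marks_std)
  expect_identical(m$n_events, 0L)
  expect_true(is.na(m$latency_first_s))
  expect_true(is.na(m$mean_duration_s))
  expect_false(m$has_se)
})

test_that("long-event and SE counting follow the 2 min and 5 min rules", {
  m <- per_animal_metrics(mk_events(c(700, 1500), c(301, 121)), marks_std)
  expect_identical(m$n_long_events, 2L)
  expect_true(m$has_se)
  m2 <- per_animal_metrics(mk_events(700, 120), marks_std)
  expect_identical(m2$n_long_events, 0L)
  ev <- mk_events(c(700, 800), c(10, 10))
  ev$animal_id <- c("a", "b")
  expect_error(per_animal_metrics(ev, marks_std), "multiple animals")
})

test_that("the pooled t-test reports df = n1 + n2 - 2", {
  set.seed(3)
  m <- data.frame(sex = rep(c("male", "female"), each = 7),
                  n_events = c(rpois(7, 6), rpois(7, 3)))
  cmp <- group_compare(m, "n_events")
  expect_identical(as.integer(cmp$df), 12L)
  expect_true(cmp$p_value >= 0 && cmp$p_value <= 1)
})

test_that("identical groups give t = 0 and p = 1", {
  m <- data.frame(sex = rep(c("male", "female"), each = 4),
                  n_events = rep(c(2, 4, 6, 8), 2))
  cmp <- group_compare(m, "n_events")
  expect_equal(cmp$statistic, 0)
  expect_equal(cmp$p_value, 1)
})

test_that("the t statistic matches the textbook pooled formula", {
  set.seed(11)
  for (i in 1:10) {
    n1 <- sample(3:9, 1); n2 <- sample(3:9, 1)
    x <- rnorm(n1, 5, 2); y <- rnorm(n2, 4, 2)
    m <- data.frame(sex = c(rep("a", n1), rep("b", n2)), v = c(x, y))
    cmp <- group_compare(m, "v")
    sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
    t_ref <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
    expect_equal(cmp$statistic, t_ref, tolerance = 1e-12)
    expect_identical(as.integer(cmp$df), n1 + n2 - 2L)
    p_ref <- 2 * pt(-abs(t_ref), n1 + n2 - 2)
    expect_equal(cmp$p_value, p_ref, tolerance = 1e-12)
  }
})

test_that("swapping group labels flips the sign of t", {
  m <- data.frame(sex = rep(c("male", "female"), each = 5),
                  v = c(6, 7, 5, 8, 6, 3, 4, 2, 3, 4))
  m2 <- m
  m2$sex <- ifelse(m$sex == "male", "female", "male")
  expect_equal(group_compare(m, "v")$statistic,
               -group_compare(m2, "v")$statistic)
})

test_that("groups with too few defined values are an error", {
  m <- data.frame(sex = c("male", "male", "female"), v = c(1, 2, 3))
  expect_error(group_compare(m, "v"), "at least 2")
  m$v[3] <- NA
  expect_error(group_compare(m, "v"), "two groups")
})

test_that("cohort summaries match hand-computed means", {
  metrics <- data.frame(
    animal_id = c("M1", "M2", "F1", "F2", "F3"),
    sex = c("male", "male", "female", "female", "female"),
    n_events = c(6L, 8L, 4L, 2L, 0L),
    n_long_events = c(0L, 1L, 0L, 0L, 0L),
    mean_duration_s = c(70, 90, 100, 80, NA),
    latency_first_s = c(200, 300, 400, 500, NA),
    has_se = c(FALSE, TRUE, FALSE, FALSE, FALSE))
  s <- cohort_summary(metrics)
  expect_identical(s$n_nonresponders, 1L)
  expect_identical(s$n_se_animals, 1L)
  # seizing animals only
  expect_equal(s$overall$mean_count, mean(c(6, 8, 4, 2)))
  male <- s$by_sex[s$by_sex$sex == "male", ]
  expect_equal(male$mean_count, 7)
  expect_equal(male$mean_duration_s, 80)
  fem <- s$by_sex[s$by_sex$sex == "female", ]
  expect_equal(fem$mean_latency_s, 450)
  # internal consistency: overall mean is the size-weighted group mean
  w <- s$by_sex$n_animals
  expect_equal(s$overall$mean_count,
               sum(s$by_sex$mean_count * w) / sum(w), tolerance = 1e-9)
})

test_that("all-identical animals give zero dispersion", {
  metrics <- data.frame(animal_id = letters[1:4], sex = rep("male", 4),
                        n_events = rep(5L, 4), n_long_events = 0L,
                        mean_duration_s = 50, latency_first_s = 100,
                        has_se = FALSE)
  s <- cohort_summary(metrics)
  expect_equal(s$overall$sd_count, 0)
})
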