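test_that("generate -> write -> read round-trips the cohort", {
  cohort <- generate_cohort(cohort_spec(20, prevalence = 0.3, seed = 2))
  d <- tempfile()
  write_cohort(cohort, d)
  eps <- read_cohort(d, quiet = TRUE)
  expect_length(eps, 20L)
  expect_length(filter_cohort(eps, quiet = TRUE), 20L)
  # retained columns survive the trip
  for (i in c(1, 20)) {
    p <- cohort[[i]]
    e <- eps[[match(p$stay_id, vapply(eps, `[[`, character(1), "stay_id"))]]
    expect_equal(e$age, p$age)
    expect_equal(e$label, p$label)
    expect_equal(sort(e$icd9_codes), sort(p$icd9_codes))
    expect_length(e$notes, length(p$notes))
    ord_p <- order(p$events$feature, p$events$time)
    ord_e <- order(e$events$feature, e$events$time)
    expect_equal(e$events$value[ord_e], p$events$value[ord_p],
                 tolerance = 1e-12)
  }
})

test_that("unknown feature rows are dropped and counted", {
  cohort <- generate_cohort(cohort_spec(3, seed = 4))
  d <- tempfile()
  write_cohort(cohort, d)
  chart <- read.csv(file.path(d, "chartevents.csv"),
                    stringsAsFactors = FALSE)
  chart <- rbind(chart, data.frame(STAY_ID = "S00001",
                                   FEATURE = "not_a_feature",
                                   CHARTTIME_H = 1, VALUENUM = 5))
  write.csv(chart, file.path(d, "chartevents.csv"), row.names = FALSE)
  eps <- read_cohort(d, quiet = TRUE)
  expect_length(eps, 3L)
  expect_equal(attr(eps, "dropped_unknown_feature"), 1L)
})

test_that("missing required columns raise a schema error naming the column", {
  cohort <- generate_cohort(cohort_spec(2, seed = 6))
  d <- tempfile()
  write_cohort(cohort, d)
  chart <- read.csv(file.path(d, "chartevents.csv"), stringsAsFactors = FALSE)
  chart$FEATURE <- NULL
  write.csv(chart, file.path(d, "chartevents.csv"), row.names = FALSE)
  expect_error(read_cohort(d, quiet = TRUE), "FEATURE")
})

test_that("empty tables yield zero episodes", {
  d <- tempfile()
  write_cohort(list(), d)
  eps <- read_cohort(d, quiet = TRUE)
  expect_length(eps, 0L)
})

test_that("categorical GCS chart values map to ordinal scores", {
  d <- tempfile(); dir.create(d)
  write.csv(data.frame(STAY_ID = "A", FEATURE = c("gcs_eye_opening",
                                                  "gcs_eye_opening",
                                                  "heart_rate"),
                       CHARTTIME_H = c(1, 2, 50),
                       VALUENUM = c("Spontaneously", "garbage!!", "80")),
            file.path(d, "chartevents.csv"), row.names = FALSE)
  write.csv(data.frame(STAY_ID = character(0), CHARTTIME_H = numeric(0),
                       CATEGORY = character(0), TEXT = character(0)),
            file.path(d, "noteevents.csv"), row.names = FALSE)
  write.csv(data.frame(STAY_ID = "A", ICD9_CODE = "4019"),
            file.path(d, "diagnoses.csv"), row.names = FALSE)
  write.csv(data.frame(STAY_ID = "A", AGE = 70, MORTALITY = 0),
            file.path(d, "labels.csv"), row.names = FALSE)
  eps <- read_cohort(d, quiet = TRUE)
  ev <- eps[[1]]$events
  expect_equal(ev$value[ev$feature == "gcs_eye_opening"], 4)
  expect_equal(attr(eps, "dropped_unparseable"), 1L)
  expect_true(eps[[1]]$chronic)
})

test_that("cohort filters are inclusive at 16 years and 48 hours", {
  eps <- list(make_episode("A", age = 15), make_episode("B", age = 16),
              make_episode("C", age = 70))
  kept <- filter_cohort(eps, quiet = TRUE)
  expect_equal(vapply(kept, `[[`, character(1), "stay_id"), c("B", "C"))
  short <- make_episode("D", events = data.frame(
    feature = "heart_rate", time = c(0.5, 47.5), value = c(80, 81)))
  expect_length(filter_cohort(list(short), quiet = TRUE), 0L)
})

test_that("filter_cohort matches a brute-force predicate scan and is idempotent", {
  set.seed(31)
  eps <- lapply(1:10, function(i) {
    make_episode(paste0("R", i), age = sample(c(12, 15, 16, 40, 90), 1),
                 events = data.frame(feature = "heart_rate",
                                     time = c(0, runif(1, 40, 60)),
                                     value = c(80, 81)))
  })
  kept <- filter_cohort(eps, quiet = TRUE)
  manual <- Filter(function(e) e$age >= 16 && max(e$events$time) >= 48, eps)
  expect_equal(vapply(kept, `[[`, character(1), "stay_id"),
               vapply(manual, `[[`, character(1), "stay_id"))
  expect_identical(unclass(filter_cohort(kept, quiet = TRUE)), unclass(kept))
})

test_that("chronic classification is set membership after normalization", {
  expect_false(classify_chronic(character(0)))
  expect_true(classify_chronic("4019", chronic_list = "4019"))
  expect_true(classify_chronic("401.9 ", chronic_list = "4019"))
  expect_false(classify_chronic("486", chronic_list = "4019"))
  set.seed(13)
  pool <- sprintf("%04d", sample(9999, 60))
  chronic <- sample(pool, 20)
  for (rep in 1:50) {
    codes <- sample(pool, sample(0:5, 1))
    expect_equal(classify_chronic(codes, chronic),
                 length(intersect(codes, chronic)) > 0)
  }
})

test_that("note selection branches on chronic status", {
  e <- make_episode(notes = list(make_note(-100, "CLINICAL HISTORY: old."),
                                 make_note(10, "CHIEF COMPLAINT: pain.")))
  b_non <- select_notes(e, 48, chronic = FALSE)
  expect_length(b_non$notes, 1L)
  expect_equal(b_non$notes[[1]]$chart_time, 10)
  expect_equal(b_non$K, 0L)
  b_chr <- select_notes(e, 48, chronic = TRUE)
  expect_length(b_chr$notes, 2L)
  expect_equal(b_chr$K, 1L)
  # non-chronic selection is always a subset of the chronic selection
  t_non <- vapply(b_non$notes, `[[`, numeric(1), "chart_time")
  t_chr <- vapply(b_chr$notes, `[[`, numeric(1), "chart_time")
  expect_true(all(t_non %in% t_chr))
})

test_that("chronic selection with no pre-window notes equals non-chronic", {
  e <- make_episode(notes = list(make_note(5, "CHIEF COMPLAINT: pain.")))
  b1 <- select_notes(e, 48, chronic = TRUE)
  b2 <- select_notes(e, 48, chronic = FALSE)
  expect_equal(b1$K, 0L)
  expect_identical(b1$notes, b2$notes)
  empty <- select_notes(make_episode(notes = list()), 48, chronic = TRUE)
  expect_length(empty$notes, 0L)
})
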