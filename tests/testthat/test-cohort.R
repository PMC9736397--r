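test_that("comorbidity identification pools codes per patient and filters", {
  rec <- tiny_records()
  m <- identify_comorbidities(rec, prevalence_floor = 0)
  # p1 has I42 + I50 + E78 pooled across two hospitalizations
  expect_equal(sort(colnames(m$incidence)[m$incidence["p1", ] == 1]),
               c("E78", "I42", "I50"))
  # injury chapter codes never make it into a matrix
  expect_false("S72" %in% colnames(m$incidence))
  expect_equal(m$n_patients, 3L)
})

test_that("prevalence floor is strict: exactly-at-floor diseases are dropped", {
  codes <- lapply(1:100, function(i) if (i == 1) c("I50", "E11") else "I50")
  rec <- make_records(sprintf("p%03d", 1:100), "male", 50L, "2015-01-01",
                      "cardiology", codes)
  m <- identify_comorbidities(rec, prevalence_floor = 0.01)
  expect_false("E11" %in% colnames(m$incidence))  # prevalence exactly 1%
  expect_true("I50" %in% colnames(m$incidence))
  expect_true(all(m$prevalence > 0.01 & m$prevalence <= 1))
})

test_that("identical disease sets give an all-ones matrix", {
  rec <- make_records(sprintf("p%02d", 1:10), "male", 50L, "2015-01-01",
                      "cardiology", rep(list(c("I50", "I42")), 10))
  m <- identify_comorbidities(rec, prevalence_floor = 0)
  expect_equal(dim(m$incidence), c(10L, 2L))
  expect_true(all(m$incidence == 1L))
  expect_equal(unname(m$prevalence), c(1, 1))
})

test_that("filtering everything raises an empty-result error", {
  rec <- make_records("p1", "male", 50L, "2015-01-01", "cardiology",
                      list("S72.1"))
  expect_error(identify_comorbidities(rec), class = "pdnet_empty_result")
})

test_that("comorbid burden summarises row sums", {
  X <- matrix(0L, 4, 3, dimnames = list(paste0("p", 1:4), c("A01", "B18", "C18")))
  X[1, 1] <- 1L; X[2, 1:2] <- 1L; X[3, 1:3] <- 1L
  b <- comorbid_burden(as_cohort(X))
  expect_equal(b$mean_burden, 1.5)
  expect_equal(b$share_multimorbid, 0.5)
  zero <- comorbid_burden(as_cohort(matrix(0L, 3, 2,
    dimnames = list(paste0("p", 1:3), c("A01", "B18")))))
  expect_equal(zero$mean_burden, 0)
  expect_equal(zero$share_multimorbid, 0)
})

test_that("age stratification assigns boundary ages to the right band", {
  rec <- make_records(c("p1", "p2", "p3"), "male", c(19L, 70L, 20L),
                      "2015-01-01", "cardiology",
                      rep(list(c("I50", "I42")), 3))
  out <- stratify_by_age(rec, prevalence_floor = 0)
  expect_equal(rownames(out[["0-19"]]$incidence), "p1")
  expect_equal(rownames(out[["70+"]]$incidence), "p2")
  expect_equal(rownames(out[["20-29"]]$incidence), "p3")
  # stratum patient counts partition the cohort
  n_by_stratum <- vapply(out, function(m) if (is.null(m)) 0L else m$n_patients, 0L)
  expect_equal(sum(n_by_stratum), 3L)
})

test_that("overlapping or gappy strata are a configuration error", {
  rec <- tiny_records()
  bad <- data.frame(lo = c(0L, 40L), hi = c(50L, 100L),
                    label = c("0-50", "40-100"))
  expect_error(stratify_by_age(rec, strata = bad),
               class = "pdnet_config_error")
})

test_that("caliper matching is exact on sex/department and respects the caliper", {
  case <- make_records("c1", "male", 50L, "2015-06-01", "cardiology",
                       list("I42.0"))
  pool_ok <- make_records("q1", "male", 51L, "2015-08-01", "cardiology",
                          list("I10"))
  m <- match_controls(case, pool_ok)
  expect_equal(m$pairs$control_id, "q1")
  expect_length(m$unmatched, 0)

  pool_bad <- make_records("q2", "female", 50L, "2015-06-01", "cardiology",
                           list("I10"))
  m2 <- match_controls(case, pool_bad)
  expect_equal(nrow(m2$pairs), 0L)
  expect_equal(m2$unmatched, "c1")

  expect_error(match_controls(case, pool_ok[0, ]),
               class = "pdnet_validation_error")
})

test_that("matching picks the nearest discharge date among eligible pool patients", {
  case <- make_records("c1", "male", 50L, "2015-06-01", "cardiology",
                       list("I42.0"))
  pool <- make_records(c("q1", "q2"), "male", 50L,
                       c("2016-06-01", "2015-07-01"), "cardiology",
                       list("I10", "E11"))
  m <- match_controls(case, pool)
  expect_equal(m$pairs$control_id, "q2")
})
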