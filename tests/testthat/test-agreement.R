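test_that("detection-count agreement splits disagreements into under and over", {
  # 266 agreeing videos, 27 undercounts, 12 overcounts
  a <- stats::setNames(rep(2, 305), paste0("v", 1:305))
  b <- a
  b[1:27] <- 1                                   # citizen sees fewer
  b[28:39] <- 3                                  # citizen sees more
  r <- detection_agreement(a, b)
  expect_equal(r$n_videos, 305)
  expect_equal(r$n_count_agree, 266)
  expect_equal(r$pct_count_agree, 87)
  expect_equal(r$n_under, 27)
  expect_equal(r$n_over, 12)
  expect_equal(r$pct_under, 69)
  expect_equal(r$mean_abs_disagreement, 1)

  identical_ <- detection_agreement(a, a)
  expect_equal(identical_$pct_count_agree, 100)
  expect_true(is.na(identical_$pct_under))
  expect_error(detection_agreement(a, b[-1]), "video sets differ")
})

test_that("swapping channels swaps under- and overcounts", {
  a <- stats::setNames(c(3, 2, 5, 1, 4), paste0("v", 1:5))
  b <- stats::setNames(c(2, 2, 6, 1, 2), paste0("v", 1:5))
  ab <- detection_agreement(a, b)
  ba <- detection_agreement(b, a)
  expect_equal(ab$n_under, ba$n_over)
  expect_equal(ab$n_over, ba$n_under)
  expect_equal(ab$mean_abs_disagreement, ba$mean_abs_disagreement)
})

test_that("ID assignment rates round half-up to the printed integers", {
  expect_equal(id_assignment_rate(907, n_total = 1068)$pct_with_id, 85)
  expect_equal(id_assignment_rate(474, n_total = 1035)$pct_with_id, 46)
  expect_equal(id_assignment_rate(0, n_total = 50)$pct_with_id, 0)
  expect_warning(r <- id_assignment_rate(0, n_total = 0), "undefined")
  expect_true(is.na(r$pct_with_id))
})

test_that("ID agreement counts matches and classifies mismatch patterns", {
  ids_a <- c(rep("same", 468), "x1", "x2", "x3")
  ids_b <- c(rep("same", 468), "y1", "y2", "y3")
  r <- id_agreement(ids_a, ids_b)
  expect_equal(r$n_total, 471)
  expect_equal(r$n_agree, 468)
  expect_equal(r$pct_agree, 99)
  expect_equal(id_agreement(c("a", "b"), c("a", "b"))$pct_agree, 100)

  # hand-counted 10-row fixture: 3 mismatches, 2 in the same age-sex class
  fa <- c("A", "B", "C", "D", "E", "F", "G", "H", "I", "J")
  fb <- c("A", "B", "C", "D", "E", "F", "G", "X", "Y", "Z")
  ca <- c(rep("adult_f", 5), rep("adult_m", 5))
  cb <- c(rep("adult_f", 5), rep("adult_m", 4), "juv")
  r2 <- id_agreement(fa, fb, ca, cb)
  expect_equal(unname(r2$mismatch_pattern["same_class"]), 2)
  expect_equal(unname(r2$mismatch_pattern["different_class"]), 1)
})

test_that("roster underestimates reproduce the printed percentages", {
  expect_equal(underestimate_pct(36, 37), 3)
  expect_equal(underestimate_pct(29, 37), 22)
  expect_equal(underestimate_pct(37, 37), 0)
  expect_error(underestimate_pct(1, 0), "positive")
})

test_that("Cohen's kappa follows the chance-corrected formula", {
  # perfect agreement
  expect_equal(cohens_kappa(diag(c(5, 8, 3))), 1)
  # hand computation: p_o = 0.7, p_e = 0.5 -> kappa = 0.4
  expect_equal(cohens_kappa(matrix(c(20, 10, 5, 15), 2)), 0.4)
  # independence: table equal to the outer product of its margins
  marg_r <- c(0.6, 0.4); marg_c <- c(0.3, 0.7)
  expect_equal(cohens_kappa(outer(marg_r, marg_c) * 100), 0)
  expect_error(cohens_kappa(matrix(1, 2, 3)))
})

test_that("prospective-ID resolution partitions and reports the resolved share", {
  status <- c(rep("resolved_to_confirmed", 18),
              rep("unresolvable_or_nonmember", 9),
              rep("unique_unconfirmed", 13))
  r <- prospective_id_resolution(status)
  expect_equal(r$n_total, 40)
  expect_equal(r$resolved_to_confirmed, 18)
  expect_equal(r$pct_resolved, 45)
  expect_equal(r$resolved_to_confirmed + r$unresolvable_or_nonmember +
                 r$unique_unconfirmed, r$n_total)
  empty <- prospective_id_resolution(character(0))
  expect_equal(empty$n_total, 0)
  expect_equal(empty$pct_resolved, 0)
  expect_error(prospective_id_resolution("nonsense"), "partition")
  # conservation on random fixtures
  set.seed(17)
  for (i in 1:5) {
    s <- sample(c("resolved_to_confirmed", "unresolvable_or_nonmember",
                  "unique_unconfirmed"), sample(1:30, 1), replace = TRUE)
    rr <- prospective_id_resolution(s)
    expect_equal(rr$resolved_to_confirmed + rr$unresolvable_or_nonmember +
                   rr$unique_unconfirmed, length(s))
  }
})

test_that("simulated channels hit their configured assignment rates", {
  dat <- simulate_community(sim_config(n_events = 800, seed = 23))
  for (ch in c("expert", "citizen")) {
    d <- dat$detections[dat$detections$channel == ch &
                          !grepl(":x", dat$detections$token, fixed = TRUE), ]
    r <- id_assignment_rate(d, ch)
    target <- if (ch == "expert") 85 else 46
    expect_gt(r$n_total, 1000)
    expect_lte(abs(r$pct_with_id - target), 2)
  }
})
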