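test_that("hypothesis and rate constructors enforce their invariants", {
  h <- dual_hypotheses(0.05, 0.2, 0.6, 0.4)
  expect_s3_class(h, "dual_hypotheses")
  expect_error(dual_hypotheses(0.2, 0.05, 0.6, 0.4), "r_nul")
  expect_error(dual_hypotheses(0.05, 0.2, 0.4, 0.6), "epd_alt")
  expect_error(dual_hypotheses(0.05, 0.5, 0.6, 0.4), "exceed 1")
  expect_error(dual_hypotheses(0.05, 1.2, 0.6, 0.4), "r_alt")

  expect_error(trinomial_rates(0.7, 0.5), "exceed 1")
  expect_error(trinomial_rates(-0.1, 0.5), "p_r")
  expect_silent(trinomial_rates(0, 1))

  expect_error(alt_mixture(list(c(0.2, 0.6)), weights = 2), "sum to 1")
  expect_error(alt_mixture(list(c(0.2, 0.6), c(0.05, 0.4)),
                           weights = c(1.1, -0.1)), "nonnegative")
  expect_silent(alt_mixture(list(c(0.2, 0.6), c(0.05, 0.4)),
                            weights = c(0.9, 0.1)))
  m <- borderline_mixture(h)
  expect_equal(m$weights, c(0.5, 0.5))
  expect_equal(m$components[[1]]$p_r, 0.2)
  expect_equal(m$components[[1]]$p_p, 0.6)
  expect_equal(m$components[[2]]$p_r, 0.05)
  expect_equal(m$components[[2]]$p_p, 0.4)
})

test_that("design constructor validates the four bounds", {
  expect_silent(desr_design(15, 15, 1, 8, 4, 14))
  expect_silent(desr_design(15, 15, 0, 16, 5, -1))   # extended encodings
  expect_error(desr_design(15, 15, -1, 8, 4, 14), "s_r")
  expect_error(desr_design(15, 15, 1, 17, 4, 14), "s_p")
  expect_error(desr_design(15, 15, 4, 8, 4, 14), "a_r")
  expect_error(desr_design(15, 15, 1, 8, 31, 14), "a_r")
  expect_error(desr_design(15, 15, 1, 8, 4, 31), "a_p")
})

test_that("trial records validate counts and name the offending field", {
  expect_error(trial_record("t", 15, 9, 7), "r1 \\+ p1")
  expect_error(trial_record("t", 15, 1, 2, n_tot = 25), "all present or all absent")
  expect_error(trial_record("t", 15, 1, 2, n_tot = 14, r_tot = 1, p_tot = 2),
               "n_tot")
  expect_error(trial_record("t", 15, 2, 2, n_tot = 25, r_tot = 1, p_tot = 5),
               "r_tot")
  expect_error(trial_record("t", 15, 1, 2, n_tot = 25, r_tot = 20, p_tot = 10),
               "exceeds n_tot")
  expect_silent(trial_record("t", 15, 1, 6, n_tot = 25, r_tot = 1, p_tot = 12))
})

test_that("the DESR verdict matches worked examples from the historical cohort", {
  th <- design_epd46()
  # 0 responses, 10 progressions of 15: joint futility signal, stop
  d <- decide_desr(trial_record("3", 15, 0, 10), th)
  expect_true(d$stage1_stop)
  expect_identical(d$final, "accept_null")
  # continued under-accrued trial rejecting on low cumulative progression
  d <- decide_desr(trial_record("13", 15, 1, 6, 25, 1, 12), th)
  expect_false(d$stage1_stop)
  expect_identical(d$final, "reject_null")
  # continued but second stage never reported: verdict unknowable
  d <- decide_desr(trial_record("2", 15, 0, 1), th)
  expect_false(d$stage1_stop)
  expect_identical(d$final, "indeterminate")
})

test_that("stage-I stopping is monotone in the observed counts", {
  th <- design_epd46()
  for (r1 in 0:6) for (p1 in 0:8) {
    s <- decide_desr(trial_record("x", 15, r1, p1), th)$stage1_stop
    if (r1 < 6) {
      s_more_resp <- decide_desr(trial_record("x", 15, r1 + 1, p1), th)$stage1_stop
      expect_false(!s && s_more_resp)   # extra response never triggers a stop
    }
    if (r1 + p1 < 15) {
      s_more_prog <- decide_desr(trial_record("x", 15, r1, p1 + 1), th)$stage1_stop
      expect_false(s && !s_more_prog)   # extra progression never rescues
    }
  }
})

test_that("verdicts are deterministic and a stage-I stop always accepts", {
  th <- design_epd35()
  rec <- trial_record("a", 15, 1, 7, 30, 2, 14)
  expect_identical(decide_desr(rec, th), decide_desr(rec, th))
  for (r1 in 0:3) for (p1 in 0:12) {
    d <- decide_desr(trial_record("b", 15, r1, p1), th)
    if (d$stage1_stop) expect_identical(d$final, "accept_null")
  }
})
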