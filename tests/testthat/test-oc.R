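test_that("trinomial pmf matches closed forms and normalises", {
  expect_equal(dtrinom(1, 0, n = 1, rates = c(0.2, 0.3)), 0.2)
  expect_equal(dtrinom(1, 1, n = 2, rates = c(0.2, 0.3)), 0.12)
  # normalisation over the full lattice, including a boundary rate pair
  for (rt in list(c(0.05, 0.6), c(0.3, 0.7), c(0, 1))) {
    kr <- rep(0:15, times = 16:1)
    kp <- unlist(lapply(0:15, function(k) 0:(15 - k)))
    expect_equal(sum(dtrinom(kr, kp, 15, rt)), 1, tolerance = 1e-12)
  }
  expect_error(dtrinom(3, 4, n = 6, rates = c(0.2, 0.3)), "k_r \\+ k_p <= n")
  expect_error(dtrinom(-1, 0, n = 6, rates = c(0.2, 0.3)), "counts")
})

test_that("trinomial pmf agrees with the multinomial density across random cases", {
  set.seed(42)
  for (i in 1:50) {
    n <- sample(1:40, 1)
    p <- as.numeric(stats::rbeta(2, 1, 2))
    while (sum(p) > 1) p <- as.numeric(stats::rbeta(2, 1, 2))
    kr <- sample(0:n, 1)
    kp <- sample(0:(n - kr), 1)
    expect_equal(dtrinom(kr, kp, n, p),
                 stats::dmultinom(c(kr, kp, n - kr - kp),
                                  prob = c(p, 1 - sum(p))),
                 tolerance = 1e-12)
  }
})

test_that("stage-I stop probability is exact at degenerate rates and vs the oracle", {
  th <- design_epd46()
  expect_equal(prob_stage1_stop(th, c(0, 1)), 1)
  expect_equal(prob_stage1_stop(th, c(1, 0)), 0)
  expect_equal(prob_stage1_stop(th, c(0.05, 0.6)),
               oracle_stage1_stop(15, 1, 8, 0.05, 0.6), tolerance = 1e-12)
})

test_that("rejection probability is exact at degenerate rates and vs the oracle", {
  th <- design_epd46()
  expect_equal(prob_reject(th, c(1, 0)), 1)   # 30 responses, no stop possible
  expect_equal(prob_reject(th, c(0, 1)), 0)   # certain stage-I stop
  expect_equal(prob_reject(th, c(0.05, 0.6)),
               oracle_reject(15, 15, 1, 8, 4, 14, 0.05, 0.6),
               tolerance = 1e-12)
})

test_that("exact enumeration matches the brute-force oracle across sampled designs", {
  set.seed(7)
  for (i in 1:12) {
    n1 <- sample(2:20, 1)
    n2 <- sample(2:20, 1)
    s_r <- sample(0:n1, 1)
    s_p <- sample(0:(n1 + 1), 1)
    a_r <- sample((s_r + 1):(n1 + n2), 1)
    a_p <- sample(-1:(n1 + n2), 1)
    p_r <- stats::runif(1, 0, 0.5)
    p_p <- stats::runif(1, 0, 1 - p_r)
    d <- desr_design(n1, n2, s_r, s_p, a_r, a_p)
    expect_equal(prob_stage1_stop(d, c(p_r, p_p)),
                 oracle_stage1_stop(n1, s_r, s_p, p_r, p_p),
                 tolerance = 1e-12)
    expect_equal(prob_reject(d, c(p_r, p_p)),
                 oracle_reject(n1, n2, s_r, s_p, a_r, a_p, p_r, p_p),
                 tolerance = 1e-12)
  }
})

test_that("stage-I stopping is monotone in the outcome rates", {
  th <- design_epd35()
  grid <- seq(0.05, 0.5, by = 0.05)
  for (p_p in c(0.3, 0.5)) {
    pes <- vapply(grid, function(p_r) prob_stage1_stop(th, c(p_r, p_p)), 0)
    expect_true(all(diff(pes) <= 1e-12))     # nonincreasing in response rate
  }
  for (p_r in c(0.05, 0.2)) {
    pes <- vapply(grid, function(p_p) prob_stage1_stop(th, c(p_r, p_p)), 0)
    expect_true(all(diff(pes) >= -1e-12))    # nondecreasing in progression rate
  }
})

test_that("expected sample size obeys the early-stopping identity", {
  th <- design_epd46()
  expect_equal(expected_sample_size(th, c(0, 1)), 15)
  expect_equal(expected_sample_size(th, c(1, 0)), 30)
  for (rt in list(c(0.05, 0.6), c(0.2, 0.6), c(0.05, 0.4))) {
    expect_identical(expected_sample_size(th, rt),
                     15 + 15 * (1 - prob_stage1_stop(th, rt)))
  }
})

test_that("design-level operating characteristics compose correctly", {
  h <- hyps_epd46()
  th <- design_epd46()
  oc <- oc_desr(th, h)
  expect_equal(oc$alpha, prob_reject(th, c(0.05, 0.6)))
  expect_equal(oc$power, 0.5 * prob_reject(th, c(0.2, 0.6)) +
                 0.5 * prob_reject(th, c(0.05, 0.4)))
  expect_equal(oc$en_nul, 15 + 15 * (1 - oc$pes_nul))
  expect_equal(oc$en_alt, 15 + 15 * (1 - oc$pes_alt))
  # degenerate mixture: power collapses to the single component
  oc1 <- oc_desr(th, h, alt = alt_mixture(list(c(0.2, 0.6), c(0.05, 0.4)),
                                          weights = c(1, 0)))
  expect_equal(oc1$power, prob_reject(th, c(0.2, 0.6)))
})

test_that("single-endpoint two-stage probabilities match the binomial oracle", {
  expect_equal(oc_single_endpoint(15, 0, 15, 4, p = 0)$reject, 0)
  expect_equal(oc_single_endpoint(15, 0, 15, 4, p = 0)$pes, 1)
  expect_equal(oc_single_endpoint(15, 0, 15, 4, p = 1)$reject, 1)
  for (p in c(0.05, 0.2, 0.35)) {
    got <- oc_single_endpoint(15, 0, 15, 4, p = p)
    expect_equal(got$reject, oracle_single_endpoint_reject(15, 0, 15, 4, p),
                 tolerance = 1e-12)
    expect_equal(got$en, 15 + 15 * (1 - got$pes))
  }
  # optional early rejection shifts mass from continuation into rejection
  er <- oc_single_endpoint(15, 0, 15, 4, p = 0.3, early_reject_bound = 6)
  base <- oc_single_endpoint(15, 0, 15, 4, p = 0.3)
  expect_gte(er$pes, base$pes)
  expect_gte(er$reject, base$reject - 1e-12)
  expect_error(oc_single_endpoint(15, 4, 15, 4, p = 0.2), "accept_bound")
})
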