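# Independent brute-force oracles. These deliberately share no code with the
# package: probabilities come from stats::dmultinom / dbinom and plain nested
# loops over the outcome lattices.

oracle_trinom <- function(k_r, k_p, n, p_r, p_p) {
  stats::dmultinom(c(k_r, k_p, n - k_r - k_p), prob = c(p_r, p_p, 1 - p_r - p_p))
}

oracle_stage1_stop <- function(n1, s_r, s_p, p_r, p_p) {
  total <- 0
  for (kr in 0:n1) for (kp in 0:(n1 - kr)) {
    if (kr <= s_r && kp >= s_p)
      total <- total + oracle_trinom(kr, kp, n1, p_r, p_p)
  }
  total
}

oracle_reject <- function(n1, n2, s_r, s_p, a_r, a_p, p_r, p_p) {
  total <- 0
  for (kr in 0:n1) for (kp in 0:(n1 - kr)) {
    if (kr <= s_r && kp >= s_p) next        # stopped at stage I
    p1 <- oracle_trinom(kr, kp, n1, p_r, p_p)
    if (p1 == 0) next
    for (jr in 0:n2) for (jp in 0:(n2 - jr)) {
      if (kr + jr >= a_r || kp + jp <= a_p)
        total <- total + p1 * oracle_trinom(jr, jp, n2, p_r, p_p)
    }
  }
  total
}

oracle_single_endpoint_reject <- function(n1, accept_bound, n2,
                                          final_reject_bound, p) {
  total <- 0
  for (x1 in 0:n1) {
    if (x1 <= accept_bound) next
    for (x2 in 0:n2) {
      if (x1 + x2 >= final_reject_bound)
        total <- total + stats::dbinom(x1, n1, p) * stats::dbinom(x2, n2, p)
    }
  }
  total
}

# Exact one-sided upper conf-level binomial bound by root-finding on the
# lower-tail probability (smallest p with P(X <= x | n, p) <= 1 - conf).
oracle_binom_upper <- function(x, n, conf) {
  if (x >= n) return(1)
  stats::uniroot(function(p) stats::pbinom(x, n, p) - (1 - conf),
                 interval = c(1e-12, 1 - 1e-12), tol = 1e-12)$root
}

# Study-condition designs used across tests: bounds for the 15 + 15 layout
# under the two EPD parameter pairs.
design_epd46 <- function() desr_design(15, 15, s_r = 1, s_p = 8, a_r = 4, a_p = 14)
design_epd35 <- function() desr_design(15, 15, s_r = 1, s_p = 6, a_r = 4, a_p = 11)
hyps_epd46 <- function() dual_hypotheses(0.05, 0.2, 0.6, 0.4)
hyps_epd35 <- function() dual_hypotheses(0.05, 0.2, 0.5, 0.3)
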