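#' Trinomial probability mass function
#'
#' Probability of observing \code{k_r} responses and \code{k_p} early
#' progressions among \code{n} independent patients with per-patient outcome
#' probabilities \code{rates}. Evaluated in log space so that it is stable for
#' the sample sizes used in phase II designs (n up to a few hundred).
#' Vectorised over \code{k_r} and \code{k_p}.
#'
#' @param k_r,k_p Response and progression counts (recycled to a common length).
#' @param n Number of patients.
#' @param rates A \code{\link{trinomial_rates}} object or \code{c(p_r, p_p)}.
#' @param log Return log probabilities?
#' @return Numeric vector of probabilities.
#' @examples
#' dtrinom(1, 1, n = 2, rates = c(0.2, 0.3))  # 2 * 0.2 * 0.3 = 0.12
#' @export
dtrinom <- function(k_r, k_p, n, rates, log = FALSE) {
  rates <- as_trinomial_rates(rates)
  m <- max(length(k_r), length(k_p))
  k_r <- rep_len(as.numeric(k_r), m)
  k_p <- rep_len(as.numeric(k_p), m)
  if (any(k_r != round(k_r) | k_p != round(k_p)))
    stop("counts must be integers", call. = FALSE)
  if (any(k_r < 0 | k_p < 0 | k_r + k_p > n))
    stop("counts must satisfy 0 <= k_r, 0 <= k_p, k_r + k_p <= n", call. = FALSE)
  k_o <- n - k_r - k_p
  q <- max(0, 1 - rates$p_r - rates$p_p)
  # 0 * log(0) taken as 0: a category with probability zero contributes
  # nothing when its count is zero, -Inf otherwise
  xlg <- function(k, p) ifelse(k == 0, 0, k * base::log(p))
  lp <- lgamma(n + 1) - lgamma(k_r + 1) - lgamma(k_p + 1) - lgamma(k_o + 1) +
    xlg(k_r, rates$p_r) + xlg(k_p, rates$p_p) + xlg(k_o, q)
  if (log) lp else exp(lp)
}

# Full stage lattice pmf as an (n+1) x (n+1) matrix, [k_r + 1, k_p + 1];
# zero where k_r + k_p > n.
trinom_lattice <- function(n, rates) {
  P <- matrix(0, n + 1L, n + 1L)
  for (kr in 0:n) {
    kp <- 0:(n - kr)
    P[kr + 1L, kp + 1L] <- dtrinom(rep(kr, length(kp)), kp, n, rates)
  }
  P
}

# P(j_r <= x AND j_p >= y) over Trinomial(n, rates), as a matrix indexed by
# [x + 2, y + 1] with x in -1..n (x = -1 row is zero) and y in 0..n+1
# (y = n+1 column is zero). Fixed summation order: cumulate over responses
# first, then progressions.
trinom_joint_tail <- function(n, rates) {
  M <- trinom_lattice(n, rates)
  A <- apply(M, 2, cumsum)                       # P(j_r <= x, j_p = y)
  B <- t(apply(A, 1, function(row) rev(cumsum(rev(row)))))  # P(j_r <= x, j_p >= y)
  out <- matrix(0, n + 2L, n + 2L)
  out[2:(n + 2L), 1:(n + 1L)] <- B
  out
}

# Stage-1 stop mask over the lattice (k_r <= s_r and k_p >= s_p).
stage1_stop_mask <- function(n1, s_r, s_p) {
  kr <- matrix(0:n1, n1 + 1L, n1 + 1L)
  kp <- t(kr)
  valid <- kr + kp <= n1
  valid & kr <= s_r & kp >= s_p
}

#' Exact stage-I stopping probability of a DESR design
#'
#' Probability that a trial run under \code{design} stops at stage I, i.e.
#' that the stage-I trinomial counts land in the joint region
#' \{responses <= s_r and progressions >= s_p\}, computed by exact summation
#' over the stage-I outcome lattice.
#'
#' @param design A \code{\link{desr_design}}.
#' @param rates True per-patient outcome rates
#'   (\code{\link{trinomial_rates}} or \code{c(p_r, p_p)}).
#' @return A probability.
#' @export
prob_stage1_stop <- function(design, rates) {
  stopifnot(inherits(design, "desr_design"))
  rates <- as_trinomial_rates(rates)
  P1 <- trinom_lattice(design$n1, rates)
  sum(P1[stage1_stop_mask(design$n1, design$s_r, design$s_p)])
}

#' Exact rejection probability of a DESR design
#'
#' Probability that the trial continues past stage I and rejects the null at
#' the end of stage II (cumulative responses >= a_r or cumulative progressions
#' <= a_p). Stage-II outcomes are independent of stage-I outcomes given the
#' rates; the computation convolves the two trinomial lattices exactly.
#'
#' At the null configuration this is the type I error; weighted over an
#' alternative mixture it is the power.
#'
#' @inheritParams prob_stage1_stop
#' @return A probability.
#' @export
prob_reject <- function(design, rates) {
  stopifnot(inherits(design, "desr_design"))
  rates <- as_trinomial_rates(rates)
  n1 <- design$n1; n2 <- design$n2
  P1 <- trinom_lattice(n1, rates)
  cont <- which(!stage1_stop_mask(n1, design$s_r, design$s_p) &
                  row(P1) - 1L + col(P1) - 1L <= n1, arr.ind = TRUE)
  if (nrow(cont) == 0L) return(0)
  kr <- cont[, 1L] - 1L
  kp <- cont[, 2L] - 1L
  pr1 <- P1[cont]
  if (n2 == 0L) {
    rej <- kr >= design$a_r | kp <= design$a_p
    return(sum(pr1[rej]))
  }
  TT <- trinom_joint_tail(n2, rates)
  # Non-rejection given continuation requires j_r <= a_r - 1 - k_r AND
  # j_p >= a_p + 1 - k_p; out-of-range bounds clamp to certain/impossible.
  u <- pmax(-1L, pmin(n2, design$a_r - 1L - kr))
  v <- pmax(0L, pmin(n2 + 1L, design$a_p + 1L - kp))
  nonrej <- TT[cbind(u + 2L, v + 1L)]
  sum(pr1 * (1 - nonrej))
}

#' Exact expected sample size of a DESR design
#'
#' Expected number of patients accrued: \code{n1 + n2 * (1 - PES)}, where PES
#' is the stage-I stopping probability at the given rates.
#'
#' @inheritParams prob_stage1_stop
#' @return Expected patient count, between \code{n1} and \code{n1 + n2}.
#' @export
expected_sample_size <- function(design, rates) {
  design$n1 + design$n2 * (1 - prob_stage1_stop(design, rates))
}

#' Exact operating characteristics of a DESR design
#'
#' Computes type I error, power, stage-I stopping probability (PES) and
#' expected sample size (EN) under the null configuration and under an
#' alternative mixture, by exact enumeration over the trinomial lattices.
#'
#' The default null is the point configuration \code{(r_nul, epd_nul)}. The
#' default alternative is the borderline-value construction: a 50/50 mixture
#' of a drug at the response boundary \code{(r_alt, epd_nul)} and a drug at
#' the progression boundary \code{(r_nul, epd_alt)}, reflecting a mixed
#' population of desirable drugs that are active on one endpoint but not
#' necessarily both. Both are overridable.
#'
#' @param design A \code{\link{desr_design}}.
#' @param hypotheses A \code{\link{dual_hypotheses}}.
#' @param null Null configuration override (\code{\link{trinomial_rates}}).
#' @param alt Alternative override (\code{\link{alt_mixture}}).
#' @return An object of class \code{"desr_oc"}: list with \code{alpha},
#'   \code{power}, \code{pes_nul}, \code{en_nul}, \code{pes_alt}, \code{en_alt}.
#' @examples
#' d <- desr_design(15, 15, s_r = 1, s_p = 8, a_r = 4, a_p = 14)
#' oc_desr(d, dual_hypotheses(0.05, 0.2, 0.6, 0.4))
#' @export
oc_desr <- function(design, hypotheses, null = NULL, alt = NULL) {
  stopifnot(inherits(design, "desr_design"), inherits(hypotheses, "dual_hypotheses"))
  if (is.null(null)) null <- trinomial_rates(hypotheses$r_nul, hypotheses$epd_nul)
  null <- as_trinomial_rates(null)
  if (is.null(alt)) alt <- borderline_mixture(hypotheses)
  if (!inherits(alt, "alt_mixture"))
    stop("'alt' must be an alt_mixture", call. = FALSE)
  alpha <- prob_reject(design, null)
  pes_nul <- prob_stage1_stop(design, null)
  pow_i <- vapply(alt$components, function(r) prob_reject(design, r), 0)
  pes_i <- vapply(alt$components, function(r) prob_stage1_stop(design, r), 0)
  power <- sum(alt$weights * pow_i)
  pes_alt <- sum(alt$weights * pes_i)
  structure(list(alpha = alpha, power = power,
                 pes_nul = pes_nul,
                 en_nul = design$n1 + design$n2 * (1 - pes_nul),
                 pes_alt = pes_alt,
                 en_alt = design$n1 + design$n2 * (1 - pes_alt)),
            class = "desr_oc")
}

#' @export
print.desr_oc <- function(x, ...) {
  cat(sprintf("  alpha = %.4f, power = %.4f\n", x$alpha, x$power))
  cat(sprintf("  null: PES = %.4f, EN = %.2f;  alt: PES = %.4f, EN = %.2f\n",
              x$pes_nul, x$en_nul, x$pes_alt, x$en_alt))
  invisible(x)
}

#' Exact operating characteristics of a single-endpoint two-stage design
#'
#' The binomial analogue used by the Fleming and Gehan rules: stage I accepts
#' the null early when responses are at most \code{accept_bound} (and, when
#' enabled, rejects early at \code{early_reject_bound} or more); otherwise
#' stage II accrues and the null is rejected when cumulative responses reach
#' \code{final_reject_bound}. Probabilities are exact binomial convolutions.
#'
#' @param n1,n2 Stage sizes.
#' @param accept_bound Early-accept bound on stage-I responses.
#' @param final_reject_bound Bound on cumulative responses for final rejection.
#' @param p True per-patient response rate.
#' @param early_reject_bound Optional stage-I early-reject bound; \code{NULL}
#'   (default) disables early rejection.
#' @return List with \code{reject} (probability of rejecting the null),
#'   \code{pes} (probability of stopping at stage I) and \code{en}
#'   (expected sample size).
#' @examples
#' # Fleming-style design: continue on >= 1/15 responses, reject on >= 4/30
#' oc_single_endpoint(15, accept_bound = 0, n2 = 15, final_reject_bound = 4,
#'                    p = 0.2)
#' @export
oc_single_endpoint <- function(n1, accept_bound, n2, final_reject_bound, p,
                               early_reject_bound = NULL) {
  stopifnot(n1 >= 1, n2 >= 0, accept_bound >= -1)
  if (accept_bound >= final_reject_bound)
    stop("'accept_bound' must be below 'final_reject_bound'", call. = FALSE)
  if (!is.null(early_reject_bound) && early_reject_bound <= accept_bound)
    stop("'early_reject_bound' must exceed 'accept_bound'", call. = FALSE)
  if (final_reject_bound > n1 + n2)
    stop("'final_reject_bound' must not exceed n1 + n2", call. = FALSE)
  x1 <- 0:n1
  p1 <- stats::dbinom(x1, n1, p)
  early_accept <- x1 <= accept_bound
  early_reject <- if (is.null(early_reject_bound)) rep(FALSE, n1 + 1L) else
    x1 >= early_reject_bound
  cont <- !early_accept & !early_reject
  # P(X2 >= b - x1) for continuing stage-1 counts
  rej2 <- stats::pbinom(final_reject_bound - 1L - x1, n2, p, lower.tail = FALSE)
  reject <- sum(p1[early_reject]) + sum(p1[cont] * rej2[cont])
  pes <- sum(p1[!cont])
  list(reject = reject, pes = pes, en = n1 + n2 * (1 - pes))
}
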