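# Run code with its own RNG stream: seeds explicitly, restores the caller's
# RNG state on exit so simulation calls never leak global state.
with_local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# Vectorised cohort of DESR trials at one rate configuration: returns a
# data.frame with stage-1 counts, totals, and the rule verdicts.
sim_trials_at <- function(design, rates, n) {
  rates <- as_trinomial_rates(rates)
  pr <- c(rates$p_r, rates$p_p, max(0, 1 - rates$p_r - rates$p_p))
  s1 <- stats::rmultinom(n, design$n1, pr)
  r1 <- s1[1L, ]; p1 <- s1[2L, ]
  stop1 <- r1 <= design$s_r & p1 >= design$s_p
  s2 <- stats::rmultinom(n, design$n2, pr)
  r_tot <- r1 + s2[1L, ]; p_tot <- p1 + s2[2L, ]
  reject <- !stop1 & (r_tot >= design$a_r | p_tot <= design$a_p)
  data.frame(r1 = r1, p1 = p1,
             r_tot = ifelse(stop1, NA_integer_, r_tot),
             p_tot = ifelse(stop1, NA_integer_, p_tot),
             stage1_stop = stop1,
             final = ifelse(stop1 | !reject, "accept_null", "reject_null"),
             n_used = ifelse(stop1, design$n1, design$n1 + design$n2))
}

#' Simulate a single DESR trial
#'
#' Draws stage-I trinomial counts from the current RNG stream, applies the
#' stage-I rule, and (if the trial continues) draws stage-II counts and
#' applies the final rule. Uses the R session RNG; seed it with
#' \code{set.seed} or use \code{\link{simulate.desr_design}} /
#' \code{\link{estimate_oc_mc}} for explicitly seeded streams.
#'
#' @param design A \code{\link{desr_design}}.
#' @param rates True outcome rates.
#' @return List with \code{decision} (a \code{trial_decision}) and
#'   \code{n_used} (patients accrued: \code{n1} or \code{n1 + n2}).
#' @export
simulate_trial <- function(design, rates) {
  stopifnot(inherits(design, "desr_design"))
  rates <- as_trinomial_rates(rates)
  pr <- c(rates$p_r, rates$p_p, max(0, 1 - rates$p_r - rates$p_p))
  s1 <- stats::rmultinom(1L, design$n1, pr)
  stop1 <- s1[1L] <= design$s_r && s1[2L] >= design$s_p
  if (stop1)
    return(list(decision = trial_decision(TRUE, "accept_null"),
                n_used = design$n1))
  s2 <- stats::rmultinom(1L, design$n2, pr)
  rej <- (s1[1L] + s2[1L]) >= design$a_r || (s1[2L] + s2[2L]) <= design$a_p
  list(decision = trial_decision(FALSE, if (rej) "reject_null" else "accept_null"),
       n_used = design$n1 + design$n2)
}

#' Simulate trials from a DESR design
#'
#' \code{simulate} method: runs \code{nsim} independent trials at the given
#' outcome rates and returns their verdicts.
#'
#' @param object A \code{\link{desr_design}}.
#' @param nsim Number of trials.
#' @param seed Seed for a private RNG stream (the caller's RNG state is
#'   untouched); \code{NULL} uses the session stream.
#' @param rates True outcome rates (defaults to the design's null
#'   configuration when hypotheses are attached).
#' @param ... Unused.
#' @return Data frame with one row per trial: stage-I counts, cumulative
#'   totals (NA when stopped), \code{stage1_stop}, \code{final}, \code{n_used}.
#' @export
simulate.desr_design <- function(object, nsim = 1, seed = NULL, rates = NULL, ...) {
  if (is.null(rates)) {
    if (is.null(object$hypotheses))
      stop("supply 'rates' (design has no attached hypotheses)", call. = FALSE)
    rates <- trinomial_rates(object$hypotheses$r_nul, object$hypotheses$epd_nul)
  }
  if (is.null(seed)) sim_trials_at(object, rates, nsim)
  else with_local_seed(seed, sim_trials_at(object, rates, nsim))
}

#' Monte Carlo estimate of DESR operating characteristics
#'
#' Independent simulation-based estimator of the quantities that
#' \code{\link{oc_desr}} computes exactly: alpha and PES/EN are estimated from
#' replicate trials at the null configuration; power and the alternative
#' PES/EN from replicates whose drug class is drawn per replicate from the
#' alternative mixture (a population of drugs, not per-patient mixing).
#' Binomial standard errors accompany every estimate.
#'
#' @param design A \code{\link{desr_design}}.
#' @param hypotheses A \code{\link{dual_hypotheses}} supplying the default
#'   null and borderline mixture; either can be overridden.
#' @param null,alt Overrides as in \code{\link{oc_desr}}.
#' @param n_reps Replicates per condition (at least 1; a warning below 1000,
#'   where the normal-theory standard errors are unreliable).
#' @param seed Integer seed for the simulation's private RNG stream.
#' @return An object of class \code{"desr_sim"}: list with \code{estimates}
#'   (a \code{desr_oc}), \code{standard_errors}, \code{n_reps}, \code{seed}.
#' @export
estimate_oc_mc <- function(design, hypotheses = NULL, null = NULL, alt = NULL,
                           n_reps = 10000, seed = 1) {
  stopifnot(inherits(design, "desr_design"))
  if (n_reps < 1) stop("'n_reps' must be at least 1", call. = FALSE)
  if (n_reps < 1000)
    warning("fewer than 1000 replicates: standard errors are unreliable")
  if (is.null(null)) {
    if (is.null(hypotheses)) stop("supply 'hypotheses' or 'null'", call. = FALSE)
    null <- trinomial_rates(hypotheses$r_nul, hypotheses$epd_nul)
  }
  null <- as_trinomial_rates(null)
  if (is.null(alt)) {
    if (is.null(hypotheses)) stop("supply 'hypotheses' or 'alt'", call. = FALSE)
    alt <- borderline_mixture(hypotheses)
  }
  stopifnot(inherits(alt, "alt_mixture"))
  with_local_seed(seed, {
    sim_nul <- sim_trials_at(design, null, n_reps)
    comp <- sample.int(length(alt$components), n_reps, replace = TRUE,
                       prob = alt$weights)
    sim_alt <- do.call(rbind, lapply(seq_along(alt$components), function(j) {
      nj <- sum(comp == j)
      if (nj == 0L) NULL else sim_trials_at(design, alt$components[[j]], nj)
    }))
    prop <- function(x) mean(x)
    se_p <- function(p, n) sqrt(p * (1 - p) / n)
    alpha <- prop(sim_nul$final == "reject_null")
    power <- prop(sim_alt$final == "reject_null")
    pes_nul <- prop(sim_nul$stage1_stop)
    pes_alt <- prop(sim_alt$stage1_stop)
    est <- structure(list(alpha = alpha, power = power,
                          pes_nul = pes_nul,
                          en_nul = design$n1 + design$n2 * (1 - pes_nul),
                          pes_alt = pes_alt,
                          en_alt = design$n1 + design$n2 * (1 - pes_alt)),
                     class = "desr_oc")
    n_alt <- nrow(sim_alt)
    se <- c(alpha = se_p(alpha, n_reps), power = se_p(power, n_alt),
            pes_nul = se_p(pes_nul, n_reps),
            en_nul = design$n2 * se_p(pes_nul, n_reps),
            pes_alt = se_p(pes_alt, n_alt),
            en_alt = design$n2 * se_p(pes_alt, n_alt))
    structure(list(estimates = est, standard_errors = se,
                   n_reps = n_reps, seed = seed),
              class = "desr_sim")
  })
}

#' @export
print.desr_sim <- function(x, ...) {
  cat(sprintf("Monte Carlo operating characteristics (%d replicates, seed %d)\n",
              x$n_reps, x$seed))
  est <- unlist(unclass(x$estimates))
  out <- data.frame(estimate = est, std.error = x$standard_errors[names(est)])
  print(round(out, 4))
  invisible(x)
}

#' Generate a synthetic cohort of trial records
#'
#' Emulates a set of phase II trials all run against drugs with the same true
#' outcome rates: stage-I counts and cumulative two-stage totals are drawn
#' from the trinomial model with full accrual of both stages (as when
#' investigators continue regardless of the formal rule). The result is a
#' valid trial table that every decision and comparison function accepts.
#'
#' @param n_trials Number of trials.
#' @param rates True outcome rates shared by the cohort.
#' @param n1,n2 Stage sizes.
#' @param seed Integer seed for the private RNG stream.
#' @return Data frame in the trial-table layout (see
#'   \code{\link{read_trial_table}}).
#' @export
generate_trial_records <- function(n_trials, rates, n1, n2, seed = 1) {
  stopifnot(n_trials >= 1, n1 >= 1, n2 >= 0)
  rates <- as_trinomial_rates(rates)
  pr <- c(rates$p_r, rates$p_p, max(0, 1 - rates$p_r - rates$p_p))
  with_local_seed(seed, {
    s1 <- stats::rmultinom(n_trials, n1, pr)
    s2 <- stats::rmultinom(n_trials, n2, pr)
    data.frame(trial_id = sprintf("sim%0*d", nchar(n_trials), seq_len(n_trials)),
               n1 = n1, r1 = s1[1L, ], p1 = s1[2L, ],
               n_tot = n1 + n2,
               r_tot = s1[1L, ] + s2[1L, ],
               p_tot = s1[2L, ] + s2[2L, ],
               investigator_stopped = FALSE)
  })
}
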