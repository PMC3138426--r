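#' Gehan stage-I sample size
#'
#' Smallest stage-I size \code{n} such that a drug with true response rate
#' \code{p_interest} has probability at most \code{beta} of showing zero
#' responses in \code{n} patients: the smallest \code{n} with
#' \code{(1 - p_interest)^n <= beta}. With the classic choices of a 20\%
#' response rate of interest and beta = 0.05 this gives 14.
#'
#' @param p_interest Response rate of interest, in (0, 1).
#' @param beta Tolerated false-negative rate at stage I, in (0, 1).
#' @return Integer stage-I sample size.
#' @examples
#' gehan_stage1_size(0.2, 0.05)  # 14
#' @export
gehan_stage1_size <- function(p_interest, beta) {
  if (!is.numeric(p_interest) || length(p_interest) != 1L ||
      p_interest <= 0 || p_interest >= 1)
    stop("'p_interest' must be a rate strictly inside (0, 1)", call. = FALSE)
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 0 || beta >= 1)
    stop("'beta' must be a probability strictly inside (0, 1)", call. = FALSE)
  as.integer(ceiling(log(beta) / log(1 - p_interest)))
}

#' Gehan stage-II sample size
#'
#' Additional patients needed after stage I so that the standard error of the
#' final response-rate estimate does not exceed \code{se_target}. Gehan sized
#' stage II from the stage-I responses via a conservative estimate of the
#' response rate; here that estimate is the exact one-sided upper
#' \code{conf}-level binomial (Clopper-Pearson) bound for \code{r1/n1}, and
#' the stage-II size is \code{max(0, ceiling(p(1-p)/se_target^2 - n1))} at
#' that bound.
#'
#' @param n1 Stage-I size.
#' @param r1 Stage-I responses.
#' @param se_target Target standard error for the final rate estimate.
#' @param conf Confidence level of the upper bound (default 0.75).
#' @return Integer stage-II sample size (possibly 0).
#' @export
gehan_stage2_size <- function(n1, r1, se_target, conf = 0.75) {
  stopifnot(n1 >= 1, r1 >= 0, r1 <= n1)
  if (!is.numeric(se_target) || length(se_target) != 1L || se_target <= 0)
    stop("'se_target' must be positive", call. = FALSE)
  p_up <- binom_upper_bound(r1, n1, conf)
  as.integer(max(0, ceiling(p_up * (1 - p_up) / se_target^2 - n1)))
}

# Exact one-sided upper confidence bound for a binomial proportion
# (Clopper-Pearson): smallest p with P(X <= x | n, p) <= 1 - conf.
binom_upper_bound <- function(x, n, conf) {
  if (x >= n) return(1)
  stats::qbeta(conf, x + 1, n - x)
}

#' Fleming-style two-stage design
#'
#' Decision bounds for a single-endpoint (response only) two-stage design:
#' accept the null early when stage-I responses are at most
#' \code{accept_bound}; optionally reject early at \code{early_reject_bound};
#' otherwise reject the null at the end of stage II when cumulative responses
#' reach \code{final_reject_bound}. Bounds are taken as given (derived
#' elsewhere from the hypothesised rates and error levels), applied as
#' inclusive absolute counts.
#'
#' @param n1,n2 Stage sizes.
#' @param accept_bound Early-accept bound on stage-I responses.
#' @param final_reject_bound Cumulative-response bound for final rejection.
#' @param early_reject_bound Optional stage-I early rejection bound;
#'   \code{NULL} disables early rejection (the historical cohorts never
#'   invoked it).
#' @return An object of class \code{"fleming_design"}.
#' @examples
#' # Continue on any response in 15 patients; activity at >= 4/30 responses.
#' fleming_design(n1 = 15, accept_bound = 0, n2 = 15, final_reject_bound = 4)
#' @export
fleming_design <- function(n1, accept_bound, n2, final_reject_bound,
                           early_reject_bound = NULL) {
  stopifnot(n1 >= 1, n2 >= 0)
  if (accept_bound < 0 || accept_bound > n1)
    stop("'accept_bound' must lie in 0..n1", call. = FALSE)
  if (final_reject_bound <= accept_bound || final_reject_bound > n1 + n2)
    stop("'final_reject_bound' must satisfy accept_bound < bound <= n1 + n2",
         call. = FALSE)
  if (!is.null(early_reject_bound) &&
      (early_reject_bound <= accept_bound || early_reject_bound > n1))
    stop("'early_reject_bound' must satisfy accept_bound < bound <= n1",
         call. = FALSE)
  structure(list(n1 = as.integer(n1), accept_bound = as.integer(accept_bound),
                 n2 = as.integer(n2),
                 final_reject_bound = as.integer(final_reject_bound),
                 early_reject_bound = if (is.null(early_reject_bound)) NULL
                 else as.integer(early_reject_bound)),
            class = "fleming_design")
}

#' @export
print.fleming_design <- function(x, ...) {
  cat(sprintf("Fleming two-stage design: n1 = %d, n2 = %d\n", x$n1, x$n2))
  cat(sprintf("  stage I: accept H_nul if responses <= %d%s\n", x$accept_bound,
              if (is.null(x$early_reject_bound)) ""
              else sprintf(", reject if >= %d", x$early_reject_bound)))
  cat(sprintf("  final  : reject H_nul if cumulative responses >= %d\n",
              x$final_reject_bound))
  invisible(x)
}

#' Gehan two-stage design
#'
#' Gehan's rule stops at stage I only when no response at all is seen; the
#' stage-I size comes from \code{\link{gehan_stage1_size}} and the stage-II
#' size from the estimation-precision rule \code{\link{gehan_stage2_size}}.
#' Gehan's original proposal frames the trial as estimation and states no
#' end-of-trial activity criterion; for rule-set comparisons the final call
#' here is "active" when the cumulative observed response rate reaches
#' \code{r_alt_eval} (a configurable evaluation convention, 0.2 by default).
#'
#' @param p_interest Response rate of interest (default 0.2).
#' @param beta Stage-I false-negative rate (default 0.05).
#' @param se_target Standard-error target for the final rate estimate
#'   (default 0.05).
#' @param r_alt_eval Observed cumulative response rate treated as evidence of
#'   activity at the end of the trial (default \code{p_interest}).
#' @return An object of class \code{"gehan_design"} (includes the implied
#'   stage-I size \code{n1}).
#' @export
gehan_design <- function(p_interest = 0.2, beta = 0.05, se_target = 0.05,
                         r_alt_eval = p_interest) {
  if (se_target <= 0) stop("'se_target' must be positive", call. = FALSE)
  if (r_alt_eval <= 0 || r_alt_eval > 1)
    stop("'r_alt_eval' must lie in (0, 1]", call. = FALSE)
  n1 <- gehan_stage1_size(p_interest, beta)
  structure(list(p_interest = p_interest, beta = beta, se_target = se_target,
                 r_alt_eval = r_alt_eval, n1 = n1),
            class = "gehan_design")
}

#' @export
print.gehan_design <- function(x, ...) {
  cat(sprintf("Gehan two-stage design: p = %g, beta = %g -> n1 = %d\n",
              x$p_interest, x$beta, x$n1))
  cat(sprintf("  stage I: stop (accept H_nul) on 0 responses; stage II sized for SE <= %g\n",
              x$se_target))
  cat(sprintf("  final  : active if observed cumulative response rate >= %g\n",
              x$r_alt_eval))
  invisible(x)
}

#' @rdname decide_desr
#' @details \code{decide_fleming} applies a \code{\link{fleming_design}}:
#'   stage-I stop (accepting the null) when responses are at most the accept
#'   bound, optional early rejection, and final rejection on the cumulative
#'   response count, again as absolute counts regardless of realised accrual.
#' @export
decide_fleming <- function(record, design) {
  stopifnot(inherits(design, "fleming_design"))
  validate_trial_record(record)
  if (record$r1 <= design$accept_bound)
    return(trial_decision(TRUE, "accept_null"))
  if (!is.null(design$early_reject_bound) &&
      record$r1 >= design$early_reject_bound)
    return(trial_decision(FALSE, "reject_null"))
  if (!has_cumulative(record))
    return(trial_decision(FALSE, "indeterminate"))
  trial_decision(FALSE, if (record$r_tot >= design$final_reject_bound)
    "reject_null" else "accept_null")
}

#' @rdname decide_desr
#' @details \code{decide_gehan} applies a \code{\link{gehan_design}}:
#'   stage-I stop only on zero responses; the final activity call compares the
#'   cumulative observed response rate with \code{r_alt_eval}.
#' @export
decide_gehan <- function(record, design) {
  stopifnot(inherits(design, "gehan_design"))
  validate_trial_record(record)
  if (record$r1 == 0L)
    return(trial_decision(TRUE, "accept_null"))
  if (!has_cumulative(record))
    return(trial_decision(FALSE, "indeterminate"))
  trial_decision(FALSE,
                 if (record$r_tot / record$n_tot >= design$r_alt_eval)
                   "reject_null" else "accept_null")
}
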