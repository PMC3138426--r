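#' Trial verdicts under a rule set
#'
#' \code{decide_desr} applies a DESR design to one trial's observed counts.
#' Stage-I stopping accepts the null; otherwise the final verdict compares the
#' cumulative counts with the stage-II bounds, or is \code{"indeterminate"}
#' when the trial continued but no cumulative data exist. Bounds are applied
#' as absolute counts even when the realised total accrual differs from
#' \code{n1 + n2}, which is how under-accrued trials are judged.
#'
#' @param record A \code{\link{trial_record}}.
#' @param design A \code{\link{desr_design}}.
#' @return An object of class \code{"trial_decision"}: list with
#'   \code{stage1_stop} (logical) and \code{final} (one of
#'   \code{"accept_null"}, \code{"reject_null"}, \code{"indeterminate"}).
#' @examples
#' th <- desr_design(n1 = 15, n2 = 15, s_r = 1, s_p = 8, a_r = 4, a_p = 14)
#' # no responses, 10 early progressions: futility stop at stage I
#' decide_desr(trial_record("ex", n1 = 15, r1 = 0, p1 = 10), th)
#' @export
decide_desr <- function(record, design) {
  stopifnot(inherits(design, "desr_design"))
  validate_trial_record(record)
  stop1 <- record$r1 <= design$s_r && record$p1 >= design$s_p
  final <- if (stop1) {
    "accept_null"
  } else if (has_cumulative(record)) {
    if (record$r_tot >= design$a_r || record$p_tot <= design$a_p)
      "reject_null" else "accept_null"
  } else {
    "indeterminate"
  }
  trial_decision(stop1, final)
}

trial_decision <- function(stage1_stop, final) {
  final <- match.arg(final, c("accept_null", "reject_null", "indeterminate"))
  if (stage1_stop && final != "accept_null")
    stop("a stage-I stop always accepts the null", call. = FALSE)
  structure(list(stage1_stop = stage1_stop, final = final),
            class = "trial_decision")
}

#' @export
print.trial_decision <- function(x, ...) {
  cat(sprintf("stage I: %s; final: %s\n",
              if (x$stage1_stop) "stop (accept H_nul)" else "continue",
              sub("_null", " H_nul", x$final)))
  invisible(x)
}

# Internal dispatch so comparison code can mix rule sets freely.
rule_decision <- function(rule, record) UseMethod("rule_decision")

#' @export
rule_decision.desr_design <- function(rule, record) decide_desr(record, rule)

#' @export
rule_decision.fleming_design <- function(rule, record) decide_fleming(record, rule)

#' @export
rule_decision.gehan_design <- function(rule, record) decide_gehan(record, rule)

#' @export
rule_decision.desr_threshold_table <- function(rule, record) {
  decide_desr(record, select_design_for_record(rule, record))
}
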