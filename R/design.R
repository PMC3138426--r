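#' Dual-endpoint hypotheses for a phase II trial
#'
#' Specifies the null and alternative configurations for a single-arm trial
#' with a trinomial endpoint of tumour response and early progressive disease
#' (EPD). The drug is uninteresting (null) when the response rate is at most
#' \code{r_nul} \emph{and} the EPD rate is at least \code{epd_nul}; it is of
#' interest (alternative) when the response rate reaches \code{r_alt} \emph{or}
#' the EPD rate is down at \code{epd_alt} -- activity on either endpoint
#' suffices.
#'
#' @param r_nul,r_alt Response rates of disinterest and interest, in (0, 1),
#'   with \code{r_nul < r_alt}.
#' @param epd_nul,epd_alt Early-progression rates of disinterest and interest,
#'   in (0, 1), with \code{epd_alt < epd_nul}.
#' @return An object of class \code{"dual_hypotheses"}.
#' @examples
#' dual_hypotheses(r_nul = 0.05, r_alt = 0.2, epd_nul = 0.6, epd_alt = 0.4)
#' @export
dual_hypotheses <- function(r_nul, r_alt, epd_nul, epd_alt) {
  for (nm in c("r_nul", "r_alt", "epd_nul", "epd_alt")) {
    x <- get(nm)
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0 || x >= 1)
      stop(sprintf("'%s' must be a single rate in (0, 1)", nm), call. = FALSE)
  }
  if (r_nul >= r_alt)
    stop("'r_nul' must be smaller than 'r_alt'", call. = FALSE)
  if (epd_alt >= epd_nul)
    stop("'epd_alt' must be smaller than 'epd_nul'", call. = FALSE)
  if (r_alt + epd_nul > 1)
    stop("'r_alt' + 'epd_nul' must not exceed 1 (null configuration must be a valid trinomial)",
         call. = FALSE)
  structure(list(r_nul = r_nul, r_alt = r_alt,
                 epd_nul = epd_nul, epd_alt = epd_alt),
            class = "dual_hypotheses")
}

#' @export
print.dual_hypotheses <- function(x, ...) {
  cat("Dual-endpoint hypotheses\n")
  cat(sprintf("  H_nul: r <= %.3g and epd >= %.3g\n", x$r_nul, x$epd_nul))
  cat(sprintf("  H_alt: r >= %.3g or  epd <= %.3g\n", x$r_alt, x$epd_alt))
  invisible(x)
}

#' Per-patient trinomial outcome rates
#'
#' The outcome model for one patient: response with probability \code{p_r},
#' early progression with probability \code{p_p}, and neither (stable disease
#' or late progression) with the remaining probability.
#'
#' @param p_r Response probability, in [0, 1].
#' @param p_p Early-progression probability, in [0, 1]; \code{p_r + p_p}
#'   must not exceed 1.
#' @return An object of class \code{"trinomial_rates"}.
#' @export
trinomial_rates <- function(p_r, p_p) {
  if (!is.numeric(p_r) || length(p_r) != 1L || is.na(p_r) || p_r < 0)
    stop("'p_r' must be a single probability >= 0", call. = FALSE)
  if (!is.numeric(p_p) || length(p_p) != 1L || is.na(p_p) || p_p < 0)
    stop("'p_p' must be a single probability >= 0", call. = FALSE)
  if (p_r + p_p > 1 + 1e-12)
    stop("'p_r' + 'p_p' must not exceed 1", call. = FALSE)
  structure(list(p_r = p_r, p_p = min(p_p, 1 - p_r)),
            class = "trinomial_rates")
}

as_trinomial_rates <- function(x) {
  if (inherits(x, "trinomial_rates")) return(x)
  if (is.numeric(x) && length(x) == 2L) return(trinomial_rates(x[[1L]], x[[2L]]))
  if (is.list(x) && all(c("p_r", "p_p") %in% names(x)))
    return(trinomial_rates(x$p_r, x$p_p))
  stop("cannot interpret 'rates'; supply trinomial_rates() or c(p_r, p_p)",
       call. = FALSE)
}

#' Mixture of trinomial outcome configurations
#'
#' A weighted population of drugs, each component a
#' \code{\link{trinomial_rates}} configuration. Used as the alternative for
#' the borderline-value power construction, under which desirable drugs sit at
#' the boundary of one endpoint: a 50/50 mix of a drug with response rate
#' \code{r_alt} (and null EPD) and a drug with EPD rate \code{epd_alt} (and
#' null response).
#'
#' @param components List of \code{\link{trinomial_rates}} (or length-2
#'   numeric vectors \code{c(p_r, p_p)}).
#' @param weights Nonnegative weights summing to 1.
#' @return An object of class \code{"alt_mixture"}.
#' @seealso \code{\link{borderline_mixture}}
#' @export
alt_mixture <- function(components, weights = rep(1 / length(components), length(components))) {
  if (!is.list(components) || length(components) == 0L)
    stop("'components' must be a nonempty list", call. = FALSE)
  components <- lapply(components, as_trinomial_rates)
  if (!is.numeric(weights) || length(weights) != length(components))
    stop("'weights' must be numeric, one per component", call. = FALSE)
  if (any(weights < 0))
    stop("'weights' must be nonnegative", call. = FALSE)
  if (abs(sum(weights) - 1) > 1e-12)
    stop("'weights' must sum to 1 (tolerance 1e-12)", call. = FALSE)
  structure(list(components = components, weights = as.numeric(weights)),
            class = "alt_mixture")
}

#' @rdname alt_mixture
#' @param hypotheses A \code{\link{dual_hypotheses}} object.
#' @export
borderline_mixture <- function(hypotheses) {
  stopifnot(inherits(hypotheses, "dual_hypotheses"))
  alt_mixture(list(trinomial_rates(hypotheses$r_alt, hypotheses$epd_nul),
                   trinomial_rates(hypotheses$r_nul, hypotheses$epd_alt)),
              weights = c(0.5, 0.5))
}

#' Dual endpoint stopping rule (DESR) design
#'
#' Constructs a two-stage DESR design from its stage sizes and the four
#' integer decision bounds. The trial stops at stage I (accepting the null)
#' when stage-I responses are at most \code{s_r} \emph{and} stage-I early
#' progressions are at least \code{s_p}; otherwise stage II accrues and the
#' null is rejected when cumulative responses reach \code{a_r} \emph{or}
#' cumulative progressions are at most \code{a_p}. All bounds are inclusive
#' absolute counts.
#'
#' When \code{hypotheses} is supplied, exact operating characteristics are
#' computed (see \code{\link{oc_desr}}) and stored in the returned object.
#'
#' @param n1,n2 Stage I and stage II sample sizes.
#' @param s_r Stage-I response bound (stop if responses <= \code{s_r}).
#' @param s_p Stage-I progression bound (stop if progressions >= \code{s_p});
#'   \code{n1 + 1} encodes "never stop on progression".
#' @param a_r Final response bound (reject null if total responses >= \code{a_r}).
#' @param a_p Final progression bound (reject null if total progressions <=
#'   \code{a_p}); \code{-1} encodes "never reject on progression".
#' @param hypotheses Optional \code{\link{dual_hypotheses}}; when given,
#'   operating characteristics are attached.
#' @param null,alt Optional overrides for the null configuration and
#'   alternative mixture passed to \code{\link{oc_desr}}.
#' @return An object of class \code{"desr_design"}: a list with the stage
#'   sizes, bounds, and optionally \code{$hypotheses} and \code{$oc}.
#' @examples
#' # Design matching r (0.05 vs 0.2), epd (0.6 vs 0.4), 15 + 15 patients:
#' d <- desr_design(n1 = 15, n2 = 15, s_r = 1, s_p = 8, a_r = 4, a_p = 14,
#'                  hypotheses = dual_hypotheses(0.05, 0.2, 0.6, 0.4))
#' d
#' @export
desr_design <- function(n1, n2, s_r, s_p, a_r, a_p,
                        hypotheses = NULL, null = NULL, alt = NULL) {
  for (nm in c("n1", "n2", "s_r", "s_p", "a_r", "a_p")) {
    x <- get(nm)
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x))
      stop(sprintf("'%s' must be a single integer", nm), call. = FALSE)
  }
  n1 <- as.integer(n1); n2 <- as.integer(n2)
  s_r <- as.integer(s_r); s_p <- as.integer(s_p)
  a_r <- as.integer(a_r); a_p <- as.integer(a_p)
  if (n1 < 1L) stop("'n1' must be at least 1", call. = FALSE)
  if (n2 < 0L) stop("'n2' must be nonnegative", call. = FALSE)
  if (s_r < 0L || s_r > n1)
    stop("'s_r' must satisfy 0 <= s_r <= n1", call. = FALSE)
  if (s_p < 0L || s_p > n1 + 1L)
    stop("'s_p' must satisfy 0 <= s_p <= n1 + 1", call. = FALSE)
  if (a_r <= s_r || a_r > n1 + n2)
    stop("'a_r' must satisfy s_r < a_r <= n1 + n2", call. = FALSE)
  if (a_p < -1L || a_p > n1 + n2)
    stop("'a_p' must satisfy -1 <= a_p <= n1 + n2", call. = FALSE)
  d <- structure(list(n1 = n1, n2 = n2, s_r = s_r, s_p = s_p,
                      a_r = a_r, a_p = a_p,
                      hypotheses = hypotheses, oc = NULL),
                 class = "desr_design")
  if (!is.null(hypotheses)) {
    stopifnot(inherits(hypotheses, "dual_hypotheses"))
    d$oc <- oc_desr(d, hypotheses, null = null, alt = alt)
  }
  d
}

#' @export
print.desr_design <- function(x, ...) {
  cat("Dual endpoint stopping rule (DESR) design\n")
  cat(sprintf("  Stage I : n1 = %d; stop (accept H_nul) if responses <= %d and progressions >= %d\n",
              x$n1, x$s_r, x$s_p))
  cat(sprintf("  Stage II: n2 = %d; reject H_nul if total responses >= %d or total progressions <= %d\n",
              x$n2, x$a_r, x$a_p))
  if (!is.null(x$oc)) {
    cat("Operating characteristics (exact):\n")
    print(x$oc)
  }
  invisible(x)
}

#' @export
summary.desr_design <- function(object, ...) {
  out <- c(n1 = object$n1, n2 = object$n2, s_r = object$s_r, s_p = object$s_p,
           a_r = object$a_r, a_p = object$a_p)
  if (!is.null(object$oc))
    out <- c(out, unlist(unclass(object$oc)))
  out
}

#' Observed counts for one trial
#'
#' One trial's observed data: stage-I responses and early progressions out of
#' \code{n1} patients, and (when stage II accrued and was reported) cumulative
#' totals over both stages. Cumulative fields are all present or all absent.
#'
#' @param trial_id Label for the trial.
#' @param n1 Stage-I patient count.
#' @param r1,p1 Stage-I responses and early progressions.
#' @param n_tot,r_tot,p_tot Optional cumulative patient/response/progression
#'   totals over both stages (as printed, e.g. "13/30"), \code{NA} when the
#'   second stage did not accrue or was not reported.
#' @param investigator_stopped Was the trial halted by the investigators
#'   irrespective of the formal rule?
#' @return An object of class \code{"trial_record"}.
#' @export
trial_record <- function(trial_id, n1, r1, p1,
                         n_tot = NA_integer_, r_tot = NA_integer_,
                         p_tot = NA_integer_, investigator_stopped = FALSE) {
  rec <- structure(list(trial_id = as.character(trial_id),
                        n1 = as.integer(n1), r1 = as.integer(r1),
                        p1 = as.integer(p1),
                        n_tot = as.integer(n_tot), r_tot = as.integer(r_tot),
                        p_tot = as.integer(p_tot),
                        investigator_stopped = isTRUE(investigator_stopped)),
                   class = "trial_record")
  validate_trial_record(rec)
  rec
}

validate_trial_record <- function(rec) {
  id <- rec$trial_id
  fail <- function(field, msg)
    stop(sprintf("trial '%s': invalid '%s': %s", id, field, msg), call. = FALSE)
  if (is.na(rec$n1) || rec$n1 < 1L) fail("n1", "must be a positive count")
  if (is.na(rec$r1) || rec$r1 < 0L) fail("r1", "must be a nonnegative count")
  if (is.na(rec$p1) || rec$p1 < 0L) fail("p1", "must be a nonnegative count")
  if (rec$r1 + rec$p1 > rec$n1)
    fail("r1", sprintf("r1 + p1 = %d exceeds n1 = %d", rec$r1 + rec$p1, rec$n1))
  cum <- c(n_tot = is.na(rec$n_tot), r_tot = is.na(rec$r_tot),
           p_tot = is.na(rec$p_tot))
  if (any(cum) && !all(cum))
    fail(names(cum)[cum][1L], "cumulative fields must be all present or all absent")
  if (!any(cum)) {
    if (rec$n_tot < rec$n1) fail("n_tot", "must be at least n1")
    if (rec$r_tot < rec$r1) fail("r_tot", "must be at least r1")
    if (rec$p_tot < rec$p1) fail("p_tot", "must be at least p1")
    if (rec$r_tot + rec$p_tot > rec$n_tot)
      fail("r_tot", sprintf("r_tot + p_tot = %d exceeds n_tot = %d",
                            rec$r_tot + rec$p_tot, rec$n_tot))
  }
  invisible(rec)
}

has_cumulative <- function(rec) !is.na(rec$n_tot)

#' @export
print.trial_record <- function(x, ...) {
  cat(sprintf("Trial %s: stage I %d/%d responses, %d/%d progressions",
              x$trial_id, x$r1, x$n1, x$p1, x$n1))
  if (has_cumulative(x))
    cat(sprintf("; cumulative %d/%d responses, %d/%d progressions",
                x$r_tot, x$n_tot, x$p_tot, x$n_tot))
  if (x$investigator_stopped) cat(" [stopped by investigators]")
  cat("\n")
  invisible(x)
}
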