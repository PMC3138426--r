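#' Search for DESR thresholds meeting alpha and power constraints
#'
#' Exhaustively enumerates the four decision bounds over their full ranges
#' (\code{s_r} in 0..n1; \code{s_p} in 0..n1+1, where n1+1 means "never stop on
#' progression"; \code{a_r} in s_r+1..n1+n2; \code{a_p} in -1..n1+n2, where -1
#' means "never reject on progression"), computes exact operating
#' characteristics for every candidate under the borderline-value alternative
#' (see \code{\link{oc_desr}}), keeps those with type I error at most
#' \code{alpha_max} and power at least \code{power_min}, and returns the
#' candidate preferred by the ordered selection criteria. The default
#' selection maximises the probability of early stopping under the null, then
#' minimises the null expected sample size, then maximises power; remaining
#' ties break on the fixed enumeration order, so the search is deterministic.
#'
#' @param hypotheses A \code{\link{dual_hypotheses}}.
#' @param n1,n2 Stage sizes.
#' @param alpha_max Maximum tolerated type I error (default 0.05).
#' @param power_min Minimum required power (default 0.8).
#' @param null,alt Optional overrides of the null configuration and
#'   alternative mixture (defaults as in \code{\link{oc_desr}}).
#' @param selection Ordered preference criteria among feasible candidates;
#'   a character vector drawn from \code{"pes_nul"}, \code{"en_nul"},
#'   \code{"power"}, \code{"alpha"}, \code{"pes_alt"}, \code{"en_alt"}.
#' @return A \code{\link{desr_design}} with operating characteristics
#'   attached, or an object of class \code{"desr_infeasible"} when no
#'   candidate meets the constraints.
#' @examples
#' \donttest{
#' desr_search(dual_hypotheses(0.05, 0.2, 0.6, 0.4), n1 = 15, n2 = 15)
#' }
#' @export
desr_search <- function(hypotheses, n1, n2, alpha_max = 0.05, power_min = 0.8,
                        null = NULL, alt = NULL,
                        selection = c("pes_nul", "en_nul", "power")) {
  stopifnot(inherits(hypotheses, "dual_hypotheses"))
  if (!is.numeric(n1) || length(n1) != 1L || n1 < 1 || n1 != round(n1))
    stop("'n1' must be a positive integer", call. = FALSE)
  if (!is.numeric(n2) || length(n2) != 1L || n2 < 1 || n2 != round(n2))
    stop("'n2' must be a positive integer", call. = FALSE)
  if (alpha_max <= 0 || alpha_max >= 1 || power_min <= 0 || power_min >= 1)
    stop("'alpha_max' and 'power_min' must lie in (0, 1)", call. = FALSE)
  n1 <- as.integer(n1); n2 <- as.integer(n2)
  if (is.null(null)) null <- trinomial_rates(hypotheses$r_nul, hypotheses$epd_nul)
  null <- as_trinomial_rates(null)
  if (is.null(alt)) alt <- borderline_mixture(hypotheses)
  stopifnot(inherits(alt, "alt_mixture"))
  crit <- match.arg(selection, c("pes_nul", "en_nul", "power", "alpha",
                                 "pes_alt", "en_alt"), several.ok = TRUE)
  # direction: +1 maximise, -1 minimise
  dir <- c(pes_nul = 1, en_nul = -1, power = 1, alpha = -1,
           pes_alt = 1, en_alt = -1)[crit]

  rate_list <- c(list(null), alt$components)
  w_alt <- alt$weights
  nr <- length(rate_list)
  P1 <- lapply(rate_list, function(r) trinom_lattice(n1, r))
  TT <- lapply(rate_list, function(r) trinom_joint_tail(n2, r))

  KR <- matrix(0:n1, n1 + 1L, n1 + 1L)
  KP <- t(KR)
  valid <- KR + KP <= n1
  a_p_grid <- (-1L):(n1 + n2)
  n_ap <- length(a_p_grid)

  best <- NULL   # list(design fields, oc fields, key)
  key_of <- function(oc) dir * unlist(oc)[crit]
  better <- function(key, ref) {
    d <- key - ref
    i <- which(abs(d) > 1e-12)
    length(i) > 0L && d[i[1L]] > 0
  }

  for (s_r in 0:n1) {
    for (s_p in 0:(n1 + 1L)) {
      stop_mask <- valid & KR <= s_r & KP >= s_p
      cont_mask <- valid & !stop_mask
      idx <- which(cont_mask, arr.ind = TRUE)
      kr <- idx[, 1L] - 1L
      kp <- idx[, 2L] - 1L
      ns <- length(kr)
      pes <- vapply(P1, function(P) sum(P[stop_mask]), 0)
      pcont <- lapply(P1, function(P) P[cont_mask])
      # column index into the stage-2 joint-tail matrix for every
      # (state, a_p) pair; constant across a_r
      vcol <- pmax(0L, pmin(n2 + 1L, outer(-kp, a_p_grid + 1L, `+`))) + 1L
      flat <- cbind(rep.int(seq_len(ns), n_ap), as.vector(vcol))
      for (a_r in (s_r + 1L):(n1 + n2)) {
        u <- pmax(-1L, pmin(n2, a_r - 1L - kr))
        rej <- matrix(0, nr, n_ap)
        for (j in seq_len(nr)) {
          R <- TT[[j]][u + 2L, , drop = FALSE]
          nonrej <- .colSums(pcont[[j]] * matrix(R[flat], ns, n_ap), ns, n_ap)
          rej[j, ] <- (1 - pes[j] - nonrej)
        }
        alpha_v <- rej[1L, ]
        power_v <- as.numeric(w_alt %*% rej[-1L, , drop = FALSE])
        ok <- which(alpha_v <= alpha_max & power_v >= power_min)
        for (m in ok) {
          oc <- list(alpha = alpha_v[m], power = power_v[m],
                     pes_nul = pes[1L], en_nul = n1 + n2 * (1 - pes[1L]),
                     pes_alt = sum(w_alt * pes[-1L]),
                     en_alt = n1 + n2 * (1 - sum(w_alt * pes[-1L])))
          key <- key_of(oc)
          if (is.null(best) || better(key, best$key)) {
            best <- list(s_r = s_r, s_p = s_p, a_r = a_r,
                         a_p = a_p_grid[m], oc = oc, key = key)
          }
        }
      }
    }
  }
  if (is.null(best)) {
    return(structure(list(hypotheses = hypotheses, n1 = n1, n2 = n2,
                          alpha_max = alpha_max, power_min = power_min),
                     class = "desr_infeasible"))
  }
  d <- desr_design(n1, n2, best$s_r, best$s_p, best$a_r, best$a_p)
  d$hypotheses <- hypotheses
  d$oc <- structure(best$oc, class = "desr_oc")
  d
}

#' @export
print.desr_infeasible <- function(x, ...) {
  cat(sprintf(paste0("No DESR thresholds with n1 = %d, n2 = %d attain ",
                     "alpha <= %g and power >= %g under the given hypotheses.\n"),
              x$n1, x$n2, x$alpha_max, x$power_min))
  invisible(x)
}

#' Derive a table of DESR designs across stage-II sizes
#'
#' Runs \code{\link{desr_search}} once per entry of \code{n2_list} and binds
#' the resulting thresholds and operating characteristics into a data frame,
#' one row per stage-II size. Infeasible searches are flagged in the
#' \code{feasible} column, never silently dropped. This mirrors the situation
#' where a fixed stage-I size must be matched to trials whose realised
#' stage-II accrual varied.
#'
#' @inheritParams desr_search
#' @param n2_list Vector of stage-II sizes (one output row each).
#' @return A data frame of class \code{"desr_threshold_table"} with columns
#'   \code{n1, n2, s_r, s_p, a_r, a_p, alpha, power, pes_nul, en_nul,
#'   pes_alt, en_alt, feasible}.
#' @export
desr_derive_table <- function(hypotheses, n1, n2_list, alpha_max = 0.05,
                              power_min = 0.8, null = NULL, alt = NULL,
                              selection = c("pes_nul", "en_nul", "power")) {
  if (length(n2_list) == 0L)
    stop("'n2_list' must be nonempty", call. = FALSE)
  rows <- lapply(n2_list, function(n2) {
    res <- desr_search(hypotheses, n1, n2, alpha_max, power_min,
                       null = null, alt = alt, selection = selection)
    if (inherits(res, "desr_infeasible")) {
      data.frame(n1 = n1, n2 = n2, s_r = NA_integer_, s_p = NA_integer_,
                 a_r = NA_integer_, a_p = NA_integer_,
                 alpha = NA_real_, power = NA_real_,
                 pes_nul = NA_real_, en_nul = NA_real_,
                 pes_alt = NA_real_, en_alt = NA_real_, feasible = FALSE)
    } else {
      data.frame(n1 = res$n1, n2 = res$n2, s_r = res$s_r, s_p = res$s_p,
                 a_r = res$a_r, a_p = res$a_p,
                 alpha = res$oc$alpha, power = res$oc$power,
                 pes_nul = res$oc$pes_nul, en_nul = res$oc$en_nul,
                 pes_alt = res$oc$pes_alt, en_alt = res$oc$en_alt,
                 feasible = TRUE)
    }
  })
  out <- do.call(rbind, rows)
  class(out) <- c("desr_threshold_table", "data.frame")
  out
}
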