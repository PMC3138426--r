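#' Pick the threshold-table row matching a trial's realised accrual
#'
#' Historical cohorts accrued varying stage-II sizes, so DESR bounds were
#' derived per study size and the row whose \code{n2} equals the trial's
#' realised stage-II accrual (\code{n_tot - n1}) is applied, with bounds
#' read as absolute counts. A trial without cumulative data never reached a
#' final verdict, so only the stage-I bounds matter; such a trial is matched
#' to the first row provided the stage-I bounds are constant across the table
#' (as they are in derived tables with fixed \code{n1}).
#'
#' @param table A \code{"desr_threshold_table"} data frame (from
#'   \code{\link{desr_derive_table}} or \code{\link{read_threshold_table}}).
#' @param record A \code{\link{trial_record}}.
#' @return A \code{\link{desr_design}} built from the matching row.
#' @export
select_design_for_record <- function(table, record) {
  stopifnot(inherits(table, "data.frame"))
  validate_trial_record(record)
  tab <- table[is.na(table$s_r) == FALSE, , drop = FALSE]
  if (nrow(tab) == 0L) stop("threshold table has no feasible rows", call. = FALSE)
  if (!has_cumulative(record)) {
    if (length(unique(tab$s_r)) > 1L || length(unique(tab$s_p)) > 1L)
      stop(sprintf(paste0("trial '%s' has no cumulative data and the table's ",
                          "stage-I bounds vary across rows"), record$trial_id),
           call. = FALSE)
    row <- tab[1L, ]
  } else {
    n2_sought <- record$n_tot - record$n1
    hit <- which(tab$n2 == n2_sought)
    if (length(hit) == 0L)
      stop(sprintf("no threshold row with n2 = %d for trial '%s'",
                   n2_sought, record$trial_id), call. = FALSE)
    row <- tab[hit[1L], ]
  }
  desr_design(row$n1, row$n2, row$s_r, row$s_p, row$a_r, row$a_p)
}

as_record_list <- function(records) {
  if (inherits(records, "trial_record")) return(list(records))
  if (is.data.frame(records)) {
    return(lapply(seq_len(nrow(records)), function(i) {
      r <- records[i, ]
      trial_record(r$trial_id, r$n1, r$r1, r$p1,
                   n_tot = if ("n_tot" %in% names(r)) r$n_tot else NA,
                   r_tot = if ("r_tot" %in% names(r)) r$r_tot else NA,
                   p_tot = if ("p_tot" %in% names(r)) r$p_tot else NA,
                   investigator_stopped =
                     if ("investigator_stopped" %in% names(r))
                       isTRUE(r$investigator_stopped) else FALSE)
    }))
  }
  if (is.list(records) && all(vapply(records, inherits, TRUE, "trial_record")))
    return(records)
  stop("'records' must be a trial table data frame or a list of trial_record",
       call. = FALSE)
}

#' Compare rule sets over a cohort of trials
#'
#' Applies each rule set (DESR designs or threshold tables, Fleming designs,
#' Gehan designs) to every trial in the cohort and tabulates per-trial
#' verdicts plus the summary counts used to contrast the rules: stage-I stops
#' and final rejections per rule, pairwise counts of trials stopped by one
#' rule but allowed to continue by another, and pairwise agreement of final
#' verdicts. An indeterminate verdict (trial continued but no stage-II data)
#' disagrees with a determinate one and agrees with another indeterminate.
#'
#' @param records A trial table (data frame, see
#'   \code{\link{read_trial_table}}) or list of \code{\link{trial_record}}.
#' @param rule_sets Named list; each element a \code{\link{desr_design}}, a
#'   threshold table, a \code{\link{fleming_design}} or a
#'   \code{\link{gehan_design}}.
#' @return An object of class \code{"desr_comparison"}: list with
#'   \code{per_trial} (data frame: trial_id, investigator_stopped, and
#'   \code{<rule>_stage1_stop} / \code{<rule>_final} per rule) and
#'   \code{summaries} (list of the counts above).
#' @export
compare_cohort <- function(records, rule_sets) {
  recs <- as_record_list(records)
  if (length(recs) == 0L) stop("'records' must be nonempty", call. = FALSE)
  if (!is.list(rule_sets) || is.null(names(rule_sets)) ||
      any(names(rule_sets) == ""))
    stop("'rule_sets' must be a fully named list", call. = FALSE)
  rn <- names(rule_sets)
  per <- data.frame(
    trial_id = vapply(recs, `[[`, "", "trial_id"),
    investigator_stopped = vapply(recs, `[[`, TRUE, "investigator_stopped"))
  for (nm in rn) {
    dec <- lapply(recs, function(rec) {
      tryCatch(rule_decision(rule_sets[[nm]], rec),
               error = function(e) stop(sprintf("rule '%s', trial '%s': %s",
                                                nm, rec$trial_id,
                                                conditionMessage(e)),
                                        call. = FALSE))
    })
    per[[paste0(nm, "_stage1_stop")]] <- vapply(dec, `[[`, TRUE, "stage1_stop")
    per[[paste0(nm, "_final")]] <- vapply(dec, `[[`, "", "final")
  }
  structure(list(per_trial = per,
                 summaries = summarise_comparison(per, rn)),
            class = "desr_comparison")
}

summarise_comparison <- function(per, rn) {
  stops <- vapply(rn, function(nm) sum(per[[paste0(nm, "_stage1_stop")]]), 0L)
  rejs <- vapply(rn, function(nm)
    sum(per[[paste0(nm, "_final")]] == "reject_null"), 0L)
  k <- length(rn)
  stopped_continued <- matrix(0L, k, k, dimnames = list(stopped_by = rn,
                                                        continued_by = rn))
  agreement <- matrix(NA_integer_, k, k, dimnames = list(rn, rn))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    si <- per[[paste0(rn[i], "_stage1_stop")]]
    sj <- per[[paste0(rn[j], "_stage1_stop")]]
    stopped_continued[i, j] <- sum(si & !sj)
    agreement[i, j] <- sum(per[[paste0(rn[i], "_final")]] ==
                             per[[paste0(rn[j], "_final")]])
  }
  list(n_trials = nrow(per),
       stage1_stops = stops,
       final_rejections = rejs,
       stopped_but_continued_by = stopped_continued,
       final_agreement = agreement,
       investigator_stopped = sum(per$investigator_stopped))
}

#' @export
print.desr_comparison <- function(x, ...) {
  s <- x$summaries
  cat(sprintf("Rule-set comparison over %d trials\n", s$n_trials))
  cat("  stage-I stops:   ",
      paste(sprintf("%s = %d", names(s$stage1_stops), s$stage1_stops),
            collapse = ", "), "\n")
  cat("  final rejections:",
      paste(sprintf("%s = %d", names(s$final_rejections), s$final_rejections),
            collapse = ", "), "\n")
  if (s$investigator_stopped > 0)
    cat(sprintf("  trials stopped by investigators: %d\n",
                s$investigator_stopped))
  invisible(x)
}

#' @export
summary.desr_comparison <- function(object, ...) object$summaries
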