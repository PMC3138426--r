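#' Read and write trial count tables
#'
#' Trial tables are UTF-8 comma-delimited files with a mandatory header and
#' one row per trial: \code{trial_id, n1, r1, p1, n_tot, r_tot, p_tot,
#' investigator_stopped}. Cumulative columns are blank (missing) for trials
#' whose second stage never accrued or was not reported; counts are stored as
#' integers with their explicit denominators (\code{n1}, \code{n_tot}),
#' matching the "13/30"-style presentation of historical trial listings.
#' Every row is validated against the trial-record invariants on read.
#'
#' @param path File path.
#' @return \code{read_trial_table}: a data frame of validated records, in
#'   file order.
#' @seealso \code{\link{desr_fixture}} for the packaged cohorts.
#' @export
read_trial_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: '%s'", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(trial_id = "character"))
  need <- c("trial_id", "n1", "r1", "p1")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop(sprintf("trial table '%s' lacks required column(s): %s",
                 path, paste(miss, collapse = ", ")), call. = FALSE)
  for (col in c("n_tot", "r_tot", "p_tot"))
    if (!col %in% names(df)) df[[col]] <- NA_integer_
  if (!"investigator_stopped" %in% names(df)) df$investigator_stopped <- FALSE
  df$investigator_stopped <- as.logical(df$investigator_stopped)
  for (i in seq_len(nrow(df))) {
    rec <- tryCatch(
      trial_record(df$trial_id[i], df$n1[i], df$r1[i], df$p1[i],
                   df$n_tot[i], df$r_tot[i], df$p_tot[i],
                   df$investigator_stopped[i]),
      error = function(e)
        stop(sprintf("%s, line %d: %s", path, i + 1L, conditionMessage(e)),
             call. = FALSE))
  }
  df[c("trial_id", "n1", "r1", "p1", "n_tot", "r_tot", "p_tot",
       "investigator_stopped")]
}

#' @rdname read_trial_table
#' @param records Trial table data frame (or list of
#'   \code{\link{trial_record}}).
#' @return \code{write_trial_table}: \code{path}, invisibly.
#' @export
write_trial_table <- function(records, path) {
  recs <- as_record_list(records)
  df <- do.call(rbind, lapply(recs, function(r)
    data.frame(trial_id = r$trial_id, n1 = r$n1, r1 = r$r1, p1 = r$p1,
               n_tot = r$n_tot, r_tot = r$r_tot, p_tot = r$p_tot,
               investigator_stopped = r$investigator_stopped)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read and write DESR threshold tables
#'
#' Threshold tables are comma-delimited files with columns \code{n1, n2, s_r,
#' s_p, a_r, a_p} and optionally the operating-characteristic columns
#' \code{power, alpha, en_nul, pes_nul, en_alt, pes_alt} plus the hypothesis
#' rates. One row per study size, as produced by
#' \code{\link{desr_derive_table}}.
#'
#' @param path File path.
#' @return A data frame of class \code{"desr_threshold_table"}.
#' @export
read_threshold_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: '%s'", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("n1", "n2", "s_r", "s_p", "a_r", "a_p")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop(sprintf("threshold table '%s' lacks column(s): %s",
                 path, paste(miss, collapse = ", ")), call. = FALSE)
  for (i in seq_len(nrow(df)))
    if (!is.na(df$s_r[i]))
      desr_design(df$n1[i], df$n2[i], df$s_r[i], df$s_p[i], df$a_r[i], df$a_p[i])
  class(df) <- c("desr_threshold_table", "data.frame")
  df
}

#' @rdname read_threshold_table
#' @param table Threshold table data frame.
#' @export
write_threshold_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}

#' Packaged fixtures: historical cohorts and their DESR threshold tables
#'
#' The package ships the observed count data of two historical phase II
#' cohorts and the DESR threshold tables derived to match them:
#' \describe{
#'   \item{\code{"fleming_cohort"}}{16 NCIC trials run under a Fleming design
#'     (continue on >= 1/15 responses; activity at >= 4/30 cumulative
#'     responses).}
#'   \item{\code{"gehan_cohort"}}{23 EORTC trials run under the Gehan design
#'     (n1 = 14; stop only on zero responses).}
#'   \item{\code{"thresholds_fleming"}}{DESR bounds for the 15 + 15 layout,
#'     one row per EPD parameter pair ((0.4, 0.6) and (0.3, 0.5)).}
#'   \item{\code{"thresholds_gehan_epd_0.4_0.6"},
#'     \code{"thresholds_gehan_epd_0.3_0.5"}}{DESR bounds matched to the
#'     realised stage-II accruals of the Gehan cohort, one row per study
#'     size, for each EPD parameter pair.}
#' }
#'
#' @param name Fixture name (see above); with no argument, lists the
#'   available names.
#' @return File path of the fixture, or a character vector of names.
#' @examples
#' cohort <- read_trial_table(desr_fixture("gehan_cohort"))
#' nrow(cohort)  # 23
#' @export
desr_fixture <- function(name = NULL) {
  files <- c(fleming_cohort = "fleming_cohort.csv",
             gehan_cohort = "gehan_cohort.csv",
             thresholds_fleming = "thresholds_fleming.csv",
             "thresholds_gehan_epd_0.4_0.6" = "thresholds_gehan_epd_0.4_0.6.csv",
             "thresholds_gehan_epd_0.3_0.5" = "thresholds_gehan_epd_0.3_0.5.csv")
  if (is.null(name)) return(names(files))
  if (!name %in% names(files))
    stop(sprintf("unknown fixture '%s'; available: %s", name,
                 paste(names(files), collapse = ", ")), call. = FALSE)
  path <- system.file("extdata", files[[name]], package = "desr")
  if (path == "") stop("fixture files not installed", call. = FALSE)
  path
}
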