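# Per-visit score tables and the cyst score rate of change between
# consecutive visits.

DAYS_PER_YEAR <- 365.25

#' Validate a visit table
#'
#' A visit table has one row per (patient, visit date, method) with the
#' cyst score and optional pulmonary-function values, all in percent of
#' predicted: `fev1_pp` (forced expiratory volume in 1 s), `fev1_fvc_pp`
#' (its ratio to forced vital capacity) and `dlco_adj_pp`
#' (hemoglobin-adjusted CO diffusion capacity).
#'
#' @param visits data frame with columns `patient_id`, `visit_date`
#'   (`Date` or ISO-8601 string), `method`, `score_pct` and optionally
#'   `fev1_pp`, `fev1_fvc_pp`, `dlco_adj_pp`.
#' @return The table with `visit_date` converted to `Date`, invisibly
#'   checked.
#' @export
as_visit_table <- function(visits) {
  need <- c("patient_id", "visit_date", "method", "score_pct")
  miss <- setdiff(need, names(visits))
  if (length(miss)) stop("visit table lacks columns: ", paste(miss, collapse = ", "))
  visits$visit_date <- as.Date(visits$visit_date)
  if (any(is.na(visits$visit_date))) stop("unparseable visit_date values")
  if (any(visits$score_pct < 0 | visits$score_pct > 100))
    stop("score_pct must lie in [0, 100]")
  for (p in c("fev1_pp", "fev1_fvc_pp", "dlco_adj_pp")) {
    if (p %in% names(visits) && any(visits[[p]] <= 0, na.rm = TRUE))
      stop(p, " must be positive when present")
  }
  key <- paste(visits$patient_id, visits$visit_date, visits$method)
  if (anyDuplicated(key))
    stop("duplicate (patient_id, visit_date, method) rows in visit table")
  visits
}

#' Read a visit table from CSV
#'
#' @param path CSV with header `patient_id, visit_date, method, score_pct`
#'   and optional PFT columns; dates in ISO-8601.
#' @return A validated visit data frame.
#' @export
read_visits <- function(path) {
  as_visit_table(read.csv(path, stringsAsFactors = FALSE))
}

#' Rate of change of the cyst score between two visits
#'
#' `(later score - earlier score) / elapsed years`, with a 365.25-day
#' year. Both records must belong to the same patient and method and the
#' later visit must be strictly after the earlier one.
#'
#' @param earlier,later single visit records: one-row data frames or lists
#'   with `patient_id`, `visit_date`, `method`, `score_pct`.
#' @return A one-row data frame with `patient_id`, `rate` (% per year),
#'   `interval_months` and `method`.
#' @examples
#' a <- list(patient_id = "p1", visit_date = "2022-01-01",
#'           method = "automatic", score_pct = 10)
#' b <- list(patient_id = "p1", visit_date = "2023-04-02",
#'           method = "automatic", score_pct = 12)
#' rate_of_change(a, b)$rate  # 2 points over ~15 months = 1.6 %/year
#' @export
rate_of_change <- function(earlier, later) {
  e_date <- as.Date(earlier$visit_date); l_date <- as.Date(later$visit_date)
  if (!identical(as.character(earlier$patient_id), as.character(later$patient_id)))
    stop("visits belong to different patients")
  if (!identical(as.character(earlier$method), as.character(later$method)))
    stop("visits were scored with different methods")
  days <- as.numeric(l_date - e_date)
  if (days <= 0) stop("later visit must be strictly after the earlier visit")
  dyears <- days / DAYS_PER_YEAR
  data.frame(
    patient_id = as.character(earlier$patient_id),
    rate = (later$score_pct - earlier$score_pct) / dyears,
    interval_months = days / (DAYS_PER_YEAR / 12),
    method = as.character(earlier$method),
    stringsAsFactors = FALSE
  )
}

#' Per-patient rates of change from the two most recent visits
#'
#' For each patient with at least two visits under the selected method,
#' computes the rate of change between the two most recent visits by
#' date. Patients with fewer than two visits are skipped; their count is
#' reported in attribute `n_skipped` and via a message.
#'
#' @param visits a visit table (see [as_visit_table()]).
#' @param method method tag to select.
#' @return Data frame of per-patient rates (see [rate_of_change()]) with
#'   attribute `n_skipped`.
#' @export
cohort_rates <- function(visits, method) {
  visits <- as_visit_table(visits)
  visits <- visits[visits$method == method, , drop = FALSE]
  if (nrow(visits) == 0L) stop("no visits for method ", method)
  out <- list(); skipped <- 0L
  for (pid in unique(visits$patient_id)) {
    v <- visits[visits$patient_id == pid, , drop = FALSE]
    if (nrow(v) < 2L) { skipped <- skipped + 1L; next }
    v <- v[order(v$visit_date), , drop = FALSE]
    n <- nrow(v)
    out[[length(out) + 1L]] <- rate_of_change(v[n - 1L, ], v[n, ])
  }
  if (length(out) == 0L) stop("no patient has two or more visits for method ", method)
  if (skipped > 0L)
    message(skipped, " patient(s) with fewer than two visits were skipped")
  res <- do.call(rbind, out)
  attr(res, "n_skipped") <- skipped
  res
}
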