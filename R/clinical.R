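# VAS pain and HADS anxiety/depression scores: ingestion, descriptive
# summaries, permutation comparisons, and MCID flagging.
#
# A clinical table is a pair of data.frames:
#   sessions: patient, session, vas_pre, vas_post   (one row per recording
#             session; VAS integers 0-10, NA allowed for missing sessions)
#   patients: patient, age, sex, burn_type, severity, hads_anx_first,
#             hads_anx_last, hads_dep_first, hads_dep_last
#             (HADS subscales 0-21; *_last may be NA when the patient left
#             before the final timepoint)

MCID_VAS <- 1.4
MCID_HADS <- 1.7

# Descriptive SDs of clinical scores use the population (N) denominator,
# matching the study's printed Table-3 values (e.g. VAS change SD 1.55).
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

validate_clinical <- function(tab) {
  stopifnot(is.list(tab), all(c("sessions", "patients") %in% names(tab)))
  s <- tab$sessions; p <- tab$patients
  stopifnot(all(c("patient", "session", "vas_pre", "vas_post") %in% names(s)),
            all(c("patient", "age", "sex", "severity", "hads_anx_first",
                  "hads_anx_last", "hads_dep_first", "hads_dep_last")
                %in% names(p)))
  vas <- c(s$vas_pre, s$vas_post)
  if (any(vas < 0 | vas > 10, na.rm = TRUE)) stop("VAS outside [0, 10]")
  hads <- unlist(p[, c("hads_anx_first", "hads_anx_last",
                       "hads_dep_first", "hads_dep_last")])
  if (any(hads < 0 | hads > 21, na.rm = TRUE)) stop("HADS outside [0, 21]")
  if (!all(p$severity %in% 1:3)) stop("severity must be 1, 2 or 3")
  invisible(tab)
}

#' Read a clinical-scores table from TSV files
#'
#' @param sessions_path TSV with one row per patient-session (`patient`,
#'   `session`, `vas_pre`, `vas_post`).
#' @param patients_path TSV with one row per patient (`patient`, `age`,
#'   `sex`, `burn_type`, `severity`, `hads_anx_first`, `hads_anx_last`,
#'   `hads_dep_first`, `hads_dep_last`).
#' @return validated clinical table (list `sessions`, `patients`).
#' @export
read_clinical_table <- function(sessions_path, patients_path) {
  tab <- list(sessions = utils::read.delim(sessions_path),
              patients = utils::read.delim(patients_path))
  validate_clinical(tab)
}

#' The clinical scores of the nine-patient observational study
#'
#' Per-patient demographics and the per-session VAS / per-patient HADS scores
#' printed in the study this package reimplements, shipped as plain TSV under
#' `inst/extdata` so the published summary statistics can be recomputed.
#'
#' @return clinical table (list `sessions`, `patients`).
#' @export
study_clinical_table <- function() {
  read_clinical_table(
    system.file("extdata", "study_clinical_sessions.tsv",
                package = "marphysio", mustWork = TRUE),
    system.file("extdata", "study_clinical_patients.tsv",
                package = "marphysio", mustWork = TRUE))
}

#' Demographic summary
#'
#' @param tab a clinical table.
#' @return list with `mean_age` (1 decimal), `age_range`, `n_patients`, and
#'   `sex_percent` (named, 1 decimal).
#' @export
summarize_demographics <- function(tab) {
  validate_clinical(tab)
  p <- tab$patients
  stopifnot(nrow(p) >= 1L)
  sexes <- table(p$sex)
  list(mean_age = round(mean(p$age), 1),
       age_range = range(p$age),
       n_patients = nrow(p),
       sex_percent = round(100 * as.numeric(sexes) / nrow(p), 1) |>
         stats::setNames(names(sexes)))
}

#' VAS pain summary with permutation comparison
#'
#' Each recording session with both measurements is one unit; the change is
#' `post - pre` per session. The p-value is the unpaired permutation test of
#' the PRE vs POST means. A per-patient averaged summary is also returned.
#'
#' @param tab a clinical table (>= 2 complete sessions).
#' @param n_perm,seed permutation-test configuration.
#' @return list with pre/post/change mean, SD and range, `p`, `n_sessions`,
#'   `mcid_reached` (|mean change| >= 1.4), and `by_patient` means.
#' @export
summarize_vas <- function(tab, n_perm = 1600L, seed = 1L) {
  validate_clinical(tab)
  s <- tab$sessions
  s <- s[!is.na(s$vas_pre) & !is.na(s$vas_post), ]
  if (nrow(s) < 2L) stop("no-data: need >= 2 sessions with both VAS values")
  change <- s$vas_post - s$vas_pre
  pt <- permutation_test(s$vas_pre, s$vas_post, n_perm = n_perm,
                         seed = derive_seed(seed, "vas"))
  per_patient <- stats::aggregate(cbind(vas_pre, vas_post) ~ patient,
                                  data = s, FUN = mean)
  list(pre = list(mean = mean(s$vas_pre), sd = pop_sd(s$vas_pre),
                  range = range(s$vas_pre)),
       post = list(mean = mean(s$vas_post), sd = pop_sd(s$vas_post),
                   range = range(s$vas_post)),
       change = list(mean = mean(change), sd = pop_sd(change),
                     range = range(change)),
       p = pt$p, n_sessions = nrow(s),
       mcid_reached = abs(mean(change)) >= MCID_VAS,
       by_patient = per_patient)
}

#' HADS summary with permutation comparison and MCID flag
#'
#' Change is `last - first` per patient; patients missing the last timepoint
#' are excluded (and counted). The total scale is the sum of the two
#' subscales, so on complete data its summaries equal the subscale sums
#' exactly.
#'
#' @param tab a clinical table (>= 2 patients with both timepoints).
#' @param n_perm,seed permutation-test configuration.
#' @return list with one element per scale (`anxiety`, `depression`,
#'   `total`): first/last means, change mean and SD, `p`, `mcid_reached`
#'   (|mean change| >= 1.7); plus `n_included` and `n_excluded`.
#' @export
summarize_hads <- function(tab, n_perm = 1600L, seed = 1L) {
  validate_clinical(tab)
  p <- tab$patients
  complete <- !is.na(p$hads_anx_last) & !is.na(p$hads_dep_last)
  inc <- p[complete, ]
  if (nrow(inc) < 2L) stop("no-data: need >= 2 patients with both timepoints")
  scale_summary <- function(first, last, label) {
    change <- last - first
    pt <- permutation_test(first, last, n_perm = n_perm,
                           seed = derive_seed(seed, "hads", label))
    list(first_mean = mean(first), last_mean = mean(last),
         change_mean = mean(change), change_sd = pop_sd(change),
         change_range = range(change), p = pt$p,
         mcid_reached = abs(mean(change)) >= MCID_HADS)
  }
  list(anxiety = scale_summary(inc$hads_anx_first, inc$hads_anx_last, "anx"),
       depression = scale_summary(inc$hads_dep_first, inc$hads_dep_last,
                                  "dep"),
       total = scale_summary(inc$hads_anx_first + inc$hads_dep_first,
                             inc$hads_anx_last + inc$hads_dep_last, "tot"),
       n_included = nrow(inc), n_excluded = sum(!complete))
}
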