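#' Packaged patient-characteristics table
#'
#' Loads the packaged transcription of the 35-patient clinical table:
#' focus side, EEG/MRI/FDG-PET findings, the equivalent-current-dipole (ECD)
#' lateralization call and the cross-validated linear-SVM call, plus
#' surgical columns. The loader validates the transcription against the
#' cohort invariants (35 rows; 16 left-sided, 19 right-sided; categorical
#' domains) and refuses to return a corrupted table. ECD spelling is
#' normalized for case (`"no spike"` appears once in the printed table).
#'
#' @param path Optional override of the packaged CSV (for testing).
#' @return Tibble with 35 rows and columns `case_no`, `sex`, `age_at_meg`,
#'   `age_at_onset`, `duration`, `side`, `eeg`, `mri`, `fdg_pet`, `ecd`,
#'   `svm`, `ice`, `surgery`, `histology`, `engel`.
#' @export
load_table1 <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "table1_patients.csv",
                        package = "meglaterality")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop("patient table fixture not found", call. = FALSE)
  }
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  tbl$ecd <- sub("^no spike$", "No spike", tbl$ecd)

  if (nrow(tbl) != 35) {
    stop("patient table corrupted: expected 35 rows, found ", nrow(tbl),
         call. = FALSE)
  }
  if (sum(tbl$side == "L") != 16 || sum(tbl$side == "R") != 19) {
    stop("patient table corrupted: expected 16 L / 19 R focus sides",
         call. = FALSE)
  }
  check_domain <- function(col, domain) {
    bad <- setdiff(unique(tbl[[col]]), domain)
    if (length(bad) > 0) {
      stop("patient table corrupted: unexpected ", col, " value(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  check_domain("side", c("L", "R"))
  check_domain("ecd", c("L", "R", "Bilateral", "No spike"))
  check_domain("svm", c("L", "R", "CTR"))
  if (!identical(sort(as.integer(tbl$case_no)), 1:35)) {
    stop("patient table corrupted: case numbers must be 1..35", call. = FALSE)
  }
  tbl
}

#' Concordance between dipole and SVM lateralization calls
#'
#' Cross-classifies each patient's two lateralization calls. A call is
#' "lateralizing" when it names one hemisphere: ECD in {L, R} (excluding
#' `Bilateral` and `No spike`), SVM in {L, R} (excluding `CTR`). Patients
#' fall into four disjoint categories: both calls lateralizing and equal;
#' only the SVM lateralizing; only the ECD lateralizing; neither (which
#' includes the both-lateralizing-but-discordant case, absent from the
#' packaged table).
#'
#' @param table1 Patient tibble from [load_table1()] (columns `ecd`, `svm`).
#' @return Tibble with one row: `both_lateralized_agree`, `svm_only`,
#'   `ecd_only`, `neither`. The four counts sum to the number of patients.
#' @examples
#' ecd_concordance(load_table1())
#' @export
ecd_concordance <- function(table1) {
  stopifnot(all(c("ecd", "svm") %in% names(table1)))
  ecd <- as.character(table1$ecd)
  svm <- as.character(table1$svm)
  bad <- c(setdiff(unique(ecd), c("L", "R", "Bilateral", "No spike")),
           setdiff(unique(svm), c("L", "R", "CTR")))
  if (length(bad) > 0) {
    stop("unknown lateralization call(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  ecd_lat <- ecd %in% c("L", "R")
  svm_lat <- svm %in% c("L", "R")
  tibble::tibble(
    both_lateralized_agree = sum(ecd_lat & svm_lat & ecd == svm),
    svm_only = sum(svm_lat & !ecd_lat),
    ecd_only = sum(ecd_lat & !svm_lat),
    neither = sum(!(ecd_lat & svm_lat & ecd == svm) & !(svm_lat & !ecd_lat) &
                    !(ecd_lat & !svm_lat))
  )
}
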