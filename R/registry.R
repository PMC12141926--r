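#' The 15-variable laboratory panel registry
#'
#' Returns the registry of the fifteen routine laboratory variables used for
#' physiological network mapping, one row per variable: column name, display
#' name, measurement unit, the organ-system tags the variable represents, and
#' a plausibility range used only for validation warnings (values outside the
#' range are flagged, never altered or dropped).
#'
#' The panel spans the inflammatory, coagulation, hematological, hepatic,
#' renal, metabolic, acid-base and endocrine systems; a variable may carry
#' more than one system tag (semicolon-separated).
#'
#' @return A data.frame with columns \code{name}, \code{label}, \code{unit},
#'   \code{systems}, \code{plausible_low}, \code{plausible_high}.
#' @examples
#' lab_registry()$name
#' @export
lab_registry <- function() {
  reg <- data.frame(
    name = c("phosphate", "arterial_ph", "urea", "hemoglobin", "lactate",
             "wbc", "sodium", "inr", "platelets", "bilirubin", "glucose",
             "creatinine", "alt", "bicarbonate", "potassium"),
    label = c("Phosphate", "Arterial pH", "Urea", "Hemoglobin", "Lactate",
              "White blood cell count", "Sodium", "INR", "Platelet count",
              "Bilirubin", "Glucose", "Creatinine", "Alanine transaminase",
              "Bicarbonate", "Potassium"),
    unit = c("mg/dL", "", "mg/dL", "mg/dL", "mmol/L", "x1000/uL", "mEq/L",
             "", "x1000/uL", "mg/dL", "mg/dL", "mg/dL", "U/L", "mEq/L",
             "mEq/L"),
    systems = c("renal;endocrine", "acid-base", "renal;metabolic",
                "hematological", "metabolic", "inflammatory;hematological",
                "renal;endocrine", "coagulation;hepatic",
                "coagulation;hematological;inflammatory", "hepatic",
                "metabolic;endocrine", "renal", "hepatic", "acid-base;renal",
                "renal;endocrine;acid-base"),
    plausible_low  = c(0.5, 6.8,   1,  3, 0.1, 0.1, 110, 0.5,   5, 0.05,
                       20, 0.1,   1,  5, 1.5),
    plausible_high = c(15,  7.8, 250, 22,  30, 150, 175,  12, 1200,   50,
                       1500, 25, 10000, 50, 9),
    stringsAsFactors = FALSE
  )
  stopifnot(!anyDuplicated(reg$name), all(reg$plausible_low < reg$plausible_high))
  reg
}

#' @rdname lab_registry
#' @format NULL
#' @details \code{lab_variables()} returns just the 15 column names in
#'   canonical order.
#' @export
lab_variables <- function() lab_registry()$name

# Mandatory non-lab columns of a cohort table, in canonical order.
cohort_meta_columns <- function() {
  c("patient_id", "time_days", "event30", "deteriorated48", "sofa",
    "ventilated", "age", "sex", "ethnicity", "elixhauser")
}
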