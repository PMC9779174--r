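#' Published UAV survey reference tables
#'
#' Two small reference tables from a published five-grade UAV grassland
#' desertification survey ship with the package as plain-text CSV:
#'
#' * `survey_reference_fvc()` - the 30-image supervised-classification
#'   results: reference FVC (percent), assigned desertification grade, and
#'   the supervised classifier's test OA (percent) and kappa per image
#'   (6 images per grade).
#' * `survey_reference_anova()` - the grade-wise one-way ANOVA summaries of
#'   the 19-index comparison (per grade and metric: Between Groups / Within
#'   Groups / Grand Total rows with TSS, df, MS, F, p as printed).
#'
#' They serve as worked inputs for [assign_grade()] and
#' [anova_consistency()] and as the fixture for the package's
#' grade-reproduction and ANOVA-audit checks.
#'
#' @return A data frame (see above).
#' @examples
#' ref <- survey_reference_fvc()
#' all(assign_grade(ref$fvc_percent) == ref$grade)
#' @export
survey_reference_fvc <- function() {
  utils::read.csv(system.file("extdata", "survey_fvc_reference.csv",
                              package = "desertvi"),
                  stringsAsFactors = FALSE)
}

#' @rdname survey_reference_fvc
#' @export
survey_reference_anova <- function() {
  utils::read.csv(system.file("extdata", "survey_anova_reference.csv",
                              package = "desertvi"),
                  stringsAsFactors = FALSE)
}
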