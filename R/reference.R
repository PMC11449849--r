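#' Published reference measurements bundled with the package
#'
#' Two plain-text tables of healthy-subject oral OCTA metric values from a
#' published repeatability and normative study, used to validate the
#' statistical operations: `reference_repeatability()` returns the
#' scan-rescan metric pairs of a repeated buccal mucosa acquisition together
#' with the published coefficients of variation; `reference_cohort()`
#' returns the per-site cohort summaries (mean, sample SD, n and the
#' published 95% confidence bounds) for buccal mucosa (n = 32), labial
#' mucosa (n = 24), floor of the mouth (n = 13) and hard palate (n = 8),
#' each for both depth-of-interest layers.
#'
#' @return A data frame.
#' @export
reference_repeatability <- function() {
  utils::read.csv(system.file("extdata", "repeatability_scans.csv",
                              package = "octaq"), stringsAsFactors = FALSE)
}

#' @rdname reference_repeatability
#' @export
reference_cohort <- function() {
  utils::read.csv(system.file("extdata", "cohort_reference.csv",
                              package = "octaq"), stringsAsFactors = FALSE)
}
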