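#' Clinical measure panel
#'
#' Metadata for the eleven longitudinal clinical measures used throughout the
#' pipeline: the eight Edinburgh Cognitive and Behavioural ALS Screen (ECAS)
#' scores, the revised ALS Functional Rating Scale (ALSFRS-R), and
#' clinician-rated upper and lower motor neuron (UMN/LMN) burden scores.
#'
#' Instrument ranges are the published score bounds.  Baseline means/SDs and
#' monthly rates of decline are fixture conventions chosen to resemble a
#' multicenter ALS natural-history cohort; they parameterize the synthetic
#' cohort generator and carry no role in model fitting.
#'
#' @return A data.frame with one row per measure: \code{measure},
#'   \code{domain} ("cognitive" or "motor"), instrument \code{min}/\code{max},
#'   baseline \code{mean}/\code{sd}, monthly \code{slope_mean}/\code{slope_sd},
#'   residual \code{noise_sd}, and \code{signal_frac}, the default fraction of
#'   between-subject baseline variance attributed to the planted genetic
#'   composite in simulations.
#' @export
#' @examples
#' clinical_measures()$measure
clinical_measures <- function() {
  m <- data.frame(
    measure = c("ECAS_ALS_Specific", "ECAS_Total", "ECAS_Executive",
                "ECAS_Language", "ECAS_Fluency", "ECAS_Memory",
                "ECAS_Visuospatial", "ECAS_ALS_NonSpecific",
                "ALSFRS_R", "UMN", "LMN"),
    domain  = c(rep("cognitive", 8), rep("motor", 3)),
    min     = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0),
    max     = c(100, 136, 48, 28, 24, 24, 12, 36, 48, 10, 10),
    mean    = c(82, 110, 38, 26, 17, 16, 11.4, 28, 35, 2.7, 2.5),
    sd      = c(10, 13, 6, 2.5, 5, 3.8, 0.7, 3.8, 7, 1.7, 1.5),
    slope_mean = c(-0.18, -0.25, -0.10, -0.04, -0.06, -0.05, -0.01, -0.06,
                   -0.65, 0.05, 0.06),
    slope_sd   = c(0.28, 0.40, 0.16, 0.07, 0.11, 0.09, 0.02, 0.10,
                   0.55, 0.08, 0.09),
    stringsAsFactors = FALSE
  )
  m$noise_sd <- 0.25 * m$sd
  # genetic composite explains most baseline variance in the ALS-specific
  # domains, less in memory/visuospatial, none in motor measures
  m$signal_frac <- c(0.30, 0.25, 0.20, 0.15, 0.12, 0.08, 0.05, 0.15,
                     0, 0, 0)
  m
}

#' @rdname clinical_measures
#' @export
measure_names <- function() clinical_measures()$measure
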