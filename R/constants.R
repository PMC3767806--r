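# Versioned default parameters for the simulated reference cohort.
#
# Values encode the published group structure of a five-group ALS T1
# morphometry cohort (neurological controls plus four ALS phenotypes):
# per-group sample sizes, age and gender distributions, clinical
# measures, and the mean/SD of each of the nine FD outcomes. They are
# the generating conditions of makeCohort(), not tuning knobs.

.WM_GROUPS <- c("Control", "ALS-FTD", "ALS-CST+", "ALS-CSTminus", "ALS-Cl")

.REFERENCE_COHORT <- local({
  groups <- .WM_GROUPS
  fdMeans <- matrix(c(
    # Control   ALS-FTD   ALS-CST+  ALS-CSTminus ALS-Cl
    2.407, 2.404, 2.420, 2.406, 2.412,   # fd_skeleton_lh
    2.409, 2.394, 2.420, 2.400, 2.403,   # fd_skeleton_rh
    2.487, 2.469, 2.501, 2.480, 2.484,   # fd_skeleton_wb
    2.462, 2.468, 2.467, 2.464, 2.471,   # fd_surface_lh
    2.467, 2.465, 2.472, 2.465, 2.468,   # fd_surface_rh
    2.549, 2.551, 2.557, 2.547, 2.557,   # fd_surface_wb
    2.582, 2.572, 2.590, 2.582, 2.590,   # fd_general_lh
    2.598, 2.583, 2.603, 2.575, 2.581,   # fd_general_rh
    2.633, 2.618, 2.638, 2.625, 2.629),  # fd_general_wb
    nrow = 9, byrow = TRUE,
    dimnames = list(fdOutcomeNames(), groups))
  fdSds <- matrix(c(
    0.018, 0.030, 0.022, 0.027, 0.022,
    0.021, 0.023, 0.021, 0.025, 0.019,
    0.018, 0.020, 0.024, 0.023, 0.017,
    0.018, 0.020, 0.015, 0.019, 0.013,
    0.024, 0.017, 0.013, 0.022, 0.014,
    0.017, 0.020, 0.013, 0.019, 0.014,
    0.054, 0.044, 0.035, 0.044, 0.041,
    0.020, 0.016, 0.033, 0.048, 0.050,
    0.013, 0.013, 0.015, 0.015, 0.015),
    nrow = 9, byrow = TRUE,
    dimnames = list(fdOutcomeNames(), groups))
  list(
    groups = groups,
    groupSizes = setNames(c(11L, 20L, 20L, 24L, 22L), groups),
    fdMeans = fdMeans,
    fdSds = fdSds,
    ageMeans = setNames(c(51.7, 66.7, 52.9, 58.0, 57.4), groups),
    ageSds = setNames(c(16.6, 9.9, 11.5, 11.5, 11.5), groups),
    maleProp = setNames(c(8 / 11, 7 / 20, 13 / 20, 14 / 24, 12 / 22),
                        groups),
    alsfrsMeans = setNames(c(NA, 30.5, 34.9, 35.0, 37.2), groups),
    alsfrsSds = setNames(c(NA, 7.2, 8.0, 8.6, 8.7), groups),
    # disease duration in months: median and quartiles per ALS group
    durationMedian = setNames(c(NA, 34, 13, 35.5, 13), groups),
    durationQ1 = setNames(c(NA, 18.8, 9.5, 17.8, 9), groups),
    durationQ3 = setNames(c(NA, 45, 18.3, 55, 52), groups),
    # diagnostic-certainty (EES 1..4) proportions per ALS group
    eesProbs = rbind(
      "Control" = c(NA, NA, NA, NA),
      "ALS-FTD" = c(7, 2, 7, 4) / 20,
      "ALS-CST+" = c(10, 4, 5, 1) / 20,
      "ALS-CSTminus" = c(18, 2, 3, 1) / 24,
      "ALS-Cl" = c(3, 6, 8, 3) / 20))
})

#' Default parameters of the simulated reference cohort
#'
#' Returns the embedded generating parameters used as defaults by
#' [makeCohort()]: group labels and sizes, per-group age and gender
#' distributions, clinical-measure distributions, and the mean/SD of
#' each of the nine FD outcomes per group.
#'
#' @return A named list of parameter tables.
#' @export
#' @examples
#' p <- referenceCohortParams()
#' p$fdMeans["fd_skeleton_wb", ]
referenceCohortParams <- function() .REFERENCE_COHORT
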