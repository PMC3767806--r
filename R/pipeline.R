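#' @include AllClasses.R
NULL

#' Pipeline configuration
#'
#' Bundles every tunable of the subject- and cohort-level pipeline with
#' its default: binarization threshold 0.5; automatic scale ladder;
#' single (zero) lattice offset; surface background connectivity 6;
#' automatic hemisphere midline; age as the model covariate; FDR level
#' 0.05; no resampling (inputs are assumed near-isotropic; set
#' \code{resample = TRUE} to resample to \code{targetMm} first).
#'
#' @param threshold Binarization threshold in (0, 1).
#' @param scales Box-counting mesh sizes, or NULL for [autoBoxScales()].
#' @param nOffsets Lattice offsets averaged per scale.
#' @param surfaceConnectivity Background connectivity for the surface.
#' @param midline Hemisphere midline: "auto" or integer slice.
#' @param lrAxis Optional left-right axis override (1, 2 or 3).
#' @param covariates Model covariates for the group comparison.
#' @param fdrAlpha FDR level for the correlation screen.
#' @param minPoints,r2Floor Scaling-window selection parameters.
#' @param resample Resample inputs to isotropic voxels first?
#' @param targetMm Isotropic target voxel edge (mm) when resampling.
#' @param seed Root seed for any stochastic stage.
#' @return A \code{PipelineConfig} list.
#' @export
pipelineConfig <- function(threshold = 0.5, scales = NULL, nOffsets = 1L,
                           surfaceConnectivity = 6, midline = "auto",
                           lrAxis = NULL, covariates = "age",
                           fdrAlpha = 0.05, minPoints = 4L,
                           r2Floor = 0.98, resample = FALSE,
                           targetMm = 1.0, seed = 1L) {
  structure(list(threshold = threshold, scales = scales,
                 nOffsets = as.integer(nOffsets),
                 surfaceConnectivity = surfaceConnectivity,
                 midline = midline, lrAxis = lrAxis,
                 covariates = covariates, fdrAlpha = fdrAlpha,
                 minPoints = as.integer(minPoints), r2Floor = r2Floor,
                 resample = resample, targetMm = targetMm,
                 seed = as.integer(seed)),
            class = "PipelineConfig")
}

.emptyFDRow <- function(subjectId) {
  row <- as.data.frame(as.list(setNames(rep(NA_real_, 9),
                                        fdOutcomeNames())))
  cbind(data.frame(subject_id = subjectId, stringsAsFactors = FALSE), row)
}

#' Extract the nine FD outcomes for one subject
#'
#' Runs the full subject-level chain: read (or accept) the probability
#' volume, optionally resample to isotropic voxels, build the three
#' shape representations for whole brain and both hemispheres, and
#' estimate an FD per feature and region. Deterministic given the
#' configuration. Any stage failure is caught and returned as a failure
#' row naming the stage rather than propagated, so one bad volume never
#' aborts a cohort run.
#'
#' @param volume Path to a NIfTI file or a
#'   \linkS4class{ProbabilityVolume}.
#' @param config A [pipelineConfig()].
#' @param subjectId Subject identifier for the output row.
#' @return One-row data frame: subject_id, the nine \code{fd_*} columns,
#'   per-feature whole-brain voxel counts, fitted scale ranges and
#'   R-squared values, plus \code{status}, \code{stage}, \code{message}.
#' @export
runSubject <- function(volume, config = pipelineConfig(),
                       subjectId = "subject") {
  stage <- "read"
  tryCatch({
    vol <- if (is(volume, "ProbabilityVolume")) volume else
      readVolume(volume)
    if (isTRUE(config$resample)) {
      stage <- "resample"
      vol <- resampleIsotropic(vol, config$targetMm)
    }
    stage <- "binarize"
    mask <- binarize(vol, config$threshold)
    if (voxelCount(mask) == 0L) stop("empty WM mask")
    stage <- "features"
    fsets <- makeFeatureSet(vol, threshold = config$threshold,
                            connectivity = config$surfaceConnectivity,
                            midline = config$midline,
                            axis = config$lrAxis)
    stage <- "fd"
    regions <- c(left = "lh", right = "rh", whole = "wb")
    row <- .emptyFDRow(subjectId)
    qc <- list()
    for (rg in names(regions)) {
      ests <- featureFD(fsets[[rg]], scales = config$scales,
                        nOffsets = config$nOffsets,
                        minPoints = config$minPoints,
                        r2Floor = config$r2Floor)
      for (f in .FD_FEATURES) {
        col <- paste("fd", f, regions[rg], sep = "_")
        row[[col]] <- fdValue(ests[[f]])
        qc[[paste0("r2_", f, "_", regions[rg])]] <-
          fdRSquared(ests[[f]])
        qc[[paste0("scales_", f, "_", regions[rg])]] <-
          paste(fdScaleRange(ests[[f]]), collapse = "-")
      }
    }
    for (f in .FD_FEATURES)
      qc[[paste0("nvox_", f, "_wb")]] <-
        voxelCount(slot(fsets$whole, f))
    cbind(row, as.data.frame(qc, stringsAsFactors = FALSE),
          data.frame(status = "ok", stage = NA_character_,
                     message = NA_character_, stringsAsFactors = FALSE))
  }, error = function(e) {
    cbind(.emptyFDRow(subjectId),
          data.frame(status = "failed", stage = stage,
                     message = conditionMessage(e),
                     stringsAsFactors = FALSE))
  })
}

#' Run the cohort-level pipeline
#'
#' Extracts FD values for every subject in the manifest, merges them
#' with the clinical table, and runs the full statistical battery: for
#' each of the nine FD outcomes a mixed-effects group model with Tukey
#' pairwise contrasts (primary analysis with the configured covariates,
#' plus a sensitivity re-fit on patients only with ALSFRS-R added when
#' available), Spearman correlation screens against ALSFRS-R,
#' log-duration and log-progression-rate with FDR flags, and a
#' Kruskal-Wallis comparison across EES strata. Results are written as
#' TSVs plus a machine-readable JSON summary when \code{outDir} is
#' given, and returned invisibly as a list.
#'
#' @param manifest Data frame with \code{subject_id} and \code{path}
#'   (NIfTI paths), or pre-loaded volumes in a \code{volume} list
#'   column; alternatively an FD table that already contains the nine
#'   \code{fd_*} columns, which skips extraction.
#' @param clinical Data frame with subject_id, group, age, gender,
#'   alsfrs_r, duration_months, ees.
#' @param config A [pipelineConfig()].
#' @param outDir Output directory, or NULL to skip writing.
#' @return (Invisibly) list with \code{fd_table}, \code{models},
#'   \code{tukey}, \code{sensitivity}, \code{correlations},
#'   \code{kruskal_ees}, \code{config}.
#' @export
runCohort <- function(manifest, clinical, config = pipelineConfig(),
                      outDir = NULL) {
  stopifnot("subject_id" %in% names(manifest),
            "subject_id" %in% names(clinical))
  unknown <- setdiff(manifest$subject_id, clinical$subject_id)
  if (length(unknown) > 0)
    stop(sprintf("manifest ids missing from the clinical table: %s",
                 paste(unknown, collapse = ", ")))
  haveFD <- all(fdOutcomeNames() %in% names(manifest))
  fdRows <- if (haveFD) {
    manifest
  } else {
    do.call(rbind, lapply(seq_len(nrow(manifest)), function(i) {
      vol <- if ("volume" %in% names(manifest))
        manifest$volume[[i]] else manifest$path[i]
      runSubject(vol, config, manifest$subject_id[i])
    }))
  }
  tab <- merge(clinical, fdRows, by = "subject_id", sort = TRUE)
  tab <- logTransformClinical(tab)

  outcomes <- fdOutcomeNames()
  models <- list(); tukey <- list(); sensitivity <- list()
  for (o in outcomes) {
    models[[o]] <- fitGroupModel(tab, o, covariates = config$covariates)
    tukey[[o]] <- tukeyPairwise(models[[o]])
    pat <- tab[tab$group != "Control", , drop = FALSE]
    nAls <- sum(!is.na(pat$alsfrs_r))
    sensitivity[[o]] <- if (nAls >= 10L) {
      sfit <- fitGroupModel(pat, o,
                            covariates = union(config$covariates,
                                               "alsfrs_r"))
      list(model = sfit, tukey = tukeyPairwise(sfit))
    } else {
      warning(sprintf(
        "%s: only %d patients with ALSFRS-R; sensitivity analysis skipped",
        o, nAls))
      NULL
    }
  }

  correlations <- list()
  for (cl in c("alsfrs_r", "ln_duration", "ln_progression_rate")) {
    correlations[[cl]] <- tryCatch(
      spearmanFDClinical(tab, cl, fdrAlpha = config$fdrAlpha),
      error = function(e) NULL)
  }

  kruskal <- lapply(outcomes, function(o) {
    tryCatch(suppressWarnings(kruskalByEES(tab, o)),
             error = function(e) NULL)
  })
  names(kruskal) <- outcomes

  res <- list(fd_table = tab, models = models, tukey = tukey,
              sensitivity = sensitivity, correlations = correlations,
              kruskal_ees = kruskal, config = config)
  if (!is.null(outDir)) .writeCohortBundle(res, outDir)
  invisible(res)
}

.writeCohortBundle <- function(res, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    write.table(df, file.path(outDir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  wt(res$fd_table, "fd_table.tsv")
  summary <- list(config = unclass(res$config)[
    !vapply(unclass(res$config), is.null, logical(1))])
  for (o in names(res$models)) {
    m <- res$models[[o]]
    wt(data.frame(term = names(m$fixed_effects),
                  estimate = unname(m$fixed_effects)),
       sprintf("model_%s.tsv", o))
    wt(res$tukey[[o]], sprintf("tukey_%s.tsv", o))
    summary$models[[o]] <- list(
      p_age = m$p_age, p_group = m$p_group,
      random_effect_variance = m$random_effect_variance,
      residual_variance = m$residual_variance,
      adjusted_group_means = as.list(m$adjusted_group_means))
  }
  for (cl in names(res$correlations)) {
    if (!is.null(res$correlations[[cl]]))
      wt(res$correlations[[cl]], sprintf("correlations_%s.tsv", cl))
  }
  summary$kruskal_ees <- lapply(res$kruskal_ees, function(k) {
    if (is.null(k)) NULL else
      list(statistic = k$statistic, df = k$df, p_value = k$p_value)
  })
  jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(outDir)
}
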