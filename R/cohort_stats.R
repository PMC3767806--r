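#' @include AllClasses.R
NULL

#' Disease progression rate from ALSFRS-R and disease duration
#'
#' Rate of functional decline in points per month, computed as the
#' total loss from the maximal score divided by the disease duration:
#' (48 - ALSFRS-R) / duration.
#'
#' @param alsfrs_r ALSFRS-R score(s), in [0, 48].
#' @param duration_months Disease duration(s) in months, > 0.
#' @return Numeric progression rate(s), points per month.
#' @export
#' @examples
#' computeProgressionRate(36, 24)  # 0.5
computeProgressionRate <- function(alsfrs_r, duration_months) {
  if (any(!is.na(duration_months) & duration_months <= 0))
    stop("duration_months must be strictly positive")
  if (any(!is.na(alsfrs_r) & (alsfrs_r < 0 | alsfrs_r > 48)))
    stop("alsfrs_r must lie in [0, 48]")
  (48 - alsfrs_r) / duration_months
}

#' Add natural-log transforms of duration and progression rate
#'
#' Appends \code{progression_rate}, \code{ln_duration} and
#' \code{ln_progression_rate} columns. Non-positive values cannot be
#' log-transformed; they are set to NA with a warning naming the
#' subjects, mirroring complete-case handling downstream.
#'
#' @param table Cohort data frame with \code{alsfrs_r} and
#'   \code{duration_months} columns.
#' @return The table with the three added columns.
#' @export
logTransformClinical <- function(table) {
  stopifnot(all(c("alsfrs_r", "duration_months") %in% names(table)))
  rate <- rep(NA_real_, nrow(table))
  ok <- !is.na(table$alsfrs_r) & !is.na(table$duration_months) &
    table$duration_months > 0
  rate[ok] <- (48 - table$alsfrs_r[ok]) / table$duration_months[ok]
  table$progression_rate <- rate
  safeLog <- function(x, what) {
    out <- rep(NA_real_, length(x))
    pos <- !is.na(x) & x > 0
    bad <- !is.na(x) & x <= 0
    if (any(bad)) {
      ids <- if ("subject_id" %in% names(table))
        table$subject_id[bad] else which(bad)
      warning(sprintf("%s non-positive for %s; excluded from log transform",
                      what, paste(ids, collapse = ", ")))
    }
    out[pos] <- log(x[pos])
    out
  }
  table$ln_duration <- safeLog(table$duration_months, "duration")
  table$ln_progression_rate <- safeLog(rate, "progression rate")
  table
}

.groupFixedFormula <- function(response, covariates) {
  stats::reformulate(c(covariates, "group"), response = response)
}

#' Flag outlier and leverage subjects for one FD outcome
#'
#' Fits the fixed-effects design (response ~ covariates + group +
#' gender) by least squares and flags rows whose externally studentized
#' residual exceeds 3 or whose leverage exceeds 3 p / n. Deterministic.
#'
#' @param table Cohort data frame.
#' @param response Name of the FD outcome column.
#' @param covariates Fixed covariates, default "age".
#' @return Character vector of flagged subject ids (possibly empty).
#' @export
detectOutliers <- function(table, response, covariates = "age") {
  keep <- !is.na(table[[response]]) &
    complete.cases(table[, c(covariates, "group", "gender"), drop = FALSE])
  dat <- table[keep, , drop = FALSE]
  if (nrow(dat) < 10L)
    stop("outlier diagnostics need at least 10 rows with the response")
  fml <- stats::reformulate(c(covariates, "group", "gender"),
                            response = response)
  fit <- lm(fml, data = dat)
  p <- length(coef(fit))
  n <- nrow(dat)
  flag <- abs(rstudent(fit)) > 3 | hatvalues(fit) > 3 * p / n
  flag[is.na(flag)] <- FALSE
  dat$subject_id[flag]
}

#' Fit the mixed-effects group model for one FD outcome
#'
#' REML fit of \code{response ~ covariates + group} with a random
#' intercept per gender, via \pkg{lmerTest}. With only two gender
#' levels the random-effect variance routinely hits the boundary
#' (zero); the fit tolerates and reports this rather than failing.
#' Marginal age and group tests use Satterthwaite type-III F tests;
#' adjusted group means are evaluated at the covariate grand means via
#' \pkg{emmeans}.
#'
#' @param table Cohort data frame.
#' @param response FD outcome column name.
#' @param covariates Character vector, \code{"age"} or
#'   \code{c("age", "alsfrs_r")}.
#' @return A \code{GroupModelFit} list: \code{fit} (the lmerMod),
#'   \code{response_name}, \code{fixed_effects},
#'   \code{random_effect_variance}, \code{residual_variance},
#'   \code{adjusted_group_means}, \code{p_age}, \code{p_group},
#'   \code{n_used}.
#' @export
fitGroupModel <- function(table, response, covariates = "age") {
  need <- c(response, covariates, "group", "gender")
  keep <- complete.cases(table[, need, drop = FALSE])
  dat <- table[keep, , drop = FALSE]
  dat$group <- factor(dat$group)
  dat$gender <- factor(dat$gender)
  tabn <- table(dat$group)
  if (length(tabn) < 2L)
    stop("group comparison needs at least 2 groups present")
  if (any(tabn < 3L))
    stop(sprintf("every group needs n >= 3 (violated by: %s)",
                 paste(names(tabn)[tabn < 3L], collapse = ", ")))
  fml <- stats::as.formula(paste(
    response, "~", paste(covariates, collapse = " + "),
    "+ group + (1 | gender)"))
  fit <- suppressMessages(suppressWarnings(
    lmerTest::lmer(fml, data = dat, REML = TRUE)))
  vc <- as.data.frame(lme4::VarCorr(fit))
  reVar <- vc$vcov[vc$grp == "gender"]
  resVar <- vc$vcov[vc$grp == "Residual"]
  an <- suppressMessages(anova(fit, type = 3))
  pOf <- function(term) {
    if (term %in% rownames(an)) an[term, "Pr(>F)"] else NA_real_
  }
  emm <- suppressMessages(
    emmeans::emmeans(fit, "group", lmer.df = "satterthwaite"))
  emmDf <- as.data.frame(emm)
  structure(list(
    fit = fit,
    response_name = response,
    covariates = covariates,
    fixed_effects = lme4::fixef(fit),
    random_effect_variance = reVar,
    residual_variance = resVar,
    adjusted_group_means = setNames(emmDf$emmean,
                                    as.character(emmDf$group)),
    emmeans = emm,
    p_age = pOf("age"),
    p_group = pOf("group"),
    n_used = nrow(dat)), class = "GroupModelFit")
}

#' @param x A \code{GroupModelFit}.
#' @param ... Ignored.
#' @method print GroupModelFit
#' @export
print.GroupModelFit <- function(x, ...) {
  cat(sprintf("GroupModelFit for %s (n = %d)\n", x$response_name, x$n_used))
  cat(sprintf("  covariates: %s; gender random-intercept variance %.3g, residual %.3g\n",
              paste(x$covariates, collapse = ", "),
              x$random_effect_variance, x$residual_variance))
  cat(sprintf("  p(age) = %.4g, p(group) = %.4g\n", x$p_age, x$p_group))
  cat("  adjusted group means:\n")
  print(round(x$adjusted_group_means, 4))
  invisible(x)
}

#' Tukey HSD pairwise group contrasts from a fitted group model
#'
#' All pairwise differences of covariate-adjusted group means with
#' Tukey-adjusted p-values, computed on the fitted mixed model's
#' estimated marginal means and error degrees of freedom.
#'
#' @param fit A \code{GroupModelFit} from [fitGroupModel()].
#' @param alpha Significance level for the \code{significant} flag.
#' @return Data frame with \code{group_a}, \code{group_b},
#'   \code{estimate}, \code{se}, \code{df}, \code{p_adjusted},
#'   \code{significant}.
#' @export
tukeyPairwise <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "GroupModelFit"))
  prs <- as.data.frame(summary(emmeans::contrast(fit$emmeans, "pairwise"),
                               adjust = "tukey"))
  ab <- strsplit(as.character(prs$contrast), " - ", fixed = TRUE)
  clean <- function(x) gsub("[()]", "", x)
  data.frame(
    group_a = clean(vapply(ab, `[`, "", 1)),
    group_b = clean(vapply(ab, `[`, "", 2)),
    estimate = prs$estimate,
    se = prs$SE,
    df = prs$df,
    p_adjusted = pmin(1, pmax(0, prs$p.value)),
    significant = prs$p.value < alpha,
    stringsAsFactors = FALSE)
}

#' Spearman correlations between the nine FD outcomes and one clinical
#' measure, with FDR control
#'
#' For each FD outcome, computes the Spearman rank correlation with the
#' clinical column over complete pairs, then applies
#' Benjamini-Hochberg across the nine tests. Outcomes with fewer than
#' \code{minPairs} complete pairs are skipped with a warning.
#'
#' @param table Cohort data frame.
#' @param clinical Name of the clinical column (e.g. "alsfrs_r").
#' @param fdrAlpha FDR level for the \code{passes_fdr} flag.
#' @param minPairs Minimum complete pairs per outcome (default 10).
#' @return Data frame with \code{outcome}, \code{clinical}, \code{n},
#'   \code{rho}, \code{p_value}, \code{p_bh}, \code{passes_fdr}.
#' @export
spearmanFDClinical <- function(table, clinical, fdrAlpha = 0.05,
                               minPairs = 10L) {
  outcomes <- fdOutcomeNames()
  rows <- lapply(outcomes, function(o) {
    ok <- !is.na(table[[o]]) & !is.na(table[[clinical]])
    if (sum(ok) < minPairs) {
      warning(sprintf("%s: only %d complete pairs with %s; skipped",
                      o, sum(ok), clinical))
      return(NULL)
    }
    ct <- suppressWarnings(cor.test(table[[o]][ok], table[[clinical]][ok],
                                    method = "spearman", exact = FALSE))
    data.frame(outcome = o, clinical = clinical, n = sum(ok),
               rho = unname(ct$estimate), p_value = ct$p.value,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res) || nrow(res) == 0L)
    stop("no outcome had enough complete pairs")
  res$p_bh <- p.adjust(res$p_value, method = "BH")
  res$passes_fdr <- res$p_bh < fdrAlpha
  res
}

#' Kruskal-Wallis comparison of one FD outcome across EES strata
#'
#' Compares the FD outcome across diagnostic-certainty strata
#' (EES 1..4) with a Kruskal-Wallis rank test; pairwise stratum
#' contrasts use Wilcoxon rank-sum tests with Bonferroni adjustment.
#' Strata with fewer than 3 subjects are dropped with a warning.
#'
#' @param table Cohort data frame with an \code{ees} column.
#' @param response FD outcome column name.
#' @return List with \code{statistic} (H), \code{df}, \code{p_value},
#'   \code{pairwise} (matrix of Bonferroni-adjusted p-values), and
#'   \code{strata_n}.
#' @export
kruskalByEES <- function(table, response) {
  ok <- !is.na(table$ees) & !is.na(table[[response]])
  dat <- table[ok, , drop = FALSE]
  cnt <- table(dat$ees)
  small <- names(cnt)[cnt < 3L]
  if (length(small) > 0) {
    warning(sprintf("dropping EES strata with n < 3: %s",
                    paste(small, collapse = ", ")))
    dat <- dat[!(dat$ees %in% as.integer(small)), , drop = FALSE]
  }
  strata <- factor(dat$ees)
  if (nlevels(strata) < 2L)
    stop("Kruskal-Wallis needs at least 2 EES strata with n >= 3")
  kt <- kruskal.test(dat[[response]], strata)
  pw <- suppressWarnings(
    pairwise.wilcox.test(dat[[response]], strata,
                         p.adjust.method = "bonferroni", exact = FALSE))
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value, pairwise = pw$p.value,
       strata_n = table(strata))
}
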