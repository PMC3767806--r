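test_that("progression rate follows (48 - ALSFRS-R) / duration", {
  expect_equal(computeProgressionRate(48, 12), 0)
  expect_equal(computeProgressionRate(36, 24), 0.5)
  expect_error(computeProgressionRate(30, 0), "positive")
  expect_error(computeProgressionRate(60, 12), "48")
})

test_that("clinical log transforms handle non-positive values by exclusion", {
  tab <- data.frame(subject_id = c("a", "b", "c"),
                    alsfrs_r = c(30, 48, 40),
                    duration_months = c(19, 10, 8))
  expect_warning(logTransformClinical(tab), "progression rate")
  out <- suppressWarnings(logTransformClinical(tab))
  expect_equal(out$ln_duration, log(c(19, 10, 8)))
  expect_equal(out$progression_rate, c(18 / 19, 0, 1))
  expect_equal(out$ln_progression_rate, c(log(18 / 19), NA, 0))
})

test_that("outlier diagnostics flag gross shifts and stay quiet on clean data", {
  tab <- makeCohort(seed = 42)
  tab$fd_skeleton_wb[10] <- tab$fd_skeleton_wb[10] + 10 * 0.02
  expect_true(tab$subject_id[10] %in% detectOutliers(tab, "fd_skeleton_wb"))

  flagged <- 0; total <- 0
  for (s in 1:20) {
    clean <- makeCohort(seed = 300 + s)
    flagged <- flagged + length(detectOutliers(clean, "fd_skeleton_wb"))
    total <- total + nrow(clean)
  }
  expect_lte(flagged / total, 0.01)

  expect_error(detectOutliers(makeCohort(seed = 1)[1:5, ], "fd_skeleton_wb"),
               "at least 10")
})

test_that("the mixed model validates its design and reports sane components", {
  tab <- makeCohort(seed = 8)
  fit <- fitGroupModel(tab, "fd_skeleton_wb")
  expect_s3_class(fit, "GroupModelFit")
  expect_gte(fit$random_effect_variance, 0)
  expect_gt(fit$residual_variance, 0)
  expect_true(all(is.finite(fit$adjusted_group_means)))
  expect_true(fit$p_group >= 0 && fit$p_group <= 1)
  expect_equal(length(fit$adjusted_group_means), 5)

  single <- tab[tab$group == "ALS-Cl", ]
  expect_error(fitGroupModel(single, "fd_skeleton_wb"), "2 groups")
  tiny <- tab[c(which(tab$group == "Control"),
                which(tab$group == "ALS-Cl")[1:2]), ]
  expect_error(fitGroupModel(tiny, "fd_skeleton_wb"), "n >= 3")
})

test_that("with boundary (zero) gender variance the fit collapses to OLS", {
  tab <- makeCohort(genderSd = 0, seed = 5)
  fit <- fitGroupModel(tab, "fd_skeleton_wb")
  expect_equal(fit$random_effect_variance, 0)
  ols <- lm(fd_skeleton_wb ~ age + factor(group), data = tab)
  expect_lt(max(abs(fit$fixed_effects - coef(ols))), 1e-6)
})

test_that("Tukey contrasts enumerate all pairs and are label-symmetric", {
  tab <- makeCohort(seed = 13)
  fit <- fitGroupModel(tab, "fd_skeleton_wb")
  tk <- tukeyPairwise(fit)
  expect_equal(nrow(tk), choose(5, 2))
  expect_true(all(tk$p_adjusted >= 0 & tk$p_adjusted <= 1))

  relabeled <- tab
  map <- setNames(paste0("G", 1:5), sort(unique(tab$group)))
  relabeled$group <- unname(map[tab$group])
  tk2 <- tukeyPairwise(fitGroupModel(relabeled, "fd_skeleton_wb"))
  expect_equal(sort(tk$p_adjusted), sort(tk2$p_adjusted), tolerance = 1e-8)
  expect_equal(sort(abs(tk$estimate)), sort(abs(tk2$estimate)),
               tolerance = 1e-8)
})

test_that("Spearman screens respect monotone structure and FDR flags", {
  tab <- makeCohort(seed = 17)
  pat <- tab[tab$group != "Control", ]
  # perfect monotone coupling
  forced <- pat
  forced$alsfrs_r <- rank(forced$fd_skeleton_wb)
  res <- spearmanFDClinical(forced, "alsfrs_r", fdrAlpha = 0.007)
  row <- res[res$outcome == "fd_skeleton_wb", ]
  expect_equal(row$rho, 1)
  expect_true(row$passes_fdr)
  flipped <- pat
  flipped$alsfrs_r <- -rank(flipped$fd_skeleton_wb)
  res2 <- spearmanFDClinical(flipped, "alsfrs_r")
  expect_equal(res2[res2$outcome == "fd_skeleton_wb", "rho"], -1)

  # invariance under strictly monotone transforms of either variable
  straight <- spearmanFDClinical(pat, "alsfrs_r")
  warped <- pat
  for (o in fdOutcomeNames()) warped[[o]] <- exp(3 * warped[[o]])
  warped$alsfrs_r <- warped$alsfrs_r^3
  res3 <- spearmanFDClinical(warped, "alsfrs_r")
  expect_equal(res3$rho, straight$rho, tolerance = 1e-12)

  few <- pat; few$alsfrs_r[-(1:5)] <- NA
  expect_error(suppressWarnings(spearmanFDClinical(few, "alsfrs_r")),
               "no outcome")
})

test_that("Kruskal-Wallis across EES strata reacts to shifts only", {
  tab <- makeCohort(seed = 19)
  shifted <- tab
  i <- shifted$ees %in% 4
  shifted$fd_skeleton_wb[i] <- shifted$fd_skeleton_wb[i] + 5 * 0.02
  k <- kruskalByEES(shifted, "fd_skeleton_wb")
  expect_lt(k$p_value, 0.001)
  expect_true(is.matrix(k$pairwise))

  # strata drawn from one distribution: near-null H
  ref <- referenceCohortParams()
  eqMeans <- ref$fdMeans; eqMeans[] <- rep(rowMeans(eqMeans), ncol(eqMeans))
  nullOK <- 0
  for (s in 1:40) {
    t2 <- makeCohort(fdMeans = eqMeans, ageSlope = 0, seed = 600 + s)
    k2 <- suppressWarnings(kruskalByEES(t2, "fd_surface_wb"))
    nullOK <- nullOK + (k2$p_value > 0.05)
  }
  expect_gte(nullOK / 40, 0.85)

  one <- tab[tab$ees %in% 1, ]
  expect_error(suppressWarnings(kruskalByEES(one, "fd_skeleton_wb")),
               "2 EES strata")
})
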