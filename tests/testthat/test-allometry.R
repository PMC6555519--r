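# Candidate design matrices, the OLS engine, AIC selection and the
# power-function parameterization.

test_that("design matrices have the Table-1 coefficient counts", {
  params <- common_slope_params()
  d <- make_species_means(params, n_per_family = 3, seed = 2)
  specs <- candidate_models("proboscis")
  labels <- vapply(specs, `[[`, character(1), "label")
  k <- vapply(specs, function(s) ncol(build_design(s, d)$X), integer(1))
  expect_equal(k[labels == "Family + IT"], 7L)        # 6 intercepts + 1 slope
  expect_equal(k[labels == "Family x IT"], 12L)       # 6 intercepts + 6 slopes
  expect_equal(k[labels == "Family Only"], 6L)
  expect_equal(k[labels == "Short- vs. Long-Tongued + IT"], 3L)
  expect_equal(k[labels == "IT Only"], 2L)

  one <- d[d$family == "Apidae", ][1:3, ]
  X <- build_design(specs[[7]], one)$X
  expect_equal(dim(X), c(3L, 2L))
  expect_equal(unname(X[, 1]), rep(1, 3))
})

test_that("fit_ols handles the degenerate and singular paths", {
  # perfect fit -> -Inf AIC sentinel
  X <- cbind(1, 0:3)
  expect_warning(f <- fit_ols(X, y = 2 + 3 * (0:3)), "perfect fit")
  expect_identical(f$aic, -Inf)
  expect_lt(f$rss, 1e-20)
  # singular design
  expect_error(fit_ols(cbind(1, c(1, 1, 1, 1), c(2, 2, 2, 2)), y = rnorm(4)),
               "singular")
  # more coefficients than points
  expect_error(fit_ols(cbind(1, 1:2), y = 1:2), "more observations")
})

test_that("adding a predictor never increases RSS and AIC ignores shifts", {
  set.seed(42)
  params <- common_slope_params()
  d <- make_species_means(params, n_per_family = 4, noise_sd = 0.15, seed = 42)
  fits <- candidate_fits("proboscis", d)
  lab <- vapply(fits, function(f) f$spec$label, character(1))
  rss <- vapply(fits, function(f) f$rss, numeric(1))
  expect_lte(rss[lab == "Family + IT"], rss[lab == "Family Only"])
  expect_lte(rss[lab == "Family x IT"], rss[lab == "Family + IT"])
  expect_lte(rss[lab == "Short- vs. Long-Tongued x IT"],
             rss[lab == "Short- vs. Long-Tongued + IT"])

  # multiplying every length by a constant shifts ln y by a constant:
  # RSS and AIC differences between candidates are unchanged
  d2 <- d
  for (col in c("mean_glossa_mm", "mean_prementum_mm", "mean_proboscis_mm"))
    d2[[col]] <- d2[[col]] * 7
  fits2 <- candidate_fits("proboscis", d2)
  aic1 <- vapply(fits, function(f) f$aic, numeric(1))
  aic2 <- vapply(fits2, function(f) f$aic, numeric(1))
  expect_equal(aic1 - min(aic1), aic2 - min(aic2), tolerance = 1e-8)
})

test_that("all seven candidates are fitted on a shared species set", {
  params <- common_slope_params()
  d <- make_species_means(params, n_per_family = 4, noise_sd = 0.1, seed = 3)
  d$mean_proboscis_mm[c(2, 9)] <- NA  # listwise deletion applies to all
  expect_warning(fits <- candidate_fits("proboscis", d), "excluded")
  expect_length(fits, 7L)
  expect_true(all(vapply(fits, function(f) f$n, numeric(1)) == nrow(d) - 2L))
})

test_that("single-family data fails grouping candidates but not IT-only", {
  params <- common_slope_params()
  d <- make_species_means(params, n_per_family = 6, noise_sd = 0.1, seed = 4)
  d <- d[d$family == "Apidae", ]
  fits <- candidate_fits("proboscis", d)
  lab <- vapply(fits, function(f) f$spec$label, character(1))
  failed <- vapply(fits, inherits, logical(1), "allom_fail")
  expect_false(failed[lab == "IT Only"])
  expect_true(all(failed[lab != "IT Only"]))
  best <- select_best(fits)
  expect_equal(best$spec$label, "IT Only")
})

test_that("selection takes the lowest AIC with the stated tie-breaks", {
  mk <- function(aic, k, label) structure(
    list(aic = aic, k = k, spec = list(label = label)), class = "allom_fit")
  expect_equal(select_best(list(mk(10, 2, "a"), mk(8, 5, "b"),
                                mk(12, 3, "c")))$spec$label, "b")
  expect_equal(select_best(list(mk(8, 5, "a"), mk(8, 3, "b")))$spec$label, "b")
  expect_equal(select_best(list(mk(8, 3, "a"), mk(8, 3, "b")))$spec$label, "a")
  expect_error(select_best(list(structure(list(), class = "allom_fail"))),
               "all candidate fits failed")
})

test_that("parameterize sums reference intercept and family offsets", {
  params <- common_slope_params()
  d <- make_species_means(params, n_per_family = 6, noise_sd = 0, seed = 6)
  # zero noise: the true model (and its superset) fit perfectly, with the
  # documented -Inf AIC sentinel; the tie falls to the smaller model
  fit <- suppressWarnings(allometry(d, "proboscis"))
  expect_equal(fit$best$spec$label, "Family + IT")
  # zero noise: the Melittidae intercept is reference + offset = 1.10 exactly
  beta <- coef(fit)
  expect_equal(unname(beta[["(Intercept)"]] + beta[["familyMelittidae"]]),
               1.10, tolerance = 1e-8)
  p <- parameterize(fit)
  expect_equal(p$a[p$family == "Melittidae"], 1.10, tolerance = 1e-8)
  expect_equal(p$a[p$family == "Andrenidae"], 1.06, tolerance = 1e-8)
  # common-slope model replicates one b across families
  expect_equal(unique(round(p$b, 10)), 0.96, tolerance = 1e-8)
  expect_true(all(p$common_slope))
})

test_that("interaction fits yield family-specific scaling exponents", {
  d <- make_species_means(published_coefficients(), n_per_family = 6,
                          noise_sd = 0, seed = 7)
  fit <- suppressWarnings(allometry(d, "prementum"))
  expect_equal(fit$best$spec$it_term, "group_slope")
  p <- parameterize(fit)
  pub <- published_coefficients("prementum")
  expect_equal(p$b[match(pub$family, p$family)], pub$b, tolerance = 1e-8)
  expect_false(any(p$common_slope))
})

test_that("parameterize refuses models without an IT term", {
  mk <- structure(list(spec = list(response = "proboscis",
                                   grouping = "family", it_term = "absent",
                                   label = "Family Only"),
                       coefficients = c("(Intercept)" = 1)),
                  class = "allom_fit")
  expect_error(parameterize(mk), "no allometric power function")
})

test_that("additive fits are parallel on the ln-ln scale", {
  params <- common_slope_params()
  d <- make_species_means(params, n_per_family = 5, noise_sd = 0.1, seed = 8)
  fit <- allometry(d, "proboscis")
  p <- parameterize(fit)
  its <- c(1, 2.5, 4)
  gap <- function(it) log(predict_length(p, "Apidae", it)) -
    log(predict_length(p, "Melittidae", it))
  gaps <- vapply(its, gap, numeric(1))
  expect_equal(max(gaps) - min(gaps), 0, tolerance = 1e-12)
})

test_that("sex-slope comparison is null for identical sexes", {
  base <- make_specimens(n = 6, it = 2)
  base$species <- rep(c("sp1", "sp2"), each = 3)
  two <- rbind(base, transform(base, sex = "male"))
  two$it_mm <- rep(c(1, 2, 3, 1.5, 2.5, 3.5), 2)
  # scatter off any exact line, but identical between the sexes
  two$glossa_mm <- rep(c(0.8, 1.7, 2.6, 1.2, 2.3, 3.4), 2)
  two$prementum_mm <- rep(c(2.1, 3.9, 6.3, 2.8, 5.2, 7.4), 2)
  two$proboscis_mm <- two$glossa_mm + two$prementum_mm
  res <- test_common_slope_by_sex(validate_specimens(two))
  expect_equal(nrow(res), 3L)
  expect_equal(res$F, rep(0, 3), tolerance = 1e-8)
  expect_equal(res$p_value, rep(1, 3), tolerance = 1e-8)
  expect_error(test_common_slope_by_sex(base), "both sexes")
})

test_that("sex-slope test has nominal size and detects slope differences", {
  gen_sex_data <- function(n, slope_diff, noise = 0.1) {
    it <- exp(runif(n, 0, 1.4))
    sex <- rep_len(c("male", "female"), n)
    sp <- rep_len(sprintf("sp%d", 1:4), n)
    b <- 1 + ifelse(sex == "male", slope_diff, 0)
    glossa <- exp(0.5 + b * log(it) + rnorm(n, 0, noise))
    validate_specimens(data.frame(
      specimen_id = as.character(seq_len(n)), species = sp, genus = "G",
      family = "Apidae", sex = sex, it_mm = it, glossa_mm = glossa,
      prementum_mm = 2 * it, region = NA_character_,
      stringsAsFactors = FALSE))
  }
  set.seed(314)
  null_p <- replicate(200, {
    test_common_slope_by_sex(gen_sex_data(80, 0), "glossa")$p_value
  })
  expect_gt(mean(null_p < 0.05), 0.02)
  expect_lt(mean(null_p < 0.05), 0.09)

  set.seed(159)
  alt_rej <- replicate(50, {
    test_common_slope_by_sex(gen_sex_data(200, 0.5), "glossa")$p_value < 0.05
  })
  expect_gt(mean(alt_rej), 0.9)
})

test_that("allometry methods expose the fitted model coherently", {
  d <- make_species_means(common_slope_params(), n_per_family = 5,
                          noise_sd = 0.1, seed = 10)
  fit <- allometry(d, "proboscis")
  tab <- summary(fit)
  expect_equal(nrow(tab), 7L)
  expect_false(is.unsorted(tab$aic))
  expect_equal(sum(tab$selected), 1L)
  expect_equal(AIC(fit), fit$best$aic)
  expect_equal(as.numeric(logLik(fit)), fit$best$loglik)
  expect_equal(length(residuals(fit)), fit$n_species)
  pred <- predict(fit, data.frame(family = "Apidae", it_mm = c(1, 2)))
  p <- parameterize(fit)
  expect_equal(pred[1], exp(p$a[p$family == "Apidae"]), tolerance = 1e-12)
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(fit$n_species, 3L))
  expect_true(all(sims > 0))
})
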