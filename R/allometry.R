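# Interspecific log-log allometric models of mouthpart length on body size.
#
# The allometric power function L = exp(a_g) * IT^b is linear on the natural
# log scale: ln L = a_g + b * ln IT.  A fixed candidate set of seven OLS
# models is fitted to species-level means for each response (proboscis,
# glossa, prementum): group intercepts (bee family, or the short-/long-
# tongued dichotomy) with a common slope, with group-specific slopes, or
# alone; plus the slope-only model.  The best-supported model is the one
# with the lowest AIC.

#' The candidate model set
#'
#' Seven model specifications per response, in a fixed order that also
#' serves as the AIC tie-break: family + IT, family x IT, family only,
#' tongue + IT, tongue x IT, tongue only, IT only.
#'
#' @param response `"proboscis"`, `"glossa"` or `"prementum"`.
#' @return list of model specifications (`response`, `grouping`, `it_term`,
#'   `label`).
#' @export
candidate_models <- function(response = MOUTHPARTS) {
  response <- match.arg(response)
  combos <- list(
    list(grouping = "family",       it_term = "common_slope", label = "Family + IT"),
    list(grouping = "family",       it_term = "group_slope",  label = "Family x IT"),
    list(grouping = "family",       it_term = "absent",       label = "Family Only"),
    list(grouping = "tongue_group", it_term = "common_slope", label = "Short- vs. Long-Tongued + IT"),
    list(grouping = "tongue_group", it_term = "group_slope",  label = "Short- vs. Long-Tongued x IT"),
    list(grouping = "tongue_group", it_term = "absent",       label = "Short- vs. Long-Tongued Only"),
    list(grouping = "none",         it_term = "common_slope", label = "IT Only")
  )
  lapply(combos, function(m) c(list(response = response), m))
}

#' Build the design matrix for one candidate model
#'
#' Response is ln(mean length), predictor ln(mean IT).  Grouping factors are
#' treatment-coded against a fixed alphabetical reference level (Andrenidae
#' for family, "long" for tongue group).
#'
#' @param spec one element of [candidate_models()].
#' @param data `"species_means"` data.frame; rows with a missing response
#'   mean are excluded with a warning.
#' @return list with `X` (design matrix), `y` (ln response), `species`,
#'   `group` (factor or NULL), `log_it`.
#' @export
build_design <- function(spec, data) {
  ycol <- paste0("mean_", spec$response, "_mm")
  check(ycol %in% names(data), "column ", ycol, " not found")
  ok <- !is.na(data[[ycol]]) & !is.na(data$mean_it_mm)
  if (any(!ok)) {
    warning(sum(!ok), " species lacking a ", spec$response,
            " or IT mean excluded", call. = FALSE)
    data <- data[ok, , drop = FALSE]
  }
  check(all(data[[ycol]] > 0) && all(data$mean_it_mm > 0),
        "means must be positive for log transformation")
  y <- log(data[[ycol]])
  lx <- log(data$mean_it_mm)
  n <- length(y)

  group <- NULL
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  if (spec$grouping != "none") {
    gl <- sort(unique(as.character(data[[spec$grouping]])))
    if (length(gl) < 2L)
      stop("grouping '", spec$grouping, "' has a single level (",
           gl, "): design would be rank-deficient", call. = FALSE)
    group <- factor(data[[spec$grouping]], levels = gl)
    D <- stats::model.matrix(~group)[, -1, drop = FALSE]
    colnames(D) <- paste0(spec$grouping, gl[-1])
    X <- cbind(X, D)
  }
  if (spec$it_term != "absent") {
    X <- cbind(X, log_it = lx)
    if (spec$it_term == "group_slope") {
      D <- stats::model.matrix(~group)[, -1, drop = FALSE]
      I <- D * lx
      colnames(I) <- paste0(spec$grouping, levels(group)[-1], ":log_it")
      X <- cbind(X, I)
    }
  }
  list(X = X, y = y, species = data$species, group = group, log_it = lx)
}

#' Fit one log-log OLS model
#'
#' Ordinary least squares on a prepared design.  The log-likelihood is the
#' Gaussian maximum-likelihood value with the error variance profiled out,
#' loglik = -(n/2) (ln 2*pi + ln(RSS/n) + 1), and
#' AIC = -2 loglik + 2 (k + 1), counting the residual variance as an
#' estimated parameter (the convention under which `stats::AIC` evaluates
#' linear models).
#'
#' @param design list from [build_design()], or a numeric matrix `X` if `y`
#'   is supplied separately.
#' @param y response vector (only when `design` is a bare matrix).
#' @param spec optional model specification carried into the result.
#' @return object of class `"allom_fit"`: coefficients, standard errors,
#'   `n`, `k`, `rss`, `loglik`, `aic`, `adj_r2`, fitted values, residuals.
#'   A perfect fit (RSS numerically zero) yields `aic = -Inf` with a
#'   warning.
#' @export
fit_ols <- function(design, y = NULL, spec = NULL) {
  if (is.matrix(design)) design <- list(X = design, y = y)
  X <- design$X
  y <- design$y
  n <- length(y)
  k <- ncol(X)
  check(n > k, "need more observations (", n, ") than coefficients (", k, ")")
  qr_x <- qr(X)
  if (qr_x$rank < k) stop("singular design matrix", call. = FALSE)
  fit <- lm.fit(X, y)
  beta <- fit$coefficients
  res <- fit$residuals
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)

  if (rss <= 1e-12 * max(tss, 1)) {
    warning("perfect fit (RSS ~ 0): AIC reported as -Inf", call. = FALSE)
    loglik <- Inf
    aic <- -Inf
    se <- rep(0, k)
    vc <- matrix(0, k, k, dimnames = list(names(beta), names(beta)))
    adj_r2 <- 1
  } else {
    loglik <- -(n / 2) * (log(2 * pi) + log(rss / n) + 1)
    aic <- -2 * loglik + 2 * (k + 1)
    sigma2 <- rss / (n - k)
    XtXinv <- chol2inv(qr.R(qr_x))
    vc <- sigma2 * XtXinv
    dimnames(vc) <- list(colnames(X), colnames(X))
    se <- sqrt(diag(vc))
    adj_r2 <- 1 - (rss / (n - k)) / (tss / (n - 1))
  }
  names(se) <- names(beta)
  structure(list(spec = spec, coefficients = beta, se = se, vcov = vc,
                 n = n, k = k,
                 rss = rss, loglik = loglik, aic = aic, adj_r2 = adj_r2,
                 fitted = fit$fitted.values, residuals = res,
                 species = design$species, group = design$group,
                 log_it = design$log_it, y = y),
            class = "allom_fit")
}

#' Fit all seven candidate models for one response
#'
#' Applies listwise deletion first -- every candidate is fitted to the same
#' species set, so the AIC values are comparable -- then fits each
#' specification.  Candidates that fail (e.g. a rank-deficient grouping when
#' only one family is present) are recorded with their error message.
#'
#' @param response mouthpart response.
#' @param data `"species_means"` data.frame.
#' @return list of `"allom_fit"` objects (failed candidates carry class
#'   `"allom_fail"` with the message).
#' @export
candidate_fits <- function(response, data) {
  ycol <- paste0("mean_", response, "_mm")
  check(ycol %in% names(data), "column ", ycol, " not found")
  keep <- !is.na(data[[ycol]]) & !is.na(data$mean_it_mm)
  if (any(!keep)) {
    warning(sum(!keep), " species without a ", response,
            " mean excluded from all candidates", call. = FALSE)
    data <- data[keep, , drop = FALSE]
  }
  lapply(candidate_models(response), function(spec) {
    tryCatch(fit_ols(build_design(spec, data), spec = spec),
             error = function(e) structure(list(spec = spec,
                                                message = conditionMessage(e)),
                                           class = "allom_fail"))
  })
}

#' Select the best-supported model
#'
#' The fit with the lowest AIC; exact ties are broken by the smaller number
#' of regression coefficients, then by candidate order.
#'
#' @param fits list from [candidate_fits()].
#' @return the winning `"allom_fit"`.
#' @export
select_best <- function(fits) {
  ok <- !vapply(fits, inherits, logical(1), "allom_fail")
  check(any(ok), "all candidate fits failed")
  fits <- fits[ok]
  aic <- vapply(fits, function(f) f$aic, numeric(1))
  k <- vapply(fits, function(f) f$k, numeric(1))
  ord <- order(aic, k, seq_along(fits))
  fits[[ord[1]]]
}

#' Interspecific allometric model selection
#'
#' The main fitting entry point: aggregates (if given specimen-level data),
#' fits the seven candidate log-log OLS models of mean mouthpart length on
#' mean intertegular distance, and selects the best by AIC.
#'
#' @param data a `"species_means"` table (or any data.frame with `species`,
#'   `family`, `mean_it_mm` and the response mean column), or a
#'   `"specimen_df"` which is aggregated with [species_means()] first.
#' @param response which mouthpart to model.
#' @param sex_filter passed to [species_means()] when `data` is
#'   specimen-level.
#' @return object of class `"allometry"` with components `response`,
#'   `candidates` (all seven fits), `best`, `data` (the species means used)
#'   and `n_species`.  Methods: `print`, `summary`, `coef`, `predict`,
#'   `fitted`, `residuals`, `plot`, `simulate`, `logLik`, `AIC`.
#' @examples
#' cfg <- synth_config(seed = 42, n_species = 5, noise_sd = 0.05)
#' fit <- allometry(gen_specimens(cfg), response = "proboscis")
#' fit
#' coef(fit)
#' @export
allometry <- function(data, response = MOUTHPARTS, sex_filter = "all") {
  response <- match.arg(response)
  if (inherits(data, "specimen_df")) data <- species_means(data, sex_filter)
  fits <- candidate_fits(response, data)
  best <- select_best(fits)
  structure(list(response = response, candidates = fits, best = best,
                 data = data, n_species = best$n),
            class = "allometry")
}

#' Model-selection table for an allometry fit
#'
#' One row per candidate, sorted by increasing AIC (best model first).
#'
#' @param object `"allometry"` object.
#' @param ... unused.
#' @return data.frame with columns `response`, `model`, `n`, `k`, `rss`,
#'   `loglik`, `aic`, `delta_aic`, `adj_r2`, `selected`.
#' @export
summary.allometry <- function(object, ...) {
  rows <- lapply(object$candidates, function(f) {
    if (inherits(f, "allom_fail"))
      data.frame(response = f$spec$response, model = f$spec$label,
                 n = NA_integer_, k = NA_integer_, rss = NA_real_,
                 loglik = NA_real_, aic = NA_real_, adj_r2 = NA_real_,
                 error = f$message, stringsAsFactors = FALSE)
    else
      data.frame(response = f$spec$response, model = f$spec$label,
                 n = f$n, k = f$k, rss = f$rss, loglik = f$loglik,
                 aic = f$aic, adj_r2 = f$adj_r2, error = NA_character_,
                 stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$aic), , drop = FALSE]
  tab$delta_aic <- tab$aic - min(tab$aic, na.rm = TRUE)
  tab$selected <- tab$model == object$best$spec$label
  rownames(tab) <- NULL
  tab[, c("response", "model", "n", "k", "rss", "loglik", "aic",
          "delta_aic", "adj_r2", "selected", "error")]
}

#' Test for a common allometric slope across sexes
#'
#' Specimen-level check that males and females share the IT scaling slope:
#' for each response, the model ln(length) ~ species + sex * ln(IT) is
#' compared with the additive ln(length) ~ species + sex + ln(IT) by an
#' F test.  A non-significant interaction supports pooling the sexes.
#'
#' @param records `"specimen_df"` with both sexes present.
#' @param responses mouthparts to test.
#' @return data.frame with one row per response: `F`, `df1`, `df2`,
#'   `p_value`.
#' @export
test_common_slope_by_sex <- function(records, responses = MOUTHPARTS) {
  records <- records[records$sex %in% c("male", "female"), , drop = FALSE]
  check(length(unique(records$sex)) == 2L,
        "both sexes must be represented in the specimen data")
  rows <- lapply(responses, function(resp) {
    col <- paste0(resp, "_mm")
    d <- records[!is.na(records[[col]]), , drop = FALSE]
    d <- data.frame(ln_len = log(d[[col]]), ln_it = log(d$it_mm),
                    species = factor(d$species), sex = factor(d$sex))
    full <- stats::lm(ln_len ~ species + sex * ln_it, data = d)
    add  <- stats::lm(ln_len ~ species + sex + ln_it, data = d)
    cmp <- stats::anova(add, full)
    Fv <- cmp$F[2]
    ## identical sexes give RSS_full == RSS_add and an F of exactly 0
    if (is.na(Fv)) Fv <- 0
    pv <- cmp$`Pr(>F)`[2]
    if (is.na(pv)) pv <- 1
    data.frame(response = resp, F = Fv, df1 = abs(cmp$Df[2]),
               df2 = cmp$Res.Df[2], p_value = pv, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
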