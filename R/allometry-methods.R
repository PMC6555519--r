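# S3 methods for "allometry" objects.

#' @export
print.allom_fit <- function(x, ...) {
  cat("Log-log OLS fit:", x$spec$label, "(", x$spec$response, ")\n")
  cat(sprintf("  n = %d species, k = %d coefficients, AIC = %.2f, adj R2 = %.3f\n",
              x$n, x$k, x$aic, x$adj_r2))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
print.allometry <- function(x, ...) {
  cat("Interspecific allometric model selection --", x$response, "length\n")
  cat(sprintf("  %d species, %d candidate models\n\n",
              x$n_species, length(x$candidates)))
  tab <- summary(x)
  show <- tab[, c("model", "k", "adj_r2", "aic", "delta_aic")]
  show$adj_r2 <- round(show$adj_r2, 2)
  show$aic <- round(show$aic, 2)
  show$delta_aic <- round(show$delta_aic, 2)
  show$model <- ifelse(tab$selected, paste0("* ", show$model), paste0("  ", show$model))
  print(show, row.names = FALSE)
  cat("\n* lowest-AIC (best-supported) model\n")
  invisible(x)
}

#' Coefficients of the best-supported model
#'
#' @param object `"allometry"` object.
#' @param ... unused.
#' @return named numeric vector (treatment-coded regression scale).  For the
#'   per-family power-function layout use [parameterize()].
#' @export
coef.allometry <- function(object, ...) object$best$coefficients

#' @export
fitted.allometry <- function(object, ...) {
  structure(object$best$fitted, names = object$best$species)
}

#' Residuals of the best-supported model (ln-mm scale)
#' @param object `"allometry"` object.
#' @param ... unused.
#' @export
residuals.allometry <- function(object, ...) {
  structure(object$best$residuals, names = object$best$species)
}

#' @export
logLik.allometry <- function(object, ...) {
  structure(object$best$loglik, df = object$best$k + 1, class = "logLik")
}

#' AIC of the best-supported model
#' @param object `"allometry"` object.
#' @param ... unused.
#' @param k penalty per parameter (2 for AIC).
#' @export
AIC.allometry <- function(object, ..., k = 2) {
  -2 * object$best$loglik + k * (object$best$k + 1)
}

#' Predict mouthpart length for new species
#'
#' Evaluates the best-supported model on new data, on the millimetre scale.
#'
#' @param object `"allometry"` object.
#' @param newdata data.frame with `family` and `it_mm` (or `mean_it_mm`)
#'   columns; defaults to the fitted species.
#' @param ... unused.
#' @return numeric vector of predicted lengths (mm).
#' @export
predict.allometry <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(exp(object$best$fitted))
  params <- parameterize(object)
  it <- if ("it_mm" %in% names(newdata)) newdata$it_mm else newdata$mean_it_mm
  check(!is.null(it), "newdata needs an it_mm or mean_it_mm column")
  predict_length(params, newdata$family, it)
}

#' Plot the interspecific allometric relationship
#'
#' Species-mean points on the ln-ln scale, one colour per family, with the
#' fitted lines of the best-supported model.
#'
#' @param x `"allometry"` object.
#' @param ... passed to `plot()`.
#' @export
plot.allometry <- function(x, ...) {
  b <- x$best
  fam <- x$data$family[match(b$species, x$data$species)]
  cols <- stats::setNames(grDevices::hcl.colors(length(BEE_FAMILIES), "Dark 3"),
                          BEE_FAMILIES)
  plot(b$log_it, b$y, col = cols[fam], pch = 19,
       xlab = "ln intertegular distance (ln mm)",
       ylab = paste0("ln ", x$response, " length (ln mm)"),
       main = paste("Allometry:", b$spec$label), ...)
  params <- tryCatch(parameterize(x), error = function(e) NULL)
  if (!is.null(params)) {
    xs <- seq(min(b$log_it), max(b$log_it), length.out = 50)
    for (f in unique(fam)) {
      p <- params[params$family == f, ]
      graphics::lines(xs, p$a[1] + p$b[1] * xs, col = cols[f])
    }
  }
  graphics::legend("topleft", legend = unique(fam), col = cols[unique(fam)],
                   pch = 19, cex = 0.8, bty = "n")
  invisible(x)
}

#' Simulate species-mean responses from the fitted model
#'
#' Draws new ln-scale responses at the observed ln IT values from the
#' best-supported model with Gaussian noise at the ML residual standard
#' deviation, and returns them on the millimetre scale.
#'
#' @param object `"allometry"` object.
#' @param nsim number of replicate datasets.
#' @param seed optional RNG seed (restores the caller's RNG state).
#' @param ... unused.
#' @return data.frame with `nsim` columns (`sim_1`, ...), one row per
#'   fitted species.
#' @export
simulate.allometry <- function(object, nsim = 1, seed = NULL, ...) {
  b <- object$best
  sd_ml <- sqrt(b$rss / b$n)
  sims <- with_seed(seed, replicate(nsim, exp(b$fitted + stats::rnorm(b$n, 0, sd_ml))))
  out <- as.data.frame(sims)
  names(out) <- paste0("sim_", seq_len(nsim))
  rownames(out) <- b$species
  out
}
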