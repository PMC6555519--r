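# Predicting mouthpart lengths and foraging distances for museum species.
#
# Museum collections hold far more intact specimens than can be dissected:
# intertegular distance is measurable on pinned material, and the fitted
# power function turns species-mean IT into proboscis / glossa / prementum
# estimates.  Foraging (homing) distance follows separately published
# log10-log10 regressions of distance (km) on body size; those coefficients
# are not bundled here and must be transcribed from the source publication
# into a small config.

#' Foraging-distance regression coefficients
#'
#' Defines one log10-log10 regression
#' `log10(distance km) = c0 + c1 * log10(IT)` with an explicit unit for the
#' IT predictor (the body-size allometry literature mixes mm and cm).  Two
#' kinds are used: the distance a bee routinely covers (`"typical"`) and the
#' farthest recorded (`"maximum"`).
#'
#' No numeric defaults ship with the package: transcribe `c0`, `c1` and the
#' IT unit for each kind from the published foraging-range regressions.
#'
#' @param kind `"typical"` or `"maximum"`.
#' @param c0 intercept (log10 km).
#' @param c1 slope (log10 km per log10 IT unit).
#' @param it_unit unit the regression expects IT in: `"mm"` or `"cm"`.
#' @return list of class `"foraging_coefficients"`.
#' @export
foraging_coefficients <- function(kind = c("typical", "maximum"),
                                  c0, c1, it_unit = c("cm", "mm")) {
  kind <- match.arg(kind)
  it_unit <- match.arg(it_unit)
  if (missing(c0) || missing(c1))
    stop("foraging-distance coefficients are not configured: supply c0 and ",
         "c1 transcribed from the published foraging-range regressions",
         call. = FALSE)
  check(is.finite(c0) && is.finite(c1), "c0 and c1 must be finite numbers")
  structure(list(kind = kind, c0 = c0, c1 = c1, it_unit = it_unit,
                 out_unit = "km"),
            class = "foraging_coefficients")
}

#' @export
print.foraging_coefficients <- function(x, ...) {
  cat(sprintf("%s foraging distance: log10(km) = %g + %g * log10(IT %s)\n",
              x$kind, x$c0, x$c1, x$it_unit))
  invisible(x)
}

#' Estimate foraging distance from body size
#'
#' Evaluates `10^(c0 + c1 * log10(IT))` after converting IT from mm to the
#' unit the regression was published in.
#'
#' @param coeffs `"foraging_coefficients"` object.
#' @param it_mm intertegular distance in mm, positive.
#' @return distance in km.
#' @export
estimate_foraging <- function(coeffs, it_mm) {
  check(inherits(coeffs, "foraging_coefficients"),
        "coeffs must come from foraging_coefficients()")
  check(all(it_mm > 0), "it_mm must be positive")
  it <- if (coeffs$it_unit == "cm") it_mm / 10 else it_mm
  10^(coeffs$c0 + coeffs$c1 * log10(it))
}

#' Batch trait and foraging-distance estimation for a species table
#'
#' Applies the power function to every species' mean IT for all three
#' mouthparts, and the foraging regressions where configured.  Per-species
#' failures (e.g. a family missing from the coefficient table) are collected
#' in the `"failures"` attribute rather than aborting the batch.
#'
#' @param params `"power_function"` table covering all three responses (or
#'   a subset; missing responses yield `NA` estimates).
#' @param species_table `"species_means"` data.frame with `species`,
#'   `family`, `mean_it_mm` and optionally `regions`.
#' @param typical,maximum optional `"foraging_coefficients"`.
#' @return data.frame of class `"trait_estimates"`: `species`, `family`,
#'   `mean_it_mm`, `est_proboscis_mm`, `est_glossa_mm`, `est_prementum_mm`,
#'   `typical_km`, `maximum_km`, `regions`; input order preserved.
#' @export
batch_estimate <- function(params, species_table,
                           typical = NULL, maximum = NULL) {
  check(all(!is.na(species_table$mean_it_mm)), "every species needs a mean IT")
  n <- nrow(species_table)
  out <- data.frame(species = species_table$species,
                    family = species_table$family,
                    mean_it_mm = species_table$mean_it_mm,
                    stringsAsFactors = FALSE)
  failures <- character(0)
  est_col <- function(resp) {
    p <- params[params$response == resp, , drop = FALSE]
    if (nrow(p) == 0L) return(rep(NA_real_, n))
    vapply(seq_len(n), function(i) {
      tryCatch(predict_length(p, out$family[i], out$mean_it_mm[i]),
               error = function(e) {
                 failures <<- c(failures, paste0(out$species[i], " (", resp,
                                                 "): ", conditionMessage(e)))
                 NA_real_
               })
    }, numeric(1))
  }
  out$est_proboscis_mm <- est_col("proboscis")
  out$est_glossa_mm <- est_col("glossa")
  out$est_prementum_mm <- est_col("prementum")
  out$typical_km <- if (is.null(typical)) NA_real_ else
    estimate_foraging(typical, out$mean_it_mm)
  out$maximum_km <- if (is.null(maximum)) NA_real_ else
    estimate_foraging(maximum, out$mean_it_mm)
  out$regions <- if ("regions" %in% names(species_table))
    species_table$regions else NA_character_
  class(out) <- c("trait_estimates", "data.frame")
  attr(out, "failures") <- failures
  out
}

#' Summarize trait estimates by rainfall region
#'
#' Species often span several rainfall-seasonality regions; each species
#' contributes to every region in its region set, so the per-region counts
#' may sum to more than the number of species.  Species with an empty region
#' set are reported under `"unassigned"`.
#'
#' @param estimates `"trait_estimates"` data.frame whose `regions` column
#'   holds comma-separated region labels.
#' @param vars columns to summarize.
#' @return data.frame with one row per (region, variable): `n_species`,
#'   `q25`, `median`, `q75`, `mean`.
#' @export
summarize_by_region <- function(estimates,
                                vars = c("mean_it_mm", "est_proboscis_mm",
                                         "est_glossa_mm", "est_prementum_mm",
                                         "typical_km", "maximum_km")) {
  regs <- strsplit(ifelse(is.na(estimates$regions) | estimates$regions == "",
                          "unassigned", estimates$regions), ",", fixed = TRUE)
  long_idx <- rep(seq_len(nrow(estimates)), lengths(regs))
  region <- unlist(regs)
  levels <- c(intersect(RAINFALL_REGIONS, unique(region)),
              setdiff(unique(region), RAINFALL_REGIONS))
  rows <- list()
  for (reg in levels) {
    idx <- long_idx[region == reg]
    for (v in vars) {
      x <- estimates[[v]][idx]
      x <- x[!is.na(x)]
      rows[[length(rows) + 1L]] <- data.frame(
        region = reg, variable = v, n_species = length(idx),
        q25 = if (length(x)) unname(stats::quantile(x, 0.25)) else NA_real_,
        median = if (length(x)) stats::median(x) else NA_real_,
        q75 = if (length(x)) unname(stats::quantile(x, 0.75)) else NA_real_,
        mean = if (length(x)) mean(x) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
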