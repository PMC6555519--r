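# Parameterizing the allometric power function L = exp(a_f) * IT^b.
#
# The best-supported regression is reported on the treatment-coded scale
# (reference intercept plus group offsets).  Field usage reports absolute
# per-family coefficients: a_f on the natural-log scale for every family,
# and either a single IT scaling exponent b (additive model) or a
# family-specific b_f (interaction model).

#' Per-family power-function coefficients from a fitted model
#'
#' Converts the treatment-coded coefficients of the best-supported model
#' into absolute per-family intercepts `a` (natural-log scale) and scaling
#' exponents `b`.  When the model groups by tongue type, both families of a
#' tongue group share that group's coefficients; when it has no grouping,
#' all families share one pair.  A model without an IT term defines no power
#' function and is an error.
#'
#' @param fit an `"allometry"` object or a single `"allom_fit"`.
#' @param families families to cover (default: the six families present in
#'   the coefficient tables).
#' @return data.frame of class `"power_function"`: `response`, `family`,
#'   `a` (ln-scale intercept), `b` (IT scaling exponent), `common_slope`
#'   (logical).
#' @export
parameterize <- function(fit, families = BEE_FAMILIES) {
  if (inherits(fit, "allometry")) fit <- fit$best
  check(inherits(fit, "allom_fit"), "need an allometry fit")
  spec <- fit$spec
  check(spec$it_term != "absent",
        "best model '", spec$label, "' has no IT term: no allometric power ",
        "function is defined")
  beta <- fit$coefficients
  grouping <- spec$grouping

  group_of <- switch(grouping,
    none = rep("all", length(families)),
    family = families,
    tongue_group = tongue_group(families))
  ## only emit families whose group actually appeared in the fitted data
  if (grouping != "none") {
    seen <- levels(fit$group)
    keep <- group_of %in% seen
    if (grouping == "family") keep <- families %in% seen
    families <- families[keep]
    group_of <- group_of[keep]
  }
  ref <- if (grouping == "none") "all" else levels(fit$group)[1]

  a <- vapply(group_of, function(g) {
    off <- if (g == ref) 0 else beta[[paste0(grouping, g)]]
    beta[["(Intercept)"]] + off
  }, numeric(1))
  b <- vapply(group_of, function(g) {
    if (spec$it_term == "common_slope" || g == ref) beta[["log_it"]]
    else beta[["log_it"]] + beta[[paste0(grouping, g, ":log_it")]]
  }, numeric(1))

  out <- data.frame(response = spec$response, family = families,
                    a = unname(a), b = unname(b),
                    common_slope = spec$it_term == "common_slope",
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("power_function", "data.frame")
  out
}

#' @export
print.power_function <- function(x, digits = 3, ...) {
  cat("Allometric power function  L = exp(a) * IT^b   (",
      x$response[1], ", ln scale coefficients)\n", sep = "")
  tab <- data.frame(family = x$family, a = round(x$a, digits),
                    b = round(x$b, digits))
  print(tab, row.names = FALSE)
  if (all(x$common_slope)) cat("common IT scaling exponent across families\n")
  invisible(x)
}

#' Predict mouthpart length from the power function
#'
#' Evaluates `L = exp(a_f) * IT^b` on the millimetre scale; exactly
#' ln-linear in ln(IT).
#'
#' @param params `"power_function"` data.frame (from [parameterize()] or
#'   [read_power_function()]).
#' @param family family of each value (recycled if scalar).
#' @param it_mm intertegular distance in mm, positive.
#' @return numeric vector of lengths (mm).
#' @export
predict_length <- function(params, family, it_mm) {
  check(all(it_mm > 0), "it_mm must be positive")
  n <- max(length(family), length(it_mm))
  family <- rep_len(family, n)
  it_mm <- rep_len(it_mm, n)
  idx <- match(family, params$family)
  if (anyNA(idx))
    stop("family not covered by the coefficient table: ",
         paste(unique(family[is.na(idx)]), collapse = ", "),
         " (covered: ", paste(params$family, collapse = ", "), ")",
         call. = FALSE)
  exp(params$a[idx] + params$b[idx] * log(it_mm))
}

#' Read / write a power-function coefficient table
#'
#' Flat CSV with columns `response`, `family`, `a`, `b` (ln-scale intercept
#' and IT scaling exponent), mirroring the published coefficient-table
#' layout.  A table may hold several responses; `read_power_function()`
#' extracts one.
#'
#' @param path CSV file.
#' @param response which response block to read (default: all rows).
#' @return `"power_function"` data.frame.
#' @export
read_power_function <- function(path, response = NULL) {
  check(file.exists(path), "file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("response", "family", "a", "b")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L)
    stop("coefficient table lacks column(s): ", paste(missing, collapse = ", "))
  if (!is.null(response)) {
    df <- df[df$response == response, , drop = FALSE]
    check(nrow(df) > 0L, "no rows for response '", response, "'")
  }
  if (!"common_slope" %in% names(df)) {
    cs <- stats::ave(df$b, df$response, FUN = function(x) length(unique(x)) == 1L)
    df$common_slope <- cs == 1
  }
  df <- df[, c("response", "family", "a", "b", "common_slope")]
  class(df) <- c("power_function", "data.frame")
  df
}

#' @rdname read_power_function
#' @param params `"power_function"` table to write.
#' @export
write_power_function <- function(params, path) {
  utils::write.csv(params[, c("response", "family", "a", "b")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Bundled power-function coefficients for the six bee families
#'
#' The published family-specific intercepts and IT scaling exponents
#' (natural-log scale) for proboscis, glossa and prementum length:
#' proboscis and glossa scale with a common exponent across families
#' (0.96 and 1.04), the prementum with family-specific exponents.
#'
#' @param response optionally restrict to one response.
#' @return `"power_function"` data.frame.
#' @export
published_coefficients <- function(response = NULL) {
  path <- system.file("extdata", "power_function_coefficients.csv",
                      package = "beeallometry", mustWork = TRUE)
  read_power_function(path, response)
}
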