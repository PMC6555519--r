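# Internal helpers shared across modules.

#' @keywords internal
#' @importFrom stats lm.fit setNames
"_PACKAGE"

## The six bee families covered by the allometric coefficient tables, and the
## tongue-group classification: the labio-maxillary complex of Apidae and
## Megachilidae has a glossa longer than the prementum ("long-tongued"); the
## remaining families are "short-tongued".
BEE_FAMILIES <- c("Andrenidae", "Apidae", "Colletidae", "Halictidae",
                  "Megachilidae", "Melittidae")
LONG_TONGUED <- c("Apidae", "Megachilidae")

RAINFALL_REGIONS <- c("winter", "aseasonal", "early_summer", "late_summer")

MOUTHPARTS <- c("proboscis", "glossa", "prementum")

#' Tongue group for a bee family
#'
#' Maps family to the classical short-/long-tongued dichotomy: Apidae and
#' Megachilidae are long-tongued, the other four covered families
#' short-tongued.
#'
#' @param family character vector of family names.
#' @return character vector, `"long"` or `"short"`.
#' @export
tongue_group <- function(family) {
  bad <- setdiff(unique(family), BEE_FAMILIES)
  if (length(bad) > 0L)
    stop("unknown bee family: ", paste(bad, collapse = ", "),
         " (expected one of ", paste(BEE_FAMILIES, collapse = ", "), ")")
  ifelse(family %in% LONG_TONGUED, "long", "short")
}

## Evaluate expr under a fixed RNG state without disturbing the caller's
## stream; NULL seed leaves the global stream in charge.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## stopifnot with a readable message
check <- function(cond, ...) if (!isTRUE(cond)) stop(..., call. = FALSE)
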