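# Reading, validating and aggregating specimen-level morphometrics.
#
# A specimen record holds the intertegular distance (IT, mm) -- the standard
# body-size proxy measured between the wing tegulae -- and, for dissected
# specimens, the glossa and prementum lengths (mm).  Proboscis length is
# defined as glossa + prementum: when the labio-maxillary complex is extended
# the two parts align and their sum is the functional tongue length.

#' Default column mapping for specimen CSV files
#'
#' Maps the internal field names onto the column names found in the file.
#' Override individual entries to read files with different headers.
#'
#' @param ... named overrides, e.g. `it_mm = "IT"`.
#' @return named character vector (internal field -> file column).
#' @export
specimen_schema <- function(...) {
  schema <- c(specimen_id = "specimen_id", species = "species",
              genus = "genus", family = "family", sex = "sex",
              it_mm = "it_mm", glossa_mm = "glossa_mm",
              prementum_mm = "prementum_mm", region = "region")
  over <- c(...)
  if (length(over) > 0L) {
    bad <- setdiff(names(over), names(schema))
    if (length(bad) > 0L) stop("unknown schema field: ", paste(bad, collapse = ", "))
    schema[names(over)] <- over
  }
  schema
}

#' Read specimen-level morphometric records from CSV
#'
#' Reads one row per measured specimen, derives the tongue group from the
#' family and the proboscis length as glossa + prementum, and validates every
#' row.  Columns `specimen_id`, `sex`, `glossa_mm`, `prementum_mm` and
#' `region` are optional in the file; IT, species, genus and family are
#' required.
#'
#' @param path CSV file with a header row (UTF-8).
#' @param schema column mapping from [specimen_schema()].
#' @param strict if `TRUE` (default) invalid rows abort with an error naming
#'   the offending file rows; if `FALSE` they are dropped with a warning.
#' @return data.frame of class `"specimen_df"` with columns `specimen_id`,
#'   `species`, `genus`, `family`, `tongue_group`, `sex`, `it_mm`,
#'   `glossa_mm`, `prementum_mm`, `proboscis_mm`, `region`.
#' @export
read_specimens <- function(path, schema = specimen_schema(), strict = TRUE) {
  check(file.exists(path), "file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8", check.names = FALSE)
  required <- c("species", "genus", "family", "it_mm")
  missing <- required[!schema[required] %in% names(raw)]
  if (length(missing) > 0L)
    stop("missing required column(s): ",
         paste(schema[missing], collapse = ", "), " in ", path)

  get_col <- function(field, default = NA) {
    col <- schema[[field]]
    if (!is.null(col) && col %in% names(raw)) raw[[col]] else rep(default, nrow(raw))
  }
  df <- data.frame(
    specimen_id  = as.character(get_col("specimen_id", NA_character_)),
    species      = as.character(get_col("species")),
    genus        = as.character(get_col("genus")),
    family       = as.character(get_col("family")),
    sex          = as.character(get_col("sex", "unknown")),
    it_mm        = suppressWarnings(as.numeric(get_col("it_mm"))),
    glossa_mm    = suppressWarnings(as.numeric(get_col("glossa_mm"))),
    prementum_mm = suppressWarnings(as.numeric(get_col("prementum_mm"))),
    region       = as.character(get_col("region", NA_character_)),
    stringsAsFactors = FALSE
  )
  if (all(is.na(df$specimen_id))) df$specimen_id <- sprintf("row%04d", seq_len(nrow(df)))
  df$sex[is.na(df$sex) | df$sex == ""] <- "unknown"
  validate_specimens(df, strict = strict)
}

#' Validate and finalize specimen records
#'
#' Derives `tongue_group` and `proboscis_mm` and checks the row-level
#' invariants: positive IT, positive mouthpart lengths where present, known
#' family, known sex and region labels.
#'
#' @param df data.frame with the specimen columns (see [read_specimens()]).
#' @param strict abort on invalid rows (`TRUE`) or drop them with a warning.
#' @return validated `"specimen_df"` data.frame.
#' @export
validate_specimens <- function(df, strict = TRUE) {
  n <- nrow(df)
  problems <- character(0)
  bad <- logical(n)
  flag <- function(rows, what) {
    if (any(rows)) {
      problems <<- c(problems,
                     paste0(what, " (row ", paste(which(rows), collapse = ", "), ")"))
      bad <<- bad | rows
    }
  }
  flag(is.na(df$it_mm) | df$it_mm <= 0, "non-positive or non-numeric it_mm")
  flag(!is.na(df$glossa_mm) & df$glossa_mm <= 0, "non-positive glossa_mm")
  flag(!is.na(df$prementum_mm) & df$prementum_mm <= 0, "non-positive prementum_mm")
  flag(!df$family %in% BEE_FAMILIES, "unknown family")
  flag(!df$sex %in% c("male", "female", "unknown"), "unknown sex label")
  flag(!is.na(df$region) & !df$region %in% RAINFALL_REGIONS, "unknown region label")
  flag(is.na(df$species) | df$species == "", "missing species")

  if (length(problems) > 0L) {
    msg <- paste("invalid specimen rows:", paste(problems, collapse = "; "))
    if (strict) stop(msg, call. = FALSE)
    warning(msg, "; ", sum(bad), " row(s) dropped", call. = FALSE)
    df <- df[!bad, , drop = FALSE]
  }
  df$tongue_group <- tongue_group(df$family)
  df$proboscis_mm <- df$glossa_mm + df$prementum_mm
  df <- df[, c("specimen_id", "species", "genus", "family", "tongue_group",
               "sex", "it_mm", "glossa_mm", "prementum_mm", "proboscis_mm",
               "region")]
  rownames(df) <- NULL
  class(df) <- c("specimen_df", "data.frame")
  df
}

#' Aggregate specimens into species-level trait means
#'
#' Computes per-species arithmetic means of IT and mouthpart lengths, the
#' regression units for the interspecific allometric models.  Specimens are
#' weighted equally.  Specimens lacking a dissected mouthpart contribute to
#' the IT mean only (museum series are typically IT-only), so mouthpart means
#' may rest on fewer specimens than `n_specimens`.
#'
#' @param records `"specimen_df"` data.frame from [read_specimens()] /
#'   [validate_specimens()] or [gen_specimens()].
#' @param sex_filter `"all"` (default, sexes pooled), `"male"` or `"female"`.
#'   Sexes are pooled by default because males and females share a common
#'   allometric slope; the filter allows single-sex reanalysis.
#' @return data.frame of class `"species_means"` with one row per species:
#'   taxonomy, `n_specimens`, `mean_it_mm`, `mean_glossa_mm`,
#'   `mean_prementum_mm`, `mean_proboscis_mm` and `regions` (comma-separated
#'   union of the specimens' region labels).
#' @export
species_means <- function(records, sex_filter = c("all", "male", "female")) {
  sex_filter <- match.arg(sex_filter)
  if (sex_filter != "all") {
    keep <- records$sex == sex_filter
    dropped <- unique(records$species[!records$species %in% records$species[keep]])
    if (length(dropped) > 0L)
      warning("species with no ", sex_filter, " specimens omitted: ",
              paste(dropped, collapse = ", "), call. = FALSE)
    records <- records[keep, , drop = FALSE]
  }
  check(nrow(records) > 0L, "no specimens left after sex filter")

  mean_or_na <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  split_idx <- split(seq_len(nrow(records)), records$species)
  rows <- lapply(split_idx, function(i) {
    r <- records[i, , drop = FALSE]
    data.frame(
      species = r$species[1], genus = r$genus[1], family = r$family[1],
      tongue_group = r$tongue_group[1],
      n_specimens = nrow(r),
      mean_it_mm = mean_or_na(r$it_mm),
      mean_glossa_mm = mean_or_na(r$glossa_mm),
      mean_prementum_mm = mean_or_na(r$prementum_mm),
      mean_proboscis_mm = mean_or_na(r$proboscis_mm),
      regions = paste(sort(unique(r$region[!is.na(r$region)])), collapse = ","),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$species), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("species_means", "data.frame")
  out
}

#' Read a species-level trait mean table from CSV
#'
#' For tables that are already aggregated (e.g. museum species means).
#' Required columns: `species`, `family`, `mean_it_mm`; the remaining
#' species-mean columns are optional.
#'
#' @param path CSV file.
#' @return `"species_means"` data.frame.
#' @export
read_species_means <- function(path) {
  check(file.exists(path), "file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  required <- c("species", "family", "mean_it_mm")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L)
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  for (col in c("genus", "regions")) if (!col %in% names(df)) df[[col]] <- NA_character_
  for (col in c("mean_glossa_mm", "mean_prementum_mm", "mean_proboscis_mm"))
    if (!col %in% names(df)) df[[col]] <- NA_real_
  if (!"n_specimens" %in% names(df)) df$n_specimens <- NA_integer_
  df$tongue_group <- tongue_group(df$family)
  check(all(df$mean_it_mm > 0, na.rm = TRUE), "mean_it_mm must be positive")
  class(df) <- c("species_means", "data.frame")
  df
}
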