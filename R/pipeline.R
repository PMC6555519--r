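# End-to-end orchestration: config-driven runs producing deterministic
# tabular reports (model-selection table, coefficient table, trait
# estimates, region-comparison report).  Reports carry a provenance header
# (package version, seed, config checksum) as comment lines; the data rows
# contain no timestamps so reruns are byte-identical.

#' Read a pipeline configuration
#'
#' Flat YAML with blocks: `paths` (specimens, species_means, tree,
#' coefficients), `sex_filter`, `responses`, `foraging` (typical/maximum
#' with `c0`, `c1`, `it_unit`), `seed`, `out_dir`.
#'
#' @param path YAML file.
#' @return list of class `"pipeline_config"` (with the config file checksum
#'   attached for the report headers).
#' @export
read_pipeline_config <- function(path) {
  check(file.exists(path), "config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  cfg$config_md5 <- unname(tools::md5sum(path))
  cfg$config_dir <- dirname(normalizePath(path))
  if (is.null(cfg$sex_filter)) cfg$sex_filter <- "all"
  if (is.null(cfg$responses)) cfg$responses <- MOUTHPARTS
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (is.null(cfg$out_dir)) cfg$out_dir <- "."
  class(cfg) <- "pipeline_config"
  cfg
}

## resolve a config-relative path
cfg_path <- function(cfg, p) {
  if (is.null(p)) return(NULL)
  if (file.exists(p)) p else file.path(cfg$config_dir, p)
}

report_header <- function(cfg) {
  c(paste0("# beeallometry ",
           as.character(utils::packageVersion("beeallometry"))),
    paste0("# seed=", cfg$seed, " config_md5=",
           if (is.null(cfg$config_md5)) "none" else cfg$config_md5))
}

write_report <- function(df, path, cfg) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(report_header(cfg), con)
  ## quote strings: the regions column holds comma-separated sets
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a report written by the pipeline (skipping the provenance header)
#' @param path report CSV.
#' @return data.frame.
#' @export
read_report <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Run the allometric model-selection stage
#'
#' Reads (or receives) specimen data, aggregates species means, fits the
#' seven candidates for every configured response, and writes two reports:
#' `model_selection.csv` (one row per candidate, AIC-ascending within
#' response, best flagged) and `coefficients.csv` (power-function layout:
#' family-specific coefficient and IT scaling coefficient per response).
#'
#' @param cfg `"pipeline_config"`, or a list with at least `seed`; specimen
#'   data can be passed directly via `specimens`.
#' @param specimens optional `"specimen_df"` (otherwise read from
#'   `cfg$paths$specimens`).
#' @param write write the reports to `cfg$out_dir` (default TRUE).
#' @return list: `selection` (combined candidate table), `coefficients`
#'   (combined power-function table), `fits` (named list of `"allometry"`
#'   objects), `paths` of written reports.
#' @export
run_fit <- function(cfg, specimens = NULL, write = TRUE) {
  if (is.null(specimens)) {
    p <- cfg_path(cfg, cfg$paths$specimens)
    check(!is.null(p), "config has no paths$specimens and no data supplied")
    specimens <- read_specimens(p)
  }
  means <- species_means(specimens, cfg$sex_filter)
  fits <- list()
  sel <- list()
  coefs <- list()
  for (resp in cfg$responses) {
    message("[fit] ", resp, ": 7 candidates, n = ", nrow(means), " species")
    fit <- allometry(means, response = resp)
    fits[[resp]] <- fit
    sel[[resp]] <- summary(fit)
    coefs[[resp]] <- tryCatch(as.data.frame(parameterize(fit)),
                              error = function(e) NULL)
  }
  selection <- do.call(rbind, sel)
  rownames(selection) <- NULL
  coefficients <- do.call(rbind, coefs)
  paths <- character(0)
  if (write) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(
      selection = write_report(selection,
                               file.path(cfg$out_dir, "model_selection.csv"),
                               cfg),
      coefficients = write_report(coefficients,
                                  file.path(cfg$out_dir, "coefficients.csv"),
                                  cfg))
  }
  list(selection = selection, coefficients = coefficients, fits = fits,
       paths = paths)
}

#' Run the trait-estimation stage
#'
#' Applies a power-function coefficient table to a species-mean table
#' (museum IT measurements) and, when foraging coefficients are configured,
#' the foraging-distance regressions; writes `estimates.csv` and
#' `region_summary.csv`.
#'
#' @param cfg `"pipeline_config"` with `paths$species_means` and
#'   `paths$coefficients`, plus an optional `foraging` block.
#' @param species_table,params optional in-memory inputs overriding the
#'   config paths.
#' @param write write reports.
#' @return list: `estimates`, `region_summary`, `paths`.
#' @export
run_estimate <- function(cfg, species_table = NULL, params = NULL,
                         write = TRUE) {
  if (is.null(species_table))
    species_table <- read_species_means(cfg_path(cfg, cfg$paths$species_means))
  if (is.null(params))
    params <- read_power_function(cfg_path(cfg, cfg$paths$coefficients))
  fc <- function(block, kind) {
    if (is.null(block)) return(NULL)
    foraging_coefficients(kind, c0 = block$c0, c1 = block$c1,
                          it_unit = block$it_unit)
  }
  typical <- fc(cfg$foraging$typical, "typical")
  maximum <- fc(cfg$foraging$maximum, "maximum")
  est <- batch_estimate(params, species_table, typical, maximum)
  if (length(attr(est, "failures")) > 0L)
    warning("estimation failures: ",
            paste(attr(est, "failures"), collapse = "; "), call. = FALSE)
  summ <- summarize_by_region(est)
  paths <- character(0)
  if (write) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(
      estimates = write_report(as.data.frame(est),
                               file.path(cfg$out_dir, "estimates.csv"), cfg),
      region_summary = write_report(summ,
                                    file.path(cfg$out_dir,
                                              "region_summary.csv"), cfg))
  }
  list(estimates = est, region_summary = summ, paths = paths)
}

#' Run the region-comparison stage (PGLS + LMM)
#'
#' Builds the comparative dataset (single modeling region per species),
#' grafts species onto the genus backbone where a mapping is implied by the
#' data, and tests the region effect on ln body size with both approaches:
#' PGLS ANOVA under Brownian motion, and the nested-taxonomy LMM compared
#' to its null by AIC.  Writes a single combined `region_tests.csv`.
#'
#' @param cfg `"pipeline_config"` with `paths$species_means` and
#'   `paths$tree` (Newick; tips may be genera, in which case species are
#'   grafted as polytomies).
#' @param species_table,tree optional in-memory inputs.
#' @param write write the report.
#' @return list: `pgls` (full fit, null fit, anova row), `lmm`
#'   (lmm_region_test result), `report`, `paths`, `tree` (the working,
#'   species-level tree).
#' @export
run_compare_regions <- function(cfg, species_table = NULL, tree = NULL,
                                write = TRUE) {
  if (is.null(species_table))
    species_table <- read_species_means(cfg_path(cfg, cfg$paths$species_means))
  if (is.null(tree))
    tree <- ape::read.tree(cfg_path(cfg, cfg$paths$tree))

  ## genus-level backbone? prune to the genera present, then graft species
  if (!any(species_table$species %in% tree$tip.label)) {
    genera <- unique(species_table$genus)
    missing <- setdiff(genera, tree$tip.label)
    if (length(missing) > 0L)
      stop("genera absent from backbone tree: ",
           paste(missing, collapse = ", "), call. = FALSE)
    tree <- prune_to_taxa(tree, intersect(tree$tip.label, genera))
    mapping <- split(species_table$species, species_table$genus)
    tree <- graft_species_polytomies(tree, mapping)
  }
  dat <- comparative_dataset(species_table, tree)
  tree <- prune_to_taxa(tree, dat$species)
  V <- brownian_covariance(tree)
  full <- pgls_fit(dat, ln_it ~ region, V)
  null <- pgls_fit(dat, ln_it ~ 1, V)
  an <- pgls_anova(full, null)
  lmm <- lmm_region_test(dat)

  report <- data.frame(
    approach = c("pgls_anova", "lmm_null", "lmm_region", "lmm_lrt"),
    statistic = c(an$F, NA, NA, lmm$lrt$chisq),
    df1 = c(an$df1, NA, NA, lmm$lrt$df),
    df2 = c(an$df2, NA, NA, NA),
    p_value = c(an$p_value, NA, NA, lmm$lrt$p_value),
    loglik = c(full$loglik, lmm$null$loglik, lmm$region$loglik, NA),
    aic = c(full$aic, lmm$null$aic, lmm$region$aic, NA),
    preferred = c(an$p_value < 0.05, lmm$best == "null",
                  lmm$best == "region", NA),
    stringsAsFactors = FALSE)
  paths <- character(0)
  if (write) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(region_tests = write_report(report,
                                           file.path(cfg$out_dir,
                                                     "region_tests.csv"),
                                           cfg))
  }
  list(pgls = list(full = full, null = null, anova = an), lmm = lmm,
       report = report, paths = paths, tree = tree)
}

#' Run the simulation stage
#'
#' Emits the same CSV/Newick formats the analysis stages consume: synthetic
#' specimens, a museum-style species table and a genus backbone tree.
#'
#' @param cfg `"pipeline_config"`; the `synth` block (seed, n_species,
#'   noise_sd, ...) overrides [synth_config()] defaults.
#' @param write write `specimens.csv`, `species_means.csv`, `backbone.nwk`.
#' @return list with the generated objects and written paths.
#' @export
run_simulate <- function(cfg, write = TRUE) {
  args <- cfg$synth
  args$seed <- cfg$seed
  sc <- do.call(synth_config, args[names(args) %in%
                                     names(formals(synth_config))])
  specimens <- gen_specimens(sc)
  museum <- gen_species_table(sc)
  backbone <- gen_tree(sc$tree$n_genera, sc$tree$birth_rate,
                       seed = sc$seed + 1,
                       labels = SYNTH_TAXONOMY$genus[seq_len(sc$tree$n_genera)])
  paths <- character(0)
  if (write) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    sp_path <- file.path(cfg$out_dir, "specimens.csv")
    utils::write.csv(as.data.frame(specimens), sp_path, row.names = FALSE)
    mu_path <- file.path(cfg$out_dir, "species_means.csv")
    utils::write.csv(as.data.frame(museum), mu_path, row.names = FALSE)
    tr_path <- file.path(cfg$out_dir, "backbone.nwk")
    ape::write.tree(backbone, tr_path)
    paths <- c(specimens = sp_path, species_means = mu_path, tree = tr_path)
  }
  list(specimens = specimens, species_table = museum, tree = backbone,
       paths = paths)
}
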