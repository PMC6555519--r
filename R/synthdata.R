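# Synthetic data with the statistical structure the analysis assumes:
# ln-linear mouthpart-IT relations with family-specific intercepts plus
# Gaussian noise on the ln scale; ultrametric pure-birth trees; Brownian
# trait evolution with optional additive region effects.  Every generator
# is a pure function of (config, seed), so each pipeline stage is testable
# end-to-end without external data.

## Nested Melittidae taxonomy used to label synthetic museum species:
## 3 subfamilies, 5 tribes, 7 genera.
SYNTH_TAXONOMY <- data.frame(
  genus = c("Melitta", "Rediviva", "Redivivoides", "Meganomia",
            "Capicola", "Haplomelitta", "Samba"),
  tribe = c("Melittini", "Redivivini", "Redivivini", "Meganomiini",
            "Dasypodaini", "Dasypodaini", "Sambini"),
  subfamily = c("Melittinae", "Melittinae", "Melittinae", "Meganomiinae",
                "Dasypodainae", "Dasypodainae", "Dasypodainae"),
  stringsAsFactors = FALSE
)

#' Configuration for the synthetic-data generators
#'
#' Defaults describe the study conditions the analysis is designed for: six
#' bee families whose mouthparts follow the published power-function
#' coefficients, species-mean IT log-uniform over the observed museum range
#' 0.99-4.42 mm, ln-scale measurement noise of 0.1 (consistent with
#' species-mean regressions explaining ~98% of proboscis variance), about
#' 110 species across the families, up to 10 specimens per species (the
#' unit-tray sampling cap), a 7-genus backbone, and no region effect on
#' body size (the null the field data supported).
#'
#' @param seed integer RNG seed.
#' @param coefficients `"power_function"` table with all three responses
#'   (default: the bundled published coefficients).
#' @param it_range species-mean IT range (mm), sampled log-uniformly.
#' @param n_species species per family (scalar or named by family).
#' @param n_specimens specimens per species.
#' @param noise_sd std dev of Gaussian noise on ln glossa and ln prementum
#'   (proboscis is re-derived as their sum, matching the measurement
#'   definition).
#' @param tree list: `n_genera`, `birth_rate` (pure-birth tree).
#' @param brownian list: `sigma2` (rate per unit depth), `root_state`
#'   (ln mm; default ln of the museum mean IT 2.58 mm).
#' @param region_effects named additive shifts of ln IT per region
#'   (all zero = null).
#' @param region_counts target per-region species counts for museum-style
#'   tables (default mirrors the field membership pattern: 44, 13, 12, 20
#'   memberships over 56 species).
#' @return list of class `"synth_config"`.
#' @export
synth_config <- function(seed = 1,
                         coefficients = published_coefficients(),
                         it_range = c(0.99, 4.42),
                         n_species = 18,
                         n_specimens = 10,
                         noise_sd = 0.1,
                         tree = list(n_genera = 7, birth_rate = 1),
                         brownian = list(sigma2 = 0.1,
                                         root_state = log(2.58)),
                         region_effects = c(winter = 0, aseasonal = 0,
                                            early_summer = 0,
                                            late_summer = 0),
                         region_counts = c(winter = 44, aseasonal = 13,
                                           early_summer = 12,
                                           late_summer = 20)) {
  check(noise_sd >= 0, "noise_sd must be non-negative")
  check(length(it_range) == 2L && all(it_range > 0) &&
          it_range[1] < it_range[2], "it_range must be positive and ordered")
  if (length(n_species) == 1L)
    n_species <- stats::setNames(rep(n_species, length(BEE_FAMILIES)),
                                 BEE_FAMILIES)
  check(all(BEE_FAMILIES %in% names(n_species)),
        "n_species must cover all six families")
  structure(list(seed = seed, coefficients = coefficients,
                 it_range = it_range, n_species = n_species,
                 n_specimens = n_specimens, noise_sd = noise_sd,
                 tree = tree, brownian = brownian,
                 region_effects = region_effects,
                 region_counts = region_counts),
            class = "synth_config")
}

## a and b for one family x response from the config coefficient table
synth_coef <- function(config, family, response) {
  p <- config$coefficients
  row <- p[p$family == family & p$response == response, , drop = FALSE]
  check(nrow(row) == 1L, "config coefficients lack ", family, "/", response)
  c(a = row$a, b = row$b)
}

#' Generate specimen-level morphometric records
#'
#' Each species receives a log-uniform mean IT; every specimen of the
#' species carries that IT (within-species body-size spread is not
#' modelled), while ln glossa and ln prementum get independent Gaussian
#' noise around the family power curves.  Proboscis is re-derived as
#' glossa + prementum after noise.  Sexes alternate male/female.
#'
#' @param config `"synth_config"`.
#' @param seed overrides `config$seed` if given.
#' @return `"specimen_df"` data.frame (see [read_specimens()]).
#' @export
gen_specimens <- function(config, seed = config$seed) {
  check(inherits(config, "synth_config"), "config must come from synth_config()")
  with_seed(seed, {
    rows <- list()
    for (fam in BEE_FAMILIES) {
      n_sp <- config$n_species[[fam]]
      if (n_sp == 0L) next
      g <- synth_coef(config, fam, "glossa")
      p <- synth_coef(config, fam, "prementum")
      it_sp <- exp(stats::runif(n_sp, log(config$it_range[1]),
                                log(config$it_range[2])))
      for (s in seq_len(n_sp)) {
        ns <- config$n_specimens
        ln_it <- log(it_sp[s])
        glossa <- exp(g["a"] + g["b"] * ln_it +
                        stats::rnorm(ns, 0, config$noise_sd))
        prementum <- exp(p["a"] + p["b"] * ln_it +
                           stats::rnorm(ns, 0, config$noise_sd))
        rows[[length(rows) + 1L]] <- data.frame(
          specimen_id = sprintf("%s_sp%02d_%03d", fam, s, seq_len(ns)),
          species = sprintf("%s_sp%02d", fam, s),
          genus = sprintf("%s_gen%d", fam, ((s - 1L) %% 3L) + 1L),
          family = fam,
          sex = rep_len(c("female", "male"), ns),
          it_mm = it_sp[s],
          glossa_mm = glossa,
          prementum_mm = prementum,
          region = NA_character_,
          stringsAsFactors = FALSE)
      }
    }
    validate_specimens(do.call(rbind, rows))
  })
}

## Rescale per-region membership counts (defined for a 56-species table)
## to another species count, by largest-remainder apportionment, clamped to
## the feasible range [n, 2n] of the dealing rule.
scale_region_counts <- function(counts, n_species, base = 56L) {
  total <- sum(counts)
  t <- round(total * n_species / base)
  t <- max(n_species, min(2L * n_species, t))
  q <- counts / total * t
  out <- floor(q)
  rem <- t - sum(out)
  if (rem > 0) {
    add <- order(q - out, decreasing = TRUE)[seq_len(rem)]
    out[add] <- out[add] + 1
  }
  out
}

#' Deterministic multi-region membership pattern
#'
#' Builds per-species region sets whose per-region counts hit the given
#' targets: the region slots (counts in the fixed region order) are dealt
#' to species 1..n as first memberships, and the overflow wraps around as
#' second memberships, never duplicating a region within a species.
#'
#' @param n_species number of species.
#' @param counts named per-region membership counts; `sum(counts)` may
#'   exceed `n_species` (multi-region species) but not `2 * n_species`.
#' @return character vector of length `n_species`, comma-separated region
#'   sets.
#' @export
region_membership <- function(n_species,
                              counts = c(winter = 44, aseasonal = 13,
                                         early_summer = 12,
                                         late_summer = 20)) {
  counts <- counts[intersect(RAINFALL_REGIONS, names(counts))]
  total <- sum(counts)
  check(total >= n_species, "fewer memberships than species")
  check(total <= 2L * n_species, "membership pattern needs > 2 regions per ",
        "species; not supported by the dealing rule")
  slots <- rep(names(counts), counts)
  sets <- vector("list", n_species)
  for (i in seq_along(slots)) {
    sp <- ((i - 1L) %% n_species) + 1L
    sets[[sp]] <- c(sets[[sp]], slots[i])
  }
  vapply(sets, function(s) paste(unique(s), collapse = ","), character(1))
}

#' Generate a museum-style species-mean table
#'
#' Species-level table of mean IT for one family (default Melittidae)
#' spread over the seven-genus taxonomy, with a multi-region membership
#' pattern hitting the configured per-region counts.
#'
#' @param config `"synth_config"`.
#' @param n_species number of species (default 56, the museum species
#'   count).  The configured `region_counts` are defined relative to the
#'   56-species table and are rescaled proportionally (largest-remainder
#'   apportionment) for other sizes.
#' @param family family label for all species.
#' @param seed overrides `config$seed`.
#' @return `"species_means"` data.frame with taxonomy columns (`genus`,
#'   `tribe`, `subfamily`) and `regions`.
#' @export
gen_species_table <- function(config, n_species = 56, family = "Melittidae",
                              seed = config$seed) {
  check(inherits(config, "synth_config"), "config must come from synth_config()")
  with_seed(seed, {
    tax <- SYNTH_TAXONOMY[rep_len(seq_len(nrow(SYNTH_TAXONOMY)), n_species), ]
    it <- exp(stats::runif(n_species, log(config$it_range[1]),
                           log(config$it_range[2])))
    out <- data.frame(
      species = sprintf("%s_%s_sp%02d", tax$genus, substr(family, 1, 3),
                        seq_len(n_species)),
      genus = tax$genus, tribe = tax$tribe, subfamily = tax$subfamily,
      family = family, tongue_group = tongue_group(family),
      n_specimens = NA_integer_,
      mean_it_mm = it,
      mean_glossa_mm = NA_real_, mean_prementum_mm = NA_real_,
      mean_proboscis_mm = NA_real_,
      regions = region_membership(n_species,
                                  scale_region_counts(config$region_counts,
                                                      n_species)),
      stringsAsFactors = FALSE)
    rownames(out) <- NULL
    class(out) <- c("species_means", "data.frame")
    out
  })
}

#' Simulate an ultrametric pure-birth tree
#'
#' Yule (pure-birth) tree conditioned on the number of tips; all tips are
#' equidistant from the root by construction.
#'
#' @param n_tips number of tips (>= 2).
#' @param birth_rate speciation rate.
#' @param seed RNG seed.
#' @param labels optional tip labels (length `n_tips`).
#' @return ultrametric `"phylo"` tree.
#' @export
gen_tree <- function(n_tips, birth_rate = 1, seed = NULL, labels = NULL) {
  check(n_tips >= 2, "need at least two tips")
  tree <- with_seed(seed, ape::rphylo(n_tips, birth = birth_rate, death = 0))
  if (!is.null(labels)) {
    check(length(labels) == n_tips, "labels must have length n_tips")
    tree$tip.label <- labels
  }
  tree
}

#' Simulate Brownian trait evolution on a tree
#'
#' Tip values are a multivariate normal draw with mean `root_state` plus
#' the per-tip region shift and covariance `sigma2 * V`, where `V` is the
#' shared-path matrix of the tree.
#'
#' @param tree `"phylo"` tree with branch lengths.
#' @param sigma2 Brownian rate (variance per unit depth).
#' @param root_state trait value at the root (ln mm for body size).
#' @param region_effects named additive shifts (may be all zero).
#' @param region_assignment named character vector tip -> region covering
#'   every tip (or NULL for no region structure).
#' @param seed RNG seed.
#' @return data.frame: `species`, `region`, `ln_it`.
#' @export
gen_brownian_traits <- function(tree, sigma2, root_state = 0,
                                region_effects = NULL,
                                region_assignment = NULL, seed = NULL) {
  V <- brownian_covariance(tree)
  n <- nrow(V)
  tips <- rownames(V)
  region <- rep(NA_character_, n)
  shift <- numeric(n)
  if (!is.null(region_assignment)) {
    check(all(tips %in% names(region_assignment)),
          "region_assignment must cover every tip")
    region <- unname(region_assignment[tips])
    if (!is.null(region_effects)) {
      check(all(region %in% names(region_effects)),
            "region_effects must cover every assigned region")
      shift <- unname(region_effects[region])
    }
  }
  z <- with_seed(seed, stats::rnorm(n))
  bm <- if (sigma2 > 0) drop(t(chol(sigma2 * V)) %*% z) else numeric(n)
  data.frame(species = tips, region = region,
             ln_it = root_state + shift + bm,
             stringsAsFactors = FALSE)
}
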