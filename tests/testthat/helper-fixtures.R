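# Shared fixtures and independent oracles, built in code at test time.

## Brute-force OLS via the normal equations: the independent oracle for the
## package's QR-based fit.
ols_oracle <- function(X, y) {
  beta <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% beta
  list(beta = drop(beta), rss = sum(res^2))
}

## Dense-matrix GLS oracle: beta = (X' V^-1 X)^-1 X' V^-1 y.
gls_oracle <- function(X, y, V) {
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  res <- y - X %*% beta
  list(beta = drop(beta), rss = drop(t(res) %*% Vi %*% res))
}

## Minimal hand-built specimen table (valid by construction).
make_specimens <- function(n = 4, family = "Apidae", species = "Apis_test",
                           it = 2, glossa = 1, prementum = 2,
                           sex = "female", region = NA_character_) {
  validate_specimens(data.frame(
    specimen_id = sprintf("s%02d", seq_len(n)),
    species = rep_len(species, n), genus = rep_len("G", n),
    family = rep_len(family, n), sex = rep_len(sex, n),
    it_mm = rep_len(it, n), glossa_mm = rep_len(glossa, n),
    prementum_mm = rep_len(prementum, n),
    region = rep_len(region, n), stringsAsFactors = FALSE))
}

## Species-mean table generated straight from a power-function table with
## optional ln-scale noise; one row per species, IT log-uniform.
make_species_means <- function(params, n_per_family = 5, noise_sd = 0,
                               it_range = c(0.99, 4.42), seed = 1) {
  set.seed(seed)
  fams <- unique(params$family)
  rows <- lapply(fams, function(f) {
    it <- exp(runif(n_per_family, log(it_range[1]), log(it_range[2])))
    len <- function(resp) {
      p <- params[params$response == resp & params$family == f, ]
      if (nrow(p) == 0) return(rep(NA_real_, n_per_family))
      exp(p$a + p$b * log(it) + rnorm(n_per_family, 0, noise_sd))
    }
    data.frame(species = sprintf("%s_sp%02d", f, seq_len(n_per_family)),
               genus = f, family = f, tongue_group = tongue_group(f),
               n_specimens = 1L, mean_it_mm = it,
               mean_glossa_mm = len("glossa"),
               mean_prementum_mm = len("prementum"),
               mean_proboscis_mm = len("proboscis"),
               regions = "", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("species_means", "data.frame")
  out
}

## A coefficient table with a single common slope for every response:
## proboscis-style intercepts, b = 0.96 throughout.
common_slope_params <- function(b = 0.96) {
  a <- c(Andrenidae = 1.06, Apidae = 2.15, Colletidae = 0.86,
         Halictidae = 1.37, Megachilidae = 1.87, Melittidae = 1.10)
  do.call(rbind, lapply(c("proboscis", "glossa", "prementum"), function(r)
    data.frame(response = r, family = names(a), a = unname(a), b = b,
               common_slope = TRUE, stringsAsFactors = FALSE)))
}
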