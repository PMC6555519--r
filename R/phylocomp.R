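# Phylogenetic comparative tests of trait-environment association.
#
# The working phylogeny starts from a genus-level backbone: it is pruned to
# the genera of interest and congeneric species are attached as polytomies
# that split the genus terminal branch at its midpoint, preserving
# ultrametricity and tip depths.  Under Brownian motion the expected trait
# covariance between two tips is proportional to their shared root-to-MRCA
# path length; PGLS uses that covariance as the error structure.

#' Prune a phylogeny to a set of tips
#'
#' Induced subtree on the kept tips: unsampled lineages are removed,
#' degree-2 nodes collapsed with branch lengths summed, so root-to-tip
#' distances of the kept tips are unchanged.
#'
#' @param tree `"phylo"` tree with branch lengths.
#' @param keep character vector of tip labels to retain.
#' @return pruned `"phylo"` tree.
#' @export
prune_to_taxa <- function(tree, keep) {
  check(inherits(tree, "phylo"), "tree must be a 'phylo' object")
  unknown <- setdiff(keep, tree$tip.label)
  if (length(unknown) > 0L)
    stop("tip(s) not in tree: ", paste(unknown, collapse = ", "), call. = FALSE)
  if (setequal(keep, tree$tip.label)) return(tree)
  pruned <- ape::keep.tip(tree, keep)
  ## keep.tip re-roots at the MRCA of the kept tips; carry the dropped
  ## root-to-MRCA path as a root edge so root-to-tip distances survive
  ref <- keep[1]
  stem <- node_depths(tree)[[ref]] - ape::node.depth.edgelength(pruned)[
    match(ref, pruned$tip.label)]
  if (stem > 1e-12)
    pruned$root.edge <- stem
  pruned
}

#' Root-to-tip distances of a tree
#'
#' Tip depths measured from the basal end of the root edge (if any); equal
#' across tips for an ultrametric tree.
#'
#' @param tree `"phylo"` tree with branch lengths.
#' @return named numeric vector, one depth per tip.
#' @export
node_depths <- function(tree) {
  d <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  if (!is.null(tree$root.edge)) d <- d + tree$root.edge
  stats::setNames(d, tree$tip.label)
}

#' Graft species onto genus tips as polytomies
#'
#' Each genus tip with terminal branch length `l` is replaced by a stem of
#' length `l/2` ending in a polytomy whose species tips all have branch
#' length `l/2`.  Root-to-tip depth is unchanged, so an ultrametric backbone
#' stays ultrametric.  A single-species genus is renamed to its species
#' (topologically identical to splitting the branch).
#'
#' @param tree `"phylo"` backbone whose tips are genera.
#' @param mapping named list: genus tip label -> character vector of species.
#' @return `"phylo"` tree whose tips are species.
#' @export
graft_species_polytomies <- function(tree, mapping) {
  check(inherits(tree, "phylo"), "tree must be a 'phylo' object")
  check(length(mapping) > 0L, "empty genus -> species mapping")
  missing <- setdiff(names(mapping), tree$tip.label)
  if (length(missing) > 0L)
    stop("genus not a tip of the backbone: ",
         paste(missing, collapse = ", "), call. = FALSE)
  all_sp <- unlist(mapping, use.names = FALSE)
  dup <- unique(all_sp[duplicated(all_sp)])
  if (length(dup) > 0L)
    stop("species listed under more than one genus: ",
         paste(dup, collapse = ", "), call. = FALSE)
  check(all(lengths(mapping) >= 1L), "every genus needs at least one species")

  for (genus in names(mapping)) {
    sp <- mapping[[genus]]
    i <- match(genus, tree$tip.label)
    if (length(sp) == 1L) {
      tree$tip.label[i] <- sp
      next
    }
    e <- which(tree$edge[, 2] == i)
    l <- tree$edge.length[e]
    tree$edge.length[e] <- l / 2
    star <- ape::stree(length(sp), type = "star", tip.label = sp)
    star$edge.length <- rep(l / 2, length(sp))
    tree <- ape::bind.tree(tree, star, where = match(genus, tree$tip.label),
                           position = 0)
  }
  tree
}

#' Brownian-motion covariance matrix of a tree
#'
#' `V[i, j]` is the root-to-MRCA shared path length of tips i and j (the
#' tip's root depth on the diagonal); under Brownian motion with rate
#' sigma^2 the trait covariance is `sigma^2 * V`.
#'
#' @param tree rooted `"phylo"` tree with non-negative branch lengths.
#' @return symmetric positive semidefinite matrix with tip labels as
#'   dimnames.
#' @export
brownian_covariance <- function(tree) {
  check(inherits(tree, "phylo"), "tree must be a 'phylo' object")
  check(!is.null(tree$edge.length), "tree has no branch lengths")
  if (any(tree$edge.length < 0))
    stop("negative branch length(s) in tree", call. = FALSE)
  ape::vcv(tree)
}

#' Phylogenetic generalized least squares under Brownian motion
#'
#' GLS fit of a model matrix to tip data with error covariance proportional
#' to `V`: beta = (X' V^-1 X)^-1 X' V^-1 y, computed by whitening both sides
#' with the Cholesky factor of `V` and running OLS on the transformed
#' problem.  The log-likelihood is the Gaussian ML value with the scale
#' sigma^2 profiled out.
#'
#' @param data data.frame with a `species` column matching the rownames of
#'   `V`, the response column, and any predictors.
#' @param formula model formula, e.g. `ln_it ~ region` or `ln_it ~ 1` for
#'   the null model.
#' @param V Brownian covariance from [brownian_covariance()] (tips x tips).
#' @param jitter diagonal jitter added when `V` is numerically singular.
#' @return object of class `"pgls"`: `coefficients`, `se`, `n`, `k`, `rss`
#'   (whitened), `loglik`, `aic`, fitted values and raw residuals.
#' @export
pgls_fit <- function(data, formula, V, jitter = 1e-10) {
  check("species" %in% names(data), "data needs a species column")
  unmatched <- c(setdiff(data$species, rownames(V)),
                 setdiff(rownames(V), data$species))
  if (length(unmatched) > 0L)
    stop("species/tip mismatch between data and V: ",
         paste(unique(unmatched), collapse = ", "), call. = FALSE)
  data <- data[match(rownames(V), data$species), , drop = FALSE]

  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  n <- length(y)
  k <- ncol(X)
  check(n > k, "need more tips (", n, ") than coefficients (", k, ")")

  L <- tryCatch(chol(V), error = function(e) {
    message("V numerically singular; adding diagonal jitter ", jitter)
    chol(V + diag(jitter, n))
  })
  ## whiten: solve L' z = y  =>  z has iid errors
  yw <- backsolve(L, y, transpose = TRUE)
  Xw <- backsolve(L, X, transpose = TRUE)
  colnames(Xw) <- colnames(X)  # backsolve drops dimnames
  qr_x <- qr(Xw)
  if (qr_x$rank < k) stop("singular design after whitening", call. = FALSE)
  fit <- lm.fit(Xw, yw)
  beta <- fit$coefficients
  rss <- sum(fit$residuals^2)
  sigma2_ml <- rss / n
  logdetV <- 2 * sum(log(diag(L)))
  loglik <- -(n / 2) * (log(2 * pi) + log(sigma2_ml) + 1) - logdetV / 2
  aic <- -2 * loglik + 2 * (k + 1)
  sigma2 <- rss / (n - k)
  XtXinv <- chol2inv(qr.R(qr_x))
  se <- sqrt(sigma2 * diag(XtXinv))
  names(se) <- names(beta)
  fitted_raw <- drop(X %*% beta)
  structure(list(coefficients = beta, se = se, n = n, k = k, rss = rss,
                 loglik = loglik, aic = aic, formula = formula,
                 fitted = fitted_raw, residuals = y - fitted_raw,
                 whitened_residuals = fit$residuals,
                 species = data$species, y = y),
            class = "pgls")
}

#' @export
print.pgls <- function(x, ...) {
  cat("PGLS fit (Brownian motion error structure):",
      deparse(x$formula), "\n")
  cat(sprintf("  n = %d tips, k = %d, logLik = %.3f, AIC = %.3f\n",
              x$n, x$k, x$loglik, x$aic))
  print(round(rbind(estimate = x$coefficients, se = x$se), 4))
  invisible(x)
}

#' @export
logLik.pgls <- function(object, ...) {
  structure(object$loglik, df = object$k + 1, class = "logLik")
}

#' ANOVA comparison of nested PGLS models
#'
#' F test on the whitened residual sums of squares:
#' `F = ((RSS_null - RSS_full) / dk) / (RSS_full / (n - k_full))` with
#' degrees of freedom `(dk, n - k_full)`.  On a star tree this reduces to
#' the classical one-way ANOVA.
#'
#' @param full,null nested `"pgls"` fits of the same response on the same
#'   tips (null has fewer coefficients).
#' @return data.frame with `F`, `df1`, `df2`, `p_value`.
#' @export
pgls_anova <- function(full, null) {
  check(inherits(full, "pgls") && inherits(null, "pgls"),
        "both arguments must be pgls fits")
  check(full$n == null$n && setequal(full$species, null$species),
        "models must be fitted to the same tips")
  check(isTRUE(all.equal(full$y, null$y[match(full$species, null$species)])),
        "models must share the response")
  check(full$k >= null$k, "'full' must have at least as many coefficients")
  df1 <- full$k - null$k
  df2 <- full$n - full$k
  if (df1 == 0L)
    return(data.frame(F = 0, df1 = 0, df2 = df2, p_value = 1))
  F <- ((null$rss - full$rss) / df1) / (full$rss / df2)
  F <- max(F, 0)
  data.frame(F = F, df1 = df1, df2 = df2,
             p_value = stats::pf(F, df1, df2, lower.tail = FALSE))
}

#' Single modeling region for species spanning several regions
#'
#' For comparative modeling each species needs one region label: the region
#' holding the majority of its specimen records wins; ties are broken by the
#' fixed region order winter, aseasonal, early_summer, late_summer.
#'
#' @param records `"specimen_df"` with `species` and `region` columns, or a
#'   data.frame with a comma-separated `regions` column (each listed region
#'   then counts once).
#' @return named character vector, species -> region.
#' @export
modeling_region <- function(records) {
  if ("regions" %in% names(records) && !"region" %in% names(records)) {
    regs <- strsplit(records$regions, ",", fixed = TRUE)
    records <- data.frame(species = rep(records$species, lengths(regs)),
                          region = unlist(regs), stringsAsFactors = FALSE)
  }
  records <- records[!is.na(records$region) & records$region != "", ,
                     drop = FALSE]
  vapply(split(records$region, records$species), function(r) {
    tab <- table(factor(r, levels = RAINFALL_REGIONS))
    names(tab)[which.max(tab)]  # which.max takes the first tie in level order
  }, character(1))
}

#' Assemble a comparative dataset for the region tests
#'
#' Joins species-mean body size (ln IT), taxonomy and the single modeling
#' region, keeping only species present in the tree.
#'
#' @param species_table `"species_means"` data.frame (with `regions`), plus
#'   optional `tribe` and `subfamily` columns for the LMM.
#' @param tree optional `"phylo"` tree; species missing from the tree are
#'   dropped with a warning.
#' @return data.frame with `species`, `genus`, `tribe`, `subfamily`,
#'   `region`, `ln_it`.
#' @export
comparative_dataset <- function(species_table, tree = NULL) {
  reg <- modeling_region(species_table)
  out <- data.frame(
    species = species_table$species,
    genus = species_table$genus,
    tribe = if ("tribe" %in% names(species_table)) species_table$tribe else NA,
    subfamily = if ("subfamily" %in% names(species_table))
      species_table$subfamily else NA,
    region = unname(reg[species_table$species]),
    ln_it = log(species_table$mean_it_mm),
    stringsAsFactors = FALSE
  )
  if (!is.null(tree)) {
    drop <- setdiff(out$species, tree$tip.label)
    if (length(drop) > 0L)
      warning("species not in tree dropped: ", paste(drop, collapse = ", "),
              call. = FALSE)
    out <- out[out$species %in% tree$tip.label, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Linear mixed model with nested taxonomic random effects
#'
#' Fits `ln_it ~ region` (or an intercept-only null) by maximum likelihood
#' with random intercepts for genus nested in tribe nested in subfamily --
#' taxonomy standing in for phylogeny where branch lengths below the genus
#' level are not meaningful.  ML (not REML) so that models differing in
#' fixed effects are comparable by AIC and likelihood-ratio test.
#'
#' @param data comparative dataset with `ln_it`, `region`, `genus`, `tribe`,
#'   `subfamily`.
#' @param fixed `"region"` or `"null"` (intercept only).
#' @return list of class `"lmm_fit"`: `model` (the lme4 fit), `loglik`,
#'   `aic`, `npar`, `fixed_effects`, `varcomp` (named variance components
#'   incl. residual).
#' @export
lmm_fit <- function(data, fixed = c("region", "null")) {
  fixed <- match.arg(fixed)
  need <- c("ln_it", "genus", "tribe", "subfamily")
  check(all(need %in% names(data)), "data needs columns ",
        paste(need, collapse = ", "))
  rhs <- if (fixed == "region") "region" else "1"
  form <- stats::as.formula(paste("ln_it ~", rhs,
                                  "+ (1 | subfamily/tribe/genus)"))
  m <- lme4::lmer(form, data = data, REML = FALSE,
                  control = lme4::lmerControl(check.conv.singular = "ignore"))
  vc <- as.data.frame(lme4::VarCorr(m))
  varcomp <- stats::setNames(vc$vcov, vc$grp)
  ll <- as.numeric(stats::logLik(m))
  npar <- attr(stats::logLik(m), "df")
  structure(list(model = m, fixed = fixed, loglik = ll,
                 aic = -2 * ll + 2 * npar, npar = npar,
                 fixed_effects = lme4::fixef(m), varcomp = varcomp,
                 n = nrow(data)),
            class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("LMM (ML), fixed =", x$fixed,
      sprintf("| n = %d, logLik = %.3f, AIC = %.3f\n", x$n, x$loglik, x$aic))
  cat("variance components:\n")
  print(round(x$varcomp, 4))
  invisible(x)
}

#' Region effect on body size: null vs region LMM
#'
#' Fits the intercept-only and region models and compares them by AIC and a
#' likelihood-ratio test.
#'
#' @param data comparative dataset (see [lmm_fit()]).
#' @return list with both fits, `aic_table`, `lrt` (chi-square, df, p) and
#'   `best` (`"null"` or `"region"`).
#' @export
lmm_region_test <- function(data) {
  null <- lmm_fit(data, "null")
  full <- lmm_fit(data, "region")
  lr <- 2 * (full$loglik - null$loglik)
  df <- full$npar - null$npar
  aic_table <- data.frame(model = c("null", "region"),
                          npar = c(null$npar, full$npar),
                          loglik = c(null$loglik, full$loglik),
                          aic = c(null$aic, full$aic),
                          stringsAsFactors = FALSE)
  list(null = null, region = full, aic_table = aic_table,
       lrt = data.frame(chisq = max(lr, 0), df = df,
                        p_value = stats::pchisq(max(lr, 0), df,
                                                lower.tail = FALSE)),
       best = aic_table$model[which.min(aic_table$aic)])
}
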