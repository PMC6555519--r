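# Tree surgery, Brownian covariance, PGLS and the taxonomy LMM.

library(ape)

test_that("pruning keeps induced path lengths", {
  tr <- read.tree(text = "((A:1,B:1):1,C:2);")
  pr <- prune_to_taxa(tr, c("A", "C"))
  expect_equal(sort(pr$tip.label), c("A", "C"))
  expect_equal(unname(node_depths(pr)), c(2, 2))
  expect_equal(write.tree(prune_to_taxa(tr, tr$tip.label)), write.tree(tr))
  expect_error(prune_to_taxa(tr, c("A", "Z")), "Z")
  # kept clade below the root: the dropped root path becomes a root edge
  deep <- read.tree(text = "(((A:1,B:1):1,C:2):2,D:4);")
  pr2 <- prune_to_taxa(deep, c("A", "B"))
  expect_equal(unname(node_depths(pr2)), c(4, 4))
})

test_that("polytomy grafting splits the genus branch at its midpoint", {
  tr <- read.tree(text = "((A:1,B:1):1,C:2);")
  out <- graft_species_polytomies(tr, list(A = c("a1", "a2", "a3")))
  expect_setequal(out$tip.label, c("a1", "a2", "a3", "B", "C"))
  depths <- node.depth.edgelength(out)[seq_along(out$tip.label)]
  expect_equal(unname(depths[match(c("a1", "a2", "a3"),
                                   out$tip.label)]), rep(2, 3))
  stem <- out$edge.length[out$edge[, 2] ==
                            which(out$tip.label == "a1")]
  expect_equal(stem, 0.5)
  # singleton list renames the genus tip, depths untouched
  one <- graft_species_polytomies(tr, list(B = "b1"))
  expect_true("b1" %in% one$tip.label)
  expect_equal(node.depth.edgelength(one)[match("b1", one$tip.label)], 2)
  # errors: unknown genus, duplicated species
  expect_error(graft_species_polytomies(tr, list(Z = "z1")), "Z")
  expect_error(graft_species_polytomies(tr, list(A = "x", B = "x")), "x")
})

test_that("grafting random Yule backbones preserves ultrametricity", {
  for (seed in 1:10) {
    bb <- gen_tree(5, birth_rate = 1, seed = seed,
                   labels = sprintf("g%d", 1:5))
    set.seed(seed)
    mapping <- lapply(setNames(bb$tip.label, bb$tip.label), function(g)
      sprintf("%s_s%d", g, seq_len(sample(1:4, 1))))
    out <- graft_species_polytomies(bb, mapping)
    expect_equal(Ntip(out), sum(lengths(mapping)))
    d <- node.depth.edgelength(out)[seq_len(Ntip(out))]
    expect_lt(max(d) - min(d), 1e-9)
    expect_equal(max(d), max(node.depth.edgelength(bb)), tolerance = 1e-9)
  }
})

test_that("prune then graft with singletons restores the original depths", {
  bb <- gen_tree(8, seed = 3, labels = sprintf("g%d", 1:8))
  keep <- sprintf("g%d", c(1, 3, 5, 8))
  pruned <- prune_to_taxa(bb, keep)
  grafted <- graft_species_polytomies(pruned,
                                      setNames(as.list(paste0(keep, "_sp")),
                                               keep))
  d0 <- node_depths(bb)[keep]
  d1 <- node_depths(grafted)[paste0(keep, "_sp")]
  expect_equal(unname(d1), unname(d0), tolerance = 1e-12)
})

test_that("Brownian covariance equals shared root-to-MRCA path lengths", {
  tr <- read.tree(text = "((A:1,B:1):1,C:2);")
  V <- brownian_covariance(tr)
  expect_equal(unname(V[c("A", "B", "C"), c("A", "B", "C")]),
               rbind(c(2, 1, 0), c(1, 2, 0), c(0, 0, 2)))
  star <- stree(4, type = "star", tip.label = letters[1:4])
  star$edge.length <- rep(1.5, 4)
  expect_equal(unname(brownian_covariance(star)), 1.5 * diag(4))
  bad <- tr
  bad$edge.length[1] <- -0.1
  expect_error(brownian_covariance(bad), "negative")
  # PSD: Cholesky succeeds (with at most the documented jitter)
  big <- gen_tree(30, seed = 5)
  expect_silent(chol(brownian_covariance(big) + diag(1e-10, 30)))
})

test_that("PGLS reduces to OLS on a star tree", {
  star <- stree(12, type = "star", tip.label = sprintf("t%d", 1:12))
  star$edge.length <- rep(1, 12)
  set.seed(8)
  dat <- data.frame(species = star$tip.label,
                    region = rep(c("winter", "aseasonal", "early_summer"), 4),
                    ln_it = rnorm(12))
  V <- brownian_covariance(star)
  g <- pgls_fit(dat, ln_it ~ region, V)
  o <- lm(ln_it ~ region, dat)
  expect_equal(g$coefficients, coef(o), tolerance = 1e-10)
  expect_equal(g$rss, sum(resid(o)^2), tolerance = 1e-10)
  # and the whitened ANOVA is the classical one-way ANOVA
  null <- pgls_fit(dat, ln_it ~ 1, V)
  an <- pgls_anova(g, null)
  cl <- anova(lm(ln_it ~ region, dat))
  expect_equal(an$F, cl$`F value`[1], tolerance = 1e-10)
  expect_equal(an$p_value, cl$`Pr(>F)`[1], tolerance = 1e-10)
  expect_equal(c(an$df1, an$df2), c(2, 9))
})

test_that("PGLS matches the dense-matrix GLS oracle on a worked tree", {
  tr <- read.tree(text = "((A:1,B:1):1,(C:0.5,D:0.5):1.5);")
  V <- brownian_covariance(tr)
  dat <- data.frame(species = c("A", "B", "C", "D"),
                    region = c("winter", "winter", "aseasonal", "aseasonal"),
                    ln_it = c(0.2, 0.5, 1.1, 0.9))
  g <- pgls_fit(dat, ln_it ~ region, V)
  # treatment coding: aseasonal is the alphabetical reference, so the dummy
  # marks the winter tips A and B
  X <- cbind(1, c(1, 1, 0, 0))
  oracle <- gls_oracle(X, dat$ln_it, unname(V))
  expect_equal(unname(g$coefficients), oracle$beta, tolerance = 1e-10)
  expect_equal(g$rss, oracle$rss, tolerance = 1e-10)
  # against nlme's reference PGLS implementation
  skip_if_not_installed("nlme")
  gls_ref <- nlme::gls(ln_it ~ region, data = dat,
                       correlation = ape::corBrownian(1, tr, form = ~species),
                       method = "ML")
  expect_equal(unname(g$coefficients), unname(coef(gls_ref)),
               tolerance = 1e-6)
})

test_that("PGLS loglik is invariant to tip reordering", {
  tr <- gen_tree(10, seed = 12, labels = sprintf("t%d", 1:10))
  V <- brownian_covariance(tr)
  dat <- gen_brownian_traits(tr, sigma2 = 0.3, root_state = 1, seed = 4)
  dat$region <- rep(c("winter", "late_summer"), 5)
  f1 <- pgls_fit(dat, ln_it ~ region, V)
  perm <- sample(10)
  f2 <- pgls_fit(dat[perm, ], ln_it ~ region, V[perm, perm])
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-10)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-10)
})

test_that("pgls_anova guards its preconditions", {
  tr <- gen_tree(6, seed = 2, labels = sprintf("t%d", 1:6))
  V <- brownian_covariance(tr)
  dat <- gen_brownian_traits(tr, 0.2, seed = 9)
  dat$region <- rep(c("winter", "aseasonal"), 3)
  full <- pgls_fit(dat, ln_it ~ region, V)
  expect_equal(pgls_anova(full, full)$F, 0)
  expect_equal(pgls_anova(full, full)$p_value, 1)
  other <- dat
  other$ln_it <- other$ln_it + 1
  expect_error(pgls_anova(full, pgls_fit(other, ln_it ~ 1, V)),
               "share the response")
  expect_error(pgls_fit(dat[-1, ], ln_it ~ 1, V), "mismatch")
})

test_that("modeling region takes the specimen majority with fixed ties", {
  recs <- data.frame(
    species = c("a", "a", "a", "b", "b", "c"),
    region = c("winter", "late_summer", "late_summer", "winter",
               "aseasonal", "early_summer"))
  reg <- modeling_region(recs)
  expect_equal(unname(reg["a"]), "late_summer")  # majority wins
  expect_equal(unname(reg["b"]), "winter")       # tie -> earlier fixed order
  expect_equal(unname(reg["c"]), "early_summer")
  # comma-separated species sets count each listed region once
  tab <- data.frame(species = c("x", "y"),
                    regions = c("aseasonal,winter", "late_summer"))
  reg2 <- modeling_region(tab)
  expect_equal(unname(reg2[c("x", "y")]), c("winter", "late_summer"))
})

test_that("LMM with null group structure reproduces the OLS likelihood", {
  # identical response sets in every group: between-group variance is 0
  base <- c(-1.3, -0.4, 0.2, 0.8, 1.6)
  d <- data.frame(ln_it = rep(base, 6),
                  genus = rep(sprintf("g%d", 1:6), each = 5),
                  tribe = rep(sprintf("t%d", 1:3), each = 10),
                  subfamily = rep(sprintf("s%d", 1:2), each = 15),
                  region = "winter")
  f <- lmm_fit(d, "null")
  ols <- logLik(lm(ln_it ~ 1, d))
  expect_equal(f$loglik, as.numeric(ols), tolerance = 1e-6)
  expect_equal(unname(f$varcomp[names(f$varcomp) != "Residual"]),
               rep(0, 3), tolerance = 1e-8)
})

test_that("null model is preferred when regions have no effect", {
  set.seed(77)
  prefer_null <- replicate(10, {
    tr <- gen_tree(40, seed = sample.int(1e6, 1))
    assign <- setNames(sample(c("winter", "aseasonal", "early_summer",
                                "late_summer"), 40, replace = TRUE),
                       tr$tip.label)
    dat <- gen_brownian_traits(tr, 0.2, root_state = 1,
                               region_effects = c(winter = 0, aseasonal = 0,
                                                  early_summer = 0,
                                                  late_summer = 0),
                               region_assignment = assign,
                               seed = sample.int(1e6, 1))
    tax <- beeallometry:::SYNTH_TAXONOMY[rep_len(1:7, 40), ]
    dat$genus <- tax$genus
    dat$tribe <- tax$tribe
    dat$subfamily <- tax$subfamily
    lmm_region_test(dat)$best == "null"
  })
  expect_gte(mean(prefer_null), 0.7)
})

test_that("PGLS ANOVA detects a strong region effect", {
  set.seed(55)
  hits <- replicate(20, {
    tr <- gen_tree(50, seed = sample.int(1e6, 1))
    assign <- setNames(rep_len(c("winter", "aseasonal"), 50), tr$tip.label)
    dat <- gen_brownian_traits(tr, 0.05, root_state = 1,
                               region_effects = c(winter = 0, aseasonal = 1.5),
                               region_assignment = assign,
                               seed = sample.int(1e6, 1))
    V <- brownian_covariance(tr)
    an <- pgls_anova(pgls_fit(dat, ln_it ~ region, V),
                     pgls_fit(dat, ln_it ~ 1, V))
    an$p_value < 0.01
  })
  expect_gte(mean(hits), 0.9)
})
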