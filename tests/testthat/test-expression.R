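# Count filtering with the within-species rescue, normalisation, the NB
# Wald contrasts, BH, set overlaps, quadrant classification, modules and
# Fisher enrichment.

test_that("the low-count filter applies the rescue rule exactly", {
  sp <- rep(c("A", "B"), c(8, 4))
  site <- rep(c("low", "high"), 6)
  # gene 1: all high counts -> retained
  # gene 2: low in 8/12, 7 of them in species A (7/8 > 75%) -> rescued
  # gene 3: low in 8/12 split 4/4 (50% <= 75%) -> discarded
  # gene 4: low in 5/12 (< 50%) -> retained without rescue
  g1 <- rep(50L, 12)
  g2 <- c(rep(0L, 7), 50L, 0L, 50L, 50L, 50L)
  g3 <- c(rep(0L, 4), rep(50L, 4), rep(0L, 4))
  g4 <- c(rep(0L, 5), rep(50L, 7))
  cm <- toy_count_matrix(rbind(g1, g2, g3, g4), sp, site)
  out <- filter_counts(cm, min_count = 5, min_fraction = 0.5,
                       rescue_fraction = 0.75)
  log <- attr(out, "filter_log")
  expect_equal(log$decision, c("retained", "rescued", "discarded", "retained"))
  expect_equal(rownames(out$counts), c("g1", "g2", "g4"))
  expect_equal(log$max_species_share[2], 7 / 8)
  expect_error(filter_counts(cm, min_fraction = 0), "min_fraction")
  expect_error(filter_counts(cm, rescue_fraction = 1.2), "rescue_fraction")
})

test_that("filtering is invariant to sample order", {
  d <- small_design(seed = 41)
  cm <- simulate_counts(d, n_genotypes = 4, n_clones = 2)
  perm <- sample(ncol(cm$counts))
  cm2 <- cm
  cm2$counts <- cm$counts[, perm]
  cm2$meta <- cm$meta[perm, ]
  k1 <- rownames(filter_counts(cm)$counts)
  k2 <- rownames(filter_counts(cm2)$counts)
  expect_identical(k1, k2)
})

test_that("median-of-ratios factors recover planted depth differences", {
  base <- matrix(rpois(100 * 2, 100), 100, 2)
  counts <- cbind(base[, 1], base[, 1] * 2L)  # sample 2 doubles sample 1
  cm <- toy_count_matrix(counts, c("A", "B"), c("low", "low"))
  sf <- normalize_counts(cm)$size_factors
  expect_equal(unname(sf[2] / sf[1]), 2, tolerance = 1e-9)
  # identical samples: equal factors
  cm2 <- toy_count_matrix(cbind(base[, 1], base[, 1]), c("A", "B"),
                          c("low", "low"))
  expect_equal(unname(diff(normalize_counts(cm2)$size_factors)), 0)
  # planted 3-fold library sizes in an NB simulation: recovered within 5%
  set.seed(42)
  mu <- exp(rnorm(400, log(100), 1))
  lib <- rep(c(1, 3), each = 4)
  counts3 <- sapply(lib, function(l) rnbinom(400, mu = mu * l, size = 10))
  cm3 <- toy_count_matrix(counts3, rep(c("A", "B"), each = 4),
                          rep("low", 8))
  sf3 <- normalize_counts(cm3)$size_factors
  ratio <- mean(sf3[5:8]) / mean(sf3[1:4])
  expect_lt(abs(ratio - 3) / 3, 0.05)
})

test_that("null DE p values are uniform and planted effects are recovered", {
  set.seed(43)
  ng <- 600; n <- 12
  mu <- exp(rnorm(ng, log(100), 1))
  counts <- matrix(rnbinom(ng * n, mu = rep(mu, n), size = 10), nrow = ng)
  cm <- toy_count_matrix(counts, rep("A", n),
                         rep(c("low", "high"), 6),
                         genotype = rep(paste0("G", 1:6), each = 2))
  de <- de_test(cm, "site_vs_home", species = "A", site = "high",
                home_site = "low")
  ks <- suppressWarnings(ks.test(de$p[!de$untestable], "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_true(all(de$padj >= de$p, na.rm = TRUE))

  # planted |LFC| = 2 in 100 genes (balanced up/down) among 500 nulls
  lfc <- c(rep(2, 50), rep(-2, 50), rep(0, 500))
  mu2 <- exp(rnorm(600, log(100), 1))
  grp <- rep(c(0, 1), each = 6)
  mu_mat <- (mu2 / 2^(lfc / 2)) * 2^(outer(lfc, grp))
  counts2 <- matrix(rnbinom(600 * n, mu = mu_mat, size = 1 / 0.1), nrow = 600)
  cm2 <- toy_count_matrix(counts2, rep("A", n),
                          rep(c("low", "high"), each = 6),
                          genotype = rep(paste0("G", 1:6), 2))
  de2 <- de_test(cm2, "site_vs_home", species = "A", site = "high",
                 home_site = "low")
  expect_lt(abs(mean((de2$lfc - lfc)[1:100])), 0.2)
})

test_that("all-zero genes are flagged untestable, not significant", {
  counts <- rbind(rep(0L, 8), matrix(rpois(40, 50), 5, 8))
  cm <- toy_count_matrix(counts, rep("A", 8), rep(c("low", "high"), each = 4))
  de <- de_test(cm, "site_vs_home", species = "A", site = "high",
                home_site = "low")
  expect_true(de$untestable[1])
  expect_false(de$sig[1])
})

test_that("BH equals the step-up definition and its hand examples", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(0.2), 0.2)
  set.seed(44)
  for (i in 1:20) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), bh_bruteforce(p), tolerance = 1e-12)
    expect_true(all(bh_adjust(p) >= p))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("set overlaps count exactly against a constructed plan", {
  uni <- sprintf("g%03d", 1:100)
  sets <- list(s500 = uni[1:30], s1000 = uni[11:40], s1500 = uni[21:50],
               s2000 = uni[c(21:30, 91:100)])
  cs <- contrast_sets(sets, uni)
  expect_equal(unname(cs$sizes), c(30L, 30L, 30L, 20L))
  expect_equal(cs$common, uni[21:30])
  excl <- cs$exclusive
  expect_equal(excl$count[excl$pattern == "s500"], 10L)       # 1:10
  expect_equal(excl$count[excl$pattern == "s2000"], 10L)      # 91:100
  expect_equal(excl$count[excl$pattern == "s500&s1000"], 10L) # 11:20
  expect_equal(sum(excl$count), length(unique(unlist(sets))))
  # identical sets: the all-set intersection equals each set
  same <- list(a = uni[1:5], b = uni[1:5])
  expect_equal(contrast_sets(same, uni)$common, uni[1:5])
  # disjoint sets: empty common
  expect_equal(length(contrast_sets(list(a = uni[1:3], b = uni[4:6]),
                                    uni)$common), 0L)
  expect_error(contrast_sets(list(a = "zzz"), uni), "outside the universe")
})

test_that("quadrant classification is an exhaustive partition with the stated rules", {
  expect_equal(as.character(quadrant_classify(2, TRUE, -2, TRUE)),
               "opposite-direction")
  expect_equal(as.character(quadrant_classify(2, TRUE, 0.1, FALSE)),
               "A-specific")
  expect_equal(as.character(quadrant_classify(0.1, FALSE, -2, TRUE)),
               "B-specific")
  expect_equal(as.character(quadrant_classify(2, TRUE, 2, TRUE,
                                              magnitude_delta = 0.5)),
               "shared-same-direction")
  expect_equal(as.character(quadrant_classify(3, TRUE, 1, TRUE,
                                              magnitude_delta = 0.5)),
               "magnitude-divergent")
  expect_equal(as.character(quadrant_classify(0.2, FALSE, 0.1, FALSE)),
               "unchanged")
  # partition property on random input
  set.seed(45)
  n <- 500
  q <- quadrant_classify(rnorm(n), runif(n) < 0.5, rnorm(n), runif(n) < 0.5)
  expect_equal(sum(table(q)), n)
  expect_false(anyNA(q))
  expect_error(quadrant_classify(Inf, TRUE, 0, FALSE), "finite")
})

test_that("planted two-module structure is recovered; pure noise yields none", {
  set.seed(46)
  n <- 24
  f1 <- rnorm(n)
  f2 <- residuals(lm(rnorm(n) ~ f1))  # in-sample orthogonal latent factor
  expr <- rbind(
    t(sapply(1:50, function(i) 2 * f1 + rnorm(n, 0, 0.6))),
    t(sapply(1:50, function(i) 2 * f2 + rnorm(n, 0, 0.6))),
    matrix(rnorm(60 * n), 60, n))
  rownames(expr) <- sprintf("g%03d", 1:160)
  mods <- detect_modules(expr, cut_height = 0.5, min_size = 10)
  planted <- rep(c("P1", "P2", "noise"), c(50, 50, 60))
  found <- ifelse(is.na(mods$module), "none", mods$module)
  core <- planted != "noise"
  expect_gte(adjusted_rand(planted[core], found[core]), 0.9)
  expect_gte(mean(!is.na(mods$module[1:100])), 0.95)
  # independent noise: no module reaches the minimum size
  noise <- matrix(rnorm(200 * n), 200, n,
                  dimnames = list(sprintf("n%03d", 1:200), NULL))
  m0 <- detect_modules(noise, cut_height = 0.5, min_size = 10)
  expect_true(all(is.na(m0$module)))
})

test_that("eigengene of perfectly correlated genes reproduces the profile", {
  set.seed(47)
  prof <- rnorm(10)
  expr <- t(sapply(1:6, function(i) 3 * prof + i))  # same standardised shape
  rownames(expr) <- paste0("g", 1:6)
  meta <- data.frame(sample = paste0("s", 1:10),
                     species = rep(c("A", "B"), each = 5),
                     elevation = rep(c(500, 1000, 1500, 2000, 2000), 2))
  colnames(expr) <- meta$sample
  eg <- module_eigengene(expr, paste0("g", 1:6), meta)
  expect_equal(eg$var_explained, 1, tolerance = 1e-12)
  expect_equal(abs(cor(eg$eigengene, prof)), 1, tolerance = 1e-12)
  expect_error(module_eigengene(rbind(expr, g7 = rep(1, 10)),
                                paste0("g", c(1, 7)), meta),
               "zero-variance")
})

test_that("species-specific latent factors give species-specific correlations", {
  d <- small_design(n_genes = 60, lfc_species = 0, lfc_site = 0,
                    lfc_interaction = 0, dispersion = 0.05,
                    module_assignments = rep(c(0L, 2L, 0L), c(20, 20, 20)),
                    module_factor_loadings = 2, seed = 48)
  # module 2's default latent factor tracks elevation only in species B
  cm <- simulate_counts(d, n_genotypes = 6, n_clones = 2)
  nm <- normalize_counts(cm)
  eg <- module_eigengene(nm$log_expr, rownames(cm$counts)[21:40], nm$meta)
  rB <- eg$elevation_cor[eg$elevation_cor$species == "B", ]
  rA <- eg$elevation_cor[eg$elevation_cor$species == "A", ]
  expect_lt(rB$p, 1e-4)
  expect_gt(abs(rB$r), 0.9)
  expect_lt(abs(rA$r), abs(rB$r) / 2)
})

test_that("Fisher enrichment equals hypergeometric enumeration for all small margins", {
  uni <- sprintf("g%03d", 1:30)
  set.seed(49)
  for (i in 1:25) {
    n_term <- sample(1:30, 1)
    n_de <- sample(1:30, 1)
    de <- sample(uni, n_de)
    term_genes <- sample(uni, n_term)
    tm <- data.frame(gene = term_genes, term = "T1")
    res <- go_enrichment(de, uni, tm)
    a <- length(intersect(de, term_genes))
    expect_equal(res$p, fisher_bruteforce(a, n_term, n_de, 30),
                 tolerance = 1e-12)
  }
  # zero overlap -> p = 1 under the one-sided greater alternative
  tm0 <- data.frame(gene = uni[21:30], term = "T0")
  expect_equal(go_enrichment(uni[1:10], uni, tm0)$p, 1)
  # worked 2x2: universe 100, term 10, DE 10, overlap 5
  uni2 <- sprintf("h%03d", 1:100)
  tm2 <- data.frame(gene = uni2[1:10], term = "T2")
  res2 <- go_enrichment(c(uni2[1:5], uni2[96:100]), uni2, tm2)
  expect_equal(res2$p, fisher_bruteforce(5, 10, 10, 100), tolerance = 1e-12)
  expect_error(go_enrichment("x", uni, tm0), "subset")
  expect_error(go_enrichment(character(0), character(0), tm0), "empty")
})
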