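# Mean standardisation, Wilks' lambda against a brute-force SSCP oracle,
# D-matrix geometry, and the plasticity/divergence vector operations.

test_that("mean standardisation divides by the grand mean and flags zeros", {
  tab <- data.frame(species = rep(c("A", "B"), each = 2),
                    genotype = paste0("g", 1:4), site = "low",
                    elevation = 500, trait = "t", value = c(1, 3, 1, 3))
  std <- mean_standardize(tab)
  expect_equal(std$value, c(0.5, 1.5, 0.5, 1.5))
  expect_equal(unname(attr(std, "grand_means")), 2)
  # any shape: per-trait standardised mean is exactly 1
  gm <- genotype_means(simulate_traits(small_design(seed = 4)))
  std2 <- mean_standardize(gm)
  per_trait <- tapply(std2$value, std2$trait, mean)
  expect_true(all(abs(per_trait - 1) < 1e-12))
  tab$value <- c(-1, 1, -1, 1)
  expect_error(mean_standardize(tab), "zero grand mean.*t")
})

test_that("Wilks' lambda equals the brute-force SSCP oracle on random balanced instances", {
  set.seed(42)
  for (rep in 1:10) {
    p <- sample(2:4, 1)
    n_sp <- 2
    n_site <- sample(2:3, 1)
    choices <- seq(p + 2, 6)
    n_geno <- choices[sample.int(length(choices), 1)]
    species <- rep(c("A", "B"), each = n_site * n_geno)
    site <- rep(rep(paste0("s", seq_len(n_site)), each = n_geno), n_sp)
    genotype <- paste0(species, "_g", rep(seq_len(n_geno), n_sp * n_site))
    Y <- matrix(rnorm(length(species) * p), ncol = p,
                dimnames = list(NULL, paste0("tr", seq_len(p))))
    tab <- wide_to_trait_table(Y, species, site, genotype)
    res <- manova_wilks(tab, "species:site")
    oracle <- wilks_bruteforce_interaction(Y, factor(species), factor(site))
    expect_equal(res$lambda, oracle, tolerance = 1e-10)
  }
})

test_that("Wilks' lambda is 1 for identical cell structure and matches stats::manova", {
  set.seed(7)
  n_geno <- 5
  species <- rep(c("A", "B"), each = 2 * n_geno)
  site <- rep(rep(c("low", "high"), each = n_geno), 2)
  genotype <- paste0(species, "_g", rep(1:n_geno, 4))
  Y <- matrix(rnorm(20 * 3), ncol = 3, dimnames = list(NULL, c("a", "b", "c")))
  tab <- wide_to_trait_table(Y, species, site, genotype)
  res <- manova_wilks(tab, "species:site")
  sm <- summary(stats::manova(Y ~ factor(species) * factor(site)),
                test = "Wilks")$stats
  expect_equal(res$lambda, sm[3, "Wilks"], tolerance = 1e-8)
  expect_equal(res$F, sm[3, "approx F"], tolerance = 1e-6)
  expect_true(res$lambda > 0 && res$lambda <= 1)
  # no real group differences: lambda near 1, p large
  expect_gt(res$p, 0.05)
})

test_that("D matrix has the promised rank, normalisation and invariances", {
  # exactly two distinct cell means -> rank 1, first axis carries 100%
  tab <- expand.grid(genotype = paste0("g", 1:4), species = c("A", "B"),
                     site = c("low", "high"), trait = c("t1", "t2"),
                     stringsAsFactors = FALSE)
  tab$genotype <- paste0(tab$species, tab$genotype)
  tab$elevation <- ifelse(tab$site == "low", 500, 2000)
  tab$value <- ifelse(tab$species == "A",
                      ifelse(tab$trait == "t1", 1, 2),
                      ifelse(tab$trait == "t1", 3, 1))
  g <- group_means(tab)
  dres <- compute_D(g)
  expect_equal(dres$proportion[1], 1)
  expect_equal(sum(dres$proportion), 1)
  expect_equal(sqrt(sum(dres$loadings[, 1]^2)), 1)
  # d_max proportional to the difference of the two distinct means
  diffvec <- c(1 - 3, 2 - 1)
  ang <- vector_angle(dres$loadings[, 1], diffvec)
  expect_true(min(ang, 180 - ang) < 1e-6)
  expect_true(isSymmetric(dres$D))
  expect_true(all(eigen(dres$D)$values > -1e-12))
  # all means identical -> zero matrix with a warning
  tab$value <- 1
  expect_warning(d0 <- compute_D(group_means(tab)), "zero matrix")
  expect_equal(length(d0$proportion), 0)
  expect_error(compute_D(structure(list(
    means = matrix(1, 1, 2), cells = data.frame(species = "A", site = "low"),
    traits = c("t1", "t2")), class = "group_mean_set")), "at least two cells")
})

test_that("unit-unit standardisation makes D invariant to trait units", {
  d <- small_design(seed = 21)
  gm <- genotype_means(simulate_traits(d))
  gm2 <- gm
  # rescale one trait's raw unit by 1000 (mm^2 -> m^2 style change)
  gm2$value[gm2$trait == "area"] <- gm2$value[gm2$trait == "area"] * 1000
  D1 <- compute_D(group_means(mean_standardize(gm)))
  D2 <- compute_D(group_means(mean_standardize(gm2)))
  expect_equal(D1$D, D2$D, tolerance = 1e-12)
})

test_that("plasticity and divergence vectors follow the difference conventions", {
  tab <- expand.grid(genotype = paste0("g", 1:3), species = c("A", "B"),
                     site = c("low", "high"), trait = c("t1", "t2"),
                     stringsAsFactors = FALSE)
  tab$genotype <- paste0(tab$species, tab$genotype)
  tab$elevation <- ifelse(tab$site == "low", 500, 2000)
  tab$value <- with(tab, ifelse(species == "A" & site == "low",
                        ifelse(trait == "t1", 2, 2),
                 ifelse(species == "A" & site == "high",
                        ifelse(trait == "t1", 1, 1),
                 ifelse(species == "B" & site == "high",
                        ifelse(trait == "t1", 1, 0),
                        ifelse(trait == "t1", 0, 1)))))
  g <- group_means(tab)
  pv <- plasticity_vector(g, "A", "low", "high")
  expect_equal(unname(pv$unit), c(1, 1) / sqrt(2))
  expect_equal(pv$magnitude, sqrt(2))
  # swapping native and novel negates the unit vector
  pv_rev <- plasticity_vector(g, "A", "high", "low")
  expect_equal(pv_rev$unit, -pv$unit)
  # divergence between native cells (A at low) - (B at high)
  dv <- divergence_vector(g, "A", "low", "B", "high")
  expect_equal(unname(dv$unit), c(1, 2) / sqrt(5))
  # degenerate: identical cells
  tab0 <- tab; tab0$value <- 1
  expect_error(plasticity_vector(group_means(tab0), "A", "low", "high"),
               "zero difference")
})

test_that("angles behave analytically and are invariant to rotation and scale", {
  expect_equal(vector_angle(c(1, 0), c(1, 0)), 0)
  expect_equal(vector_angle(c(1, 0), c(0, 1)), 90)
  expect_equal(vector_angle(c(1, 0), c(-1, 0)), 180)
  expect_equal(vector_angle(c(1, 0), c(1, 1)), 45)
  expect_error(vector_angle(c(0, 0), c(1, 0)), "zero vector")
  set.seed(5)
  for (i in 1:10) {
    a <- rnorm(3); b <- rnorm(3)
    ang <- vector_angle(a, b)
    expect_equal(vector_angle(5.3 * a, 0.02 * b), ang, tolerance = 1e-9)
    qr_q <- qr.Q(qr(matrix(rnorm(9), 3)))  # random rotation
    expect_equal(vector_angle(qr_q %*% a, qr_q %*% b), ang,
                 tolerance = 1e-9)
  }
})

test_that("adaptive alignment flags perfect alignment and orthogonality", {
  tab <- expand.grid(genotype = paste0("g", 1:3), species = c("A", "B"),
                     site = c("low", "high"), trait = c("t1", "t2"),
                     stringsAsFactors = FALSE)
  tab$genotype <- paste0(tab$species, tab$genotype)
  tab$elevation <- ifelse(tab$site == "low", 500, 2000)
  # A's away-from-home plasticity exactly reaches B's native phenotype
  val <- function(sp, si, tr)
    if (sp == "A" && si == "low") c(t1 = 1, t2 = 1)[tr] else
    if (sp == "A" && si == "high") c(t1 = 2, t2 = 2)[tr] else
    if (sp == "B" && si == "high") c(t1 = 2, t2 = 2)[tr] else
                                   c(t1 = 2, t2 = 1)[tr]
  tab$value <- mapply(val, tab$species, tab$site, tab$trait)
  al <- adaptive_alignment(group_means(tab), c(A = "low", B = "high"))
  a_row <- al[al$comparison == "plasticity_vs_divergence" & al$species == "A", ]
  expect_equal(a_row$angle_deg, 0, tolerance = 1e-5)
  expect_true(a_row$aligned)
  # B: home-to-away plasticity (1,0) -> (2,1)-(2,2)=(0,-1) vs divergence
  # (1,1)-(2,2)=(-1,-1): 90 and 45 degrees apart respectively by construction
  b_row <- al[al$comparison == "plasticity_vs_divergence" & al$species == "B", ]
  expect_equal(b_row$angle_deg, 45)
})

test_that("planted divergence direction is recovered at large n", {
  # plant divergence along (3,4)/5 in standardised units via species offsets
  sites <- c(low = 500, high = 2000)
  m1 <- rbind(c(10, 10), c(10 * (1 - 0.3), 10 * (1 - 0.3)))
  m2 <- rbind(c(5, 5), c(5 * (1 - 0.4), 5 * (1 - 0.4)))
  dimnames(m1) <- dimnames(m2) <- list(c("A", "B"), names(sites))
  d <- simulation_design(species = c("A", "B"), elevations = sites,
                         n_genotypes_per_species = 80,
                         trait_means = list(t1 = m1, t2 = m2),
                         var_genotype_by_site = 0.01, var_block = 0.005,
                         var_residual = 0.02, seed = 17)
  g <- group_means(mean_standardize(genotype_means(clone_means(simulate_traits(d)))))
  dv <- divergence_vector(g, "A", "low", "B", "high")
  # standardised planted divergence ~ (0.3/0.85, 0.4/0.8)-ish; compute exactly:
  # grand means: t1: (10+10+7+7)/4=8.5 -> gap 3/8.5; t2: (5+5+3+3)/4=4 -> 2/4
  planted <- c(3 / 8.5, 2 / 4)
  expect_lt(vector_angle(dv$raw, planted), 1)
})
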