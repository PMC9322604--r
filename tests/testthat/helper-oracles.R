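# Independent brute-force oracles and small fixture builders shared across
# the test files. The oracles deliberately re-derive each quantity from
# first principles, without touching the implementation under test.

# --- fixtures -------------------------------------------------------------

small_design <- function(seed = 1, ...) {
  args <- list(species = c("A", "B"),
               elevations = c(low = 500, mid1 = 1000, mid2 = 1500, high = 2000),
               n_genotypes_per_species = 6, n_blocks_per_site = 2,
               n_clones_per_genotype_block = 2, n_genes = 60, seed = seed)
  extra <- list(...)
  do.call(simulation_design, utils::modifyList(args, extra))
}

# additive (no species:site interaction) cell means for null simulations
additive_trait_means <- function(species, sites, sd_scale = 1) {
  grad <- seq(0, 1, length.out = length(sites))
  m <- rbind(10 + 2 * grad, 11 + 2 * grad)
  dimnames(m) <- list(species, sites)
  list(y = m)
}

# long trait_table from an explicit units x traits matrix (one clone each)
wide_to_trait_table <- function(Y, species, site, genotype) {
  do.call(rbind, lapply(seq_len(ncol(Y)), function(j) {
    data.frame(species = species, genotype = genotype, site = site,
               elevation = as.numeric(factor(site)), block = "B1",
               clone = paste0(genotype, ".", site),
               trait = colnames(Y)[j], value = Y[, j],
               stringsAsFactors = FALSE)
  }))
}

toy_count_matrix <- function(counts, species, site, genotype = NULL,
                             elevation = NULL) {
  n <- ncol(counts)
  if (is.null(genotype)) genotype <- paste0(species, "_g", seq_len(n))
  if (is.null(elevation))
    elevation <- as.numeric(factor(site, levels = unique(site))) * 500
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("g%03d", seq_len(nrow(counts)))
  colnames(counts) <- sprintf("s%03d", seq_len(n))
  meta <- data.frame(sample = colnames(counts), species = species,
                     genotype = genotype, site = site,
                     elevation = elevation,
                     clone = paste0(genotype, ".", site),
                     stringsAsFactors = FALSE)
  structure(list(counts = counts, meta = meta), class = "count_matrix")
}

# --- oracles --------------------------------------------------------------

# Wilks' lambda for the two-way interaction on a balanced layout, from
# explicit group-mean SSCP sums (classical balanced two-way MANOVA).
wilks_bruteforce_interaction <- function(Y, f1, f2) {
  cells <- interaction(f1, f2, drop = FALSE)
  gbar <- colMeans(Y)
  E <- matrix(0, ncol(Y), ncol(Y))
  H <- matrix(0, ncol(Y), ncol(Y))
  m1 <- apply(Y, 2, function(y) tapply(y, f1, mean))
  m2 <- apply(Y, 2, function(y) tapply(y, f2, mean))
  for (cl in levels(cells)) {
    idx <- cells == cl
    n_c <- sum(idx)
    mc <- colMeans(Y[idx, , drop = FALSE])
    for (i in which(idx)) {
      d <- Y[i, ] - mc
      E <- E + outer(d, d)
    }
    a <- levels(f1)[as.integer(f1[idx][1])]
    b <- levels(f2)[as.integer(f2[idx][1])]
    d <- mc - m1[a, ] - m2[b, ] + gbar
    H <- H + n_c * outer(d, d)
  }
  det(E) / det(E + H)
}

# Breslow partial log-likelihood for a single binary covariate.
breslow_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    d <- which(time == t & event == 1)
    risk <- which(time >= t)
    ll <- ll + beta * sum(x[d]) -
      length(d) * log(sum(exp(beta * x[risk])))
  }
  ll
}

# Step-up BH from the definition.
bh_bruteforce <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(1, adj)
  out
}

# One-sided hypergeometric tail by enumeration: P(X >= a) for overlap of a
# DE set of size n_de with a term of size n_term in a universe of size N.
fisher_bruteforce <- function(a, n_term, n_de, N) {
  ks <- a:min(n_term, n_de)
  sum(choose(n_term, ks) * choose(N - n_term, n_de - ks) / choose(N, n_de))
}

# Adjusted Rand index between two labellings.
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  (sum_ij - expected) / (maxi - expected)
}
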