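# Synthetic reciprocal-transplant data generator: traits, survival and
# RNA-seq counts sharing one design object so every downstream stage can be
# exercised without field data.

#' Define a synthetic reciprocal-transplant design
#'
#' Bundles the experimental layout (species, transplant elevations,
#' genotypes, blocks, clones) with the generative parameters of the three
#' data layers: Gaussian trait means and variance components for the
#' reaction-norm model, per-day log hazard rates with a log-normal genotype
#' frailty for survival, and per-gene negative-binomial parameters with
#' latent coexpression modules for counts.
#'
#' @param species Character vector of species labels (default the two focal
#'   taxa of the transplant design).
#' @param elevations Named numeric vector of site elevations in metres
#'   above sea level; names are the site labels.
#' @param n_genotypes_per_species Integer vector (recycled to the number of
#'   species) of genotypes sampled per species.
#' @param n_blocks_per_site Number of experimental blocks at each site.
#' @param n_clones_per_genotype_block Cuttings of each genotype planted in
#'   each block.
#' @param trait_means Named list of species x site matrices of cell means,
#'   one per trait (rows = species, columns = sites). Holds the fixed
#'   species, site and species-by-site structure of the trait model.
#' @param var_genotype_by_site Variance of the genotype-by-site random
#'   deviation (trait units squared).
#' @param var_block Variance of the block-within-site random deviation.
#' @param var_residual Residual variance.
#' @param hazard_log_rates Species x site matrix of log baseline hazard
#'   rates per day; \code{-Inf} is an accepted sentinel for a zero hazard.
#' @param frailty_variance Variance of the per-genotype log-frailty.
#' @param n_genes Number of genes for the count layer.
#' @param lfc_species,lfc_site,lfc_interaction Per-gene log2 effects
#'   (recycled to \code{n_genes}): species offset, slope over elevation
#'   scaled to \eqn{[0, 1]}, and the species-specific difference in that
#'   slope.
#' @param dispersion Per-gene negative-binomial dispersion \eqn{\alpha}
#'   (variance \eqn{\mu + \alpha \mu^2}); recycled.
#' @param module_assignments Integer vector (length \code{n_genes}) of
#'   latent module labels; 0 = unassigned.
#' @param module_factor_loadings Per-gene loading on the latent factor of
#'   its module (ignored for unassigned genes).
#' @param library_size_sdlog Log-normal sd of sample library-size factors.
#' @param var_genotype_expr Variance of the per-gene-per-genotype log2
#'   expression deviation.
#' @param seed Master seed; all three generators draw from substreams
#'   derived deterministically from it.
#' @return An object of class \code{sim_design}.
#' @export
simulation_design <- function(species = c("S_chrysanthemifolius", "S_aethnensis"),
                              elevations = c(low = 500, mid1 = 1000,
                                             mid2 = 1500, high = 2000),
                              n_genotypes_per_species = c(21, 25),
                              n_blocks_per_site = 3,
                              n_clones_per_genotype_block = 3,
                              trait_means = default_trait_means(species, names(elevations)),
                              var_genotype_by_site = 0.05,
                              var_block = 0.02,
                              var_residual = 0.1,
                              hazard_log_rates = default_hazard_log_rates(species, names(elevations)),
                              frailty_variance = 0.1,
                              n_genes = 200,
                              lfc_species = default_lfc(n_genes, prop = 0.10, size = 2, stream = 1),
                              lfc_site = default_lfc(n_genes, prop = 0.10, size = 2, stream = 2),
                              lfc_interaction = default_lfc(n_genes, prop = 0.05, size = 2, stream = 3),
                              dispersion = 0.1,
                              module_assignments = default_modules(n_genes),
                              module_factor_loadings = rep(1, n_genes),
                              library_size_sdlog = 0.2,
                              var_genotype_expr = 0.02,
                              seed = 1L) {
  species <- as.character(species)
  if (is.null(names(elevations))) names(elevations) <- as.character(elevations)
  n_genotypes_per_species <- rep_len(as.integer(n_genotypes_per_species),
                                     length(species))
  d <- structure(list(
    species = species,
    elevations = elevations,
    n_genotypes_per_species = n_genotypes_per_species,
    n_blocks_per_site = as.integer(n_blocks_per_site),
    n_clones_per_genotype_block = as.integer(n_clones_per_genotype_block),
    trait_means = trait_means,
    var_genotype_by_site = var_genotype_by_site,
    var_block = var_block,
    var_residual = var_residual,
    hazard_log_rates = hazard_log_rates,
    frailty_variance = frailty_variance,
    n_genes = as.integer(n_genes),
    lfc_species = rep_len(lfc_species, n_genes),
    lfc_site = rep_len(lfc_site, n_genes),
    lfc_interaction = rep_len(lfc_interaction, n_genes),
    dispersion = rep_len(dispersion, n_genes),
    module_assignments = rep_len(as.integer(module_assignments), n_genes),
    module_factor_loadings = rep_len(module_factor_loadings, n_genes),
    library_size_sdlog = library_size_sdlog,
    var_genotype_expr = var_genotype_expr,
    seed = as.integer(seed)
  ), class = "sim_design")
  validate_design(d)
  d
}

#' @export
print.sim_design <- function(x, ...) {
  cat("Synthetic reciprocal-transplant design\n")
  cat(sprintf("  %d species x %d sites (%s m)\n", length(x$species),
              length(x$elevations), paste(x$elevations, collapse = "/")))
  cat(sprintf("  genotypes/species: %s; %d blocks/site; %d clones/genotype/block\n",
              paste(x$n_genotypes_per_species, collapse = ", "),
              x$n_blocks_per_site, x$n_clones_per_genotype_block))
  cat(sprintf("  traits: %s\n", paste(names(x$trait_means), collapse = ", ")))
  cat(sprintf("  genes: %d; seed: %d\n", x$n_genes, x$seed))
  invisible(x)
}

validate_design <- function(d) {
  if (length(d$species) < 1L) stop("design needs at least one species")
  if (anyDuplicated(names(d$elevations)))
    stop("site labels must be unique")
  counts <- c(d$n_genotypes_per_species, d$n_blocks_per_site,
              d$n_clones_per_genotype_block)
  if (any(!is.finite(counts)) || any(counts <= 0))
    stop("invalid design: genotype, block and clone counts must be positive")
  vars <- c(d$var_genotype_by_site, d$var_block, d$var_residual,
            d$frailty_variance, d$var_genotype_expr)
  if (any(vars < 0)) stop("invalid design: variances must be non-negative")
  if (any(d$dispersion <= 0)) stop("invalid design: dispersions must be > 0")
  for (nm in names(d$trait_means)) {
    m <- d$trait_means[[nm]]
    if (!all(dim(m) == c(length(d$species), length(d$elevations))))
      stop(sprintf("trait_means[['%s']] must be a %d x %d species x site matrix",
                   nm, length(d$species), length(d$elevations)))
  }
  if (!all(dim(d$hazard_log_rates) == c(length(d$species), length(d$elevations))))
    stop("hazard_log_rates must be a species x site matrix")
  if (any(is.nan(d$hazard_log_rates)))
    stop("hazard_log_rates must be finite or -Inf")
  invisible(TRUE)
}

# Default cell means echo the qualitative reaction norms of the study
# system: leaf area shrinks with elevation in both species; complexity
# drops with elevation only in the low-elevation species; indent density
# drops with elevation only in the high-elevation species; SLA rises at low
# elevation, more steeply in the high-elevation species.
default_trait_means <- function(species, sites) {
  ns <- length(sites)
  grad <- seq(0, 1, length.out = ns)  # 0 = lowest, 1 = highest site
  mk <- function(a, b) {
    m <- rbind(a, b)
    dimnames(m) <- list(species, sites)
    m
  }
  list(
    area           = mk(10 - 3 * grad, 8 - 3 * grad),
    complexity     = mk(30 - 10 * grad, 12 + 0 * grad),
    indent_density = mk(1.4 + 0 * grad, 1.0 - 0.4 * grad),
    sla            = mk(22 - 4 * grad, 28 - 10 * grad)
  )
}

# Species from low elevation dies faster the higher it is moved; mirror
# pattern for the high-elevation species.
default_hazard_log_rates <- function(species, sites) {
  ns <- length(sites)
  up <- log(seq(0.0015, 0.008, length.out = ns))
  m <- rbind(up, rev(up))
  dimnames(m) <- list(species, sites)
  m
}

default_lfc <- function(n_genes, prop, size, stream) {
  # deterministic pattern, independent of the RNG state at call time
  k <- max(0L, round(prop * n_genes))
  v <- numeric(n_genes)
  if (k > 0) {
    idx <- (seq_len(k) * 7L + stream * 3L) %% n_genes + 1L
    idx <- unique(idx)[seq_len(min(k, n_genes))]
    v[idx] <- size * rep_len(c(1, -1), length(idx))
  }
  v
}

default_modules <- function(n_genes, module_size = 50L, n_modules = 2L) {
  m <- integer(n_genes)
  for (j in seq_len(n_modules)) {
    lo <- (j - 1L) * module_size + 1L
    hi <- min(j * module_size, n_genes)
    if (lo <= hi) m[lo:hi] <- j
  }
  m
}

# Independent substreams per data layer from one master seed.
substream_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + stream * 65537) %% 2147483587L) + 1L
}

# Expand the combinatorial plan: one row per planted cutting.
design_plan <- function(d) {
  sites <- names(d$elevations)
  rows <- list()
  for (si in seq_along(d$species)) {
    sp <- d$species[si]
    genos <- sprintf("%s_g%02d", abbreviate(sp, 4), seq_len(d$n_genotypes_per_species[si]))
    g <- expand.grid(clone_rep = seq_len(d$n_clones_per_genotype_block),
                     genotype = genos,
                     block = sprintf("B%d", seq_len(d$n_blocks_per_site)),
                     site = sites,
                     stringsAsFactors = FALSE)
    g$species <- sp
    rows[[si]] <- g
  }
  plan <- do.call(rbind, rows)
  plan$elevation <- unname(d$elevations[plan$site])
  plan$clone <- sprintf("%s.%s.%s.c%d", plan$genotype, plan$site, plan$block,
                        plan$clone_rep)
  plan$plant_id <- seq_len(nrow(plan))
  plan[, c("plant_id", "species", "genotype", "site", "elevation", "block",
           "clone")]
}

#' Simulate a per-clone trait table
#'
#' Draws one value per clone per trait from the additive model behind the
#' univariate reaction-norm analysis: a fixed species-by-site cell mean
#' plus independent Gaussian genotype-by-site, block-within-site and
#' residual deviations.
#'
#' @param design A \code{sim_design}.
#' @return A \code{trait_table} data frame in long format with columns
#'   species, genotype, site, elevation, block, clone, trait, value.
#' @export
simulate_traits <- function(design) {
  validate_design(design)
  plan <- design_plan(design)
  sites <- names(design$elevations)
  out <- list()
  set.seed(substream_seed(design$seed, 11L))
  for (tr in names(design$trait_means)) {
    mu <- design$trait_means[[tr]]
    cell_mu <- mu[cbind(match(plan$species, design$species),
                        match(plan$site, sites))]
    gs_key <- interaction(plan$genotype, plan$site, drop = TRUE)
    gs_dev <- stats::rnorm(nlevels(gs_key), 0, sqrt(design$var_genotype_by_site))
    bl_key <- interaction(plan$site, plan$block, drop = TRUE)
    bl_dev <- stats::rnorm(nlevels(bl_key), 0, sqrt(design$var_block))
    resid <- stats::rnorm(nrow(plan), 0, sqrt(design$var_residual))
    val <- cell_mu + gs_dev[as.integer(gs_key)] + bl_dev[as.integer(bl_key)] + resid
    out[[tr]] <- data.frame(plan[, c("species", "genotype", "site",
                                     "elevation", "block", "clone")],
                            trait = tr, value = val,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("trait_table", "data.frame")
  res
}

#' Simulate per-plant survival records
#'
#' Event times are exponential with per-plant rate
#' \eqn{\exp(\log\lambda_{species,site} + u_{genotype})}, where the
#' genotype log-frailty \eqn{u} is Gaussian. Times beyond the follow-up are
#' censored at the follow-up, mirroring censoring at the last survey of a
#' field transplant.
#'
#' @param design A \code{sim_design}.
#' @param follow_up_days Length of the observation window (days).
#' @return A \code{survival_table} data frame with columns plant_id,
#'   species, genotype, site, elevation, block, time, event.
#' @export
simulate_survival <- function(design, follow_up_days = 150) {
  validate_design(design)
  if (!is.finite(follow_up_days) || follow_up_days <= 0)
    stop("follow_up_days must be positive")
  plan <- design_plan(design)
  sites <- names(design$elevations)
  set.seed(substream_seed(design$seed, 23L))
  genos <- unique(plan$genotype)
  frailty <- stats::rnorm(length(genos), 0, sqrt(design$frailty_variance))
  names(frailty) <- genos
  lograte <- design$hazard_log_rates[cbind(match(plan$species, design$species),
                                           match(plan$site, sites))] +
    frailty[plan$genotype]
  n <- nrow(plan)
  t_raw <- rep(Inf, n)
  alive_rate <- is.finite(lograte)
  t_raw[alive_rate] <- stats::rexp(sum(alive_rate), rate = exp(lograte[alive_rate]))
  event <- as.integer(t_raw <= follow_up_days)
  time <- pmin(t_raw, follow_up_days)
  res <- data.frame(plan[, c("plant_id", "species", "genotype", "site",
                             "elevation", "block")],
                    time = time, event = event, stringsAsFactors = FALSE)
  class(res) <- c("survival_table", "data.frame")
  res
}

#' Simulate a gene x sample count matrix
#'
#' Negative-binomial counts whose log2 mean combines a per-gene baseline,
#' species, elevation and species-by-elevation effects, a genotype
#' deviation, and a latent module factor (linear in scaled elevation,
#' optionally species-specific) scaled by the gene's loading. Library sizes
#' are log-normal.
#'
#' @param design A \code{sim_design}.
#' @param n_genotypes Genotypes per species carried into the expression
#'   assay (the field study sequenced a subset).
#' @param n_clones Clones per genotype per site sampled for RNA.
#' @param module_factors Optional function(elev_scaled, species_index)
#'   returning the latent factor value per sample for a module; the default
#'   makes module 1 track elevation in both species and module 2 track
#'   elevation only in the second species.
#' @return A \code{count_matrix}: list with integer matrix \code{counts}
#'   (genes x samples), \code{meta} sample metadata and \code{lib_size}.
#' @export
simulate_counts <- function(design, n_genotypes = 12L, n_clones = 3L,
                            module_factors = NULL) {
  validate_design(design)
  if (design$n_genes <= 0) stop("n_genes must be positive")
  sites <- names(design$elevations)
  n_genotypes <- pmin(as.integer(n_genotypes), design$n_genotypes_per_species)
  meta <- list()
  for (si in seq_along(design$species)) {
    sp <- design$species[si]
    genos <- sprintf("%s_g%02d", abbreviate(sp, 4), seq_len(n_genotypes[min(si, length(n_genotypes))]))
    g <- expand.grid(clone_rep = seq_len(n_clones), genotype = genos,
                     site = sites, stringsAsFactors = FALSE)
    g$species <- sp
    meta[[si]] <- g
  }
  meta <- do.call(rbind, meta)
  meta$elevation <- unname(design$elevations[meta$site])
  meta$clone <- sprintf("%s.%s.c%d", meta$genotype, meta$site, meta$clone_rep)
  meta$sample <- sprintf("s%03d", seq_len(nrow(meta)))
  meta <- meta[, c("sample", "species", "genotype", "site", "elevation",
                   "clone")]
  ns <- nrow(meta)
  ng <- design$n_genes
  set.seed(substream_seed(design$seed, 37L))
  lib <- exp(stats::rnorm(ns, 0, design$library_size_sdlog))
  lib <- lib / mean(lib)
  base <- exp(stats::rnorm(ng, log(100), 1))
  elev_rng <- range(design$elevations)
  x <- if (diff(elev_rng) > 0)
    (meta$elevation - elev_rng[1]) / diff(elev_rng) else rep(0, ns)
  is_b <- as.numeric(meta$species == design$species[min(2, length(design$species))])
  if (is.null(module_factors))
    module_factors <- function(xs, spb, module) {
      if (module == 2) xs * spb else xs
    }
  # per-sample latent factor value for each module
  mods <- sort(unique(design$module_assignments[design$module_assignments > 0]))
  fac <- sapply(mods, function(m) module_factors(x, is_b, m))
  if (length(mods)) fac <- matrix(fac, nrow = ns)
  geno_key <- interaction(meta$genotype, drop = TRUE)
  geno_dev <- matrix(stats::rnorm(ng * nlevels(geno_key), 0,
                                  sqrt(design$var_genotype_expr)),
                     nrow = ng)
  eta <- matrix(0, ng, ns)  # log2 scale
  for (s in seq_len(ns)) {
    e <- design$lfc_species * is_b[s] + design$lfc_site * x[s] +
      design$lfc_interaction * is_b[s] * x[s] +
      geno_dev[, as.integer(geno_key)[s]]
    ma <- design$module_assignments
    if (length(mods)) {
      mi <- match(ma, mods)
      has <- !is.na(mi)
      e[has] <- e[has] + design$module_factor_loadings[has] * fac[s, mi[has]]
    }
    eta[, s] <- e
  }
  mu <- sweep(base * 2^eta, 2, lib, `*`)
  counts <- matrix(stats::rnbinom(ng * ns, mu = mu,
                                  size = rep(1 / design$dispersion, ns)),
                   nrow = ng)
  dimnames(counts) <- list(sprintf("gene%04d", seq_len(ng)), meta$sample)
  structure(list(counts = counts, meta = meta, lib_size = lib),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(unique(x$meta$species), collapse = ", ")))
  invisible(x)
}

#' Design with two species' plasticity directions planted at a known angle
#'
#' Builds a \code{sim_design} whose species-by-site trait means place the
#' two species' multivariate plasticity vectors (native minus novel, on
#' the mean-standardised scale) at exactly \code{theta_deg} degrees in the
#' plane of the first two traits, with deviations centred across sites so
#' mean standardisation leaves the planted directions untouched. Used to
#' check end-to-end recovery of a known inter-species plasticity angle.
#'
#' @param theta_deg Planted angle between the plasticity vectors, degrees.
#' @param n_genotypes Genotypes per species.
#' @param effect_scale Relative trait change across the elevation range
#'   (1 = twofold variation, comparable to leaf-trait reaction norms).
#' @param var_genotype_by_site,var_block,var_residual Variance components;
#'   defaults are small so the Monte-Carlo angle error stays well below a
#'   degree at the default genotype count.
#' @param seed Master seed.
#' @return A \code{sim_design}; the native sites are the attribute
#'   \code{"native_sites"} (species A native low, species B native high).
#' @export
planted_angle_design <- function(theta_deg = 60, n_genotypes = 40,
                                 effect_scale = 1,
                                 var_genotype_by_site = 0.005,
                                 var_block = 0.002, var_residual = 0.01,
                                 seed = 1L) {
  th <- theta_deg * pi / 180
  u <- c(1, 0, 0, 0)
  v <- c(cos(th), sin(th), 0, 0)
  sites <- c(low = 500, mid1 = 1000, mid2 = 1500, high = 2000)
  grad <- seq(0, 1, length.out = 4) - 0.5  # centred: grand mean unchanged
  base <- c(10, 8, 6, 4)
  tm <- lapply(1:4, function(k) {
    m <- rbind(base[k] * (1 - effect_scale * u[k] * grad),
               base[k] * (1 + effect_scale * v[k] * grad))
    dimnames(m) <- list(c("A", "B"), names(sites))
    m
  })
  names(tm) <- paste0("t", 1:4)
  d <- simulation_design(species = c("A", "B"), elevations = sites,
                         n_genotypes_per_species = c(n_genotypes, n_genotypes),
                         trait_means = tm,
                         var_genotype_by_site = var_genotype_by_site,
                         var_block = var_block, var_residual = var_residual,
                         seed = seed)
  attr(d, "native_sites") <- c(A = "low", B = "high")
  attr(d, "theta_deg") <- theta_deg
  d
}
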