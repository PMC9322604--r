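# Trait derivation and univariate reaction-norm analyses.

#' Derive leaf traits from raw leaf measurements
#'
#' Computes margin complexity (perimeter^2 / area, dimensionless), indent
#' density (indentations per mm of perimeter) and specific leaf area
#' (area per unit dry mass, mm^2/mg). All arguments are vectorised.
#'
#' @param area Leaf area, mm^2 (> 0).
#' @param perimeter Leaf perimeter, mm (> 0).
#' @param n_indents Number of margin indentations (>= 0).
#' @param dry_weight Leaf dry weight, mg (> 0).
#' @return A data frame with columns complexity, indent_density, sla.
#' @examples
#' derive_leaf_traits(area = 300, perimeter = 80, n_indents = 12,
#'                    dry_weight = 15)
#' @export
derive_leaf_traits <- function(area, perimeter, n_indents, dry_weight) {
  for (fld in c("area", "perimeter", "dry_weight")) {
    v <- get(fld)
    if (any(!is.finite(v)) || any(v <= 0))
      stop(sprintf("'%s' must be positive and finite", fld))
  }
  if (any(n_indents < 0)) stop("'n_indents' must be non-negative")
  data.frame(complexity = perimeter^2 / area,
             indent_density = n_indents / perimeter,
             sla = area / dry_weight)
}

#' Derive physiological traits from gas exchange and fluorometry
#'
#' Intrinsic water-use efficiency is the ratio of net photosynthesis to
#' stomatal conductance. The quantum-yield partition uses the standard
#' saturation-pulse decomposition: \eqn{Y(II) = (Fm' - F)/Fm'},
#' \eqn{Y(NO) = F/Fm} (relative to the dark-adapted maximum) and
#' \eqn{Y(NPQ) = F/Fm' - F/Fm}, so the three yields sum to one.
#'
#' @param A Net photosynthesis, umol CO2 m^-2 s^-1.
#' @param gs Stomatal conductance, mol m^-2 s^-1 (> 0).
#' @param F0 Dark-adapted minimal fluorescence.
#' @param Fm Dark-adapted maximal fluorescence (> F0).
#' @param Fs Steady-state fluorescence in the light.
#' @param Fm_prime Light-adapted maximal fluorescence (>= Fs, <= Fm).
#' @return A data frame with wue, y_ii, y_npq, y_no.
#' @export
derive_physiology <- function(A, gs, F0, Fm, Fs, Fm_prime) {
  if (any(gs <= 0)) stop("stomatal conductance must be > 0 for WUE")
  if (any(Fm <= F0)) stop("invalid fluorescence: Fm must exceed F0")
  if (any(Fm_prime > Fm) || any(Fs > Fm_prime))
    stop("invalid fluorescence: require Fs <= Fm' <= Fm")
  y_ii <- (Fm_prime - Fs) / Fm_prime
  y_no <- Fs / Fm
  y_npq <- Fs / Fm_prime - Fs / Fm
  data.frame(wue = A / gs, y_ii = y_ii, y_npq = y_npq, y_no = y_no)
}

#' Total performance index from a fast fluorescence induction curve
#'
#' The JIP-test performance index for energy conservation from photons
#' absorbed by PSII to the reduction of PSI end acceptors, computed as the
#' product of four flux-ratio factors:
#' \deqn{PI_{total} = \frac{RC}{ABS} \cdot
#'   \frac{\varphi_{P0}}{1 - \varphi_{P0}} \cdot
#'   \frac{\psi_{E0}}{1 - \psi_{E0}} \cdot
#'   \frac{\delta_{R0}}{1 - \delta_{R0}}}
#' with \eqn{\varphi_{P0} = 1 - F_0/F_m}, \eqn{V_J} and \eqn{V_I} the
#' relative variable fluorescence at the J and I steps,
#' \eqn{\psi_{E0} = 1 - V_J}, \eqn{\delta_{R0} = (1 - V_I)/(1 - V_J)},
#' \eqn{M_0 = 4 (F_{300\mu s} - F_0)/(F_m - F_0)} and
#' \eqn{RC/ABS = \varphi_{P0} \, V_J / M_0}.
#'
#' @param F0 Fluorescence at 20-50 us (origin).
#' @param F300 Fluorescence at 300 us.
#' @param FJ Fluorescence at 2 ms (J step).
#' @param FI Fluorescence at 30 ms (I step).
#' @param Fm Maximal fluorescence (> F0).
#' @return Numeric PI_total (dimensionless).
#' @export
pi_total <- function(F0, F300, FJ, FI, Fm) {
  if (any(Fm <= F0)) stop("invalid fluorescence: Fm must exceed F0")
  fv <- Fm - F0
  vj <- (FJ - F0) / fv
  vi <- (FI - F0) / fv
  m0 <- 4 * (F300 - F0) / fv
  phi_p0 <- 1 - F0 / Fm
  psi_e0 <- 1 - vj
  delta_r0 <- (1 - vi) / (1 - vj)
  rc_abs <- phi_p0 * vj / m0
  rc_abs * (phi_p0 / (1 - phi_p0)) * (psi_e0 / (1 - psi_e0)) *
    (delta_r0 / (1 - delta_r0))
}

#' Average trait observations to one value per clone, or per genotype
#'
#' Field analyses first average repeated leaf measurements within each
#' cutting (clone), then summarise clones to genotype means within each
#' site. Empty groups are dropped with a warning rather than an error.
#'
#' @param tab A \code{trait_table} in long format.
#' @return A \code{trait_table} aggregated to the requested level, with a
#'   column \code{n_obs} giving the group count.
#' @export
clone_means <- function(tab) {
  aggregate_trait_table(tab, c("species", "genotype", "site", "elevation",
                               "block", "clone"))
}

#' @rdname clone_means
#' @export
genotype_means <- function(tab) {
  aggregate_trait_table(tab, c("species", "genotype", "site", "elevation"))
}

aggregate_trait_table <- function(tab, keys) {
  check_trait_table(tab, require = c(keys, "trait", "value"))
  bad <- is.na(tab$value)
  if (any(bad)) {
    warning(sprintf("dropping %d missing trait observations", sum(bad)))
    tab <- tab[!bad, , drop = FALSE]
  }
  agg <- stats::aggregate(tab["value"], by = tab[c(keys, "trait")], FUN = mean)
  cnt <- stats::aggregate(list(n_obs = tab$value), by = tab[c(keys, "trait")],
                          FUN = length)
  res <- merge(agg, cnt, by = c(keys, "trait"), sort = TRUE)
  res <- res[order(res$trait, res$species, res$site, res$genotype), ]
  rownames(res) <- NULL
  class(res) <- c("trait_table", "data.frame")
  res
}

check_trait_table <- function(tab, require = c("species", "genotype", "site",
                                               "trait", "value")) {
  missing_cols <- setdiff(require, names(tab))
  if (length(missing_cols))
    stop("trait table is missing columns: ", paste(missing_cols, collapse = ", "))
  sp_per_geno <- tapply(tab$species, tab$genotype,
                        function(s) length(unique(s)))
  if (any(sp_per_geno > 1))
    stop("each genotype must belong to exactly one species")
  invisible(TRUE)
}

#' Fit the univariate reaction-norm mixed model for one trait
#'
#' Models the clone-mean trait value as species + site + species:site fixed
#' effects with genotype-by-site and block-within-site Gaussian random
#' intercepts (REML). The species-by-site interaction is tested by a
#' likelihood-ratio test between full and additive fixed structures refit
#' under full maximum likelihood, and the p value is multiplied by
#' \code{n_tests} (capped at 1) to correct across traits.
#'
#' @param tab A clone-mean \code{trait_table}.
#' @param trait Name of the trait to fit.
#' @param n_tests Number of traits tested in the family (Bonferroni-style
#'   multiplier).
#' @param fast If TRUE, skip derivative-based convergence checks (useful in
#'   large simulation loops).
#' @return An object of class \code{trait_fit}: fixed effects, variance
#'   components, interaction LRT (chisq, df, p, adj_p), convergence flags
#'   and the underlying REML fit.
#' @export
fit_trait_model <- function(tab, trait, n_tests = 1, fast = FALSE) {
  check_trait_table(tab)
  dat <- tab[tab$trait == trait, , drop = FALSE]
  if (!nrow(dat)) stop(sprintf("trait '%s' not present", trait))
  dat$species <- factor(dat$species)
  dat$site <- factor(dat$site)
  if (nlevels(dat$species) < 2 || nlevels(dat$site) < 2)
    stop("model needs at least two species and two sites; the design is singular otherwise")
  if (min(table(dat$species)) < 2)
    stop("each species needs at least two genotypes")
  dat$gxs <- interaction(dat$genotype, dat$site, drop = TRUE)
  dat$blk <- interaction(dat$site, dat$block, drop = TRUE)
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = !fast)
  fit_quiet <- function(formula, reml) {
    warn <- character()
    m <- withCallingHandlers(
      lme4::lmer(formula, data = dat, REML = reml, control = ctrl),
      warning = function(w) {
        warn <<- c(warn, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    list(model = m, warnings = warn)
  }
  full_reml <- fit_quiet(value ~ species * site + (1 | gxs) + (1 | blk), TRUE)
  full_ml <- fit_quiet(value ~ species * site + (1 | gxs) + (1 | blk), FALSE)
  red_ml <- fit_quiet(value ~ species + site + (1 | gxs) + (1 | blk), FALSE)
  lrt_chisq <- max(0, 2 * (as.numeric(stats::logLik(full_ml$model)) -
                           as.numeric(stats::logLik(red_ml$model))))
  lrt_df <- attr(stats::logLik(full_ml$model), "df") -
    attr(stats::logLik(red_ml$model), "df")
  p <- stats::pchisq(lrt_chisq, df = lrt_df, lower.tail = FALSE)
  vc <- as.data.frame(lme4::VarCorr(full_reml$model))
  vcomp <- stats::setNames(vc$vcov, vc$grp)
  names(vcomp)[names(vcomp) == "gxs"] <- "genotype_by_site"
  names(vcomp)[names(vcomp) == "blk"] <- "block_within_site"
  names(vcomp)[names(vcomp) == "Residual"] <- "residual"
  structure(list(
    trait = trait,
    fixed = lme4::fixef(full_reml$model),
    varcomp = vcomp,
    lrt = list(chisq = lrt_chisq, df = lrt_df, p = p,
               adj_p = adjust_p(p, n_tests)),
    n_tests = n_tests,
    converged = !length(c(full_reml$warnings, full_ml$warnings,
                          red_ml$warnings)),
    warnings = unique(c(full_reml$warnings, full_ml$warnings,
                        red_ml$warnings)),
    model = full_reml$model
  ), class = "trait_fit")
}

#' @export
print.trait_fit <- function(x, ...) {
  cat(sprintf("Reaction-norm fit for '%s'\n", x$trait))
  cat(sprintf("  species x site LRT: chisq(%d) = %.3f, p = %.3g, adj. p = %.3g\n",
              x$lrt$df, x$lrt$chisq, x$lrt$p, x$lrt$adj_p))
  cat("  variance components:\n")
  for (nm in names(x$varcomp))
    cat(sprintf("    %-18s %.4g\n", nm, x$varcomp[nm]))
  if (!x$converged) cat("  NOTE: fit raised warnings; inspect $warnings\n")
  invisible(x)
}

# Bonferroni-style multiply-by-n rule, capped at 1.
adjust_p <- function(p, n_tests) pmin(1, p * n_tests)

#' Pairwise site contrasts within each species, with letter groupings
#'
#' Tests all within-species site pairs on estimated marginal means of the
#' fitted reaction-norm model, adjusts p values across the pairs, and
#' assigns compact letters so that sites sharing a letter are not
#' significantly different. Sites are processed in ascending elevation; a
#' site joins the first existing letter group with which it has no
#' significant contrast.
#'
#' @param fit A \code{trait_fit}.
#' @param alpha Significance level for the letter grouping.
#' @param adjust Multiplicity adjustment passed to \code{emmeans}
#'   (default "bonferroni", matching the multiply-by-n convention).
#' @return A list with \code{contrasts} (one row per species and site
#'   pair) and \code{letters} (one row per species and site).
#' @export
pairwise_site_tests <- function(fit, alpha = 0.05, adjust = "bonferroni") {
  stopifnot(inherits(fit, "trait_fit"))
  emm <- emmeans::emmeans(fit$model, ~ site | species,
                          lmer.df = "asymptotic")
  prs <- summary(emmeans::contrast(emm, method = "pairwise", adjust = adjust))
  contrasts <- as.data.frame(prs)
  site_levels <- levels(fit$model@frame$site)
  letters_tab <- do.call(rbind, lapply(split(contrasts, contrasts$species),
    function(cc) {
      pm <- pair_p_matrix(cc, site_levels)
      data.frame(species = cc$species[1], site = site_levels,
                 letters = assign_letters(pm, alpha),
                 stringsAsFactors = FALSE)
    }))
  rownames(letters_tab) <- NULL
  list(contrasts = contrasts, letters = letters_tab)
}

pair_p_matrix <- function(cc, site_levels) {
  k <- length(site_levels)
  pm <- matrix(1, k, k, dimnames = list(site_levels, site_levels))
  halves <- strsplit(as.character(cc$contrast), " - ", fixed = TRUE)
  for (i in seq_len(nrow(cc))) {
    a <- halves[[i]][1]; b <- halves[[i]][2]
    pm[a, b] <- pm[b, a] <- cc$p.value[i]
  }
  pm
}

# Greedy insert: sites in level (elevation) order join the first group with
# which all pairwise contrasts are non-significant.
assign_letters <- function(p_matrix, alpha) {
  sites <- rownames(p_matrix)
  groups <- list()
  for (s in sites) {
    placed <- FALSE
    for (gi in seq_along(groups)) {
      if (all(p_matrix[s, groups[[gi]]] >= alpha)) {
        groups[[gi]] <- c(groups[[gi]], s)
        placed <- TRUE
      }
    }
    if (!placed) groups[[length(groups) + 1L]] <- s
  }
  out <- stats::setNames(rep("", length(sites)), sites)
  for (gi in seq_along(groups))
    for (s in groups[[gi]]) out[s] <- paste0(out[s], letters[gi])
  out
}

#' Two-sample species comparison with unequal-variance t test
#'
#' Welch's t test between species for one trait, with the family-wise
#' multiply-by-n p-value adjustment.
#'
#' @param tab A \code{trait_table}.
#' @param trait Trait name.
#' @param n_tests Number of traits in the testing family.
#' @return A list with t, df, p, adj_p and the group means.
#' @export
species_comparison_test <- function(tab, trait, n_tests = 1) {
  check_trait_table(tab, require = c("species", "trait", "value"))
  dat <- tab[tab$trait == trait, , drop = FALSE]
  sp <- unique(dat$species)
  if (length(sp) != 2) stop("exactly two species required")
  x <- dat$value[dat$species == sp[1]]
  y <- dat$value[dat$species == sp[2]]
  if (length(x) < 2 || length(y) < 2)
    stop("each species needs at least two observations")
  if (stats::sd(x) == 0 && stats::sd(y) == 0 && mean(x) == mean(y)) {
    tt <- list(statistic = c(t = 0), parameter = c(df = length(x) + length(y) - 2),
               p.value = 1)
  } else {
    tt <- stats::t.test(x, y, var.equal = FALSE)
  }
  list(trait = trait, t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, adj_p = adjust_p(tt$p.value, n_tests),
       means = stats::setNames(c(mean(x), mean(y)), sp))
}

#' Classical multidimensional scaling of soil (or other site) profiles
#'
#' Torgerson MDS of a distance matrix, or of Euclidean distances between
#' standardised variables when a raw sample x variable table is supplied.
#' Axes are ordered by eigenvalue; each axis is reflected so that its
#' largest-magnitude coordinate is positive.
#'
#' @param x A symmetric distance matrix / \code{dist}, or a numeric data
#'   frame of raw variables (rows = samples).
#' @param k Number of axes to return.
#' @return A list with \code{points} (samples x k), \code{eig} and
#'   \code{prop} (share of positive eigenvalue mass per returned axis).
#' @export
soil_mds <- function(x, k = 2) {
  if (inherits(x, "dist")) {
    d <- x
  } else if (is.matrix(x) && nrow(x) == ncol(x) &&
             all(abs(x - t(x)) < 1e-8)) {
    if (any(x < 0)) stop("distances must be non-negative")
    d <- stats::as.dist(x)
  } else if (is.matrix(x) && nrow(x) == ncol(x)) {
    stop("distance matrix must be symmetric")
  } else {
    num <- as.matrix(as.data.frame(x))
    sds <- apply(num, 2, stats::sd)
    num <- scale(num, center = TRUE, scale = ifelse(sds > 0, sds, 1))
    d <- stats::dist(num)
  }
  fit <- suppressWarnings(stats::cmdscale(d, k = k, eig = TRUE))
  pts <- fit$points
  if (is.null(pts) || ncol(pts) < k) {  # degenerate (e.g. all-zero distances)
    pts2 <- matrix(0, attr(d, "Size"), k)
    if (!is.null(pts) && ncol(pts) > 0) pts2[, seq_len(ncol(pts))] <- pts
    pts <- pts2
  }
  for (j in seq_len(ncol(pts))) {
    i <- which.max(abs(pts[, j]))
    if (length(i) && pts[i, j] < 0) pts[, j] <- -pts[, j]
  }
  pos <- sum(pmax(fit$eig, 0))
  prop <- if (pos > 0) pmax(fit$eig[seq_len(k)], 0) / pos else rep(NA_real_, k)
  colnames(pts) <- paste0("MDS", seq_len(ncol(pts)))
  list(points = pts, eig = fit$eig, prop = prop)
}
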