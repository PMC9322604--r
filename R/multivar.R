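# Multivariate geometry of plasticity and divergence: mean standardisation,
# MANOVA on the genotype-within-cell stratum, the D matrix, and plasticity /
# divergence vectors compared by angles.

#' Mean-standardise a genotype-mean trait table
#'
#' Divides every value of each trait by that trait's grand mean over all
#' species, sites and genotypes, making traits dimensionless with grand
#' mean one so that they are comparable in a joint analysis.
#'
#' @param tab A genotype-mean \code{trait_table}.
#' @return The standardised table, with the per-trait grand means attached
#'   as attribute \code{"grand_means"}.
#' @export
mean_standardize <- function(tab) {
  check_trait_table(tab, require = c("species", "genotype", "site", "trait",
                                     "value"))
  gm <- c(tapply(tab$value, tab$trait, mean))  # drop the 1-d array dim
  zero <- names(gm)[abs(gm) < .Machine$double.eps^.5]
  if (length(zero))
    stop("cannot mean-standardise trait(s) with zero grand mean: ",
         paste(zero, collapse = ", "))
  tab$value <- as.numeric(tab$value / gm[as.character(tab$trait)])
  attr(tab, "grand_means") <- gm
  tab
}

#' Collapse a genotype-mean table to species-by-site cell means
#'
#' @param tab A (typically mean-standardised) genotype-mean
#'   \code{trait_table}.
#' @return A \code{group_mean_set}: list with \code{means} (cells x traits
#'   matrix, rownames "species|site"), \code{cells} (species, site,
#'   elevation, n genotypes) and \code{traits}.
#' @export
group_means <- function(tab) {
  check_trait_table(tab)
  traits <- sort(unique(tab$trait))
  key <- interaction(tab$species, tab$site, sep = "|", drop = TRUE)
  cells <- unique(data.frame(cell = as.character(key), species = tab$species,
                             site = tab$site,
                             elevation = if ("elevation" %in% names(tab))
                               tab$elevation else NA_real_,
                             stringsAsFactors = FALSE))
  # keep species in order of appearance (design order), sites by elevation
  cells <- cells[order(match(cells$species, unique(tab$species)),
                       cells$elevation, cells$site), ]
  m <- matrix(NA_real_, nrow(cells), length(traits),
              dimnames = list(cells$cell, traits))
  n <- integer(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    sub <- tab[as.character(key) == cells$cell[i], ]
    n[i] <- length(unique(sub$genotype))
    mu <- tapply(sub$value, sub$trait, mean)
    if (!all(traits %in% names(mu)))
      stop(sprintf("cell %s is missing traits: %s", cells$cell[i],
                   paste(setdiff(traits, names(mu)), collapse = ", ")))
    m[i, ] <- mu[traits]
  }
  cells$n <- n
  rownames(cells) <- NULL
  structure(list(means = m, cells = cells, traits = traits),
            class = "group_mean_set")
}

#' @export
print.group_mean_set <- function(x, ...) {
  cat(sprintf("group_mean_set: %d cells x %d traits\n", nrow(x$means),
              length(x$traits)))
  print(round(x$means, 4))
  invisible(x)
}

#' MANOVA with the genotype-within-cell error stratum
#'
#' Tests a multivariate effect (species, site, or their interaction) on the
#' genotype-mean trait matrix, using the variation among genotype-by-site
#' units within species-by-site cells as the error SSCP -- the denominator
#' that asks whether cell differences exceed differences among genotypes.
#' Wilks' lambda is det(E)/det(H+E) with H obtained as the difference in
#' residual SSCP between nested mean models (type-II style: main effects
#' are tested against the additive model); significance uses Rao's F
#' approximation.
#'
#' @param tab A mean-standardised genotype-mean \code{trait_table}.
#' @param effect One of "species:site", "species", "site".
#' @return A \code{manova_result}: list with lambda, F, df1, df2, p,
#'   effect, and the H and E matrices.
#' @export
manova_wilks <- function(tab, effect = c("species:site", "species", "site")) {
  effect <- match.arg(effect)
  check_trait_table(tab)
  wide <- trait_table_wide(tab)
  Y <- wide$Y
  f_species <- factor(wide$units$species)
  f_site <- factor(wide$units$site)
  if (nlevels(f_species) < 2 || nlevels(f_site) < 2)
    stop("need at least two species and two sites")
  n <- nrow(Y); p <- ncol(Y)
  rss <- function(formula_rhs) {
    X <- stats::model.matrix(formula_rhs, data.frame(species = f_species,
                                                     site = f_site))
    crossprod(stats::lm.fit(X, Y)$residuals)
  }
  E <- rss(~ species * site)
  full_rank <- qr(stats::model.matrix(~ species * site,
                                      data.frame(species = f_species,
                                                 site = f_site)))$rank
  v <- n - full_rank
  if (v < p)
    stop("singular error SSCP: fewer genotype-by-site units than traits; reduce the trait set")
  H <- switch(effect,
    "species:site" = rss(~ species + site) - E,
    "species" = rss(~ site) - rss(~ species + site),
    "site" = rss(~ species) - rss(~ species + site))
  q <- switch(effect,
    "species:site" = (nlevels(f_species) - 1) * (nlevels(f_site) - 1),
    "species" = nlevels(f_species) - 1,
    "site" = nlevels(f_site) - 1)
  lambda <- det(E) / det(E + H)
  if (!is.finite(lambda))
    stop("singular error SSCP: reduce the trait set")
  ft <- rao_f(lambda, p, q, v)
  structure(list(effect = effect, lambda = lambda, F = ft$F, df1 = ft$df1,
                 df2 = ft$df2, p = ft$p, H = H, E = E, error_df = v,
                 error_stratum = "genotype-by-site units within cells"),
            class = "manova_result")
}

#' @export
print.manova_result <- function(x, ...) {
  cat(sprintf("MANOVA (%s), error = %s\n", x$effect, x$error_stratum))
  cat(sprintf("  Wilks' lambda = %.4f, F(%.0f, %.1f) = %.3f, p = %.3g\n",
              x$lambda, x$df1, x$df2, x$F, x$p))
  invisible(x)
}

# Rao's F approximation for Wilks' lambda with p variables, q hypothesis df
# and v error df.
rao_f <- function(lambda, p, q, v) {
  s <- if (p^2 + q^2 - 5 > 0) sqrt((p^2 * q^2 - 4) / (p^2 + q^2 - 5)) else 1
  m <- v - (p - q + 1) / 2
  df1 <- p * q
  df2 <- m * s - (p * q) / 2 + 1
  lam_s <- lambda^(1 / s)
  Fstat <- (1 - lam_s) / lam_s * df2 / df1
  list(F = Fstat, df1 = df1, df2 = df2,
       p = stats::pf(Fstat, df1, df2, lower.tail = FALSE))
}

# one row per genotype-by-site unit, one column per trait
trait_table_wide <- function(tab) {
  traits <- sort(unique(tab$trait))
  key <- interaction(tab$species, tab$site, tab$genotype, sep = "\r",
                     drop = TRUE)
  units <- unique(data.frame(key = as.character(key), species = tab$species,
                             site = tab$site, genotype = tab$genotype,
                             stringsAsFactors = FALSE))
  Y <- matrix(NA_real_, nrow(units), length(traits),
              dimnames = list(NULL, traits))
  for (j in seq_along(traits)) {
    sub <- tab[tab$trait == traits[j], ]
    mu <- tapply(sub$value, interaction(sub$species, sub$site, sub$genotype,
                                        sep = "\r", drop = TRUE), mean)
    Y[, j] <- mu[units$key]
  }
  if (anyNA(Y)) stop("every genotype-by-site unit needs every trait")
  list(Y = Y, units = units)
}

#' Among-group divergence (D) matrix and its eigenaxes
#'
#' The D matrix is the covariance of the species-by-site cell mean vectors
#' (cells equally weighted by default; set \code{weighted = TRUE} to weight
#' cells by genotype count). Its leading eigenvectors d_max, d_2, ... are
#' the main axes of multivariate divergence; cell means are projected onto
#' them as scores. Eigenvectors are unit length, ordered by descending
#' eigenvalue, and reflected so each axis' largest-magnitude trait loading
#' is positive.
#'
#' @param g A \code{group_mean_set}.
#' @param weighted Weight cells by genotype count instead of equally.
#' @return A \code{dmatrix_result}: D, eigenvalues, loadings (traits x
#'   axes), proportion of variance per axis, and cell scores.
#' @export
compute_D <- function(g, weighted = FALSE) {
  stopifnot(inherits(g, "group_mean_set"))
  M <- g$means
  if (nrow(M) < 2) stop("need at least two cells to define divergence")
  if (weighted) {
    cw <- stats::cov.wt(M, wt = g$cells$n / sum(g$cells$n),
                        method = "unbiased")
    D <- cw$cov
    center <- cw$center
  } else {
    D <- stats::cov(M)
    center <- colMeans(M)
  }
  ev <- eigen(D, symmetric = TRUE)
  vals <- pmax(ev$values, 0)
  vecs <- ev$vectors
  for (j in seq_len(ncol(vecs))) {
    i <- which.max(abs(vecs[, j]))
    if (vecs[i, j] < 0) vecs[, j] <- -vecs[, j]
  }
  dimnames(vecs) <- list(g$traits, paste0("d_", c("max", seq_len(ncol(vecs) - 1) + 1)))
  tr <- sum(vals)
  if (tr <= .Machine$double.eps * nrow(D)) {
    warning("all cell means are equal: D is the zero matrix, proportions undefined")
    prop <- numeric(0)
  } else {
    prop <- vals / tr
  }
  scores <- sweep(M, 2, center) %*% vecs
  structure(list(D = D, eigenvalues = vals, loadings = vecs,
                 proportion = prop, scores = scores, center = center,
                 weighted = weighted),
            class = "dmatrix_result")
}

#' @export
print.dmatrix_result <- function(x, ...) {
  cat(sprintf("D matrix over %d traits (%s cells)\n", nrow(x$D),
              if (x$weighted) "genotype-weighted" else "equally weighted"))
  if (length(x$proportion))
    cat(sprintf("  %% divergence: %s\n",
                paste(sprintf("%s %.1f%%", colnames(x$loadings),
                              100 * x$proportion), collapse = ", ")))
  invisible(x)
}

fetch_cell <- function(g, species, site) {
  i <- which(g$cells$species == species & g$cells$site == site)
  if (length(i) != 1)
    stop(sprintf("no unique cell for species '%s' at site '%s'", species, site))
  g$means[i, ]
}

make_vector <- function(raw, species, from, to, type) {
  mag <- sqrt(sum(raw^2))
  if (mag < .Machine$double.eps^0.5)
    stop("zero difference vector: direction undefined")
  structure(list(species = species, from = from, to = to, raw = raw,
                 unit = raw / mag, magnitude = mag, type = type),
            class = "phenotype_vector")
}

#' @export
print.phenotype_vector <- function(x, ...) {
  cat(sprintf("%s vector [%s]: %s -> %s, |v| = %.4f\n", x$type,
              paste(x$species, collapse = " vs "), x$from, x$to, x$magnitude))
  print(round(x$unit, 4))
  invisible(x)
}

#' Multivariate plasticity vector for one species
#'
#' The change in mean-standardised multivariate phenotype between two sites
#' for one species, reported as the raw difference (native minus novel, the
#' home-to-away reaction read from the native end), its unit vector and
#' its magnitude.
#'
#' @param g A \code{group_mean_set}.
#' @param species Focal species.
#' @param native_site,novel_site Site labels of the native and novel cells.
#' @return A \code{phenotype_vector}.
#' @export
plasticity_vector <- function(g, species, native_site, novel_site) {
  raw <- fetch_cell(g, species, native_site) - fetch_cell(g, species, novel_site)
  make_vector(raw, species, native_site, novel_site, "plasticity")
}

#' Between-species divergence vector at the native sites
#'
#' Difference between the two species' multivariate phenotypes in their own
#' native habitats (species A at its native site minus species B at its
#' native site).
#'
#' @param g A \code{group_mean_set}.
#' @param species_a,species_b The two species.
#' @param native_a,native_b Their native sites.
#' @return A \code{phenotype_vector}.
#' @export
divergence_vector <- function(g, species_a, native_a, species_b, native_b) {
  raw <- fetch_cell(g, species_a, native_a) - fetch_cell(g, species_b, native_b)
  make_vector(raw, c(species_a, species_b), native_a, native_b, "divergence")
}

#' Angle between two multivariate vectors, in degrees
#'
#' @param a,b \code{phenotype_vector} objects or non-zero numeric vectors.
#' @return Angle in degrees, in \eqn{[0, 180]}.
#' @export
vector_angle <- function(a, b) {
  ua <- unit_of(a); ub <- unit_of(b)
  if (length(ua) != length(ub)) stop("vectors must have equal length")
  acos(max(-1, min(1, sum(ua * ub)))) * 180 / pi
}

unit_of <- function(v) {
  if (inherits(v, "phenotype_vector")) return(v$unit)
  v <- as.numeric(v)
  n <- sqrt(sum(v^2))
  if (n < .Machine$double.eps^0.5) stop("zero vector has no direction")
  v / n
}

#' Adaptive-alignment report for a two-species transplant
#'
#' Computes (i) the angle between the two species' plasticity vectors
#' (each taken native minus novel, the shared orientation of the
#' reaction-norm difference) and (ii), per species, the angle between its
#' plasticity read from home toward the novel extreme (novel minus native)
#' and the divergence vector pointing from its own native phenotype toward
#' the other species' native phenotype. Plasticity is called "aligned"
#' (putatively adaptive) when that angle is below \code{threshold}.
#'
#' @param g A \code{group_mean_set} containing both species at both native
#'   sites.
#' @param native_sites Named character vector mapping each species to its
#'   native site; defaults to the lowest-elevation cell for the first
#'   species and the highest for the second.
#' @param threshold Alignment flag threshold, degrees.
#' @return A data frame with one row per comparison: comparison, species,
#'   angle_deg, aligned.
#' @export
adaptive_alignment <- function(g, native_sites = NULL, threshold = 45) {
  stopifnot(inherits(g, "group_mean_set"))
  sp <- unique(g$cells$species)
  if (length(sp) != 2) stop("adaptive alignment needs exactly two species")
  if (is.null(native_sites)) {
    ord <- order(g$cells$elevation)
    lo <- g$cells$site[ord[1]]; hi <- g$cells$site[ord[length(ord)]]
    native_sites <- stats::setNames(c(lo, hi), sp)
  }
  if (!all(sp %in% names(native_sites)))
    stop("native_sites must name every species")
  nat <- native_sites[sp]
  # Eq-style plasticity (native - novel) for the species-vs-species angle
  pl <- lapply(seq_along(sp), function(i) {
    plasticity_vector(g, sp[i], nat[i], nat[-i][1])
  })
  between <- vector_angle(pl[[1]], pl[[2]])
  rows <- data.frame(comparison = "plasticity_between_species",
                     species = paste(sp, collapse = " vs "),
                     angle_deg = between, aligned = NA,
                     stringsAsFactors = FALSE)
  for (i in seq_along(sp)) {
    other <- sp[-i][1]
    # home-to-away plasticity vs divergence toward the resident's phenotype
    toward_novel <- fetch_cell(g, sp[i], nat[other]) - fetch_cell(g, sp[i], nat[i])
    toward_other <- fetch_cell(g, other, nat[other]) - fetch_cell(g, sp[i], nat[i])
    ang <- vector_angle(toward_novel, toward_other)
    rows <- rbind(rows, data.frame(
      comparison = "plasticity_vs_divergence", species = sp[i],
      angle_deg = ang, aligned = ang < threshold, stringsAsFactors = FALSE))
  }
  rownames(rows) <- NULL
  rows
}
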