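# Expression-plasticity layer: count filtering with the within-species
# rescue rule, negative-binomial Wald contrasts against each species' home
# site, set overlaps, reaction-norm quadrant classification, simplified
# coexpression modules with eigengene-elevation tests, and Fisher GO
# enrichment.

check_count_matrix <- function(cm) {
  if (!inherits(cm, "count_matrix"))
    stop("expected a count_matrix (see read_counts()/simulate_counts())")
  if (any(cm$counts < 0) || any(cm$counts != round(cm$counts)))
    stop("counts must be non-negative integers")
  if (!all(colnames(cm$counts) == cm$meta$sample))
    stop("metadata must cover every sample, in column order")
  invisible(TRUE)
}

#' Low-count filter with the within-species rescue rule
#'
#' A gene is discarded when at least \code{min_fraction} of all samples
#' have counts below \code{min_count} -- unless more than
#' \code{rescue_fraction} of those low-count samples belong to a single
#' species, in which case the gene is retained (it may simply be silent in
#' one species while informative in the other).
#'
#' @param cm A \code{count_matrix} with two species in the metadata.
#' @param min_count Count threshold defining a "low" sample.
#' @param min_fraction Fraction of low samples at which a gene becomes a
#'   discard candidate.
#' @param rescue_fraction Share of the low samples that must fall in one
#'   species (strictly greater) for the candidate to be rescued.
#' @return The filtered \code{count_matrix}; the per-gene decision log
#'   (gene, frac_low, max_species_share, decision) is attached as
#'   attribute \code{"filter_log"}.
#' @export
filter_counts <- function(cm, min_count = 5, min_fraction = 0.5,
                          rescue_fraction = 0.75) {
  check_count_matrix(cm)
  for (nm in c("min_fraction", "rescue_fraction")) {
    v <- get(nm)
    if (!is.finite(v) || v <= 0 || v > 1)
      stop(sprintf("'%s' must lie in (0, 1]", nm))
  }
  sp <- cm$meta$species
  if (length(unique(sp)) < 2)
    stop("rescue rule needs two species in the metadata")
  low <- cm$counts < min_count
  frac_low <- rowMeans(low)
  max_share <- apply(low, 1, function(l) {
    if (!any(l)) return(0)
    max(table(sp[l])) / sum(l)
  })
  candidate <- frac_low >= min_fraction
  rescued <- candidate & max_share > rescue_fraction
  keep <- !candidate | rescued
  log <- data.frame(gene = rownames(cm$counts), frac_low = frac_low,
                    max_species_share = max_share,
                    decision = ifelse(!candidate, "retained",
                                      ifelse(rescued, "rescued", "discarded")),
                    stringsAsFactors = FALSE)
  rownames(log) <- NULL
  out <- cm
  out$counts <- cm$counts[keep, , drop = FALSE]
  attr(out, "filter_log") <- log
  out
}

#' Median-of-ratios size factors and log2 normalised counts
#'
#' Size factors are per-sample medians of count ratios against the
#' geometric-mean reference gene profile (genes with a zero anywhere are
#' excluded from the reference). When no gene is expressed in every sample
#' the function falls back to library-size factors with a warning.
#'
#' @param cm A \code{count_matrix}.
#' @return A list with \code{size_factors} (geometric mean 1),
#'   \code{log_expr} (log2(count/sf + 0.5), genes x samples) and the
#'   original \code{meta}.
#' @export
normalize_counts <- function(cm) {
  check_count_matrix(cm)
  if (any(colSums(cm$counts) == 0)) stop("all-zero sample in count matrix")
  allpos <- rowSums(cm$counts == 0) == 0
  if (any(allpos)) {
    ref <- exp(rowMeans(log(cm$counts[allpos, , drop = FALSE])))
    sf <- apply(cm$counts[allpos, , drop = FALSE], 2,
                function(col) stats::median(col / ref))
  } else {
    warning("no gene expressed in every sample; using library-size factors")
    sf <- colSums(cm$counts)
  }
  sf <- sf / exp(mean(log(sf)))
  log_expr <- log2(sweep(cm$counts, 2, sf, `/`) + 0.5)
  list(size_factors = sf, log_expr = log_expr, meta = cm$meta)
}

# Method-of-moments NB dispersion from counts scaled to common depth.
# Within each replicate group, E[sum (z - zbar)^2] = (n-1)(mu + alpha mu^2),
# so alpha = sum_g [SS_g - (n_g - 1) m_g] / sum_g (n_g - 1) m_g^2.
mom_dispersion <- function(y, group, sf, floor = 1e-4, ceiling = 20) {
  z <- y / sf
  num <- 0; den <- 0
  for (g in unique(group)) {
    zi <- z[group == g]
    if (length(zi) < 2) next
    m <- mean(zi)
    num <- num + sum((zi - m)^2) - (length(zi) - 1) * m
    den <- den + (length(zi) - 1) * m^2
  }
  if (den <= 0) return(floor)
  min(ceiling, max(floor, num / den))
}

#' Per-gene negative-binomial Wald contrasts
#'
#' Fits, gene by gene, a negative-binomial log-linear model of the count
#' design (species, transplant site, their interaction, and genotype as a
#' fixed covariate factor) restricted to the samples the contrast needs,
#' and tests the contrast coefficient by a Wald z test. Dispersion is
#' estimated per gene by method of moments (floored at 1e-4) and held
#' fixed during the fit; no shrinkage across genes is applied. Two
#' contrast types are supported:
#' \describe{
#'   \item{site_vs_home}{within one species, each site against that
#'     species' home site (genotype in the model);}
#'   \item{species_at_site}{between species at one site (genotype is
#'     nested in species and therefore omitted).}
#' }
#'
#' @param cm A (filtered) \code{count_matrix}.
#' @param type Contrast type.
#' @param species Focal species (site_vs_home).
#' @param site Site to contrast.
#' @param home_site Reference (home) site of the focal species.
#' @param alpha Adjusted-p significance threshold.
#' @return A \code{de_result} data frame: gene, contrast, lfc (log2),
#'   se, p, padj (Benjamini-Hochberg), sig, untestable.
#' @export
de_test <- function(cm, type = c("site_vs_home", "species_at_site"),
                    species = NULL, site = NULL, home_site = NULL,
                    alpha = 0.01) {
  type <- match.arg(type)
  check_count_matrix(cm)
  meta <- cm$meta
  if (type == "site_vs_home") {
    if (is.null(species) || is.null(site) || is.null(home_site))
      stop("site_vs_home needs species, site and home_site")
    idx <- meta$species == species & meta$site %in% c(home_site, site)
    sub <- meta[idx, , drop = FALSE]
    fac <- factor(sub$site, levels = c(home_site, site))
    covar <- factor(sub$genotype)
    label <- sprintf("%s: %s vs home (%s)", species, site, home_site)
  } else {
    if (is.null(site)) stop("species_at_site needs site")
    idx <- meta$site == site
    sub <- meta[idx, , drop = FALSE]
    fac <- factor(sub$species)
    covar <- NULL
    label <- sprintf("species at %s", site)
  }
  if (min(table(fac)) < 2) stop("need at least two replicates per group")
  counts <- cm$counts[, idx, drop = FALSE]
  sf <- normalize_counts(list_as_count_matrix(counts, sub))$size_factors
  X <- if (is.null(covar) || nlevels(droplevels(covar)) < 2)
    stats::model.matrix(~fac) else stats::model.matrix(~ fac + covar)
  res <- t(vapply(seq_len(nrow(counts)), function(g) {
    nb_wald_one(counts[g, ], fac, X, sf)
  }, numeric(3)))
  out <- data.frame(gene = rownames(counts), contrast = label,
                    lfc = res[, 1], se = res[, 2], p = res[, 3],
                    stringsAsFactors = FALSE)
  out$untestable <- is.na(out$p)
  out$padj <- NA_real_
  ok <- !out$untestable
  out$padj[ok] <- bh_adjust(out$p[ok])
  out$sig <- !is.na(out$padj) & out$padj < alpha
  rownames(out) <- NULL
  class(out) <- c("de_result", "data.frame")
  out
}

list_as_count_matrix <- function(counts, meta) {
  structure(list(counts = counts, meta = meta), class = "count_matrix")
}

nb_wald_one <- function(y, fac, X, sf) {
  if (all(y == 0)) return(c(NA_real_, NA_real_, NA_real_))
  disp <- mom_dispersion(y, fac, sf)
  fit <- tryCatch(
    suppressWarnings(stats::glm.fit(
      X, y, family = MASS::negative.binomial(theta = 1 / disp),
      offset = log(sf))),
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged && fit$iter >= 25)
    return(c(NA_real_, NA_real_, NA_real_))
  co <- fit$coefficients[2]  # contrast level vs reference
  # dispersion-fixed GLM covariance
  w <- fit$weights
  XtWX <- crossprod(X * sqrt(w))
  vc <- tryCatch(solve(XtWX), error = function(e) NULL)
  if (is.null(vc)) return(c(NA_real_, NA_real_, NA_real_))
  se <- sqrt(vc[2, 2])
  z <- co / se
  # t reference with residual df: the plug-in dispersion is estimated from
  # few replicates, so the normal reference is anticonservative
  df <- max(1, length(y) - ncol(X))
  c(co / log(2), se / log(2), 2 * stats::pt(-abs(z), df = df))
}

#' Benjamini-Hochberg step-up adjusted p values
#'
#' @param p Numeric vector of p values in \eqn{[0, 1]}.
#' @return Adjusted p values (monotone, capped at 1).
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Overlap tables for collections of differentially expressed gene sets
#'
#' Computes, for named gene sets over one gene universe, the per-set sizes,
#' the intersection over all sets, and the exclusive (upset-style) counts
#' of every non-empty membership pattern.
#'
#' @param sets Named list of character vectors of gene ids.
#' @param universe Character vector containing every gene in every set.
#' @return A list with \code{sizes}, \code{common} (genes in every set)
#'   and \code{exclusive} (data frame: pattern, count, genes).
#' @export
contrast_sets <- function(sets, universe) {
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop("sets must be named")
  for (nm in names(sets))
    if (!all(sets[[nm]] %in% universe))
      stop(sprintf("set '%s' contains genes outside the universe", nm))
  members <- unique(unlist(sets))
  mm <- vapply(sets, function(s) members %in% s, logical(length(members)))
  mm <- matrix(mm, nrow = length(members),
               dimnames = list(members, names(sets)))
  pattern <- apply(mm, 1, function(r) paste(names(sets)[r], collapse = "&"))
  excl <- lapply(split(members, pattern), sort)
  exclusive <- data.frame(pattern = names(excl),
                          count = vapply(excl, length, integer(1)),
                          stringsAsFactors = FALSE)
  exclusive$genes <- unname(excl)
  exclusive <- exclusive[order(-exclusive$count), ]
  rownames(exclusive) <- NULL
  list(sizes = vapply(sets, length, integer(1)),
       common = sort(Reduce(intersect, sets)),
       exclusive = exclusive)
}

#' Classify reaction-norm direction and magnitude across two species
#'
#' Given each gene's log2 fold change across the elevational extremes in
#' species A and in species B (with significance calls), assigns exactly
#' one category: \code{opposite-direction} (both significant, opposite
#' signs), \code{magnitude-divergent} (both significant, same sign, |lfc
#' difference| > \code{magnitude_delta}), \code{shared-same-direction}
#' (both significant, same sign, similar magnitude), \code{A-specific} /
#' \code{B-specific} (only one significant), or \code{unchanged}.
#'
#' @param lfc_a,lfc_b Log2 fold changes in the two species.
#' @param sig_a,sig_b Logical significance flags.
#' @param magnitude_delta Threshold (log2 units) separating shared from
#'   magnitude-divergent responses.
#' @return Factor of categories, one per gene.
#' @export
quadrant_classify <- function(lfc_a, sig_a, lfc_b, sig_b,
                              magnitude_delta = 1) {
  stopifnot(length(lfc_a) == length(lfc_b),
            length(sig_a) == length(lfc_a),
            length(sig_b) == length(lfc_a))
  if (any(!is.finite(lfc_a)) || any(!is.finite(lfc_b)))
    stop("log fold changes must be finite")
  lv <- c("shared-same-direction", "magnitude-divergent",
          "opposite-direction", "A-specific", "B-specific", "unchanged")
  out <- rep("unchanged", length(lfc_a))
  both <- sig_a & sig_b
  out[both & sign(lfc_a) != sign(lfc_b)] <- "opposite-direction"
  same <- both & sign(lfc_a) == sign(lfc_b)
  out[same & abs(lfc_a - lfc_b) > magnitude_delta] <- "magnitude-divergent"
  out[same & abs(lfc_a - lfc_b) <= magnitude_delta] <- "shared-same-direction"
  out[sig_a & !sig_b] <- "A-specific"
  out[!sig_a & sig_b] <- "B-specific"
  factor(out, levels = lv)
}

#' Detect coexpression modules by correlation clustering
#'
#' Average-linkage hierarchical clustering of gene expression profiles on
#' the distance 1 - |Pearson correlation|, cut at a fixed height; clusters
#' below the minimum size join the unassigned pool. This is a deliberately
#' simple stand-in for full weighted-network module detection; the
#' eigengene layer downstream follows the usual definitions exactly.
#'
#' @param log_expr Genes x samples matrix of normalised log expression.
#' @param cut_height Tree cut height on the 1 - |r| scale.
#' @param min_size Minimum module size.
#' @return A data frame gene/module ("M1", "M2", ... by decreasing size;
#'   NA = unassigned). Constant genes are excluded with a warning.
#' @export
detect_modules <- function(log_expr, cut_height = 0.5, min_size = 10) {
  if (ncol(log_expr) < 3) stop("need at least three samples")
  sds <- apply(log_expr, 1, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("excluding %d constant-expression gene(s)", sum(sds == 0)))
    log_expr <- log_expr[sds > 0, , drop = FALSE]
  }
  cc <- abs(stats::cor(t(log_expr)))
  hc <- stats::hclust(stats::as.dist(1 - cc), method = "average")
  cl <- stats::cutree(hc, h = cut_height)
  tab <- table(cl)
  big <- names(tab)[tab >= min_size]
  big <- big[order(-tab[big])]
  module <- rep(NA_character_, length(cl))
  for (i in seq_along(big)) module[cl == big[i]] <- paste0("M", i)
  data.frame(gene = rownames(log_expr), module = module,
             stringsAsFactors = FALSE)
}

#' Module eigengene and its correlation with elevation
#'
#' The eigengene is the first principal component of the standardised
#' expression of the module's member genes: one score per sample, scaled
#' to unit variance and oriented to correlate positively with the mean
#' member profile. Its Pearson correlation with transplant elevation is
#' tested within each species.
#'
#' @param log_expr Genes x samples matrix of normalised log expression.
#' @param genes Member genes of the module.
#' @param meta Sample metadata with species and elevation.
#' @return A \code{module_result}: eigengene scores, explained variance
#'   share, and per-species correlation with elevation (r, p).
#' @export
module_eigengene <- function(log_expr, genes, meta) {
  if (length(genes) < 2) stop("module must have at least two genes")
  X <- log_expr[genes, , drop = FALSE]
  sds <- apply(X, 1, stats::sd)
  if (any(sds == 0)) stop("module contains zero-variance gene(s)")
  Xs <- (X - rowMeans(X)) / sds
  sv <- svd(t(Xs))  # samples x genes
  eg <- sv$u[, 1]
  eg <- eg / stats::sd(eg)
  if (stats::cor(eg, colMeans(Xs)) < 0) eg <- -eg
  varexpl <- sv$d[1]^2 / sum(sv$d^2)
  cors <- do.call(rbind, lapply(split(seq_len(nrow(meta)), meta$species),
    function(i) {
      ct <- stats::cor.test(eg[i], meta$elevation[i])
      data.frame(species = meta$species[i[1]], r = unname(ct$estimate),
                 p = ct$p.value, stringsAsFactors = FALSE)
    }))
  rownames(cors) <- NULL
  structure(list(genes = genes, eigengene = stats::setNames(eg, meta$sample),
                 var_explained = varexpl, elevation_cor = cors),
            class = "module_result")
}

#' @export
print.module_result <- function(x, ...) {
  cat(sprintf("module of %d genes; eigengene explains %.1f%% of member variance\n",
              length(x$genes), 100 * x$var_explained))
  print(x$elevation_cor)
  invisible(x)
}

#' Fisher exact GO-term enrichment
#'
#' One-sided (greater) Fisher exact test per term of the 2x2 table
#' (DE-and-term, DE-not-term, term-not-DE, neither) against the gene
#' universe. Terms are taken from a two-column gene-to-term map; genes
#' without terms are allowed.
#'
#' @param de_genes Character vector of differentially expressed genes
#'   (subset of \code{universe}).
#' @param universe Character vector of all tested genes.
#' @param term_map Data frame with columns \code{gene} and \code{term}.
#' @param alpha Significance threshold for the reported flag.
#' @return Data frame: term, n_term, overlap, expected, fold_enrichment,
#'   p, sig; ordered by p.
#' @export
go_enrichment <- function(de_genes, universe, term_map, alpha = 0.05) {
  if (!length(universe)) stop("empty gene universe")
  if (!all(de_genes %in% universe))
    stop("de_genes must be a subset of the universe")
  if (!all(c("gene", "term") %in% names(term_map)))
    stop("term_map needs columns 'gene' and 'term'")
  term_map <- term_map[term_map$gene %in% universe, , drop = FALSE]
  N <- length(universe)
  nde <- length(de_genes)
  rows <- lapply(split(term_map$gene, term_map$term), function(g) {
    g <- unique(g)
    a <- sum(g %in% de_genes)
    tbl <- matrix(c(a, nde - a, length(g) - a, N - nde - length(g) + a), 2)
    p <- stats::fisher.test(tbl, alternative = "greater")$p.value
    expected <- nde * length(g) / N
    data.frame(n_term = length(g), overlap = a, expected = expected,
               fold_enrichment = if (expected > 0) a / expected else NA_real_,
               p = p)
  })
  out <- do.call(rbind, rows)
  out <- data.frame(term = names(rows), out, sig = out$p < alpha,
                    stringsAsFactors = FALSE)
  out <- out[order(out$p, out$term), ]
  rownames(out) <- NULL
  out
}
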