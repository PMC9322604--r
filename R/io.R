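# Readers, writers and the end-to-end pipeline driver.

#' Read and write the long-format trait table
#'
#' CSV schema: species, genotype, site, block, clone, trait, value, plus an
#' optional numeric elevation column (derived from the site label when that
#' label is numeric). Malformed rows are reported with their line numbers.
#'
#' @param path CSV file path.
#' @return A \code{trait_table}.
#' @export
read_trait_table <- function(path) {
  if (!file.exists(path)) stop("trait table not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "genotype", "site", "block", "clone", "trait", "value")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("trait CSV must have columns ", paste(need, collapse = ", "),
         "; missing: ", paste(miss, collapse = ", "))
  bad <- which(!is.finite(tab$value))
  if (length(bad))
    stop("non-numeric trait values at line(s) ",
         paste(utils::head(bad + 1L, 10), collapse = ", "))
  if (!"elevation" %in% names(tab)) {
    ele <- suppressWarnings(as.numeric(tab$site))
    tab$elevation <- ele
  }
  check_trait_table(tab)
  class(tab) <- c("trait_table", "data.frame")
  tab
}

#' @rdname read_trait_table
#' @param tab Table to write.
#' @export
write_trait_table <- function(tab, path) {
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE)
  invisible(path)
}

#' Read and write per-plant survival records
#'
#' CSV schema: plant_id, species, genotype, site, block, time, event, plus
#' optional elevation.
#'
#' @param path CSV file path.
#' @return A \code{survival_table}.
#' @export
read_survival <- function(path) {
  if (!file.exists(path)) stop("survival table not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "genotype", "site", "time", "event")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("survival CSV missing columns: ", paste(miss, collapse = ", "))
  bad <- which(!(tab$event %in% c(0, 1)) | !is.finite(tab$time) | tab$time <= 0)
  if (length(bad))
    stop("invalid time/event at line(s) ",
         paste(utils::head(bad + 1L, 10), collapse = ", "))
  class(tab) <- c("survival_table", "data.frame")
  tab
}

#' @rdname read_survival
#' @param tab Table to write.
#' @export
write_survival <- function(tab, path) {
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE)
  invisible(path)
}

#' Read a gene x sample count matrix with sample metadata
#'
#' Dense form: a TSV whose first column holds gene ids and whose remaining
#' columns are samples. Sparse form: a MatrixMarket file plus plain-text
#' gene and sample lists (one id per line). Metadata is a CSV with columns
#' sample, species, site, elevation, genotype (clone optional), covering
#' every sample.
#'
#' @param path Dense TSV path, or MTX path when \code{genes_path} and
#'   \code{samples_path} are given.
#' @param meta_path Sample metadata CSV path.
#' @param genes_path,samples_path Row/column id files for the MTX triplet.
#' @return A \code{count_matrix}.
#' @export
read_counts <- function(path, meta_path, genes_path = NULL,
                        samples_path = NULL) {
  if (!is.null(genes_path)) {
    m <- as.matrix(Matrix::readMM(path))
    rownames(m) <- readLines(genes_path)
    colnames(m) <- readLines(samples_path)
  } else {
    tab <- utils::read.delim(path, check.names = FALSE,
                             stringsAsFactors = FALSE)
    m <- as.matrix(tab[, -1, drop = FALSE])
    rownames(m) <- tab[[1]]
  }
  bad <- which(m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad))
    stop("counts must be non-negative integers; first offence at data line ",
         bad[1, 1] + 1L, " (gene ", rownames(m)[bad[1, 1]], ")")
  storage.mode(m) <- "integer"
  meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
  need <- c("sample", "species", "site", "elevation", "genotype")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop("sample metadata missing columns: ", paste(miss, collapse = ", "))
  if (!all(colnames(m) %in% meta$sample))
    stop("metadata must cover every sample in the count matrix")
  meta <- meta[match(colnames(m), meta$sample), , drop = FALSE]
  rownames(meta) <- NULL
  structure(list(counts = m, meta = meta, lib_size = colSums(m)),
            class = "count_matrix")
}

#' @rdname read_counts
#' @param cm Count matrix to write (dense TSV + metadata CSV).
#' @export
write_counts <- function(cm, path, meta_path) {
  check_count_matrix(cm)
  tab <- data.frame(gene = rownames(cm$counts), cm$counts,
                    check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.csv(cm$meta, meta_path, row.names = FALSE)
  invisible(path)
}

#' Configure the end-to-end pipeline
#'
#' Collects thresholds, native-site assignments and either a synthetic
#' design or input file paths for a full run.
#'
#' @param design A \code{sim_design} for a synthetic run, or NULL to read
#'   the three input files.
#' @param trait_path,survival_path,counts_path,counts_meta_path Input
#'   paths (ignored when \code{design} is given).
#' @param native_sites Named character vector species -> native site label;
#'   default: lowest-elevation site for the first species, highest for the
#'   second.
#' @param traits Traits to fit univariately (default: all present).
#' @param alpha Significance level for trait LRTs and pairwise tests.
#' @param de_alpha Adjusted-p threshold for differential expression.
#' @param magnitude_delta Log2 threshold for magnitude-divergent calls.
#' @param filter_min_count,filter_min_fraction,filter_rescue_fraction
#'   Low-count filter parameters.
#' @param module_cut_height,module_min_size Module detection parameters.
#' @param shock_window_days Transplant-shock pre-filter for survival.
#' @param follow_up_days Synthetic survival follow-up.
#' @param seed Seed for every stochastic step of the run.
#' @param out_dir Output directory (NULL = no files written).
#' @return A \code{pipeline_config}.
#' @export
pipeline_config <- function(design = NULL, trait_path = NULL,
                            survival_path = NULL, counts_path = NULL,
                            counts_meta_path = NULL, native_sites = NULL,
                            traits = NULL, alpha = 0.05, de_alpha = 0.01,
                            magnitude_delta = 1, filter_min_count = 5,
                            filter_min_fraction = 0.5,
                            filter_rescue_fraction = 0.75,
                            module_cut_height = 0.5, module_min_size = 10,
                            shock_window_days = 3, follow_up_days = 150,
                            seed = 1L, out_dir = NULL) {
  if (is.null(design) && (is.null(trait_path) || is.null(survival_path)))
    stop("provide either a sim_design or input paths")
  for (nm in c("alpha", "de_alpha"))
    if (get(nm) <= 0 || get(nm) >= 1) stop(nm, " must lie in (0, 1)")
  structure(list(design = design, trait_path = trait_path,
                 survival_path = survival_path, counts_path = counts_path,
                 counts_meta_path = counts_meta_path,
                 native_sites = native_sites, traits = traits,
                 alpha = alpha, de_alpha = de_alpha,
                 magnitude_delta = magnitude_delta,
                 filter_min_count = filter_min_count,
                 filter_min_fraction = filter_min_fraction,
                 filter_rescue_fraction = filter_rescue_fraction,
                 module_cut_height = module_cut_height,
                 module_min_size = module_min_size,
                 shock_window_days = shock_window_days,
                 follow_up_days = follow_up_days,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full plasticity / divergence pipeline
#'
#' Stages, in dependency order: data acquisition (simulation or file
#' input), clone and genotype means, univariate reaction-norm fits with
#' interaction LRTs, mean standardisation, MANOVA, D-matrix eigenanalysis,
#' plasticity/divergence angles, transplant-shock filtering and the
#' survival interaction test, and the expression layer (filter, normalise,
#' home-versus-extreme contrasts per species, quadrant classification,
#' modules and eigengene-elevation correlations). A machine-readable
#' summary is returned and, when \code{out_dir} is set, written as JSON
#' alongside the stage CSVs.
#'
#' @param config A \code{pipeline_config}.
#' @return A summary list (invisibly returns stage objects as attribute
#'   \code{"stages"}).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  stage <- "input"
  res <- tryCatch({
    if (!is.null(config$design)) {
      traits_raw <- simulate_traits(config$design)
      surv <- simulate_survival(config$design, config$follow_up_days)
      cm <- simulate_counts(config$design)
    } else {
      traits_raw <- read_trait_table(config$trait_path)
      surv <- read_survival(config$survival_path)
      cm <- if (!is.null(config$counts_path))
        read_counts(config$counts_path, config$counts_meta_path) else NULL
    }

    stage <- "traits"
    cl <- clone_means(traits_raw)
    gm_tab <- genotype_means(traits_raw)
    trait_list <- config$traits
    if (is.null(trait_list)) trait_list <- sort(unique(cl$trait))
    fits <- lapply(trait_list, function(tr)
      fit_trait_model(cl, tr, n_tests = length(trait_list)))
    names(fits) <- trait_list
    trait_lrt <- data.frame(
      trait = trait_list,
      chisq = vapply(fits, function(f) f$lrt$chisq, numeric(1)),
      df = vapply(fits, function(f) f$lrt$df, numeric(1)),
      p = vapply(fits, function(f) f$lrt$p, numeric(1)),
      adj_p = vapply(fits, function(f) f$lrt$adj_p, numeric(1)),
      row.names = NULL)

    stage <- "multivar"
    std <- mean_standardize(gm_tab)
    gms <- group_means(std)
    manova <- manova_wilks(std, "species:site")
    dres <- compute_D(gms)
    # species order: design order when simulating (first species native to
    # the lowest site), otherwise order of appearance in the data
    sp <- if (!is.null(config$design)) config$design$species
          else unique(gms$cells$species)
    native <- config$native_sites
    if (is.null(native)) {
      ord <- order(gms$cells$elevation)
      native <- stats::setNames(c(gms$cells$site[ord[1]],
                                  gms$cells$site[ord[length(ord)]]), sp)
    }
    sp <- names(native)
    align <- adaptive_alignment(gms, native)

    stage <- "survival"
    surv_f <- filter_transplant_shock(surv, config$shock_window_days)
    km <- km_curve(surv_f)
    surv_test <- survival_interaction_test(surv_f, frailty = FALSE)

    stage <- "expression"
    expr <- NULL
    if (!is.null(cm)) {
      fcm <- filter_counts(cm, config$filter_min_count,
                           config$filter_min_fraction,
                           config$filter_rescue_fraction)
      norm <- normalize_counts(fcm)
      extremes <- stats::setNames(native[rev(seq_along(native))], names(native))
      de <- lapply(sp, function(s)
        de_test(fcm, "site_vs_home", species = s, site = extremes[s],
                home_site = native[s], alpha = config$de_alpha))
      names(de) <- sp
      quad <- quadrant_classify(de[[1]]$lfc, de[[1]]$sig,
                                de[[2]]$lfc, de[[2]]$sig,
                                config$magnitude_delta)
      mods <- detect_modules(norm$log_expr, config$module_cut_height,
                             config$module_min_size)
      mod_ids <- sort(unique(mods$module[!is.na(mods$module)]))
      eigs <- lapply(mod_ids, function(m)
        module_eigengene(norm$log_expr, mods$gene[!is.na(mods$module) &
                                                  mods$module == m],
                         norm$meta))
      names(eigs) <- mod_ids
      expr <- list(filtered = fcm, norm = norm, de = de, quadrants = quad,
                   modules = mods, eigengenes = eigs)
    }
    list(traits_raw = traits_raw, clone_means = cl, genotype_means = gm_tab,
         fits = fits, trait_lrt = trait_lrt, std = std, gms = gms,
         manova = manova, D = dres, align = align, km = km,
         surv_test = surv_test, expr = expr, native = native)
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })

  summary <- list(
    seed = config$seed,
    n_trait_observations = nrow(res$traits_raw),
    trait_lrt = res$trait_lrt,
    wilks_lambda = res$manova$lambda,
    manova_F = res$manova$F,
    manova_p = res$manova$p,
    d_max_proportion = if (length(res$D$proportion)) res$D$proportion[1] else NA,
    d2_proportion = if (length(res$D$proportion) > 1) res$D$proportion[2] else NA,
    angles = res$align,
    survival_interaction = res$surv_test[c("chisq", "df", "p")])
  if (!is.null(res$expr)) {
    summary$n_genes_kept <- nrow(res$expr$filtered$counts)
    summary$n_de <- vapply(res$expr$de, function(d) sum(d$sig), integer(1))
    summary$quadrant_counts <- as.list(table(res$expr$quadrants))
    summary$n_modules <- length(res$expr$eigengenes)
    summary$eigengene_elevation_cor <- lapply(res$expr$eigengenes,
                                              function(e) e$elevation_cor)
  }
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    o <- function(f) file.path(config$out_dir, f)
    write_trait_table(res$genotype_means, o("genotype_means.csv"))
    utils::write.csv(res$trait_lrt, o("trait_lrt.csv"), row.names = FALSE)
    utils::write.csv(data.frame(trait = rownames(res$D$loadings),
                                res$D$loadings, check.names = FALSE),
                     o("d_loadings.csv"), row.names = FALSE)
    utils::write.csv(res$align, o("angles.csv"), row.names = FALSE)
    utils::write.csv(res$km, o("km_curves.csv"), row.names = FALSE)
    jsonlite::write_json(summary, o("summary.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, force = TRUE)
  }
  attr(summary, "stages") <- res
  invisible(summary)
}
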