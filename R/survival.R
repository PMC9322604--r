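# Survival analysis of transplanted cuttings: Kaplan-Meier curves and the
# proportional-hazards species-by-elevation interaction test.

check_survival_table <- function(records) {
  need <- c("species", "genotype", "site", "time", "event")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("survival table is missing columns: ", paste(miss, collapse = ", "))
  if (any(records$time <= 0)) stop("all times must be positive")
  if (!all(records$event %in% c(0, 1))) stop("event must be 0 or 1")
  invisible(TRUE)
}

#' Remove transplant-shock deaths
#'
#' Cuttings that die within the first days after transplanting reflect
#' handling shock rather than site suitability; this pre-filter drops
#' records with an event at or before the shock window.
#'
#' @param records A \code{survival_table}.
#' @param window_days Length of the shock window (days).
#' @return The filtered table; the number removed is attached as attribute
#'   \code{"n_removed"}.
#' @export
filter_transplant_shock <- function(records, window_days = 3) {
  check_survival_table(records)
  drop <- records$event == 1 & records$time <= window_days
  out <- records[!drop, , drop = FALSE]
  attr(out, "n_removed") <- sum(drop)
  out
}

#' Kaplan-Meier survival curves by group
#'
#' Product-limit estimate with Greenwood variance and log-log confidence
#' bands, per level of the grouping variable(s). A fully censored group
#' yields a flat curve at one.
#'
#' @param records A \code{survival_table}.
#' @param group Character vector of metadata columns to stratify by
#'   (default species and site).
#' @param conf_level Confidence level of the band.
#' @return A data frame with columns group, time, n_risk, n_event, surv,
#'   lower, upper.
#' @export
km_curve <- function(records, group = c("species", "site"),
                     conf_level = 0.95) {
  check_survival_table(records)
  g <- interaction(records[group], sep = "|", drop = TRUE)
  fit <- survival::survfit(survival::Surv(records$time, records$event) ~ g,
                           conf.type = "log-log", conf.int = conf_level)
  s <- summary(fit, censored = TRUE)
  grp <- if (is.null(s$strata)) rep(levels(g)[1], length(s$time))
         else sub("^g=", "", as.character(s$strata))
  data.frame(group = grp, time = s$time, n_risk = s$n.risk,
             n_event = s$n.event, surv = s$surv,
             lower = ifelse(is.na(s$lower) & s$surv == 1, 1, s$lower),
             upper = ifelse(is.na(s$upper) & s$surv == 1, 1, s$upper),
             stringsAsFactors = FALSE)
}

#' Proportional-hazards fit with species-by-site interaction
#'
#' Cox partial-likelihood fit of species, site and their interaction, with
#' Breslow tie handling by default. The genotype random effect is modelled
#' as a gamma frailty; the block effect, when requested, enters as a fixed
#' factor adjustment (a documented approximation of a second random term).
#' If the frailty fit fails the function falls back to the fixed-effects
#' model and records a note.
#'
#' @param records A \code{survival_table}.
#' @param interaction Include the species-by-site interaction (drop for the
#'   reduced model of the likelihood-ratio test).
#' @param frailty Model genotype as a gamma frailty.
#' @param block Adjust for experimental block (fixed factor).
#' @param ties "breslow" (default) or "efron".
#' @return A \code{cox_fit}: coefficients, se, loglik (null, fitted),
#'   n_events, frailty variance if any, convergence flag and notes.
#' @export
cox_fit <- function(records, interaction = TRUE, frailty = TRUE,
                    block = FALSE, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  check_survival_table(records)
  if (sum(records$event) < 2) stop("need at least two events")
  dat <- as.data.frame(records)
  dat$species <- factor(dat$species)
  dat$site <- factor(dat$site)
  dat$genotype <- factor(dat$genotype)
  # drop degenerate factors (e.g. a single-site subset) from the design
  terms_fixed <- c(if (nlevels(dat$species) > 1) "species",
                   if (nlevels(dat$site) > 1) "site")
  if (!length(terms_fixed)) stop("no non-constant fixed factor to fit")
  rhs <- paste(terms_fixed, collapse = " + ")
  if (interaction && length(terms_fixed) == 2)
    rhs <- "species * site"
  if (block) {
    dat$blk <- interaction(dat$site, dat$block, drop = TRUE)
    rhs <- paste(rhs, "+ blk")
  }
  notes <- character()
  build <- function(with_frailty) {
    # frailty() must appear unprefixed for coxph's special-term detection
    f <- stats::as.formula(paste(
      "survival::Surv(time, event) ~", rhs,
      if (with_frailty) "+ frailty(genotype, distribution = 'gamma')" else ""),
      env = environment())
    survival::coxph(f, data = dat, ties = ties, model = TRUE)
  }
  fit <- NULL
  used_frailty <- frailty
  if (frailty) {
    fit <- tryCatch(suppressWarnings(build(TRUE)), error = function(e) NULL)
    if (is.null(fit)) {
      notes <- c(notes, "frailty fit failed; fell back to fixed-effects Cox model")
      used_frailty <- FALSE
    }
  }
  if (is.null(fit)) fit <- suppressWarnings(build(FALSE))
  co <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))[seq_along(co)]
  mono <- any(abs(co) > 15, na.rm = TRUE)
  if (mono)
    notes <- c(notes,
               "possible monotone likelihood (complete separation); coefficients unreliable")
  fr_var <- if (used_frailty && !is.null(fit$history))
    fit$history[[1]]$theta else NA_real_
  structure(list(
    coefficients = co, se = se,
    loglik = fit$loglik, n = fit$n, n_events = fit$nevent,
    interaction = interaction, frailty = used_frailty,
    frailty_variance = fr_var, ties = ties,
    n_fixed_coef = length(co), converged = !mono, notes = notes,
    model = fit
  ), class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox PH fit (%s ties%s): %d subjects, %d events\n", x$ties,
              if (x$frailty) ", gamma genotype frailty" else "", x$n,
              x$n_events))
  print(round(cbind(coef = x$coefficients, `exp(coef)` = exp(x$coefficients),
                    se = x$se), 4))
  for (nt in x$notes) cat("  NOTE:", nt, "\n")
  invisible(x)
}

#' Likelihood-ratio test between nested Cox fits
#'
#' Twice the difference in maximised partial log-likelihood, referred to a
#' chi-square with degrees of freedom equal to the number of fixed
#' coefficients dropped.
#'
#' @param full,reduced \code{cox_fit} objects; \code{reduced} must be
#'   nested in \code{full} (same data, fewer fixed terms).
#' @return A list with chisq, df, p.
#' @export
interaction_lrt <- function(full, reduced) {
  stopifnot(inherits(full, "cox_fit"), inherits(reduced, "cox_fit"))
  if (full$n != reduced$n || full$n_events != reduced$n_events)
    stop("fits are not on the same data")
  nm_red <- names(reduced$coefficients)
  if (!all(nm_red %in% names(full$coefficients)))
    stop("models are not nested: reduced has terms absent from full")
  df <- full$n_fixed_coef - reduced$n_fixed_coef
  if (df < 0) stop("models are not nested: reduced has more parameters")
  chisq <- max(0, 2 * (full$loglik[2] - reduced$loglik[2]))
  p <- if (df == 0) 1 else stats::pchisq(chisq, df, lower.tail = FALSE)
  list(chisq = chisq, df = df, p = p)
}

#' Species-by-elevation interaction test for survival
#'
#' Convenience wrapper fitting the full and additive proportional-hazards
#' models and returning their likelihood-ratio comparison -- the adaptive
#' divergence test: does relative survival of the two species change
#' across elevation?
#'
#' @param records A \code{survival_table}.
#' @param shock_window_days Drop deaths within this many days of
#'   transplant before fitting (0 disables).
#' @param ... Passed to \code{\link{cox_fit}}.
#' @return A list with the LRT (chisq, df, p) and both fits.
#' @export
survival_interaction_test <- function(records, shock_window_days = 0, ...) {
  if (shock_window_days > 0)
    records <- filter_transplant_shock(records, shock_window_days)
  full <- cox_fit(records, interaction = TRUE, ...)
  reduced <- cox_fit(records, interaction = FALSE, ...)
  c(interaction_lrt(full, reduced), list(full = full, reduced = reduced))
}
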