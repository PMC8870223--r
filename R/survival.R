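#' Top-quartile expression split
#'
#' Sorts patients by descending expression and labels the top
#' ceiling(q * n) as `top25`, the rest as `rest`.  Ties at the boundary
#' are broken by patient id, so the split is deterministic; an all-equal
#' expression vector triggers a warning.
#'
#' @param cohort data.frame with columns `patient`, `expression`, `time`,
#'   `event`.
#' @param q quantile fraction in the top group (default 0.25).
#' @return factor of labels (`top25`, `rest`) aligned to `cohort` rows.
#' @export
top_quartile_split <- function(cohort, q = 0.25) {
  n <- nrow(cohort)
  if (n < 8) stopf("cohort too small for a quartile split (n = %d < 8)", n)
  if (length(unique(cohort$expression)) == 1)
    warnf("all expression values equal; top-quartile split is id-order only")
  k <- ceiling(q * n)
  ord <- order(-cohort$expression, cohort$patient)
  lab <- rep("rest", n)
  lab[ord[seq_len(k)]] <- "top25"
  factor(lab, levels = c("rest", "top25"))
}

#' Kaplan-Meier product-limit curve
#'
#' Thin wrapper over `survival::survfit` returning the stepwise estimate
#' as a data.frame.  Censored times do not drop the curve.
#'
#' @param cohort data.frame with `time`, `event` (1 = death, 0 =
#'   censored).
#' @return data.frame: `time`, `n_risk`, `n_event`, `surv`.
#' @export
km_curve <- function(cohort) {
  check_cohort(cohort)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = cohort)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             surv = fit$surv)
}

#' Log-rank test between two survival groups
#'
#' Standard observed-minus-expected log-rank over the pooled event times
#' (hypergeometric variance, no continuity correction), chi-square with
#' one degree of freedom.
#'
#' @param cohort data.frame with `time`, `event`.
#' @param group two-level factor aligned to `cohort` rows.
#' @return list: `chisq`, `pvalue`, `obs`, `exp` (per-group observed and
#'   expected event counts).
#' @export
logrank_test <- function(cohort, group) {
  check_cohort(cohort)
  group <- factor(group)
  if (nlevels(group) != 2) stopf("log-rank needs exactly two groups")
  if (sum(cohort$event) == 0)
    stopf("degenerate input: no events observed in either group")
  sd <- survival::survdiff(survival::Surv(cohort$time, cohort$event) ~ group)
  list(chisq = unname(sd$chisq),
       pvalue = pchisq(sd$chisq, df = 1, lower.tail = FALSE),
       obs = sd$obs, exp = sd$exp)
}

#' Cox proportional-hazards ratio for a binary grouping
#'
#' Single binary covariate Cox model (partial likelihood, Breslow tie
#' handling by default) with the Wald confidence interval.  When one
#' group's events all precede the other's first event the partial
#' likelihood is monotone and the hazard ratio diverges; the fit is then
#' flagged `monotone = TRUE` and the HR reported as +/-Inf.
#'
#' @param cohort data.frame with `time`, `event`.
#' @param group two-level factor; the hazard ratio is for the second
#'   level relative to the first.
#' @param ties tie handling, `"breslow"` (default) or `"efron"`.
#' @param conf confidence level for the Wald interval (default 0.95).
#' @return list: `hr`, `beta`, `se`, `ci` (length 2), `pvalue`,
#'   `monotone`.
#' @export
cox_hr_binary <- function(cohort, group, ties = c("breslow", "efron"),
                          conf = 0.95) {
  check_cohort(cohort)
  ties <- match.arg(ties)
  group <- factor(group)
  if (nlevels(group) != 2) stopf("Cox grouping must have two levels")
  ev <- tapply(cohort$event, group, sum)
  if (any(ev == 0))
    stopf("both groups need >= 1 event (got %s)", paste(ev, collapse = ", "))
  fit <- tryCatch(
    survival::coxph(survival::Surv(cohort$time, cohort$event) ~ group,
                    ties = ties),
    warning = function(w) {
      f <- suppressWarnings(
        survival::coxph(survival::Surv(cohort$time, cohort$event) ~ group,
                        ties = ties))
      attr(f, "monotone") <- grepl("infinite", conditionMessage(w))
      f
    })
  beta <- unname(fit$coefficients)
  se <- sqrt(unname(fit$var[1, 1]))
  monotone <- isTRUE(attr(fit, "monotone")) || abs(beta) > 15
  if (monotone) {
    warnf("monotone partial likelihood: hazard ratio unbounded")
    hr <- if (beta > 0) Inf else 0
    return(list(hr = hr, beta = beta, se = se, ci = c(NA, NA),
                pvalue = NA_real_, monotone = TRUE))
  }
  z <- qnorm(1 - (1 - conf) / 2)
  list(hr = exp(beta), beta = beta, se = se,
       ci = exp(beta + c(-z, z) * se),
       pvalue = 2 * pnorm(-abs(beta / se)),
       monotone = FALSE)
}

check_cohort <- function(cohort) {
  need <- c("time", "event")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) stopf("cohort lacks column(s): %s", paste(miss, collapse = ", "))
  if (nrow(cohort) == 0) stopf("empty cohort")
  if (any(cohort$time <= 0)) stopf("survival times must be positive")
  if (!all(cohort$event %in% c(0, 1))) stopf("event must be 0 or 1")
  invisible(cohort)
}

#' Multi-cohort unfavorable-marker decision
#'
#' A cohort "supports" a gene iff the top-quartile split gives log-rank
#' p < `alpha` and Cox hazard ratio > `min_hr`; the gene is an
#' unfavorable prognostic marker iff the primary cohort supports it and
#' at least one other cohort does too.
#'
#' @param per_cohort data.frame with one row per cohort: `cohort`,
#'   `pvalue`, `hr`.
#' @param primary id of the primary cohort.
#' @param alpha log-rank significance cutoff (default 0.05).
#' @param min_hr hazard-ratio floor (default 1).
#' @return list: `marker` (logical), `support` (named logical per
#'   cohort).
#' @export
marker_call <- function(per_cohort, primary, alpha = 0.05, min_hr = 1) {
  if (!primary %in% per_cohort$cohort)
    stopf("primary cohort '%s' missing from results", primary)
  support <- with(per_cohort,
                  !is.na(pvalue) & !is.na(hr) & pvalue < alpha & hr > min_hr)
  names(support) <- per_cohort$cohort
  marker <- support[[primary]] && any(support[names(support) != primary])
  list(marker = marker, support = support)
}

#' Survival-based marker screen over genes and cohorts
#'
#' For every gene and cohort: top-quartile split, log-rank p, Cox HR;
#' then the multi-cohort [marker_call()].  Cohorts where a gene's split
#' leaves a group without events are treated as non-supporting.
#'
#' @param cohorts named list of cohort tables, each a data.frame with
#'   `patient`, `time`, `event` and one expression column per gene.
#' @param genes gene ids to screen (default: all shared expression
#'   columns).
#' @param primary name of the primary cohort (default: first).
#' @param alpha,min_hr support thresholds (defaults 0.05 and 1).
#' @param q top-group fraction (default 0.25).
#' @return data.frame: one row per gene x cohort with `gene`, `cohort`,
#'   `pvalue`, `hr`, `support`, plus an aggregate `marker` flag repeated
#'   per gene.
#' @export
survival_screen <- function(cohorts, genes = NULL, primary = names(cohorts)[1],
                            alpha = 0.05, min_hr = 1, q = 0.25) {
  if (is.null(names(cohorts))) stopf("cohorts must be a named list")
  if (!primary %in% names(cohorts)) stopf("primary cohort '%s' absent", primary)
  meta <- c("patient", "time", "event")
  if (is.null(genes))
    genes <- Reduce(intersect, lapply(cohorts, function(d) setdiff(names(d), meta)))
  rows <- list()
  for (g in genes) {
    per <- lapply(names(cohorts), function(cn) {
      d <- cohorts[[cn]]
      rec <- data.frame(patient = d$patient, expression = d[[g]],
                        time = d$time, event = d$event)
      grp <- suppressWarnings(top_quartile_split(rec, q))
      res <- tryCatch({
        lr <- suppressWarnings(logrank_test(rec, grp))
        cx <- suppressWarnings(cox_hr_binary(rec, grp))
        list(p = lr$pvalue, hr = cx$hr)
      }, error = function(e) list(p = NA_real_, hr = NA_real_))
      data.frame(gene = g, cohort = cn, pvalue = res$p, hr = res$hr,
                 stringsAsFactors = FALSE)
    })
    per <- do.call(rbind, per)
    mc <- marker_call(per, primary, alpha, min_hr)
    per$support <- unname(mc$support)
    per$marker <- mc$marker
    rows[[g]] <- per
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
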