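# Clinical characterization: CPI, composite survival endpoints,
# Kaplan-Meier / log-rank, Cox proportional-hazards models, and the
# baseline-characteristics comparison table.

#' Composite physiologic index (CPI)
#'
#' `CPI = 91.0 - 0.65 * DLco% - 0.53 * FVC% + 0.34 * FEV1%`. Higher values
#' indicate more severe functional impairment. Subjects with any missing
#' input get a missing CPI (they are excluded from adjusted models, with a
#' log line).
#'
#' @param fvc_pct,dlco_pct,fev1_pct lung function, % predicted.
#' @return Numeric vector of CPI values (NA where any input is missing).
#' @export
compute_cpi <- function(fvc_pct, dlco_pct, fev1_pct) {
  cpi <- 91.0 - 0.65 * dlco_pct - 0.53 * fvc_pct + 0.34 * fev1_pct
  n_missing <- sum(is.na(cpi))
  if (n_missing > 0)
    snf_log(n_missing, " subject(s) with missing CPI inputs; CPI left missing")
  cpi
}

# shared core: earliest of the candidate event times, else censoring
derive_outcome_core <- function(clinical, events, decline, endpoint) {
  stopifnot(all(events$subject %in% clinical$subject))
  events <- events[match(clinical$subject, events$subject), ]
  enroll <- as.Date(clinical$enrollment_date)
  tmonths <- function(d) days_to_months(as.Date(d) - enroll)
  cand <- cbind(fvc_decline = if (is.null(decline)) rep(NA_real_, nrow(clinical))
                              else decline,
                transplant = tmonths(events$transplant_date),
                death = tmonths(events$death_date))
  if (any(cand < 0, na.rm = TRUE))
    stop("event dated before enrollment")
  has_event <- rowSums(!is.na(cand)) > 0
  idx <- apply(cand, 1, function(r) if (all(is.na(r))) NA_integer_ else which.min(r))
  time <- ifelse(has_event,
                 cand[cbind(seq_len(nrow(cand)), ifelse(is.na(idx), 1L, idx))],
                 tmonths(events$last_followup_date))
  if (any(is.na(time)))
    stop("missing last follow-up date for censored subject(s)")
  if (any(time < 0)) stop("negative follow-up time")
  data.frame(subject = clinical$subject,
             endpoint = endpoint,
             time_months = as.numeric(time),
             event = has_event,
             event_type = ifelse(has_event, colnames(cand)[idx], "censored"),
             stringsAsFactors = FALSE)
}

#' Progression-free survival outcome
#'
#' Composite endpoint: first of (i) the first post-enrollment visit whose
#' FVC % predicted is >= 10 percentage points (absolute) below the
#' enrollment value, (ii) lung transplant, (iii) death. Subjects with no
#' event are censored at their last follow-up.
#'
#' @param clinical clinical table with `subject`, `fvc_pct`,
#'   `enrollment_date`.
#' @param fvc_long longitudinal table with `subject`, `visit_date`,
#'   `fvc_pct`.
#' @param events table with `subject`, `transplant_date`, `death_date`,
#'   `last_followup_date` (missing dates allowed).
#' @return data.frame of per-subject outcomes (`time_months`, `event`,
#'   `event_type`).
#' @export
derive_progression_outcome <- function(clinical, fvc_long, events) {
  enroll <- as.Date(clinical$enrollment_date)[match(fvc_long$subject,
                                                    clinical$subject)]
  base_fvc <- clinical$fvc_pct[match(fvc_long$subject, clinical$subject)]
  dt <- as.numeric(as.Date(fvc_long$visit_date) - enroll)
  if (any(dt < 0)) stop("visit dated before enrollment")
  qualifies <- dt > 0 & (base_fvc - fvc_long$fvc_pct) >= 10
  decline <- rep(NA_real_, nrow(clinical))
  if (any(qualifies)) {
    first <- tapply(days_to_months(dt[qualifies]), fvc_long$subject[qualifies],
                    min)
    pos <- match(names(first), clinical$subject)
    decline[pos] <- as.numeric(first)
  }
  derive_outcome_core(clinical, events, decline, "progression_free")
}

#' Transplant-free survival outcome
#'
#' Composite endpoint: first of lung transplant or death; otherwise
#' censored at last follow-up.
#'
#' @inheritParams derive_progression_outcome
#' @return data.frame of per-subject outcomes.
#' @export
derive_transplant_free_outcome <- function(clinical, events) {
  derive_outcome_core(clinical, events, NULL, "transplant_free")
}

#' Orient cluster labels by baseline severity
#'
#' Renumbers a two-cluster assignment so cluster 1 is the one with higher
#' mean CPI (more severe baseline disease), the reporting convention of
#' the subtype analysis. Assignments with more than two clusters are
#' returned unchanged.
#'
#' @param labels `cluster_assignment` or named label vector.
#' @param clinical clinical table containing `subject` and `cpi`.
#' @return A `cluster_assignment` with severity-oriented numbering.
#' @export
orient_labels_by_severity <- function(labels, clinical) {
  labels <- as_labels(labels)
  if (length(unique(labels)) != 2) return(cluster_assignment(labels))
  cpi <- clinical$cpi[match(names(labels), clinical$subject)]
  means <- tapply(cpi, labels, mean, na.rm = TRUE)
  severe <- as.integer(names(means)[which.max(means)])
  out <- ifelse(labels == severe, 1L, 2L)
  names(out) <- names(labels)
  structure(list(labels = out, k = 2L), class = "cluster_assignment")
}

#' Kaplan-Meier curves and log-rank test by group
#'
#' @param outcomes outcome table from the derive functions.
#' @param groups named (by subject) or aligned group vector.
#' @return List: `fit` (a [survival::survfit] object), `median` (median
#'   survival per group), `logrank_p`.
#' @export
km_logrank <- function(outcomes, groups) {
  g <- align_group(outcomes, groups)
  if (length(unique(g)) < 2) stop("need >= 2 groups")
  if (sum(outcomes$event) == 0) stop("no events observed")
  df <- data.frame(time = outcomes$time_months, event = outcomes$event,
                   group = factor(g))
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  p <- stats::pchisq(sd$chisq, df = length(sd$n) - 1, lower.tail = FALSE)
  med <- summary(fit)$table
  list(fit = fit, median = med[, "median"], logrank_p = p)
}

align_group <- function(outcomes, groups) {
  groups <- as_labels(groups)
  if (!is.null(names(groups))) {
    if (!all(outcomes$subject %in% names(groups)))
      stop("group labels missing for some subjects")
    groups <- groups[outcomes$subject]
  } else if (length(groups) != nrow(outcomes)) {
    stop("group vector length does not match outcomes")
  }
  groups
}

#' Cox proportional-hazards model for a group contrast
#'
#' Partial-likelihood fit (Efron tie handling) of the group indicator,
#' optionally adjusted for covariates; the default adjustment set of the
#' analysis is CPI + antifibrotic treatment category. Reports the hazard
#' ratio of `group == comparison` versus the reference with a 95% Wald CI.
#' Subjects with missing covariates are dropped with a log line.
#'
#' @param outcomes outcome table.
#' @param groups group labels (named vector or `cluster_assignment`).
#' @param comparison group level whose hazard is contrasted against the
#'   rest (default `1`, i.e. subtype 1 vs subtype 2).
#' @param clinical clinical table (needed when `covariates` given).
#' @param covariates character vector of clinical columns to adjust for,
#'   e.g. `c("cpi", "antifibrotic")`; `NULL` for unadjusted.
#' @return data.frame with `term`, `hr`, `ci_lower`, `ci_upper`, `p`,
#'   `n`, `n_events`, `covariates`.
#' @export
cox_fit <- function(outcomes, groups, comparison = 1, clinical = NULL,
                    covariates = NULL) {
  g <- align_group(outcomes, groups)
  df <- data.frame(time = outcomes$time_months, event = outcomes$event,
                   group = factor(ifelse(g == comparison, "cmp", "ref"),
                                  levels = c("ref", "cmp")))
  if (length(unique(g)) < 2) stop("need >= 2 groups")
  if (!is.null(covariates)) {
    if (is.null(clinical)) stop("clinical table required for covariates")
    cl <- clinical[match(outcomes$subject, clinical$subject), covariates,
                   drop = FALSE]
    for (cv in covariates)
      df[[cv]] <- if (is.character(cl[[cv]])) factor(cl[[cv]]) else cl[[cv]]
    drop <- !stats::complete.cases(df)
    if (any(drop)) {
      snf_log(sum(drop), " subject(s) dropped from adjusted model ",
              "(missing covariates)")
      df <- df[!drop, ]
    }
  }
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~ group",
                                 if (length(covariates))
                                   paste("+", paste(covariates, collapse = " + "))
                                 else ""))
  fit <- survival::coxph(fml, data = df, ties = "efron")
  sm <- summary(fit)
  row <- "groupcmp"
  data.frame(term = paste0("group=", comparison),
             hr = unname(sm$conf.int[row, "exp(coef)"]),
             ci_lower = unname(sm$conf.int[row, "lower .95"]),
             ci_upper = unname(sm$conf.int[row, "upper .95"]),
             p = unname(sm$coefficients[row, "Pr(>|z|)"]),
             n = sm$n, n_events = sm$nevent,
             covariates = if (length(covariates))
               paste(covariates, collapse = "+") else "none",
             stringsAsFactors = FALSE)
}

#' Baseline characteristics comparison table
#'
#' Mean (SD) per group with Kruskal-Wallis p for continuous variables;
#' count (%) with chi-square p for categorical variables (Yates continuity
#' correction for 2x2 tables, plain Pearson otherwise — the default of
#' [stats::chisq.test()]). Rows missing a variable are dropped for that
#' variable only; p-values are reported rounded to 2 decimals alongside
#' the exact value.
#'
#' @param clinical clinical table (must contain `subject`).
#' @param labels group labels (named vector or `cluster_assignment`).
#' @param variables columns to compare; default: every column except
#'   `subject` and date columns.
#' @return data.frame with one row per variable level and columns per
#'   group plus `p` (2 dp) and `p_exact`.
#' @export
baseline_table <- function(clinical, labels, variables = NULL) {
  labels <- as_labels(labels)
  if (!is.null(names(labels))) labels <- labels[clinical$subject]
  g <- factor(labels)
  if (is.null(variables))
    variables <- setdiff(names(clinical),
                         c("subject", grep("date", names(clinical), value = TRUE)))
  rows <- list()
  for (v in variables) {
    x <- clinical[[v]]
    ok <- !is.na(x)
    xi <- x[ok]; gi <- g[ok]
    if (is.numeric(xi) && length(unique(xi)) > 5) {
      p <- stats::kruskal.test(xi, gi)$p.value
      stats_by <- vapply(levels(g), function(l)
        sprintf("%.2f (%.2f)", mean(xi[gi == l]), stats::sd(xi[gi == l])), "")
      rows[[length(rows) + 1]] <- data.frame(
        variable = v, level = "", t(stats_by), p = round(p, 2), p_exact = p,
        stringsAsFactors = FALSE, check.names = FALSE)
    } else {
      xi <- factor(xi)
      if (nlevels(xi) < 2) stop("variable '", v, "' has a single level")
      tab <- table(xi, gi)
      p <- suppressWarnings(stats::chisq.test(tab)$p.value)
      for (lv in levels(xi)) {
        cnt <- vapply(levels(g), function(l) {
          nle <- sum(xi == lv & gi == l)
          sprintf("%d (%.1f%%)", nle, 100 * nle / sum(gi == l))
        }, "")
        rows[[length(rows) + 1]] <- data.frame(
          variable = v, level = lv, t(cnt), p = round(p, 2), p_exact = p,
          stringsAsFactors = FALSE, check.names = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  names(out)[3:(2 + nlevels(g))] <- paste0("group", levels(g))
  rownames(out) <- NULL
  out
}
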