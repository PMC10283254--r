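# Agreement between the molecular subtypes and an external binary risk
# grouping: Cohen's kappa with an asymptotic CI, cross-tabulation, and
# risk-group survival models.

#' Read a risk-group labelling
#'
#' Two-column delimited file: subject, label (two levels, e.g. high/low).
#'
#' @param path file path.
#' @param delim delimiter.
#' @return Named character vector subject -> label.
#' @export
read_risk_groups <- function(path, delim = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          stringsAsFactors = FALSE)
  stats::setNames(as.character(df[[2]]), df[[1]])
}

#' Median-split risk grouping from a per-subject score
#'
#' Plug-in interface for users supplying their own gene list and scoring
#' rule: scores above the median are labelled high risk.
#'
#' @param scores named numeric vector subject -> risk score.
#' @return Named character vector subject -> high/low.
#' @export
risk_groups_from_scores <- function(scores) {
  stats::setNames(ifelse(scores > stats::median(scores), "high", "low"),
                  names(scores))
}

#' Cohen's kappa between two binary labelings
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)` from the
#' 2x2 contingency table, with the standard large-sample (delta-method)
#' standard error and a 95% Wald CI. Because the pairing of levels across
#' the two labelings is arbitrary, the kappa under the agreement-maximizing
#' pairing is reported alongside the raw value.
#'
#' @param a,b label vectors (two levels each) over the same subjects;
#'   named vectors are aligned by name.
#' @return List: `kappa`, `se`, `ci` (length 2), `kappa_oriented` (under
#'   the max-agreement pairing), `table`, `n`. `kappa` is `NA` when either
#'   labelling is degenerate (single level).
#' @export
cohens_kappa <- function(a, b) {
  a <- as_labels(a); b <- as_labels(b)
  if (!is.null(names(a)) && !is.null(names(b))) {
    if (!setequal(names(a), names(b))) stop("mismatched subject sets")
    b <- b[names(a)]
  } else if (length(a) != length(b)) stop("mismatched subject sets")
  a <- factor(a); b <- factor(b)
  tab <- table(a, b)
  if (nlevels(a) < 2 || nlevels(b) < 2) {
    snf_log("degenerate labelling: kappa undefined")
    return(list(kappa = NA_real_, se = NA_real_, ci = c(NA_real_, NA_real_),
                kappa_oriented = NA_real_, table = tab, n = sum(tab)))
  }
  if (nlevels(a) != 2 || nlevels(b) != 2)
    stop("both labelings must be binary")
  kappa_of <- function(tab) {
    n <- sum(tab); p <- tab / n
    po <- sum(diag(p)); pe <- sum(rowSums(p) * colSums(p))
    (po - pe) / (1 - pe)
  }
  n <- sum(tab); p <- tab / n
  po <- sum(diag(p)); pe <- sum(rowSums(p) * colSums(p))
  k <- (po - pe) / (1 - pe)
  # Fleiss-Cohen-Everitt large-sample variance
  ri <- rowSums(p); ci <- colSums(p)
  termA <- sum(diag(p) * ((1 - pe) - (ri + ci) * (1 - po))^2)
  offd <- p; diag(offd) <- 0
  termB <- (1 - po)^2 *
    sum(offd * (outer(rep(1, nrow(p)), ri) + outer(ci, rep(1, ncol(p))))^2)
  termC <- (po * pe - 2 * pe + po)^2
  se <- sqrt((termA + termB - termC) / (n * (1 - pe)^4))
  flipped <- tab[, 2:1]
  list(kappa = k, se = se, ci = c(k - 1.96 * se, k + 1.96 * se),
       kappa_oriented = max(kappa_of(tab), kappa_of(flipped)),
       table = tab, n = n)
}

#' Survival by external risk group
#'
#' Kaplan-Meier curves plus unadjusted and adjusted (CPI + antifibrotic)
#' Cox models of high- vs low-risk membership for each supplied composite
#' endpoint, reusing the subtype survival machinery.
#'
#' @param outcomes_list named list of outcome tables (one per endpoint).
#' @param risk named risk labels (`"high"`/`"low"`), or any two-level
#'   labelling; the hazard is reported for `comparison` (default
#'   `"high"`) versus the other level.
#' @param clinical clinical table for the adjusted models.
#' @param comparison risk level whose hazard is contrasted.
#' @param covariates adjustment set for the adjusted model.
#' @return data.frame of Cox results (endpoint x adjustment), with the KM
#'   fits attached as attribute `"km"`.
#' @export
risk_group_survival <- function(outcomes_list, risk, clinical,
                                comparison = "high",
                                covariates = c("cpi", "antifibrotic")) {
  if (length(unique(as_labels(risk))) < 2)
    stop("risk labelling has a single group")
  res <- list(); km <- list()
  for (ep in names(outcomes_list)) {
    oc <- outcomes_list[[ep]]
    km[[ep]] <- km_logrank(oc, risk)
    un <- cox_fit(oc, risk, comparison = comparison)
    ad <- cox_fit(oc, risk, comparison = comparison, clinical = clinical,
                  covariates = covariates)
    un$endpoint <- ad$endpoint <- ep
    un$model <- "unadjusted"; ad$model <- "adjusted"
    res[[length(res) + 1]] <- un
    res[[length(res) + 1]] <- ad
  }
  out <- do.call(rbind, res)
  attr(out, "km") <- km
  out
}
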