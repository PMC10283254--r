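# Synthetic multi-omics study generator: planted two-subtype structure in
# the protein and miRNA blocks (none in toRNA), Table-1-like clinical
# baselines, and subtype/CPI-dependent censored survival outcomes.

#' Simulation configuration
#'
#' Defines the generative conditions for a synthetic study. The defaults
#' are the "cohort-like" preset: 232 subjects split ~45/55 between two
#' subtypes, with subtype signal planted in the protein and miRNA blocks
#' only (the toRNA block is pure noise), lung-function baselines shifted
#' so subtype 1 is more severe, and exponential event times whose hazard
#' depends on subtype and CPI.
#'
#' @param n_subjects number of subjects.
#' @param cluster_proportions probability vector over subtypes (sums to 1).
#' @param n_features named counts of features per modality.
#' @param informative_fraction named fractions (per modality) of features
#'   given a subtype-dependent mean shift; the preset keeps toRNA at 0.
#' @param effect_size mean shift between subtypes for informative
#'   features, in units of the within-cluster SD.
#' @param noise_sd within-cluster SD of every feature.
#' @param survival list: `hazard_transplant_death` and `hazard_decline`
#'   (baseline monthly hazards), `log_hr_subtype` (log hazard ratio of
#'   subtype-1 membership), `log_hr_cpi` (log-HR per CPI unit, centred at
#'   CPI 52), `censor_months` (administrative censoring), `dropout_rate`
#'   (monthly hazard of random loss to follow-up), `transplant_share`
#'   (probability a transplant/death event is a transplant).
#' @param fvc_visit_months spacing of the longitudinal FVC visit grid.
#' @param fvc_noise_sd measurement noise (FVC percentage points) on visits.
#' @param seed master seed; every draw derives from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 232,
                       cluster_proportions = c(0.45, 0.55),
                       n_features = c(protein = 1300, mirna = 750, torna = 1600),
                       informative_fraction = c(protein = 0.10, mirna = 0.10,
                                                torna = 0),
                       effect_size = 2,
                       noise_sd = 1,
                       survival = list(),
                       fvc_visit_months = 4,
                       fvc_noise_sd = 1.5,
                       seed = 1L) {
  surv_default <- list(hazard_transplant_death = 0.012,
                       hazard_decline = 0.02,
                       log_hr_subtype = log(1.8),
                       log_hr_cpi = 0.04,
                       censor_months = 48,
                       dropout_rate = 0.01,
                       transplant_share = 0.19)
  survival <- utils::modifyList(surv_default, survival)
  if (abs(sum(cluster_proportions) - 1) > 1e-8)
    stop("cluster_proportions must sum to 1")
  if (n_subjects < 1 || any(n_features < 1))
    stop("all counts must be positive")
  if (any(informative_fraction < 0) || any(informative_fraction > 1))
    stop("informative_fraction must lie in [0, 1]")
  if (!identical(sort(names(n_features)), sort(MODALITIES)) ||
      !identical(sort(names(informative_fraction)), sort(MODALITIES)))
    stop("n_features and informative_fraction must be named by modality: ",
         paste(MODALITIES, collapse = ", "))
  if (survival$hazard_transplant_death < 0 || survival$hazard_decline < 0)
    stop("baseline hazards must be nonnegative")
  if (survival$censor_months < 0) stop("censoring time must be >= 0")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  structure(
    list(n_subjects = as.integer(n_subjects),
         cluster_proportions = cluster_proportions,
         n_features = n_features,
         informative_fraction = informative_fraction,
         effect_size = effect_size, noise_sd = noise_sd,
         survival = survival,
         fvc_visit_months = fvc_visit_months,
         fvc_noise_sd = fvc_noise_sd,
         seed = as.integer(seed)),
    class = "sim_config")
}

#' Ten-subject smoke-test preset
#'
#' Tiny configuration for end-to-end plumbing checks (seconds, not
#' minutes). Not intended to carry statistical signal.
#' @param seed master seed.
#' @return A [sim_config()].
#' @export
smoke_config <- function(seed = 1L) {
  sim_config(n_subjects = 10,
             n_features = c(protein = 40, mirna = 30, torna = 50),
             seed = seed)
}

simulate_labels <- function(config) {
  k <- length(config$cluster_proportions)
  ids <- sprintf("S%04d", seq_len(config$n_subjects))
  labels <- with_seed(derive_seed(config$seed, 1L),
                      sample.int(k, config$n_subjects, replace = TRUE,
                                 prob = config$cluster_proportions))
  stats::setNames(labels, ids)
}

modality_prefix <- c(protein = "PROT", mirna = "MIR", torna = "TORNA")

#' Simulate one omics block with planted subtype structure
#'
#' Gaussian draws on a normalized scale: the first
#' `ceiling(informative_fraction * F)` features get cluster-specific means
#' separated by `effect_size * noise_sd` (direction alternating by
#' feature); the rest share a common mean. The planted informative feature
#' identifiers are attached as attribute `"informative"`.
#'
#' @param config a [sim_config()].
#' @param modality modality name.
#' @param labels named subtype labels covering all subjects.
#' @return An [omics_block()].
#' @export
simulate_omics_block <- function(config, modality, labels) {
  modality <- match.arg(modality, MODALITIES)
  n <- config$n_subjects
  if (length(labels) != n) stop("labels must cover all subjects")
  nf <- as.integer(config$n_features[[modality]])
  if (nf < 1) stop("non-positive feature count for ", modality)
  n_info <- ceiling(config$informative_fraction[[modality]] * nf)
  delta <- config$effect_size * config$noise_sd
  feature_ids <- sprintf("%s%05d", modality_prefix[[modality]], seq_len(nf))
  salt <- 100L + match(modality, MODALITIES)
  vals <- with_seed(derive_seed(config$seed, salt), {
    m <- matrix(stats::rnorm(n * nf, sd = config$noise_sd), n, nf)
    if (n_info > 0) {
      sign <- rep_len(c(1, -1), n_info)
      shift <- outer(ifelse(labels == 1, 0.5, -0.5), sign * delta)
      m[, seq_len(n_info)] <- m[, seq_len(n_info)] + shift
    }
    m
  })
  rownames(vals) <- names(labels)
  colnames(vals) <- feature_ids
  block <- omics_block(vals, modality, scale = "simulated-normalized")
  attr(block, "informative") <- feature_ids[seq_len(n_info)]
  block
}

#' Simulate clinical baselines, longitudinal FVC, and event dates
#'
#' Baseline lung function (FVC/DLco/FEV1 % predicted) is drawn with
#' subtype-1 means shifted lower; CPI is computed from the three values by
#' [compute_cpi()], making it a genuine confounder when
#' `survival$log_hr_cpi != 0`. Transplant/death times are exponential with
#' log-linear subtype and CPI effects; FVC trajectories are linear per
#' subject with the slope chosen so the 10-point decline threshold is
#' crossed at an exponential latent time with the same log-linear hazard
#' structure, then observed with noise on a fixed visit grid.
#'
#' @param config a [sim_config()].
#' @param labels named subtype labels covering all subjects.
#' @return List with `clinical`, `fvc_long`, `events` data frames.
#' @export
simulate_clinical_and_survival <- function(config, labels) {
  n <- config$n_subjects
  if (length(labels) != n) stop("labels must cover all subjects")
  sv <- config$survival
  ids <- names(labels)
  s1 <- labels == 1

  clin <- with_seed(derive_seed(config$seed, 200L), {
    clamp <- function(x) pmin(pmax(x, 5), 148)
    fvc  <- clamp(stats::rnorm(n, ifelse(s1, 67.9, 73.8), ifelse(s1, 15.2, 17.7)))
    dlco <- clamp(stats::rnorm(n, ifelse(s1, 38.3, 43.1), ifelse(s1, 12.5, 14.7)))
    fev1 <- clamp(stats::rnorm(n, ifelse(s1, 76.1, 81.0), ifelse(s1, 16.1, 20.0)))
    data.frame(
      subject = ids,
      age = round(stats::rnorm(n, 69.7, 7.8), 1),
      sex = sample(c("M", "F"), n, TRUE, prob = c(0.74, 0.26)),
      ever_smoker = sample(c("Y", "N"), n, TRUE, prob = c(0.67, 0.33)),
      cad = sample(c("Y", "N"), n, TRUE, prob = c(0.31, 0.69)),
      copd = sample(c("Y", "N"), n, TRUE, prob = c(0.18, 0.82)),
      diabetes = sample(c("Y", "N"), n, TRUE, prob = c(0.19, 0.81)),
      antifibrotic = sample(c("nintedanib", "pirfenidone", "neither"), n, TRUE,
                            prob = c(0.18, 0.36, 0.46)),
      fvc_pct = round(fvc, 1), dlco_pct = round(dlco, 1),
      fev1_pct = round(fev1, 1),
      gap_stage = sample(1:3, n, TRUE, prob = c(0.27, 0.58, 0.15)),
      diagnostic_category = sample(c("definite", "probable", "possible"), n,
                                   TRUE, prob = c(0.74, 0.22, 0.04)),
      enrollment_date = as.Date("2014-07-01") +
        sample.int(3 * 365, n, replace = TRUE),
      stringsAsFactors = FALSE)
  })
  clin$cpi <- round(compute_cpi(clin$fvc_pct, clin$dlco_pct, clin$fev1_pct), 1)

  lp <- sv$log_hr_subtype * s1 + sv$log_hr_cpi * (clin$cpi - 52)
  tt <- with_seed(derive_seed(config$seed, 300L), {
    rexp_safe <- function(rate) ifelse(rate > 0, stats::rexp(n, rate), Inf)
    t_td  <- rexp_safe(sv$hazard_transplant_death * exp(lp))
    t_dec <- rexp_safe(sv$hazard_decline * exp(lp))
    transplant <- stats::runif(n) < sv$transplant_share
    dropout <- rexp_safe(rep(sv$dropout_rate, n))
    list(t_td = t_td, t_dec = t_dec, transplant = transplant,
         dropout = dropout)
  })
  cens <- pmin(tt$dropout, sv$censor_months)
  followup_end <- pmin(tt$t_td, cens)   # months on study
  had_td <- tt$t_td <= cens

  events <- data.frame(
    subject = ids,
    transplant_date = as.Date(ifelse(had_td & tt$transplant,
      clin$enrollment_date + months_to_days(tt$t_td), NA),
      origin = "1970-01-01"),
    death_date = as.Date(ifelse(had_td & !tt$transplant,
      clin$enrollment_date + months_to_days(tt$t_td), NA),
      origin = "1970-01-01"),
    last_followup_date = clin$enrollment_date + months_to_days(followup_end),
    stringsAsFactors = FALSE)

  # Linear FVC trajectory crossing -10 points exactly at the latent decline
  # time; observed with noise at the fixed visit grid while on study.
  slope <- -10 / pmax(tt$t_dec, 0.25)
  fvc_long <- with_seed(derive_seed(config$seed, 400L), {
    rows <- lapply(seq_len(n), function(i) {
      tgrid <- seq(0, followup_end[i], by = config$fvc_visit_months)
      if (length(tgrid) == 0) return(NULL)
      data.frame(
        subject = ids[i],
        visit_date = clin$enrollment_date[i] + months_to_days(tgrid),
        fvc_pct = round(clin$fvc_pct[i] + slope[i] * tgrid +
                          stats::rnorm(length(tgrid), 0, config$fvc_noise_sd), 1),
        stringsAsFactors = FALSE)
    })
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  })
  if (is.null(fvc_long))
    fvc_long <- data.frame(subject = character(), visit_date = as.Date(character()),
                           fvc_pct = numeric())

  list(clinical = clin, fvc_long = fvc_long, events = events)
}

#' Simulate risk-group labels (external gene-signature stand-in)
#'
#' Synthetic stand-in for a previously published transcriptomic mortality
#' risk classifier: a noisy median split on CPI, so the grouping tracks
#' baseline severity (and hence transplant-free survival) but agrees
#' little with the planted molecular subtypes.
#'
#' @param clinical clinical table from [simulate_clinical_and_survival()].
#' @param seed integer seed.
#' @param noise_sd SD of the noise added to CPI before the split.
#' @return data.frame with `subject` and `risk_group` (high/low).
#' @export
simulate_risk_groups <- function(clinical, seed = 1L, noise_sd = 8) {
  score <- with_seed(derive_seed(seed, 500L),
                     clinical$cpi + stats::rnorm(nrow(clinical), 0, noise_sd))
  data.frame(subject = clinical$subject,
             risk_group = ifelse(score > stats::median(score), "high", "low"),
             stringsAsFactors = FALSE)
}

#' Simulate a complete multi-omics study
#'
#' Composes the omics-block and clinical/survival generators, plus the
#' synthetic risk grouping, miRNA target map and gene-set collection
#' needed by the enrichment stage. Optionally writes every table to a
#' directory in the pipeline's input formats.
#'
#' @param config a [sim_config()].
#' @param dir optional output directory; created if missing.
#' @return An object of class `simulated_study`: `blocks` (per modality),
#'   `clinical`, `fvc_long`, `events`, `risk_groups`, `mirna_targets`,
#'   `gene_sets` (GMT-style named list), and `true_labels` (kept separate
#'   from anything a pipeline stage reads as input).
#' @export
simulate_study <- function(config, dir = NULL) {
  labels <- simulate_labels(config)
  blocks <- lapply(MODALITIES, function(m)
    simulate_omics_block(config, m, labels))
  names(blocks) <- MODALITIES
  tabs <- simulate_clinical_and_survival(config, labels)
  risk <- simulate_risk_groups(tabs$clinical, seed = config$seed)
  ann <- simulate_annotation(config, blocks)

  study <- structure(
    c(list(blocks = blocks), tabs,
      list(risk_groups = risk, mirna_targets = ann$mirna_targets,
           gene_sets = ann$gene_sets, true_labels = labels,
           config = config)),
    class = "simulated_study")

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (m in MODALITIES)
      write_omics_matrix(blocks[[m]], file.path(dir, paste0(m, ".tsv")))
    wt <- function(df, name)
      utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                         row.names = FALSE)
    wt(tabs$clinical, "clinical.tsv")
    wt(tabs$fvc_long, "fvc_long.tsv")
    wt(tabs$events, "events.tsv")
    wt(risk, "risk_groups.tsv")
    wt(data.frame(subject = names(labels), label = unname(labels)),
       "truth.tsv")
    wt(ann$mirna_targets, "mirna_targets.tsv")
    write_gmt(ann$gene_sets, file.path(dir, "gene_sets.gmt"))
  }
  study
}

# Synthetic annotation layer for the enrichment stage: a gene universe, a
# miRNA -> target-gene map, and pathway gene sets. Pathways are biased to
# draw from genes "near" the planted informative features so that true DE
# hits concentrate in a subset of pathways.
simulate_annotation <- function(config, blocks) {
  n_genes <- 1500L
  genes <- sprintf("GENE%05d", seq_len(n_genes))
  prot_ids <- blocks$protein$feature_ids
  mir_ids <- blocks$mirna$feature_ids
  info_prot <- attr(blocks$protein, "informative")
  info_mir <- attr(blocks$mirna, "informative")
  with_seed(derive_seed(config$seed, 600L), {
    # informative proteins/miRNA targets concentrate in the first 400 genes
    signal_pool <- genes[seq_len(400)]
    noise_pool <- genes[-seq_len(400)]
    pick <- function(informative) {
      if (informative) c(sample(signal_pool, sample(3:8, 1)),
                         sample(noise_pool, sample(0:2, 1)))
      else sample(noise_pool, sample(3:10, 1))
    }
    tgt <- lapply(mir_ids, function(id) pick(id %in% info_mir))
    mirna_targets <- data.frame(
      mirna_id = rep(mir_ids, lengths(tgt)),
      gene_symbol = unlist(tgt), stringsAsFactors = FALSE)
    # protein features are identified with gene symbols via a lookup so the
    # protein ORA query is in gene space: informative -> signal pool
    prot_gene <- character(length(prot_ids))
    prot_gene[prot_ids %in% info_prot] <-
      sample(signal_pool, sum(prot_ids %in% info_prot), replace = TRUE)
    prot_gene[!(prot_ids %in% info_prot)] <-
      sample(noise_pool, sum(!(prot_ids %in% info_prot)), replace = TRUE)
    mirna_targets <- rbind(mirna_targets,
      data.frame(mirna_id = paste0("map:", prot_ids), gene_symbol = prot_gene,
                 stringsAsFactors = FALSE))
    sets <- c(
      lapply(seq_len(10), function(i)
        unique(c(sample(signal_pool, 25), sample(noise_pool, 10)))),
      lapply(seq_len(40), function(i) sample(noise_pool, sample(15:40, 1))))
    names(sets) <- c(sprintf("SIGNAL_PATHWAY_%02d", 1:10),
                     sprintf("BACKGROUND_PATHWAY_%02d", 1:40))
    list(mirna_targets = mirna_targets, gene_sets = sets)
  })
}

# Minimal GMT writer (name, description, genes...) for simulated gene sets.
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "synthetic", sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}
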