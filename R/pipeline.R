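# Pipeline orchestration: nested YAML config, staged execution with a
# run manifest (digests of inputs and outputs), and a report collating
# the headline numbers of a run.

#' Default pipeline configuration
#'
#' Every analysis constant is a named default here: consensus clustering
#' with 100 iterations and 0.8 subsampling, k assessed over 2..10, the
#' toRNA top-10% variance filter, FDR 0.05, 5 classifier folds with a
#' 3-of-5 selection threshold, and the 10-percentage-point FVC decline
#' rule implied by the endpoint derivation.
#'
#' @param n_subjects subjects for the simulate stage.
#' @param seed master seed; per-stage seeds derive from it.
#' @return Nested configuration list.
#' @export
default_config <- function(n_subjects = 232, seed = 1L) {
  list(
    seed = as.integer(seed),
    simulate = list(n_subjects = n_subjects,
                    cluster_proportions = c(0.45, 0.55),
                    effect_size = 2, noise_sd = 1),
    preprocess = list(variance_filter = list(protein = 1.0, mirna = 1.0,
                                             torna = 0.10)),
    snf = list(K = 20, mu = 0.5, t_iter = 20),
    cluster = list(iterations = 100, ratio = 0.8, k_min = 2, k_max = 10),
    survival = list(covariates = c("cpi", "antifibrotic")),
    classifier = list(n_folds = 5, selection_threshold = 3,
                      num_trees = 500, screen_size = 50,
                      modalities = c("protein", "mirna")),
    diffexp = list(fdr_threshold = 0.05),
    enrich = list(fdr_threshold = 0.05))
}

#' Read / write a pipeline configuration
#'
#' @param path YAML file.
#' @return `read_config`: the configuration list merged over the
#'   defaults; `write_config`: `path`, invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  utils::modifyList(default_config(), user)
}

#' @rdname read_config
#' @param config configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

PIPELINE_STAGES <- c("simulate", "cluster", "contribution", "survival",
                     "concordance", "classify", "diffexp", "enrich",
                     "report")

need_files <- function(dir, files) {
  paths <- file.path(dir, files)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("missing required input file(s): ", paste(missing, collapse = ", "))
  paths
}

manifest_update <- function(outdir, stage, config, outputs) {
  path <- file.path(outdir, "manifest.json")
  man <- if (file.exists(path)) jsonlite::read_json(path) else
    list(config = config, stages = list())
  outputs <- outputs[file.exists(outputs)]
  man$package_version <- as.character(utils::packageVersion("snfsubtypes"))
  man$stages[[stage]] <- list(
    outputs = as.list(stats::setNames(unname(tools::md5sum(outputs)),
                                      basename(outputs))))
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

read_tsv <- function(path, ...)
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    ...)

write_tsv <- function(df, path)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)

# Load, filter, standardize and align the omics blocks of a run.
load_dataset <- function(indir, config) {
  blocks <- lapply(MODALITIES, function(m) {
    b <- read_omics_matrix(file.path(indir, paste0(m, ".tsv")), m)
    q <- config$preprocess$variance_filter[[m]] %||% 1.0
    if (q < 1) b <- variance_filter(b, q)
    standardize_features(b)
  })
  align_subjects(blocks)
}

stage_simulate <- function(config, outdir) {
  n <- config$simulate$n_subjects
  nf <- if (n <= 20) c(protein = 40, mirna = 30, torna = 50)
        else c(protein = 1300, mirna = 750, torna = 1600)
  sc <- sim_config(n_subjects = n,
                   cluster_proportions = config$simulate$cluster_proportions,
                   n_features = nf,
                   effect_size = config$simulate$effect_size,
                   noise_sd = config$simulate$noise_sd,
                   seed = derive_seed(config$seed, 1L))
  indir <- file.path(outdir, "input")
  simulate_study(sc, dir = indir)
  invisible(indir)
}

auto_k <- function(config, n) {
  k <- config$snf$K
  if (k >= n) {
    k <- max(2L, floor((n - 1) / 2))
    snf_log("K reduced to ", k, " for n = ", n)
  }
  k
}

stage_cluster <- function(config, outdir) {
  indir <- file.path(outdir, "input")
  need_files(indir, paste0(MODALITIES, ".tsv"))
  dataset <- load_dataset(indir, config)
  n <- length(dataset$subject_ids)
  params <- snf_params(K = auto_k(config, n), mu = config$snf$mu,
                       t_iter = config$snf$t_iter)
  fused <- snf(dataset, params)
  k_max <- min(config$cluster$k_max, floor(config$cluster$ratio * n) - 2)
  profile <- silhouette_profile(
    fused$W, k_range = config$cluster$k_min:k_max,
    iterations = config$cluster$iterations, ratio = config$cluster$ratio,
    seed = derive_seed(config$seed, 2L))
  k <- select_k(profile)
  run <- profile$runs[[as.character(k)]]
  # reporting convention: subtype 1 is the more severe cluster (higher CPI)
  clin_path <- file.path(indir, "clinical.tsv")
  if (file.exists(clin_path) && k == 2)
    run$assignment <- orient_labels_by_severity(run$assignment,
                                                load_clinical(indir))
  write_fused_network(fused, file.path(outdir, "fused.tsv"))
  write_tsv(data.frame(subject = names(run$assignment$labels),
                       label = unname(run$assignment$labels)),
            file.path(outdir, "subtypes.tsv"))
  write_fused_network(run$consensus,
                      file.path(outdir, sprintf("consensus_k%d.tsv", k)))
  write_tsv(data.frame(k = profile$k_range,
                       mean_silhouette = unname(profile$scores)),
            file.path(outdir, "silhouette.tsv"))
  invisible(list(fused = fused, profile = profile, k = k))
}

read_subtypes <- function(outdir) {
  df <- read_tsv(need_files(outdir, "subtypes.tsv"))
  stats::setNames(as.integer(df$label), df$subject)
}

stage_contribution <- function(config, outdir) {
  indir <- file.path(outdir, "input")
  labels <- read_subtypes(outdir)
  dataset <- load_dataset(indir, config)
  n <- length(dataset$subject_ids)
  params <- snf_params(K = auto_k(config, n), mu = config$snf$mu,
                       t_iter = config$snf$t_iter)
  k <- length(unique(labels))
  contrib <- modality_contribution(
    dataset, cluster_assignment(labels), k, params,
    iterations = config$cluster$iterations, ratio = config$cluster$ratio,
    seed = derive_seed(config$seed, 3L))
  write_tsv(data.frame(modality = names(contrib), nmi = unname(contrib)),
            file.path(outdir, "contribution.tsv"))
  invisible(contrib)
}

load_clinical <- function(indir) {
  clinical <- read_tsv(file.path(indir, "clinical.tsv"))
  clinical$enrollment_date <- as.Date(clinical$enrollment_date)
  clinical
}

derive_both_outcomes <- function(indir) {
  clinical <- load_clinical(indir)
  fvc <- read_tsv(file.path(indir, "fvc_long.tsv"))
  events <- read_tsv(file.path(indir, "events.tsv"))
  list(clinical = clinical,
       outcomes = list(
         transplant_free = derive_transplant_free_outcome(clinical, events),
         progression_free = derive_progression_outcome(clinical, fvc, events)))
}

stage_survival <- function(config, outdir) {
  indir <- file.path(outdir, "input")
  need_files(indir, c("clinical.tsv", "fvc_long.tsv", "events.tsv"))
  labels <- read_subtypes(outdir)
  dd <- derive_both_outcomes(indir)
  write_tsv(do.call(rbind, dd$outcomes), file.path(outdir, "outcomes.tsv"))
  bt <- baseline_table(dd$clinical, labels)
  write_tsv(bt, file.path(outdir, "baseline_table.tsv"))
  cox <- list()
  for (ep in names(dd$outcomes)) {
    oc <- dd$outcomes[[ep]]
    km <- tryCatch(km_logrank(oc, labels), error = function(e) NULL)
    if (!is.null(km)) {
      grDevices::pdf(file.path(outdir, sprintf("km_%s.pdf", ep)))
      plot(km$fit, col = c("steelblue", "firebrick"), xlab = "Months",
           ylab = "Survival probability", main = ep)
      grDevices::dev.off()
    }
    for (mod in c("unadjusted", "adjusted")) {
      fit <- tryCatch(
        cox_fit(oc, labels, comparison = 1,
                clinical = if (mod == "adjusted") dd$clinical,
                covariates = if (mod == "adjusted")
                  config$survival$covariates),
        error = function(e) NULL)
      if (is.null(fit)) next
      fit$endpoint <- ep; fit$model <- mod
      fit$logrank_p <- if (!is.null(km) && mod == "unadjusted")
        km$logrank_p else NA_real_
      cox[[length(cox) + 1]] <- fit
    }
  }
  write_tsv(do.call(rbind, cox), file.path(outdir, "cox_results.tsv"))
  invisible(NULL)
}

stage_concordance <- function(config, outdir) {
  indir <- file.path(outdir, "input")
  need_files(indir, "risk_groups.tsv")
  labels <- read_subtypes(outdir)
  risk <- read_risk_groups(file.path(indir, "risk_groups.tsv"))
  # map binary subtypes to the risk scale for the kappa table: subtype 1
  # (the more severe cluster) is paired with "high"
  sub_bin <- stats::setNames(ifelse(labels == 1, "high", "low"), names(labels))
  kp <- cohens_kappa(sub_bin, risk)
  write_tsv(data.frame(kappa = kp$kappa, se = kp$se,
                       ci_lower = kp$ci[1], ci_upper = kp$ci[2],
                       kappa_oriented = kp$kappa_oriented, n = kp$n),
            file.path(outdir, "kappa.tsv"))
  write_tsv(as.data.frame.matrix(kp$table), file.path(outdir, "crosstab.tsv"))
  dd <- derive_both_outcomes(indir)
  rs <- tryCatch(
    risk_group_survival(dd$outcomes, risk, dd$clinical,
                        covariates = config$survival$covariates),
    error = function(e) NULL)
  if (!is.null(rs))
    write_tsv(rs, file.path(outdir, "risk_cox_results.tsv"))
  invisible(kp)
}

stage_classify <- function(config, outdir) {
  indir <- file.path(outdir, "input")
  labels <- read_subtypes(outdir)
  dataset <- load_dataset(indir, config)
  mods <- intersect(config$classifier$modalities, names(dataset$blocks))
  x <- do.call(cbind, lapply(dataset$blocks[mods], `[[`, "values"))
  modality <- unlist(lapply(dataset$blocks[mods], function(b)
    stats::setNames(rep(b$modality, length(b$feature_ids)), b$feature_ids)))
  cfg <- classifier_config(
    n_folds = config$classifier$n_folds,
    selection_threshold = config$classifier$selection_threshold,
    num_trees = config$classifier$num_trees,
    screen_size = config$classifier$screen_size,
    seed = derive_seed(config$seed, 4L))
  report <- run_cv_classifier(x, labels, cfg, modality = modality)
  write_tsv(data.frame(fold = seq_along(report$fold_auc),
                       auc = report$fold_auc,
                       mean_auc = report$mean_auc, sd_auc = report$sd_auc),
            file.path(outdir, "classifier_report.tsv"))
  write_tsv(tally_selected_features(report),
            file.path(outdir, "feature_ledger.tsv"))
  dd <- derive_both_outcomes(indir)
  write_tsv(validate_clinical_consistency(report, dd$outcomes),
            file.path(outdir, "fold_hr.tsv"))
  invisible(report)
}

stage_diffexp <- function(config, outdir) {
  indir <- file.path(outdir, "input")
  labels <- read_subtypes(outdir)
  dataset <- load_dataset(indir, config)
  for (m in names(dataset$blocks)) {
    de <- differential_expression(dataset$blocks[[m]],
                                  cluster_assignment(labels),
                                  fdr_threshold = config$diffexp$fdr_threshold)
    write_tsv(de, file.path(outdir, sprintf("de_%s.tsv", m)))
  }
  invisible(NULL)
}

stage_enrich <- function(config, outdir) {
  indir <- file.path(outdir, "input")
  need_files(indir, c("gene_sets.gmt", "mirna_targets.tsv"))
  need_files(outdir, c("de_protein.tsv", "de_mirna.tsv"))
  collection <- read_gene_sets(file.path(indir, "gene_sets.gmt"))
  tmap <- read_mirna_targets(file.path(indir, "mirna_targets.tsv"))
  de_prot <- read_tsv(file.path(outdir, "de_protein.tsv"))
  de_mir <- read_tsv(file.path(outdir, "de_mirna.tsv"))
  thr <- config$enrich$fdr_threshold
  # protein features map to gene symbols through the "map:" entries of the
  # target table (identity mapping when absent)
  prot_map <- tmap[grepl("^map:", names(tmap))]
  names(prot_map) <- sub("^map:", "", names(prot_map))
  to_genes <- function(ids) {
    mapped <- unlist(prot_map[intersect(ids, names(prot_map))])
    unique(c(mapped, setdiff(ids, names(prot_map))))
  }
  down_prot <- de_prot$feature[de_prot$significant &
                                 de_prot$direction == "down" &
                                 !is.na(de_prot$direction)]
  mir_targets <- map_mirna_targets(de_mir,
                                   tmap[!grepl("^map:", names(tmap))])
  queries <- list(protein_down = to_genes(down_prot),
                  mirna_targets_up = mir_targets$up,
                  mirna_targets_down = mir_targets$down)
  enriched <- list()
  for (nm in names(queries)) {
    res <- suppressWarnings(
      ora_hypergeometric(queries[[nm]], collection, fdr_threshold = thr,
                         direction = nm))
    write_tsv(res, file.path(outdir, sprintf("ora_%s.tsv", nm)))
    enriched[[nm]] <- res$pathway[res$enriched]
  }
  write_tsv(enrichment_overlap(enriched), file.path(outdir, "overlap.tsv"))
  invisible(enriched)
}

#' Collate a run into a summary report
#'
#' Reads the outputs under `outdir` and writes `report.json` (headline
#' numbers) plus a human-readable `summary.txt`. Missing stages are
#' marked absent with a warning; regenerating the report is byte-stable.
#'
#' @param outdir run directory.
#' @return The report list, invisibly.
#' @export
pipeline_report <- function(outdir) {
  rep <- list()
  grab <- function(file, fn) {
    p <- file.path(outdir, file)
    if (!file.exists(p)) { warning("report: missing ", file); return(NULL) }
    fn(read_tsv(p))
  }
  # missing sections must stay in the report as explicit nulls, so the
  # index assignment form (which keeps the name for NULL values) is used
  rep["subtypes"] <- list(grab("subtypes.tsv", function(d)
    as.list(table(d$label))))
  rep["silhouette"] <- list(grab("silhouette.tsv", function(d)
    list(selected_k = d$k[which.max(d$mean_silhouette)],
         scores = stats::setNames(as.list(d$mean_silhouette), d$k))))
  rep["contribution"] <- list(grab("contribution.tsv", function(d)
    stats::setNames(as.list(d$nmi), d$modality)))
  rep["cox"] <- list(grab("cox_results.tsv", function(d)
    lapply(seq_len(nrow(d)), function(i) as.list(d[i, ]))))
  rep["kappa"] <- list(grab("kappa.tsv", function(d) as.list(d[1, ])))
  rep["classifier"] <- list(grab("classifier_report.tsv", function(d)
    list(mean_auc = d$mean_auc[1], sd_auc = d$sd_auc[1])))
  rep["ledger_size"] <- list(grab("feature_ledger.tsv", function(d) nrow(d)))
  for (m in MODALITIES)
    rep[paste0("de_", m)] <- list(grab(sprintf("de_%s.tsv", m), function(d)
      sum(d$significant)))
  rep["overlap"] <- list(grab("overlap.tsv", function(d)
    stats::setNames(as.list(d$n), d$region)))
  jsonlite::write_json(rep, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  lines <- c("snfsubtypes run summary", "=======================",
             vapply(names(rep), function(nm) {
               val <- rep[[nm]]
               paste0(nm, ": ", if (is.null(val)) "ABSENT" else
                 paste(utils::capture.output(utils::str(val, give.head = FALSE)),
                       collapse = " "))
             }, ""))
  writeLines(lines, file.path(outdir, "summary.txt"))
  invisible(rep)
}

#' Run the analysis pipeline
#'
#' Executes one stage, or all stages in dependency order. Inputs are read
#' from `outdir/input` (written there by the simulate stage, or supplied
#' by the user in the same formats); each stage records content digests of
#' its outputs in `manifest.json`, so deterministic stages reproduce
#' identical digests under the same configuration and seed.
#'
#' @param config configuration list (see [default_config()]) or a YAML
#'   path.
#' @param outdir run directory (created if missing).
#' @param stage one of `"simulate"`, `"cluster"`, `"contribution"`,
#'   `"survival"`, `"concordance"`, `"classify"`, `"diffexp"`,
#'   `"enrich"`, `"report"`, `"all"`.
#' @param seed optional master-seed override.
#' @return Invisibly, the report (for `report`/`all`) or `NULL`.
#' @export
run_pipeline <- function(config = default_config(), outdir, stage = "all",
                         seed = NULL) {
  if (is.character(config)) config <- read_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  stage <- match.arg(stage, c(PIPELINE_STAGES, "all"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stages <- if (stage == "all") PIPELINE_STAGES else stage
  out <- NULL
  for (st in stages) {
    snf_log("stage: ", st)
    out <- switch(st,
      simulate = stage_simulate(config, outdir),
      cluster = stage_cluster(config, outdir),
      contribution = stage_contribution(config, outdir),
      survival = stage_survival(config, outdir),
      concordance = stage_concordance(config, outdir),
      classify = stage_classify(config, outdir),
      diffexp = stage_diffexp(config, outdir),
      enrich = stage_enrich(config, outdir),
      report = pipeline_report(outdir))
    manifest_update(outdir, st, config,
                    list.files(outdir, full.names = TRUE, recursive = TRUE,
                               pattern = "\\.(tsv|gmt|json|txt)$"))
  }
  invisible(out)
}
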