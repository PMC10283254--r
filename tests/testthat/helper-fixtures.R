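# Shared fixtures, built in code at test time.

# small omics block with controllable structure
make_block <- function(n = 20, f = 6, modality = "protein", seed = 1,
                       values = NULL) {
  if (is.null(values)) {
    set.seed(seed)
    values <- matrix(rnorm(n * f), n, f)
  }
  rownames(values) <- sprintf("S%03d", seq_len(nrow(values)))
  colnames(values) <- sprintf("F%03d", seq_len(ncol(values)))
  omics_block(values, modality)
}

# affinity matrix with two planted blocks and optional cross-block noise
planted_affinity <- function(sizes = c(5, 5), within = 1, between = 0,
                             noise = 0, seed = 1) {
  n <- sum(sizes)
  lab <- rep(seq_along(sizes), sizes)
  W <- matrix(between, n, n)
  for (g in seq_along(sizes)) W[lab == g, lab == g] <- within
  if (noise > 0) {
    set.seed(seed)
    E <- matrix(abs(rnorm(n * n, 0, noise)), n, n)
    W <- W + (E + t(E)) / 2
  }
  diag(W) <- 1
  dimnames(W) <- list(sprintf("S%03d", 1:n), sprintf("S%03d", 1:n))
  attr(W, "labels") <- setNames(lab, rownames(W))
  W
}

# Cohort baseline counts (by molecular subtype) reconstructed as a
# per-subject clinical frame: each categorical variable is expanded from
# its printed per-subtype counts.
baseline_counts_clinical <- function() {
  expand <- function(counts1, counts2, levels) {
    c(rep(levels, counts1), rep(levels, counts2))
  }
  n1 <- 105; n2 <- 127
  data.frame(
    subject = sprintf("S%03d", 1:(n1 + n2)),
    sex = expand(c(83, 22), c(89, 38), c("M", "F")),
    ever_smoker = expand(c(73, 32), c(83, 44), c("Y", "N")),
    # one subtype-2 subject carries missing medical history, so the
    # diabetes column has 126 + 1 NA entries in that group
    diabetes = c(rep(c("Y", "N"), c(24, 81)),
                 rep(c("Y", "N"), c(19, 107)), NA)[c(1:105, 232, 106:231)],
    antifibrotic = expand(c(24, 41, 40), c(18, 43, 66),
                          c("nintedanib", "pirfenidone", "neither")),
    gap_stage = expand(c(22, 64, 19), c(40, 71, 16), c("1", "2", "3")),
    diagnostic_category = expand(c(77, 22, 6), c(95, 29, 3),
                                 c("definite", "probable", "possible")),
    stringsAsFactors = FALSE)
}

baseline_counts_labels <- function() {
  setNames(rep(c(1L, 2L), c(105, 127)), sprintf("S%03d", 1:232))
}

# hand-constructed survival fixture: enrollment FVC, visit series, event
# dates, and the hand-computed expected event time/type per subject
endpoint_fixture <- function() {
  enroll <- as.Date("2015-01-01")
  mo <- function(m) enroll + snfsubtypes:::months_to_days(m)
  subj <- sprintf("P%02d", 1:12)
  clinical <- data.frame(
    subject = subj, fvc_pct = 70, enrollment_date = enroll,
    stringsAsFactors = FALSE)
  fvc <- rbind(
    data.frame(subject = "P01", visit_date = mo(c(6, 12)), fvc_pct = c(65, 58)),
    data.frame(subject = "P02", visit_date = mo(c(4, 12)), fvc_pct = c(66, 62)),
    data.frame(subject = "P03", visit_date = mo(c(6, 12)), fvc_pct = c(55, 50)),
    data.frame(subject = "P04", visit_date = mo(12), fvc_pct = 58),
    data.frame(subject = "P05", visit_date = mo(c(6, 18)), fvc_pct = c(68, 66)),
    data.frame(subject = "P06", visit_date = mo(6), fvc_pct = 60),
    data.frame(subject = "P07", visit_date = mo(6), fvc_pct = 69),
    data.frame(subject = "P08", visit_date = mo(c(4, 8)), fvc_pct = c(71, 59)),
    data.frame(subject = "P09", visit_date = mo(30), fvc_pct = 68),
    data.frame(subject = "P10", visit_date = mo(6), fvc_pct = 60.5),
    data.frame(subject = "P11", visit_date = mo(c(4, 8, 16)),
               fvc_pct = c(67, 64, 59.9)),
    data.frame(subject = "P12", visit_date = mo(6), fvc_pct = 65))
  events <- data.frame(
    subject = subj,
    transplant_date = c(NA, NA, NA, NA, NA, NA, mo(8), NA, NA, NA, NA, NA)[
      c(1:12)],
    death_date = c(NA, NA, NA, NA, NA, mo(4), mo(12), NA, NA, NA, NA,
                   mo(20))[c(1:12)],
    last_followup_date = mo(c(12, 12, 12, 12, 18, 4, 8, 8, 30, 6, 16, 20)),
    stringsAsFactors = FALSE)
  events$transplant_date <- as.Date(events$transplant_date,
                                    origin = "1970-01-01")
  events$death_date <- as.Date(events$death_date, origin = "1970-01-01")
  # hand-computed progression outcomes (10-point absolute decline rule):
  # P01 drop 5 @6 then 12 @12 -> decline at 12; P02 drops 4, 8 -> censored 12
  # P03 drop 15 @6 -> decline at 6; P04 drop 12 @12 -> decline at 12
  # P05 drops 2,4 -> censored 18; P06 death @4 before any qualifying visit
  # P07 transplant @8 precedes death @12, visit drop 1 -> transplant at 8
  # P08 drop @8 -> decline at 8 (4-month visit does not qualify)
  # P09 drop 2 @30 -> censored 30; P10 drop 9.5 -> censored 6 (boundary < 10)
  # P11 drop 10.1 @16 -> decline at 16 (boundary >= 10)
  # P12 drop 5 @6, death @20 -> death at 20
  expected <- data.frame(
    subject = subj,
    time = c(12, 12, 6, 12, 18, 4, 8, 8, 30, 6, 16, 20),
    event = c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE,
              FALSE, TRUE, TRUE),
    type = c("fvc_decline", "censored", "fvc_decline", "fvc_decline",
             "censored", "death", "transplant", "fvc_decline", "censored",
             "censored", "fvc_decline", "death"),
    stringsAsFactors = FALSE)
  list(clinical = clinical, fvc = fvc, events = events, expected = expected)
}

# preprocess a simulated study the way the pipeline does
preprocess_study <- function(study, torna_q = 0.10) {
  blocks <- list(study$blocks$protein, study$blocks$mirna,
                 variance_filter(study$blocks$torna, torna_q))
  align_subjects(lapply(blocks, standardize_features))
}
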