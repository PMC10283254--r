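# Internal helpers: seeded evaluation, seed derivation, label matching,
# agreement indices, rank AUC.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded internals never disturb the
#' caller's RNG stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

# Deterministic fan-out of a master seed into per-stage/per-iteration seeds.
# Kept strictly below 2^31 - 1 so the result is always a valid integer seed.
derive_seed <- function(seed, salt) {
  seed <- as.double(seed %% 2147483647L)
  salt <- as.double(salt %% 2147483647L)
  as.integer((seed * 48271 + salt * 16807 + 11) %% 2147483647)
}

# Lightweight logging: message() with a package tag so callers can suppress.
snf_log <- function(...) {
  message("[snfsubtypes] ", ...)
}

# Exact maximum-weight one-to-one assignment on a square k x k matrix by
# dynamic programming over column subsets (O(k * 2^k); k is a cluster
# count, always small). Returns the column assigned to each row.
solve_assignment <- function(w) {
  k <- nrow(w)
  full <- bitwShiftL(1L, k) - 1L
  dp <- rep(-Inf, full + 1L)
  choice <- integer(full + 1L)
  dp[1] <- 0
  n_bits <- vapply(0:full, function(m) sum(bitwAnd(m, bitwShiftL(1L, 0:(k - 1))) > 0), 0L)
  for (mask in 1:full) {
    r <- n_bits[mask + 1L]          # rows 1..r assigned to columns in mask
    for (j in seq_len(k)) {
      bit <- bitwShiftL(1L, j - 1L)
      if (bitwAnd(mask, bit) == 0) next
      cand <- dp[mask - bit + 1L] + w[r, j]
      if (cand > dp[mask + 1L]) {
        dp[mask + 1L] <- cand
        choice[mask + 1L] <- j
      }
    }
  }
  perm <- integer(k)
  mask <- full
  for (r in rev(seq_len(k))) {
    j <- choice[mask + 1L]
    perm[r] <- j
    mask <- mask - bitwShiftL(1L, j - 1L)
  }
  perm
}

#' Match cluster labels between two assignments
#'
#' Finds the one-to-one label pairing that maximizes agreement (optimal
#' assignment on the confusion matrix) and returns `labels` relabelled into
#' the reference labelling's terms. Used before any cross-run label
#' comparison so that arbitrary cluster numbering never masquerades as
#' disagreement.
#'
#' @param labels integer vector of cluster labels to be relabelled.
#' @param reference integer vector of reference labels, same length.
#' @return Integer vector: `labels` mapped onto the reference numbering.
#' @export
match_labels <- function(labels, reference) {
  stopifnot(length(labels) == length(reference))
  la <- sort(unique(labels))
  lr <- sort(unique(reference))
  k <- max(length(la), length(lr))
  conf <- matrix(0, k, k)
  for (i in seq_along(la))
    for (j in seq_along(lr))
      conf[i, j] <- sum(labels == la[i] & reference == lr[j])
  perm <- solve_assignment(conf)
  out <- labels
  for (i in seq_along(la)) {
    target <- if (perm[i] <= length(lr)) lr[perm[i]]
              else max(lr) + (perm[i] - length(lr))
    out[labels == la[i]] <- target
  }
  out
}

#' Adjusted Rand index between two partitions
#'
#' Hubert-Arabie adjusted Rand index; 1 for identical partitions (up to
#' label names), ~0 for independent ones.
#'
#' @param a,b label vectors over the same subjects.
#' @return Numeric scalar.
#' @export
adjusted_rand <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

# Rank (Mann-Whitney) AUC of `scores` for predicting `positive` (logical).
# Returns NA when either class is absent.
auc_rank <- function(scores, positive) {
  positive <- as.logical(positive)
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# months <-> days conversion used for all survival times
DAYS_PER_MONTH <- 30.4375

days_to_months <- function(d) as.numeric(d) / DAYS_PER_MONTH
months_to_days <- function(m) round(m * DAYS_PER_MONTH)
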