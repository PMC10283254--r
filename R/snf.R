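# Similarity network fusion: scaled-exponential affinity kernels, the
# full/KNN normalization pair, and the iterative cross-diffusion update
# that fuses per-modality patient-similarity networks.

#' SNF hyperparameters
#'
#' @param K neighbourhood size for the kernel bandwidth and the sparse
#'   diffusion operator. Must be smaller than the number of subjects.
#' @param mu kernel bandwidth scaling (positive).
#' @param t_iter number of cross-diffusion iterations (>= 1).
#' @return An object of class `snf_params`.
#' @export
snf_params <- function(K = 20, mu = 0.5, t_iter = 20) {
  if (mu <= 0) stop("mu must be positive")
  if (K < 1) stop("K must be >= 1")
  if (t_iter < 1) stop("t_iter must be >= 1")
  structure(list(K = as.integer(K), mu = mu, t_iter = as.integer(t_iter)),
            class = "snf_params")
}

#' Euclidean distance matrix between subjects
#'
#' @param block an [omics_block()] (expected standardized).
#' @return Symmetric n x n matrix with zero diagonal, subject IDs on both
#'   axes.
#' @export
pairwise_distance <- function(block) {
  if (length(block$subject_ids) == 0) stop("empty block")
  D <- as.matrix(stats::dist(block$values))
  dimnames(D) <- list(block$subject_ids, block$subject_ids)
  D
}

#' Scaled exponential similarity kernel
#'
#' Converts distances into affinities with a locally adaptive bandwidth:
#' for pair (i, j), `eps(i,j)` averages i's mean distance to its K nearest
#' neighbours, j's, and `d(i,j)` itself, and
#' `W(i,j) = exp(-d(i,j)^2 / (mu * eps(i,j)))`. The diagonal is 1 by
#' construction and W is symmetric because eps is.
#'
#' @param D symmetric distance matrix.
#' @param params an [snf_params()]; `K` must satisfy `K < n`.
#' @return Symmetric nonnegative affinity matrix with unit diagonal.
#' @export
affinity_from_distance <- function(D, params = snf_params()) {
  n <- nrow(D)
  if (params$K >= n) stop("K must be smaller than the number of subjects")
  # mean distance of each subject to its K nearest neighbours (self excluded)
  mk <- vapply(seq_len(n), function(i) {
    di <- sort(D[i, -i], partial = params$K)[seq_len(params$K)]
    mean(di)
  }, 0)
  eps <- (outer(mk, mk, "+") + D) / 3
  if (any(eps <= 0))
    stop("zero kernel bandwidth: subjects with all-identical profiles; ",
         "jitter the data or remove duplicates")
  W <- exp(-D^2 / (params$mu * eps))
  (W + t(W)) / 2
}

#' Full (global) normalization of an affinity matrix
#'
#' Returns the row-stochastic matrix carrying global structure:
#' `P(i,i) = 1/2` and, for j != i,
#' `P(i,j) = W(i,j) / (2 * sum_{k != i} W(i,k))`, so every row sums to 1
#' with half its mass on the diagonal. This is the "status" form the
#' diffusion maintains each iteration.
#'
#' @param W affinity matrix.
#' @return Row-stochastic matrix P.
#' @export
full_normalize <- function(W) {
  W0 <- W
  diag(W0) <- 0          # sum off-diagonal mass directly: subtracting the
  off <- rowSums(W0)     # diagonal underflows when affinities are tiny
  if (any(off <= 0))
    stop("row(s) with zero off-diagonal mass; cannot normalize")
  P <- W / (2 * off)
  diag(P) <- 0.5
  P
}

#' K-nearest-neighbour normalization of an affinity matrix
#'
#' Sparse row-stochastic operator used to diffuse information: each row
#' keeps only its K strongest off-diagonal affinities (ties broken by
#' column order), renormalized to sum to 1.
#'
#' @param W affinity matrix.
#' @param K neighbourhood size (`K <= n - 1`).
#' @return Row-stochastic sparse (masked) matrix S.
#' @export
knn_normalize <- function(W, K) {
  n <- nrow(W)
  if (K >= n) stop("K must be smaller than the number of subjects")
  S <- matrix(0, n, n, dimnames = dimnames(W))
  for (i in seq_len(n)) {
    w <- W[i, ]
    w[i] <- -Inf
    nb <- order(w, decreasing = TRUE)[seq_len(K)]
    tot <- sum(W[i, nb])
    if (tot <= 0) stop("row ", i, " has zero mass on its neighbourhood")
    S[i, nb] <- W[i, nb] / tot
  }
  S
}

#' Fuse per-modality networks by iterative cross-diffusion
#'
#' Each modality's status matrix is replaced by
#' `S_v %*% mean(P_others) %*% t(S_v)` (synchronously across modalities),
#' then re-symmetrized; from the second iteration on, statuses are first
#' re-normalized to the P-form (diagonal 1/2, off-diagonal mass halved) so
#' the diagonal stays regularized throughout the diffusion. The fused
#' network is the symmetrized average of the final statuses. With two
#' modalities and `t_iter = 1` this reduces to the closed form
#' `(S1 P2 S1' + S2 P1 S2') / 2`.
#'
#' @param P_list list of full-normalized status matrices (one per
#'   modality, identical subject order).
#' @param S_list list of matching KNN-normalized operators.
#' @param params an [snf_params()] (only `t_iter` is used here).
#' @return An object of class `fused_network`: `W` (fused matrix),
#'   `modalities`, `params`.
#' @export
snf_fuse <- function(P_list, S_list, params = snf_params()) {
  V <- length(P_list)
  if (V < 2) stop("need at least two modalities to fuse")
  if (length(S_list) != V) stop("P_list and S_list lengths differ")
  dims <- vapply(c(P_list, S_list), nrow, 0L)
  if (length(unique(dims)) != 1)
    stop("dimension mismatch across modalities")
  P <- P_list
  for (t in seq_len(params$t_iter)) {
    if (t > 1) P <- lapply(P, full_normalize)
    P <- lapply(seq_len(V), function(v) {
      avg <- Reduce(`+`, P[-v]) / (V - 1)
      M <- S_list[[v]] %*% avg %*% t(S_list[[v]])
      (M + t(M)) / 2
    })
  }
  fused <- Reduce(`+`, P) / V
  fused <- (fused + t(fused)) / 2
  dimnames(fused) <- dimnames(P_list[[1]])
  structure(list(W = fused,
                 modalities = names(P_list) %||% paste0("modality", seq_len(V)),
                 params = params),
            class = "fused_network")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.fused_network <- function(x, ...) {
  cat(sprintf("<fused_network> %d subjects, modalities: %s (K=%d, mu=%g, T=%d)\n",
              nrow(x$W), paste(x$modalities, collapse = ", "),
              x$params$K, x$params$mu, x$params$t_iter))
  invisible(x)
}

#' Build and fuse similarity networks from standardized blocks
#'
#' Convenience wrapper: Euclidean distances per modality, affinity
#' kernels, the normalization pair, then [snf_fuse()].
#'
#' @param dataset a `multi_omics_dataset` from [align_subjects()] whose
#'   blocks are standardized.
#' @param params an [snf_params()].
#' @return A `fused_network`.
#' @export
snf <- function(dataset, params = snf_params()) {
  W_list <- lapply(dataset$blocks, function(b)
    affinity_from_distance(pairwise_distance(b), params))
  P_list <- lapply(W_list, full_normalize)
  S_list <- lapply(W_list, knn_normalize, K = params$K)
  snf_fuse(P_list, S_list, params)
}

#' Write a fused network as square TSV
#'
#' @param net a `fused_network` (or plain square matrix).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fused_network <- function(net, path) {
  W <- if (inherits(net, "fused_network")) net$W else net
  df <- data.frame(subject = rownames(W), W, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
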