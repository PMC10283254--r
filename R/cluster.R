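# Spectral clustering on affinity matrices, consensus clustering over
# subject subsamples, silhouette-based selection of k, and agreement
# metrics (NMI, modality contribution).

#' Spectral clustering of an affinity matrix
#'
#' Builds the symmetric-normalized graph Laplacian of `W`, embeds subjects
#' in the k eigenvectors of smallest Laplacian eigenvalue, row-normalizes
#' the embedding and partitions it with k-means over deterministic seeded
#' restarts (best within-cluster sum of squares wins; ties go to the
#' earliest restart). Labels are canonicalized so cluster 1 contains the
#' lexicographically smallest subject identifier.
#'
#' @param W symmetric nonnegative affinity matrix (subject IDs as
#'   dimnames; row indices used otherwise).
#' @param k number of clusters, `2 <= k < n`.
#' @param seed master seed for the k-means restarts.
#' @param nstart number of seeded k-means restarts.
#' @return An object of class `cluster_assignment`: named integer `labels`
#'   in 1..k, plus `k`.
#' @export
spectral_cluster <- function(W, k, seed = 0L, nstart = 25L) {
  n <- nrow(W)
  if (k < 2 || k >= n) stop("k must satisfy 2 <= k < n")
  ids <- rownames(W) %||% sprintf("%d", seq_len(n))
  W <- unname(W)
  diag(W) <- 0   # self-loops carry no pairwise information and can swamp
                 # the spectrum when off-diagonal affinities are small
  d <- pmax(rowSums(W), .Machine$double.eps)
  inv <- 1 / sqrt(d)
  A <- W * outer(inv, inv)            # D^{-1/2} W D^{-1/2}
  A <- (A + t(A)) / 2
  emb <- eigen(A, symmetric = TRUE)$vectors[, seq_len(k), drop = FALSE]
  rn <- sqrt(rowSums(emb^2))
  emb <- emb / pmax(rn, .Machine$double.eps)

  best <- NULL
  for (r in seq_len(nstart)) {
    # Hartigan-Wong warns on nearly duplicated rows (Quick-TRANSfer); the
    # result is still valid and the best restart wins, so keep it quiet
    km <- with_seed(derive_seed(seed, r), tryCatch(
      suppressWarnings(stats::kmeans(emb, centers = k, iter.max = 100L)),
      error = function(e) NULL))
    if (!is.null(km) && (is.null(best) || km$tot.withinss < best$tot.withinss - 1e-12))
      best <- km
  }
  if (is.null(best)) {
    # degenerate embeddings (e.g. exact duplicate rows, fewer unique rows
    # than restarts can seed): cluster the unique rows directly
    uu <- unique(round(emb, 10))
    if (nrow(uu) < k) stop("fewer distinct embedding rows than clusters")
    key <- apply(round(emb, 10), 1, paste, collapse = ",")
    ukey <- apply(uu, 1, paste, collapse = ",")
    labels <- match(key, ukey)
    labels <- ((labels - 1) %% k) + 1
  } else {
    labels <- best$cluster
  }
  cluster_assignment(stats::setNames(as.integer(labels), ids), k)
}

#' Construct (and canonicalize) a cluster assignment
#'
#' @param labels named integer vector of cluster labels.
#' @param k number of clusters.
#' @return A `cluster_assignment`.
#' @export
cluster_assignment <- function(labels, k = length(unique(labels))) {
  if (is.null(names(labels))) stop("labels must be named by subject")
  # canonical numbering: clusters ordered by the lexicographic rank of
  # their smallest member, so repeated runs report stable labels
  present <- unique(labels[order(names(labels))])
  map <- stats::setNames(seq_along(present), present)
  out <- as.integer(map[as.character(labels)])
  names(out) <- names(labels)
  structure(list(labels = out, k = as.integer(k)),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> %d subjects in %d clusters (%s)\n",
              length(x$labels), x$k,
              paste(table(x$labels), collapse = "/")))
  invisible(x)
}

as_labels <- function(x) {
  if (inherits(x, "cluster_assignment")) x$labels else x
}

#' Consensus clustering over subject subsamples
#'
#' Repeatedly subsamples `floor(ratio * n)` subjects without replacement,
#' spectral-clusters the restricted affinity matrix, and accumulates
#' co-clustering and co-sampling counts. The consensus matrix is their
#' elementwise ratio; the final assignment spectral-clusters the consensus
#' matrix itself (treated as an affinity) at the same k.
#'
#' @param W affinity matrix.
#' @param k number of clusters.
#' @param iterations number of subsampling iterations.
#' @param ratio subsampling ratio in (0, 1].
#' @param seed master seed.
#' @param nstart k-means restarts inside each spectral run.
#' @return An object of class `consensus_result`: `consensus` (proportion
#'   matrix), `co_sampled` (count matrix), `assignment`, `iterations`,
#'   `ratio`, `k`.
#' @export
consensus_cluster <- function(W, k, iterations = 100L, ratio = 0.8,
                              seed = 0L, nstart = 25L) {
  n <- nrow(W)
  m <- floor(ratio * n)
  if (m < k + 1) stop("subsample too small for k clusters")
  co_cluster <- matrix(0, n, n)
  co_sample <- matrix(0, n, n)
  for (it in seq_len(iterations)) {
    idx <- with_seed(derive_seed(seed, it), sort(sample.int(n, m)))
    ca <- spectral_cluster(W[idx, idx, drop = FALSE], k,
                           seed = derive_seed(seed, 100000L + it),
                           nstart = nstart)
    Z <- outer(ca$labels, seq_len(k), `==`) * 1
    co_cluster[idx, idx] <- co_cluster[idx, idx] + Z %*% t(Z)
    co_sample[idx, idx] <- co_sample[idx, idx] + 1
  }
  if (any(co_sample == 0))
    stop("some subject pair was never co-sampled; increase iterations")
  consensus <- co_cluster / co_sample
  dimnames(consensus) <- dimnames(W)
  assignment <- spectral_cluster(consensus, k,
                                 seed = derive_seed(seed, 999999L),
                                 nstart = nstart)
  structure(list(consensus = consensus, co_sampled = co_sample,
                 assignment = assignment, iterations = iterations,
                 ratio = ratio, k = as.integer(k)),
            class = "consensus_result")
}

# Mean silhouette of a labelling under a dissimilarity matrix D.
# Singleton clusters score 0 by convention.
mean_silhouette <- function(labels, D) {
  labels <- as_labels(labels)
  n <- length(labels)
  ks <- sort(unique(labels))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1) { s[i] <- 0; next }
    a <- mean(D[i, own & seq_len(n) != i])
    b <- min(vapply(ks[ks != labels[i]], function(g)
      mean(D[i, labels == g]), 0))
    denom <- max(a, b)
    s[i] <- if (denom > 0) (b - a) / denom else 0
  }
  mean(s)
}

#' Silhouette profile over candidate cluster numbers
#'
#' For each k in `k_range`, runs its own consensus clustering and scores
#' the resulting labels with the mean silhouette under dissimilarity
#' `1 - consensus(i, j)` for that k's consensus matrix.
#'
#' @param W affinity matrix (typically the fused network).
#' @param k_range contiguous integer range of candidate k (default 2..10).
#' @param iterations,ratio,seed,nstart passed to [consensus_cluster()].
#' @return An object of class `silhouette_profile`: `scores` (named by
#'   k), `k_range`, and `runs` (the per-k `consensus_result`s).
#' @export
silhouette_profile <- function(W, k_range = 2:10, iterations = 100L,
                               ratio = 0.8, seed = 0L, nstart = 25L) {
  n <- nrow(W)
  if (min(k_range) < 2 || max(k_range) > n - 1)
    stop("k_range must lie within [2, n-1]")
  runs <- lapply(k_range, function(k)
    consensus_cluster(W, k, iterations = iterations, ratio = ratio,
                      seed = derive_seed(seed, 1000L * k), nstart = nstart))
  names(runs) <- as.character(k_range)
  scores <- vapply(runs, function(r)
    mean_silhouette(r$assignment, 1 - r$consensus), 0)
  structure(list(scores = scores, k_range = k_range, runs = runs),
            class = "silhouette_profile")
}

#' Select the number of clusters from a silhouette profile
#'
#' Argmax of the mean silhouette; ties resolve to the smallest k.
#'
#' @param profile a [silhouette_profile()].
#' @return Integer k.
#' @export
select_k <- function(profile) {
  as.integer(profile$k_range[which.max(profile$scores)])
}

#' @export
print.silhouette_profile <- function(x, ...) {
  cat("<silhouette_profile>\n")
  print(round(x$scores, 4))
  cat("selected k:", select_k(x), "\n")
  invisible(x)
}

#' Normalized mutual information between two labelings
#'
#' Mutual information of the label contingency table normalized by the
#' geometric mean of the two label entropies. Invariant to label names;
#' 1 for identical partitions. When both labelings are single-cluster
#' (both entropies zero) the agreement is perfect and NMI is defined as 1;
#' when exactly one is single-cluster, NMI is 0.
#'
#' @param a,b `cluster_assignment`s or named label vectors over the same
#'   subjects.
#' @return NMI in \[0, 1\].
#' @export
nmi <- function(a, b) {
  a <- as_labels(a); b <- as_labels(b)
  if (!is.null(names(a)) && !is.null(names(b))) {
    if (!setequal(names(a), names(b)))
      stop("mismatched subject sets")
    b <- b[names(a)]
  } else if (length(a) != length(b)) {
    stop("mismatched subject sets")
  }
  tab <- table(a, b)
  n <- sum(tab)
  pij <- tab / n
  pi <- rowSums(pij); pj <- colSums(pij)
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  ha <- ent(pi); hb <- ent(pj)
  if (ha == 0 && hb == 0) return(1)
  if (ha == 0 || hb == 0) return(0)
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / outer(pi, pj)[nz]))
  max(0, min(1, mi / sqrt(ha * hb)))
}

#' Per-modality contribution to the fused clustering
#'
#' Clusters each modality on its own (same affinity construction and
#' consensus procedure, at the selected k) and reports agreement with the
#' fused labels as NMI. Near-zero NMI identifies a modality that did not
#' shape the fused subtypes.
#'
#' @param dataset a `multi_omics_dataset` of standardized blocks.
#' @param fused_labels `cluster_assignment` from the fused network.
#' @param k number of clusters (the selected k).
#' @param params an [snf_params()] (kernel settings reused per modality).
#' @param iterations,ratio,seed passed to [consensus_cluster()].
#' @return Named numeric vector: modality -> NMI with the fused labels.
#' @export
modality_contribution <- function(dataset, fused_labels, k,
                                  params = snf_params(),
                                  iterations = 100L, ratio = 0.8,
                                  seed = 0L) {
  vapply(names(dataset$blocks), function(m) {
    W <- affinity_from_distance(pairwise_distance(dataset$blocks[[m]]), params)
    # degree-normalize (the diffusion status form) before clustering: raw
    # kernels can have degree spreads of orders of magnitude, which
    # localize the Laplacian eigenvectors on hubs instead of clusters
    P <- full_normalize(W)
    P <- (P + t(P)) / 2
    cc <- consensus_cluster(P, k, iterations = iterations, ratio = ratio,
                            seed = derive_seed(seed, match(m, names(dataset$blocks))))
    nmi(cc$assignment, fused_labels)
  }, 0)
}
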