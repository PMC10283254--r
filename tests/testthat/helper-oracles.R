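# straight-line transcription of the kernel and diffusion update, kept
# deliberately naive (double loops) as an independent oracle
oracle_affinity <- function(D, K, mu) {
  n <- nrow(D)
  W <- matrix(0, n, n)
  mk <- numeric(n)
  for (i in 1:n) mk[i] <- mean(sort(D[i, -i])[1:K])
  for (i in 1:n) for (j in 1:n) {
    eps <- (mk[i] + mk[j] + D[i, j]) / 3
    W[i, j] <- exp(-D[i, j]^2 / (mu * eps))
  }
  (W + t(W)) / 2
}

oracle_pform <- function(W) {
  n <- nrow(W)
  P <- matrix(0, n, n)
  for (i in 1:n) {
    denom <- 2 * sum(W[i, -i])
    for (j in 1:n) P[i, j] <- if (i == j) 0.5 else W[i, j] / denom
  }
  P
}

oracle_sform <- function(W, K) {
  n <- nrow(W)
  S <- matrix(0, n, n)
  for (i in 1:n) {
    nb <- setdiff(order(W[i, ], decreasing = TRUE), i)[1:K]
    for (j in nb) S[i, j] <- W[i, j] / sum(W[i, nb])
  }
  S
}

oracle_fuse <- function(P_list, S_list, t_iter) {
  V <- length(P_list)
  P <- P_list
  for (t in 1:t_iter) {
    if (t > 1) P <- lapply(P, oracle_pform)
    Pn <- vector("list", V)
    for (v in 1:V) {
      avg <- Reduce(`+`, P[-v]) / (V - 1)
      M <- S_list[[v]] %*% avg %*% t(S_list[[v]])
      Pn[[v]] <- (M + t(M)) / 2
    }
    P <- Pn
  }
  F <- Reduce(`+`, P) / V
  (F + t(F)) / 2
}

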