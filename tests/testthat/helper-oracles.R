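# Independent brute-force oracles and shared toy fixtures.

# NODF by the literal pairwise definition: double loop over ordered
# row pairs and column pairs, overlap over the smaller marginal,
# zero for equal marginals.
nodf_oracle <- function(A) {
  A <- (unclass(A) != 0) * 1
  pair_sum <- function(M) {
    n <- nrow(M)
    tot <- 0
    np <- 0
    if (n < 2) return(c(0, 0))
    k <- rowSums(M)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        np <- np + 1
        if (k[i] != k[j] && min(k[i], k[j]) > 0) {
          ov <- sum(M[i, ] == 1 & M[j, ] == 1)
          tot <- tot + 100 * ov / min(k[i], k[j])
        }
      }
    }
    c(tot, np)
  }
  r <- pair_sum(A)
  cc <- pair_sum(t(A))
  (r[1] + cc[1]) / (r[2] + cc[2])
}

# Barber Q by direct triple-loop summation of the defining formula.
barber_oracle <- function(A, hm, gm) {
  A <- (unclass(A) != 0) * 1
  m <- sum(A)
  if (m == 0) return(0)
  k <- rowSums(A)
  d <- colSums(A)
  q <- 0
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(ncol(A))) {
      if (hm[i] == gm[j]) q <- q + A[i, j] - k[i] * d[j] / m
    }
  }
  as.numeric(q / m)
}

# Betweenness/closeness on an arbitrary adjacency matrix by
# Floyd-Warshall distances and explicit shortest-path counting.
path_oracle <- function(adj) {
  n <- nrow(adj)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[adj == 1] <- 1
  for (k in 1:n) {
    for (i in 1:n) {
      for (j in 1:n) if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
    }
  }
  sig <- matrix(0, n, n)  # sig[v, s] = number of geodesics s -> v
  for (s in 1:n) {
    sg <- numeric(n)
    sg[s] <- 1
    for (v in order(D[s, ])) {
      if (v != s && is.finite(D[s, v])) {
        pred <- which(adj[, v] == 1 & D[s, ] == D[s, v] - 1)
        sg[v] <- sum(sg[pred])
      }
    }
    sig[, s] <- sg
  }
  btw <- numeric(n)
  for (v in 1:n) {
    for (s in 1:(n - 1)) {
      for (t in (s + 1):n) {
        if (s != v && t != v && is.finite(D[s, t]) &&
            D[s, v] + D[v, t] == D[s, t]) {
          btw[v] <- btw[v] + sig[v, s] * sig[t, v] / sig[t, s]
        }
      }
    }
  }
  clo <- apply(D, 1, function(dr) {
    dr <- dr[is.finite(dr) & dr > 0]
    if (length(dr) == 0) 0 else length(dr) / sum(dr)
  })
  list(betweenness = btw / ((n - 1) * (n - 2) / 2), closeness = unname(clo))
}

# full (hosts + guests) adjacency of an incidence matrix
full_adjacency <- function(A) {
  A <- (unclass(A) != 0) * 1
  R <- nrow(A)
  C <- ncol(A)
  rbind(cbind(matrix(0, R, R), A), cbind(t(A), matrix(0, C, C)))
}

# Thompson-Sharp asymmetry regression by the closed-form weighted
# normal equations with multiplicative overdispersion.
thompson_oracle <- function(yi, vi) {
  sei <- sqrt(vi)
  w <- 1 / vi
  X <- cbind(1, sei)
  XtWX <- t(X) %*% (X * w)
  bhat <- solve(XtWX, t(X) %*% (yi * w))
  res <- yi - X %*% bhat
  kk <- length(yi)
  phi <- sum(w * res^2) / (kk - 2)
  covb <- solve(XtWX) * phi
  tstat <- bhat[2] / sqrt(covb[2, 2])
  list(statistic = as.numeric(tstat),
       p = 2 * stats::pt(-abs(tstat), df = kk - 2))
}

named_matrix <- function(M) {
  dimnames(M) <- list(sprintf("h%02d", seq_len(nrow(M))),
                      sprintf("g%02d", seq_len(ncol(M))))
  M
}

staircase_matrix <- function(n = 4) {
  M <- matrix(0L, n, n)
  for (i in seq_len(n)) M[i, seq_len(n - i + 1)] <- 1L
  named_matrix(M)
}

two_block_matrix <- function() {
  M <- matrix(0L, 4, 4)
  M[1:2, 1:2] <- 1L
  M[3:4, 3:4] <- 1L
  named_matrix(M)
}

block_partition <- function(M, hm, gm) {
  list(hosts = stats::setNames(hm, rownames(M)),
       guests = stats::setNames(gm, colnames(M)))
}

# Bernoulli random binary matrix (possibly with empty lines; fine for
# metric-level oracle tests)
rand_matrix <- function(R, C, p, seed) {
  set.seed(seed)
  named_matrix(matrix(stats::rbinom(R * C, 1, p), R, C))
}

planted_blocks <- function(n_blocks, hosts_per, guests_per) {
  hm <- rep(seq_len(n_blocks), each = hosts_per)
  gm <- rep(seq_len(n_blocks), each = guests_per)
  A <- outer(hm, gm, "==") * 1L
  list(A = named_matrix(A), hm = hm, gm = gm)
}
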