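#' Nestedness metric based on overlap and decreasing fill (NODF)
#'
#' For every ordered pair of rows with strictly decreasing marginal
#' totals (`k_i > k_j`) the paired term is `100 * |N_i intersect N_j| /
#' k_j`; pairs with equal totals contribute zero ("decreasing fill").
#' Column pairs are treated identically, and the score is the mean of
#' the paired terms over the full set of row pairs and column pairs
#' together, ranging from 0 (not nested) to 100 (perfectly nested).
#'
#' @param A Binary incidence matrix (any non-zero entry counts as a
#'   link).
#' @return NODF score in `[0, 100]`.
#' @export
nodf <- function(A) {
  A <- (unclass(A) != 0) * 1
  if (nrow(A) < 2 && ncol(A) < 2) {
    stop("NODF is undefined for a single-row, single-column matrix: ",
         "no row or column pairs exist", call. = FALSE)
  }
  part <- function(M) {
    n <- nrow(M)
    if (n < 2) return(c(0, 0))
    k <- rowSums(M)
    O <- tcrossprod(M)
    ut <- upper.tri(O)
    kmin <- outer(k, k, pmin)[ut]
    keep <- outer(k, k, "!=")[ut] & kmin > 0
    c(sum(100 * O[ut][keep] / kmin[keep]), n * (n - 1) / 2)
  }
  rp <- part(A)
  cp <- part(t(A))
  (rp[1] + cp[1]) / (rp[2] + cp[2])
}

#' Barber bipartite modularity Q of a module partition
#'
#' `Q = (1/m) * sum_ij (A_ij - k_i d_j / m) * delta(g_i, g_j)` where
#' `k_i` and `d_j` are host and guest degrees, `m` the number of links,
#' and `delta` indicates co-membership. A single shared module gives
#' exactly 0 for every matrix.
#'
#' @param A Binary incidence matrix with host row names and guest
#'   column names.
#' @param partition A `module_partition`, or a list with named integer
#'   vectors `hosts` and `guests` assigning every species to a module.
#' @return Modularity Q (dimensionless, at most 1).
#' @export
barber_q <- function(A, partition) {
  A <- (unclass(A) != 0) * 1
  hm <- partition$hosts[rownames(A)]
  gm <- partition$guests[colnames(A)]
  if (anyNA(hm) || anyNA(gm)) {
    miss <- c(rownames(A)[is.na(hm)], colnames(A)[is.na(gm)])
    stop("partition does not cover all species; missing: ",
         paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  }
  m <- sum(A)
  if (m == 0) return(0)
  k <- rowSums(A)
  d <- colSums(A)
  q <- 0
  for (s in intersect(unique(hm), unique(gm))) {
    hi <- hm == s
    gi <- gm == s
    q <- q + sum(A[hi, gi, drop = FALSE]) - sum(k[hi]) * sum(d[gi]) / m
  }
  q / m
}

new_module_partition <- function(hosts, guests, Q) {
  ids <- sort(unique(c(hosts, guests)))
  relab <- match(hosts, ids)
  names(relab) <- names(hosts)
  grelab <- match(guests, ids)
  names(grelab) <- names(guests)
  structure(list(hosts = relab, guests = grelab,
                 n_modules = length(ids), Q = Q),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat("Module partition: ", x$n_modules, " modules over ",
      length(x$hosts), " hosts + ", length(x$guests),
      " guests; Barber Q = ", signif(x$Q, 4), "\n", sep = "")
  invisible(x)
}

# links from host i to guests of each module (and the symmetric guest view)
.links_to_modules <- function(Arow, gm, n_mod) {
  out <- numeric(n_mod)
  t <- tapply(Arow, gm, sum)
  out[as.integer(names(t))] <- t
  out
}

#' Find a high-modularity module partition by simulated annealing
#'
#' Stochastic search over bipartite module assignments in the QuanBiMo
#' family: single-species reassignments (to an existing or a fresh
#' module) interleaved with whole-module merge proposals, accepted with
#' probability `exp(dQ / T)` under a geometric cooling schedule. The
#' best partition encountered is polished by a deterministic hill-climb
#' (best single moves to convergence) so the reported Q is a local
#' optimum and never below the best annealed value.
#'
#' @param A Binary incidence matrix.
#' @param steps Number of annealing proposals per restart.
#' @param seed Optional integer seed for reproducibility.
#' @param restarts Independent annealing runs; the best result wins.
#' @param t0,t_end Initial and final temperature as multiples of `1/m`
#'   (the natural scale of single-move Q changes).
#' @param p_merge Fraction of proposals that are module merges.
#' @return A `module_partition` with elements `hosts`, `guests`,
#'   `n_modules` and `Q`.
#' @export
optimize_modules <- function(A, steps = 1e5, seed = NULL, restarts = 2,
                             t0 = 10, t_end = 0.01, p_merge = 0.1) {
  if (!is.null(seed)) set.seed(seed)
  A <- (unclass(A) != 0) * 1
  R <- nrow(A)
  C <- ncol(A)
  m <- sum(A)
  hostn <- rownames(A) %||% paste0("h", seq_len(R))
  guestn <- colnames(A) %||% paste0("g", seq_len(C))
  if (m == 0) {
    hm <- stats::setNames(rep(1L, R), hostn)
    gm <- stats::setNames(rep(1L, C), guestn)
    return(new_module_partition(hm, gm, 0))
  }
  k <- rowSums(A)
  d <- colSums(A)

  q_of <- function(hm, gm) {
    q <- 0
    for (s in unique(hm)) {
      gi <- gm == s
      if (any(gi)) {
        hi <- hm == s
        q <- q + sum(A[hi, gi, drop = FALSE]) - sum(k[hi]) * sum(d[gi]) / m
      }
    }
    q / m
  }

  # move gain for one node: links of the node to guests/hosts of each
  # module, minus the degree-product expectation
  gains <- function(is_host, i, hm, gm, Ks, Ds, n_mod) {
    if (is_host) {
      L <- .links_to_modules(A[i, ], gm, n_mod)
      (L - k[i] * Ds / m) / m
    } else {
      L <- .links_to_modules(A[, i], hm, n_mod)
      (L - d[i] * Ks / m) / m
    }
  }

  anneal_once <- function() {
    # random initial assignment into ~sqrt(min(R, C)) modules
    K <- max(2L, as.integer(ceiling(sqrt(min(R, C)))))
    hm <- sample.int(K, R, replace = TRUE)
    gm <- sample.int(K, C, replace = TRUE)
    n_mod <- K
    Ks <- .links_to_modules(k, hm, n_mod)  # degree mass per module
    Ds <- .links_to_modules(d, gm, n_mod)
    Q <- q_of(hm, gm)
    bestQ <- Q
    best <- list(hm = hm, gm = gm)
    cool <- (t_end / t0)^(1 / max(1, steps))
    Temp <- t0 / m
    for (step in seq_len(steps)) {
      if (stats::runif(1) < p_merge && n_mod > 1) {
        ab <- sample.int(n_mod, 2)
        a <- ab[1]; b <- ab[2]
        ha <- hm == a; hb <- hm == b
        ga <- gm == a; gb <- gm == b
        dq <- (sum(A[ha, gb, drop = FALSE]) + sum(A[hb, ga, drop = FALSE]) -
                 (Ks[a] * Ds[b] + Ks[b] * Ds[a]) / m) / m
        if (dq > 0 || stats::runif(1) < exp(dq / Temp)) {
          hm[hb] <- a; gm[gb] <- a
          Ks[a] <- Ks[a] + Ks[b]; Ks[b] <- 0
          Ds[a] <- Ds[a] + Ds[b]; Ds[b] <- 0
          Q <- Q + dq
        }
      } else {
        is_host <- stats::runif(1) < R / (R + C)
        i <- if (is_host) sample.int(R, 1) else sample.int(C, 1)
        cur <- if (is_host) hm[i] else gm[i]
        g <- gains(is_host, i, hm, gm, Ks, Ds, n_mod)
        # candidate: any existing module or a fresh empty one (gain 0)
        tgt <- sample.int(n_mod + 1L, 1)
        gt <- if (tgt > n_mod) 0 else g[tgt]
        dq <- gt - g[cur]
        if (tgt != cur && (dq > 0 || stats::runif(1) < exp(dq / Temp))) {
          if (tgt > n_mod) {
            n_mod <- n_mod + 1L
            Ks <- c(Ks, 0); Ds <- c(Ds, 0)
          }
          if (is_host) {
            hm[i] <- tgt
            Ks[cur] <- Ks[cur] - k[i]; Ks[tgt] <- Ks[tgt] + k[i]
          } else {
            gm[i] <- tgt
            Ds[cur] <- Ds[cur] - d[i]; Ds[tgt] <- Ds[tgt] + d[i]
          }
          Q <- Q + dq
          if (Q > bestQ + 1e-12) {
            bestQ <- Q
            best <- list(hm = hm, gm = gm)
          }
        }
      }
      Temp <- Temp * cool
    }
    list(hm = best$hm, gm = best$gm, Q = bestQ)
  }

  hill_climb <- function(hm, gm) {
    n_mod <- max(hm, gm)
    Ks <- .links_to_modules(k, hm, n_mod)
    Ds <- .links_to_modules(d, gm, n_mod)
    repeat {
      improved <- FALSE
      for (i in seq_len(R + C)) {
        is_host <- i <= R
        idx <- if (is_host) i else i - R
        cur <- if (is_host) hm[idx] else gm[idx]
        g <- gains(is_host, idx, hm, gm, Ks, Ds, n_mod)
        g <- c(g, 0)  # fresh module
        tgt <- which.max(g)
        if (g[tgt] > g[cur] + 1e-12) {
          if (tgt > n_mod) {
            n_mod <- n_mod + 1L
            Ks <- c(Ks, 0); Ds <- c(Ds, 0)
          }
          if (is_host) {
            hm[idx] <- tgt
            Ks[cur] <- Ks[cur] - k[idx]; Ks[tgt] <- Ks[tgt] + k[idx]
          } else {
            gm[idx] <- tgt
            Ds[cur] <- Ds[cur] - d[idx]; Ds[tgt] <- Ds[tgt] + d[idx]
          }
          improved <- TRUE
        }
      }
      if (!improved) break
    }
    list(hm = hm, gm = gm)
  }

  best <- NULL
  for (r in seq_len(max(1, restarts))) {
    cand <- anneal_once()
    pol <- hill_climb(cand$hm, cand$gm)
    Q <- q_of(pol$hm, pol$gm)
    if (is.null(best) || Q > best$Q) {
      best <- list(hm = pol$hm, gm = pol$gm, Q = Q)
    }
  }
  hm <- stats::setNames(best$hm, hostn)
  gm <- stats::setNames(best$gm, guestn)
  new_module_partition(hm, gm, best$Q)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate null incidence matrices
#'
#' Two binary null models. `"fill"` (the default) places the observed
#' number of links uniformly at random among all cells, preserving the
#' matrix dimensions and connectance. `"marginals"` runs curveball
#' trades from the observed matrix, preserving every row and column
#' total exactly.
#'
#' @param A Binary incidence matrix.
#' @param n Number of null matrices.
#' @param model `"fill"` or `"marginals"`.
#' @param seed Optional integer seed.
#' @param n_swaps Curveball trades per draw (marginals model).
#' @return List of `n` binary matrices with the dimnames of `A`.
#' @export
null_matrices <- function(A, n, model = c("fill", "marginals"),
                          seed = NULL, n_swaps = NULL) {
  model <- match.arg(model)
  if (!is.null(seed)) set.seed(seed)
  A <- (unclass(A) != 0) * 1L
  R <- nrow(A)
  C <- ncol(A)
  m <- sum(A)
  if (model == "fill") {
    if (m > R * C) stop("more links than cells: impossible fill", call. = FALSE)
    lapply(seq_len(n), function(i) {
      B <- matrix(0L, R, C, dimnames = dimnames(A))
      B[sample.int(R * C, m)] <- 1L
      B
    })
  } else {
    if (is.null(n_swaps)) n_swaps <- max(1000L, 5L * R)
    # curveball: trade the non-shared guests of two random hosts
    lapply(seq_len(n), function(i) {
      B <- A
      for (s in seq_len(n_swaps)) {
        ij <- sample.int(R, 2)
        ri <- B[ij[1], ] == 1L
        rj <- B[ij[2], ] == 1L
        i_only <- which(ri & !rj)
        j_only <- which(rj & !ri)
        pool <- c(i_only, j_only)
        if (length(i_only) == 0 || length(j_only) == 0) next
        pick <- sample(pool, length(i_only))
        B[ij[1], pool] <- 0L
        B[ij[2], pool] <- 0L
        B[ij[1], pick] <- 1L
        B[ij[2], setdiff(pool, pick)] <- 1L
      }
      B
    })
  }
}

#' Null-model significance of nestedness or modularity
#'
#' Compares the observed metric with its distribution over a null
#' ensemble. For modularity every null matrix is optimized with the
#' same annealing step budget as the observed one. The p-value is the
#' one-sided upper-tail proportion with the `(r + 1) / (n + 1)`
#' continuity correction, so it is never exactly zero.
#'
#' @param A Binary incidence matrix.
#' @param metric `"nodf"` or `"modularity"`.
#' @param n_null Ensemble size (the study design uses 1000).
#' @param model Null model passed to [null_matrices()].
#' @param seed Optional integer seed covering ensemble generation and,
#'   for modularity, the per-matrix optimizations.
#' @param steps,restarts Annealing budget per matrix (modularity only).
#' @return A `null_ensemble` list: `metric`, `observed`, `null_values`,
#'   `z` (`NA` when the null spread is zero), `p`, `model`.
#' @export
significance <- function(A, metric = c("nodf", "modularity"),
                         n_null = 1000, model = c("fill", "marginals"),
                         seed = NULL, steps = 1e4, restarts = 1) {
  metric <- match.arg(metric)
  model <- match.arg(model)
  if (n_null < 100) stop("n_null must be at least 100", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  f <- if (metric == "nodf") {
    nodf
  } else {
    function(M) optimize_modules(M, steps = steps, restarts = restarts)$Q
  }
  obs <- f(A)
  nulls <- null_matrices(A, n_null, model = model)
  nv <- vapply(nulls, f, numeric(1))
  s <- stats::sd(nv)
  z <- if (s == 0) NA_real_ else (obs - mean(nv)) / s
  p <- (sum(nv >= obs) + 1) / (n_null + 1)
  structure(list(metric = metric, observed = obs, null_values = nv,
                 z = z, p = p, model = model, n_null = n_null),
            class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat("Null-model test (", x$model, " model, n = ", x$n_null, ")\n",
      "  ", x$metric, " observed = ", signif(x$observed, 4),
      ", null mean = ", signif(mean(x$null_values), 4),
      ", z = ", signif(x$z, 3), ", p = ", signif(x$p, 3), "\n", sep = "")
  invisible(x)
}
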