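#' Host degrees
#'
#' Number of guest species linked to each host: the row sums of the
#' binary incidence matrix.
#'
#' @param A Binary incidence matrix.
#' @param host Optional host name (or vector of names) to look up.
#' @return Named integer vector of degrees.
#' @export
host_degree <- function(A, host = NULL) {
  k <- rowSums(unclass(A) != 0)
  if (is.null(host)) return(k)
  if (!all(host %in% names(k))) {
    stop("unknown host: ", paste(setdiff(host, names(k)), collapse = ", "),
         call. = FALSE)
  }
  k[host]
}

# the bipartite graph as an undirected igraph over hosts + guests;
# optionally the one-mode host projection
.as_graph <- function(A, projection = FALSE) {
  A <- (unclass(A) != 0) * 1
  g <- igraph::graph_from_biadjacency_matrix(A)
  if (projection) {
    igraph::bipartite_projection(g, which = "false")  # host side
  } else {
    g
  }
}

#' Shortest-path centralities on the interaction graph
#'
#' The bipartite network is treated as an undirected, unweighted graph
#' over hosts and guests together, so paths alternate between the two
#' levels. Betweenness is Brandes shortest-path betweenness with
#' Freeman normalization `(n - 1)(n - 2) / 2` over the full vertex
#' count; closeness is computed within connected components as
#' `(reachable - 1) / sum(geodesic distances)`, with 0 for isolated
#' vertices.
#'
#' @param A Binary incidence matrix.
#' @param projection If `TRUE`, compute on the one-mode host projection
#'   instead of the full two-mode graph (sensitivity analysis).
#' @return A data.frame with `species`, `level` (`host`/`guest`),
#'   `betweenness`, `closeness`; projection mode returns hosts only.
#' @export
path_centralities <- function(A, projection = FALSE) {
  g <- .as_graph(A, projection)
  n <- igraph::vcount(g)
  btw <- if (n > 2) {
    igraph::betweenness(g, directed = FALSE) / ((n - 1) * (n - 2) / 2)
  } else {
    stats::setNames(rep(0, n), igraph::V(g)$name)
  }
  D <- igraph::distances(g)
  clo <- apply(D, 1, function(dr) {
    dr <- dr[is.finite(dr) & dr > 0]
    if (length(dr) == 0) 0 else length(dr) / sum(dr)
  })
  lvl <- if (projection) {
    rep("host", n)
  } else {
    ifelse(igraph::V(g)$type, "guest", "host")
  }
  data.frame(species = igraph::V(g)$name, level = lvl,
             betweenness = unname(btw[igraph::V(g)$name]),
             closeness = unname(clo[igraph::V(g)$name]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Katz centrality
#'
#' Attenuated count of all walks leaving each species on the full
#' (hosts + guests) adjacency matrix `B`:
#' `K = ((I - alpha B)^{-1} - I) 1`, the closed form of
#' `sum_{t >= 1} alpha^t B^t 1`. Requires `alpha < 1 / lambda_max(B)`.
#'
#' @param A Binary incidence matrix.
#' @param alpha Attenuation factor; default `0.9 / lambda_max`, which
#'   is always convergent while keeping long walks influential.
#' @return List with `scores` (named vector over hosts then guests),
#'   `hosts` (the host rows), `alpha`, and `lambda_max`.
#' @export
katz_centrality <- function(A, alpha = NULL) {
  A <- (unclass(A) != 0) * 1
  R <- nrow(A)
  C <- ncol(A)
  B <- rbind(cbind(matrix(0, R, R), A),
             cbind(t(A), matrix(0, C, C)))
  nm <- c(rownames(A), colnames(A))
  dimnames(B) <- list(nm, nm)
  lam <- if (sum(A) == 0) 0 else max(abs(eigen(B, symmetric = TRUE,
                                               only.values = TRUE)$values))
  if (is.null(alpha)) {
    alpha <- if (lam == 0) 0.5 else 0.9 / lam
  }
  if (lam > 0 && alpha >= 1 / lam) {
    stop("alpha = ", alpha, " >= 1/lambda_max = ", signif(1 / lam, 6),
         ": Katz series diverges", call. = FALSE)
  }
  n <- R + C
  K <- solve(diag(n) - alpha * B, rep(1, n)) - 1
  names(K) <- nm
  list(scores = K, hosts = K[seq_len(R)], alpha = alpha, lambda_max = lam)
}

#' Module-based species roles: participation and within-module degree
#'
#' Among-module connectivity `c_i = 1 - sum_s (k_is / k_i)^2` measures
#' how evenly a species spreads its links across modules (0 when all
#' links stay in one module). Within-module standardized degree `z_i`
#' standardizes a species' link count into its own module against the
#' within-module link counts of all members (hosts and guests) of that
#' module; when that spread is zero, `z_i = 0`.
#'
#' @param A Binary incidence matrix.
#' @param partition A `module_partition` covering all species.
#' @return Data.frame with `species`, `level`, `ci`, `zi`.
#' @export
module_roles <- function(A, partition) {
  A <- (unclass(A) != 0) * 1
  hm <- partition$hosts[rownames(A)]
  gm <- partition$guests[colnames(A)]
  if (anyNA(hm) || anyNA(gm)) {
    stop("partition does not cover all species", call. = FALSE)
  }
  n_mod <- max(hm, gm)
  # within-module and per-module link counts for every species
  host_by_mod <- sapply(seq_len(n_mod), function(s)
    rowSums(A[, gm == s, drop = FALSE]))
  guest_by_mod <- sapply(seq_len(n_mod), function(s)
    colSums(A[hm == s, , drop = FALSE]))
  host_by_mod <- matrix(host_by_mod, nrow = nrow(A))
  guest_by_mod <- matrix(guest_by_mod, nrow = ncol(A))
  ci_of <- function(by_mod, k) {
    ifelse(k == 0, 0, 1 - rowSums((by_mod / pmax(k, 1))^2))
  }
  k <- rowSums(A)
  d <- colSums(A)
  ci <- c(ci_of(host_by_mod, k), ci_of(guest_by_mod, d))
  # kappa: links into the species' own module
  kappa_h <- host_by_mod[cbind(seq_len(nrow(A)), hm)]
  kappa_g <- guest_by_mod[cbind(seq_len(ncol(A)), gm)]
  kappa <- c(kappa_h, kappa_g)
  mod_of <- c(hm, gm)
  zi <- numeric(length(kappa))
  for (s in unique(mod_of)) {
    idx <- mod_of == s
    mu <- mean(kappa[idx])
    sg <- stats::sd(kappa[idx])
    zi[idx] <- if (is.na(sg) || sg == 0) 0 else (kappa[idx] - mu) / sg
  }
  data.frame(species = c(rownames(A), colnames(A)),
             level = rep(c("host", "guest"), c(nrow(A), ncol(A))),
             ci = unname(ci), zi = zi,
             row.names = NULL, stringsAsFactors = FALSE)
}

# Bascompte probabilistic-null sampling weights for a host row:
# P(link to guest j) proportional to (row fill + column fill) / 2
.row_null_prob <- function(A, i) {
  (rowSums(A)[i] / ncol(A) + colSums(A) / nrow(A)) / 2
}

#' Per-species contribution to nestedness
#'
#' The focal host's row is replaced `n_rand` times by a random row of
#' the same degree, with partners drawn with probability proportional
#' to the mean of the original matrix's row fill and column fill
#' (probabilistic cell null). The contribution is the z-score
#' `(NODF_obs - mean(NODF_rand)) / sd(NODF_rand)`; a positive value
#' means the species' observed partner choice makes the network more
#' nested than random partner choice would. A zero null spread gives 0.
#'
#' @param A Binary incidence matrix.
#' @param host Host name(s); default all hosts.
#' @param n_rand Randomizations per species.
#' @param seed Optional integer seed.
#' @return Named numeric vector of contributions (z-score units).
#' @export
nestedness_contribution <- function(A, host = NULL, n_rand = 1000,
                                    seed = NULL) {
  if (n_rand < 100) stop("n_rand must be at least 100", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  A <- (unclass(A) != 0) * 1
  if (is.null(host)) host <- rownames(A)
  k <- rowSums(A)
  if (any(k[host] == 0)) {
    stop("nestedness contribution undefined for degree-0 host(s): ",
         paste(host[k[host] == 0], collapse = ", "), call. = FALSE)
  }
  obs <- nodf(A)
  C <- ncol(A)
  storage.mode(A) <- "integer"
  Or0 <- tcrossprod(A)
  Oc0 <- crossprod(A)
  vapply(host, function(h) {
    i <- match(h, rownames(A))
    p <- .row_null_prob(A, h)
    deg <- k[h]
    # degree-preserving replacement rows, drawn up front so the RNG
    # stream per host is a plain sequence of weighted draws
    B <- matrix(0L, n_rand, C)
    for (r in seq_len(n_rand)) {
      B[r, sample.int(C, deg, prob = p)] <- 1L
    }
    vals <- cni_nodf_draws(A, i, B, Or0, Oc0)
    s <- stats::sd(vals)
    if (s == 0) 0 else (obs - mean(vals)) / s
  }, numeric(1))
}

#' Assemble the seven species-level structural descriptors for hosts
#'
#' Computes, for every host sponge, its degree, normalized betweenness
#' and closeness, Katz centrality, among-module connectivity `ci`,
#' within-module standardized degree `zi`, and nestedness contribution
#' `cni`. Guests take part in all underlying computations (paths,
#' modules) but only hosts are returned, since hosts are the species
#' being scored.
#'
#' @param A Binary incidence matrix.
#' @param partition A `module_partition`; computed with default
#'   settings when omitted.
#' @param alpha Katz attenuation (default `0.9 / lambda_max`).
#' @param n_rand Randomizations for the nestedness contribution.
#' @param seed Optional integer seed (module search + contribution).
#' @param projection Use the one-mode host projection for path
#'   centralities (default: full two-mode graph).
#' @return A `data.frame` with one row per host and columns `species`,
#'   `degree`, `betweenness`, `closeness`, `katz`, `ci`, `zi`, `cni`.
#' @export
descriptor_table <- function(A, partition = NULL, alpha = NULL,
                             n_rand = 1000, seed = NULL,
                             projection = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(partition)) partition <- optimize_modules(A)
  hosts <- rownames(A)
  deg <- host_degree(A)
  pc <- path_centralities(A, projection = projection)
  pc <- pc[match(hosts, pc$species), ]
  kz <- katz_centrality(A, alpha = alpha)
  mr <- module_roles(A, partition)
  mr <- mr[match(hosts, mr$species), ]
  cni <- nestedness_contribution(A, n_rand = n_rand)
  data.frame(species = hosts,
             degree = unname(deg[hosts]),
             betweenness = pc$betweenness,
             closeness = pc$closeness,
             katz = unname(kz$hosts[hosts]),
             ci = mr$ci,
             zi = mr$zi,
             cni = unname(cni[hosts]),
             row.names = NULL, stringsAsFactors = FALSE)
}
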