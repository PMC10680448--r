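test_that("degree is the row sum, with name-safe lookup", {
  A <- named_matrix(matrix(c(1L, 1L), 1, 2))
  expect_equal(unname(host_degree(A, "h01")), 2)
  for (s in 1:5) {
    B <- rand_matrix(6, 9, 0.4, seed = s)
    expect_equal(host_degree(B), rowSums(B))
  }
  expect_error(host_degree(A, "nope"), "unknown host")
})

test_that("path centralities match the exhaustive shortest-path oracle", {
  # star: 1 host, 5 guests; hub carries every geodesic
  star <- named_matrix(matrix(1L, 1, 5))
  pc <- path_centralities(star)
  expect_equal(pc$betweenness[pc$level == "host"], 1)
  expect_equal(pc$betweenness[pc$level == "guest"], rep(0, 5))

  # path h1 - g1 - h2: the guest lies on the single host-host geodesic
  pth <- named_matrix(matrix(c(1L, 1L), 2, 1))
  pc <- path_centralities(pth)
  expect_equal(pc$betweenness[pc$species == "g01"], 1)
  orc <- path_oracle(full_adjacency(pth))
  expect_equal(pc$betweenness, orc$betweenness[c(1, 2, 3)])

  # two disconnected stars: closeness stays within components
  two <- named_matrix(rbind(c(1L, 1L, 0L, 0L), c(0L, 0L, 1L, 1L)))
  pc <- path_centralities(two)
  orc <- path_oracle(full_adjacency(two))
  expect_equal(pc$closeness, orc$closeness)

  # property sweep on random graphs with <= 10 vertices
  for (s in 1:6) {
    A <- rand_matrix(4, 5, 0.4, seed = 500 + s)
    pc <- path_centralities(A)
    orc <- path_oracle(full_adjacency(A))
    expect_equal(pc$betweenness, orc$betweenness, tolerance = 1e-12)
    expect_equal(pc$closeness, orc$closeness, tolerance = 1e-12)
  }
})

test_that("Katz closed form equals the truncated power series", {
  # 3-vertex path (2 hosts sharing 1 guest), alpha = 0.1
  pth <- named_matrix(matrix(c(1L, 1L), 2, 1))
  B <- full_adjacency(pth)
  kz <- katz_centrality(pth, alpha = 0.1)
  series <- rep(0, 3)
  P <- diag(3)
  for (t in 1:50) {
    P <- P %*% (0.1 * B)
    series <- series + rowSums(P)
  }
  expect_equal(unname(kz$scores), series, tolerance = 1e-10)

  # same identity at the default attenuation on a random graph
  A <- rand_matrix(5, 7, 0.4, seed = 21)
  kz <- katz_centrality(A)
  B <- full_adjacency(A)
  series <- rep(0, 12)
  P <- diag(12)
  for (t in 1:200) {
    P <- P %*% (kz$alpha * B)
    series <- series + rowSums(P)
  }
  expect_equal(unname(kz$scores), series, tolerance = 1e-8)

  # edgeless graph scores zero; hub dominates leaves; divergence guarded
  empty <- named_matrix(matrix(0L, 3, 2))
  expect_equal(unname(katz_centrality(empty, alpha = 0.3)$scores),
               rep(0, 5))
  star <- named_matrix(matrix(1L, 1, 5))
  kz <- katz_centrality(star)
  expect_gt(kz$hosts[1], max(kz$scores[-1]))
  expect_error(katz_centrality(star, alpha = 1), "diverges")
})

test_that("module roles follow the participation/z-score formulas", {
  tb <- two_block_matrix()
  part <- block_partition(tb, c(1, 1, 2, 2), c(1, 1, 2, 2))
  mr <- module_roles(tb, part)
  expect_equal(mr$ci, rep(0, 8))  # all links inside own module

  # degree 2 split across 2 modules: ci = 1 - 2 (1/2)^2 = 0.5
  A <- named_matrix(rbind(c(1L, 1L), c(1L, 0L), c(0L, 1L)))
  part <- block_partition(A, c(1, 1, 2), c(1, 2))
  mr <- module_roles(A, part)
  expect_equal(mr$ci[mr$species == "h01"], 0.5)

  # seeded 3-module network vs a direct contingency-table oracle
  set.seed(31)
  A <- rand_matrix(9, 12, 0.35, seed = 31)
  hm <- sample.int(3, 9, TRUE)
  gm <- sample.int(3, 12, TRUE)
  mr <- module_roles(A, block_partition(A, hm, gm))
  k <- rowSums(A)
  for (i in seq_len(9)) {
    kis <- vapply(1:3, function(s) sum(A[i, gm == s]), numeric(1))
    ci_exp <- if (k[i] == 0) 0 else 1 - sum((kis / k[i])^2)
    expect_equal(mr$ci[i], ci_exp)
  }
  # zi standardizes within-own-module degree over the module's members
  kappa <- c(vapply(seq_len(9), function(i) sum(A[i, gm == hm[i]]),
                    numeric(1)),
             vapply(seq_len(12), function(j) sum(A[hm == gm[j], j]),
                    numeric(1)))
  mod_of <- c(hm, gm)
  for (s in 1:3) {
    idx <- mod_of == s
    sg <- stats::sd(kappa[idx])
    zi_exp <- if (is.na(sg) || sg == 0) {
      rep(0, sum(idx))
    } else {
      (kappa[idx] - mean(kappa[idx])) / sg
    }
    expect_equal(mr$zi[idx], zi_exp)
    if (!is.na(sg) && sg > 0) expect_equal(mean(mr$zi[idx]), 0)
  }
})

test_that("nestedness contribution matches an independent resampler", {
  # saturated focal row admits a single rearrangement: contribution 0
  A <- named_matrix(rbind(rep(1L, 5), c(1L, 0L, 1L, 0L, 0L),
                          c(0L, 1L, 0L, 0L, 1L)))
  expect_equal(unname(nestedness_contribution(A, "h01", n_rand = 100,
                                              seed = 1)), 0)
  B <- A
  B[2, ] <- 0L
  expect_error(nestedness_contribution(B, "h02", n_rand = 100),
               "degree-0")

  # naive oracle: rebuild the matrix and call nodf() on every draw
  naive_cni <- function(A, n_rand, seed) {
    set.seed(seed)
    A <- unclass(A)
    k <- rowSums(A)
    obs <- nodf(A)
    vapply(rownames(A), function(h) {
      p <- (k[h] / ncol(A) + colSums(A) / nrow(A)) / 2
      vals <- replicate(n_rand, {
        Bm <- A
        row <- integer(ncol(A))
        row[sample.int(ncol(A), k[h], prob = p)] <- 1L
        Bm[h, ] <- row
        nodf(Bm)
      })
      s <- stats::sd(vals)
      if (s == 0) 0 else (obs - mean(vals)) / s
    }, numeric(1))
  }
  A <- rand_matrix(6, 8, 0.4, seed = 61)
  A <- A[rowSums(A) > 0, , drop = FALSE]
  expect_equal(nestedness_contribution(A, n_rand = 500, seed = 8),
               naive_cni(A, 500, 8), tolerance = 1e-12)

  # placing the hub's links on the highest-fill guests (maximally
  # nested placement) scores a larger contribution than placing them
  # on the lowest-fill guests (anti-nested placement)
  gaps <- vapply(1:20, function(s) {
    net <- generate_network(network_config(n_hosts = 15, n_guests = 25,
                                           connectance = 0.2,
                                           nestedness_strength = 2,
                                           n_modules = 1,
                                           module_mixing = 0, seed = s))
    A <- unclass(net$matrix)
    hub <- which.max(rowSums(A))
    deg <- max(rowSums(A))
    top <- A
    top[hub, ] <- 0L
    top[hub, order(colSums(A), decreasing = TRUE)[1:deg]] <- 1L
    bot <- A
    bot[hub, ] <- 0L
    bot[hub, order(colSums(A), decreasing = FALSE)[1:deg]] <- 1L
    class(top) <- class(bot) <- c("incidence_matrix", "matrix")
    unname(nestedness_contribution(top, rownames(A)[hub], n_rand = 200,
                                   seed = s + 100)) -
      unname(nestedness_contribution(bot, rownames(A)[hub], n_rand = 200,
                                     seed = s + 100))
  }, numeric(1))
  expect_gt(mean(gaps), 0)
  expect_gte(mean(gaps > 0), 0.6)
})

test_that("the descriptor table composes its seven columns faithfully", {
  tb <- two_block_matrix()
  part <- optimize_modules(tb, steps = 5000, seed = 3)
  desc <- descriptor_table(tb, partition = part, n_rand = 100, seed = 4)
  expect_equal(names(desc), c("species", "degree", "betweenness",
                              "closeness", "katz", "ci", "zi", "cni"))
  expect_equal(nrow(desc), 4)
  expect_equal(desc$degree, unname(host_degree(tb)))
  pc <- path_centralities(tb)
  expect_equal(desc$betweenness,
               pc$betweenness[match(desc$species, pc$species)])
  expect_equal(desc$closeness,
               pc$closeness[match(desc$species, pc$species)])
  expect_equal(desc$katz, unname(katz_centrality(tb)$hosts))
  mr <- module_roles(tb, part)
  expect_equal(desc$ci, mr$ci[match(desc$species, mr$species)])

  # descriptors are strongly inter-correlated on a nested network
  # (the premise for collapsing them onto one ordination axis)
  net <- generate_network(network_config(n_hosts = 25, n_guests = 50,
                                         connectance = 0.12,
                                         n_modules = 1, seed = 19))
  part <- optimize_modules(net$matrix, steps = 3000, seed = 20,
                           restarts = 1)
  desc <- descriptor_table(net$matrix, partition = part, n_rand = 100,
                           seed = 21)
  expect_gt(stats::cor(desc$degree, desc$katz), 0.8)
  expect_gt(stats::cor(desc$degree, desc$betweenness), 0.6)
})
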