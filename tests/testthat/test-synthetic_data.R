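test_that("generated bundles pass input validation unchanged", {
  cfg <- network_config(n_hosts = 15, n_guests = 30, connectance = 0.12,
                        seed = 2)
  bun <- generate_bundle(cfg)
  expect_no_warning(v <- validate_interactions(bun$interactions))
  expect_equal(nrow(v), nrow(bun$interactions))
  expect_true(all(is_species_level(bun$interactions$host_species)))
  A <- build_incidence(bun$interactions)
  expect_equal(unclass(A), unclass(bun$network$matrix)[rownames(A),
                                                       colnames(A)])
  expect_setequal(bun$traits$morphology %in% morphology_classes(), TRUE)
  expect_equal(sort(unique(bun$occurrences$species)), rownames(A))
})

test_that("generation is seed-reproducible and respects dimensions", {
  cfg <- network_config(n_hosts = 12, n_guests = 20, connectance = 0.15,
                        seed = 5)
  a <- generate_network(cfg)
  b <- generate_network(cfg)
  expect_identical(unclass(a$matrix), unclass(b$matrix))
  expect_equal(dim(a$matrix), c(12L, 20L))
  expect_true(all(rowSums(a$matrix) > 0))
  expect_true(all(colSums(a$matrix) > 0))
  expect_error(network_config(connectance = 0), "connectance")
})

test_that("realized fill tracks the configured connectance", {
  R <- 30; C <- 60; conn <- 0.1
  target <- conn * R * C
  se3 <- 3 * sqrt(target * (1 - conn))
  fills <- vapply(1:20, function(s) {
    sum(generate_network(network_config(n_hosts = R, n_guests = C,
                                        connectance = conn,
                                        nestedness_strength = 1,
                                        seed = s))$matrix)
  }, numeric(1))
  expect_true(all(abs(fills - target) <= se3))
})

test_that("planted structure is detectable and its absence is not", {
  # strength 2: strongly nested against the fill null
  sig <- vapply(1:30, function(s) {
    net <- generate_network(network_config(n_hosts = 20, n_guests = 40,
                                           connectance = 0.12,
                                           nestedness_strength = 2,
                                           n_modules = 1,
                                           module_mixing = 0, seed = s))
    significance(net$matrix, "nodf", n_null = 100, seed = s + 500)$p < 0.05
  }, logical(1))
  expect_gte(mean(sig), 0.95)

  # strength 0, one module: the network is its own null
  fp <- vapply(1:30, function(s) {
    net <- generate_network(network_config(n_hosts = 20, n_guests = 40,
                                           connectance = 0.12,
                                           nestedness_strength = 0,
                                           n_modules = 1,
                                           module_mixing = 0, seed = s))
    significance(net$matrix, "nodf", n_null = 100, seed = s + 900)$p > 0.05
  }, logical(1))
  expect_gte(mean(fp), 0.8)
})

test_that("module mixing dilutes planted blocks but zero mixing keeps them", {
  skip_if_not_installed("mclust")
  ari <- vapply(1:10, function(s) {
    net <- generate_network(network_config(n_hosts = 18, n_guests = 30,
                                           connectance = 0.25,
                                           nestedness_strength = 0,
                                           n_modules = 3,
                                           module_mixing = 0, seed = s))
    part <- optimize_modules(net$matrix, steps = 4000, seed = s + 50,
                             restarts = 1)
    mclust::adjustedRandIndex(
      c(part$hosts, part$guests),
      c(net$modules_host, net$modules_guest))
  }, numeric(1))
  expect_gte(mean(ari), 0.8)
})

test_that("occurrence counts decouple from degree when the slope is zero", {
  cors <- vapply(1:50, function(s) {
    cfg <- network_config(n_hosts = 20, n_guests = 40,
                          connectance = 0.12, area_coupling = 0,
                          seed = s)
    net <- generate_network(cfg)
    tro <- generate_traits_and_occurrences(net, cfg)
    counts <- table(factor(tro$occurrences$species,
                           levels = rownames(net$matrix)))
    suppressWarnings(stats::cor(rowSums(unclass(net$matrix)),
                                as.numeric(counts)))
  }, numeric(1))
  expect_lt(abs(mean(cors, na.rm = TRUE)), 0.1)

  # positive coupling shows through the full area pipeline; the
  # geometric occurrence counts are noisy, so judge the median rank
  # correlation over seeds
  sp <- vapply(1:15, function(s) {
    set.seed(s)
    cfg <- network_config(n_hosts = 25, n_guests = 50,
                          connectance = 0.1, area_coupling = 1)
    net <- generate_network(cfg)
    tro <- generate_traits_and_occurrences(net, cfg)
    ar <- accumulated_area(tro$occurrences, tro$reefs)
    k <- rowSums(unclass(net$matrix))
    stats::cor(k[ar$species], ar$accumulated_area, method = "spearman")
  }, numeric(1))
  expect_gt(stats::median(sp), 0.3)
  expect_gt(mean(sp), 0)
})

test_that("bundles written to disk load back through the io layer", {
  dir <- withr::local_tempdir()
  cfg <- network_config(n_hosts = 10, n_guests = 18, connectance = 0.15,
                        seed = 9)
  bun <- generate_bundle(cfg, dir = dir)
  expect_true(all(file.exists(file.path(dir,
    c("interactions.csv", "traits.csv", "occurrences.csv",
      "reefs.geojson", "truth.json")))))
  rec <- read_interactions(file.path(dir, "interactions.csv"))
  expect_equal(nrow(rec), nrow(bun$interactions))
  reefs <- read_reefs(file.path(dir, "reefs.geojson"))
  expect_length(reefs, length(bun$reefs))
  tr <- read_traits(file.path(dir, "traits.csv"))
  expect_equal(tr$species, bun$traits$species)
})
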