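#' Configuration for the synthetic interaction-network generator
#'
#' Defaults emulate the empirical study system: a 76-host by 268-guest
#' binary network with 745 expected links (connectance ~0.037), a
#' right-skewed host degree distribution with a few hub hosts, and
#' simultaneous nested (within-block degree gradient) and modular
#' (planted blocks) structure.
#'
#' @param n_hosts,n_guests Matrix dimensions.
#' @param connectance Expected fill (links / cells).
#' @param nestedness_strength Exponent of the within-block rank-decay
#'   `(1 - (i - 1) / R)^strength`; 0 gives Erdos-Renyi-like fill.
#' @param n_modules Number of planted blocks.
#' @param module_mixing Fraction of links rewired uniformly across the
#'   whole matrix after block sampling.
#' @param morphology_effects Named multiplicative degree effects per
#'   functional-morphology class; all-equal values decouple morphology
#'   from degree (the type-I-error null).
#' @param area_coupling Slope of log expected occurrence count on log
#'   degree; 0 decouples records from degree.
#' @param occurrence_base Expected occurrence count of a degree-1 host.
#' @param seed Optional integer seed stored in the config.
#' @return A list of class `generator_config`.
#' @export
network_config <- function(n_hosts = 76, n_guests = 268,
                           connectance = 745 / (76 * 268),
                           nestedness_strength = 2,
                           n_modules = 5,
                           module_mixing = 0.2,
                           morphology_effects = c("Cup-like" = 2.5,
                                                  "Massive" = 2.2,
                                                  "Crust-like" = 1.0,
                                                  "Erect" = 0.5),
                           area_coupling = 1,
                           occurrence_base = 2,
                           seed = NULL) {
  stopifnot(connectance > 0, connectance <= 1,
            module_mixing >= 0, module_mixing <= 1,
            nestedness_strength >= 0, n_modules >= 1)
  structure(list(n_hosts = n_hosts, n_guests = n_guests,
                 connectance = connectance,
                 nestedness_strength = nestedness_strength,
                 n_modules = n_modules, module_mixing = module_mixing,
                 morphology_effects = morphology_effects,
                 area_coupling = area_coupling,
                 occurrence_base = occurrence_base, seed = seed),
            class = "generator_config")
}

#' Generate a binary network with planted nested and modular structure
#'
#' Hosts and guests are split into blocks; within each block the cell
#' probability is proportional to the product of the two species'
#' rank-decay weights `(1 - (rank - 1) / size)^strength` (computed on
#' within-block ranks), scaled so the expected fill equals
#' `connectance * R * C` and truncated at 1. A `module_mixing` fraction
#' of sampled links is then rewired to uniformly random empty cells.
#' Rows or columns left empty are first resampled from their cell
#' probabilities (up to 5 sweeps); any still-empty line finally
#' receives a single link drawn from its probability profile, so the
#' matrix is guaranteed to have no all-zero row or column.
#'
#' @param config A `generator_config`.
#' @return List: `matrix` (an `incidence_matrix`), `modules_host` /
#'   `modules_guest` (named planted block labels), `config`.
#' @export
generate_network <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  R <- config$n_hosts
  C <- config$n_guests
  target_m <- config$connectance * R * C
  if (target_m > R * C) stop("unattainable connectance", call. = FALSE)
  hm <- sort(rep_len(seq_len(config$n_modules), R))
  gm <- sort(rep_len(seq_len(config$n_modules), C))
  decay <- function(labels) {
    w <- numeric(length(labels))
    for (s in unique(labels)) {
      idx <- which(labels == s)
      n <- length(idx)
      w[idx] <- (1 - (seq_len(n) - 1) / n)^config$nestedness_strength
    }
    w
  }
  W <- outer(decay(hm), decay(gm)) * outer(hm, gm, "==")
  P <- W * target_m / sum(W)
  P[P > 1] <- 1
  A <- matrix(as.integer(stats::runif(R * C) < P), R, C)
  # rewire a fraction of links anywhere, diluting the planted structure
  n_move <- round(config$module_mixing * sum(A))
  if (n_move > 0) {
    ones <- which(A == 1L)
    mv <- sample(ones, n_move)
    A[mv] <- 0L
    zeros <- which(A == 0L)
    A[sample(zeros, n_move)] <- 1L
  }
  # guarantee no empty row or column
  for (sweep in 1:5) {
    ec <- which(colSums(A) == 0)
    for (j in ec) A[, j] <- as.integer(stats::runif(R) < P[, j])
    er <- which(rowSums(A) == 0)
    for (i in er) A[i, ] <- as.integer(stats::runif(C) < P[i, ])
    if (!any(colSums(A) == 0) && !any(rowSums(A) == 0)) break
  }
  for (j in which(colSums(A) == 0)) {
    A[sample.int(R, 1, prob = P[, j] + 1e-12), j] <- 1L
  }
  for (i in which(rowSums(A) == 0)) {
    A[i, sample.int(C, 1, prob = P[i, ] + 1e-12)] <- 1L
  }
  hostn <- sprintf("Hostia species%03d", seq_len(R))
  guestn <- sprintf("Guestia species%03d", seq_len(C))
  dimnames(A) <- list(hostn, guestn)
  class(A) <- c("incidence_matrix", class(A))
  list(matrix = A,
       modules_host = stats::setNames(hm, hostn),
       modules_guest = stats::setNames(gm, guestn),
       config = config)
}

.meow_ecoregions <- function() {
  c("Bahamian", "Bermuda", "Eastern Caribbean", "Floridian",
    "Greater Antilles", "Northern Gulf of Mexico", "Southern Caribbean",
    "Southern Gulf of Mexico", "Southwestern Caribbean",
    "Western Caribbean")
}

#' Expand a generated network into an interaction record table
#'
#' One record per link, with ecoregion, coordinates inside the
#' Caribbean / Gulf of Mexico window, and a reference label, so the
#' result passes the interaction-table validation unchanged.
#'
#' @param net Output of [generate_network()].
#' @param n_references Distinct synthetic publication labels.
#' @return Data.frame in the [read_interactions()] layout.
#' @export
generate_interactions <- function(net, n_references = 25) {
  idx <- which(unclass(net$matrix) != 0, arr.ind = TRUE)
  n <- nrow(idx)
  data.frame(host_species = rownames(net$matrix)[idx[, 1]],
             guest_species = colnames(net$matrix)[idx[, 2]],
             ecoregion = sample(.meow_ecoregions(), n, replace = TRUE),
             latitude = stats::runif(n, 10, 30),
             longitude = stats::runif(n, -95, -60),
             reference = sprintf("ref%03d",
                                 sample.int(n_references, n, replace = TRUE)),
             stringsAsFactors = FALSE)
}

#' Generate traits, occurrence records and reef polygons for a network
#'
#' Morphology classes are assigned with probability proportional to
#' `effect^z`, where `z` is the host's standardized log-degree, so the
#' class-conditional expected degree increases with the configured
#' effect (all-equal effects give degree-independent assignment).
#' Occurrence counts are geometric (overdispersed) with mean
#' `occurrence_base * degree^area_coupling`; coordinates fall uniformly
#' inside randomly placed rectangular reef polygons, so every record's
#' buffer lies on reef.
#'
#' @param net Output of [generate_network()].
#' @param config The same `generator_config` (defaults to
#'   `net$config`).
#' @param n_reefs Number of rectangular reef polygons.
#' @return List: `traits` (species, morphology, order), `occurrences`
#'   (species, latitude, longitude, source), `reefs`
#'   (a `reef_polygons`).
#' @export
generate_traits_and_occurrences <- function(net, config = net$config,
                                            n_reefs = 12) {
  A <- unclass(net$matrix)
  k <- rowSums(A)
  hosts <- rownames(A)
  eff <- config$morphology_effects
  z <- if (stats::sd(log(k)) == 0) {
    rep(0, length(k))
  } else {
    as.numeric(scale(log(k)))
  }
  morph <- vapply(z, function(zi) {
    sample(names(eff), 1, prob = eff^zi)
  }, character(1))
  orders <- sprintf("Order%02d", sample.int(6, length(hosts), replace = TRUE))
  traits <- data.frame(species = hosts, morphology = morph, order = orders,
                       stringsAsFactors = FALSE)
  # rectangular reefs in the Caribbean / Gulf window
  reefs <- lapply(seq_len(n_reefs), function(i) {
    lon0 <- stats::runif(1, -95, -63)
    lat0 <- stats::runif(1, 10, 28)
    w <- stats::runif(1, 0.5, 3)
    h <- stats::runif(1, 0.5, 2)
    ring <- cbind(c(lon0, lon0 + w, lon0 + w, lon0, lon0),
                  c(lat0, lat0, lat0 + h, lat0 + h, lat0))
    list(ring)
  })
  class(reefs) <- "reef_polygons"
  mu <- pmax(1, config$occurrence_base * k^config$area_coupling)
  counts <- 1L + stats::rgeom(length(k), prob = 1 / mu)
  occ <- do.call(rbind, lapply(seq_along(hosts), function(i) {
    ri <- sample.int(n_reefs, counts[i], replace = TRUE)
    pts <- t(vapply(ri, function(r) {
      ring <- reefs[[r]][[1]]
      margin <- 0.001  # keep metre-scale buffers inside the rectangle
      c(stats::runif(1, min(ring[, 1]) + margin, max(ring[, 1]) - margin),
        stats::runif(1, min(ring[, 2]) + margin, max(ring[, 2]) - margin))
    }, numeric(2)))
    data.frame(species = hosts[i], latitude = pts[, 2],
               longitude = pts[, 1], source = "synthetic",
               stringsAsFactors = FALSE)
  }))
  rownames(occ) <- NULL
  list(traits = traits, occurrences = occ, reefs = reefs)
}

#' Generate and optionally write a complete synthetic input bundle
#'
#' Produces everything the pipeline consumes: interaction records,
#' traits, occurrences and reef polygons, plus the planted truth.
#'
#' @param config A `generator_config`.
#' @param dir If given, the bundle is written there as
#'   `interactions.csv`, `traits.csv`, `occurrences.csv`,
#'   `reefs.geojson` and `truth.json`.
#' @return List: `interactions`, `traits`, `occurrences`, `reefs`,
#'   `network` (the generated matrix and planted labels), `config`.
#' @export
generate_bundle <- function(config = network_config(), dir = NULL) {
  net <- generate_network(config)
  inter <- generate_interactions(net)
  tro <- generate_traits_and_occurrences(net)
  out <- list(interactions = inter, traits = tro$traits,
              occurrences = tro$occurrences, reefs = tro$reefs,
              network = net, config = config)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(inter, file.path(dir, "interactions.csv"),
                     row.names = FALSE)
    utils::write.csv(tro$traits, file.path(dir, "traits.csv"),
                     row.names = FALSE)
    utils::write.csv(tro$occurrences, file.path(dir, "occurrences.csv"),
                     row.names = FALSE)
    write_reefs_geojson(tro$reefs, file.path(dir, "reefs.geojson"))
    jsonlite::write_json(list(modules_host = as.list(net$modules_host),
                              modules_guest = as.list(net$modules_guest),
                              config = unclass(config)),
                         file.path(dir, "truth.json"), auto_unbox = TRUE)
  }
  out
}
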