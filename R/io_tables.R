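#' Read host-guest interaction records from CSV
#'
#' Reads a comma-delimited interaction table and validates every row.
#' Rows that fail validation (out-of-range coordinates, empty species
#' names) are collected in the `invalid` attribute rather than silently
#' dropped, so the caller can inspect or report them.
#'
#' @param path Path to a UTF-8 CSV file with a header row.
#' @param columns Named list mapping the canonical field names
#'   (`host`, `guest`, `ecoregion`, `latitude`, `longitude`, `reference`)
#'   to the column names actually present in the file. Fields other than
#'   `host` and `guest` are optional; missing optional columns are filled
#'   with `NA`.
#' @return A `data.frame` with columns `host_species`, `guest_species`,
#'   `ecoregion`, `latitude`, `longitude`, `reference`, one row per valid
#'   input row, with an `invalid` attribute holding the offending rows
#'   (with a `reason` column) if any were found.
#' @export
read_interactions <- function(path,
                              columns = list(host = "host_species",
                                             guest = "guest_species",
                                             ecoregion = "ecoregion",
                                             latitude = "latitude",
                                             longitude = "longitude",
                                             reference = "reference")) {
  if (!file.exists(path)) {
    stop("interaction file not found: ", path, call. = FALSE)
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8", check.names = FALSE)
  required <- c("host", "guest")
  for (fld in required) {
    if (is.null(columns[[fld]]) || !columns[[fld]] %in% names(raw)) {
      stop("required column missing from ", path, ": ",
           if (is.null(columns[[fld]])) fld else columns[[fld]],
           call. = FALSE)
    }
  }
  pick <- function(fld, as_num = FALSE) {
    nm <- columns[[fld]]
    if (is.null(nm) || !nm %in% names(raw)) {
      rep(if (as_num) NA_real_ else NA_character_, nrow(raw))
    } else if (as_num) {
      suppressWarnings(as.numeric(raw[[nm]]))
    } else {
      as.character(raw[[nm]])
    }
  }
  rec <- data.frame(host_species = pick("host"),
                    guest_species = pick("guest"),
                    ecoregion = pick("ecoregion"),
                    latitude = pick("latitude", as_num = TRUE),
                    longitude = pick("longitude", as_num = TRUE),
                    reference = pick("reference"),
                    stringsAsFactors = FALSE)
  validate_interactions(rec)
}

#' Validate interaction records
#'
#' Checks species-name presence and coordinate bounds
#' (latitude in [-90, 90], longitude in [-180, 180]). Coordinates given
#' in the source but unparsable arrive here as `NA` and are flagged.
#'
#' @param records Data frame in the `read_interactions()` layout.
#' @return The valid rows, with failing rows in the `invalid` attribute.
#' @export
validate_interactions <- function(records) {
  reason <- character(nrow(records))
  bad_host <- is.na(records$host_species) | !nzchar(trimws(records$host_species))
  bad_guest <- is.na(records$guest_species) | !nzchar(trimws(records$guest_species))
  bad_lat <- !is.na(records$latitude) &
    (records$latitude < -90 | records$latitude > 90)
  bad_lon <- !is.na(records$longitude) &
    (records$longitude < -180 | records$longitude > 180)
  reason[bad_host] <- "empty host_species"
  reason[bad_guest] <- paste0(reason[bad_guest], ";empty guest_species")
  reason[bad_lat] <- paste0(reason[bad_lat], ";latitude out of [-90,90]")
  reason[bad_lon] <- paste0(reason[bad_lon], ";longitude out of [-180,180]")
  bad <- nzchar(reason)
  out <- records[!bad, , drop = FALSE]
  rownames(out) <- NULL
  if (any(bad)) {
    inv <- records[bad, , drop = FALSE]
    inv$reason <- sub("^;", "", reason[bad])
    attr(out, "invalid") <- inv
    warning(sum(bad), " interaction record(s) failed validation; ",
            "see attr(, 'invalid')", call. = FALSE)
  }
  out
}

#' Is a name a species-level binomial?
#'
#' A species-level name is two whitespace-separated tokens, optionally
#' with a parenthesised subgenus between them, e.g.
#' `"Callyspongia (Cladochalina) aculeata"`. Names whose epithet is
#' `sp.`/`spp.` (any case, with or without the dot) and single-token
#' names are genus-level and rejected.
#'
#' @param x Character vector of taxon names.
#' @return Logical vector.
#' @export
is_species_level <- function(x) {
  x <- trimws(as.character(x))
  # drop a parenthesised subgenus token if present
  x <- gsub("\\([^)]*\\)", " ", x)
  x <- gsub("\\s+", " ", trimws(x))
  parts <- strsplit(x, " ", fixed = TRUE)
  vapply(parts, function(p) {
    length(p) == 2L && !grepl("^spp?\\.?$", p[2L], ignore.case = TRUE)
  }, logical(1))
}

#' Filter records to species-level host sponges
#'
#' Keeps only records whose host name is a species-level binomial; the
#' number of removed records is reported via `message()` and stored in
#' the `n_removed` attribute.
#'
#' @param records Validated interaction records.
#' @return The surviving records.
#' @export
filter_species_level <- function(records) {
  keep <- is_species_level(records$host_species)
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(!keep)
  if (any(!keep)) {
    message(sum(!keep), " record(s) with genus-level hosts removed")
  }
  out
}

#' Build the binary host x guest incidence matrix
#'
#' One represents at least one recorded association between a host and a
#' guest, zero its absence; duplicate records collapse to a single one.
#' Hosts (rows) and guests (columns) are ordered lexicographically so
#' that downstream seeded algorithms are deterministic. By construction
#' the matrix has no all-zero row or column.
#'
#' @param records Species-level-filtered interaction records, or any
#'   data frame with `host_species` and `guest_species` columns.
#' @return An `incidence_matrix`: a binary integer matrix with host row
#'   names and guest column names.
#' @export
build_incidence <- function(records) {
  if (nrow(records) == 0L) {
    stop("no interaction records: cannot build an incidence matrix",
         call. = FALSE)
  }
  hosts <- sort(unique(records$host_species), method = "radix")
  guests <- sort(unique(records$guest_species), method = "radix")
  A <- matrix(0L, length(hosts), length(guests),
              dimnames = list(hosts, guests))
  A[cbind(match(records$host_species, hosts),
          match(records$guest_species, guests))] <- 1L
  class(A) <- c("incidence_matrix", class(A))
  A
}

#' @export
print.incidence_matrix <- function(x, ...) {
  cat("Host-guest incidence matrix: ", nrow(x), " hosts x ", ncol(x),
      " guests, ", sum(x), " links (connectance ",
      signif(sum(x) / length(x), 3), ")\n", sep = "")
  invisible(x)
}

#' Total number of links in an incidence matrix
#' @param A Binary incidence matrix.
#' @return Integer link count (number of 1-cells).
#' @export
n_links <- function(A) sum(A != 0)

#' Summarize an interaction dataset
#'
#' Counts unique host-guest pairs, hosts and guests, and per-ecoregion
#' interactions, locations and publications. A location is a unique
#' (latitude, longitude) pair after rounding to `location_digits`
#' decimal places; a publication is a unique reference string. Records
#' with a missing ecoregion are bucketed under `"unclassified"` with a
#' warning.
#'
#' @param records Interaction records.
#' @param location_digits Decimal places defining a distinct location.
#' @return A list of class `dataset_summary` with elements
#'   `n_interactions`, `n_hosts`, `n_guests` and `per_ecoregion` (a
#'   data.frame with columns `ecoregion`, `interactions`, `locations`,
#'   `publications`).
#' @export
summarize_dataset <- function(records, location_digits = 3) {
  eco <- records$ecoregion
  if (anyNA(eco) || any(!nzchar(trimws(eco)), na.rm = TRUE)) {
    warning("records without an ecoregion bucketed under 'unclassified'",
            call. = FALSE)
    eco[is.na(eco) | !nzchar(trimws(eco))] <- "unclassified"
  }
  pair <- paste(records$host_species, records$guest_species, sep = "\r")
  loc <- paste(round(records$latitude, location_digits),
               round(records$longitude, location_digits), sep = ",")
  per <- do.call(rbind, lapply(split(seq_len(nrow(records)), eco), function(i) {
    data.frame(interactions = length(unique(pair[i])),
               locations = length(unique(loc[i][!is.na(records$latitude[i])])),
               publications = length(unique(records$reference[i][
                 !is.na(records$reference[i])])))
  }))
  per <- data.frame(ecoregion = rownames(per), per, row.names = NULL,
                    stringsAsFactors = FALSE)
  out <- list(n_interactions = length(unique(pair)),
              n_hosts = length(unique(records$host_species)),
              n_guests = length(unique(records$guest_species)),
              per_ecoregion = per)
  class(out) <- "dataset_summary"
  out
}

#' @export
print.dataset_summary <- function(x, ...) {
  cat("Interaction dataset: ", x$n_interactions,
      " unique host-guest pairs (", x$n_hosts, " hosts, ", x$n_guests,
      " guests)\n", sep = "")
  print(x$per_ecoregion, row.names = FALSE)
  invisible(x)
}

#' Write an incidence matrix as CSV and as an edge list
#'
#' @param A Incidence matrix.
#' @param matrix_path Optional path for the hosts-as-rows CSV.
#' @param edgelist_path Optional path for a two-column host,guest edge
#'   list of the 1-cells.
#' @return Invisibly, `A`.
#' @export
write_incidence <- function(A, matrix_path = NULL, edgelist_path = NULL) {
  if (!is.null(matrix_path)) {
    utils::write.csv(as.data.frame(unclass(A)), matrix_path)
  }
  if (!is.null(edgelist_path)) {
    idx <- which(A != 0, arr.ind = TRUE)
    el <- data.frame(host = rownames(A)[idx[, 1]],
                     guest = colnames(A)[idx[, 2]])
    el <- el[order(el$host, el$guest), ]
    utils::write.csv(el, edgelist_path, row.names = FALSE)
  }
  invisible(A)
}
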