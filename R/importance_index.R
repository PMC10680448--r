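#' Principal coordinate ordination of the descriptor table
#'
#' Classical metric scaling (Gower double-centering plus
#' eigendecomposition, via [stats::cmdscale()]) of the Euclidean
#' distances between hosts in descriptor space. With
#' `standardize = TRUE` every descriptor column is z-scored first;
#' constant columns are dropped with a warning in that case. On
#' Euclidean distances the axis scores coincide, up to sign, with
#' centered principal-component scores. Axis 1 is sign-oriented so that
#' it correlates positively with degree, making "larger score = more
#' connected" hold by construction.
#'
#' @param descriptors Output of [descriptor_table()] (or any data.frame
#'   with a `species` column and numeric descriptor columns).
#' @param standardize Z-score columns before the distance computation.
#' @return A list of class `pco_ordination`: `scores` (hosts x axes,
#'   axis scores = eigenvector times sqrt(eigenvalue)), `eigenvalues`,
#'   `variance_explained` (percent of the positive-eigenvalue total per
#'   axis), and `standardize`.
#' @export
pco <- function(descriptors, standardize = FALSE) {
  num <- descriptors[vapply(descriptors, is.numeric, logical(1))]
  if (nrow(num) < 2) stop("PCO needs at least two hosts", call. = FALSE)
  if (anyNA(num)) stop("descriptor table contains missing cells", call. = FALSE)
  X <- as.matrix(num)
  rownames(X) <- descriptors$species
  if (standardize) {
    sds <- apply(X, 2, stats::sd)
    if (any(sds == 0)) {
      warning("dropping constant descriptor column(s): ",
              paste(colnames(X)[sds == 0], collapse = ", "), call. = FALSE)
      X <- X[, sds > 0, drop = FALSE]
    }
    X <- scale(X)
  }
  mds <- withCallingHandlers(
    stats::cmdscale(stats::dist(X), k = nrow(X) - 1, eig = TRUE),
    # trailing zero eigenvalues are expected: n - 1 axes are requested
    # but rank is at most the number of descriptor columns
    warning = function(w) {
      if (grepl("eigenvalues are > 0", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  eig <- mds$eig
  if (any(eig < -1e-8 * max(abs(eig)))) {
    stop("negative eigenvalue from Euclidean distances: numerical ",
         "contract violated", call. = FALSE)
  }
  pos <- eig[eig > 1e-12 * max(abs(eig))]
  scores <- mds$points
  # orient axis 1 along increasing degree when a degree column exists
  if ("degree" %in% colnames(num) && ncol(scores) >= 1) {
    r <- suppressWarnings(stats::cor(scores[, 1], num$degree))
    if (!is.na(r) && r < 0) scores[, 1] <- -scores[, 1]
  }
  ve <- rep(0, ncol(scores))
  ve[seq_along(pos)] <- 100 * pos / sum(pos)
  structure(list(scores = scores, eigenvalues = eig[seq_len(ncol(scores))],
                 variance_explained = ve, standardize = standardize),
            class = "pco_ordination")
}

#' @export
print.pco_ordination <- function(x, ...) {
  cat("Principal coordinate ordination of ", nrow(x$scores), " hosts\n",
      "  axis 1 explains ", signif(x$variance_explained[1], 4),
      "% of the variation", if (x$standardize) " (z-scored descriptors)",
      "\n", sep = "")
  invisible(x)
}

#' Zero-shifted square-root importance index from axis-1 scores
#'
#' Raw ordination scores are both positive and negative and span a wide
#' range, so the starting point is moved to zero
#' (`shifted = raw - min(raw)`) and the square root taken
#' (`importance = sqrt(shifted)`). The transform is monotone, so the
#' importance ranking equals the raw axis-1 ranking.
#'
#' @param pco1_raw Named numeric vector of raw axis-1 scores per host.
#' @param variance_explained Percent of variation carried by axis 1
#'   (stored alongside, for reporting).
#' @return A data.frame of class `importance_scores` with columns
#'   `species`, `pco1_raw`, `pco1_shifted`, `importance`, and attribute
#'   `variance_explained_axis1`.
#' @export
importance_transform <- function(pco1_raw, variance_explained = NA_real_) {
  if (any(!is.finite(pco1_raw))) {
    stop("non-finite axis-1 scores", call. = FALSE)
  }
  shifted <- pco1_raw - min(pco1_raw)
  out <- data.frame(species = names(pco1_raw) %||%
                      as.character(seq_along(pco1_raw)),
                    pco1_raw = unname(pco1_raw),
                    pco1_shifted = unname(shifted),
                    importance = unname(sqrt(shifted)),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "variance_explained_axis1") <- variance_explained
  class(out) <- c("importance_scores", class(out))
  out
}

#' Species importance from the descriptor table in one call
#'
#' Runs the ordination and the zero-shift square-root transform.
#'
#' @inheritParams pco
#' @return An `importance_scores` data.frame (see
#'   [importance_transform()]).
#' @export
importance_scores <- function(descriptors, standardize = FALSE) {
  ord <- pco(descriptors, standardize = standardize)
  sc <- stats::setNames(ord$scores[, 1], rownames(ord$scores))
  importance_transform(sc, variance_explained = ord$variance_explained[1])
}
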