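#' Read the host trait table
#'
#' @param path CSV with columns `species`, `morphology`, `order`.
#' @return Data.frame; morphology is validated against the four
#'   functional classes (Crust-like, Massive, Cup-like, Erect).
#' @export
read_traits <- function(path) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  need <- c("species", "morphology", "order")
  if (!all(need %in% names(tr))) {
    stop("trait file must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  bad <- !tr$morphology %in% morphology_classes()
  if (any(bad)) {
    stop("unknown morphology class(es): ",
         paste(unique(tr$morphology[bad]), collapse = ", "), call. = FALSE)
  }
  tr
}

#' The four sponge functional-morphology classes
#' @return Character vector.
#' @export
morphology_classes <- function() {
  c("Crust-like", "Massive", "Cup-like", "Erect")
}

#' Poisson GLM of species importance on accumulated geographic area
#'
#' Log-link Poisson-family fit (iteratively reweighted least squares
#' via [stats::glm()]). The response is the continuous, non-negative
#' importance index, so the Poisson family acts as a quasi-likelihood
#' working model: coefficient estimates solve the same score equations
#' as for count data, and standard errors are taken from the Fisher
#' information at dispersion 1, matching a plain Poisson fit. The
#' non-integer-response warnings this provokes are intercepted.
#'
#' @param importance Non-negative numeric response per host.
#' @param area Accumulated area per host (km^2), same order.
#' @return List of class `glm_fit`: `coefficients`, `se`, `z`,
#'   `p`, `deviance`, `null_deviance`, `n`, and the underlying `model`.
#' @export
poisson_glm <- function(importance, area) {
  if (any(importance < 0)) {
    stop("importance must be non-negative", call. = FALSE)
  }
  if (all(importance == 0)) {
    stop("all-zero response: degenerate fit", call. = FALSE)
  }
  if (any(!is.finite(area))) stop("non-finite predictor", call. = FALSE)
  dat <- data.frame(y = importance, x = area)
  fit <- withCallingHandlers(
    stats::glm(y ~ x, family = stats::poisson(link = "log"), data = dat,
               control = stats::glm.control(epsilon = 1e-10, maxit = 100)),
    warning = function(w) {
      if (grepl("non-integer", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  if (!fit$converged) {
    stop("IRLS did not converge in 100 iterations; deviance = ",
         signif(fit$deviance, 6), call. = FALSE)
  }
  sm <- summary(fit, dispersion = 1)
  co <- sm$coefficients
  structure(list(coefficients = co[, "Estimate"],
                 se = co[, "Std. Error"],
                 z = co[, "z value"],
                 p = co[, "Pr(>|z|)"],
                 deviance = fit$deviance,
                 null_deviance = fit$null.deviance,
                 n = nrow(dat),
                 model = fit),
            class = "glm_fit")
}

#' @export
print.glm_fit <- function(x, ...) {
  cat("Poisson GLM (log link), n = ", x$n, "\n", sep = "")
  print(data.frame(estimate = x$coefficients, se = x$se, z = x$z, p = x$p))
  invisible(x)
}

#' One-way ANOVA of importance across trait groups
#'
#' Classical fixed-effects decomposition
#' (`F = MS_between / MS_within`) via [stats::aov()], with per-group
#' means and, by default, standard errors (`dispersion = "sd"` switches
#' to standard deviations).
#'
#' @param values Numeric response (importance per host).
#' @param groups Grouping labels (morphology or taxonomic order).
#' @param dispersion `"se"` or `"sd"` for the per-group spread column.
#' @return List of class `anova_result`: `F`, `df_between`,
#'   `df_within`, `p`, `group_stats`.
#' @export
anova_oneway <- function(values, groups, dispersion = c("se", "sd")) {
  dispersion <- match.arg(dispersion)
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) < 2) stop("need at least two groups", call. = FALSE)
  if (any(table(groups) == 0)) stop("empty group", call. = FALSE)
  fit <- stats::aov(values ~ groups)
  tab <- summary(fit)[[1]]
  # degenerate-variance guards on a scale-relative tolerance
  sst <- sum((values - mean(values))^2)
  ssw <- sum(unlist(lapply(split(values, groups),
                           function(v) (v - mean(v))^2)))
  eps <- 1e-12 * max(1, mean(values)^2) * length(values)
  flat <- sst <= eps
  if (tab["Residuals", "Df"] == 0 || (!flat && ssw <= eps)) {
    stop("zero within-group variance: F undefined", call. = FALSE)
  }
  # a completely flat response carries no evidence against equality
  Fv <- if (flat) 0 else tab["groups", "F value"]
  pv <- if (flat) 1 else tab["groups", "Pr(>F)"]
  gs <- do.call(rbind, lapply(split(values, groups), function(v) {
    spread <- if (dispersion == "se") {
      stats::sd(v) / sqrt(length(v))
    } else {
      stats::sd(v)
    }
    data.frame(n = length(v), mean = mean(v), spread = spread)
  }))
  gs <- data.frame(group = rownames(gs), gs, row.names = NULL)
  names(gs)[names(gs) == "spread"] <- dispersion
  structure(list(F = Fv,
                 df_between = tab["groups", "Df"],
                 df_within = tab["Residuals", "Df"],
                 p = pv,
                 group_stats = gs),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat("One-way ANOVA: F(", x$df_between, ", ", x$df_within, ") = ",
      signif(x$F, 4), ", p = ", signif(x$p, 3), "\n", sep = "")
  print(x$group_stats, row.names = FALSE)
  invisible(x)
}

#' Publication-bias meta-analysis of per-ecoregion publication effort
#'
#' Each ecoregion's publication count is treated as a proportion of the
#' total publication effort; the logit-transformed proportions are
#' pooled by an inverse-variance random-effects model with
#' maximum-likelihood tau^2 (via [metafor::rma()]), heterogeneity is
#' assessed with Cochran's Q, and small-study asymmetry with the
#' Thompson-Sharp test: a weighted regression of the effect on its
#' standard error with multiplicative overdispersion
#' (`metafor::regtest(model = "lm", predictor = "sei")`). Zero counts
#' receive the usual 0.5 continuity correction (logged via message).
#'
#' @param publications Named integer vector: publications per
#'   ecoregion.
#' @param total Total publication effort the proportions refer to;
#'   defaults to `sum(publications)`.
#' @return List of class `meta_bias_result`: `pooled_proportion`,
#'   `tau2`, `heterogeneity_Q`, `heterogeneity_p`,
#'   `bias_test_statistic`, `bias_p`, `n_regions`.
#' @export
publication_bias <- function(publications, total = sum(publications)) {
  if (length(publications) < 3) {
    stop("bias regression needs at least 3 ecoregions", call. = FALSE)
  }
  if (any(publications == 0)) {
    message("zero publication count(s): 0.5 continuity correction applied")
  }
  es <- metafor::escalc(measure = "PLO", xi = publications,
                        ni = rep(total, length(publications)),
                        add = 1 / 2, to = "only0")
  fit <- metafor::rma(yi, vi, data = es, method = "ML")
  # with no spread in the standard errors the asymmetry regression is
  # rank-deficient: there is trivially no small-study trend
  reg <- tryCatch(metafor::regtest(fit, model = "lm", predictor = "sei"),
                  error = function(e) {
                    message("degenerate asymmetry regression ",
                            "(constant standard errors): slope 0 reported")
                    list(zval = 0, pval = NA_real_)
                  })
  structure(list(pooled_proportion =
                   as.numeric(metafor::transf.ilogit(fit$b[1])),
                 tau2 = fit$tau2,
                 heterogeneity_Q = fit$QE,
                 heterogeneity_p = fit$QEp,
                 bias_test_statistic = as.numeric(reg$zval),
                 bias_p = as.numeric(reg$pval),
                 n_regions = length(publications)),
            class = "meta_bias_result")
}

#' @export
print.meta_bias_result <- function(x, ...) {
  cat("Meta-analysis of publication proportions over ", x$n_regions,
      " ecoregions\n  pooled proportion = ", signif(x$pooled_proportion, 3),
      ", tau^2 (ML) = ", signif(x$tau2, 3),
      "\n  heterogeneity Q p = ", signif(x$heterogeneity_p, 3),
      "; Thompson-Sharp bias p = ", signif(x$bias_p, 3), "\n", sep = "")
  invisible(x)
}
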