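#' Univariate regression of improvement on activation
#'
#' Ordinary least squares with improvement as the dependent variable and one
#' activation score as the predictor. Reports the two-sided p-value of the
#' slope (t-statistic, n - 2 df) and the adjusted coefficient of
#' determination `r2_adj = 1 - (1 - R2) (n - 1) / (n - 2)`. Hemispheres
#' enter as separate pooled observations; no multiple-testing correction is
#' applied across structures (raw p-values are reported).
#'
#' @param activation,improvement numeric vectors of equal length (n >= 3),
#'   or `activation` may be a data frame with those two columns.
#' @return An object of class `regression_result`: list with `slope`,
#'   `intercept`, `slope_p`, `r2`, `r2_adj`, `n`.
#' @export
fit_univariate <- function(activation, improvement = NULL) {
  xy <- as_xy(activation, improvement)
  x <- xy$x; y <- xy$y; n <- length(x)
  assert_that(n >= 3L, "insufficient_data", "need n >= 3 observations, got %d", n)
  assert_that(stats::var(x) > 0, "degenerate_predictor",
              "activation has zero variance; regression is undefined")
  fit <- stats::lm(y ~ x)
  s <- summary(fit)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 slope_p = unname(s$coefficients[2L, 4L]),
                 r2 = s$r.squared, r2_adj = s$adj.r.squared, n = n),
            class = "regression_result")
}

as_xy <- function(activation, improvement) {
  if (is.data.frame(activation)) {
    improvement <- activation$improvement
    activation <- activation$activation
  }
  assert_that(is.numeric(activation) && is.numeric(improvement) &&
              length(activation) == length(improvement) &&
              all(is.finite(activation)) && all(is.finite(improvement)),
              "parameter_error", "need equal-length finite activation/improvement vectors")
  list(x = activation, y = improvement)
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("OLS (n = %d): slope %.4g (p = %.3g), intercept %.4g, adj. R2 %.4f\n",
              x$n, x$slope, x$slope_p, x$intercept, x$r2_adj))
  invisible(x)
}

#' Leave-one-out validation of the univariate regression
#'
#' Each observation is predicted from a model fit on the remaining n - 1;
#' the reported error is the mean squared out-of-sample prediction error
#' normalized by the improvement variance over the whole group (the same
#' normalizer for every fold), and its complement `r2_loo = 1 -
#' one_minus_r2` — which can be negative when out-of-sample predictions are
#' worse than the group mean. Per-fold predictions use the closed-form
#' leave-one-out residual e_i / (1 - h_ii) of OLS.
#'
#' @inheritParams fit_univariate
#' @param variance `"population"` (divide by n; default) or `"sample"`
#'   (divide by n - 1) convention for the group variance normalizer.
#' @return An object of class `loo_result`: list with `one_minus_r2`,
#'   `r2_loo`, `n`.
#' @export
loo_cv <- function(activation, improvement = NULL,
                   variance = c("population", "sample")) {
  variance <- match.arg(variance)
  xy <- as_xy(activation, improvement)
  x <- xy$x; y <- xy$y; n <- length(x)
  assert_that(n >= 4L, "insufficient_data", "need n >= 4 observations, got %d", n)
  degenerate <- which(vapply(seq_len(n), function(i) stats::var(x[-i]) == 0,
                             logical(1)))
  assert_that(length(degenerate) == 0L, "degenerate_fold",
              "removing observation(s) %s leaves a constant predictor",
              paste(degenerate, collapse = ", "))
  fit <- stats::lm(y ~ x)
  h <- stats::lm.influence(fit, do.coef = FALSE)$hat
  e_loo <- stats::residuals(fit) / (1 - h)
  denom <- if (variance == "population") mean((y - mean(y))^2) else stats::var(y)
  assert_that(denom > 0, "degenerate_outcome", "improvement has zero variance")
  one_minus_r2 <- mean(e_loo^2) / denom
  structure(list(one_minus_r2 = one_minus_r2, r2_loo = 1 - one_minus_r2, n = n),
            class = "loo_result")
}

#' @export
print.loo_result <- function(x, ...) {
  cat(sprintf("LOO (n = %d): 1 - R2 = %.4f, R2_loo = %.4f\n",
              x$n, x$one_minus_r2, x$r2_loo))
  invisible(x)
}

#' Screen structures for activation-outcome association
#'
#' Runs [fit_univariate()] and [loo_cv()] per structure and per partition
#' (each cohort separately plus all cohorts jointly, when the observation
#' table has a `cohort` column; otherwise joint only). Failures of a single
#' structure/partition (e.g. a degenerate predictor) are recorded in the
#' `error` column without aborting the screen.
#'
#' @param obs observation table from [build_observations()].
#' @param variance passed to [loo_cv()].
#' @return data frame with columns `structure`, `partition`, `n`, `slope`,
#'   `p`, `r2_adj`, `r2_loo`, `error`, sorted by `r2_adj` descending (NA
#'   last).
#' @export
structure_screen <- function(obs, variance = "population") {
  assert_that(is.data.frame(obs) && all(c("structure", "activation",
                                          "improvement") %in% names(obs)),
              "parameter_error", "obs must be an observation table")
  assert_that(length(unique(obs$structure)) >= 1L, "parameter_error",
              "need at least one structure")
  partitions <- list(joint = rep(TRUE, nrow(obs)))
  if (!is.null(obs$cohort))
    for (co in sort(unique(obs$cohort)))
      partitions[[co]] <- obs$cohort == co
  rows <- list()
  for (sname in sort(unique(obs$structure))) {
    for (pname in names(partitions)) {
      sel <- obs$structure == sname & partitions[[pname]]
      sub <- obs[sel, , drop = FALSE]
      row <- data.frame(structure = sname, partition = pname, n = nrow(sub),
                        slope = NA_real_, p = NA_real_, r2_adj = NA_real_,
                        r2_loo = NA_real_, error = NA_character_,
                        stringsAsFactors = FALSE)
      res <- tryCatch({
        fit <- fit_univariate(sub$activation, sub$improvement)
        loo <- loo_cv(sub$activation, sub$improvement, variance = variance)
        row$slope <- fit$slope; row$p <- fit$slope_p
        row$r2_adj <- fit$r2_adj; row$r2_loo <- loo$r2_loo
        row
      }, stimtract_error = function(e) {
        row$error <- conditionMessage(e)
        row
      })
      rows[[length(rows) + 1L]] <- res
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$r2_adj, out$structure, out$partition, na.last = TRUE), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
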