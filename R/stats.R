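#' Greedy correlation filter for heterogeneity metrics
#'
#' Removes collinear predictors before regression: while any pair of
#' columns has |Pearson r| above the threshold, the member of the worst
#' (largest |r|) pair with the higher mean absolute correlation to all
#' other columns is dropped; ties break alphabetically (the later name is
#' dropped). The removal rule is one defensible fixed choice — the member
#' dropped from a correlated pair is not dictated by theory.
#'
#' @param metric_table data.frame of numeric columns
#' @param threshold absolute Pearson correlation above which a pair is
#'   considered redundant (default 0.7)
#' @return reduced data.frame; attribute `dropped` lists removed columns
#' @export
correlation_filter <- function(metric_table, threshold = 0.7) {
  stopifnot(ncol(metric_table) >= 2)
  keep <- names(metric_table)
  dropped <- character(0)
  repeat {
    if (length(keep) < 2) break
    cm <- abs(stats::cor(metric_table[keep]))
    diag(cm) <- 0
    worst <- max(cm)
    if (worst <= threshold) break
    pair <- which(cm == worst, arr.ind = TRUE)[1, ]
    a <- keep[pair[1]]; b <- keep[pair[2]]
    mean_abs <- function(v) mean(cm[v, keep != v])
    ma <- mean_abs(a); mb <- mean_abs(b)
    drop <- if (ma > mb) a else if (mb > ma) b else sort(c(a, b))[2]
    keep <- setdiff(keep, drop)
    dropped <- c(dropped, drop)
  }
  out <- metric_table[keep]
  attr(out, "dropped") <- dropped
  out
}

# Gaussian OLS AIC on the maximized-likelihood scale used by stepwise
# comparisons: n * log(RSS / n) + 2 * k (additive constant dropped)
ols_aic <- function(fit) {
  rss <- sum(stats::residuals(fit)^2)
  n <- length(stats::residuals(fit))
  k <- length(stats::coef(fit))
  n * log(rss / n) + 2 * k
}

#' Backward-stepwise AIC multiple regression
#'
#' Ordinary least squares of the response on the offered predictors,
#' followed by backward elimination: at each pass the term whose removal
#' most lowers the AIC is dropped, until no removal lowers it. Reports
#' the retained coefficients with p-values, adjusted R-squared and the
#' overall model p-value (F test; `NA` for an intercept-only model).
#' With few observations (n <= 12, e.g. ten study landscapes) a
#' small-sample flag is set and a warning issued.
#'
#' @param data data.frame holding response and predictors
#' @param response response column name
#' @param predictors character vector of predictor column names
#' @return list of class `stepwise_fit`: response, retained, coefficients
#'   (term, estimate, p_value), adj_r2, model_p, aic, aic_full,
#'   small_sample, fit (the final `lm`)
#' @export
stepwise_fit <- function(data, response, predictors) {
  n <- nrow(data)
  if (n <= length(predictors) + 2) {
    stop("stepwise_fit: need more observations than predictors + 2")
  }
  small_sample <- n <= 12
  if (small_sample) {
    warning(sprintf("stepwise_fit: only %d observations; estimates are fragile", n))
  }
  form <- stats::reformulate(predictors, response)
  fit <- stats::lm(form, data = data)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("stepwise_fit: rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  aic_full <- ols_aic(fit)

  terms_now <- predictors
  repeat {
    current <- ols_aic(fit)
    if (length(terms_now) == 0) break
    cand_aic <- vapply(terms_now, function(tm) {
      left <- setdiff(terms_now, tm)
      f <- if (length(left)) stats::reformulate(left, response)
           else stats::as.formula(paste(response, "~ 1"))
      ols_aic(stats::lm(f, data = data))
    }, numeric(1))
    best <- which.min(cand_aic)
    if (cand_aic[best] < current) {
      terms_now <- setdiff(terms_now, names(cand_aic)[best])
      fit <- if (length(terms_now)) {
        stats::lm(stats::reformulate(terms_now, response), data = data)
      } else {
        stats::lm(stats::as.formula(paste(response, "~ 1")), data = data)
      }
    } else break
  }

  sm <- summary(fit)
  coefs <- stats::coef(sm)
  model_p <- if (!is.null(sm$fstatistic)) {
    unname(stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                     lower.tail = FALSE))
  } else NA_real_
  out <- list(
    response = response,
    retained = terms_now,
    coefficients = data.frame(term = rownames(coefs),
                              estimate = coefs[, "Estimate"],
                              p_value = coefs[, "Pr(>|t|)"],
                              row.names = NULL),
    adj_r2 = sm$adj.r.squared,
    model_p = model_p,
    aic = ols_aic(fit),
    aic_full = aic_full,
    small_sample = small_sample,
    fit = fit
  )
  stopifnot(out$aic <= aic_full + 1e-9)
  class(out) <- "stepwise_fit"
  out
}

#' @export
print.stepwise_fit <- function(x, ...) {
  cat(sprintf("stepwise_fit: %s ~ %s\n", x$response,
              if (length(x$retained)) paste(x$retained, collapse = " + ")
              else "1 (intercept only)"))
  cat(sprintf("  adj R2 = %.3f, model p = %s, AIC = %.2f (full %.2f)\n",
              x$adj_r2,
              if (is.na(x$model_p)) "NA" else format.pval(x$model_p, digits = 3),
              x$aic, x$aic_full))
  if (x$small_sample) cat("  [small-sample flag set]\n")
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Heterogeneity-vs-endpoint regression stage
#'
#' Convenience wrapper reproducing the analysis pipeline: correlation-filter
#' the metric table, then backward-stepwise fit each endpoint (or endpoint
#' change) on the retained metrics.
#'
#' @param metric_table data.frame of heterogeneity metrics, one row per
#'   landscape
#' @param endpoint_table data.frame of responses, rows aligned with
#'   `metric_table`
#' @param threshold correlation-filter threshold
#' @return named list of `stepwise_fit` objects, one per endpoint column;
#'   attribute `retained_metrics` lists the filtered predictor set
#' @export
heterogeneity_regression <- function(metric_table, endpoint_table,
                                     threshold = 0.7) {
  filtered <- correlation_filter(metric_table, threshold)
  preds <- names(filtered)
  out <- lapply(names(endpoint_table), function(ep) {
    d <- cbind(filtered, endpoint_table[ep])
    stepwise_fit(d, ep, preds)
  })
  names(out) <- names(endpoint_table)
  attr(out, "retained_metrics") <- preds
  out
}
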