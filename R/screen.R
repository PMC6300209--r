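# Exhaustive AICc screening of linear models S_i ~ L, P, D with
# hierarchical interactions, plus regression diagnostics and the
# outlier-removal protocol.

#' Enumerate hierarchical model term sets
#'
#' Returns every marginality-respecting (downward-closed) set of terms
#' over the given main effects and their interactions: an interaction is
#' included only when all its constituent main effects are present. The
#' intercept-only (empty) set is first; order is by size then
#' lexicographic.
#'
#' @param predictors Character vector of main-effect names.
#' @return List of character vectors (term sets); `character(0)` is the
#'   intercept-only model. For three predictors there are 19 models.
#' @export
enumerate_models <- function(predictors = c("L", "P", "D")) {
  stopifnot(length(predictors) >= 1)
  terms <- character(0)
  for (k in seq_along(predictors)) {
    terms <- c(terms, utils::combn(predictors, k, FUN = paste, collapse = ":"))
  }
  parts <- strsplit(terms, ":", fixed = TRUE)
  keep <- list(character(0))
  for (code in seq_len(2^length(terms) - 1)) {
    sel <- which(bitwAnd(code, bitwShiftL(1L, seq_along(terms) - 1L)) != 0)
    set <- terms[sel]
    ok <- TRUE
    for (s in sel) {
      p <- parts[[s]]
      if (length(p) > 1) {
        # every lower-order margin of this interaction must be present
        for (k in seq_len(length(p) - 1)) {
          need <- utils::combn(p, k, FUN = paste, collapse = ":")
          if (!all(need %in% set)) { ok <- FALSE; break }
        }
      }
      if (!ok) break
    }
    if (ok) keep <- c(keep, list(set))
  }
  sizes <- vapply(keep, length, 0L)
  labs <- vapply(keep, paste, "", collapse = "+")
  keep[order(sizes, labs)]
}

#' Small-sample corrected AIC
#'
#' `AICc = AIC + 2k(k+1)/(n - k - 1)` where `k` is the number of
#' estimated parameters: for Gaussian linear models the coefficients plus
#' the error variance; for binomial GLMs the coefficients only.
#'
#' @param fit An `lm` or `glm` object.
#' @return AICc value (`NA` with a warning when `n <= k + 1`).
#' @export
aicc <- function(fit) {
  ll <- stats::logLik(fit)
  k <- attr(ll, "df")
  n <- stats::nobs(fit)
  if (n <= k + 1) {
    warning("AICc undefined: n <= k + 1")
    return(NA_real_)
  }
  -2 * as.numeric(ll) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

terms_to_formula <- function(response, term_set) {
  rhs <- if (length(term_set) == 0) "1" else paste(term_set, collapse = " + ")
  stats::as.formula(paste(response, "~", rhs))
}

#' Fit one linear model for a space-use measure
#'
#' Ordinary least squares of `response` on a hierarchical term set over
#' the predictors L (lameness), P (parity) and D (days in milk), with
#' AICc and the overall F test against the intercept-only model.
#'
#' @param data data.frame with the response column and columns `L`, `P`,
#'   `D`.
#' @param response Response column name (e.g. `"S4"`).
#' @param term_set Character vector of terms (empty = intercept only).
#' @return List of class `screen_fit`: `lm` object plus `response`,
#'   `terms`, `aicc`, `f_stat`, `f_p`, coefficient table.
#' @export
fit_linear <- function(data, response, term_set = character(0)) {
  data <- data[stats::complete.cases(data[, c(response, "L", "P", "D")]), ,
               drop = FALSE]
  f <- terms_to_formula(response, term_set)
  fit <- stats::lm(f, data = data)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; collinear term(s): ",
         paste(bad, collapse = ", "))
  }
  sm <- summary(fit)
  fs <- sm$fstatistic
  structure(list(
    fit = fit, response = response, terms = term_set,
    n = stats::nobs(fit),
    aicc = suppressWarnings(aicc(fit)),
    f_stat = if (is.null(fs)) NA_real_ else unname(fs[1]),
    f_p = if (is.null(fs)) NA_real_ else
      unname(stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE)),
    coef = sm$coefficients,
    removed = character(0)
  ), class = "screen_fit")
}

#' @export
print.screen_fit <- function(x, ...) {
  cat(sprintf("%s ~ %s  (n = %d, AICc = %.2f)\n", x$response,
              if (length(x$terms)) paste(x$terms, collapse = " + ") else "1",
              x$n, x$aicc))
  stats::printCoefmat(x$coef, ...)
  invisible(x)
}

#' Non-constant variance (Cook-Weisberg) score test
#'
#' Score test of the error variance against the fitted values: with
#' `u = e^2 / sigma2_hat`, the statistic is half the regression sum of
#' squares of `u` on the fitted values, compared to chi-squared with 1
#' degree of freedom.
#'
#' @param fit An `lm` object.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
ncv_test <- function(fit) {
  e <- stats::residuals(fit)
  if (length(e) < 3 || stats::sd(e) < 1e-12)
    return(list(statistic = NA_real_, df = 1, p_value = NA_real_))
  s2 <- sum(e^2) / length(e)
  u <- e^2 / s2
  aux <- stats::lm(u ~ stats::fitted(fit))
  ssr <- sum((stats::fitted(aux) - mean(u))^2)
  stat <- ssr / 2
  list(statistic = stat, df = 1,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Variance inflation factors for the main predictors
#'
#' `VIF_j = 1 / (1 - R^2_j)` from regressing predictor `j` on the other
#' predictors (main effects only, computed on the metadata regardless of
#' which terms a particular model selected).
#'
#' @param data data.frame containing the predictor columns.
#' @param predictors Predictor column names.
#' @return Named vector of VIF scores (`Inf` for a perfectly collinear
#'   predictor).
#' @export
vif_scores <- function(data, predictors = c("L", "P", "D")) {
  out <- stats::setNames(rep(NA_real_, length(predictors)), predictors)
  for (j in seq_along(predictors)) {
    others <- predictors[-j]
    f <- stats::as.formula(paste(predictors[j], "~",
                                 paste(others, collapse = " + ")))
    r2 <- summary(stats::lm(f, data = data))$r.squared
    out[j] <- if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  out
}

#' Diagnostic battery for a fitted screen model
#'
#' Shapiro-Wilk normality of residuals, the non-constant variance score
#' test, and VIFs of the main predictors, with 5% flags (VIF flag at 10).
#'
#' @param sfit A [fit_linear()] result.
#' @param data Data used for the fit (for VIF computation).
#' @param alpha Significance level for flags.
#' @return List with `shapiro_p`, `ncv_p`, `vif`, and logical flags.
#' @export
model_diagnostics <- function(sfit, data, alpha = 0.05) {
  e <- stats::residuals(sfit$fit)
  sw <- if (length(e) >= 3 && stats::sd(e) > 0)
    stats::shapiro.test(e)$p.value else NA_real_
  nc <- ncv_test(sfit$fit)
  vif <- vif_scores(data)
  list(shapiro_p = sw, ncv_p = nc$p_value, vif = vif,
       normality_rejected = !is.na(sw) && sw < alpha,
       heteroscedastic = !is.na(nc$p_value) && nc$p_value < alpha,
       collinear = any(vif > 10))
}

#' Outlier-removal protocol
#'
#' While the Shapiro-Wilk test rejects residual normality at the 5% level
#' and fewer than `max_removals` observations have been removed, drops the
#' observation with the largest absolute studentized residual and refits.
#' If normality is still rejected afterwards the fit is flagged invalid.
#' Named observations can be force-removed first via `force_remove`.
#'
#' @param data data.frame with response and predictors; must contain a
#'   `cow_id` column used to report removed ids.
#' @param response Response column name.
#' @param term_set Terms of the model under the protocol.
#' @param max_removals Maximum number of removals (default 2).
#' @param alpha Normality significance level.
#' @param force_remove Character vector of `cow_id`s to drop before
#'   testing.
#' @return A `screen_fit` with `removed` (ids), `shapiro_p`, and
#'   `invalid` flag.
#' @export
outlier_protocol <- function(data, response, term_set, max_removals = 2,
                             alpha = 0.05, force_remove = character(0)) {
  stopifnot("cow_id" %in% names(data))
  dat <- data[!data$cow_id %in% force_remove, , drop = FALSE]
  removed <- intersect(force_remove, data$cow_id)
  repeat {
    sfit <- fit_linear(dat, response, term_set)
    e <- stats::residuals(sfit$fit)
    sw <- if (length(e) >= 3 && stats::sd(e) > 0)
      stats::shapiro.test(e)$p.value else NA_real_
    if (is.na(sw) || sw >= alpha || length(removed) >= max_removals) break
    rs <- abs(stats::rstudent(sfit$fit))
    worst <- which.max(rs)
    removed <- c(removed, dat$cow_id[worst])
    dat <- dat[-worst, , drop = FALSE]
  }
  sfit$removed <- removed
  sfit$shapiro_p <- sw
  sfit$invalid <- !is.na(sw) && sw < alpha
  sfit
}

#' Screen all space-use measures against L, P and D
#'
#' For each response: fits every hierarchical term set, selects the
#' minimum-AICc model, applies the outlier protocol to the selected model,
#' and reports coefficients, the F test against intercept-only, and the
#' diagnostic battery.
#'
#' @param features Feature table (columns `cow_id`, `S1`..`S16`).
#' @param metadata Metadata table (columns `cow_id`, `lame`, `parity`,
#'   `dim`).
#' @param responses Responses to screen (default all S columns present).
#' @param max_removals Outlier-protocol cap.
#' @param alpha Significance level.
#' @return Object of class `screen_report`: list with `table` (one row
#'   per response), `fits` (named list of `screen_fit`s) and `vif`.
#' @export
screen_all <- function(features, metadata,
                       responses = grep("^S[0-9]+$", names(features), value = TRUE),
                       max_removals = 2, alpha = 0.05) {
  data <- merge_features(features, metadata)
  vif <- vif_scores(data)
  fits <- list(); rows <- list()
  for (resp in responses) {
    usable <- sum(stats::complete.cases(data[, c(resp, "L", "P", "D")]))
    if (usable < 3) {
      rows[[resp]] <- data.frame(
        response = resp, terms = NA_character_, n = usable,
        aicc = NA_real_, f_stat = NA_real_, f_p = NA_real_,
        shapiro_p = NA_real_, ncv_p = NA_real_,
        n_removed = NA_integer_, removed = NA_character_,
        significant = NA, invalid = TRUE, stringsAsFactors = FALSE)
      next
    }
    cand <- enumerate_models()
    best <- NULL
    for (ts in cand) {
      # skip models that cannot be fitted at this sample size
      if (usable < length(ts) + 3) next
      sf <- tryCatch(fit_linear(data, resp, ts), error = function(e) NULL)
      if (is.null(sf) || is.na(sf$aicc)) next
      if (is.null(best) || sf$aicc < best$aicc) best <- sf
    }
    final <- outlier_protocol(data, resp, best$terms, max_removals, alpha)
    diag <- model_diagnostics(final, data, alpha)
    fits[[resp]] <- final
    coefs <- final$coef
    sig <- nrow(coefs) > 1 && any(coefs[-1, "Pr(>|t|)"] < alpha)
    rows[[resp]] <- data.frame(
      response = resp,
      terms = if (length(final$terms)) paste(final$terms, collapse = "+") else "(intercept)",
      n = final$n, aicc = final$aicc,
      f_stat = final$f_stat, f_p = final$f_p,
      shapiro_p = final$shapiro_p, ncv_p = diag$ncv_p,
      n_removed = length(final$removed),
      removed = paste(final$removed, collapse = ";"),
      significant = sig, invalid = isTRUE(final$invalid),
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(list(table = tab, fits = fits, vif = vif),
            class = "screen_report")
}

# join features with metadata and expose the canonical predictor names
merge_features <- function(features, metadata) {
  need <- c("cow_id", "lame", "parity", "dim")
  miss <- setdiff(need, names(metadata))
  if (length(miss))
    stop("metadata is missing column(s): ", paste(miss, collapse = ", "))
  data <- merge(features, metadata, by = "cow_id")
  data$L <- as.numeric(data$lame)
  data$P <- as.numeric(data$parity)
  data$D <- as.numeric(data$dim)
  data
}

#' @export
print.screen_report <- function(x, ...) {
  cat("Model screen:", nrow(x$table), "responses\n")
  cat("VIF:", paste(sprintf("%s = %.3f", names(x$vif), x$vif), collapse = ", "),
      "\n\n")
  print(x$table[, c("response", "terms", "n", "aicc", "f_p", "significant")],
        digits = 4)
  invisible(x)
}

#' Write a screen report to delimited text plus JSON
#'
#' @param report A `screen_report`.
#' @param path Output path for the table; coefficients go to
#'   `<path>.json`.
#' @export
write_screen_report <- function(report, path) {
  utils::write.table(report$table, path, sep = ",", row.names = FALSE,
                     quote = FALSE)
  side <- lapply(report$fits, function(f) {
    list(terms = f$terms, removed = f$removed,
         coefficients = apply(f$coef, 1, as.list))
  })
  jsonlite::write_json(list(vif = as.list(report$vif), models = side),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
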