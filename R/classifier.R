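# Logistic lameness classifier: AICc subset selection over the measures
# found significant in the linear screen, with in-sample (and
# leave-one-out) accuracy reporting.

#' Candidate feature pool from a screen report
#'
#' The measures whose selected linear model has at least one significant
#' (5% by default) non-intercept coefficient. Intercept-only selections
#' never qualify.
#'
#' @param report A [screen_all()] report.
#' @param alpha Significance level.
#' @return Character vector of measure names (possibly empty).
#' @export
candidate_features <- function(report, alpha = 0.05) {
  stopifnot(inherits(report, "screen_report"))
  pool <- character(0)
  for (resp in names(report$fits)) {
    co <- report$fits[[resp]]$coef
    if (nrow(co) > 1 && any(co[-1, "Pr(>|t|)"] < alpha))
      pool <- c(pool, resp)
  }
  pool
}

logistic_aicc <- function(fit) {
  ll <- stats::logLik(fit)
  k <- attr(ll, "df")   # binomial: number of coefficients
  n <- stats::nobs(fit)
  if (n <= k + 1) return(NA_real_)
  -2 * as.numeric(ll) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

fit_logistic <- function(data, subset_vars) {
  f <- terms_to_formula("lame", subset_vars)
  warned <- FALSE
  fit <- withCallingHandlers(
    stats::glm(f, data = data, family = stats::binomial()),
    warning = function(w) {
      warned <<- TRUE
      invokeRestart("muffleWarning")
    })
  p <- stats::fitted(fit)
  # complete/quasi-separation: fitted probabilities driven to 0/1 or
  # exploding coefficients
  separated <- warned || any(p > 1 - 1e-8 | p < 1e-8) ||
    any(abs(stats::coef(fit)) > 1e3)
  cls <- as.integer(p >= 0.5)
  list(fit = fit, separated = separated, converged = fit$converged,
       prob = p, class = cls)
}

#' AICc subset selection for the logistic lameness model
#'
#' Fits a maximum-likelihood logistic regression of lameness on every
#' subset of the candidate pool of size 1..`max_size`, ranks converged,
#' non-separated fits by AICc, and reports in-sample classification at
#' the p >= 0.5 threshold (ties classify as lame). Separated or
#' non-converged fits are kept in the output but flagged and ranked after
#' all clean fits.
#'
#' @param features Feature table (columns `cow_id`, measures).
#' @param metadata Metadata with binary `lame` labels.
#' @param pool Candidate measure names (see [candidate_features()]).
#' @param max_size Largest subset size (default 3).
#' @param loo Also compute leave-one-out accuracy per model (an extension
#'   beyond the in-sample metric; default TRUE).
#' @return Object of class `lameness_ranking`: list with `table` (one row
#'   per subset, AICc ascending) and `fits` (named list).
#' @export
select_logistic <- function(features, metadata, pool, max_size = 3,
                            loo = TRUE) {
  if (length(pool) == 0) {
    warning("empty candidate pool; classifier skipped")
    return(structure(list(table = NULL, fits = list()),
                     class = "lameness_ranking"))
  }
  stopifnot(all(pool %in% names(features)), all(metadata$lame %in% 0:1))
  data <- merge(features, metadata[, c("cow_id", "lame")], by = "cow_id")
  data <- data[stats::complete.cases(data[, c("lame", pool)]), , drop = FALSE]
  subsets <- list()
  for (k in seq_len(min(max_size, length(pool)))) {
    subsets <- c(subsets, utils::combn(sort(pool), k, simplify = FALSE))
  }
  rows <- list(); fits <- list()
  for (sv in subsets) {
    lab <- paste(sv, collapse = "+")
    lf <- tryCatch(fit_logistic(data, sv), error = function(e) NULL)
    if (is.null(lf)) next
    correct <- sum(lf$class == data$lame)
    mis <- data$cow_id[lf$class != data$lame]
    acc_loo <- if (loo) loo_accuracy(data, sv) else NA_real_
    rows[[lab]] <- data.frame(
      subset = lab, size = length(sv),
      aicc = logistic_aicc(lf$fit),
      correct = correct, n = nrow(data),
      misclassified = paste(mis, collapse = ";"),
      separated = lf$separated, converged = lf$converged,
      loo_accuracy = acc_loo, stringsAsFactors = FALSE)
    fits[[lab]] <- lf
  }
  tab <- do.call(rbind, rows)
  clean <- !tab$separated & tab$converged & !is.na(tab$aicc)
  tab <- tab[order(!clean, tab$aicc), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(table = tab, fits = fits), class = "lameness_ranking")
}

loo_accuracy <- function(data, sv) {
  n <- nrow(data)
  hit <- logical(n)
  for (i in seq_len(n)) {
    lf <- tryCatch(fit_logistic(data[-i, , drop = FALSE], sv),
                   error = function(e) NULL)
    if (is.null(lf)) { hit[i] <- NA; next }
    p <- suppressWarnings(
      stats::predict(lf$fit, newdata = data[i, , drop = FALSE],
                     type = "response"))
    hit[i] <- as.integer(p >= 0.5) == data$lame[i]
  }
  mean(hit, na.rm = TRUE)
}

#' @export
print.lameness_ranking <- function(x, ...) {
  if (is.null(x$table)) {
    cat("Lameness classifier: no candidate features\n")
    return(invisible(x))
  }
  cat("Lameness classifier ranking (AICc ascending):\n")
  print(utils::head(
    x$table[, c("subset", "aicc", "correct", "n", "misclassified", "separated")],
    10), digits = 4)
  invisible(x)
}

#' Predict lameness probability and class for new cows
#'
#' Applies the logistic decision rule `p = plogis(beta . x)`; a cow is
#' classified lame when `p >= 0.5` (ties go to lame).
#'
#' @param fit A fitted entry from [select_logistic()] (`$fits[[subset]]`),
#'   or any binomial `glm`.
#' @param newdata data.frame with the model's feature columns; rows with
#'   missing features get `NA` predictions.
#' @return data.frame with `prob` and `class` columns.
#' @export
predict_lameness <- function(fit, newdata) {
  glmfit <- if (inherits(fit, "glm")) fit else fit$fit
  vars <- attr(stats::terms(glmfit), "term.labels")
  ok <- stats::complete.cases(newdata[, vars, drop = FALSE])
  prob <- rep(NA_real_, nrow(newdata))
  prob[ok] <- suppressWarnings(
    stats::predict(glmfit, newdata = newdata[ok, , drop = FALSE],
                   type = "response"))
  data.frame(prob = prob, class = ifelse(is.na(prob), NA_integer_,
                                         as.integer(prob >= 0.5)))
}
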