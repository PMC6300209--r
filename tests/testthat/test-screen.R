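test_that("model enumeration is exhaustive and marginality-respecting", {
  expect_equal(enumerate_models("A"), list(character(0), "A"))
  m2 <- enumerate_models(c("A", "B"))
  expect_length(m2, 5)
  expect_true(list(c("A", "B", "A:B")) %in% m2 ||
              any(vapply(m2, function(s) setequal(s, c("A", "B", "A:B")), TRUE)))
  # every set containing an interaction contains its margins
  m3 <- enumerate_models(c("L", "P", "D"))
  for (s in m3) {
    for (term in s) {
      parts <- strsplit(term, ":")[[1]]
      if (length(parts) > 1) expect_true(all(parts %in% s))
    }
    # downward-closed also for the three-way term's two-way margins
    if ("L:P:D" %in% s)
      expect_true(all(c("L:P", "L:D", "P:D") %in% s))
  }
  # intercept-only first; no duplicates
  expect_equal(m3[[1]], character(0))
  labs <- vapply(m3, paste, "", collapse = "+")
  expect_equal(anyDuplicated(labs), 0L)
  expect_length(m3, 19)
})

test_that("fit_linear recovers noiseless coefficients and the sample mean", {
  md <- make_meta(20)
  md$L <- md$lame; md$P <- md$parity; md$D <- md$dim
  md$y <- 2 + 3 * md$P
  f <- fit_linear(md, "y", "P")
  expect_equal(unname(f$coef[, "Estimate"]), c(2, 3), tolerance = 1e-8)
  expect_lt(max(abs(residuals(f$fit))), 1e-8)
  md$y3 <- rep(c(2, 4, 6), length.out = 20)
  f0 <- fit_linear(md, "y3", character(0))
  expect_equal(unname(f0$coef[1, "Estimate"]), mean(md$y3))
  # rank-deficient designs are named
  md$L2 <- md$L
  expect_error(fit_linear(md, "y", c("L", "L2")), "collinear")
})

test_that("AICc matches the independent formula oracle", {
  set.seed(33)
  n <- 20
  md <- make_meta(n)
  md$L <- md$lame; md$P <- md$parity; md$D <- md$dim
  md$y <- 1 + 0.5 * md$L - 0.2 * md$P + rnorm(n)
  for (ts in list(character(0), "L", c("L", "P"), c("L", "P", "D"))) {
    f <- fit_linear(md, "y", ts)
    X <- cbind(1, as.matrix(md[, ts, drop = FALSE]))
    expect_equal(f$aicc, aicc_oracle(md$y, X), tolerance = 1e-10,
                 info = paste(ts, collapse = "+"))
  }
  # glm-based binomial AICc oracle for the classifier's count convention
  y <- md$lame
  g <- glm(y ~ md$P, family = binomial())
  k <- 2
  expect_equal(barnspace:::logistic_aicc(g),
               -2 * as.numeric(logLik(g)) + 2 * k + 2 * k * (k + 1) / (n - k - 1))
})

test_that("VIF: orthogonality, duplication, and the R2 = 0.75 case", {
  set.seed(44)
  n <- 64
  d <- data.frame(L = rep(c(0, 1), n / 2), P = rep(c(0, 0, 1, 1), n / 4))
  d$D <- rnorm(n)
  v <- vif_scores(d, c("L", "P", "D"))
  expect_equal(unname(v), rep(1, 3), tolerance = 0.15)
  # duplicated predictor -> infinite VIF (over threshold)
  d$L2 <- d$L
  v <- vif_scores(d, c("L", "L2", "D"))
  expect_true(is.infinite(v[["L"]]) && is.infinite(v[["L2"]]))
  # construct predictor with R2 exactly 0.75 against the others
  z <- rnorm(n); z <- residuals(lm(z ~ d$L))
  z <- z / sqrt(sum(z^2))
  x <- scale(d$L, scale = FALSE); x <- x / sqrt(sum(x^2))
  d$J <- sqrt(0.75) * x + sqrt(0.25) * z
  v <- vif_scores(d, c("J", "L"))
  expect_equal(v[["J"]], 4, tolerance = 1e-8)
})

test_that("NCV score test flags planted heteroscedasticity", {
  set.seed(55)
  n <- 200
  x <- runif(n)
  hom <- lm(y ~ x, data = data.frame(x = x, y = 1 + x + rnorm(n)))
  het <- lm(y ~ x, data = data.frame(x = x, y = 1 + x + rnorm(n, 0, 0.2 + 2 * x)))
  expect_gt(ncv_test(hom)$p_value, 0.05)
  expect_lt(ncv_test(het)$p_value, 0.05)
  # degenerate residuals are flagged undefined
  const <- lm(y ~ 1, data = data.frame(y = rep(2, 5)))
  expect_true(is.na(ncv_test(const)$p_value))
})

test_that("outlier protocol removes the planted outlier and respects its cap", {
  md <- make_meta(20)
  md$L <- md$lame; md$P <- md$parity; md$D <- md$dim
  set.seed(60)
  md$y <- 1 + rnorm(20, 0, 0.5)
  # well-behaved data: zero removals
  f <- outlier_protocol(md, "y", "L")
  expect_length(f$removed, 0)
  # plant a 10-sigma outlier
  md$y[7] <- md$y[7] + 10 * 0.5
  f <- outlier_protocol(md, "y", "L")
  expect_equal(f$removed, md$cow_id[7])
  expect_equal(f$n, 19)
  # removals never exceed the cap, even for wild data
  md$y <- rcauchy(20)
  f <- outlier_protocol(md, "y", "L", max_removals = 2)
  expect_lte(length(f$removed), 2)
  # forced named removal is honoured
  f <- outlier_protocol(md, "y", "L", force_remove = c("c03", "c09"))
  expect_true(all(c("c03", "c09") %in% f$removed))
})

test_that("screen_all: report shape, selection consistency, recovery", {
  set.seed(77)
  md <- make_meta(20)
  ft <- data.frame(cow_id = md$cow_id)
  for (k in 1:16) ft[[paste0("S", k)]] <- rnorm(20)
  # plant a strong lameness effect on S4 only
  ft$S4 <- 0.32 - 0.2 * md$lame + rnorm(20, 0, 0.04)
  rep <- screen_all(ft, md)
  expect_equal(nrow(rep$table), 16)
  expect_equal(rep$table$response, paste0("S", 1:16))
  s4 <- rep$fits[["S4"]]
  expect_true("L" %in% s4$terms)
  expect_lt(s4$coef["L", "Estimate"], 0)
  # the selected AICc is the minimum over all candidate fits
  data <- barnspace:::merge_features(ft, md)
  all_aicc <- vapply(enumerate_models(), function(ts)
    fit_linear(data, "S4", ts)$aicc, 0)
  best_full <- min(all_aicc)
  # protocol may have removed points, so compare on the pre-removal fit
  pre <- fit_linear(data, "S4", s4$terms)
  expect_equal(pre$aicc, best_full)
  # noiseless recovery through the full screen
  ft$S1 <- 5 + 2 * md$parity
  rep2 <- screen_all(ft, md, responses = "S1")
  f1 <- rep2$fits[["S1"]]
  expect_true("P" %in% f1$terms)
  expect_equal(f1$coef["(Intercept)", "Estimate"], 5, tolerance = 1e-6)
  expect_equal(f1$coef["P", "Estimate"], 2, tolerance = 1e-6)
})
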