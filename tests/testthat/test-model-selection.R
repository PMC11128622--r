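test_that("AICc applies the small-sample correction exactly", {
  expect_equal(aicc(100, 3, 128), 100 + 24 / 124, tolerance = 1e-12)
  expect_equal(aicc(100, 3, 5), 124)          # n - k - 1 = 1 is allowed
  expect_error(aicc(100, 3, 4), "n - k - 1")  # denominator 0
  expect_error(aicc(100, 3, 2), "n - k - 1")
  expect_lt(aicc(100, 3, 1e6) - 100, 1e-4)    # correction vanishes
  # ordering is invariant to a common shift of all log-likelihoods
  a <- c(100, 112, 95); shift <- 17.3
  expect_equal(order(vapply(a, aicc, numeric(1), k = 3, n = 50)),
               order(vapply(a + 2 * shift, aicc, numeric(1), k = 3, n = 50)))
})

test_that("logistic fits reproduce closed-form identities", {
  # saturated 2x2: exposed 10 cases / 5 controls, unexposed 10 / 20
  y <- c(rep(1, 10), rep(0, 5), rep(1, 10), rep(0, 20))
  x <- c(rep(1, 15), rep(0, 30))
  fit <- fit_logistic(y, cbind(intercept = 1, exposure = x))
  expect_equal(unname(exp(fit$coef["exposure"])), (10 * 20) / (10 * 5),
               tolerance = 1e-5)
  # intercept-only on a 50/50 outcome
  y2 <- rep(c(1, 0), 50)
  fit2 <- fit_logistic(y2, cbind(intercept = rep(1, 100)))
  expect_equal(fit2$log_likelihood, 100 * log(0.5), tolerance = 1e-8)
  expect_equal(fit2$aic, 2 - 2 * 100 * log(0.5), tolerance = 1e-8)
  expect_equal(fit2$aicc, aicc(fit2$aic, 1, 100))
  # defects are named
  expect_error(fit_logistic(y, cbind(intercept = 1, a = x, b = x)),
               "collinear.*b")
  expect_error(fit_logistic(rep(1, 30), cbind(intercept = rep(1, 30))),
               "constant outcome")
})

test_that("the retention rule requires every delta strictly above threshold", {
  expect_true(retained_by_delta_aic(c(12.3, 15.1, 10.5)))
  expect_false(retained_by_delta_aic(c(12.3, 9.9, 30.0)))
  expect_false(retained_by_delta_aic(c(10.0, 25, 25)))   # exactly 10: no
  expect_true(retained_by_delta_aic(c(10.0, 25, 25), threshold = 9.5))
  expect_false(retained_by_delta_aic(c(NA, 25, 25)))
})

test_that("all four competing models are fitted on the same samples", {
  set.seed(404)
  co <- simulate_epistatic_pair(default_penetrance_table(), 100, 100)
  # inject missingness into each variant separately
  co$dosage[1:7, 1] <- NA
  co$dosage[8:12, 2] <- NA
  cmp <- compete_models(co, "rsEPI1", "rsEPI2", c("1/1", "0/2"))
  expect_true(is.na(cmp$unevaluable))
  ns <- vapply(cmp$fits, `[[`, numeric(1), "n")
  expect_equal(unname(ns), rep(200 - 12, 4))
  expect_equal(names(cmp$fits), c("INTERACTION", "VAR1", "VAR2", "VAR1+VAR2"))
  expect_equal(cmp$delta, -cmp$delta_signed_interaction_minus)
  ks <- vapply(cmp$fits, `[[`, numeric(1), "k")
  expect_equal(unname(ks), c(3, 3, 3, 4))  # intercept + sex + terms
})

test_that("category effects are retained and purely marginal effects are not", {
  set.seed(515)
  co <- simulate_epistatic_pair(default_penetrance_table(), 120, 120)
  fit <- mbmdr(co, qc = FALSE)
  top <- fit$results[fit$results$significant, ][1, ]
  cmp <- compete_models(co, "rsEPI1", "rsEPI2",
                        strsplit(top$cells, ";")[[1]])
  expect_true(cmp$retained)
  expect_true(all(cmp$delta > 10))
  # additive marginal-only signal: the interaction indicator cannot beat
  # the additive dosage model by a decisive margin
  com <- simulate_epistatic_pair(additive_penetrance_table(), 120, 120)
  fm <- mbmdr(com, qc = FALSE)
  rm_ <- fm$results[fm$results$significant, ]
  if (nrow(rm_)) {
    cm <- compete_models(com, "rsEPI1", "rsEPI2",
                         strsplit(rm_$cells[1], ";")[[1]])
    expect_false(isTRUE(cm$retained))
  }
  # AICc consistency between the comparison and its component fits
  expect_equal(unname(cmp$aicc["VAR1"] - cmp$aicc["INTERACTION"]),
               unname(cmp$delta["VAR1"]))
})
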