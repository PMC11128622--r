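#' Small-sample corrected Akaike information criterion
#'
#' `AICc = AIC + 2k(k + 1) / (n - k - 1)`, defined for `n - k - 1 >= 1`.
#'
#' @param aic the AIC of a fitted model (`2k - 2 logLik`).
#' @param k number of estimated parameters (including intercept and any
#'   covariate terms).
#' @param n sample size.
#' @return the corrected criterion.
#' @export
aicc <- function(aic, k, n) {
  if (n - k - 1 < 1)
    stop("AICc undefined: need n - k - 1 >= 1 (n = ", n, ", k = ", k, ")")
  aic + 2 * k * (k + 1) / (n - k - 1)
}

#' Fit a logistic model from an explicit design matrix
#'
#' Maximum-likelihood logistic regression of a binary outcome on the given
#' design columns (the caller supplies the intercept and any sex column).
#' On detected separation the coefficients are re-estimated by a
#' Firth-type penalized fit, flagged in the result; the reported
#' log-likelihood is always the maximum-likelihood value so that
#' information criteria remain comparable across models.
#'
#' @param outcome binary 0/1 vector (or `"case"`/`"control"`).
#' @param design numeric design matrix with named columns, including the
#'   intercept.
#' @return an object of class `"model_fit"`: list with `coef`, `se`, `k`,
#'   `n`, `log_likelihood`, `aic`, `aicc` (`NA` when undefined) and
#'   `firth`.
#' @export
fit_logistic <- function(outcome, design) {
  if (is.character(outcome)) outcome <- as.integer(outcome == "case")
  y <- as.numeric(outcome)
  if (anyNA(y) || !all(y %in% c(0, 1))) stop("outcome must be binary 0/1")
  if (length(unique(y)) < 2) stop("constant outcome")
  X <- as.matrix(design)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dep <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(dep, collapse = ", "))
  }
  fit <- logit_fit_safe(X, y)
  k <- ncol(X)
  n <- length(y)
  ll <- fit$ml_loglik
  aic <- 2 * k - 2 * ll
  structure(list(coef = setNames(fit$coef, colnames(X)),
                 se = setNames(fit$se, colnames(X)),
                 k = k, n = n, log_likelihood = ll, aic = aic,
                 aicc = if (n - k - 1 >= 1) aicc(aic, k, n) else NA_real_,
                 firth = fit$firth),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("<model_fit> k = %d, n = %d, logLik = %.3f, AICc = %.3f%s\n",
              x$k, x$n, x$log_likelihood, x$aicc,
              if (x$firth) " (Firth fallback)" else ""))
  print(data.frame(coef = x$coef, se = x$se), digits = 4)
  invisible(x)
}

#' Retention rule on AICc differences
#'
#' A category-interaction model is retained only when its AICc beats
#' every competing model by strictly more than `threshold` (the
#' Burnham-Anderson "decisive support" convention); a difference of
#' exactly `threshold` does not retain.
#'
#' @param deltas numeric vector `AICc(competing) - AICc(interaction)`.
#' @param threshold retention threshold (default 10).
#' @return `TRUE` when all deltas exceed the threshold.
#' @export
retained_by_delta_aic <- function(deltas, threshold = 10) {
  all(!is.na(deltas)) && all(deltas > threshold)
}

#' Compete the category-interaction model against dosage models
#'
#' Fits four sex-adjusted logistic models on the identical
#' pairwise-complete sample set: the interaction model
#' `affection ~ sex + 1[cell in category]` and the three competitors
#' `VAR1` (`~ sex + dosage1`), `VAR2` (`~ sex + dosage2`) and
#' `VAR1+VAR2` (`~ sex + dosage1 + dosage2`, additive dosage coding).
#' Computes each model's AICc, the three differences
#' `delta = AICc(competing) - AICc(interaction)` (positive when the
#' interaction model is better), and retains the interaction model when
#' every delta is strictly greater than `delta_threshold`. The negated
#' differences are also emitted (`delta_signed_interaction_minus`), the
#' convention under which a favoured interaction model prints negative
#' values.
#'
#' @param x a [cohort()] with pedigree attached.
#' @param var1,var2 variant ids of the pair.
#' @param cells the category's cells: character `"g1/g2"` codes, a
#'   2-column dosage matrix, or cell indices 1..9.
#' @param delta_threshold retention threshold (default 10).
#' @param adjust_sex include the sex covariate (default `TRUE`; dropped
#'   automatically when sex is constant).
#' @return an object of class `"model_comparison"`: list with `fits`
#'   (named list of [fit_logistic()] results: INTERACTION, VAR1, VAR2,
#'   `VAR1+VAR2`), `aicc`, `delta`, `delta_signed_interaction_minus`,
#'   `retained` and `unevaluable` (reason string or `NA`).
#' @export
compete_models <- function(x, var1, var2, cells, delta_threshold = 10,
                           adjust_sex = TRUE) {
  d1 <- x$dosage[, var1]
  d2 <- x$dosage[, var2]
  aff <- affected01(x$samples)
  sexv <- sex01(x$samples)
  ok <- !is.na(d1) & !is.na(d2) & !is.na(aff)
  if (adjust_sex) ok <- ok & !is.na(sexv)
  y <- aff[ok]
  idx <- parse_cells(cells)
  ind <- as.numeric(cell_index(d1[ok], d2[ok]) %in% idx)
  base <- cbind(`(Intercept)` = rep(1, sum(ok)))
  if (adjust_sex && length(unique(sexv[ok])) > 1)
    base <- cbind(base, sex = sexv[ok])
  designs <- list(
    INTERACTION = cbind(base, category = ind),
    VAR1 = cbind(base, dosage1 = d1[ok]),
    VAR2 = cbind(base, dosage2 = d2[ok]),
    `VAR1+VAR2` = cbind(base, dosage1 = d1[ok], dosage2 = d2[ok]))
  fits <- list()
  for (m in names(designs)) {
    f <- tryCatch(fit_logistic(y, designs[[m]]), error = function(e) e)
    if (inherits(f, "error") ||
        (inherits(f, "model_fit") && is.na(f$aicc))) {
      reason <- if (inherits(f, "error")) conditionMessage(f) else
        "AICc undefined (n - k - 1 < 1)"
      return(structure(list(pair = paste(var1, var2, sep = "*"),
                            cells = format_cells(idx), fits = NULL,
                            aicc = NULL, delta = NULL,
                            delta_signed_interaction_minus = NULL,
                            retained = NA,
                            unevaluable = sprintf("model %s: %s", m, reason)),
                       class = "model_comparison"))
    }
    fits[[m]] <- f
  }
  av <- vapply(fits, `[[`, numeric(1), "aicc")
  delta <- av[c("VAR1", "VAR2", "VAR1+VAR2")] - av[["INTERACTION"]]
  structure(list(pair = paste(var1, var2, sep = "*"),
                 cells = format_cells(idx),
                 fits = fits, aicc = av, delta = delta,
                 delta_signed_interaction_minus = -delta,
                 retained = retained_by_delta_aic(delta, delta_threshold),
                 delta_threshold = delta_threshold,
                 unevaluable = NA_character_),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("<model_comparison> %s, cells {%s}\n", x$pair, x$cells))
  if (!is.na(x$unevaluable)) {
    cat("  unevaluable:", x$unevaluable, "\n")
    return(invisible(x))
  }
  cat("  AICc:", paste(sprintf("%s=%.2f", names(x$aicc), x$aicc),
                       collapse = ", "), "\n")
  cat("  delta (competing - interaction):",
      paste(sprintf("%.2f", x$delta), collapse = ", "), "\n")
  cat(sprintf("  retained (all > %g): %s\n", x$delta_threshold, x$retained))
  invisible(x)
}

#' Run model competition for an MB-MDR scan's categories
#'
#' Applies [compete_models()] to each selected category of a fitted scan.
#'
#' @param fit an [mbmdr()] object.
#' @param x the [cohort()] the scan was fitted on.
#' @param which `"significant"` (default) or `"all"`.
#' @param delta_threshold retention threshold (default 10).
#' @return data frame with one row per competed category: pair, category,
#'   cells, the four AICc values, the three deltas and `retained`.
#' @export
mbmdr_compete <- function(fit, x, which = c("significant", "all"),
                          delta_threshold = 10) {
  stopifnot(inherits(fit, "mbmdr"))
  which <- match.arg(which)
  res <- fit$results
  rows <- if (which == "significant") which(res$significant) else seq_len(nrow(res))
  out <- lapply(rows, function(i) {
    cmp <- compete_models(x, res$var1[i], res$var2[i],
                          strsplit(res$cells[i], ";", fixed = TRUE)[[1]],
                          delta_threshold = delta_threshold,
                          adjust_sex = fit$params$adjust_sex)
    if (!is.na(cmp$unevaluable))
      return(data.frame(pair = res$pair[i], category = res$category[i],
                        cells = res$cells[i], aicc_interaction = NA_real_,
                        aicc_var1 = NA_real_, aicc_var2 = NA_real_,
                        aicc_var1_var2 = NA_real_, delta_var1 = NA_real_,
                        delta_var2 = NA_real_, delta_var1_var2 = NA_real_,
                        retained = NA, unevaluable = cmp$unevaluable,
                        stringsAsFactors = FALSE))
    data.frame(pair = res$pair[i], category = res$category[i],
               cells = res$cells[i],
               aicc_interaction = cmp$aicc[["INTERACTION"]],
               aicc_var1 = cmp$aicc[["VAR1"]],
               aicc_var2 = cmp$aicc[["VAR2"]],
               aicc_var1_var2 = cmp$aicc[["VAR1+VAR2"]],
               delta_var1 = cmp$delta[["VAR1"]],
               delta_var2 = cmp$delta[["VAR2"]],
               delta_var1_var2 = cmp$delta[["VAR1+VAR2"]],
               retained = cmp$retained, unevaluable = NA_character_,
               stringsAsFactors = FALSE)
  })
  if (length(out)) do.call(rbind, out) else
    data.frame(pair = character(0), category = character(0),
               cells = character(0), aicc_interaction = numeric(0),
               aicc_var1 = numeric(0), aicc_var2 = numeric(0),
               aicc_var1_var2 = numeric(0), delta_var1 = numeric(0),
               delta_var2 = numeric(0), delta_var1_var2 = numeric(0),
               retained = logical(0), unevaluable = character(0))
}
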