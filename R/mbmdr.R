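#' Pair-level quality-control thresholds
#'
#' A variant pair enters the epistasis scan only when each variant has a
#' missing genotype rate strictly below `max_missing`, each variant shows
#' no deviation from Hardy-Weinberg equilibrium in controls
#' (`p > hwe_alpha`, exact test), and the two variants are not in linkage
#' disequilibrium (composite genotype `r^2 < max_r2`, strict).
#'
#' @param max_missing maximum missing genotype rate (exclusive,
#'   default 0.05).
#' @param hwe_alpha HWE rejection level in controls (default 0.01).
#' @param max_r2 maximum composite-LD r-squared (exclusive, default 0.2).
#' @return an object of class `"pair_qc_thresholds"`.
#' @export
pair_qc_thresholds <- function(max_missing = 0.05, hwe_alpha = 0.01,
                               max_r2 = 0.2) {
  structure(list(max_missing = max_missing, hwe_alpha = hwe_alpha,
                 max_r2 = max_r2), class = "pair_qc_thresholds")
}

#' Missing genotype rate of a dosage column
#'
#' @param dosage dosage vector (`NA` = missing).
#' @return fraction of missing entries.
#' @export
missing_rate <- function(dosage) {
  if (length(dosage) == 0) stop("empty dosage column")
  mean(is.na(dosage))
}

#' Composite linkage-disequilibrium r-squared of two dosage columns
#'
#' Squared Pearson correlation of genotype dosages over pairwise-complete
#' samples (phase-free composite LD). Returns `NA` when either column is
#' constant on the complete subset (the pair is then excluded from
#' scanning with reason `"r2_undefined"`).
#'
#' @param dosage_i,dosage_j dosage vectors of equal length.
#' @return r-squared in \[0, 1\], or `NA` when undefined.
#' @export
genotype_r2 <- function(dosage_i, dosage_j) {
  stopifnot(length(dosage_i) == length(dosage_j))
  ok <- !is.na(dosage_i) & !is.na(dosage_j)
  if (sum(ok) < 2) stop("fewer than 2 pairwise-complete samples")
  x <- dosage_i[ok]; y <- dosage_j[ok]
  if (length(unique(x)) < 2 || length(unique(y)) < 2) return(NA_real_)
  cor(x, y)^2
}

#' Pair-level quality control
#'
#' @param x a [cohort()] with pedigree attached.
#' @param var1,var2 variant ids.
#' @param thresholds a [pair_qc_thresholds()].
#' @return list with the per-rule values (`missing_rate_1/2`,
#'   `hwe_p_controls_1/2`, `r_squared`), `pass` and `first_fail`
#'   (`"pass"` when all rules hold).
#' @export
pair_qc <- function(x, var1, var2, thresholds = pair_qc_thresholds()) {
  d1 <- x$dosage[, var1]
  d2 <- x$dosage[, var2]
  ctrl <- which(x$samples$affected == "control")
  t <- thresholds
  hwe_of <- function(d) {
    dc <- d[ctrl]
    dc <- dc[!is.na(dc)]
    if (length(dc) == 0) return(NA_real_)
    hwe_exact_p(sum(dc == 0), sum(dc == 1), sum(dc == 2))
  }
  m1 <- missing_rate(d1); m2 <- missing_rate(d2)
  h1 <- hwe_of(d1); h2 <- hwe_of(d2)
  r2 <- tryCatch(genotype_r2(d1, d2), error = function(e) NA_real_)
  checks <- list(
    missing_1 = m1 < t$max_missing,
    missing_2 = m2 < t$max_missing,
    hwe_1 = !is.na(h1) && h1 > t$hwe_alpha,
    hwe_2 = !is.na(h2) && h2 > t$hwe_alpha,
    ld_r2 = !is.na(r2) && r2 < t$max_r2)
  fails <- names(checks)[!vapply(checks, isTRUE, logical(1))]
  if (length(fails) && is.na(r2) && "ld_r2" %in% fails)
    fails[fails == "ld_r2"] <- "r2_undefined"
  list(var1 = var1, var2 = var2,
       missing_rate_1 = m1, missing_rate_2 = m2,
       hwe_p_controls_1 = h1, hwe_p_controls_2 = h2,
       r_squared = r2,
       pass = length(fails) == 0,
       first_fail = if (length(fails)) fails[1] else "pass")
}

# ---- cell machinery -------------------------------------------------------

# cell index 1..9 from a dosage pair: 3*g1 + g2 + 1; NA when either missing
cell_index <- function(d1, d2) 3L * d1 + d2 + 1L

cell_labels_grid <- function() {
  g <- expand.grid(g2 = 0:2, g1 = 0:2)
  sprintf("%d/%d", g$g1, g$g2)  # "g1/g2" for cells 1..9
}

#' Build the 3x3 genotype cell table for a variant pair
#'
#' Cross-classifies samples by the dosage pair (additive 0/1/2 coding on
#' both axes) and counts cases and controls per cell. Samples with either
#' dosage missing are excluded from this pair only.
#'
#' @param x a [cohort()] with pedigree attached.
#' @param var1,var2 variant ids.
#' @return an object of class `"cell_table"`: list with `n_cases` and
#'   `n_controls` (3x3 matrices, rows = dosage of `var1`), `cell`
#'   (per-sample cell index 1..9, `NA` when incomplete), `complete`
#'   (logical), and the variant ids.
#' @export
build_cell_table <- function(x, var1, var2) {
  d1 <- x$dosage[, var1]
  d2 <- x$dosage[, var2]
  aff <- affected01(x$samples)
  complete <- !is.na(d1) & !is.na(d2) & !is.na(aff)
  cell <- ifelse(complete, cell_index(d1, d2), NA_integer_)
  nc <- matrix(0L, 3, 3, dimnames = list(g1 = 0:2, g2 = 0:2))
  nk <- nc
  tc <- tabulate(cell[complete & aff == 1L], nbins = 9)
  tk <- tabulate(cell[complete & aff == 0L], nbins = 9)
  # cell index runs g2 fastest within g1: fill by row
  nc[] <- matrix(tc, 3, 3, byrow = TRUE)
  nk[] <- matrix(tk, 3, 3, byrow = TRUE)
  structure(list(var1 = var1, var2 = var2, n_cases = nc, n_controls = nk,
                 cell = cell, complete = complete),
            class = "cell_table")
}

# core H/L/O labelling + pooled tests on raw vectors; used by the scan and
# re-run inside every permutation. `cell` is the 1..9 index over complete
# samples only; y is 0/1 affection; sex is 0/1 or NULL.
mbmdr_core <- function(cell, y, sex, alpha_cell = 0.1, min_cell = 10,
                       adjust_sex = TRUE, pooled = TRUE) {
  n_cell <- tabulate(cell, nbins = 9)
  sexv <- if (adjust_sex) sex else NULL
  if (!is.null(sexv) && anyNA(sexv)) sexv <- NULL
  p0 <- null_probs(y, sexv)
  Z <- if (!is.null(sexv) && length(unique(sexv)) > 1) cbind(1, sexv)
       else matrix(1, length(y), 1)
  labels <- rep("O", 9)
  cell_stat <- rep(NA_real_, 9)
  cell_p <- rep(NA_real_, 9)
  for (cc in which(n_cell >= min_cell)) {
    if (n_cell[cc] == length(y)) next   # single occupied cell: no contrast
    st <- score_test_indicator(as.numeric(cell == cc), y, p0, Z)
    cell_stat[cc] <- st$stat * st$direction
    cell_p[cc] <- st$p
    if (st$p <= alpha_cell && st$direction > 0) labels[cc] <- "H"
    else if (st$p <= alpha_cell && st$direction < 0) labels[cc] <- "L"
  }
  out <- list(labels = labels, cell_stat = cell_stat, cell_p = cell_p)
  if (pooled) {
    out$H <- pooled_test_core(cell, y, sexv, which(labels == "H"))
    out$L <- pooled_test_core(cell, y, sexv, which(labels == "L"))
  }
  out
}

pooled_test_core <- function(cell, y, sex, cells) {
  if (length(cells) == 0) return(NULL)
  xind <- as.numeric(cell %in% cells)
  if (all(xind == 1) || all(xind == 0)) return(NULL)
  w <- wald_indicator_test(xind, y, sex)
  # unadjusted cross-product OR (Haldane correction on zero margins)
  a <- sum(xind == 1 & y == 1); b <- sum(xind == 1 & y == 0)
  cc <- sum(xind == 0 & y == 1); d <- sum(xind == 0 & y == 0)
  if (any(c(a, b, cc, d) == 0)) { a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5 }
  w$or_unadjusted <- (a * d) / (b * cc)
  w$cells <- cells
  w$n_exposed <- sum(xind)
  w
}

#' Label the genotype cells of a pair as H, L or O
#'
#' Each cell holding at least `min_cell` samples is tested for association
#' of cell membership with affection by a sex-adjusted logistic score
#' test. A cell is labelled `H` (high risk) when the score direction is
#' positive and `p <= alpha_cell`, `L` (low risk) when negative and
#' significant, and `O` otherwise; cells below `min_cell` are `O`.
#' Because the score statistic is evaluated under the null fit
#' (intercept + sex), sparse cells cannot cause separation here.
#'
#' @param tab a [build_cell_table()] result.
#' @param x the [cohort()] the table was built from.
#' @param alpha_cell per-cell significance level (default 0.1).
#' @param min_cell minimum cell occupancy to test (default 10).
#' @param adjust_sex adjust for sex (default `TRUE`).
#' @return `tab` with added 3x3 matrices `labels`, `cell_stat` (signed
#'   score chi-square) and `cell_p`.
#' @export
label_cells <- function(tab, x, alpha_cell = 0.1, min_cell = 10,
                        adjust_sex = TRUE) {
  ok <- tab$complete
  core <- mbmdr_core(tab$cell[ok], affected01(x$samples)[ok],
                     sex01(x$samples)[ok], alpha_cell, min_cell,
                     adjust_sex, pooled = FALSE)
  to_mat <- function(v) matrix(v, 3, 3, byrow = TRUE,
                               dimnames = list(g1 = 0:2, g2 = 0:2))
  tab$labels <- to_mat(core$labels)
  tab$cell_stat <- to_mat(core$cell_stat)
  tab$cell_p <- to_mat(core$cell_p)
  tab$alpha_cell <- alpha_cell
  tab$min_cell <- min_cell
  tab
}

#' Pooled association test of an H or L category
#'
#' Pools the cells of one category into a single exposure indicator and
#' tests it against affection by sex-adjusted logistic regression (Wald
#' test; Firth-penalized fallback under separation, flagged). Also
#' reports the unadjusted 2x2 cross-product odds ratio.
#'
#' @param tab a labelled [cell_table][build_cell_table()] (see
#'   [label_cells()]), or an unlabelled one if `cells` is given.
#' @param x the [cohort()] the table was built from.
#' @param category `"H"` or `"L"`; ignored when `cells` is supplied.
#' @param cells optional explicit cell set, as a character vector of
#'   `"g1/g2"` codes or a 2-column matrix of dosages.
#' @param adjust_sex adjust for sex (default `TRUE`).
#' @return `NULL` when the category is empty, else a list with `stat`
#'   (Wald chi-square), `p`, `or`, `ci`, `or_unadjusted`, `cells`
#'   (indices), `n_exposed` and `firth`.
#' @export
pooled_category_test <- function(tab, x, category = c("H", "L"),
                                 cells = NULL, adjust_sex = TRUE) {
  ok <- tab$complete
  y <- affected01(x$samples)[ok]
  sexv <- if (adjust_sex) sex01(x$samples)[ok] else NULL
  if (is.null(cells)) {
    category <- match.arg(category)
    if (is.null(tab$labels)) stop("cell table is unlabelled; run label_cells()")
    idx <- which(t(tab$labels) == category)  # back to cell index order
  } else {
    idx <- parse_cells(cells)
  }
  if (length(idx) == 9) stop("category covers all cells: constant predictor")
  pooled_test_core(tab$cell[ok], y, sexv, idx)
}

# cells as "g1/g2" strings or k x 2 dosage matrix -> cell indices 1..9
parse_cells <- function(cells) {
  if (is.numeric(cells) && is.null(dim(cells))) return(as.integer(cells))
  if (is.matrix(cells)) return(cell_index(cells[, 1], cells[, 2]))
  m <- do.call(rbind, strsplit(as.character(cells), "/", fixed = TRUE))
  cell_index(as.integer(m[, 1]), as.integer(m[, 2]))
}

format_cells <- function(idx) {
  paste(cell_labels_grid()[idx], collapse = ";")
}

#' Fit an MB-MDR pairwise epistasis scan
#'
#' For every variant pair, builds the 3x3 dosage cell table, labels cells
#' as high-risk (H), low-risk (L) or uninformative (O) via sex-adjusted
#' score tests, and tests the pooled H and pooled L categories against
#' affection by sex-adjusted logistic regression. Benjamini-Hochberg
#' false-discovery rates are computed jointly across all H and L category
#' p-values of the scan; categories with `fdr_q < fdr_level` are flagged
#' significant. Results are ranked by p-value, breaking ties by
#' descending absolute statistic and then lexicographic pair id.
#'
#' Pairs failing pair-level QC ([pair_qc()]) are excluded and reported
#' with their first failing rule.
#'
#' @param x a [cohort()] with pedigree attached.
#' @param pairs optional 2-column matrix/data frame of variant ids to
#'   test; default all unordered pairs of variants in `x`.
#' @param alpha_cell,min_cell cell-labelling parameters, see
#'   [label_cells()].
#' @param fdr_level significance level on the category FDR (default
#'   0.05).
#' @param adjust_sex adjust all tests for sex (default `TRUE`).
#' @param qc run pair-level QC (default `TRUE`).
#' @param qc_thresholds a [pair_qc_thresholds()].
#' @return an object of class `"mbmdr"` with components `results` (one
#'   row per non-empty category: pair, genes, category, cells, statistic,
#'   p, fdr_q, significant, adjusted and unadjusted odds ratios, CI), `qc`
#'   (per-pair QC report), `tables` (labelled cell tables keyed by pair)
#'   and the scan parameters.
#' @export
mbmdr <- function(x, pairs = NULL, alpha_cell = 0.1, min_cell = 10,
                  fdr_level = 0.05, adjust_sex = TRUE, qc = TRUE,
                  qc_thresholds = pair_qc_thresholds()) {
  stopifnot(inherits(x, "cohort"))
  if (is.null(pairs)) {
    ids <- x$variants$variant_id
    if (length(ids) < 2) {
      pairs <- matrix(character(0), ncol = 2)
    } else pairs <- t(combn(ids, 2))
  }
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2) stop("pairs must have two columns")

  qc_rows <- list(); res_rows <- list(); tables <- list()
  for (i in seq_len(nrow(pairs))) {
    v1 <- pairs[i, 1]; v2 <- pairs[i, 2]
    pid <- paste(v1, v2, sep = "*")
    if (qc) {
      rep <- pair_qc(x, v1, v2, qc_thresholds)
      qc_rows[[i]] <- data.frame(pair = pid, var1 = v1, var2 = v2,
                                 missing_rate_1 = rep$missing_rate_1,
                                 missing_rate_2 = rep$missing_rate_2,
                                 hwe_p_controls_1 = rep$hwe_p_controls_1,
                                 hwe_p_controls_2 = rep$hwe_p_controls_2,
                                 r_squared = rep$r_squared,
                                 pass = rep$pass, first_fail = rep$first_fail,
                                 stringsAsFactors = FALSE)
      if (!rep$pass) next
    }
    tab <- build_cell_table(x, v1, v2)
    tab <- label_cells(tab, x, alpha_cell, min_cell, adjust_sex)
    tables[[pid]] <- tab
    ok <- tab$complete
    core <- list(H = pooled_category_test(tab, x, "H", adjust_sex = adjust_sex),
                 L = pooled_category_test(tab, x, "L", adjust_sex = adjust_sex))
    g1 <- x$variants$gene[match(v1, x$variants$variant_id)]
    g2 <- x$variants$gene[match(v2, x$variants$variant_id)]
    for (cat in c("H", "L")) {
      ct <- core[[cat]]
      if (is.null(ct)) next
      res_rows[[length(res_rows) + 1L]] <- data.frame(
        pair = pid, var1 = v1, var2 = v2, gene1 = g1, gene2 = g2,
        category = cat, cells = format_cells(ct$cells),
        n_cells = length(ct$cells), n_exposed = ct$n_exposed,
        n_complete = sum(ok),
        statistic = ct$stat, p = ct$p,
        or = ct$or, ci_lo = ct$ci[1], ci_hi = ct$ci[2],
        or_unadjusted = ct$or_unadjusted, firth = ct$firth,
        stringsAsFactors = FALSE)
    }
  }
  results <- if (length(res_rows)) do.call(rbind, res_rows) else
    data.frame(pair = character(0), var1 = character(0), var2 = character(0),
               gene1 = character(0), gene2 = character(0),
               category = character(0), cells = character(0),
               n_cells = integer(0), n_exposed = integer(0),
               n_complete = integer(0), statistic = numeric(0),
               p = numeric(0), or = numeric(0), ci_lo = numeric(0),
               ci_hi = numeric(0), or_unadjusted = numeric(0),
               firth = logical(0))
  if (nrow(results)) {
    results$fdr_q <- bh_adjust(results$p)
    results$significant <- results$fdr_q < fdr_level
    ord <- order(results$p, -abs(results$statistic), results$pair,
                 results$category)
    results <- results[ord, , drop = FALSE]
    rownames(results) <- NULL
  } else {
    results$fdr_q <- numeric(0)
    results$significant <- logical(0)
  }
  structure(list(results = results,
                 qc = if (length(qc_rows)) do.call(rbind, qc_rows) else NULL,
                 tables = tables,
                 params = list(alpha_cell = alpha_cell, min_cell = min_cell,
                               fdr_level = fdr_level, adjust_sex = adjust_sex),
                 call = match.call()),
            class = "mbmdr")
}

#' @export
print.mbmdr <- function(x, n = 6, ...) {
  nr <- nrow(x$results)
  nsig <- sum(x$results$significant)
  nexcl <- if (!is.null(x$qc)) sum(!x$qc$pass) else 0L
  cat(sprintf("<mbmdr> %d categories over %d pairs tested (%d pairs excluded by QC); %d significant at FDR < %g\n",
              nr, length(x$tables), nexcl, nsig, x$params$fdr_level))
  if (nr) {
    cols <- c("pair", "category", "cells", "statistic", "p", "fdr_q", "or")
    print(head(x$results[, cols], n), digits = 4)
  }
  invisible(x)
}

#' @export
summary.mbmdr <- function(object, ...) {
  res <- object$results
  structure(list(n_categories = nrow(res),
                 n_pairs = length(object$tables),
                 n_excluded = if (!is.null(object$qc)) sum(!object$qc$pass) else 0L,
                 significant = res[res$significant, , drop = FALSE],
                 params = object$params),
            class = "summary.mbmdr")
}

#' @export
print.summary.mbmdr <- function(x, ...) {
  cat(sprintf("MB-MDR scan: %d pairs, %d categories, %d excluded by QC\n",
              x$n_pairs, x$n_categories, x$n_excluded))
  cat(sprintf("Significant categories (FDR < %g): %d\n",
              x$params$fdr_level, nrow(x$significant)))
  if (nrow(x$significant))
    print(x$significant[, c("pair", "category", "cells", "p", "fdr_q",
                            "or", "ci_lo", "ci_hi")], digits = 4)
  invisible(x)
}

#' Permutation p-value for one pair's H or L category
#'
#' Permutes affection labels (within sex strata by default, preserving
#' the sex-phenotype margin that the adjustment models), re-runs cell
#' labelling and the pooled category test for each permutation, and
#' returns `p = (1 + #\{permuted statistic >= observed\}) / (B + 1)`. A
#' permutation in which the category is empty contributes a statistic of
#' zero.
#'
#' @param x a [cohort()] with pedigree attached.
#' @param var1,var2 variant ids.
#' @param category `"H"` or `"L"`.
#' @param B number of permutations (default 999).
#' @param seed optional integer seed (reproducible).
#' @param stratify_by_sex permute within sex strata (default `TRUE`).
#' @param alpha_cell,min_cell,adjust_sex scan parameters, as in
#'   [mbmdr()].
#' @return list with `p`, `observed` statistic, `B` and `n_ge` (number of
#'   permuted statistics at least as large).
#' @export
permutation_p <- function(x, var1, var2, category = c("H", "L"), B = 999,
                          seed = NULL, stratify_by_sex = TRUE,
                          alpha_cell = 0.1, min_cell = 10,
                          adjust_sex = TRUE) {
  category <- match.arg(category)
  if (B < 1) stop("B must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  tab <- build_cell_table(x, var1, var2)
  ok <- tab$complete
  cell <- tab$cell[ok]
  y <- affected01(x$samples)[ok]
  sexv <- sex01(x$samples)[ok]
  if (anyNA(sexv)) sexv <- NULL

  stat_of <- function(yy) {
    core <- mbmdr_core(cell, yy, sexv, alpha_cell, min_cell, adjust_sex)
    ct <- core[[category]]
    if (is.null(ct)) 0 else ct$stat
  }
  observed <- stat_of(y)
  strata <- if (stratify_by_sex && !is.null(sexv)) sexv else rep(0L, length(y))
  idx_by <- split(seq_along(y), strata)
  n_ge <- 0L
  for (b in seq_len(B)) {
    yp <- y
    for (idx in idx_by) yp[idx] <- y[sample(idx)]
    if (stat_of(yp) >= observed) n_ge <- n_ge + 1L
  }
  list(p = (1 + n_ge) / (B + 1), observed = observed, B = B, n_ge = n_ge)
}

#' Add permutation p-values to an MB-MDR scan
#'
#' Runs [permutation_p()] for the scan's significant categories
#' (`fdr_q < fdr_level`, the trigger used for permutation confirmation),
#' capped at the `top_k` most significant categories by rank.
#'
#' @param fit an [mbmdr()] object.
#' @param x the [cohort()] the scan was fitted on.
#' @param B permutations per category (default 999).
#' @param seed optional integer seed.
#' @param top_k maximum number of categories to evaluate (default 1000).
#' @param only_significant restrict to `fdr_q < fdr_level` categories
#'   (default `TRUE`).
#' @param stratify_by_sex permute within sex strata (default `TRUE`).
#' @return `fit` with a `permutation_p` column added to `results`.
#' @export
mbmdr_permute <- function(fit, x, B = 999, seed = NULL, top_k = 1000,
                          only_significant = TRUE, stratify_by_sex = TRUE) {
  stopifnot(inherits(fit, "mbmdr"))
  res <- fit$results
  res$permutation_p <- NA_real_
  eligible <- if (only_significant) which(res$significant) else seq_len(nrow(res))
  eligible <- head(eligible, top_k)   # results are already ranked
  if (!is.null(seed)) set.seed(seed)
  for (i in eligible) {
    pp <- permutation_p(x, res$var1[i], res$var2[i], res$category[i], B = B,
                        seed = NULL, stratify_by_sex = stratify_by_sex,
                        alpha_cell = fit$params$alpha_cell,
                        min_cell = fit$params$min_cell,
                        adjust_sex = fit$params$adjust_sex)
    res$permutation_p[i] <- pp$p
  }
  fit$results <- res
  fit
}
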