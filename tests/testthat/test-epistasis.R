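test_that("HWE exact p matches enumeration on canonical configurations", {
  expect_equal(hwe_exact_p(1, 0, 1), 1 / 3, tolerance = 1e-12)
  expect_equal(hwe_exact_p(0, 2, 0), 1)
  expect_equal(hwe_exact_p(7, 0, 0), 1)   # monomorphic
  expect_error(hwe_exact_p(-1, 0, 1), "non-negative")
  expect_error(hwe_exact_p(0, 0, 0), ">= 1")
  # against the slot-enumeration oracle on a handful of configurations
  for (cfg in list(c(2, 1, 1), c(3, 1, 0), c(1, 2, 2), c(2, 2, 1))) {
    expect_equal(hwe_exact_p(cfg[1], cfg[2], cfg[3]),
                 hwe_oracle(cfg[1], cfg[2], cfg[3]), tolerance = 1e-12)
  }
})

test_that("missing rate uses a strict below-5% rule in pair QC", {
  expect_equal(missing_rate(c(1, NA, 0, 2)), 0.25)
  expect_equal(missing_rate(rep(0, 10)), 0)
  expect_error(missing_rate(integer(0)), "empty")
  d_ok <- c(rep(NA, 4), sample(0:2, 96, TRUE))     # 4% missing
  d_bad <- c(rep(NA, 5), sample(0:2, 95, TRUE))    # exactly 5%
  expect_true(missing_rate(d_ok) < 0.05)
  expect_false(missing_rate(d_bad) < 0.05)
})

test_that("genotype r2 is the squared dosage correlation with symmetry", {
  g <- c(0, 0, 1, 1, 2, 2)
  expect_equal(genotype_r2(g, g), 1)
  expect_equal(genotype_r2(g, 2 - g), 1)  # allele-label swap
  expect_equal(genotype_r2(c(0, 0, 1, 1, 2, 2), c(0, 1, 0, 2, 1, 2)), 0.25)
  expect_true(is.na(genotype_r2(c(1, 1, 1, 1), c(0, 1, 2, 0))))
  expect_error(genotype_r2(c(NA, NA, 1), c(0, 1, NA)), "pairwise-complete")
})

test_that("pair QC applies every rule with strict boundaries", {
  set.seed(34)
  n <- 120
  d1 <- rbinom(n, 2, 0.4); d2 <- rbinom(n, 2, 0.3)
  aff <- rep(c(TRUE, FALSE), n / 2)
  co <- make_cohort(cbind(d1, d2), aff)
  ok <- pair_qc(co, "v01", "v02")
  expect_true(ok$pass)
  expect_equal(ok$first_fail, "pass")
  # exactly 5% missing fails the first missingness rule
  d1m <- d1; d1m[1:6] <- NA   # 6/120 = 5%
  com <- make_cohort(cbind(d1m, d2), aff)
  qr <- pair_qc(com, "v01", "v02")
  expect_false(qr$pass)
  expect_equal(qr$first_fail, "missing_1")
  # r2 at exactly 0.2 is excluded (strict <)
  x <- rep(c(2, 1, 1, 2, 1, 2), 20)
  y <- rep(c(2, 0, 0, 0, 1, 1), 20)
  expect_equal(genotype_r2(x, y), 0.2, tolerance = 1e-12)
  cold <- make_cohort(cbind(x, y), aff)
  qld <- pair_qc(cold, "v01", "v02")
  expect_false(qld$pass)
  expect_equal(qld$first_fail, "ld_r2")
  # strong heterozygote deficit in controls violates HWE
  dhwe <- ifelse(aff, rbinom(n, 2, 0.4), sample(c(0, 2), n, TRUE))
  chwe <- make_cohort(cbind(dhwe, d2), aff)
  qh <- pair_qc(chwe, "v01", "v02")
  expect_false(qh$pass)
  expect_equal(qh$first_fail, "hwe_1")
  expect_lt(qh$hwe_p_controls_1, 0.01)
})

test_that("cell tables conserve counts and transpose under pair swap", {
  set.seed(12)
  n <- 80
  d1 <- rbinom(n, 2, 0.5); d2 <- rbinom(n, 2, 0.5)
  d1[3] <- NA
  co <- make_cohort(cbind(d1, d2), rep(c(TRUE, FALSE), n / 2))
  tab <- build_cell_table(co, "v01", "v02")
  expect_equal(sum(tab$n_cases) + sum(tab$n_controls), sum(!is.na(d1)))
  tab2 <- build_cell_table(co, "v02", "v01")
  expect_equal(tab2$n_cases, t(tab$n_cases), ignore_attr = TRUE)
  expect_equal(tab2$n_controls, t(tab$n_controls), ignore_attr = TRUE)
})

test_that("cells are labelled H/L/O by directed score tests with occupancy floor", {
  # one cell of 8 cases / 0 controls against a 12/30 remainder: the
  # covariate-free reduction of this test is Fisher's exact on the 2x2,
  # p << 0.1, so the cell must be labelled H once the occupancy floor
  # admits it
  d1 <- c(rep(1L, 8), rep(0L, 42))
  aff <- c(rep(TRUE, 8), rep(TRUE, 12), rep(FALSE, 30))
  co <- make_cohort(cbind(d1, d1), aff, sex = rep("female", 50))
  tab <- build_cell_table(co, "v01", "v02")
  lab <- label_cells(tab, co, alpha_cell = 0.1, min_cell = 5)
  expect_equal(lab$labels["1", "1"], "H")
  expect_lt(lab$cell_p["1", "1"], 0.001)
  # below the occupancy floor the same cell is O regardless of content
  lab10 <- label_cells(tab, co, alpha_cell = 0.1, min_cell = 10)
  expect_equal(lab10$labels["1", "1"], "O")
  # a cell whose case fraction equals the remainder's is O
  d <- c(rep(1L, 20), rep(0L, 20))
  aff_eq <- rep(c(TRUE, FALSE), 20)
  co_eq <- make_cohort(cbind(d, d), aff_eq, sex = rep("female", 40))
  lab_eq <- label_cells(build_cell_table(co_eq, "v01", "v02"), co_eq)
  expect_equal(lab_eq$labels["1", "1"], "O")
})

test_that("labels are sample-order invariant and flip under phenotype inversion", {
  set.seed(61)
  co <- simulate_epistatic_pair(default_penetrance_table(), 100, 100)
  tab <- label_cells(build_cell_table(co, "rsEPI1", "rsEPI2"), co)
  perm <- sample(nrow(co$samples))
  cop <- co[perm, ]
  tabp <- label_cells(build_cell_table(cop, "rsEPI1", "rsEPI2"), cop)
  expect_equal(tabp$labels, tab$labels)
  # invert case/control: H and L swap
  coi <- co
  coi$samples$affected <- ifelse(co$samples$affected == "case",
                                 "control", "case")
  tabi <- label_cells(build_cell_table(coi, "rsEPI1", "rsEPI2"), coi)
  swap <- c(H = "L", L = "H", O = "O")
  expect_equal(unname(c(tabi$labels)), unname(swap[c(tab$labels)]))
})

test_that("the pooled category test equals the cross-product OR on saturated tables", {
  co <- make_2x2_cohort(15, 5, 5, 15)
  tab <- label_cells(build_cell_table(co, "v01", "v02"), co, min_cell = 5)
  res <- pooled_category_test(tab, co, cells = "1/1")
  expect_equal(res$or, 9, tolerance = 1e-5)
  expect_equal(res$or_unadjusted, 9, tolerance = 1e-12)
  # pooling is invariant to how the member cells are listed
  res2 <- pooled_category_test(tab, co, cells = c("1/1"))
  expect_equal(res$stat, res2$stat)
  expect_error(pooled_category_test(tab, co, cells = cell_labels <-
    sprintf("%d/%d", rep(0:2, each = 3), rep(0:2, 3))), "all cells")
})

test_that("the scan is deterministic and ranks a planted pair first", {
  set.seed(202)
  co <- simulate_epistatic_pair(default_penetrance_table(), 120, 120)
  # add two null variants so several pairs compete
  extra <- matrix(rbinom(2 * 240, 2, 0.4), ncol = 2)
  co2 <- cohort(co$samples,
                rbind(co$variants,
                      within(co$variants, {
                        variant_id <- c("n1", "n2")
                        gene <- c("GENEN1", "GENEN2")
                        pos <- pos + 5000L
                      })),
                cbind(co$dosage, extra))
  fit1 <- mbmdr(co2, qc = FALSE)
  fit2 <- mbmdr(co2, qc = FALSE)
  expect_identical(fit1$results, fit2$results)
  sig <- fit1$results[fit1$results$significant, ]
  expect_true("rsEPI1*rsEPI2" %in% sig$pair)
  # a duplicated input pair yields identical result rows
  fitd <- mbmdr(co2, qc = FALSE,
                pairs = rbind(c("rsEPI1", "rsEPI2"),
                              c("rsEPI1", "rsEPI2")))
  r <- fitd$results
  h <- r[r$category == "H", ]
  expect_equal(h[1, setdiff(names(h), "fdr_q")],
               h[2, setdiff(names(h), "fdr_q")], ignore_attr = TRUE)
})

test_that("permutation p is seeded, bounded and floors at 1/(B+1)", {
  set.seed(55)
  co <- simulate_epistatic_pair(default_penetrance_table(), 120, 120)
  p1 <- permutation_p(co, "rsEPI1", "rsEPI2", "H", B = 99, seed = 9)
  p2 <- permutation_p(co, "rsEPI1", "rsEPI2", "H", B = 99, seed = 9)
  expect_identical(p1, p2)
  # the planted signal dwarfs every permutation
  expect_equal(p1$p, 1 / 100)
  expect_gte(p1$p, 1 / (99 + 1))
  expect_lte(p1$p, 1)
  expect_error(permutation_p(co, "rsEPI1", "rsEPI2", "H", B = 0), "B must be")
})
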