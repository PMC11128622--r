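qc_row <- function(dp = 60, mq = 60, qd = 20, fs = 1, cr = 1,
                   impact = "NONE", cadd = NA, ...) {
  af <- list(...)
  out <- data.frame(variant_id = "v", dp = dp, mq = mq, qd = qd, fs = fs,
                    call_rate = cr, impact = impact, cadd_phred = cadd,
                    stringsAsFactors = FALSE)
  for (nm in names(af)) out[[nm]] <- af[[nm]]
  out
}

test_that("site QC thresholds are inclusive exactly as specified", {
  # all metrics exactly on their boundary pass
  expect_true(site_qc_pass(qc_row(dp = 12, mq = 30, qd = 2, fs = 25, cr = 0.95))[[1]])
  expect_false(site_qc_pass(qc_row(dp = 11, mq = 60, qd = 10, fs = 0, cr = 1))[[1]])
  expect_false(site_qc_pass(qc_row(dp = 100, mq = 60, qd = 10, fs = 25.01, cr = 1))[[1]])
  expect_false(site_qc_pass(qc_row(mq = 29.99))[[1]])
  expect_false(site_qc_pass(qc_row(qd = 1.99))[[1]])
  expect_false(site_qc_pass(qc_row(cr = 0.9499))[[1]])
  # unevaluable record (missing metric) fails
  expect_false(site_qc_pass(qc_row(dp = NA))[[1]])
})

test_that("rarity requires every observed panel frequency strictly below 1%", {
  expect_true(is_rare(qc_row(af_kg = 0.005, af_ex = 1e-4, af_esp = 0))[[1]])
  expect_false(is_rare(qc_row(af_kg = 0.01))[[1]])  # not *below* 1%
  expect_false(is_rare(qc_row(af_kg = 0.001, af_ex = 0.02))[[1]])
  # absent from all panels counts as rare (unobserved, private variant)
  expect_true(is_rare(qc_row(af_kg = NA_real_))[[1]])
  expect_true(is_rare(qc_row())[[1]])
})

test_that("non-neutrality is impact-class OR CADD at the inclusive floor", {
  expect_true(is_non_neutral(qc_row(impact = "MODERATE", cadd = 3.1))[[1]])
  expect_true(is_non_neutral(qc_row(impact = "LOW", cadd = 15))[[1]])
  expect_false(is_non_neutral(qc_row(impact = "LOW", cadd = 14.99))[[1]])
  expect_true(is_non_neutral(qc_row(impact = "MODIFIER"))[[1]])
  expect_false(is_non_neutral(qc_row(impact = "NONE"))[[1]])
})

test_that("relaxing any threshold never shrinks the passing set", {
  set.seed(99)
  v <- data.frame(variant_id = sprintf("v%03d", 1:300),
                  dp = runif(300, 0, 40), mq = runif(300, 0, 70),
                  qd = runif(300, 0, 6), fs = runif(300, 0, 40),
                  call_rate = runif(300, 0.8, 1),
                  impact = sample(c("HIGH", "LOW", "NONE"), 300, TRUE),
                  cadd_phred = runif(300, 0, 30),
                  af_kg = runif(300, 0, 0.03), stringsAsFactors = FALSE)
  t0 <- filter_thresholds()
  base <- site_qc_pass(v, t0) & is_rare(v, t0) & is_non_neutral(v, t0)
  relaxed <- list(
    filter_thresholds(min_dp = 6), filter_thresholds(min_mq = 10),
    filter_thresholds(min_qd = 1), filter_thresholds(max_fs = 35),
    filter_thresholds(min_call_rate = 0.85),
    filter_thresholds(rare_maf_ceiling = 0.05),
    filter_thresholds(cadd_floor = 5),
    filter_thresholds(qualifying_impacts = c("HIGH", "MODERATE", "MODIFIER", "LOW")))
  for (t1 in relaxed) {
    wider <- site_qc_pass(v, t1) & is_rare(v, t1) & is_non_neutral(v, t1)
    expect_true(all(wider[base]), info = "relaxation must keep all passers")
  }
})

test_that("filter predicates compose order-independently", {
  set.seed(7)
  v <- data.frame(variant_id = sprintf("v%02d", 1:50),
                  dp = runif(50, 5, 40), mq = runif(50, 20, 70),
                  qd = runif(50, 0, 6), fs = runif(50, 0, 40),
                  call_rate = runif(50, 0.9, 1),
                  impact = sample(c("HIGH", "NONE"), 50, TRUE),
                  cadd_phred = runif(50, 0, 30),
                  af_kg = runif(50, 0, 0.03), stringsAsFactors = FALSE)
  a <- site_qc_pass(v); b <- is_rare(v); c_ <- is_non_neutral(v)
  expect_identical(a & b & c_, c_ & a & b)
  expect_identical(which(a & (b & c_)), which((c_ & b) & a))
})

test_that("the 20-record toy VCF yields the hand-counted survivor set", {
  path <- system.file("extdata", "toy20.vcf", package = "epifam")
  co <- read_vcf(path)
  expect_equal(nrow(co$variants), 20)
  t <- filter_thresholds()
  qc <- site_qc_pass(co, t)
  keep <- qc & is_rare(co$variants, t) & is_non_neutral(co$variants, t)
  # hand count over the fixture: 13 records pass site QC, of which 8 are
  # both rare and non-neutral
  expect_equal(sum(qc), 13)
  expect_equal(sum(keep), 8)
  expect_setequal(names(which(keep)),
                  c("rs01", "rs02", "rs03", "rs04", "rs05", "rs10",
                    "rs11", "rs20"))
  # audit names the first failing rule
  aud <- filter_variants(co, t)$audit
  expect_equal(aud$first_fail[aud$variant_id == "rs13"], "dp")
  expect_equal(aud$first_fail[aud$variant_id == "rs16"], "fs")
})
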