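mendel_ok <- function(child, father, mother) {
  poss_f <- if (father == 0) 0 else if (father == 2) 1 else c(0, 1)
  poss_m <- if (mother == 0) 0 else if (mother == 2) 1 else c(0, 1)
  child %in% outer(poss_f, poss_m, `+`)
}

test_that("gene drops are Mendelian-consistent and match founder expectations", {
  ped <- default_pedigrees()$F8
  set.seed(9)
  for (i in 1:300) {
    d <- gene_drop(ped, 0.3)
    for (j in which(ped$father != "0")) {
      expect_true(mendel_ok(d[ped$member_id[j]], d[ped$father[j]],
                            d[ped$mother[j]]))
    }
  }
  # founder dosage mean 2q over many founders
  nf <- 10000
  founders <- data.frame(member_id = sprintf("I%05d", 1:nf),
                         father = "0", mother = "0",
                         sex = "female", carrier = FALSE,
                         stringsAsFactors = FALSE)
  d <- gene_drop(founders, 0.3)
  se <- sqrt(2 * 0.3 * 0.7 / nf)
  expect_lt(abs(mean(d) - 0.6), 3 * se)
  # a cyclic pedigree can never resolve
  cyc <- data.frame(member_id = c("A", "B"), father = c("B", "A"),
                    mother = c("B", "A"), stringsAsFactors = FALSE)
  expect_error(gene_drop(cyc, 0.3), "cyclic")
})

test_that("planting controls penetrance and phenocopy behaviour", {
  ped <- default_pedigrees()$F8
  set.seed(31)
  # penetrance < 1 produces incomplete penetrance with positive frequency
  verdicts <- replicate(100, {
    p <- plant_cosegregating_variant(ped, penetrance = 0.5)
    family_verdict(p$dosage, p$affected)
  })
  expect_true(any(verdicts == "incomplete_penetrance"))
  expect_false(any(verdicts == "phenocopy"))
  # phenocopy rate 1 on a family with non-carriers
  p1 <- plant_cosegregating_variant(ped, penetrance = 1, phenocopy_rate = 1)
  expect_true(family_verdict(p1$dosage, p1$affected) %in%
                c("phenocopy", "untyped"))
})

test_that("epistatic-pair simulation honours quotas, seeds and HWE", {
  pen <- default_penetrance_table()
  co <- simulate_epistatic_pair(pen, 120, 120, seed = 5)
  expect_equal(sum(co$samples$affected == "case"), 120)
  expect_equal(sum(co$samples$affected == "control"), 120)
  co2 <- simulate_epistatic_pair(pen, 120, 120, seed = 5)
  expect_identical(co, co2)
  # under a flat table genotypes stay at their Hardy-Weinberg frequencies
  flat <- flat_penetrance_table(f0 = 0.5, q1 = 0.4)
  big <- simulate_epistatic_pair(flat, 3000, 3000, seed = 6)
  g1 <- big$dosage[, 1]
  exp_freq <- c(0.36, 0.48, 0.16)
  for (g in 0:2) {
    ph <- mean(g1 == g)
    se <- sqrt(exp_freq[g + 1] * (1 - exp_freq[g + 1]) / 6000)
    expect_lt(abs(ph - exp_freq[g + 1]), 4 * se)
  }
  # unreachable quotas are errors
  expect_error(simulate_epistatic_pair(
    penetrance_table(matrix(0, 3, 3), 0.5, 0.5), 10, 10), "unreachable")
  expect_error(simulate_epistatic_pair(
    penetrance_table(matrix(1, 3, 3), 0.5, 0.5), 10, 10), "unreachable")
})

test_that("prevalence converges to the penetrance-weighted HWE mass", {
  pen <- default_penetrance_table(sex_or_female = 1)
  hw <- function(q) c((1 - q)^2, 2 * q * (1 - q), q^2)
  expected <- sum(outer(hw(0.5), hw(0.5)) * pen$f)
  set.seed(77)
  g1 <- rbinom(20000, 2, 0.5); g2 <- rbinom(20000, 2, 0.5)
  y <- rbinom(20000, 1, risk_prob(pen, g1, g2, rep("male", 20000)))
  se <- sqrt(expected * (1 - expected) / 20000)
  expect_lt(abs(mean(y) - expected), 3 * se)
})

test_that("the full study fixture has the designed composition", {
  cfg <- sim_config()
  x <- simulate_study(cfg, seed = 123)
  fam <- x$samples$family_id != "UNRELATED"
  expect_equal(sum(fam), 30)
  expect_equal(sum(x$samples$affected[fam] == "case"), 19)
  expect_equal(sum(x$samples$affected[fam] == "control"), 11)
  expect_equal(sum(!fam), 98)
  expect_true(all(x$samples$affected[!fam] == "control"))
  expect_equal(nrow(x$variants), 17 + 2 + 60)
  # planted co-segregating variants always qualify in their family
  seg <- select_cosegregating(x, variants = cfg$coseg$variant_id)
  expect_setequal(seg$selected, cfg$coseg$variant_id)
  # family genotypes of planted epistatic and null variants stay Mendelian
  for (f in c("F1", "F8")) {
    ped <- cfg$pedigrees[[f]]
    idx <- match(ped$member_id, x$samples$sample_id)
    for (v in c("rsEPI1", "rsEPI2", "rsNULL001")) {
      d <- x$dosage[idx, v]
      if (anyNA(d)) next
      for (j in which(ped$father != "0")) {
        expect_true(mendel_ok(d[j], d[ped$member_id == ped$father[j]],
                              d[ped$member_id == ped$mother[j]]))
      }
    }
  }
})

test_that("fixture emission is deterministic and round-trips through io", {
  cfg <- sim_config(n_null_variants = 10, missing_rate = 0.02)
  dir1 <- tempfile(); dir2 <- tempfile()
  p1 <- emit_fixture(cfg, dir1, seed = 99)
  p2 <- emit_fixture(cfg, dir2, seed = 99)
  for (f in c("vcf", "ped", "gmt", "manifest")) {
    expect_identical(readLines(p1[[f]]), readLines(p2[[f]]),
                     info = paste("file", f))
  }
  sim <- attr(p1, "cohort")
  back <- attach_pedigree(read_vcf(p1$vcf), read_pedigree(p1$ped))
  m <- match(sim$samples$sample_id, back$samples$sample_id)
  expect_equal(unname(back$dosage[m, sim$variants$variant_id]),
               unname(sim$dosage))
  expect_equal(back$samples$affected[m], sim$samples$affected)
})

test_that("planted QC failures are the only records failing site QC", {
  cfg <- sim_config(n_null_variants = 10, n_qc_fail = 3, missing_rate = 0)
  x <- simulate_study(cfg, seed = 7)
  qc <- site_qc_pass(x)
  expect_equal(sum(!qc), 3)
  expect_setequal(names(which(!qc)), sprintf("rsNULL%03d", 1:3))
})
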