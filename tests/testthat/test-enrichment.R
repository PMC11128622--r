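test_that("hypergeometric upper tail is an exact tail sum", {
  expect_equal(hypergeom_upper_tail(5, 5, 10, 20), 3003 / 184756,
               tolerance = 1e-12)
  expect_equal(hypergeom_upper_tail(0, 5, 10, 20), 1)
  expect_equal(hypergeom_upper_tail(10, 20, 10, 20), 1)  # overlap forced
  expect_error(hypergeom_upper_tail(6, 5, 10, 20), "inconsistent")
  expect_error(hypergeom_upper_tail(1, 25, 10, 20), "inconsistent")
  # spot-check against full draw enumeration
  for (inst in list(c(2, 3, 4, 9), c(1, 2, 5, 8), c(4, 6, 6, 11))) {
    expect_equal(hypergeom_upper_tail(inst[1], inst[2], inst[3], inst[4]),
                 hyper_oracle(inst[1], inst[2], inst[3], inst[4]),
                 tolerance = 1e-12)
  }
})

test_that("BH adjustment matches the hand-worked and oracle values", {
  expect_equal(bh_adjust(c(0.005, 0.011, 0.02, 0.04)),
               c(0.02, 0.022, 0.02 + 0.02 / 3, 0.04), tolerance = 1e-12)
  expect_equal(bh_adjust(0.123), 0.123)
  expect_equal(bh_adjust(rep(0.2, 7)), rep(0.2, 7))
  expect_error(bh_adjust(c(0.1, 0)), "0, 1")
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")
  set.seed(5)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    q <- bh_adjust(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(q >= p))
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-12))  # monotone over sorted p
    # BH rejections contain Bonferroni rejections
    expect_true(all(q[p <= 0.05 / length(p)] <= 0.05))
  }
})

test_that("over-representation flags the planted set and is order-invariant", {
  universe <- sprintf("G%03d", 1:60)
  sets <- list(PATH = sprintf("G%03d", 1:10),
               OTHER = sprintf("G%03d", 31:45),
               EMPTY = c("ZZZ1", "ZZZ2"))
  selected <- sprintf("G%03d", 1:8)
  expect_warning(res <- run_ora(selected, sets, universe), "EMPTY")
  expect_equal(nrow(res), 2)
  expect_equal(res$set_id[which.min(res$p_value)], "PATH")
  expect_true(res$significant[res$set_id == "PATH"])
  expect_equal(res$k_overlap[res$set_id == "PATH"], 8)
  expect_true(all(res$fdr_q >= res$p_value))
  # permuting set order leaves every q unchanged
  expect_warning(res2 <- run_ora(selected, sets[c(2, 3, 1)], universe))
  m <- match(res$set_id, res2$set_id)
  expect_equal(res$fdr_q, res2$fdr_q[m])
  expect_error(run_ora(c("NOT_IN_UNIVERSE"), sets, universe), "outside")
  expect_error(run_ora("G001", sets, character(0)), "empty universe")
})

test_that("uniform-null selection rejects at most at the nominal rate", {
  set.seed(42)
  universe <- sprintf("G%03d", 1:200)
  sets <- split(universe[1:80], rep(1:4, each = 20))  # disjoint sets
  B <- 2000
  alpha <- 0.05
  rej <- 0L
  for (b in seq_len(B)) {
    sel <- sample(universe, 30)
    for (s in sets) {
      k <- length(intersect(s, sel))
      if (hypergeom_upper_tail(k, 20, 30, 200) < alpha) rej <- rej + 1L
    }
  }
  frac <- rej / (B * 4)
  expect_lt(frac, alpha + 3 * sqrt(alpha * (1 - alpha) / B))
})

test_that("the resampled background null is seeded and conservative by construction", {
  set.seed(8)
  background <- data.frame(
    variant_id = sprintf("var%04d", 1:500),
    gene = sample(sprintf("G%03d", 1:60), 500, TRUE),
    stringsAsFactors = FALSE)
  sets <- list(PATH = sprintf("G%03d", 1:10), DECOY = sprintf("G%03d", 40:55))
  a <- resampled_null(background, sets, n_draws = 10, set_size = 50, seed = 11)
  b <- resampled_null(background, sets, n_draws = 10, set_size = 50, seed = 11)
  expect_identical(a, b)
  expect_true(all(a$counts <= a$n_draws))
  # background disjoint from every set: no draw can be significant
  bg2 <- data.frame(variant_id = sprintf("x%03d", 1:120),
                    gene = sprintf("H%03d", 1:120), stringsAsFactors = FALSE)
  suppressWarnings(z <- resampled_null(bg2, sets,
                                       universe = c(bg2$gene, unlist(sets)),
                                       n_draws = 5, set_size = 60, seed = 2))
  expect_true(all(z$counts == 0))
  # degenerate and invalid configurations
  e <- resampled_null(background, sets, n_draws = 0, set_size = 50, seed = 1)
  expect_equal(e$n_draws_any_significant, 0L)
  expect_error(resampled_null(background, sets, set_size = 10000),
               "smaller than set_size")
})
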