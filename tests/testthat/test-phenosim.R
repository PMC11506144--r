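# Trait-pair simulation: QTL sampling, LD pairing, effects, TBVs,
# heritability construction.

test_that("signed gamma effects have the configured moments", {
  b <- sample_effects(1e5, seed = 61)
  expect_lt(abs(mean(abs(b)) / (0.4 * 2 / 3) - 1), 0.02)
  expect_lt(abs(mean(b > 0) - 0.5), 0.01)
  expect_identical(b, sample_effects(1e5, seed = 61))
})

test_that("TBVs are effect-weighted dosage sums", {
  d <- matrix(c(0, 1, 2,
                2, 0, 1,
                1, 1, 1), 3, 3, byrow = FALSE)
  expect_equal(compute_tbv(d, 1, 2), c(0, 2, 4))
  expect_equal(compute_tbv(d, 1:3, c(0, 0, 0)), c(0, 0, 0))
  # 3-QTL toy against a by-hand sum: individual 1: 0*1.5+2*(-1)+1*0.5
  b <- c(1.5, -1, 0.5)
  expect_equal(compute_tbv(d, 1:3, b),
               c(0 * 1.5 + 2 * -1 + 1 * 0.5,
                 1 * 1.5 + 0 * -1 + 1 * 0.5,
                 2 * 1.5 + 1 * -1 + 1 * 0.5))
  expect_error(compute_tbv(d, 4, 1), "out of range")
})

test_that("residual variance follows the heritability identity", {
  expect_equal(residual_variance(7.3, 0.5), 7.3)
  # from a reference additive variance of 45.919:
  expect_equal(residual_variance(45.919, 0.1), 413.271, tolerance = 1e-6)
  expect_equal(residual_variance(45.919, 0.3), 107.144, tolerance = 1e-4)
  expect_error(residual_variance(1, 0), "h2")
  expect_error(residual_variance(1, 1), "h2")
  expect_error(residual_variance(0, 0.5), "positive")
})

test_that("QTL sampling avoids monomorphic loci", {
  pan <- simulate_founders(60, n_chrom = 1, snps_per_chrom = 50, seed = 62)
  pan$hap1[, 7] <- 0L; pan$hap2[, 7] <- 0L     # force a monomorphic locus
  d <- dosages(pan)
  for (rep in 1:5)
    expect_false(7 %in% sample_qtls(d, 45, seed = rep))
  expect_setequal(sample_qtls(d, 49, seed = 1), setdiff(1:50, 7))
  expect_error(sample_qtls(d, 50), "segregating")
})

test_that("LD pairing hits the target within tolerance, no duplicates", {
  pan <- simulate_founders(800, n_chrom = 2, snps_per_chrom = 600,
                           adjacency_rho = 0.9, seed = 63)
  qtl <- sample_qtls(pan, 100, seed = 64)
  pr <- pair_qtls(pan, qtl, target_r = 0.8, seed = 65)
  expect_true(all(abs(pr$realized_r - 0.8) <= 0.05))
  expect_equal(anyDuplicated(c(pr$qtl_a, pr$qtl_b)), 0)
  d <- dosages(pan)
  # reported realized r is the actual signed dosage correlation
  for (k in sample(100, 5))
    expect_equal(pr$realized_r[k], ld_r(d[, pr$qtl_a[k]], d[, pr$qtl_b[k]]))
  # unsatisfiable target fails with an explicit message
  expect_error(pair_qtls(pan, qtl, target_r = 0.999, tolerance = 0.001,
                         max_resample = 50, seed = 66),
               "pairing failed")
})

test_that("trait pairs realise their heritability and share TBVs across h2", {
  pan <- simulate_founders(2000, n_chrom = 2, snps_per_chrom = 1000,
                           seed = 67)
  lo <- simulate_trait_pair(pan, trait_spec(0.1), trait_spec(0.1), 0.5,
                            seed = 68)
  hi <- simulate_trait_pair(pan, trait_spec(0.5), trait_spec(0.5), 0.5,
                            seed = 68)
  # same seed, different heritability: identical QTLs and TBVs
  expect_identical(hi$qtls$qtl_a, lo$qtls$qtl_a)
  expect_equal(hi$trait_a$tbv, lo$trait_a$tbv)
  # realized heritability matches the configured value
  expect_lt(abs(var(hi$trait_a$tbv) / var(hi$trait_a$phenotype) - 0.5), 0.05)
  expect_lt(abs(var(lo$trait_b$tbv) / var(lo$trait_b$phenotype) - 0.1), 0.05)
  # residuals of the two traits are uncorrelated
  ra <- hi$trait_a$phenotype - hi$trait_a$tbv
  rb <- hi$trait_b$phenotype - hi$trait_b$tbv
  expect_lt(abs(cor(ra, rb)), 0.06)
  # near-unit heritability collapses phenotype onto TBV
  nh <- simulate_trait_pair(pan, trait_spec(0.999), trait_spec(0.999), 0.5,
                            seed = 68)
  expect_gt(cor(nh$trait_a$phenotype, nh$trait_a$tbv), 0.999)
})

test_that("realized genetic correlation tracks the LD target", {
  pan <- simulate_founders(2000, n_chrom = 3, snps_per_chrom = 1000,
                           seed = 69)
  rg_of <- function(target, s) {
    sim <- simulate_trait_pair(pan, trait_spec(0.5), trait_spec(0.5),
                               target, seed = s)
    cor(sim$trait_a$tbv, sim$trait_b$tbv)
  }
  # high target: replicate-level agreement
  rgs <- vapply(1:6, function(s) rg_of(0.8, s), 0)
  expect_gte(mean(abs(rgs - 0.8) <= 0.05), 5 / 6)
  # mid and low targets are noisier replicate-to-replicate (cross-pair LD
  # interacting with the heavy-tailed effects) but unbiased
  for (target in c(0.2, 0.5)) {
    rgs <- vapply(1:8, function(s) rg_of(target, s), 0)
    expect_lt(abs(mean(rgs) - target), 0.05)
  }
})
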