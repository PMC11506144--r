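# Gamete formation, mating design and F1 construction.

test_that("crossover counts are uniform on {4, 5, 6}", {
  x <- sample_crossover_count(10000, seed = 41)
  expect_equal(range(x), c(4L, 6L))
  expect_true(all(abs(tabulate(x - 3L, 3L) / 10000 - 1 / 3) < 0.02))
  expect_identical(sample_crossover_count(5, seed = 42),
                   sample_crossover_count(5, seed = 42))
})

test_that("gametes are faithful mosaics of the parental haplotypes", {
  # 4-SNP toy: switch after SNP 2, starting on hap_a
  expect_identical(make_gamete(c(0L, 0L, 0L, 0L), c(1L, 1L, 1L, 1L),
                               crossovers = 2L, start_on_a = TRUE),
                   c(0L, 0L, 1L, 1L))
  # identical homologs: any crossover set returns the same sequence
  h <- c(1L, 0L, 1L, 1L, 0L, 0L, 1L, 0L, 1L, 1L)
  expect_identical(make_gamete(h, h, seed = 5), h)
  # forced zero crossovers: an intact parental haplotype
  a <- c(0L, 1L, 0L, 1L, 1L); b <- c(1L, 1L, 0L, 0L, 0L)
  g0 <- make_gamete(a, b, crossovers = integer(0), start_on_a = FALSE)
  expect_identical(g0, b)
  # between consecutive crossovers the gamete matches one parent exactly
  set.seed(43)
  a <- as.integer(rbinom(40, 1, 0.5)); b <- as.integer(rbinom(40, 1, 0.5))
  cx <- c(10L, 25L)
  g <- make_gamete(a, b, crossovers = cx, start_on_a = TRUE)
  expect_identical(g[1:10], a[1:10])
  expect_identical(g[11:25], b[11:25])
  expect_identical(g[26:40], a[26:40])
  expect_error(make_gamete(a, b, crossovers = c(5L, 60L)), "out of range")
  expect_error(make_gamete(a, b, crossovers = c(5L, 5L)), "increasing")
})

test_that("F1 construction honours the 1:24 design and loses no alleles", {
  fou <- simulate_founders(25, n_chrom = 2, snps_per_chrom = 60,
                           n_males = 1, seed = 44)
  des <- mating_design(fou, dams_per_sire = 24, offspring_per_dam = 12,
                       seed = 45)
  f1 <- build_f1(fou, des, seed = 46)
  expect_equal(length(f1$panel$ids), 24 * 12)          # 288 offspring
  expect_identical(sort(unique(f1$pedigree$sire)), des$sires)
  expect_equal(unname(table(f1$pedigree$dam)), rep(12L, 24),
               ignore_attr = TRUE)
  # no mutation: every offspring allele exists in the right parent
  for (k in sample(seq_along(f1$panel$ids), 5)) {
    ped <- f1$pedigree[k, ]
    di <- match(ped$dam, fou$ids); si <- match(ped$sire, fou$ids)
    expect_true(all(f1$panel$hap1[k, ] == fou$hap1[di, ] |
                      f1$panel$hap1[k, ] == fou$hap2[di, ]))
    expect_true(all(f1$panel$hap2[k, ] == fou$hap1[si, ] |
                      f1$panel$hap2[k, ] == fou$hap2[si, ]))
  }
  expect_identical(build_f1(fou, des, seed = 46)$panel$hap1, f1$panel$hap1)
})

test_that("mating design validates sex counts and parent identity", {
  fou <- simulate_founders(30, n_chrom = 1, snps_per_chrom = 30,
                           n_males = 2, seed = 47)
  expect_error(mating_design(fou, dams_per_sire = 24), "infeasible")
  fou2 <- simulate_founders(50, n_chrom = 1, snps_per_chrom = 30,
                            n_males = 2, seed = 48)
  des <- mating_design(fou2, dams_per_sire = 24, seed = 49)
  fou3 <- subset_panel(fou2, fou2$ids[-3])
  expect_error(build_f1(fou3, des, seed = 50), "unknown parents")
})

test_that("F1 allele frequencies stay near parental frequencies", {
  fou <- simulate_founders(250, n_chrom = 2, snps_per_chrom = 100,
                           n_males = 10, seed = 51)
  des <- mating_design(fou, dams_per_sire = 24, offspring_per_dam = 12,
                       seed = 52)
  f1 <- build_f1(fou, des, seed = 53)
  # expected offspring frequency: mean of dam-pool and sire-pool
  # frequencies (sires are few, so the plain founder mean is not the
  # transmission expectation)
  fd <- allele_freq(dosages(subset_panel(fou, des$dams)))
  fs <- allele_freq(dosages(subset_panel(fou, des$sires)))
  op <- allele_freq(dosages(f1$panel))
  expect_lt(mean(abs((fd + fs) / 2 - op)), 0.02)
})

test_that("parent-offspring genomic relationship is near 0.5", {
  fou <- simulate_founders(125, n_chrom = 2, snps_per_chrom = 1000,
                           n_males = 5, seed = 54)
  des <- mating_design(fou, dams_per_sire = 24, offspring_per_dam = 2,
                       seed = 55)
  f1 <- build_f1(fou, des, seed = 56)
  keep <- sample_candidates(f1$panel, 60, seed = 57)
  pan <- combine_panels(fou, subset_panel(f1$panel, keep))
  G <- compute_grm(dosages(pan))
  ped <- f1$pedigree[match(keep, f1$pedigree$id), ]
  po <- c(G[cbind(ped$id, ped$sire)], G[cbind(ped$id, ped$dam)])
  expect_lt(abs(mean(po) - 0.5), 0.05)
})

test_that("candidate sampling is uniform, unique and seeded", {
  ids <- sprintf("c%d", 1:100)
  s <- sample_candidates(ids, 40, seed = 58)
  expect_equal(length(unique(s)), 40)
  expect_identical(s, sample_candidates(ids, 40, seed = 58))
  expect_setequal(sample_candidates(ids, 100, seed = 59), ids)
  expect_error(sample_candidates(ids, 101), "cannot sample")
})
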