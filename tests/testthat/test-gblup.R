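# REML variance components and BLUP breeding values.

test_that("restricted log-likelihood matches the dense-matrix definition", {
  G <- toy_grm(8, seed = 81)
  set.seed(82)
  y <- drop(chol(unclass(G) * 2) %*% rnorm(8)) + rnorm(8, sd = 1.5) + 3
  names(y) <- rownames(G)
  th <- c(1.7, 2.2)
  expect_equal(as.numeric(reml_loglik(th, y, G, gradient = FALSE)),
               naive_reml_ll(th, matrix(y, dimnames = list(names(y))), G),
               tolerance = 1e-8)
  biv <- draw_bivariate(G, matrix(c(2, 1, 1, 1.5), 2),
                        matrix(c(3, .5, .5, 2), 2), seed = 83)
  th6 <- c(1.5, 0.6, 1.1, 2.4, 0.2, 1.9)
  expect_equal(as.numeric(reml_loglik(th6, biv$Y, G, gradient = FALSE)),
               naive_reml_ll(th6, biv$Y, G), tolerance = 1e-8)
})

test_that("analytic gradients match central finite differences", {
  G <- toy_grm(8, seed = 84)
  biv <- draw_bivariate(G, matrix(c(2, 1, 1, 1.5), 2),
                        matrix(c(3, .5, .5, 2), 2), seed = 85)
  fd_check <- function(th, y) {
    gr <- attr(reml_loglik(th, y, G), "gradient")
    fd <- vapply(seq_along(th), function(i) {
      h <- 1e-5 * max(1, abs(th[i]))
      tp <- th; tm <- th; tp[i] <- tp[i] + h; tm[i] <- tm[i] - h
      (as.numeric(reml_loglik(tp, y, G, FALSE)) -
         as.numeric(reml_loglik(tm, y, G, FALSE))) / (2 * h)
    }, 0)
    expect_lt(max(abs(gr - fd) / (abs(fd) + 1e-6)), 1e-4)
  }
  fd_check(c(1.3, 2.1), biv$Y[, 1])
  fd_check(c(1.5, 0.6, 1.1, 2.4, 0.2, 1.9), biv$Y)
})

test_that("likelihood is invariant to phenotype translation and nests", {
  G <- toy_grm(10, seed = 86)
  biv <- draw_bivariate(G, matrix(c(2, 1, 1, 1.5), 2), diag(2) * 2,
                        seed = 87)
  y <- biv$Y[, 1]
  th <- c(1.2, 1.8)
  expect_equal(as.numeric(reml_loglik(th, y, G, FALSE)),
               as.numeric(reml_loglik(th, y + 100, G, FALSE)),
               tolerance = 1e-6)
  # with zero cross-covariances the bivariate likelihood is the sum of the
  # two single-trait likelihoods
  tha <- c(1.2, 1.8); thb <- c(0.9, 2.5)
  expect_equal(
    as.numeric(reml_loglik(c(tha[1], 0, thb[1], tha[2], 0, thb[2]),
                           biv$Y, G, FALSE)),
    as.numeric(reml_loglik(tha, biv$Y[, 1], G, FALSE)) +
      as.numeric(reml_loglik(thb, biv$Y[, 2], G, FALSE)),
    tolerance = 1e-8)
})

test_that("single-trait REML matches a grid search of the likelihood", {
  G <- toy_grm(6, m = 40, seed = 88)
  set.seed(89)
  y <- drop(chol(unclass(G) * 3) %*% rnorm(6)) + rnorm(6)
  names(y) <- rownames(G)
  fit <- gblup(y, G)
  vp <- var(y)
  grid <- seq(vp / 200, 3 * vp, length.out = 200)
  ll <- outer(grid, grid, Vectorize(function(a, e)
    as.numeric(reml_loglik(c(a, e), y, G, FALSE))))
  best <- which(ll == max(ll), arr.ind = TRUE)[1, ]
  step <- diff(grid)[1]
  expect_lt(abs(fit$varcomp[1] - grid[best[1]]), step + 1e-9)
  expect_lt(abs(fit$varcomp[2] - grid[best[2]]), step + 1e-9)
  expect_gte(fit$loglik, max(ll) - 1e-9)
})

test_that("bivariate optimum beats 1000 random parameter points", {
  G <- toy_grm(5, m = 30, seed = 90)
  biv <- draw_bivariate(G, matrix(c(2, 1, 1, 2), 2), diag(2), seed = 91)
  fit <- gblup(biv$Y, G)
  set.seed(92)
  vp <- mean(diag(cov(biv$Y)))
  lls <- replicate(1000, {
    A <- matrix(rnorm(4), 2); B <- matrix(rnorm(4), 2)
    M <- crossprod(A) * vp; R <- crossprod(B) * vp
    naive_reml_ll(c(M[1, 1], M[1, 2], M[2, 2], R[1, 1], R[1, 2], R[2, 2]),
                  biv$Y, G)
  })
  expect_gte(fit$loglik, max(lls) - 1e-6)
})

test_that("estimates are scale-equivariant", {
  G <- toy_grm(60, seed = 93)
  biv <- draw_bivariate(G, matrix(c(2, 1, 1, 1.5), 2), diag(2) * 2,
                        seed = 94)
  f1 <- gblup(biv$Y, G)
  f2 <- gblup(biv$Y * 10, G)
  expect_equal(f2$varcomp, f1$varcomp * 100, tolerance = 1e-4)
  expect_equal(f2$gebv, f1$gebv * 10, tolerance = 1e-4)
  expect_equal(f2$mu, f1$mu * 10, tolerance = 1e-4)
})

test_that("variance components are recovered on synthetic data", {
  pan <- simulate_founders(1000, n_chrom = 2, snps_per_chrom = 1000,
                           seed = 95)
  sim <- simulate_trait_pair(pan, trait_spec(0.5), trait_spec(0.5), 0.8,
                             seed = 96)
  G <- compute_grm(dosages(pan))
  fit <- gblup(sim$trait_a$phenotype, G)
  expect_true(fit$converged)
  expect_lt(abs(fit$h2 - 0.5), 0.1)
  # ascent property: accepted iterations never decrease the log-likelihood
  expect_true(all(diff(fit$trace$loglik) > -1e-8))
})

test_that("candidates receive GEBVs through the relationship structure", {
  pan <- simulate_founders(500, n_chrom = 2, snps_per_chrom = 800,
                           seed = 97)
  sim <- simulate_trait_pair(pan, trait_spec(0.5), trait_spec(0.5), 0.8,
                             seed = 98)
  G <- compute_grm(dosages(pan))
  obs <- pan$ids[1:400]; cand <- pan$ids[401:500]
  fit <- gblup(sim$trait_a$phenotype[obs], G)
  expect_equal(rownames(fit$gebv), pan$ids)
  expect_equal(rownames(fitted(fit)), obs)
  # candidate predictions carry real signal
  expect_gt(cor(predict(fit, cand)[, 1], sim$trait_a$tbv[cand]), 0.3)
  expect_error(predict(fit, "nobody"), "unknown id")
  expect_equal(dim(residuals(fit)), c(400L, 1L))
  expect_equal(length(coef(fit)), 1L)
})

test_that("uncorrelated traits decouple the bivariate prediction", {
  pan <- simulate_founders(600, n_chrom = 2, snps_per_chrom = 800,
                           seed = 99)
  d <- dosages(pan)
  set.seed(100)
  qa <- sample_qtls(d, 80); qb <- setdiff(sample_qtls(d, 160), qa)[1:80]
  tba <- compute_tbv(d, qa, sample_effects(80))
  tbb <- compute_tbv(d, qb, sample_effects(80))
  ya <- tba + rnorm(600, 0, sd(tba)); yb <- tbb + rnorm(600, 0, sd(tbb))
  names(ya) <- names(yb) <- pan$ids
  G <- compute_grm(d)
  fs <- gblup(ya, G)
  fm <- gblup(cbind(ya, yb), G)
  expect_lt(abs(fm$rg), 0.25)
  expect_gt(cor(fs$gebv[, 1], fm$gebv[, 1]), 0.99)
})

test_that("degenerate and ill-posed inputs are handled gracefully", {
  G <- toy_grm(30, seed = 101)
  y <- rep(5, 30); names(y) <- rownames(G)
  fit <- gblup(y, G)                   # constant phenotype: boundary, no crash
  expect_true(all(fit$varcomp >= 0))
  set.seed(102)
  y2 <- rnorm(30); names(y2) <- rownames(G)
  f_short <- gblup(y2, G, max_iter = 1)
  expect_false(f_short$converged)
  expect_identical(f_short$status, "max_iter")
  Y <- cbind(y2, y2 + rnorm(30))
  rownames(Y) <- rownames(G); Y[3, 2] <- NA
  expect_error(gblup(Y, G), "both traits or neither")
  expect_error(gblup(unname(y2), G), "named")
})
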