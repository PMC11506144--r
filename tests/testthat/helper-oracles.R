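# Independent oracles and small fixture builders used across the suite.

# Dense-matrix restricted log-likelihood, straight from the definition
# -0.5 (log|V| + log|X'V^-1 X| + y'Py): no eigendecomposition shortcut,
# so it checks the fast engine through a different route.
naive_reml_ll <- function(theta, Y, G) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  nt <- ncol(Y)
  G <- unclass(G)[rownames(Y), rownames(Y)]
  if (nt == 1) {
    V <- theta[1] * G + theta[2] * diag(n)
    X <- matrix(1, n, 1)
  } else {
    M <- matrix(theta[c(1, 2, 2, 3)], 2, 2)
    R <- matrix(theta[c(4, 5, 5, 6)], 2, 2)
    V <- kronecker(M, G) + kronecker(R, diag(n))
    X <- kronecker(diag(2), matrix(1, n, 1))
  }
  y <- c(Y)
  Vi <- solve(V)
  XVX <- crossprod(X, Vi %*% X)
  P <- Vi - Vi %*% X %*% solve(XVX, crossprod(X, Vi))
  -0.5 * (as.numeric(determinant(V)$modulus) +
            as.numeric(determinant(XVX)$modulus) +
            drop(t(y) %*% P %*% y))
}

# Exact Hardy-Weinberg p-value by combinatorial enumeration: count the
# allele arrangements realising each feasible heterozygote number.
hwe_enum <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  R <- min(nA, 2 * n - nA)
  if (R == 0) return(1)
  h <- seq(R %% 2, R, by = 2)
  ways <- choose(n, (R - h) / 2) * choose(n - (R - h) / 2, h) * 2^h
  pr <- ways / sum(ways)
  obs <- pr[match(n_Aa, h)]
  min(1, sum(pr[pr <= obs * (1 + 1e-9)]))
}

# Hand-assembled 3-individual, 4-SNP phased panel (alt alleles marked 1).
toy_panel <- function() {
  map <- data.frame(chrom = c(1L, 1L, 2L, 2L),
                    snp_id = c("s1", "s2", "s3", "s4"),
                    bp = c(100L, 200L, 50L, 150L),
                    allele_ref = "A", allele_alt = "B",
                    stringsAsFactors = FALSE)
  h1 <- rbind(c(0L, 1L, 1L, 0L), c(1L, 1L, 0L, 0L), c(0L, 0L, 1L, 1L))
  h2 <- rbind(c(0L, 0L, 1L, 1L), c(1L, 0L, 0L, 0L), c(1L, 0L, 1L, 0L))
  mtgblup:::new_hap_panel(c("a", "b", "c"), c("M", "F", "F"), h1, h2, map)
}

# GRM over iid standardised markers: dense, well-conditioned test matrix.
toy_grm <- function(n, m = 4 * n, seed = 1) {
  set.seed(seed)
  d <- matrix(rbinom(n * m, 2, 0.5), n, m,
              dimnames = list(sprintf("i%d", 1:n), NULL))
  compute_grm(d)
}

# Bivariate phenotypes drawn exactly from the GBLUP model on a given GRM.
draw_bivariate <- function(G, M, R, mu = c(0, 0), seed = 1) {
  set.seed(seed)
  n <- nrow(G)
  eg <- eigen(unclass(G), symmetric = TRUE)
  L <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)))
  g <- L %*% matrix(rnorm(2 * n), n, 2) %*% chol(M)
  e <- matrix(rnorm(2 * n), n, 2) %*% chol(R)
  Y <- sweep(g + e, 2, mu, "+")
  rownames(Y) <- rownames(G)
  list(Y = Y, g = g)
}
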