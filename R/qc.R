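# Genotype quality control: call-rate, minor-allele-frequency and
# Hardy-Weinberg filters matching standard SNP-chip practice.

#' Exact Hardy-Weinberg equilibrium test
#'
#' Computes the exact conditional p-value for departure from
#' Hardy-Weinberg proportions given the observed genotype counts: under the
#' null, conditional on the allele counts, the heterozygote count follows
#' the classical hypergeometric-type distribution, and the p-value sums the
#' probabilities of all heterozygote configurations no more probable than
#' the observed one.  A chi-square (1 df, no continuity correction)
#' alternative is available.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (non-negative, positive total).
#' @param method \code{"exact"} (default) or \code{"chisq"}.
#' @return P-value in \code{(0, 1]}.
#' @examples
#' hwe_pvalue(25, 50, 25)   # perfect equilibrium, p = 1
#' hwe_pvalue(0, 100, 0)    # extreme heterozygote excess
#' @export
hwe_pvalue <- function(n_AA, n_Aa, n_aa, method = c("exact", "chisq")) {
  method <- match.arg(method)
  cnt <- c(n_AA, n_Aa, n_aa)
  if (any(cnt < 0) || any(cnt != round(cnt)))
    stop("genotype counts must be non-negative integers")
  n <- sum(cnt)
  if (n == 0) stop("zero genotypes: HWE test undefined")
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  R <- min(nA, na)                 # rare-allele count
  if (R == 0) return(1)            # monomorphic
  if (method == "chisq") {
    p <- nA / (2 * n)
    e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
    x2 <- sum((cnt - e)^2 / e)
    return(stats::pchisq(x2, df = 1, lower.tail = FALSE))
  }
  h <- seq(R %% 2, R, by = 2)      # feasible heterozygote counts
  # log P(h | n, R) for the conditional null distribution
  lp <- h * log(2) + lfactorial(n) - lfactorial((R - h) / 2) -
    lfactorial(h) - lfactorial(n - (R + h) / 2) +
    lfactorial(R) + lfactorial(2 * n - R) - lfactorial(2 * n)
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  obs <- pr[match(n_Aa, h)]
  min(1, sum(pr[pr <= obs * (1 + 1e-9)]))
}

#' Quality-control filtering of a genotype matrix
#'
#' Applies the standard chip-QC cascade: individuals with call rate below
#' \code{ind_call} are removed first; then SNPs are retained only if they
#' simultaneously satisfy the SNP call-rate, minor-allele-frequency and
#' Hardy-Weinberg thresholds (all evaluated on the individual-filtered
#' matrix).  The filter is idempotent.
#'
#' @param dosage Individual-by-SNP matrix of alternate-allele counts in
#'   \{0, 1, 2\}, \code{NA} = missing.
#' @param ind_call Minimum individual call rate (default 0.95).
#' @param snp_call Minimum SNP call rate (default 0.95).
#' @param maf Minimum minor allele frequency (default 0.05).
#' @param hwe_p Hardy-Weinberg exclusion threshold: SNPs with
#'   p < \code{hwe_p} are removed (default 1e-5).
#' @param hwe_method Passed to \code{\link{hwe_pvalue}}.
#' @return List with \code{dosages} (filtered matrix) and \code{report}
#'   (a \code{qc_report}: removal tallies per filter and thresholds used).
#' @export
qc_filter <- function(dosage, ind_call = 0.95, snp_call = 0.95,
                      maf = 0.05, hwe_p = 1e-5,
                      hwe_method = c("exact", "chisq")) {
  hwe_method <- match.arg(hwe_method)
  for (th in c(ind_call, snp_call, maf, hwe_p))
    stopifnot_scalar_prob(th, "threshold")
  n0 <- nrow(dosage); m0 <- ncol(dosage)
  ind_cr <- 1 - rowMeans(is.na(dosage))
  keep_ind <- ind_cr >= ind_call
  d <- dosage[keep_ind, , drop = FALSE]

  snp_cr <- 1 - colMeans(is.na(d))
  f <- colMeans(d, na.rm = TRUE) / 2
  f[is.nan(f)] <- 0
  maf_obs <- pmin(f, 1 - f)
  hwe <- vapply(seq_len(ncol(d)), function(j) {
    g <- d[, j]
    hwe_pvalue(sum(g == 2, na.rm = TRUE), sum(g == 1, na.rm = TRUE),
               sum(g == 0, na.rm = TRUE), method = hwe_method)
  }, 0)

  fail_cr <- snp_cr < snp_call
  fail_maf <- maf_obs < maf
  fail_hwe <- hwe < hwe_p
  keep_snp <- !(fail_cr | fail_maf | fail_hwe)
  if (!any(keep_snp))
    stop("QC removed every SNP; relax the thresholds or check the input")

  report <- structure(list(
    n_individuals_in = n0, n_snps_in = m0,
    individuals_removed_call_rate = sum(!keep_ind),
    snps_failing_call_rate = sum(fail_cr),
    snps_failing_maf = sum(fail_maf),
    snps_failing_hwe = sum(fail_hwe),
    snps_removed = sum(!keep_snp),
    n_individuals_out = sum(keep_ind), n_snps_out = sum(keep_snp),
    thresholds = c(ind_call = ind_call, snp_call = snp_call,
                   maf = maf, hwe_p = hwe_p)), class = "qc_report")
  list(dosages = d[, keep_snp, drop = FALSE], report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC: %d/%d individuals retained (%d below call rate %.2f)\n",
              x$n_individuals_out, x$n_individuals_in,
              x$individuals_removed_call_rate, x$thresholds["ind_call"]))
  cat(sprintf(
    "    %d/%d SNPs retained (%d failing call rate, %d MAF < %.2f, %d HWE p < %g)\n",
    x$n_snps_out, x$n_snps_in, x$snps_failing_call_rate,
    x$snps_failing_maf, x$thresholds["maf"], x$snps_failing_hwe,
    x$thresholds["hwe_p"]))
  invisible(x)
}
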