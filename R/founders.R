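#' Simulate a phased founder population with tunable linkage disequilibrium
#'
#' Generates diploid, biallelic, fully phased founder genomes on
#' \code{n_chrom} chromosomes.  Along each chromosome, every haplotype is
#' produced by a first-order Markov "copy" process: the allele at SNP
#' \eqn{j} equals the allele at SNP \eqn{j-1} with probability
#' \code{adjacency_rho}, and is otherwise redrawn from the marginal
#' alternate-allele frequency of SNP \eqn{j}.  Pairwise haplotype (and hence
#' dosage) correlation therefore decays approximately geometrically with
#' marker distance, \eqn{r(k) \approx \rho^k}, so that around any locus
#' partner loci exist with signed dosage correlation near any target in
#' \eqn{(0, \rho)} — the substrate needed to build LD-matched QTL pairs.
#'
#' Marginal alternate-allele frequencies are drawn uniformly on
#' \code{[maf_low, 1 - maf_low]}, emulating a post-QC SNP chip on which
#' minor allele frequencies below \code{maf_low} have been removed.
#'
#' @param n_individuals Number of diploid founders.
#' @param n_chrom Number of chromosomes.
#' @param snps_per_chrom Markers per chromosome (at least 2).
#' @param chrom_length_bp Physical chromosome length; marker positions are
#'   drawn uniformly without replacement and sorted.
#' @param adjacency_rho Copy probability of the Markov process, in
#'   \code{[0, 1)}; equals the expected signed correlation between adjacent
#'   haplotype alleles.
#' @param maf_low Lower bound of the allele-frequency spectrum, in
#'   \code{(0, 0.5]}.
#' @param n_males Number of male founders. Defaults to
#'   \code{round(prop_male * n_individuals)}.
#' @param prop_male Proportion of males when \code{n_males} is not given;
#'   the default 0.1 mirrors a commercial pig nucleus (boar:sow near 1:9).
#' @param seed Integer seed; the same seed reproduces the panel exactly.
#'
#' @return A \code{hap_panel}: a list with elements \code{ids}, \code{sex}
#'   (\code{"M"}/\code{"F"}), \code{hap1} and \code{hap2} (individual-by-SNP
#'   0/1 integer matrices, 1 = alternate allele), and \code{map} (data frame
#'   with \code{chrom}, \code{snp_id}, \code{bp}, \code{allele_ref},
#'   \code{allele_alt}).
#'
#' @examples
#' pan <- simulate_founders(50, n_chrom = 2, snps_per_chrom = 100, seed = 1)
#' d <- dosages(pan)
#' range(d)
#' @export
simulate_founders <- function(n_individuals, n_chrom = 3,
                              snps_per_chrom = 1000,
                              chrom_length_bp = 1e8,
                              adjacency_rho = 0.9, maf_low = 0.05,
                              n_males = NULL, prop_male = 0.1,
                              seed = NULL) {
  if (n_individuals < 1) stop("'n_individuals' must be positive")
  if (snps_per_chrom < 2) stop("'snps_per_chrom' must be at least 2")
  stopifnot_scalar_prob(adjacency_rho, "adjacency_rho", 0, 1, open_hi = TRUE)
  stopifnot_scalar_prob(maf_low, "maf_low", 0, 0.5, open_lo = TRUE)
  n <- as.integer(n_individuals)
  m_chr <- as.integer(snps_per_chrom)
  n_males <- as.integer(n_males %||% round(prop_male * n))
  if (n_males < 0 || n_males > n) stop("'n_males' out of range")

  with_seed(seed, {
    nh <- 2L * n
    hap_chr <- vector("list", n_chrom)
    map_chr <- vector("list", n_chrom)
    for (cc in seq_len(n_chrom)) {
      p <- stats::runif(m_chr, maf_low, 1 - maf_low)
      H <- matrix(0L, nh, m_chr)
      H[, 1L] <- stats::rbinom(nh, 1L, p[1L])
      if (m_chr > 1L) for (j in 2:m_chr) {
        copy <- stats::runif(nh) < adjacency_rho
        fresh <- stats::rbinom(nh, 1L, p[j])
        H[, j] <- ifelse(copy, H[, j - 1L], fresh)
      }
      bp <- sort(sample.int(chrom_length_bp, m_chr))
      map_chr[[cc]] <- data.frame(
        chrom = rep(cc, m_chr),
        snp_id = sprintf("chr%d_snp%d", cc, seq_len(m_chr)),
        bp = bp,
        allele_ref = "A", allele_alt = "B",
        stringsAsFactors = FALSE)
      hap_chr[[cc]] <- H
    }
    H <- do.call(cbind, hap_chr)
    map <- do.call(rbind, map_chr)
    ids <- sprintf("F%0*d", nchar(n), seq_len(n))
    sex <- rep("F", n)
    if (n_males > 0L) sex[sample.int(n, n_males)] <- "M"
    new_hap_panel(ids, sex, H[seq_len(n), , drop = FALSE],
                  H[n + seq_len(n), , drop = FALSE], map)
  })
}

new_hap_panel <- function(ids, sex, hap1, hap2, map) {
  storage.mode(hap1) <- "integer"
  storage.mode(hap2) <- "integer"
  dimnames(hap1) <- dimnames(hap2) <- list(ids, map$snp_id)
  stopifnot(ncol(hap1) == nrow(map), nrow(hap1) == length(ids),
            identical(dim(hap1), dim(hap2)))
  if (anyDuplicated(map$snp_id)) stop("duplicate SNP ids in map")
  structure(list(ids = ids, sex = sex, hap1 = hap1, hap2 = hap2, map = map),
            class = "hap_panel")
}

#' @export
print.hap_panel <- function(x, ...) {
  cat(sprintf(
    "Phased haplotype panel: %d individuals (%d M / %d F), %d SNPs on %d chromosome(s)\n",
    length(x$ids), sum(x$sex == "M"), sum(x$sex == "F"),
    nrow(x$map), length(unique(x$map$chrom))))
  invisible(x)
}

#' Allele dosages of a haplotype panel
#'
#' @param panel A \code{hap_panel}.
#' @return Integer matrix (individuals by SNPs) of alternate-allele counts
#'   in \{0, 1, 2\}.
#' @export
dosages <- function(panel) {
  stopifnot(inherits(panel, "hap_panel"))
  panel$hap1 + panel$hap2
}

#' Alternate-allele frequencies from a dosage matrix
#'
#' @param dosage Numeric matrix of dosages in \{0, 1, 2\} (no missing values).
#' @return Vector of per-SNP alternate-allele frequencies.
#' @export
allele_freq <- function(dosage) {
  if (anyNA(dosage)) stop("dosage matrix contains missing values")
  colMeans(dosage) / 2
}

#' Signed linkage disequilibrium between two loci
#'
#' LD is measured as the signed Pearson correlation of allele dosages (not
#' \eqn{r^2}).  The sign matters: giving identical effects to a locus pair
#' induces a genetic correlation equal to the signed \eqn{r}.
#'
#' @param dosage_i,dosage_j Equal-length dosage vectors.
#' @return Correlation in \code{[-1, 1]}.
#' @export
ld_r <- function(dosage_i, dosage_j) {
  if (length(dosage_i) != length(dosage_j))
    stop("dosage vectors must have equal length")
  if (stats::var(dosage_i) == 0 || stats::var(dosage_j) == 0)
    stop("LD undefined: a locus has zero dosage variance")
  stats::cor(dosage_i, dosage_j)
}

#' Subset a haplotype panel by individual
#'
#' @param panel A \code{hap_panel}.
#' @param ids Individual ids to keep (order preserved).
#' @return A \code{hap_panel} restricted to \code{ids}.
#' @export
subset_panel <- function(panel, ids) {
  stopifnot(inherits(panel, "hap_panel"))
  idx <- match(ids, panel$ids)
  if (anyNA(idx)) stop("unknown individual id(s): ",
                       paste(ids[is.na(idx)][1:min(3, sum(is.na(idx)))],
                             collapse = ", "))
  new_hap_panel(panel$ids[idx], panel$sex[idx],
                panel$hap1[idx, , drop = FALSE],
                panel$hap2[idx, , drop = FALSE], panel$map)
}

#' Stack two haplotype panels sharing one marker map
#'
#' Used to assemble founders and their offspring into a single panel so
#' that true breeding values and the genomic relationship matrix can be
#' computed over reference and candidate individuals jointly.
#'
#' @param a,b \code{hap_panel} objects with identical maps and disjoint ids.
#' @return Combined \code{hap_panel}.
#' @export
combine_panels <- function(a, b) {
  stopifnot(inherits(a, "hap_panel"), inherits(b, "hap_panel"))
  if (!identical(a$map$snp_id, b$map$snp_id))
    stop("panels have different marker maps")
  if (any(b$ids %in% a$ids)) stop("panels share individual ids")
  new_hap_panel(c(a$ids, b$ids), c(a$sex, b$sex),
                rbind(a$hap1, b$hap1), rbind(a$hap2, b$hap2), a$map)
}
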