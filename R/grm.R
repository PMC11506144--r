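#' VanRaden genomic relationship matrix
#'
#' Builds \eqn{G = M M' / \sum_j 2 p_j (1 - p_j)} (VanRaden method 1),
#' where column \eqn{j} of \eqn{M} is the dosage vector centered by
#' \eqn{2 p_j} and \eqn{p_j} is the frequency of the counted (alternate)
#' allele.  Frequencies are computed from the supplied matrix itself —
#' reference and candidate individuals jointly — unless given.  A small
#' \code{epsilon} is added to the diagonal so the matrix is strictly
#' positive definite for downstream mixed-model solves.
#'
#' @param dosage Individual-by-SNP dosage matrix in \{0, 1, 2\}, no
#'   missing values (run \code{\link{qc_filter}} first).
#' @param freqs Optional per-SNP counted-allele frequencies.
#' @param epsilon Diagonal stabilisation constant (default 1e-6).
#' @return A \code{grm} object: the n-by-n relationship matrix with
#'   individual ids as dimnames and attributes \code{freqs} and
#'   \code{epsilon}.
#' @examples
#' d <- matrix(c(0, 2), 2, 1, dimnames = list(c("a", "b"), "s1"))
#' compute_grm(d)  # [[2, -2], [-2, 2]] plus epsilon on the diagonal
#' @export
compute_grm <- function(dosage, freqs = NULL, epsilon = 1e-6) {
  if (anyNA(dosage))
    stop("dosage matrix has missing values; apply qc_filter() first")
  if (nrow(dosage) < 2) stop("at least two individuals required")
  p <- freqs %||% allele_freq(dosage)
  seg <- p > 0 & p < 1 & matrixVar(dosage) > 0
  if (!any(seg)) stop("all SNPs monomorphic: GRM undefined")
  denom <- sum(2 * p[seg] * (1 - p[seg]))
  M <- sweep(dosage[, seg, drop = FALSE], 2L, 2 * p[seg])
  G <- tcrossprod(M) / denom
  diag(G) <- diag(G) + epsilon
  ids <- rownames(dosage) %||% sprintf("I%d", seq_len(nrow(dosage)))
  dimnames(G) <- list(ids, ids)
  structure(G, freqs = p, epsilon = epsilon, class = c("grm", "matrix"))
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("Genomic relationship matrix: %d individuals, mean diagonal %.3f\n",
              nrow(x), mean(diag(x))))
  invisible(x)
}

#' Write a GRM as lower-triangle text
#'
#' Plain interoperable format: one line per pair \code{(id_i, id_j, value)}
#' with \code{j <= i}, tab-separated.
#'
#' @param grm A \code{grm} (or symmetric matrix with dimnames).
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_grm <- function(grm, path) {
  n <- nrow(grm)
  ij <- which(lower.tri(grm, diag = TRUE), arr.ind = TRUE)
  utils::write.table(
    data.frame(id_i = rownames(grm)[ij[, 1]], id_j = colnames(grm)[ij[, 2]],
               value = grm[ij]),
    path, quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t")
  invisible(path)
}
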