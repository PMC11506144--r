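# Simulation of pairs of genetically correlated quantitative traits.
# Trait A receives randomly sampled QTLs with signed gamma-distributed
# effects; trait B receives, for each trait-A QTL, an LD-matched partner
# locus carrying the *identical* signed effect.  Because the genetic
# covariance contributed by a pair is proportional to the signed dosage
# correlation of its two loci, the realized genetic correlation of the two
# traits approaches the LD target.

#' Specification of one simulated trait
#'
#' @param h2 Narrow-sense heritability, in (0, 1).
#' @param n_qtl Number of causal loci (default 500).
#' @param gamma_shape,gamma_scale Parameters of the gamma distribution of
#'   effect magnitudes (defaults 0.4 and 2/3).
#' @return A \code{trait_spec} list.
#' @export
trait_spec <- function(h2, n_qtl = 500, gamma_shape = 0.4,
                       gamma_scale = 2 / 3) {
  stopifnot_scalar_prob(h2, "h2", 0, 1, open_lo = TRUE, open_hi = TRUE)
  if (n_qtl < 1) stop("'n_qtl' must be at least 1")
  if (gamma_shape <= 0 || gamma_scale <= 0)
    stop("gamma parameters must be positive")
  structure(list(h2 = h2, n_qtl = as.integer(n_qtl),
                 gamma_shape = gamma_shape, gamma_scale = gamma_scale),
            class = "trait_spec")
}

#' Sample QTL positions uniformly from segregating loci
#'
#' @param panel A \code{hap_panel} or dosage matrix.
#' @param n_qtl Number of QTLs.
#' @param seed Optional seed.
#' @return Integer vector of unique column indices, all segregating.
#' @export
sample_qtls <- function(panel, n_qtl, seed = NULL) {
  d <- if (inherits(panel, "hap_panel")) dosages(panel) else panel
  seg <- which(matrixVar(d) > 0)
  if (length(seg) < n_qtl)
    stop(sprintf("only %d segregating loci available for %d QTLs",
                 length(seg), n_qtl))
  with_seed(seed, sort(sample(seg, n_qtl)))
}

# column variances without apply()
matrixVar <- function(x) {
  n <- nrow(x)
  (colMeans(x^2) - colMeans(x)^2) * n / (n - 1)
}

#' Pair each QTL with an LD-matched partner locus
#'
#' For every trait-A QTL, searches within \code{window_snps} markers on the
#' same chromosome for the non-QTL locus whose signed dosage correlation
#' with the QTL is closest to \code{target_r} and within
#' \code{tolerance}; QTLs with no qualifying partner are resampled from the
#' remaining segregating loci and the search repeated.  Partners are
#' distinct from all QTLs of both traits.
#'
#' @param panel \code{hap_panel} or dosage matrix on which LD is measured
#'   (the founder population).
#' @param qtl_a Candidate trait-A QTL indices (e.g. from
#'   \code{\link{sample_qtls}}).
#' @param target_r Signed LD target in (0, 1).
#' @param window_snps Search half-window in markers (default 50).
#' @param tolerance Maximum |realized - target| (default 0.05).
#' @param max_resample Resampling budget across all QTL slots (default
#'   10 times the number of QTLs).
#' @param seed Optional seed.
#' @param chrom Optional chromosome label per column when \code{panel} is a
#'   bare dosage matrix; partners are never sought across a chromosome
#'   boundary.
#' @return A \code{qtl_pairs} list: \code{qtl_a}, \code{qtl_b},
#'   \code{realized_r}, \code{target_r} (effects are attached by
#'   \code{\link{simulate_trait_pair}}).
#' @export
pair_qtls <- function(panel, qtl_a, target_r, window_snps = 50,
                      tolerance = 0.05, max_resample = NULL, seed = NULL,
                      chrom = NULL) {
  stopifnot_scalar_prob(target_r, "target_r", 0, 1,
                        open_lo = TRUE, open_hi = TRUE)
  if (window_snps < 1) stop("'window_snps' must be at least 1")
  d <- if (inherits(panel, "hap_panel")) dosages(panel) else panel
  chrom <- if (inherits(panel, "hap_panel")) panel$map$chrom
           else chrom %||% rep(1L, ncol(d))
  n <- nrow(d); m <- ncol(d)
  mu <- colMeans(d)
  sdv <- sqrt(matrixVar(d))
  seg <- which(sdv > 0)
  max_resample <- max_resample %||% (10L * length(qtl_a))

  q <- as.integer(qtl_a)
  nq <- length(q)
  partner <- integer(nq)
  rr <- numeric(nq)
  used <- rep(FALSE, m)      # loci reserved as QTLs of either trait
  used[q] <- TRUE
  resamples <- 0L

  window_r <- function(qi) {
    w <- seq(max(1L, qi - window_snps), min(m, qi + window_snps))
    w <- w[w != qi & chrom[w] == chrom[qi] & sdv[w] > 0 & !used[w]]
    if (!length(w)) return(NULL)
    r <- as.vector(crossprod(d[, w, drop = FALSE], d[, qi]) / n -
                     mu[w] * mu[qi]) * (n / (n - 1)) / (sdv[w] * sdv[qi])
    list(w = w, r = r)
  }

  with_seed(seed, for (i in seq_len(nq)) {
    repeat {
      cand <- window_r(q[i])
      j <- NA_integer_
      if (!is.null(cand)) {
        dev <- abs(cand$r - target_r)
        best <- which.min(dev)
        if (dev[best] <= tolerance) j <- best
      }
      if (!is.na(j)) {
        partner[i] <- cand$w[j]
        rr[i] <- cand$r[j]
        used[partner[i]] <- TRUE
        break
      }
      # no qualifying partner: resample this trait-A QTL
      resamples <- resamples + 1L
      if (resamples > max_resample)
        stop(sprintf(
          "QTL pairing failed: no partner with |r - %.3g| <= %.3g within %d SNPs after %d resamples",
          target_r, tolerance, window_snps, max_resample))
      used[q[i]] <- FALSE
      free <- seg[!used[seg]]
      if (!length(free)) stop("QTL pairing failed: no segregating loci left")
      q[i] <- if (length(free) == 1L) free else sample(free, 1L)
      used[q[i]] <- TRUE
    }
  })
  structure(list(qtl_a = q, qtl_b = partner, realized_r = rr,
                 target_r = target_r, effects = NULL),
            class = "qtl_pairs")
}

#' Sample signed QTL effects
#'
#' Effect magnitudes are i.i.d. Gamma(\code{shape}, scale = \code{scale});
#' signs are independent fair coin flips.  Both traits of a pair share one
#' signed effect vector.
#'
#' @param n_qtl Number of effects.
#' @param shape,scale Gamma parameters (defaults 0.4 and 2/3).
#' @param seed Optional seed.
#' @return Numeric vector of signed effects.
#' @export
sample_effects <- function(n_qtl, shape = 0.4, scale = 2 / 3, seed = NULL) {
  if (shape <= 0 || scale <= 0) stop("gamma parameters must be positive")
  with_seed(seed, {
    mag <- stats::rgamma(n_qtl, shape = shape, scale = scale)
    sgn <- sample(c(-1, 1), n_qtl, replace = TRUE)
    mag * sgn
  })
}

#' True breeding values from QTL effects
#'
#' \eqn{TBV_i = \sum_j \beta_j \, dosage_{ij}} over the causal loci.
#'
#' @param dosage Individual-by-SNP dosage matrix.
#' @param qtl_indices Column indices of the causal loci.
#' @param effects Signed effects, same length as \code{qtl_indices}.
#' @return Named numeric vector of TBVs.
#' @export
compute_tbv <- function(dosage, qtl_indices, effects) {
  if (length(qtl_indices) != length(effects))
    stop("'qtl_indices' and 'effects' differ in length")
  if (any(qtl_indices < 1 | qtl_indices > ncol(dosage)))
    stop("QTL index out of range")
  drop(dosage[, qtl_indices, drop = FALSE] %*% effects)
}

#' Residual variance implied by a heritability
#'
#' From \eqn{h^2 = V_g / (V_g + V_e)}: \eqn{V_e = V_g (1 - h^2) / h^2}.
#'
#' @param v_g Additive genetic variance (> 0).
#' @param h2 Narrow-sense heritability in (0, 1).
#' @return Residual variance \eqn{V_e}.
#' @export
residual_variance <- function(v_g, h2) {
  if (v_g <= 0) stop("'v_g' must be positive")
  stopifnot_scalar_prob(h2, "h2", 0, 1, open_lo = TRUE, open_hi = TRUE)
  v_g * (1 - h2) / h2
}

#' Simulate a genetically correlated trait pair
#'
#' Runs the full pipeline: sample trait-A QTLs on the founder panel, pair
#' each with an LD-matched partner, draw one shared signed effect vector,
#' compute both TBV vectors on the full panel (founders plus offspring, so
#' candidate TBVs exist for later evaluation), set each trait's residual
#' variance from its own realized founder additive variance and
#' heritability, and add independent normal residuals.
#'
#' @param panel \code{hap_panel} holding every individual that needs a TBV
#'   and phenotype (founders first, offspring appended).
#' @param spec_a,spec_b \code{\link{trait_spec}}s; QTL counts must match.
#' @param target_r Signed LD / genetic-correlation target in (0, 1).
#' @param founder_ids Ids of the founder (reference) individuals on which
#'   LD is measured and \eqn{V_g} is computed; defaults to all individuals.
#' @param window_snps,tolerance Passed to \code{\link{pair_qtls}}.
#' @param seed Optional seed; the same seed yields identical QTLs, effects
#'   and TBVs for every heritability setting (only the residual scale
#'   changes).
#' @return List with \code{trait_a}, \code{trait_b} (each a
#'   \code{trait_data}: \code{tbv}, \code{phenotype}, \code{v_g},
#'   \code{v_e}, \code{h2}) and \code{qtls} (a \code{qtl_pairs} with the
#'   shared \code{effects} attached).
#' @export
simulate_trait_pair <- function(panel, spec_a, spec_b, target_r,
                                founder_ids = NULL, window_snps = 50,
                                tolerance = 0.05, seed = NULL) {
  stopifnot(inherits(panel, "hap_panel"),
            inherits(spec_a, "trait_spec"), inherits(spec_b, "trait_spec"))
  if (spec_a$n_qtl != spec_b$n_qtl)
    stop("paired traits must use the same number of QTLs")
  d_all <- dosages(panel)
  founder_ids <- founder_ids %||% panel$ids
  fidx <- match(founder_ids, panel$ids)
  if (anyNA(fidx)) stop("unknown founder id(s)")
  d_founder <- d_all[fidx, , drop = FALSE]
  chrom <- panel$map$chrom

  with_seed(seed, {
    qtl_a <- sample_qtls(d_founder, spec_a$n_qtl)
    pairs <- pair_qtls(d_founder, qtl_a, target_r, window_snps, tolerance,
                       chrom = chrom)
    effects <- sample_effects(spec_a$n_qtl, spec_a$gamma_shape,
                              spec_a$gamma_scale)
    pairs$effects <- effects
    make_trait <- function(idx, spec) {
      tbv <- compute_tbv(d_all, idx, effects)
      v_g <- stats::var(tbv[fidx])
      v_e <- residual_variance(v_g, spec$h2)
      resid <- stats::rnorm(nrow(d_all), 0, sqrt(v_e))
      structure(list(tbv = stats::setNames(tbv, panel$ids),
                     phenotype = stats::setNames(tbv + resid, panel$ids),
                     v_g = v_g, v_e = v_e, h2 = spec$h2),
                class = "trait_data")
    }
    trait_a <- make_trait(pairs$qtl_a, spec_a)
    trait_b <- make_trait(pairs$qtl_b, spec_b)
    list(trait_a = trait_a, trait_b = trait_b, qtls = pairs)
  })
}

#' Tidy table of simulated QTL pairs
#'
#' @param x A \code{qtl_pairs} object.
#' @param ... Unused.
#' @return Data frame with \code{index_a}, \code{index_b}, \code{effect},
#'   \code{realized_r}.
#' @export
as.data.frame.qtl_pairs <- function(x, ...) {
  data.frame(index_a = x$qtl_a, index_b = x$qtl_b,
             effect = if (is.null(x$effects)) NA_real_ else x$effects,
             realized_r = x$realized_r)
}

#' Tidy phenotype/TBV table for a trait pair
#'
#' @param sim Result of \code{\link{simulate_trait_pair}}.
#' @return Long data frame with \code{id}, \code{trait}, \code{tbv},
#'   \code{phenotype}.
#' @export
trait_table <- function(sim) {
  ids <- names(sim$trait_a$tbv)
  rbind(
    data.frame(id = ids, trait = "A", tbv = unname(sim$trait_a$tbv),
               phenotype = unname(sim$trait_a$phenotype)),
    data.frame(id = ids, trait = "B", tbv = unname(sim$trait_b$tbv),
               phenotype = unname(sim$trait_b$phenotype)))
}
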