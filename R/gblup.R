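#' Fit a GBLUP model by average-information REML
#'
#' Fits the genomic best linear unbiased prediction mixed model.  With a
#' single response the model is \eqn{y = 1\mu + Zg + e} with
#' \eqn{g \sim N(0, G\sigma_a^2)} and \eqn{e \sim N(0, I\sigma_e^2)}.
#' With a two-column response the bivariate model is fitted, with additive
#' effects \eqn{N(0, G \otimes M)} and residuals \eqn{N(0, I \otimes R)},
#' where \eqn{M} and \eqn{R} are free 2x2 covariance matrices (six
#' parameters).  Variance components maximise the restricted likelihood by
#' AI-REML with covariance bending and an ascent-guaranteed line search;
#' breeding values for every individual in \code{grm} — including
#' unphenotyped selection candidates — are then obtained from the
#' mixed-model equations, candidates entering with zero incidence rows
#' (computed in the equivalent conditional-expectation form
#' \eqn{\hat g = \mathrm{Cov}(g, y) V^{-1} (y - X\hat\beta)}).
#'
#' Phenotypes are matched to \code{grm} by name: individuals present in
#' \code{grm} but absent from \code{y} (or \code{NA}) are treated as
#' candidates.  In the bivariate model an individual must be phenotyped for
#' both traits or for neither; other missingness patterns are rejected.
#'
#' @param y Named numeric vector (single trait) or two-column matrix with
#'   row names (bivariate).  \code{NA} marks unphenotyped individuals.
#' @param grm Genomic relationship matrix from \code{\link{compute_grm}}
#'   (any symmetric positive-definite matrix with id dimnames works).
#' @param start Optional starting values: \code{c(sigma_a2, sigma_e2)} or
#'   \code{c(m11, m12, m22, r11, r12, r22)}.  Defaults put half the
#'   phenotypic (co)variance on the additive and residual parts.
#' @param tol Relative parameter-change convergence threshold (default
#'   1e-8); convergence additionally requires a log-likelihood change
#'   below 1e-6.
#' @param max_iter Maximum REML iterations (default 200).  Non-convergence
#'   is a flagged status on the returned object, not an error.
#' @return An object of class \code{gblup} with components
#'   \code{varcomp} (named vector; single trait \code{sigma_a2},
#'   \code{sigma_e2}; bivariate the six (co)variances), \code{M_cov} and
#'   \code{R_cov} (bivariate only), \code{mu} (fixed mean per trait),
#'   \code{gebv} (matrix of breeding values, all individuals by traits),
#'   \code{h2} (estimated heritability per trait), \code{rg} (estimated
#'   genetic correlation, bivariate only), \code{loglik}, \code{converged},
#'   \code{status}, \code{trace} (per-iteration log) and bookkeeping
#'   fields.
#' @examples
#' pan <- simulate_founders(300, n_chrom = 1, snps_per_chrom = 400, seed = 7)
#' sim <- simulate_trait_pair(pan, trait_spec(0.5), trait_spec(0.5),
#'                            target_r = 0.8, seed = 8)
#' G <- compute_grm(dosages(pan))
#' fit <- gblup(sim$trait_a$phenotype, G)
#' fit
#' @seealso \code{\link{reml_loglik}}, \code{\link{accuracy}}
#' @export
gblup <- function(y, grm, start = NULL, tol = 1e-8, max_iter = 200) {
  cl <- match.call()
  ids <- rownames(grm)
  if (is.null(ids)) stop("GRM must carry individual ids as dimnames")
  Y <- if (is.matrix(y)) y else matrix(y, dimnames = list(names(y), NULL))
  if (is.null(rownames(Y)))
    stop("'y' must be named (vector) or have row names (matrix)")
  nt <- ncol(Y)
  if (!nt %in% 1:2) stop("'y' must have one or two columns")
  unknown <- setdiff(rownames(Y), ids)
  if (length(unknown))
    stop("phenotyped id(s) not in the GRM: ",
         paste(utils::head(unknown, 3), collapse = ", "))
  nmiss <- rowSums(is.na(Y))
  if (nt == 2 && any(nmiss == 1))
    stop("bivariate phenotypes must be observed for both traits or neither")
  obs_ids <- rownames(Y)[nmiss == 0]
  n <- length(obs_ids)
  if (n < 3) stop("need at least 3 phenotyped individuals")
  Yo <- Y[obs_ids, , drop = FALSE]

  pre <- reml_prepare(grm, obs_ids)
  xt <- drop(crossprod(pre$U, rep(1, n)))
  Yt <- crossprod(pre$U, Yo)

  if (nt == 1) {
    vp <- max(stats::var(Yo[, 1]), 1e-12)
    th0 <- start %||% c(vp / 2, vp / 2)
    if (length(th0) != 2) stop("'start' must have length 2")
    lb <- c(1e-10 * vp, 1e-8 * vp)
    fit <- reml_maximize(
      function(th, derivs = FALSE) reml_eval1(th, pre$d, xt, Yt[, 1], derivs),
      function(th) fixup1(th, lb), th0, tol, max_iter, lower = lb)
    theta <- stats::setNames(fit$theta, c("sigma_a2", "sigma_e2"))
    alpha <- pre$U %*% fit$r          # V^{-1}(y - X beta) per trait
    gebv <- theta[1] * unclass(grm)[, pre$oi, drop = FALSE] %*% alpha
    M_cov <- R_cov <- NULL
    h2 <- unname(theta[1] / (theta[1] + theta[2]))
    rg <- NULL
  } else {
    Vp <- stats::cov(Yo)
    if (any(!is.finite(Vp)) || det(Vp) <= 0) Vp <- diag(pmax(diag(Vp), 1e-8))
    th0 <- start %||% 0.5 * Vp[c(1, 2, 4, 1, 2, 4)]
    if (length(th0) != 6) stop("'start' must have length 6")
    lb <- 1e-10 * c(mean(diag(Vp)), mean(diag(Vp)))
    fit <- reml_maximize(
      function(th, derivs = FALSE) reml_eval2(th, pre$d, xt, Yt, derivs),
      function(th) fixup2(th, lb), th0, tol, max_iter)
    theta <- stats::setNames(fit$theta,
                             c("sigma_g1", "sigma_g12", "sigma_g2",
                               "sigma_e1", "sigma_e12", "sigma_e2"))
    M_cov <- matrix(fit$theta[c(1, 2, 2, 3)], 2, 2)
    R_cov <- matrix(fit$theta[c(4, 5, 5, 6)], 2, 2)
    alpha <- pre$U %*% fit$r          # n x 2
    gebv <- unclass(grm)[, pre$oi, drop = FALSE] %*% (alpha %*% M_cov)
    h2 <- unname(diag(M_cov) / (diag(M_cov) + diag(R_cov)))
    rg <- unname(M_cov[1, 2] / sqrt(M_cov[1, 1] * M_cov[2, 2]))
  }
  colnames(gebv) <- colnames(Y) %||% paste0("trait", seq_len(nt))
  rownames(gebv) <- ids

  structure(list(
    call = cl, n_traits = nt, varcomp = theta, M_cov = M_cov, R_cov = R_cov,
    mu = stats::setNames(fit$beta, colnames(gebv)), gebv = gebv,
    h2 = h2, rg = rg, loglik = fit$ll, converged = fit$converged,
    status = fit$status, trace = fit$trace,
    n_obs = n, n_total = length(ids), obs_ids = obs_ids,
    y = Y), class = "gblup")
}

#' Restricted log-likelihood of the GBLUP model
#'
#' Evaluates the REML log-likelihood (up to an additive constant) at
#' arbitrary variance components, with its analytic gradient.  Useful for
#' verifying the optimiser against grid or random search.
#'
#' @param theta \code{c(sigma_a2, sigma_e2)} for a single trait, or
#'   \code{c(m11, m12, m22, r11, r12, r22)} for the bivariate model.
#' @param y Named vector or two-column matrix of phenotypes (no \code{NA}
#'   rows are used).
#' @param grm Relationship matrix covering the phenotyped ids.
#' @param gradient Attach the analytic gradient as attribute
#'   \code{"gradient"}? (default \code{TRUE})
#' @return Scalar log-likelihood; \code{-Inf} outside the positive-definite
#'   region raises an error.
#' @export
reml_loglik <- function(theta, y, grm, gradient = TRUE) {
  Y <- if (is.matrix(y)) y else matrix(y, dimnames = list(names(y), NULL))
  Y <- Y[rowSums(is.na(Y)) == 0, , drop = FALSE]
  pre <- reml_prepare(grm, rownames(Y))
  xt <- drop(crossprod(pre$U, rep(1, nrow(Y))))
  Yt <- crossprod(pre$U, Y)
  ev <- if (ncol(Y) == 1) {
    if (length(theta) != 2) stop("single-trait 'theta' has length 2")
    reml_eval1(theta, pre$d, xt, Yt[, 1], derivs = gradient)
  } else {
    if (length(theta) != 6) stop("bivariate 'theta' has length 6")
    reml_eval2(theta, pre$d, xt, Yt, derivs = gradient)
  }
  if (!is.finite(ev$ll))
    stop("covariance parameters outside the positive-definite region")
  out <- ev$ll
  if (gradient) attr(out, "gradient") <- ev$score
  out
}

#' Squared-correlation accuracy of predicted breeding values
#'
#' The model-comparison metric: the squared Pearson correlation
#' (coefficient of determination) between predicted and true breeding
#' values over the candidate individuals.  Plain (signed) correlation is
#' available for sensitivity checks.
#'
#' @param pbv,tbv Equal-length vectors of predicted and true breeding
#'   values.
#' @param squared Return \eqn{r^2} (default) rather than \eqn{r}.
#' @return Scalar accuracy.
#' @export
accuracy <- function(pbv, tbv, squared = TRUE) {
  if (length(pbv) != length(tbv)) stop("'pbv' and 'tbv' differ in length")
  if (stats::var(pbv) == 0 || stats::var(tbv) == 0)
    stop("accuracy undefined: zero variance in breeding values")
  r <- stats::cor(pbv, tbv)
  if (squared) r^2 else r
}

# ---- methods --------------------------------------------------------------

#' @export
print.gblup <- function(x, digits = 4, ...) {
  cat(sprintf("%s GBLUP fit (AI-REML), %d phenotyped of %d individuals\n",
              if (x$n_traits == 1) "Single-trait" else "Bivariate",
              x$n_obs, x$n_total))
  cat("Variance components:\n")
  print(round(x$varcomp, digits))
  if (x$n_traits == 1) {
    cat(sprintf("Heritability: %.3f\n", x$h2))
  } else {
    cat(sprintf("Heritabilities: %.3f / %.3f; genetic correlation: %.3f\n",
                x$h2[1], x$h2[2], x$rg))
  }
  cat(sprintf("Restricted log-likelihood: %.4f (%s, %d iterations)\n",
              x$loglik, x$status, max(x$trace$iter)))
  invisible(x)
}

#' @export
summary.gblup <- function(object, ...) {
  structure(list(fit = object), class = "summary.gblup")
}

#' @export
print.summary.gblup <- function(x, ...) {
  f <- x$fit
  print(f)
  cat(sprintf("Fixed mean(s): %s\n",
              paste(sprintf("%.4f", f$mu), collapse = ", ")))
  cand <- setdiff(rownames(f$gebv), f$obs_ids)
  cat(sprintf("GEBVs: %d individuals (%d candidates)\n",
              nrow(f$gebv), length(cand)))
  invisible(x)
}

#' @export
coef.gblup <- function(object, ...) object$mu

#' @export
fitted.gblup <- function(object, ...) {
  object$gebv[object$obs_ids, , drop = FALSE]
}

#' Predicted breeding values
#'
#' @param object A \code{gblup} fit.
#' @param ids Individuals to report (default: all in the GRM, phenotyped
#'   and candidates alike).
#' @param ... Unused.
#' @return Matrix of GEBVs (individuals by traits).
#' @export
predict.gblup <- function(object, ids = NULL, ...) {
  g <- object$gebv
  if (is.null(ids)) return(g)
  idx <- match(ids, rownames(g))
  if (anyNA(idx)) stop("unknown id(s) in 'ids'")
  g[idx, , drop = FALSE]
}

#' @export
residuals.gblup <- function(object, ...) {
  yo <- object$y[object$obs_ids, , drop = FALSE]
  yo - matrix(object$mu, nrow(yo), object$n_traits, byrow = TRUE) -
    object$gebv[object$obs_ids, , drop = FALSE]
}

#' @export
logLik.gblup <- function(object, ...) {
  structure(object$loglik, df = length(object$varcomp),
            nobs = object$n_obs * object$n_traits, class = "logLik")
}

#' @export
plot.gblup <- function(x, ...) {
  graphics::plot(x$trace$iter, x$trace$loglik, type = "b", pch = 16,
                 xlab = "REML iteration", ylab = "restricted log-likelihood",
                 main = sprintf("%s GBLUP convergence (%s)",
                                if (x$n_traits == 1) "single-trait"
                                else "bivariate", x$status), ...)
  invisible(x)
}
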