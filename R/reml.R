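# Restricted-maximum-likelihood engine for the GBLUP mixed model, single
# trait and bivariate.  All computations run in the eigenbasis of the
# phenotyped block of the genomic relationship matrix: after one symmetric
# eigendecomposition G_oo = U diag(d) U', the phenotypic covariance is
# diagonal (single trait) or 2x2-block-diagonal (bivariate), so the
# restricted log-likelihood, its gradient and the average-information
# matrix all cost O(n) per evaluation.
#
# Maximisation is by average-information (AI) steps with an ascent
# guarantee: a step that leaves the parameter space is pulled back by
# covariance bending (eigenvalue flooring), and a step that would lower the
# restricted log-likelihood is halved; if the AI direction fails entirely
# the iteration falls back to a line search along the score.  Accepted
# iterations therefore never decrease the log-likelihood.

reml_prepare <- function(grm, obs_ids) {
  ids <- rownames(grm)
  if (is.null(ids)) stop("GRM must carry individual ids as dimnames")
  oi <- match(obs_ids, ids)
  if (anyNA(oi)) stop("phenotyped id(s) missing from the GRM")
  Goo <- unclass(grm)[oi, oi, drop = FALSE]
  eg <- eigen(Goo, symmetric = TRUE)
  if (min(eg$values) < -1e-6 * max(abs(eg$values)))
    stop("GRM is not positive definite on the phenotyped individuals")
  list(U = eg$vectors, d = pmax(eg$values, 1e-12), oi = oi, ids = ids)
}

# ---- single trait ---------------------------------------------------------

# th = c(sigma_a2, sigma_e2).  Returns ll (and score/AI when derivs).
reml_eval1 <- function(th, d, xt, yt, derivs = FALSE) {
  v <- th[1] * d + th[2]
  if (any(v <= 0)) return(list(ll = -Inf))
  Cxx <- sum(xt^2 / v)
  beta <- sum(xt * yt / v) / Cxx
  e <- yt - xt * beta
  r <- e / v
  ll <- -0.5 * (sum(log(v)) + log(Cxx) + sum(e * r))
  if (!derivs) return(list(ll = ll, beta = beta, r = r))
  trP <- c(sum(d / v) - sum(xt^2 * d / v^2) / Cxx,
           sum(1 / v) - sum(xt^2 / v^2) / Cxx)
  quad <- c(sum(r^2 * d), sum(r^2))
  score <- -0.5 * (trP - quad)
  w <- list(d * r, r)
  AI <- matrix(0, 2, 2)
  for (i in 1:2) for (j in i:2) {
    val <- sum(w[[i]] * w[[j]] / v) -
      sum(xt * w[[i]] / v) * sum(xt * w[[j]] / v) / Cxx
    AI[i, j] <- AI[j, i] <- 0.5 * val
  }
  list(ll = ll, score = score, AI = AI, beta = beta, r = r)
}

# ---- bivariate ------------------------------------------------------------

# th = c(m11, m12, m22, r11, r12, r22); M additive, R residual 2x2.
reml_eval2 <- function(th, d, xt, Yt, derivs = FALSE) {
  a <- th[1] * d + th[4]
  b <- th[2] * d + th[5]
  cc <- th[3] * d + th[6]
  det <- a * cc - b^2
  if (any(det <= 0) || any(a <= 0)) return(list(ll = -Inf))
  W11 <- cc / det; W22 <- a / det; W12 <- -b / det
  x2 <- xt^2
  Cxx <- matrix(c(sum(x2 * W11), sum(x2 * W12),
                  sum(x2 * W12), sum(x2 * W22)), 2, 2)
  cdet <- Cxx[1, 1] * Cxx[2, 2] - Cxx[1, 2]^2
  if (cdet <= 0) return(list(ll = -Inf))
  Ci <- matrix(c(Cxx[2, 2], -Cxx[1, 2], -Cxx[1, 2], Cxx[1, 1]), 2, 2) / cdet
  y1 <- Yt[, 1]; y2 <- Yt[, 2]
  cxy <- c(sum(xt * (W11 * y1 + W12 * y2)), sum(xt * (W12 * y1 + W22 * y2)))
  beta <- drop(Ci %*% cxy)
  e1 <- y1 - xt * beta[1]; e2 <- y2 - xt * beta[2]
  r1 <- W11 * e1 + W12 * e2
  r2 <- W12 * e1 + W22 * e2
  yPy <- sum(e1 * r1 + e2 * r2)
  ll <- -0.5 * (sum(log(det)) + log(cdet) + yPy)
  if (!derivs) return(list(ll = ll, beta = beta, r = cbind(r1, r2)))

  # per-parameter direction matrices are coef * E with coef d (additive
  # block) or 1 (residual block) and E in {E11, E12+E21, E22}
  coefs <- list(d, d, d, 1, 1, 1)
  etype <- c(1L, 3L, 2L, 1L, 3L, 2L)   # 1 = E11, 2 = E22, 3 = symmetric E12
  score <- numeric(6)
  Wv <- list(W11 = W11, W12 = W12, W22 = W22)
  w1 <- vector("list", 6); w2 <- vector("list", 6)
  p1 <- vector("list", 6); p2 <- vector("list", 6)
  u <- vector("list", 6)
  for (i in 1:6) {
    cf <- coefs[[i]]
    if (etype[i] == 1L) {
      trV <- sum(cf * W11)
      s11 <- sum(x2 * cf * W11^2); s12 <- sum(x2 * cf * W11 * W12)
      s22 <- sum(x2 * cf * W12^2)
      quad <- sum(cf * r1^2)
      wi1 <- cf * r1; wi2 <- 0 * r1
    } else if (etype[i] == 2L) {
      trV <- sum(cf * W22)
      s11 <- sum(x2 * cf * W12^2); s12 <- sum(x2 * cf * W12 * W22)
      s22 <- sum(x2 * cf * W22^2)
      quad <- sum(cf * r2^2)
      wi1 <- 0 * r1; wi2 <- cf * r2
    } else {
      trV <- 2 * sum(cf * W12)
      s11 <- 2 * sum(x2 * cf * W11 * W12)
      s12 <- sum(x2 * cf * (W11 * W22 + W12^2))
      s22 <- 2 * sum(x2 * cf * W12 * W22)
      quad <- 2 * sum(cf * r1 * r2)
      wi1 <- cf * r2; wi2 <- cf * r1
    }
    trP <- trV - (Ci[1, 1] * s11 + 2 * Ci[1, 2] * s12 + Ci[2, 2] * s22)
    score[i] <- -0.5 * (trP - quad)
    w1[[i]] <- wi1; w2[[i]] <- wi2
    p1[[i]] <- W11 * wi1 + W12 * wi2
    p2[[i]] <- W12 * wi1 + W22 * wi2
    u[[i]] <- c(sum(xt * p1[[i]]), sum(xt * p2[[i]]))
  }
  AI <- matrix(0, 6, 6)
  for (i in 1:6) for (j in i:6) {
    val <- sum(w1[[i]] * p1[[j]] + w2[[i]] * p2[[j]]) -
      drop(crossprod(u[[i]], Ci %*% u[[j]]))
    AI[i, j] <- AI[j, i] <- 0.5 * val
  }
  list(ll = ll, score = score, AI = AI, beta = beta, r = cbind(r1, r2),
       Wv = Wv)
}

# ---- parameter-space repair ----------------------------------------------

# floor the eigenvalues of a symmetric 2x2 at `floor_frac` of its trace
bend2 <- function(S, floor_frac = 1e-6, min_abs = 1e-12) {
  eg <- eigen(S, symmetric = TRUE)
  lo <- max(abs(sum(diag(S))) * floor_frac, min_abs)
  if (all(eg$values >= lo)) return(S)
  eg$vectors %*% diag(pmax(eg$values, lo)) %*% t(eg$vectors)
}

fixup1 <- function(th, lb) pmax(th, lb)

fixup2 <- function(th, lb) {
  M <- bend2(matrix(th[c(1, 2, 2, 3)], 2, 2), min_abs = lb[1])
  R <- bend2(matrix(th[c(4, 5, 5, 6)], 2, 2), min_abs = lb[2])
  c(M[1, 1], M[1, 2], M[2, 2], R[1, 1], R[1, 2], R[2, 2])
}

# ---- driver ---------------------------------------------------------------

reml_maximize <- function(evalfun, fixup, th0, tol = 1e-8, max_iter = 200,
                          ll_tol = 1e-6, lower = NULL) {
  th <- fixup(th0)
  cur <- evalfun(th, derivs = TRUE)
  if (!is.finite(cur$ll)) stop("invalid starting values for REML")
  trace <- list(data.frame(iter = 0L, loglik = cur$ll, step = "start",
                           t(th)))
  status <- "max_iter"
  for (it in seq_len(max_iter)) {
    delta <- tryCatch(solve(cur$AI, cur$score), error = function(e) NULL)
    accepted <- FALSE
    for (kind in c("AI", "gradient")) {
      if (kind == "AI" && is.null(delta)) next
      if (kind == "gradient") {
        sc <- cur$score
        # projected gradient: drop components pinned at a lower bound and
        # still pushing outward, so boundary parameters cannot stall the
        # line search for the free ones
        if (!is.null(lower)) sc[th <= lower * (1 + 1e-9) & sc < 0] <- 0
        mx <- max(abs(sc))
        if (mx == 0) { delta <- 0 * th }
        else delta <- sc * (0.1 * max(abs(th)) / mx)
      }
      step <- 1
      for (h in 1:30) {
        cand <- fixup(th + step * delta)
        ev <- evalfun(cand, derivs = FALSE)
        if (is.finite(ev$ll) && ev$ll >= cur$ll - 1e-10) {
          accepted <- TRUE
          stype <- if (kind == "AI" && h == 1) "AI"
                   else if (kind == "AI") "AI-halved" else "gradient"
          break
        }
        step <- step / 2
      }
      if (accepted) break
    }
    if (!accepted) { status <- "stalled"; break }
    new_th <- fixup(th + step * delta)
    new <- evalfun(new_th, derivs = TRUE)
    rel <- max(abs(new_th - th) / (abs(th) + 1e-10))
    dll <- new$ll - cur$ll
    trace[[length(trace) + 1L]] <-
      data.frame(iter = it, loglik = new$ll, step = stype, t(new_th))
    th <- new_th; cur <- new
    if (rel < tol && abs(dll) < ll_tol) { status <- "converged"; break }
  }
  trace <- do.call(rbind, trace)
  names(trace)[-(1:3)] <- paste0("theta", seq_along(th))
  list(theta = th, ll = cur$ll, beta = cur$beta, r = cur$r,
       status = status, trace = trace,
       converged = status == "converged")
}
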