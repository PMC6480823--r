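#' Fit a model to sample moments by least-squares discrepancy minimization
#'
#' Minimizes \eqn{F(\theta) = \sum_m w_m (s_m - \sigma_m(\theta))^2} over the
#' nonredundant moments (criterion diagonals excluded, they are fixed at 1).
#' `ULS` uses unit weights; `DWLS` uses user-supplied weights (or
#' normal-theory inverse moment variances when none are given); `ML` uses the
#' normal-theory log-determinant discrepancy on the full matrix.  Estimation
#' proceeds via `nlminb` from data-informed start values, with a seeded
#' jittered-restart schedule, followed by Gauss--Newton polishing of the
#' least-squares solutions until the gradient infinity-norm is below
#' tolerance.
#'
#' The minimized discrepancy times \eqn{n - 1} is reported as an (unscaled)
#' chi-square-type statistic; for moments assembled from polychoric and
#' polyserial correlations this is not the mean-and-variance-adjusted test
#' statistic a raw-data weighted estimator would produce, and it is labeled by
#' the estimator tag accordingly.
#'
#' @param model a `bfid_model`.
#' @param moments a `bfid_moments` object covering all model variables.
#' @param estimator `"ULS"` (default), `"DWLS"`, or `"ML"`.
#' @param weights optional positive weight vector (length = number of
#'   nonredundant moments) for `DWLS`.
#' @param control list: `restarts` (default 5), `seed` (default 1),
#'   `grad_tol` (default 1e-8), `iter_max`.
#' @return an object of class `bfid_fit`.
#' @export
fit_model <- function(model, moments, estimator = c("ULS", "DWLS", "ML"),
                      weights = NULL, control = list()) {
  estimator <- match.arg(estimator)
  restarts <- control$restarts %||% 5L
  seed <- control$seed %||% 1L
  grad_tol <- control$grad_tol %||% 1e-8
  iter_max <- control$iter_max %||% 500L

  S <- align_moments(model, moments)
  mi <- moment_index(model)
  s <- moment_vector(S, model, mi)
  nm <- length(s)

  w <- rep(1, nm)
  if (estimator == "DWLS") {
    if (!is.null(weights)) {
      stopifnot(length(weights) == nm, all(weights > 0))
      w <- weights
    } else {
      ## normal-theory diagonal: Var(s_ij) prop. to s_ii s_jj + s_ij^2
      i <- mi$pairs[, 1]; j <- mi$pairs[, 2]
      w <- 1 / (diag(S)[i] * diag(S)[j] + S[cbind(i, j)]^2)
    }
  }

  objective <- if (estimator == "ML") {
    p <- length(model$obs)
    ldS <- determinant(S, logarithm = TRUE)$modulus
    function(theta) {
      Sg <- implied_sigma(model, theta)
      ev <- tryCatch(chol(Sg), error = function(e) NULL)
      if (is.null(ev)) return(1e10)
      ld <- 2 * sum(log(diag(ev)))
      as.numeric(ld + sum(diag(chol2inv(ev) %*% S)) - ldS - p)
    }
  } else {
    function(theta) {
      sg <- moment_vector(implied_sigma(model, theta), model, mi)
      sum(w * (s - sg)^2)
    }
  }

  theta0 <- start_values(model, S)
  best <- NULL
  old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  set.seed(seed)
  for (r in 0:restarts) {
    st <- if (r == 0L) theta0 else jitter_start(model, theta0)
    opt <- tryCatch(
      stats::nlminb(st, objective,
                    control = list(iter.max = iter_max, eval.max = 4L * iter_max,
                                   rel.tol = 1e-14)),
      error = function(e) NULL)
    if (is.null(opt)) next
    cand <- list(theta = opt$par, value = opt$objective)
    if (estimator != "ML")
      cand <- gn_polish(model, cand$theta, s, w, mi, grad_tol)
    if (is.null(best) || cand$value < best$value - 1e-12) best <- cand
    if (!is.null(best) && best$grad_norm %||% Inf <= grad_tol && r >= 0L) break
  }
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  if (is.null(best)) stop("non-convergence: all optimizer starts failed")

  theta_hat <- best$theta
  names(theta_hat) <- theta_labels(model)
  grad_norm <- best$grad_norm %||% fd_grad_norm(objective, theta_hat)
  converged <- grad_norm <= max(grad_tol, 1e-6)
  if (!converged)
    warning(sprintf("fit did not reach gradient tolerance (|g|_inf = %.2e)",
                    grad_norm))
  Sigma_hat <- implied_sigma(model, theta_hat)
  heywood_check(model, theta_hat)

  structure(list(
    model = model, moments = moments, estimator = estimator, weights = w,
    theta = theta_hat, discrepancy = best$value,
    chisq = (moments$n - 1) * best$value, df = model$df, n = moments$n,
    converged = converged, grad_norm = grad_norm,
    implied = Sigma_hat, sample = S), class = "bfid_fit")
}

## Gauss-Newton refinement of a least-squares solution; the ridge term keeps
## steps defined for rank-deficient (nonidentified) models, where the minimum
## is attained on a manifold rather than at a point.
gn_polish <- function(model, theta, s, w, mi, grad_tol, max_iter = 50L) {
  f <- function(th) {
    sg <- moment_vector(implied_sigma(model, th), model, mi)
    sum(w * (s - sg)^2)
  }
  value <- f(theta)
  grad_norm <- Inf
  for (it in seq_len(max_iter)) {
    J <- implied_jacobian(model, theta)
    r <- s - moment_vector(implied_sigma(model, theta), model, mi)
    g <- -2 * crossprod(J, w * r)
    grad_norm <- max(abs(g))
    if (grad_norm <= grad_tol) break
    A <- crossprod(J, w * J)
    step <- tryCatch(solve(A + diag(1e-10, ncol(A)), crossprod(J, w * r)),
                     error = function(e) NULL)
    if (is.null(step)) break
    lam <- 1
    repeat {
      cand <- theta + lam * as.numeric(step)
      vc <- f(cand)
      if (vc <= value + 1e-14) { theta <- cand; value <- vc; break }
      lam <- lam / 2
      if (lam < 1e-6) break
    }
    if (lam < 1e-6) break
  }
  list(theta = theta, value = value, grad_norm = grad_norm)
}

fd_grad_norm <- function(f, theta, h = 1e-7) {
  g <- vapply(seq_along(theta), function(j) {
    hj <- h * max(1, abs(theta[j]))
    tp <- theta; tp[j] <- tp[j] + hj
    tm <- theta; tm[j] <- tm[j] - hj
    (f(tp) - f(tm)) / (2 * hj)
  }, numeric(1))
  max(abs(g))
}

## data-informed start values: loadings 1, factor variances half the average
## indicator variance (per factor), error variances half the indicator
## variance, covariances and regressions 0
start_values <- function(model, S) {
  theta <- theta_pack(model)
  pt <- model$par_table
  vS <- diag(S)
  for (k in seq_len(nrow(pt))) {
    if (pt$matrix[k] == "error_cov") {
      theta[k] <- vS[pt$row[k]] / 2
    } else if (pt$matrix[k] == "factor_cov" && pt$row[k] == pt$col[k] &&
               pt$row[k] %in% model$fac) {
      load_on <- rownames(model$idx$Lambda)[
        model$idx$Lambda[, pt$row[k]] > 0 | model$tmpl$Lambda[, pt$row[k]] != 0]
      load_on <- intersect(load_on, model$indicators)
      theta[k] <- if (length(load_on)) mean(vS[load_on]) / 2 else 0.5
    }
  }
  theta
}

jitter_start <- function(model, theta0) {
  pt <- model$par_table
  varlike <- (pt$matrix == "error_cov") |
    (pt$matrix == "factor_cov" & pt$row == pt$col)
  th <- theta0
  th[varlike] <- th[varlike] * stats::runif(sum(varlike), 0.5, 1.5)
  th[!varlike] <- th[!varlike] + stats::rnorm(sum(!varlike), 0, 0.2)
  th
}

heywood_check <- function(model, theta) {
  m <- theta_unpack(model, theta)
  bad <- character()
  tv <- diag(m$Theta)[model$indicators]
  bad <- c(bad, sprintf("theta[%s]", names(tv)[tv < -1e-8]))
  fv <- diag(m$Phi)[model$fac]
  bad <- c(bad, sprintf("phi[%s]", names(fv)[fv < -1e-8]))
  if (model$mode == "regression" && length(model$criteria)) {
    rv <- criterion_residual_var(model, theta)
    bad <- c(bad, sprintf("residual[%s]", names(rv)[rv < -1e-8]))
  }
  if (length(bad))
    warning("Heywood case: negative variance estimate in ",
            paste(bad, collapse = ", "))
  invisible(bad)
}

#' @export
print.bfid_fit <- function(x, ...) {
  cat(sprintf("<bfid_fit> %s %s model (%s)\n", x$estimator,
              x$model$structure, x$model$mode))
  cat(sprintf("  discrepancy = %.6g, (n-1)*F = %.3f, df = %d, converged: %s\n",
              x$discrepancy, x$chisq, x$df, x$converged))
  invisible(x)
}

#' Standardized solution of a fitted model
#'
#' Standardized loadings (`lambda * SD(factor) / SD(indicator)`), factor
#' correlations (including factor--criterion correlations in covariance
#' mode), standardized regression coefficients
#' (`b_s = b * SD(predictor) / SD(criterion)`), per-criterion R-squared,
#' indicator reliabilities (1 minus standardized residual variance), and the
#' standardized criterion residual covariance (regression mode).
#'
#' @param fit a converged `bfid_fit`.
#' @return an object of class `bfid_std`.
#' @export
standardize <- function(fit) {
  model <- fit$model
  m <- theta_unpack(model, fit$theta)
  Sg <- fit$implied
  nC <- length(model$criteria)

  ## full latent covariance matrix (criterion latents appended in regression
  ## mode so both modes expose factor-criterion correlations uniformly)
  if (model$mode == "regression" && nC) {
    cross <- m$Beta %*% m$Phi
    expl <- cross %*% t(m$Beta)
    Pcc <- expl + m$Psi; diag(Pcc) <- 1
    Phi_full <- rbind(cbind(m$Phi, t(cross)), cbind(cross, Pcc))
    dimnames(Phi_full) <- list(c(model$lat, model$criteria),
                               c(model$lat, model$criteria))
  } else {
    Phi_full <- m$Phi
  }
  dPhi <- diag(Phi_full)
  if (any(dPhi <= 0))
    stop("nonpositive latent variance; standardization undefined")
  dSig <- diag(Sg)
  if (any(dSig <= 0)) stop("nonpositive implied variance")
  fac_sd <- sqrt(dPhi)
  obs_sd <- sqrt(dSig)

  loadings <- NULL
  lam_cells <- which(model$idx$Lambda > 0 | model$tmpl$Lambda != 0,
                     arr.ind = TRUE)
  lam_cells <- lam_cells[rownames(model$idx$Lambda)[lam_cells[, 1]] %in%
                           model$indicators, , drop = FALSE]
  loadings <- data.frame(
    indicator = model$obs[lam_cells[, 1]],
    factor = colnames(model$tmpl$Lambda)[lam_cells[, 2]],
    est = m$Lambda[lam_cells],
    std = m$Lambda[lam_cells] *
      fac_sd[colnames(model$tmpl$Lambda)[lam_cells[, 2]]] /
      obs_sd[model$obs[lam_cells[, 1]]],
    stringsAsFactors = FALSE)

  factor_corr <- stats::cov2cor(Phi_full)
  reliability <- 1 - diag(m$Theta)[model$indicators] /
    dSig[model$indicators]

  regression <- NULL; r2 <- NULL; resid_corr <- NULL
  if (model$mode == "regression" && nC) {
    cells <- which(model$idx$Beta > 0, arr.ind = TRUE)
    regression <- data.frame(
      criterion = model$criteria[cells[, 1]],
      predictor = model$lat[cells[, 2]],
      b = m$Beta[cells],
      b_s = m$Beta[cells] * fac_sd[model$lat[cells[, 2]]] /
        sqrt(diag(Pcc))[cells[, 1]],
      stringsAsFactors = FALSE)
    r2 <- diag(expl) / diag(Pcc)
    names(r2) <- model$criteria
    psi_d <- 1 - diag(expl)
    if (nC > 1) {
      resid_corr <- m$Psi / tcrossprod(sqrt(psi_d))
      diag(resid_corr) <- 1
      dimnames(resid_corr) <- list(model$criteria, model$criteria)
    }
  }

  structure(list(loadings = loadings, factor_corr = factor_corr,
                 factor_sd = fac_sd, reliability = reliability,
                 regression = regression, r2 = r2, resid_corr = resid_corr,
                 mode = model$mode), class = "bfid_std")
}

#' @export
print.bfid_std <- function(x, ...) {
  cat("<bfid_std> standardized solution\n\nLoadings:\n")
  print(transform(x$loadings, est = round(est, 3), std = round(std, 3)))
  cat("\nLatent correlations:\n")
  print(round(x$factor_corr, 3))
  if (!is.null(x$regression)) {
    cat("\nRegressions:\n")
    print(transform(x$regression, b = round(b, 3), b_s = round(b_s, 3)))
    cat("\nR-squared:\n"); print(round(x$r2, 3))
  }
  invisible(x)
}

#' Proportion of criterion variance explained
#'
#' `R^2 = 1 - residual variance / total implied criterion variance`, which
#' for unit-variance latent-response criteria equals
#' \eqn{\beta^\top \Phi \beta}.  Defined only for regression-extension fits.
#'
#' @param fit a `bfid_fit` in regression mode.
#' @return named numeric vector, one entry per criterion.
#' @export
rsquared <- function(fit) {
  if (fit$model$mode != "regression")
    stop("rsquared() is defined for regression-extension fits only")
  standardize(fit)$r2
}

#' Delta-method standard errors of the free parameters
#'
#' Sandwich-form standard errors
#' \eqn{(J^\top W J)^{-1} J^\top W \Gamma W J (J^\top W J)^{-1} / (n-1)} with
#' \eqn{\Gamma} the normal-theory covariance of the sample moments evaluated
#' at the fitted implied matrix.  For moments assembled from published
#' polychoric/polyserial correlations this approximates — but does not
#' equal — the standard errors a raw-data weighted estimator (e.g. WLSMV)
#' would report; significance patterns, not digits, are the supported use.
#'
#' @param fit a converged `bfid_fit`.
#' @return data.frame with columns `label`, `est`, `se`, `z`.
#' @export
standard_errors <- function(fit) {
  model <- fit$model
  if (!fit$converged) stop("standard errors require a converged fit")
  mi <- moment_index(model)
  J <- implied_jacobian(model, fit$theta)
  sv <- svd(J)$d
  tol <- max(dim(J)) * .Machine$double.eps * sv[1] * 1e3
  if (sum(sv > tol) < model$n_free)
    stop("model is not locally identified at the estimate (rank-deficient ",
         "Jacobian); see local_identification_rank()")
  Gamma <- moment_gamma(fit$implied, mi)
  w <- fit$weights
  A <- solve(crossprod(J, w * J))
  B <- crossprod(w * J, Gamma %*% (w * J))
  acov <- A %*% B %*% A / (fit$n - 1)
  se <- sqrt(pmax(diag(acov), 0))
  data.frame(label = theta_labels(model), est = unname(fit$theta), se = se,
             z = unname(fit$theta) / se, stringsAsFactors = FALSE)
}

## normal-theory asymptotic covariance of sample moments:
## n * Cov(s_ij, s_kl) = sigma_ik sigma_jl + sigma_il sigma_jk
moment_gamma <- function(Sigma, mi) {
  prs <- mi$pairs
  nm <- nrow(prs)
  G <- matrix(0, nm, nm, dimnames = list(mi$labels, mi$labels))
  for (a in seq_len(nm)) {
    i <- prs[a, 1]; j <- prs[a, 2]
    G[a, ] <- Sigma[i, prs[, 1]] * Sigma[j, prs[, 2]] +
      Sigma[i, prs[, 2]] * Sigma[j, prs[, 1]]
  }
  (G + t(G)) / 2
}
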