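#' Local identification via the rank of the implied-moment Jacobian
#'
#' A model is locally identified at a parameter point if the Jacobian of the
#' nonredundant implied moments with respect to the free parameters has full
#' column rank there.  The rank is evaluated numerically (SVD) at a sample of
#' random admissible parameter points; the reported rank is the maximum over
#' points (the generic rank), the deficiency is `n_free - rank`, and the
#' labeled null-space basis is taken from a point attaining the maximum rank.
#' Singular values below `max(dim) * eps * sigma_max * 1e3` count as zero;
#' the full singular spectrum of the best point is returned so borderline,
#' nearly nonidentified models (e.g. free loadings that are almost equal) can
#' be audited.
#'
#' @param model a `bfid_model`.
#' @param n_points number of random evaluation points (default 25).
#' @param seed RNG seed for the sampling plan.
#' @param svd_tol_factor multiplier on the machine-precision rank threshold.
#' @return an object of class `bfid_identification`: `n_free`, `rank`,
#'   `deficiency`, `null_directions` (orthonormal columns labeled by
#'   parameter), `singular_values`, `n_points`, `tolerance`, and
#'   `max_null_residual` (largest `|J v|` entry over all evaluation points and
#'   null directions).
#' @export
local_identification_rank <- function(model, n_points = 25L, seed = 42L,
                                      svd_tol_factor = 1e3) {
  old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  set.seed(seed)
  pts <- vector("list", n_points)
  tries <- 0L
  while (length(Filter(Negate(is.null), pts)) < n_points) {
    tries <- tries + 1L
    if (tries > 50L * n_points) stop("no admissible evaluation point found")
    k <- which(vapply(pts, is.null, logical(1)))[1]
    pts[[k]] <- random_admissible_theta(model)
  }
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())

  best <- NULL; tol_used <- NA_real_
  Js <- vector("list", n_points)
  ranks <- integer(n_points)
  for (k in seq_len(n_points)) {
    J <- implied_jacobian(model, pts[[k]])
    sv <- svd(J, nu = 0, nv = 0)$d
    tol <- max(dim(J)) * .Machine$double.eps * sv[1] * svd_tol_factor
    ranks[k] <- sum(sv > tol)
    Js[[k]] <- J
    if (is.null(best) || ranks[k] > ranks[best]) { best <- k; tol_used <- tol }
  }
  rank <- max(ranks)
  deficiency <- model$n_free - rank
  null_dirs <- NULL; max_resid <- 0
  if (deficiency > 0) {
    dec <- svd(Js[[best]])
    null_dirs <- dec$v[, (rank + 1L):model$n_free, drop = FALSE]
    rownames(null_dirs) <- theta_labels(model)
    colnames(null_dirs) <- paste0("null", seq_len(deficiency))
    for (k in seq_len(n_points))
      max_resid <- max(max_resid, abs(Js[[k]] %*% null_dirs))
  }
  structure(list(n_free = model$n_free, rank = rank, deficiency = deficiency,
                 null_directions = null_dirs,
                 singular_values = svd(Js[[best]], nu = 0, nv = 0)$d,
                 n_points = n_points, tolerance = tol_used,
                 max_null_residual = max_resid),
            class = "bfid_identification")
}

#' @export
print.bfid_identification <- function(x, ...) {
  cat(sprintf("<bfid_identification> free = %d, rank = %d, deficiency = %d (%d points)\n",
              x$n_free, x$rank, x$deficiency, x$n_points))
  if (x$deficiency > 0) {
    cat("null-space directions (entries > 0.05 in absolute value):\n")
    nd <- x$null_directions
    for (k in seq_len(ncol(nd))) {
      big <- which(abs(nd[, k]) > 0.05)
      cat(sprintf("  %s: %s\n", colnames(nd)[k],
                  paste(sprintf("%s=%.3f", rownames(nd)[big], nd[big, k]),
                        collapse = ", ")))
    }
  }
  invisible(x)
}

## draw a random admissible parameter point: positive variances, factor
## covariances scaled to keep Phi positive definite, moderate loadings and
## regression weights with residual-variance headroom for the criteria
random_admissible_theta <- function(model, max_tries = 100L) {
  pt <- model$par_table
  for (try in seq_len(max_tries)) {
    theta <- numeric(model$n_free)
    for (k in seq_len(model$n_free)) {
      theta[k] <- switch(pt$matrix[k],
        error_cov = stats::runif(1, 0.5, 2),
        factor_cov = if (pt$row[k] == pt$col[k]) stats::runif(1, 0.5, 2)
                     else stats::runif(1, -0.4, 0.4),
        loading = stats::runif(1, 0.5, 1.5),
        regression = stats::runif(1, -0.3, 0.3),
        criterion_residual_cov = stats::runif(1, -0.2, 0.2))
    }
    ## rescale off-diagonal factor covariances by the variances involved
    m <- theta_unpack(model, theta)
    P <- m$Phi
    d <- sqrt(diag(P))
    off <- which(upper.tri(P) | lower.tri(P), arr.ind = TRUE)
    P[off] <- P[off] * d[off[, 1]] * d[off[, 2]]
    ## write back the scaled covariances into theta
    ii <- model$idx$Phi > 0
    theta[model$idx$Phi[ii]] <- P[ii]
    ok <- all(eigen(P, symmetric = TRUE, only.values = TRUE)$values > 1e-8)
    if (ok && model$mode == "regression" && length(model$criteria))
      ok <- all(criterion_residual_var(model, theta) > 0.05)
    if (ok) { names(theta) <- pt$label; return(theta) }
  }
  stop("no admissible evaluation point found")
}

#' The observationally equivalent parameter family of the equal-loadings
#' extended bifactor model
#'
#' When all loadings of a bifactor model are fixed to a common value, the
#' covariance of every indicator with a criterion decomposes into the same
#' two components, the covariance of the criterion with the general factor
#' plus its covariance with one specific factor.  Shifting
#' `Cov(G,C) -> Cov(G,C) + delta` and `Cov(S_k,C) -> Cov(S_k,C) - delta` for
#' all facets `k` therefore leaves every implied moment unchanged, which is
#' exactly why the model is not identified.  In regression mode the
#' equivalent shift is `beta_G + delta/Var(G)`, `beta_k - delta/Var(S_k)`,
#' with the criterion residual covariance recompensated.
#'
#' @param model an equal-loadings extended bifactor `bfid_model`.
#' @param theta parameter vector.
#' @param delta shift magnitude; scalar (applied to every criterion) or a
#'   named vector over criteria.
#' @return a parameter vector `theta2` with `implied_covariance(model,
#'   theta2)` equal to `implied_covariance(model, theta)` to machine
#'   precision.
#' @export
nonidentification_family <- function(model, theta, delta) {
  if (model$structure != "bifactor")
    stop("the equivalence family is defined for bifactor models")
  lam_free <- any(model$idx$Lambda[model$indicators, , drop = FALSE] > 0)
  if (lam_free)
    stop("the equivalence family requires all loadings fixed (equal)")
  lam_vals <- model$tmpl$Lambda[model$indicators, model$fac, drop = FALSE]
  if (length(unique(lam_vals[lam_vals != 0])) != 1L)
    stop("the equivalence family requires equal fixed loadings")
  if (!length(model$criteria))
    stop("model has no criterion variables")
  if (is.null(names(delta))) {
    delta <- rep(delta[1], length(model$criteria))
    names(delta) <- model$criteria
  }
  gname <- model$factors$name[model$factors$kind == "general"]
  snames <- model$factors$name[model$factors$kind == "specific"]
  theta2 <- theta
  if (model$mode == "covariance") {
    for (cr in names(delta)) {
      sg <- model$idx$Phi[gname, cr]
      if (sg == 0) stop("Cov(", gname, ",", cr, ") is not a free cell")
      theta2[sg] <- theta2[sg] + delta[cr]
      for (s in snames) {
        ss <- model$idx$Phi[s, cr]
        if (ss == 0) stop("Cov(", s, ",", cr, ") is not a free cell")
        theta2[ss] <- theta2[ss] - delta[cr]
      }
    }
  } else if (model$mode == "regression") {
    m <- theta_unpack(model, theta)
    vG <- m$Phi[gname, gname]
    for (cr in names(delta)) {
      sg <- model$idx$Beta[cr, gname]
      if (sg == 0) stop("beta(", cr, "~", gname, ") is not a free cell")
      theta2[sg] <- theta2[sg] + delta[cr] / vG
      for (s in snames) {
        ss <- model$idx$Beta[cr, s]
        if (ss == 0) stop("beta(", cr, "~", s, ") is not a free cell")
        theta2[ss] <- theta2[ss] - delta[cr] / m$Phi[s, s]
      }
    }
    rv <- criterion_residual_var(model, theta2)
    if (any(rv <= 0))
      stop("delta exhausts the residual variance of: ",
           paste(names(rv)[rv <= 0], collapse = ", "))
    ## recompensate the residual covariance so Cov(C1,C2) is unchanged
    if (length(model$criteria) > 1L) {
      m1 <- theta_unpack(model, theta)
      m2 <- theta_unpack(model, theta2)
      e1 <- m1$Beta %*% m1$Phi %*% t(m1$Beta)
      e2 <- m2$Beta %*% m2$Phi %*% t(m2$Beta)
      for (a in 2:length(model$criteria)) for (b in seq_len(a - 1L)) {
        sp <- model$idx$Psi[a, b]
        if (sp > 0) theta2[sp] <- theta2[sp] + (e1[a, b] - e2[a, b])
      }
    }
  } else stop("measurement-mode models have no criterion parameters to shift")
  theta2
}
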