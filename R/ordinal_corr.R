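## Standard bivariate normal CDF P(X <= h, Y <= k) for correlation r,
## via the Drezner--Wesolowsky/Genz Gauss-Legendre quadrature (absolute
## error well below 1e-7 over the whole parameter range).
pbvn <- function(h, k, r) {
  bvnd_upper(-h, -k, r)
}

## P(X > dh, Y > dk); port of the published quadrature algorithm
bvnd_upper <- function(dh, dk, r) {
  stopifnot(abs(r) <= 1)
  if (!is.finite(dh) || !is.finite(dk)) {
    if (dh == Inf || dk == Inf) return(0)
    if (dh == -Inf) return(stats::pnorm(-dk))
    if (dk == -Inf) return(stats::pnorm(-dh))
  }
  twopi <- 2 * pi
  gauss <- if (abs(r) < 0.3) list(
    w = c(0.1713244923791705, 0.3607615730481384, 0.4679139345726904),
    x = c(-0.9324695142031522, -0.6612093864662647, -0.2386191860831970))
  else if (abs(r) < 0.75) list(
    w = c(0.04717533638651177, 0.1069393259953183, 0.1600783285433464,
          0.2031674267230659, 0.2334925365383547, 0.2491470458134029),
    x = c(-0.9815606342467191, -0.9041172563704750, -0.7699026741943050,
          -0.5873179542866171, -0.3678314989981802, -0.1252334085114692))
  else list(
    w = c(0.01761400713915212, 0.04060142980038694, 0.06267204833410906,
          0.08327674157670475, 0.1019301198172404, 0.1181945319615184,
          0.1316886384491766, 0.1420961093183821, 0.1491729864726037,
          0.1527533871307259),
    x = c(-0.9931285991850949, -0.9639719272779138, -0.9122344282513259,
          -0.8391169718222188, -0.7463319064601508, -0.6360536807265150,
          -0.5108670019508271, -0.3737060887154196, -0.2277858511416451,
          -0.07652652113349733))
  h <- dh; k <- dk; hk <- h * k; bvn <- 0
  if (abs(r) < 0.925) {
    if (abs(r) > 0) {
      hs <- (h * h + k * k) / 2
      asr <- asin(r)
      for (i in seq_along(gauss$x)) for (is in c(-1, 1)) {
        sn <- sin(asr * (is * gauss$x[i] + 1) / 2)
        bvn <- bvn + gauss$w[i] * exp((sn * hk - hs) / (1 - sn * sn))
      }
      bvn <- bvn * asr / (2 * twopi)
    }
    bvn <- bvn + stats::pnorm(-h) * stats::pnorm(-k)
  } else {
    if (r < 0) { k <- -k; hk <- -hk }
    if (abs(r) < 1) {
      as_ <- (1 - r) * (1 + r); a <- sqrt(as_); bs <- (h - k)^2
      cc <- (4 - hk) / 8; d <- (12 - hk) / 16
      asr <- -(bs / as_ + hk) / 2
      if (asr > -100)
        bvn <- a * exp(asr) *
          (1 - cc * (bs - as_) * (1 - d * bs / 5) / 3 + cc * d * as_ * as_ / 5)
      if (-hk < 100) {
        b <- sqrt(bs)
        sp <- sqrt(twopi) * stats::pnorm(-b / a)
        bvn <- bvn - exp(-hk / 2) * sp * b * (1 - cc * bs * (1 - d * bs / 5) / 3)
      }
      a <- a / 2
      for (i in seq_along(gauss$x)) for (is in c(-1, 1)) {
        xs <- (a * (is * gauss$x[i] + 1))^2
        rs <- sqrt(1 - xs)
        asr <- -(bs / xs + hk) / 2
        if (asr > -100) {
          sp <- 1 + cc * xs * (1 + d * xs)
          ep <- exp(-hk * (1 - rs) / (2 * (1 + rs))) / rs
          bvn <- bvn + a * gauss$w[i] * exp(asr) * (ep - sp)
        }
      }
      bvn <- -bvn / twopi
    }
    if (r > 0) bvn <- bvn + stats::pnorm(-max(h, k))
    else {
      bvn <- -bvn
      if (k > h) bvn <- bvn + stats::pnorm(k) - stats::pnorm(h)
    }
  }
  max(0, min(1, bvn))
}

## thresholds from marginal proportions of an ordinal variable
thresholds_from_props <- function(props) {
  props <- props / sum(props)
  stats::qnorm(cumsum(props)[-length(props)])
}

## merge empty margin categories into the adjacent category toward the median
collapse_empty <- function(tab, margin) {
  counts <- margin.table(tab, margin)
  while (any(counts == 0) && length(counts) > 2L) {
    k <- which(counts == 0)[1]
    med <- which.min(abs(cumsum(counts) / sum(counts) - 0.5))
    into <- if (k < med || k == length(counts)) k - 1L else k + 1L
    into <- max(1L, min(length(counts), into))
    if (into == k) into <- if (k == 1L) 2L else k - 1L
    message("collapsing empty category ", k, " into ", into,
            " on margin ", margin)
    idx <- seq_len(dim(tab)[margin])
    grp <- idx; grp[k] <- into
    tab <- if (margin == 1L) rowsum(tab, grp) else t(rowsum(t(tab), grp))
    counts <- margin.table(tab, margin)
  }
  tab
}

#' Polychoric correlation from a contingency table
#'
#' Two-step estimator: thresholds from the marginal cumulative proportions by
#' inverse-normal transform, then one-dimensional maximum likelihood over the
#' latent correlation using bivariate-normal rectangle probabilities.
#'
#' @param tab K x L contingency table of counts (K, L >= 2).
#' @return an object of class `bfid_corr`: `value`, `type = "polychoric"`,
#'   `thresholds` (list with `row`, `col`), `converged`, `n`.
#' @export
polychoric <- function(tab) {
  tab <- as.matrix(tab)
  if (any(dim(tab) < 2L)) stop("need at least 2 categories per margin")
  n <- sum(tab)
  if (n <= 0) stop("empty table")
  tab <- collapse_empty(tab, 1L)
  tab <- collapse_empty(tab, 2L)
  tr <- thresholds_from_props(rowSums(tab))
  tc <- thresholds_from_props(colSums(tab))
  a <- c(-Inf, tr, Inf); b <- c(-Inf, tc, Inf)
  nll <- function(rho) {
    ll <- 0
    for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
      if (tab[i, j] == 0) next
      p <- pbvn(a[i + 1], b[j + 1], rho) - pbvn(a[i], b[j + 1], rho) -
        pbvn(a[i + 1], b[j], rho) + pbvn(a[i], b[j], rho)
      ll <- ll + tab[i, j] * log(max(p, 1e-12))
    }
    -ll
  }
  opt <- stats::optimize(nll, c(-1 + 1e-6, 1 - 1e-6), tol = 1e-8)
  value <- opt$minimum
  clamped <- abs(value) > 1 - 1e-5
  if (clamped) {
    value <- sign(value) * (1 - 1e-6)
    warning("polychoric estimate at the boundary; clamped")
  }
  structure(list(value = value, type = "polychoric",
                 thresholds = list(row = tr, col = tc),
                 converged = !clamped, n = n), class = "bfid_corr")
}

#' Polyserial correlation between a continuous and an ordinal variable
#'
#' Two-step estimator: ordinal thresholds from the marginal proportions, the
#' continuous variable standardized by its sample moments, then
#' one-dimensional maximum likelihood over the latent correlation of the
#' conditional ordinal likelihood.
#'
#' @param x numeric vector (non-constant).
#' @param y ordinal codes (integer or factor, at least 2 observed
#'   categories).
#' @return a `bfid_corr` object with `type = "polyserial"`.
#' @export
polyserial <- function(x, y) {
  y <- as.integer(factor(y))
  if (length(unique(y)) < 2L) stop("y has a single observed category")
  if (stats::sd(x) == 0) stop("x is constant")
  z <- (x - mean(x)) / stats::sd(x)
  counts <- tabulate(y)
  tau <- thresholds_from_props(counts)
  upper <- c(tau, Inf)[y]
  lower <- c(-Inf, tau)[y]
  nll <- function(rho) {
    s <- sqrt(1 - rho^2)
    p <- stats::pnorm((upper - rho * z) / s) -
      stats::pnorm((lower - rho * z) / s)
    -sum(log(pmax(p, 1e-300)))
  }
  opt <- stats::optimize(nll, c(-1 + 1e-6, 1 - 1e-6), tol = 1e-8)
  value <- opt$minimum
  clamped <- abs(value) > 1 - 1e-5
  if (clamped) {
    value <- sign(value) * (1 - 1e-6)
    warning("polyserial estimate at the boundary; clamped")
  }
  structure(list(value = value, type = "polyserial",
                 thresholds = list(y = tau), converged = !clamped,
                 n = length(x)), class = "bfid_corr")
}

#' @export
print.bfid_corr <- function(x, ...) {
  cat(sprintf("<bfid_corr> %s = %.4f (n = %d)\n", x$type, x$value, x$n))
  invisible(x)
}

#' Mixed Pearson/polychoric/polyserial moment matrix from raw data
#'
#' Pairwise dispatch by declared scale type: Pearson covariances between
#' continuous pairs (variances on the diagonal), polyserial correlation times
#' the continuous SD for mixed pairs, polychoric correlations between ordinal
#' pairs (unit diagonal) — the moment metric that models with unit-variance
#' latent-response criteria are fitted to.
#'
#' @param data data.frame of raw observations.
#' @param types named character vector (`"continuous"` / `"ordinal"`) for
#'   every column used.
#' @return a `bfid_moments` object with `source = "raw"`.
#' @export
mixed_matrix <- function(data, types) {
  vars <- names(types)
  if (!all(vars %in% names(data)))
    stop("data lacks column(s): ",
         paste(setdiff(vars, names(data)), collapse = ", "))
  p <- length(vars)
  M <- matrix(0, p, p, dimnames = list(vars, vars))
  cont <- vars[types == "continuous"]
  if (length(cont)) {
    CV <- stats::cov(data[cont])
    M[cont, cont] <- CV
  }
  for (v in vars[types == "ordinal"]) M[v, v] <- 1
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i >= j) next
    vi <- vars[i]; vj <- vars[j]
    ti <- types[[vi]]; tj <- types[[vj]]
    val <- tryCatch({
      if (ti == "continuous" && tj == "continuous") {
        M[vi, vj]
      } else if (ti == "ordinal" && tj == "ordinal") {
        polychoric(table(data[[vi]], data[[vj]]))$value
      } else {
        xv <- if (ti == "continuous") vi else vj
        yv <- if (ti == "continuous") vj else vi
        polyserial(data[[xv]], data[[yv]])$value * stats::sd(data[[xv]])
      }
    }, error = function(e)
      stop("moment estimation failed for pair (", vi, ",", vj, "): ",
           conditionMessage(e)))
    M[vi, vj] <- M[vj, vi] <- val
  }
  sample_moments(M, n = nrow(data), types = types, source = "raw")
}
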