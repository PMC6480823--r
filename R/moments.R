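#' Assemble a sample moment matrix from a printed correlation/variance summary
#'
#' Published summaries of mixed continuous/ordinal data typically print
#' Pearson correlations among the continuous variables with their variances on
#' the diagonal, polyserial correlations between continuous variables and the
#' latent responses of ordinal variables, and polychoric correlations among
#' the ordinal variables.  This function turns such a table into the moment
#' matrix the models are fitted to: correlations between continuous pairs are
#' rescaled to covariances using the diagonal variances, rows of ordinal
#' (latent-response, unit-variance) variables are kept on the correlation
#' metric, and cross entries become correlation times the SD of the
#' continuous variable.
#'
#' @param tab square numeric matrix with dimnames; at least the lower triangle
#'   must be filled (upper-triangle entries may be `NA` or must mirror the
#'   lower triangle).  Diagonal entries of continuous variables are variances;
#'   ordinal diagonals may be `NA` or 1.
#' @param types named character vector mapping each variable to
#'   `"continuous"` or `"ordinal"`.
#' @param n sample size.
#' @return an object of class `bfid_moments` with elements `order`, `matrix`
#'   (full symmetric moment matrix), `n`, `types`, `source`.
#' @export
assemble_moments <- function(tab, types, n) {
  stopifnot(is_square(tab), !is.null(rownames(tab)))
  vars <- rownames(tab)
  if (!all(vars %in% names(types)))
    stop("missing scale type for: ",
         paste(setdiff(vars, names(types)), collapse = ", "))
  types <- match.arg(types[vars], c("continuous", "ordinal"),
                     several.ok = TRUE)
  names(types) <- vars
  p <- length(vars)
  ## symmetrize input, checking consistency where both triangles are given
  m <- tab
  for (i in seq_len(p)) for (j in seq_len(p)) {
    lo <- m[max(i, j), min(i, j)]; up <- tab[min(i, j), max(i, j)]
    if (i != j && !is.na(up) && !is.na(lo) && abs(up - lo) > 1e-10)
      stop("asymmetric input at (", vars[i], ",", vars[j], ")")
    m[i, j] <- lo
  }
  offs <- m[lower.tri(m)]
  if (any(abs(offs[!is.na(offs)]) > 1)) stop("|correlation| > 1 in input")
  sds <- numeric(p)
  for (i in seq_len(p)) {
    if (types[i] == "continuous") {
      if (is.na(m[i, i]) || m[i, i] <= 0)
        stop("missing or nonpositive variance for continuous variable ",
             vars[i])
      sds[i] <- sqrt(m[i, i])
    } else {
      if (!is.na(m[i, i]) && abs(m[i, i] - 1) > 1e-10)
        stop("latent-response variable ", vars[i],
             " must have (fixed) unit variance")
      m[i, i] <- 1
      sds[i] <- 1
    }
  }
  out <- m
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i != j) out[i, j] <- m[i, j] * sds[i] * sds[j]
  }
  structure(list(order = vars, matrix = out, n = n, types = types,
                 source = "assembled"),
            class = "bfid_moments")
}

#' Wrap an existing covariance matrix as sample moments
#'
#' Unlike [assemble_moments()], no rescaling is applied: `matrix` is taken to
#' already be on the moment metric (covariances for continuous variables,
#' unit-variance latent responses for ordinal ones).
#'
#' @param matrix full symmetric moment matrix with dimnames.
#' @param n sample size.
#' @param types optional named type vector; defaults to all continuous.
#' @param source provenance tag.
#' @return a `bfid_moments` object.
#' @export
sample_moments <- function(matrix, n, types = NULL, source = "raw") {
  stopifnot(is_square(matrix), !is.null(rownames(matrix)))
  vars <- rownames(matrix)
  if (is.null(types)) {
    types <- rep("continuous", length(vars)); names(types) <- vars
  }
  structure(list(order = vars, matrix = (matrix + t(matrix)) / 2, n = n,
                 types = types[vars], source = source),
            class = "bfid_moments")
}

#' @export
print.bfid_moments <- function(x, ...) {
  cat(sprintf("<bfid_moments> %d variables, n = %d (%s)\n",
              length(x$order), x$n, x$source))
  print(round(x$matrix, 3))
  invisible(x)
}

#' Write / read a moment matrix as CSV plus a JSON sidecar
#'
#' The CSV holds the lower triangle (row names in the first column, header row
#' of variable names); the sidecar records `n` and the scale type of each
#' variable.
#'
#' @param moments a `bfid_moments` object.
#' @param csv,meta file paths.
#' @export
write_moments <- function(moments, csv, meta) {
  m <- moments$matrix
  m[upper.tri(m)] <- NA
  df <- data.frame(var = rownames(m), m, check.names = FALSE)
  utils::write.csv(df, csv, row.names = FALSE, na = "")
  jsonlite::write_json(list(n = moments$n, types = as.list(moments$types),
                            source = moments$source),
                       meta, auto_unbox = TRUE, digits = NA)
}

#' @rdname write_moments
#' @return `read_moments()` returns a `bfid_moments` object.
#' @export
read_moments <- function(csv, meta) {
  df <- utils::read.csv(csv, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m[upper.tri(m)] <- t(m)[upper.tri(m)]  # mirror lower triangle
  info <- jsonlite::read_json(meta, simplifyVector = TRUE)
  sample_moments(m, n = info$n, types = unlist(info$types),
                 source = info$source %||% "raw")
}

## nonredundant moment index of a model: lower triangle, row-major, with
## criterion diagonal moments excluded (they are fixed at 1 by convention)
moment_index <- function(model) {
  p <- length(model$obs)
  prs <- vech_pairs(p)
  crit <- model$obs %in% model$criteria
  keep <- !(prs[, 1] == prs[, 2] & crit[prs[, 1]])
  prs <- prs[keep, , drop = FALSE]
  lab <- paste0(model$obs[prs[, 1]], "~", model$obs[prs[, 2]])
  list(pairs = prs, labels = lab)
}

## extract the nonredundant moment vector of a (model-ordered) matrix
moment_vector <- function(S, model, mi = moment_index(model)) {
  S[cbind(mi$pairs[, 1], mi$pairs[, 2])]
}

## reorder a bfid_moments matrix to the model's observed order
align_moments <- function(model, moments) {
  missing <- setdiff(model$obs, moments$order)
  if (length(missing))
    stop("moment matrix lacks variable(s): ", paste(missing, collapse = ", "))
  moments$matrix[model$obs, model$obs, drop = FALSE]
}

#' Model-implied moment matrix
#'
#' Computes the implied covariance matrix of the observed variables.  In
#' covariance-extension (and measurement) mode this is
#' \eqn{\Sigma = \Lambda \Phi \Lambda^\top + \Theta}, with criterion
#' latent-response variables carried inside \eqn{\Phi} at fixed unit variance.
#' In regression-extension mode the criterion block is composed through the
#' regression paths: \eqn{Cov(Y, C) = \Lambda \Phi \beta^\top}, the explained
#' criterion covariance is \eqn{\beta \Phi \beta^\top}, residual variances are
#' implicit (total criterion variance fixed at 1) and the residual covariance
#' is a free parameter.
#'
#' @param model a `bfid_model`.
#' @param theta free-parameter vector.
#' @return an object of class `bfid_implied`: list with `matrix`, `theta`,
#'   `model`.
#' @export
implied_covariance <- function(model, theta) {
  structure(list(matrix = implied_sigma(model, theta), theta = theta,
                 model = model), class = "bfid_implied")
}

## fast internal kernel returning just the matrix
implied_sigma <- function(model, theta) {
  m <- theta_unpack(model, theta)
  nC <- length(model$criteria)
  if (model$mode == "regression" && nC) {
    ind <- model$indicators
    P <- m$Phi; B <- m$Beta
    L <- m$Lambda[ind, , drop = FALSE]
    cross <- B %*% P                      # criteria x latents
    expl <- cross %*% t(B)                # explained criterion covariance
    Pcc <- expl + m$Psi
    diag(Pcc) <- 1                        # total latent-response variance
    Syy <- L %*% P %*% t(L) + m$Theta[ind, ind, drop = FALSE]
    Syc <- L %*% t(cross)
    S <- rbind(cbind(Syy, Syc), cbind(t(Syc), Pcc))
    dimnames(S) <- list(model$obs, model$obs)
  } else {
    S <- m$Lambda %*% m$Phi %*% t(m$Lambda) + m$Theta
  }
  (S + t(S)) / 2
}

## implicit criterion residual variances in regression mode
criterion_residual_var <- function(model, theta) {
  m <- theta_unpack(model, theta)
  expl <- m$Beta %*% m$Phi %*% t(m$Beta)
  v <- 1 - diag(expl)
  names(v) <- model$criteria
  v
}

#' Jacobian of the implied nonredundant moments
#'
#' Column \eqn{j} is the partial derivative of the nonredundant moment vector
#' with respect to free parameter \eqn{j}, by central finite differences with
#' relative step `h` (step `h * max(1, |theta_j|)`).  With
#' `analytic = TRUE`, columns of error-covariance and factor-covariance
#' parameters (covariance/measurement modes) are computed analytically
#' instead; the two routes agree to about `1e-6`.
#'
#' @param model a `bfid_model`.
#' @param theta parameter vector.
#' @param h relative finite-difference step.
#' @param analytic use analytic columns where available.
#' @return matrix of size (nonredundant moments) x (free parameters) with
#'   labeled dimnames.
#' @export
implied_jacobian <- function(model, theta, h = 1e-6, analytic = FALSE) {
  mi <- moment_index(model)
  J <- matrix(NA_real_, nrow(mi$pairs), model$n_free,
              dimnames = list(mi$labels, theta_labels(model)))
  ana <- rep(FALSE, model$n_free)
  if (analytic && model$mode != "regression") {
    m <- theta_unpack(model, theta)
    for (s in seq_len(model$n_free)) {
      mat <- model$par_table$matrix[s]
      if (!mat %in% c("factor_cov", "error_cov")) next
      dS <- matrix(0, length(model$obs), length(model$obs))
      if (mat == "factor_cov") {
        dP <- (model$idx$Phi == s) * 1
        dS <- m$Lambda %*% dP %*% t(m$Lambda)
      } else {
        dS <- (model$idx$Theta == s) * 1
      }
      J[, s] <- dS[cbind(mi$pairs[, 1], mi$pairs[, 2])]
      ana[s] <- TRUE
    }
  }
  for (s in which(!ana)) {
    hs <- h * max(1, abs(theta[s]))
    tp <- theta; tp[s] <- tp[s] + hs
    tm <- theta; tm[s] <- tm[s] - hs
    J[, s] <- (moment_vector(implied_sigma(model, tp), model, mi) -
                 moment_vector(implied_sigma(model, tm), model, mi)) / (2 * hs)
  }
  if (any(!is.finite(J))) stop("non-finite entries in implied-moment Jacobian")
  J
}
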