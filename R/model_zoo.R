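## Canonical variable layout of the bundled empirical example: three
## intelligence facets measured by odd/even test halves, two ordinal grades.
paper_facets <- function() list(NS = c("NS1", "NS2"), AN = c("AN1", "AN2"),
                                UN = c("UN1", "UN2"))
paper_criteria <- function() c("Math", "Eng")

#' Catalog of ready-made models for the bundled empirical example
#'
#' @return character vector of catalog keys accepted by
#'   [make_paper_model()].
#' @export
model_catalog <- function() c(
  "fig1a_equal",      # bifactor, equal loadings, no criteria (df 11)
  "fig1b_equal",      # + correlating criteria: NOT identified (deficiency 2)
  "fig1b_equal_sc0",  # specific-criterion covariances fixed 0 (df 21)
  "fig1b_equal_gc0",  # g-criterion covariances fixed 0 (df 17)
  "fig1b_free_g",     # free g loadings, correlating criteria (df 10)
  "fig1b_free_g_sc0", # df 16
  "fig1b_free_g_gc0", # df 12
  "fig1c",            # free-g bifactor, latent regression (df 10)
  "fig2a",            # first-order, no criteria (df 9)
  "fig2b",            # first-order + correlating criteria (df 15)
  "fig2c",            # first-order latent regression (df 15)
  "fig2d",            # = fig2c with composite-factor reformulation
  "fig3a",            # bifactor(S-1), no criteria (needs reference)
  "fig3b",            # bifactor(S-1) + correlating criteria (df 15)
  "fig3c")            # bifactor(S-1) latent regression (df 15)

#' Build a catalog model for the bundled empirical example
#'
#' Constructs the model corresponding to a catalog key (see
#' [model_catalog()]) over the standard variable layout `NS1, NS2, AN1, AN2,
#' UN1, UN2, Math, Eng`.  Bifactor(S-1) keys require a reference facet and
#' also accept suffixed keys such as `"fig3b_refAN"` or `"fig3c_refNS"`.
#'
#' @param name catalog key.
#' @param reference reference facet (`"NS"`, `"AN"`, or `"UN"`) for
#'   bifactor(S-1) keys.
#' @return a `bfid_model`.
#' @examples
#' make_paper_model("fig2b")$df        # 15
#' make_paper_model("fig3b", "AN")$df  # 15
#' @export
make_paper_model <- function(name, reference = NULL) {
  if (grepl("^fig3[abc]_ref", name)) {
    reference <- sub("^fig3[abc]_ref", "", name)
    name <- substr(name, 1, 5)
  }
  base <- list(name = name, facets = paper_facets(),
               criteria = paper_criteria())
  cfg <- switch(name,
    fig1a_equal = c(base, list(structure = "bifactor", mode = "measurement")),
    fig1b_equal = c(base, list(structure = "bifactor", mode = "covariance")),
    fig1b_equal_sc0 = c(base, list(structure = "bifactor",
      mode = "covariance", fix_zero = "specific~criteria")),
    fig1b_equal_gc0 = c(base, list(structure = "bifactor",
      mode = "covariance", fix_zero = "general~criteria")),
    fig1b_free_g = c(base, list(structure = "bifactor", mode = "covariance",
      general_loadings = "free")),
    fig1b_free_g_sc0 = c(base, list(structure = "bifactor",
      mode = "covariance", general_loadings = "free",
      fix_zero = "specific~criteria")),
    fig1b_free_g_gc0 = c(base, list(structure = "bifactor",
      mode = "covariance", general_loadings = "free",
      fix_zero = "general~criteria")),
    fig1c = c(base, list(structure = "bifactor", mode = "regression",
      general_loadings = "free")),
    fig2a = c(base, list(structure = "first_order", mode = "measurement")),
    fig2b = c(base, list(structure = "first_order", mode = "covariance")),
    fig2c = c(base, list(structure = "first_order", mode = "regression")),
    fig2d = c(base, list(structure = "first_order", mode = "regression")),
    fig3a = , fig3b = , fig3c = {
      if (is.null(reference))
        stop("bifactor(S-1) catalog keys require a reference facet")
      mode <- switch(name, fig3a = "measurement", fig3b = "covariance",
                     fig3c = "regression")
      c(base, list(structure = "bifactor_s1", mode = mode,
                   reference = reference))
    },
    stop("unknown catalog key: ", name))
  build_model(cfg)
}

#' Composite ability factor implied by a latent multiple regression
#'
#' Reformulates a fitted first-order latent regression for one criterion as a
#' composite factor: an exact linear combination of the facet factors whose
#' values are the criterion values predicted by the facets.  Its weights are
#' the regression coefficients and its correlation with the criterion equals
#' \eqn{\sqrt{b_s^\top R\, b_s} = \sqrt{R^2}}, which the function asserts.
#'
#' @param fit a converged regression-extension `bfid_fit`.
#' @param criterion criterion name.
#' @return an object of class `bfid_composite`: `criterion`, `weights`
#'   (unstandardized regression coefficients per facet factor),
#'   `std_weights`, `correlation` (composite-criterion correlation), and
#'   `degenerate` (`TRUE` when all weights are 0).
#' @export
composite_from_regression <- function(fit, criterion) {
  model <- fit$model
  if (model$mode != "regression")
    stop("composite factors are defined for regression-extension fits")
  if (!criterion %in% model$criteria) stop("unknown criterion: ", criterion)
  std <- standardize(fit)
  reg <- std$regression[std$regression$criterion == criterion, ]
  R <- std$factor_corr[reg$predictor, reg$predictor, drop = FALSE]
  bs <- reg$b_s
  corr <- sqrt(max(0, as.numeric(t(bs) %*% R %*% bs)))
  r2 <- std$r2[[criterion]]
  if (abs(corr - sqrt(max(0, r2))) > 1e-8)
    stop("composite-criterion correlation does not match sqrt(R^2)")
  degenerate <- all(abs(reg$b) < 1e-6)
  if (degenerate)
    warning("degenerate composite: all regression weights are zero")
  structure(list(criterion = criterion,
                 weights = stats::setNames(reg$b, reg$predictor),
                 std_weights = stats::setNames(bs, reg$predictor),
                 correlation = corr, degenerate = degenerate),
            class = "bfid_composite")
}

#' @export
print.bfid_composite <- function(x, ...) {
  cat(sprintf("<bfid_composite> %s: corr(composite, criterion) = %.3f%s\n",
              x$criterion, x$correlation,
              if (x$degenerate) " [degenerate]" else ""))
  print(round(x$weights, 3))
  invisible(x)
}

#' Part correlations of a fitted bifactor(S-1) model
#'
#' In a bifactor(S-1) model the non-reference factors are residualized with
#' respect to the reference facet, so their standardized correlations with a
#' criterion are part (semi-partial) correlations; the reference factor's
#' correlations are ordinary zero-order correlations.
#'
#' @param fit a converged covariance-extension bifactor(S-1) `bfid_fit`.
#' @param se compute delta-method standard errors and z statistics for the
#'   underlying covariance parameters (default `TRUE`).
#' @return data.frame with columns `factor`, `criterion`, `correlation`,
#'   `type` (`"zero-order"` or `"part"`), and when `se = TRUE` also `se_cov`,
#'   `z` for the unstandardized covariance.
#' @export
s1_part_correlations <- function(fit, se = TRUE) {
  model <- fit$model
  if (model$structure != "bifactor_s1" || model$mode != "covariance")
    stop("part correlations are defined for covariance-extension ",
         "bifactor(S-1) fits")
  std <- standardize(fit)
  ref <- model$factors$name[model$factors$kind == "reference"]
  out <- expand.grid(factor = model$fac, criterion = model$criteria,
                     stringsAsFactors = FALSE)
  out$correlation <- std$factor_corr[cbind(out$factor, out$criterion)]
  out$type <- ifelse(out$factor == ref, "zero-order", "part")
  if (se) {
    ses <- standard_errors(fit)
    key <- sprintf("phi[%s,%s]", out$factor, out$criterion)
    idx <- match(key, ses$label)
    out$se_cov <- ses$se[idx]
    out$z <- ses$z[idx]
  }
  out
}
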