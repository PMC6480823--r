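#' Build a latent-variable model from a declarative configuration
#'
#' Constructs a validated model object for one of the three supported model
#' families: a correlated first-order factor model (one factor per facet), a
#' bifactor model (orthogonal general factor plus one specific factor per
#' facet), or a bifactor(S-1) model (the factor of a chosen reference facet
#' replaces the general factor and the remaining specific factors may
#' correlate).  Each model may be extended with criterion variables, either by
#' free factor--criterion covariances (`mode = "covariance"`) or by a latent
#' multiple regression of the criteria on the factors
#' (`mode = "regression"`).  Criterion variables are treated as unit-variance
#' latent-response variables (the continuous variable underlying an ordinal
#' grade), so their diagonal moments are fixed at 1 and are not counted as
#' data.
#'
#' @param config a list with elements:
#' \describe{
#'   \item{structure}{one of `"first_order"`, `"bifactor"`, `"bifactor_s1"`.}
#'   \item{facets}{named list; each element is the character vector of
#'     indicator names belonging to that facet.}
#'   \item{criteria}{character vector of criterion (latent-response) variable
#'     names; may be empty.}
#'   \item{mode}{`"covariance"`, `"regression"`, or `"measurement"` (no
#'     criteria).  Defaults to `"covariance"` when criteria are present.}
#'   \item{reference}{facet name used as reference facet
#'     (`structure = "bifactor_s1"` only).}
#'   \item{facet_loadings}{`"fixed_one"` (all loadings fixed to 1, the
#'     default) or `"free"` (first indicator per facet fixed to 1, the rest
#'     free); first-order models only.}
#'   \item{general_loadings}{`"fixed_one"` (default) or `"free"` (first
#'     indicator fixed to 1); loadings on the general factor of a bifactor
#'     model.}
#'   \item{specific_cov}{logical; free covariance between the specific
#'     factors of a bifactor(S-1) model (default `TRUE`).}
#'   \item{fix_zero}{character vector of `"Factor~Criterion"` pairs whose
#'     covariance (or regression coefficient) is fixed to 0; the shortcuts
#'     `"specific~criteria"` and `"general~criteria"` expand to all such
#'     pairs.}
#' }
#' @return an object of class `bfid_model`.
#' @examples
#' m <- build_model(list(
#'   structure = "first_order",
#'   facets = list(NS = c("NS1", "NS2"), AN = c("AN1", "AN2"),
#'                 UN = c("UN1", "UN2")),
#'   criteria = c("Math", "Eng")))
#' m$n_free  # 19 free parameters, df = 34 - 19 = 15
#' @export
build_model <- function(config) {
  structure_kind <- match.arg(config$structure,
                              c("first_order", "bifactor", "bifactor_s1"))
  facets <- config$facets
  if (!is.list(facets) || length(facets) < 1L || is.null(names(facets)) ||
      any(!nzchar(names(facets))))
    stop("'facets' must be a named list of indicator name vectors")
  indicators <- unlist(facets, use.names = FALSE)
  if (length(indicators) < 2L) stop("need at least 2 indicators")
  criteria <- as.character(config$criteria %||% character())
  mode <- config$mode %||% if (length(criteria)) "covariance" else "measurement"
  mode <- match.arg(mode, c("covariance", "regression", "measurement"))
  if (mode == "measurement") criteria <- character()
  if (mode != "measurement" && !length(criteria))
    stop("modes with criterion extension require at least one criterion")
  all_names <- c(indicators, criteria)
  if (anyDuplicated(all_names))
    stop("variable names must be unique: ",
         paste(unique(all_names[duplicated(all_names)]), collapse = ", "))

  facet_of <- rep(names(facets), lengths(facets))
  names(facet_of) <- indicators

  variables <- data.frame(
    name = all_names,
    role = c(rep("indicator", length(indicators)),
             rep("criterion", length(criteria))),
    facet = c(facet_of, rep(NA_character_, length(criteria))),
    scale = c(rep("continuous", length(indicators)),
              rep("latent-response", length(criteria))),
    stringsAsFactors = FALSE)

  ## ---- factor layout per structure -------------------------------------
  cells <- list()
  add <- function(matrix, row, col, status, value = NA_real_,
                  label = NA_character_, start = NA_real_) {
    cells[[length(cells) + 1L]] <<- data.frame(
      matrix = matrix, row = row, col = col, status = status,
      value = value, label = label, start = start, stringsAsFactors = FALSE)
  }
  lab_load <- function(r, c) sprintf("lambda[%s,%s]", r, c)
  lab_phi <- function(r, c) if (r == c) sprintf("phi[%s]", r)
                            else sprintf("phi[%s,%s]", r, c)
  lab_theta <- function(r) sprintf("theta[%s]", r)

  if (structure_kind == "first_order") {
    fac_names <- names(facets)
    fac_kind <- rep("facet", length(fac_names))
    floapt <- match.arg(config$facet_loadings %||% "fixed_one",
                        c("fixed_one", "free"))
    for (k in seq_along(facets)) {
      ind <- facets[[k]]
      for (i in seq_along(ind)) {
        if (floapt == "fixed_one" || i == 1L)
          add("loading", ind[i], fac_names[k], "fixed", value = 1)
        else
          add("loading", ind[i], fac_names[k], "free",
              label = lab_load(ind[i], fac_names[k]), start = 1)
      }
    }
    ## free variances, free covariances between all facet factors
    for (a in seq_along(fac_names)) {
      add("factor_cov", fac_names[a], fac_names[a], "free",
          label = lab_phi(fac_names[a], fac_names[a]), start = 1)
      if (a > 1L) for (b in seq_len(a - 1L))
        add("factor_cov", fac_names[a], fac_names[b], "free",
            label = lab_phi(fac_names[a], fac_names[b]), start = 0)
    }
  } else if (structure_kind == "bifactor") {
    fac_names <- c("G", paste0(names(facets), "-S"))
    fac_kind <- c("general", rep("specific", length(facets)))
    gload <- match.arg(config$general_loadings %||% "fixed_one",
                       c("fixed_one", "free"))
    for (i in seq_along(indicators)) {
      if (gload == "fixed_one" || i == 1L)
        add("loading", indicators[i], "G", "fixed", value = 1)
      else
        add("loading", indicators[i], "G", "free",
            label = lab_load(indicators[i], "G"), start = 1)
    }
    for (k in seq_along(facets)) for (ind in facets[[k]])
      add("loading", ind, paste0(names(facets)[k], "-S"), "fixed", value = 1)
    for (a in seq_along(fac_names)) {
      add("factor_cov", fac_names[a], fac_names[a], "free",
          label = lab_phi(fac_names[a], fac_names[a]), start = 1)
      if (a > 1L) for (b in seq_len(a - 1L))
        add("factor_cov", fac_names[a], fac_names[b], "fixed", value = 0)
    }
  } else { ## bifactor_s1
    reference <- config$reference
    if (is.null(reference) || !reference %in% names(facets))
      stop("bifactor(S-1) models require 'reference', one of: ",
           paste(names(facets), collapse = ", "))
    nonref <- setdiff(names(facets), reference)
    fac_names <- c(reference, paste0(nonref, "-S"))
    fac_kind <- c("reference", rep("specific", length(nonref)))
    ## reference facet indicators: loadings fixed to 1 on the reference factor
    for (ind in facets[[reference]])
      add("loading", ind, reference, "fixed", value = 1)
    ## non-reference indicators: equal free loading (per facet) on the
    ## reference factor, loading 1 on their own specific factor
    for (f in nonref) {
      shared <- sprintf("lambda[%s,on_%s]", f, reference)
      for (ind in facets[[f]]) {
        add("loading", ind, reference, "equal", label = shared, start = 0.5)
        add("loading", ind, paste0(f, "-S"), "fixed", value = 1)
      }
    }
    for (a in seq_along(fac_names)) {
      add("factor_cov", fac_names[a], fac_names[a], "free",
          label = lab_phi(fac_names[a], fac_names[a]), start = 1)
    }
    ## reference factor orthogonal to specific factors; specific factors may
    ## correlate (distinguishing feature vs the classical bifactor model)
    spec_free <- isTRUE(config$specific_cov %||% TRUE)
    sfacs <- paste0(nonref, "-S")
    for (s in sfacs) add("factor_cov", s, reference, "fixed", value = 0)
    if (length(sfacs) > 1L)
      for (a in 2:length(sfacs)) for (b in seq_len(a - 1L)) {
        if (spec_free)
          add("factor_cov", sfacs[a], sfacs[b], "free",
              label = lab_phi(sfacs[a], sfacs[b]), start = 0)
        else
          add("factor_cov", sfacs[a], sfacs[b], "fixed", value = 0)
      }
  }

  ## ---- error variances --------------------------------------------------
  for (ind in indicators)
    add("error_cov", ind, ind, "free", label = lab_theta(ind), start = 1)

  ## ---- criterion extension ---------------------------------------------
  fix_zero <- expand_fix_zero(config$fix_zero %||% character(),
                              fac_names, fac_kind, criteria)
  if (length(criteria)) {
    if (mode == "covariance") {
      for (cr in criteria) {
        add("factor_cov", cr, cr, "fixed", value = 1) # latent response var
        for (f in fac_names) {
          if (paste0(f, "~", cr) %in% fix_zero)
            add("factor_cov", cr, f, "fixed", value = 0)
          else
            add("factor_cov", cr, f, "free",
                label = lab_phi(f, cr), start = 0)
        }
      }
      if (length(criteria) > 1L)
        for (a in 2:length(criteria)) for (b in seq_len(a - 1L))
          add("factor_cov", criteria[a], criteria[b], "free",
              label = lab_phi(criteria[b], criteria[a]), start = 0)
    } else { ## regression
      for (cr in criteria) for (f in fac_names) {
        if (paste0(f, "~", cr) %in% fix_zero)
          add("regression", cr, f, "fixed", value = 0)
        else
          add("regression", cr, f, "free",
              label = sprintf("beta[%s~%s]", cr, f), start = 0)
      }
      if (length(criteria) > 1L)
        for (a in 2:length(criteria)) for (b in seq_len(a - 1L))
          add("criterion_residual_cov", criteria[a], criteria[b], "free",
              label = sprintf("psi[%s,%s]", criteria[b], criteria[a]),
              start = 0)
    }
  }

  factors <- data.frame(
    name = fac_names, kind = fac_kind,
    scaling = rep("one-loading-fixed", length(fac_names)),
    stringsAsFactors = FALSE)
  if (mode == "covariance" && length(criteria))
    factors <- rbind(factors, data.frame(
      name = criteria, kind = "criterion-latent", scaling = "variance-fixed",
      stringsAsFactors = FALSE))

  cells <- do.call(rbind, cells)
  compile_model(variables, factors, cells, mode, structure_kind,
                facets = facets, reference = config$reference %||% NA_character_,
                name = config$name %||% NA_character_)
}

## expand "specific~criteria" / "general~criteria" shortcuts and validate
expand_fix_zero <- function(fix_zero, fac_names, fac_kind, criteria) {
  out <- character()
  for (fz in fix_zero) {
    if (fz == "specific~criteria") {
      out <- c(out, as.vector(outer(fac_names[fac_kind == "specific"],
                                    criteria, paste, sep = "~")))
    } else if (fz == "general~criteria") {
      out <- c(out, as.vector(outer(fac_names[fac_kind == "general"],
                                    criteria, paste, sep = "~")))
    } else {
      parts <- strsplit(fz, "~", fixed = TRUE)[[1]]
      if (length(parts) != 2L || !parts[1] %in% fac_names ||
          !parts[2] %in% criteria)
        stop("fix_zero entry '", fz, "' names an unknown factor or criterion")
      out <- c(out, fz)
    }
  }
  unique(out)
}

## turn the cell list into index/template matrices and a flat parameter map
compile_model <- function(variables, factors, cells, mode, structure_kind,
                          facets, reference, name) {
  indicators <- variables$name[variables$role == "indicator"]
  criteria <- variables$name[variables$role == "criterion"]
  obs <- c(indicators, criteria)
  lat <- if (mode == "covariance") c(factors$name[factors$kind != "criterion-latent"], criteria)
         else factors$name[factors$kind != "criterion-latent"]
  fac <- factors$name[factors$kind != "criterion-latent"]

  ## validate cells
  bad <- !cells$row %in% c(obs, lat) | !cells$col %in% c(obs, lat)
  if (any(bad))
    stop("unknown variable in cell(s): ",
         paste(unique(c(cells$row[bad], cells$col[bad])), collapse = ", "))
  if (any(cells$status == "fixed" & !is.finite(cells$value)))
    stop("fixed cells must carry a finite value")
  for (lb in unique(cells$label[!is.na(cells$label)])) {
    st <- cells$status[!is.na(cells$label) & cells$label == lb]
    if (any(st == "fixed"))
      stop("contradictory equality label '", lb, "': used on a fixed cell")
  }
  ## every indicator loads on >= 1 factor
  loaded <- unique(cells$row[cells$matrix == "loading"])
  if (!all(indicators %in% loaded))
    stop("indicator(s) without any loading: ",
         paste(setdiff(indicators, loaded), collapse = ", "))
  ## every factor carries exactly one scaling device in this dialect:
  ## either a fixed loading or a fixed variance
  for (f in fac) {
    has_fixed_load <- any(cells$matrix == "loading" & cells$col == f &
                            cells$status == "fixed" & cells$value != 0)
    if (!has_fixed_load)
      stop("factor without scaling (no fixed nonzero loading): ", f)
  }

  free_rows <- cells$status %in% c("free", "equal")
  labels <- unique(cells$label[free_rows])
  slot_of <- function(lb) match(lb, labels)

  nO <- length(obs); nL <- length(lat); nC <- length(criteria)
  zero_m <- function(nr, nc, rn, cn)
    matrix(0, nr, nc, dimnames = list(rn, cn))
  tmpl <- list(Lambda = zero_m(nO, nL, obs, lat),
               Phi = zero_m(nL, nL, lat, lat),
               Theta = zero_m(nO, nO, obs, obs))
  idx <- list(Lambda = zero_m(nO, nL, obs, lat),
              Phi = zero_m(nL, nL, lat, lat),
              Theta = zero_m(nO, nO, obs, obs))
  if (mode == "regression" && nC) {
    tmpl$Beta <- zero_m(nC, nL, criteria, lat)
    idx$Beta <- zero_m(nC, nL, criteria, lat)
    tmpl$Psi <- zero_m(nC, nC, criteria, criteria)
    idx$Psi <- zero_m(nC, nC, criteria, criteria)
  }
  if (mode == "covariance" && nC) {
    ## observed criterion = its latent response, exactly
    for (cr in criteria) tmpl$Lambda[cr, cr] <- 1
  }

  mat_key <- c(loading = "Lambda", factor_cov = "Phi", error_cov = "Theta",
               regression = "Beta", criterion_residual_cov = "Psi")
  for (r in seq_len(nrow(cells))) {
    mk <- mat_key[[cells$matrix[r]]]
    if (is.null(tmpl[[mk]]))
      stop("cell matrix '", cells$matrix[r], "' not available in mode ", mode)
    i <- cells$row[r]; j <- cells$col[r]
    sym <- mk %in% c("Phi", "Theta", "Psi")
    if (free_rows[r]) {
      s <- slot_of(cells$label[r])
      idx[[mk]][i, j] <- s
      if (sym) idx[[mk]][j, i] <- s
    } else {
      tmpl[[mk]][i, j] <- cells$value[r]
      if (sym) tmpl[[mk]][j, i] <- cells$value[r]
    }
  }

  ## flat parameter table: one row per slot, first occurrence wins for start
  first <- !duplicated(cells$label) & free_rows
  par_table <- cells[first, c("label", "matrix", "row", "col", "start")]
  par_table <- par_table[order(match(par_table$label, labels)), ]
  rownames(par_table) <- NULL

  n_free <- length(labels)
  n_moments <- nO * (nO + 1L) / 2L - nC  # criterion diagonals fixed at 1
  model <- structure(list(
    name = name, variables = variables, factors = factors, cells = cells,
    mode = mode, structure = structure_kind, facets = facets,
    reference = reference, obs = obs, lat = lat, fac = fac,
    criteria = criteria, indicators = indicators,
    tmpl = tmpl, idx = idx, par_table = par_table,
    n_free = n_free, n_moments = n_moments, df = n_moments - n_free),
    class = "bfid_model")
  model
}

#' @export
print.bfid_model <- function(x, ...) {
  cat(sprintf("<bfid_model> %s (%s mode)\n",
              x$structure, x$mode))
  cat(sprintf("  observed: %d indicators + %d criteria; latent: %s\n",
              length(x$indicators), length(x$criteria),
              paste(x$lat, collapse = ", ")))
  cat(sprintf("  free parameters: %d; nonredundant moments: %d; df: %d\n",
              x$n_free, x$n_moments, x$df))
  invisible(x)
}

#' Flat parameter vector of a model
#'
#' `theta_pack()` maps filled model matrices (or the model's start values) to
#' the flat vector of free parameters; `theta_unpack()` performs the inverse
#' mapping.  Equality-constrained cells share a single slot.  The round trip
#' `theta_pack(model, theta_unpack(model, theta))` is exact.
#'
#' @param model a `bfid_model`.
#' @param matrices optional named list of filled matrices (`Lambda`, `Phi`,
#'   `Theta`, and in regression mode `Beta`, `Psi`) from which free values are
#'   read; when omitted, start values are returned.
#' @return a named numeric vector of length `model$n_free`.
#' @export
theta_pack <- function(model, matrices = NULL) {
  if (is.null(matrices)) {
    theta <- model$par_table$start
    names(theta) <- model$par_table$label
    return(theta)
  }
  theta <- numeric(model$n_free)
  for (mk in names(model$idx)) {
    ii <- model$idx[[mk]] > 0
    if (any(ii)) theta[model$idx[[mk]][ii]] <- matrices[[mk]][ii]
  }
  names(theta) <- model$par_table$label
  theta
}

#' @rdname theta_pack
#' @param theta numeric vector of length `model$n_free`.
#' @return for `theta_unpack()`, a named list of filled matrices.
#' @export
theta_unpack <- function(model, theta) {
  if (length(theta) != model$n_free)
    stop("theta has length ", length(theta), ", expected ", model$n_free)
  out <- model$tmpl
  for (mk in names(out)) {
    ii <- model$idx[[mk]] > 0
    if (any(ii)) out[[mk]][ii] <- theta[model$idx[[mk]][ii]]
  }
  out
}

#' Parameter labels of a model's free parameters
#' @param model a `bfid_model`.
#' @return character vector of labels in flat-vector order.
#' @export
theta_labels <- function(model) model$par_table$label

#' Read a model configuration from a JSON file
#'
#' @param path path to a JSON file holding a configuration understood by
#'   [build_model()].
#' @return a `bfid_model`.
#' @export
read_model_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(cfg$facets)) cfg$facets <- as.list(cfg$facets)
  build_model(cfg)
}
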