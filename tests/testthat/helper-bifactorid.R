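## shared fixtures: the bundled moment matrix is loaded once per session,
## and fits of catalog models are memoized because several test files (and
## the acceptance suite) reuse them

t1_env <- new.env(parent = emptyenv())

t1_fixture <- function() {
  if (is.null(t1_env$t1)) t1_env$t1 <- table1_moments()
  t1_env$t1
}

fit_fixture <- function(key, reference = NULL) {
  id <- paste0(key, "_", reference %||% "")
  if (is.null(t1_env[[id]]))
    t1_env[[id]] <- suppressWarnings(
      fit_model(make_paper_model(key, reference = reference), t1_fixture()))
  t1_env[[id]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## tiny toy: one factor, two indicators, loadings fixed to 1
toy_single_factor <- function(n_ind = 2L, facet_loadings = "fixed_one") {
  build_model(list(structure = "first_order",
                   facets = list(F1 = paste0("y", seq_len(n_ind))),
                   facet_loadings = facet_loadings))
}

paper_config <- function(...) {
  utils::modifyList(list(structure = "first_order",
                         facets = list(NS = c("NS1", "NS2"),
                                       AN = c("AN1", "AN2"),
                                       UN = c("UN1", "UN2")),
                         criteria = c("Math", "Eng")),
                    list(...))
}
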