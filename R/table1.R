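#' Bundled moment matrix of the empirical intelligence-facet example
#'
#' The printed summary the package's worked example is based on: Pearson
#' correlations among six intelligence test halves (number series, verbal
#' analogies, unfolding; variances on the diagonal), polyserial correlations
#' of the test halves with the latent responses of two ordinal school grades
#' (mathematics, English), and the polychoric correlation between the grades;
#' n = 219.  The correlations are assembled to the covariance/correlation
#' hybrid moment metric via [assemble_moments()].
#'
#' @return a `bfid_moments` object over
#'   `NS1, NS2, AN1, AN2, UN1, UN2, Math, Eng`.
#' @export
table1_moments <- function() {
  csv <- system.file("extdata", "table1_lower.csv", package = "bifactorid",
                     mustWork = TRUE)
  meta <- system.file("extdata", "table1_meta.json", package = "bifactorid",
                      mustWork = TRUE)
  df <- utils::read.csv(csv, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  info <- jsonlite::read_json(meta, simplifyVector = TRUE)
  assemble_moments(m, types = unlist(info$types), n = info$n)
}

#' Marginal category proportions of the bundled ordinal grades
#'
#' @return named list of proportion vectors (five grade categories each) for
#'   `Math` and `Eng`, renormalized to sum to one.
#' @export
grade_proportions <- function() {
  meta <- system.file("extdata", "table1_meta.json", package = "bifactorid",
                      mustWork = TRUE)
  info <- jsonlite::read_json(meta, simplifyVector = TRUE)
  lapply(info$grade_proportions, function(p) p / sum(p))
}
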