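test_that("assemble_moments rescales by the stated rule", {
  t1 <- t1_fixture()
  ## continuous pair: correlation times both SDs
  expect_equal(t1$matrix["NS2", "NS1"], 0.787 * sqrt(4.456 * 4.487))
  ## ordinal pair stays on the correlation metric
  expect_equal(t1$matrix["Eng", "Math"], 0.469)
  expect_equal(t1$matrix["Math", "Math"], 1)
  ## mixed pair: correlation times the continuous SD
  expect_equal(t1$matrix["Math", "NS1"], 0.349 * sqrt(4.456))
  expect_true(isSymmetric(t1$matrix))
  expect_equal(t1$n, 219L)
})

test_that("identity correlations with unit variances assemble to identity", {
  m <- diag(3)
  dimnames(m) <- list(c("a", "b", "c"), c("a", "b", "c"))
  types <- c(a = "continuous", b = "continuous", c = "ordinal")
  out <- assemble_moments(m, types, n = 100)
  expect_equal(out$matrix, m)
})

test_that("assemble_moments rejects malformed input", {
  m <- matrix(c(1, 0.5, 0.5, NA), 2, 2,
              dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(assemble_moments(m, c(a = "continuous", b = "continuous"),
                                n = 10), "missing or nonpositive variance")
  m2 <- matrix(c(1, 1.2, 1.2, 1), 2, 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(assemble_moments(m2, c(a = "continuous", b = "continuous"),
                                n = 10), "> 1")
  m3 <- matrix(c(1, 0.2, 0.5, 1), 2, 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(assemble_moments(m3, c(a = "continuous", b = "continuous"),
                                n = 10), "asymmetric")
})

test_that("moments CSV round-trips through write/read", {
  t1 <- t1_fixture()
  csv <- withr::local_tempfile(fileext = ".csv")
  meta <- withr::local_tempfile(fileext = ".json")
  write_moments(t1, csv, meta)
  back <- read_moments(csv, meta)
  expect_equal(back$matrix, t1$matrix)
  expect_equal(back$n, t1$n)
  expect_equal(back$types, t1$types)
})

test_that("implied covariance follows the loading decomposition", {
  mb <- build_model(paper_config(structure = "bifactor"))
  th <- theta_pack(mb)
  ## all factor variances 0, criterion covariances 0 -> diagonal of errors
  th[] <- 0
  th[grepl("^theta", names(th))] <- seq(0.5, 3, length.out = 6)
  ## criterion latent variances stay fixed at 1
  S <- implied_covariance(mb, th)$matrix
  expect_equal(diag(S)[1:6], unname(th[grepl("^theta", names(th))]),
               ignore_attr = TRUE)
  expect_equal(S[lower.tri(S)][abs(S[lower.tri(S)]) > 0], numeric(0))

  ## equal loadings: Cov(Y_ik, C) = Cov(G,C) + Cov(S_k,C) for every i
  set.seed(5)
  th2 <- theta_pack(mb)
  th2[grepl("^phi\\[.*(Math|Eng)\\]", names(th2))] <- stats::runif(9, -0.2, 0.2)
  S2 <- implied_covariance(mb, th2)$matrix
  for (facet in c("NS", "AN", "UN")) for (cr in c("Math", "Eng")) {
    want <- th2[sprintf("phi[G,%s]", cr)] + th2[sprintf("phi[%s-S,%s]", facet, cr)]
    expect_equal(unname(S2[paste0(facet, "1"), cr]), unname(want))
    expect_equal(unname(S2[paste0(facet, "2"), cr]), unname(want))
  }
})

test_that("regression and covariance parameterizations imply the same moments", {
  ## map a regression-mode parameter vector to its covariance-mode image and
  ## compare implied matrices
  mreg <- build_model(paper_config(mode = "regression"))
  mcov <- build_model(paper_config(mode = "covariance"))
  set.seed(11)
  th <- theta_pack(mreg)
  th[grepl("^phi\\[(NS|AN|UN)\\]$", names(th))] <- stats::runif(3, 1, 3)
  th[grepl("^phi\\[.*,.*\\]$", names(th))] <- stats::runif(3, 0.2, 0.8)
  th[grepl("^theta", names(th))] <- stats::runif(6, 0.5, 2)
  th[grepl("^beta", names(th))] <- stats::runif(6, -0.2, 0.2)
  th[grepl("^psi", names(th))] <- 0.15
  mats <- theta_unpack(mreg, th)
  cross <- mats$Beta %*% mats$Phi
  expl <- cross %*% t(mats$Beta)
  thc <- theta_pack(mcov)
  thc[names(th)[!grepl("beta|psi", names(th))]] <-
    th[!grepl("beta|psi", names(th))]
  for (cr in c("Math", "Eng")) for (f in c("NS", "AN", "UN"))
    thc[sprintf("phi[%s,%s]", f, cr)] <- cross[cr, f]
  thc["phi[Math,Eng]"] <- expl["Math", "Eng"] + th["psi[Math,Eng]"]
  expect_equal(implied_covariance(mreg, th)$matrix,
               implied_covariance(mcov, thc)$matrix, tolerance = 1e-12)
})

test_that("Jacobian columns match analytic structure and finite differences", {
  mb <- build_model(paper_config(structure = "bifactor"))
  set.seed(2)
  th <- theta_pack(mb) + stats::runif(mb$n_free, 0.05, 0.3)
  J <- implied_jacobian(mb, th)
  Ja <- implied_jacobian(mb, th, analytic = TRUE)
  expect_lt(max(abs(J - Ja)), 1e-6)

  labs <- rownames(J)
  ## error-variance column: unit vector on that diagonal moment
  jcol <- J[, "theta[AN1]"]
  expect_equal(unname(jcol[labs == "AN1~AN1"]), 1, tolerance = 1e-8)
  expect_lt(max(abs(jcol[labs != "AN1~AN1"])), 1e-8)

  ## Cov(G,Math) column: ones at the six indicator-criterion moments
  gcol <- J[, "phi[G,Math]"]
  ycm <- labs %in% paste0("Math~", c("NS1", "NS2", "AN1", "AN2", "UN1", "UN2"))
  expect_equal(unname(gcol[ycm]), rep(1, 6), tolerance = 1e-7)
  expect_lt(max(abs(gcol[!ycm])), 1e-7)

  ## sum rule: the Cov(G,C) column equals the sum of the Cov(S_k,C) columns
  ## on the indicator-criterion moments
  ssum <- J[, "phi[NS-S,Math]"] + J[, "phi[AN-S,Math]"] + J[, "phi[UN-S,Math]"]
  expect_equal(unname(gcol[ycm]), unname(ssum[ycm]), tolerance = 1e-7)
})
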