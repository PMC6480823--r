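test_that("optimizer reproduces the closed-form single-factor solution", {
  ## with both loadings fixed to 1: factor variance = Cov(y1, y2),
  ## error variances = Var(y_i) - Cov(y1, y2)
  toy <- toy_single_factor()
  S <- matrix(c(2.5, 1.1, 1.1, 3.2), 2, 2,
              dimnames = list(c("y1", "y2"), c("y1", "y2")))
  ft <- fit_model(toy, sample_moments(S, n = 200))
  expect_true(ft$converged)
  expect_equal(unname(ft$theta["phi[F1]"]), 1.1, tolerance = 1e-8)
  expect_equal(unname(ft$theta["theta[y1]"]), 2.5 - 1.1, tolerance = 1e-8)
  expect_equal(unname(ft$theta["theta[y2]"]), 3.2 - 1.1, tolerance = 1e-8)
  expect_equal(ft$discrepancy, 0, tolerance = 1e-12)
})

test_that("fitting a model to its own implied moments recovers theta", {
  for (key in c("fig2b", "fig2c")) {
    m <- make_paper_model(key)
    set.seed(23)
    th0 <- theta_pack(m)
    th0[grepl("^phi\\[(NS|AN|UN)\\]$", names(th0))] <- stats::runif(3, 1, 4)
    th0[grepl("^phi\\[(NS|AN|UN),(NS|AN|UN)", names(th0))] <- 0.8
    th0[grepl("^theta", names(th0))] <- stats::runif(6, 0.5, 2)
    th0[grepl("^phi\\[.*(Math|Eng)\\]|^beta|^psi", names(th0))] <- 0.2
    S0 <- implied_covariance(m, th0)$matrix
    ft <- fit_model(m, sample_moments(S0, n = 219,
                                      types = t1_fixture()$types))
    expect_lt(ft$discrepancy, 1e-12)
    expect_equal(unname(ft$theta), unname(th0), tolerance = 1e-5)
  }
})

test_that("ULS fit of the first-order extended model tracks the published one", {
  ft <- fit_fixture("fig2b")
  expect_true(ft$converged)
  expect_equal(ft$df, 15L)
  std <- standardize(ft)
  fc <- std$factor_corr
  ## published: 0.394/0.400/0.349 with Math, 0.242/0.304/0.142 with Eng
  expect_equal(unname(fc["NS", "Math"]), 0.394, tolerance = 0.01)
  expect_equal(unname(fc["AN", "Math"]), 0.400, tolerance = 0.01)
  expect_equal(unname(fc["UN", "Math"]), 0.349, tolerance = 0.01)
  expect_equal(unname(fc["AN", "Eng"]), 0.304, tolerance = 0.01)
  ## standardized loadings 0.889/0.886/0.807/0.851/0.844/0.815
  expect_equal(std$loadings$std, c(0.889, 0.886, 0.807, 0.851, 0.844, 0.815),
               tolerance = 0.01)
  ## reliabilities are 1 minus standardized residual variances
  expect_equal(unname(std$reliability),
               1 - unname(diag(theta_unpack(ft$model, ft$theta)$Theta)[1:6] /
                            diag(ft$implied)[1:6]))
  ## implied indicator correlation equals the standardized path product
  ## (0.889 * 0.464 * 0.807 ~= 0.333)
  R <- stats::cov2cor(ft$implied)
  expect_equal(unname(R["NS1", "AN1"]),
               std$loadings$std[1] * fc["NS", "AN"] * std$loadings$std[3],
               ignore_attr = TRUE, tolerance = 1e-10)
  expect_equal(unname(R["NS1", "AN1"]), 0.333, tolerance = 0.01)
})

test_that("standardization identities hold for the regression extension", {
  ft <- fit_fixture("fig2c")
  std <- standardize(ft)
  ## b_s = b * SD(predictor) (criterion SD is 1 by convention)
  expect_equal(std$regression$b_s,
               std$regression$b * unname(std$factor_sd[std$regression$predictor]))
  ## R^2 = b_s' Corr(predictors) b_s
  for (cr in c("Math", "Eng")) {
    bs <- std$regression$b_s[std$regression$criterion == cr]
    pred <- std$regression$predictor[std$regression$criterion == cr]
    R <- std$factor_corr[pred, pred]
    expect_equal(unname(std$r2[cr]), as.numeric(t(bs) %*% R %*% bs),
                 ignore_attr = TRUE, tolerance = 1e-10)
  }
  ## published: b(AN -> Math) = 0.140, b_s = 0.239
  b <- std$regression[std$regression$criterion == "Math" &
                        std$regression$predictor == "AN", ]
  expect_equal(b$b, 0.140, tolerance = 0.01)
  expect_equal(b$b_s, 0.239, tolerance = 0.01)
  ## rsquared() errors for covariance-extension fits
  expect_error(rsquared(fit_fixture("fig2b")), "regression-extension")
})

test_that("degenerate standardization inputs raise errors", {
  toy <- toy_single_factor()
  S <- matrix(c(1, -0.2, -0.2, 1), 2, 2,
              dimnames = list(c("y1", "y2"), c("y1", "y2")))
  ft <- suppressWarnings(fit_model(toy, sample_moments(S, n = 100)))
  ## negative factor variance estimate: Heywood warning at fit time,
  ## standardization refuses to divide by it
  expect_warning(fit_model(toy, sample_moments(S, n = 100)), "Heywood")
  expect_error(standardize(ft), "nonpositive latent variance")
})

test_that("regression and covariance extensions reach the same fit", {
  expect_equal(fit_fixture("fig2c")$discrepancy,
               fit_fixture("fig2b")$discrepancy, tolerance = 1e-8)
  expect_equal(fit_fixture("fig1c")$discrepancy,
               fit_fixture("fig1b_free_g")$discrepancy, tolerance = 1e-8)
  ## and the implied moment matrices agree
  expect_equal(fit_fixture("fig2c")$implied, fit_fixture("fig2b")$implied,
               tolerance = 1e-5)
})

test_that("standard errors reproduce the published significance pattern", {
  ## free-loading extended bifactor: no factor-criterion parameter significant
  se <- standard_errors(fit_fixture("fig1b_free_g"))
  fc <- grepl("^phi\\[(G|NS-S|AN-S|UN-S),(Math|Eng)\\]", se$label)
  expect_equal(sum(fc), 8L)
  expect_true(all(abs(se$z[fc]) < 1.96))
  ## fixing the specific-criterion covariances to zero more than halves the
  ## SE of the g-Math covariance and makes it significant
  se2 <- standard_errors(fit_fixture("fig1b_free_g_sc0"))
  expect_lt(se2$se[se2$label == "phi[G,Math]"],
            0.5 * se$se[se$label == "phi[G,Math]"])
  expect_gt(abs(se2$z[se2$label == "phi[G,Math]"]), 1.96)
  expect_gt(abs(se2$z[se2$label == "phi[G,Eng]"]), 1.96)
  ## the nonidentified equal-loadings extension has no standard errors
  expect_error(standard_errors(fit_fixture("fig1b_equal")),
               "not locally identified")
})

test_that("DWLS and ML estimators run and agree closely on Table 1", {
  t1 <- t1_fixture()
  m <- make_paper_model("fig2b")
  uls <- fit_fixture("fig2b")
  dwls <- fit_model(m, t1, estimator = "DWLS")
  expect_true(dwls$converged)
  expect_equal(unname(dwls$theta), unname(uls$theta), tolerance = 0.05)
  ml <- fit_model(m, t1, estimator = "ML")
  expect_equal(unname(ml$theta), unname(uls$theta), tolerance = 0.05)
})
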