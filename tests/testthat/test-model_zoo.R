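test_that("catalog keys build, with reference-facet handling", {
  for (k in setdiff(model_catalog(), c("fig3a", "fig3b", "fig3c")))
    expect_s3_class(make_paper_model(k), "bfid_model")
  expect_error(make_paper_model("fig3b"), "reference facet")
  expect_error(make_paper_model("nope"), "unknown catalog key")
  ## suffixed reference keys
  m <- make_paper_model("fig3c_refNS")
  expect_equal(m$reference, "NS")
  expect_equal(m$df, 15L)
})

test_that("bifactor(S-1) reproduces the first-order fit exactly", {
  fb <- fit_fixture("fig2b")
  f3 <- fit_fixture("fig3b", "AN")
  expect_equal(f3$discrepancy, fb$discrepancy, tolerance = 1e-8)
  expect_equal(f3$implied, fb$implied, tolerance = 1e-6)
  ## swapping the reference facet changes labels, not fit, df, or R^2
  f3ns <- fit_fixture("fig3b", "NS")
  expect_equal(f3ns$discrepancy, f3$discrepancy, tolerance = 1e-8)
  expect_equal(f3ns$df, f3$df)
  expect_equal(unname(rsquared(fit_fixture("fig3c", "NS"))),
               unname(rsquared(fit_fixture("fig3c", "AN"))),
               tolerance = 1e-6)
})

test_that("part correlations carry the published structure", {
  pc <- s1_part_correlations(fit_fixture("fig3b", "AN"))
  expect_setequal(pc$type[pc$factor == "AN"], "zero-order")
  expect_setequal(pc$type[pc$factor != "AN"], "part")
  ## reference-criterion correlations equal the first-order ones
  std <- standardize(fit_fixture("fig2b"))
  for (cr in c("Math", "Eng"))
    expect_equal(pc$correlation[pc$factor == "AN" & pc$criterion == cr],
                 unname(std$factor_corr["AN", cr]), tolerance = 1e-6)
  ## published: NS-S and UN-S not significant for English
  expect_true(all(abs(pc$z[pc$criterion == "Eng" & pc$type == "part"]) < 1.96))
  expect_true(all(abs(pc$z[pc$criterion == "Math"]) > 1.96))
  expect_error(s1_part_correlations(fit_fixture("fig2b")), "bifactor\\(S-1\\)")
})

test_that("part correlations vanish under an orthogonal null population", {
  ## population where the criteria correlate with the reference factor only:
  ## the residualized facets carry no criterion association
  m <- build_model(paper_config(structure = "bifactor_s1", reference = "AN"))
  th <- theta_pack(m)
  th[grepl("^phi\\[(AN|NS-S|UN-S)\\]$", names(th))] <- c(2, 1.5, 1.8)
  th[grepl("^theta", names(th))] <- 1
  th["lambda[NS,on_AN]"] <- 0.5
  th["lambda[UN,on_AN]"] <- 0.4
  th[grepl("^phi\\[AN,(Math|Eng)\\]", names(th))] <- 0.4
  th[grepl("^phi\\[(NS|UN)-S,(Math|Eng)\\]", names(th))] <- 0
  th["phi[Math,Eng]"] <- 0.3
  S0 <- implied_covariance(m, th)$matrix
  ft <- fit_model(m, sample_moments(S0, n = 1000, types = t1_fixture()$types))
  pc <- s1_part_correlations(ft, se = FALSE)
  expect_equal(pc$correlation[pc$type == "part"], rep(0, 4), tolerance = 1e-6)
})

test_that("S-1 regression coefficients relate to the first-order ones as claimed", {
  s1 <- standardize(fit_fixture("fig3c", "AN"))$regression
  fo <- standardize(fit_fixture("fig2c"))$regression
  ## non-reference coefficients equal the first-order multiple-regression ones
  for (cr in c("Math", "Eng")) for (f in c("NS", "UN"))
    expect_equal(s1$b[s1$criterion == cr & s1$predictor == paste0(f, "-S")],
                 fo$b[fo$criterion == cr & fo$predictor == f],
                 tolerance = 1e-4)
  ## the reference coefficient equals the one-facet simple regression
  simple <- build_model(list(structure = "first_order",
                             facets = list(AN = c("AN1", "AN2")),
                             criteria = c("Math", "Eng"),
                             mode = "regression"))
  fts <- fit_model(simple, t1_fixture())
  bs <- standardize(fts)$regression
  for (cr in c("Math", "Eng"))
    expect_equal(s1$b[s1$criterion == cr & s1$predictor == "AN"],
                 bs$b[bs$criterion == cr & bs$predictor == "AN"],
                 tolerance = 0.01)
})

test_that("composite factors reformulate the multiple regression", {
  ft <- fit_fixture("fig2c")
  co <- composite_from_regression(ft, "Math")
  expect_equal(co$correlation, sqrt(rsquared(ft)[["Math"]]), tolerance = 1e-10)
  expect_equal(co$correlation, sqrt(0.233), tolerance = 0.01)
  ## weights are the regression coefficients
  reg <- standardize(ft)$regression
  expect_equal(unname(co$weights),
               reg$b[reg$criterion == "Math"][match(names(co$weights),
                 reg$predictor[reg$criterion == "Math"])])
  ## the English composite is dominated by the verbal-analogies weight
  se <- standard_errors(ft)
  zE <- se$z[grepl("^beta\\[Eng", se$label)]
  names(zE) <- sub("beta\\[Eng~(.*)\\]", "\\1", se$label[grepl("^beta\\[Eng", se$label)])
  expect_gt(abs(zE[["AN"]]), 1.96)
  expect_true(all(abs(zE[c("NS", "UN")]) < 1.96))
  expect_error(composite_from_regression(fit_fixture("fig2b"), "Math"),
               "regression-extension")
  expect_error(composite_from_regression(ft, "History"), "unknown criterion")
})

test_that("an all-zero regression yields a degenerate composite", {
  m <- build_model(paper_config(mode = "regression"))
  th <- theta_pack(m)
  th[grepl("^phi\\[(NS|AN|UN)\\]$", names(th))] <- 2
  th[grepl("^theta", names(th))] <- 1
  S0 <- implied_covariance(m, th)$matrix
  ft <- fit_model(m, sample_moments(S0, n = 500, types = t1_fixture()$types))
  expect_warning(co <- composite_from_regression(ft, "Math"), "degenerate")
  expect_equal(co$correlation, 0, tolerance = 1e-5)
})
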