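cb11 <- atr_codebook()

test_that("IPM spec builder: masks, counts, and validation", {
  s222 <- build_ipm_spec(cb11, 2, 2, 2)
  expect_equal(n_free_params(s222), 85) # 3 x (22 - 1 echelon zero) + 11 + 11
  expect_equal(n_free_params(build_ipm_spec(cb11, 1, 1, 1)), 55)
  expect_equal(n_free_params(build_ipm_spec(cb11, 1, 0, 1)), 44)
  # by-class pattern: 3 prescription vs 8 illicit loadings per factor pair
  scls <- build_ipm_spec(cb11, 2, 2, 2, pattern = "by_class_tag")
  expect_equal(colSums(scls$mask_a), c(3, 8))
  expect_equal(n_free_params(scls), 3 * 11 + 22)
  expect_error(build_ipm_spec(cb11, 1, 1, 1, pattern = "by_class_tag"),
    "requires a factor count of 2")
  expect_error(build_ipm_spec(cb11, 1, 0, 1, drops = list(specific_e = "pom")),
    "specific E")
  expect_error(build_ipm_spec(cb11, 3, 0, 1), "0, 1, or 2")
  # general count for a single-factor model: 3p general + 2p specifics
  expect_equal(n_free_params(build_ipm_spec(h_codebook3(), 1, 1, 1)), 3 * 3 + 2 * 3)
})

test_that("reduced specs drop the right parameters", {
  illicit <- cb11$name[cb11$class_tag == "illicit"]
  rx <- cb11$name[cb11$class_tag == "prescription"]
  red <- build_ipm_spec(cb11, 1, 0, 1, drops = list(
    general_e = "cannabis",
    specific_a = c("stimulant_rx", illicit),
    specific_c = c(rx, "heroin", "cocaine", "hallucinogen", "dissociative")
  ))
  expect_equal(n_free_params(red), 27) # 44 - 17
  expect_setequal(
    red$par_info$name[red$par_info$block == "sa"],
    c("as_pom", "as_sedative_rx")
  )
  full <- build_ipm_spec(cb11, 1, 0, 1)
  expect_length(setdiff(full$par_info$name, red$par_info$name), 17)
})

test_that("CPM spec builder and parameter count", {
  sc <- build_cpm_spec(cb11)
  expect_equal(n_free_params(sc), 11 + 2 + 11 + 11)
  red <- build_cpm_spec(cb11, drops = list(
    specific_a = c("heroin", "cocaine", "stimulant_illicit",
      "hallucinogen", "solvent", "dissociative"),
    specific_c = c("pom", "stimulant_rx", "sedative_rx", "cannabis", "inhalant")
  ))
  expect_equal(n_free_params(sc) - n_free_params(red), 11)
})

test_that("expected correlations reproduce univariate ACE algebra", {
  spec <- univariate_ace_spec(codebook("pom", class_tag = "prescription"))
  th <- setNames(c(sqrt(.37), sqrt(.10)), spec$par_info$name)
  mz <- expected_correlation_matrix(spec, th, "MZ")
  dz <- expected_correlation_matrix(spec, th, "DZ")
  expect_equal(mz[1, 2], 0.47)
  expect_equal(dz[1, 2], 0.5 * .37 + .10)
  expect_equal(diag(mz), setNames(rep(1, 2), colnames(mz)))
})

test_that("specific-only model has null cross-trait structure", {
  cb <- h_codebook3()
  spec <- build_ipm_spec(cb, 0, 0, 0)
  th <- setNames(c(.3, .4, .25, .2, .1, .15), spec$par_info$name) # variances
  mz <- expected_correlation_matrix(spec, th, "MZ")
  dz <- expected_correlation_matrix(spec, th, "DZ")
  expect_equal(mz[1, 2], 0); expect_equal(mz[1, 6], 0)
  expect_equal(mz[1, 4], .3 + .2) # kappa * v_sa + v_sc
  expect_equal(dz[1, 4], .5 * .3 + .2)
})

test_that("symmetry, unit diagonal, and PSD over randomized parameters", {
  set.seed(31)
  cb <- h_codebook3()
  for (i in 1:25) {
    spec <- build_ipm_spec(cb, sample(0:2, 1), sample(0:1, 1), sample(0:1, 1))
    th <- setNames(runif(n_free_params(spec), 0.05, 0.45), spec$par_info$name)
    # keep specific variances (sa/sc blocks) on the variance scale
    th <- twinpath:::repair_start(spec, th)
    for (z in c("MZ", "DZ")) {
      S <- expected_correlation_matrix(spec, th, z)
      expect_equal(S, t(S))
      expect_equal(unname(diag(S)), rep(1, 6))
      ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
      expect_gt(min(ev), -1e-10)
    }
  }
})

test_that("MZ-minus-DZ cross block equals half the additive structure", {
  spec <- h_spec3()
  th <- h_theta3()
  mz <- expected_correlation_matrix(spec, th, "MZ")
  dz <- expected_correlation_matrix(spec, th, "DZ")
  st <- twinpath:::theta_to_struct(spec, th)
  expect_equal(
    (mz - dz)[1:3, 4:6],
    0.5 * (tcrossprod(st$La) + diag(st$v_sa)),
    ignore_attr = TRUE
  )
})

test_that("CPM is nested in the 1-1-1 IPM (constructive equivalence)", {
  cb <- h_codebook3()
  cpm <- build_cpm_spec(cb, drops = list(specific_a = "i1", specific_c = c("p1", "p2")))
  thc <- setNames(
    c(sqrt(.5), sqrt(.6), sqrt(.7), sqrt(.47), sqrt(.34), .15, .1, .12),
    cpm$par_info$name
  )
  lam <- thc[1:3]; aF <- thc[["a_F"]]; cF <- thc[["c_F"]]
  eF <- sqrt(1 - aF^2 - cF^2)
  ipm <- build_ipm_spec(cb, 1, 1, 1, drops = list(specific_a = "i1", specific_c = c("p1", "p2")))
  thi <- setNames(
    c(lam * aF, lam * cF, lam * eF, thc[c("as_p1", "as_p2", "cs_i1")]),
    ipm$par_info$name
  )
  for (z in c("MZ", "DZ")) {
    expect_equal(
      expected_correlation_matrix(cpm, thc, z),
      expected_correlation_matrix(ipm, thi, z),
      ignore_attr = TRUE, tolerance = 1e-12
    )
  }
  # cross-twin cross-trait MZ entry is lambda_j lambda_m (a_F^2 + c_F^2)
  mz <- expected_correlation_matrix(cpm, thc, "MZ")
  expect_equal(mz[1, 5], lam[[1]] * lam[[2]] * (aF^2 + cF^2))
})

test_that("bivariate Cholesky reproduces a target correlation structure", {
  cb <- codebook(c("pom", "heroin"), class_tag = c("prescription", "illicit"))
  spec <- bivariate_cholesky_spec(cb)
  expect_equal(n_free_params(spec), 7)
  th <- setNames(c(.6, .35, .45, .3, .5, .25, .2), spec$par_info$name)
  mz <- expected_correlation_matrix(spec, th, "MZ")
  st <- twinpath:::theta_to_struct(spec, th)
  A <- matrix(c(.6, 0, .35, .45), 2, 2, byrow = TRUE)
  C <- matrix(c(.3, 0, .5, .25), 2, 2, byrow = TRUE)
  E <- matrix(c(st$se[1], 0, .2, st$se[2]), 2, 2, byrow = TRUE)
  W <- tcrossprod(A) + tcrossprod(C) + tcrossprod(E)
  expect_equal(mz[1:2, 1:2], W, ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(mz[1:2, 3:4], tcrossprod(A) + tcrossprod(C),
    ignore_attr = TRUE, tolerance = 1e-12
  )
  expect_equal(unname(diag(W)), c(1, 1), tolerance = 1e-12)
})

test_that("standardize sums to one and reports CPM through-factor shares", {
  spec <- h_spec3()
  dec <- standardize(spec, h_theta3())
  expect_equal(rowSums(dec[, -1]), rep(1, 3), ignore_attr = TRUE)
  cpm <- build_cpm_spec(h_codebook3())
  thc <- setNames(
    c(sqrt(.8), sqrt(.25), sqrt(.5), sqrt(.47), sqrt(.34), 0, 0, .1, 0, 0, .2),
    cpm$par_info$name
  )
  decc <- standardize(cpm, thc)
  expect_equal(decc$general_a[1], 0.8 * 0.47, tolerance = 1e-12)
  expect_equal(decc$general_c[2], 0.25 * 0.34, tolerance = 1e-12)
  expect_equal(attr(decc, "factor_shares")[["a_F2"]], 0.47, tolerance = 1e-12)
  expect_equal(rowSums(decc[, c(
    "general_a", "general_c", "general_e",
    "specific_a", "specific_c", "specific_e"
  )]), rep(1, 3), ignore_attr = TRUE)
})

test_that("theta violating unit variance raises in the strict interface", {
  spec <- h_spec3()
  th <- h_theta3()
  th[1] <- 2 # explained variance > 1
  expect_error(expected_correlation_matrix(spec, th, "MZ"), "unit liability")
})

test_that("Falconer closed forms", {
  f <- falconer_estimates(0.8, 0.5)
  expect_equal(unlist(f[1, 1:3]), c(a2 = .6, c2 = .2, e2 = .2))
  expect_false(f$boundary)
  f2 <- falconer_estimates(0.47, 0.285)
  expect_equal(unlist(f2[1, 1:3]), c(a2 = .37, c2 = .10, e2 = .53))
  f3 <- falconer_estimates(0.5, 0.25)
  expect_equal(f3$c2, 0)
  expect_false(f3$boundary)
  expect_true(falconer_estimates(0.2, 0.4)$boundary) # a2 < 0
})
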