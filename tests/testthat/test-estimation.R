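pop_mom <- twinpath:::population_moments

test_that("population self-consistency: small specs recover exactly", {
  # univariate
  su <- univariate_ace_spec(codebook("x", class_tag = "illicit"))
  thu <- setNames(c(sqrt(.6), sqrt(.2)), su$par_info$name)
  fu <- fit_wls(su, pop_mom(su, thu), weight_mode = "identity", n_starts = 3, seed = 1)
  expect_true(fu$converged)
  expect_lt(fu$F_min, 1e-10)
  expect_lt(max(abs(fu$theta - thu)), 1e-6)
  # bivariate Cholesky
  sb <- bivariate_cholesky_spec(codebook(c("x", "y"), class_tag = "illicit"))
  thb <- setNames(c(.6, .35, .45, .3, .5, .25, .2), sb$par_info$name)
  fb <- fit_wls(sb, pop_mom(sb, thb), weight_mode = "identity", n_starts = 3, seed = 2)
  expect_true(fb$converged)
  expect_lt(fb$F_min, 1e-10)
  expect_lt(max(abs(fb$theta - thb)), 1e-6)
  # reduced IPM and CPM on three phenotypes
  sp <- h_spec3()
  fp <- fit_wls(sp, pop_mom(sp, h_theta3()), weight_mode = "identity", n_starts = 3, seed = 3)
  expect_lt(fp$F_min, 1e-10)
  expect_lt(max(abs(fp$theta - h_theta3())), 1e-6)
  sc <- build_cpm_spec(h_codebook3(), drops = list(specific_a = "i1", specific_c = c("p1", "p2")))
  thc <- setNames(
    c(sqrt(.5), sqrt(.6), sqrt(.7), sqrt(.47), sqrt(.34), .15, .1, .12),
    sc$par_info$name
  )
  fc <- fit_wls(sc, pop_mom(sc, thc), weight_mode = "identity", n_starts = 3, seed = 4)
  expect_lt(fc$F_min, 1e-10)
  expect_lt(max(abs(fc$theta - thc)), 1e-6)
})

test_that("exactly identified univariate WLS equals the Falconer closed form", {
  su <- univariate_ace_spec(codebook("x", class_tag = "illicit"))
  th_star <- setNames(c(sqrt(.6), sqrt(.2)), su$par_info$name) # r_MZ=.8, r_DZ=.5
  pm <- pop_mom(su, th_star)
  fit <- fit_wls(su, pm, weight_mode = "identity", n_starts = 3, seed = 5)
  fal <- falconer_estimates(0.8, 0.5)
  expect_equal(unname(fit$theta[1]^2), fal$a2, tolerance = 1e-8)
  expect_equal(unname(fit$theta[2]^2), fal$c2, tolerance = 1e-8)
  expect_equal(fit$decomposition$specific_e, fal$e2, tolerance = 1e-8)
})

test_that("F is nonnegative, zero only at reproducible moments", {
  mom <- h_mom3(101, 1000)
  fit <- fit_wls(h_spec3(), mom, n_starts = 2, seed = 1)
  expect_gte(fit$F_min, 0)
  expect_gt(fit$F_min, 1e-6) # sampled moments are not exactly reproducible
  sp <- h_spec3()
  f0 <- fit_wls(sp, pop_mom(sp, h_theta3()), weight_mode = "identity", n_starts = 2, seed = 1)
  expect_lt(f0$F_min, 1e-10)
})

test_that("nested specs: adding free parameters never increases F_min", {
  mom <- h_mom3(101, 1000)
  cb <- h_codebook3()
  chain <- list(
    build_ipm_spec(cb, 1, 0, 0, drops = list(specific_c = c("p1", "p2", "i1"))),
    h_spec3(), # adds general e
    build_ipm_spec(cb, 1, 0, 1, drops = list(specific_c = c("p1", "p2", "i1"))),
    build_ipm_spec(cb, 1, 0, 1),
    build_ipm_spec(cb, 1, 1, 1)
  )
  fmins <- vapply(chain, function(s) {
    fit_wls(s, mom, n_starts = 3, seed = 2)$F_min
  }, numeric(1))
  expect_true(all(diff(fmins) <= 1e-10))
})

test_that("fit is invariant to twin ordering and phenotype ordering", {
  ds <- h_ds3(55, 400)
  cb <- twin_codebook_of(ds)
  fit0 <- fit_wls(h_spec3(), all_group_moments(ds), n_starts = 2, seed = 1)
  # twin relabelling (complete pairs only)
  sw <- as.data.frame(ds)
  keep <- rowSums(!is.na(sw[, paste0(cb$name, "_t2")])) > 0
  sw <- sw[keep, ]
  for (ph in cb$name) {
    a <- sw[[paste0(ph, "_t1")]]
    sw[[paste0(ph, "_t1")]] <- sw[[paste0(ph, "_t2")]]
    sw[[paste0(ph, "_t2")]] <- a
  }
  ds_kept <- twin_data(as.data.frame(ds)[keep, ], cb)
  fit_kept <- fit_wls(h_spec3(), all_group_moments(ds_kept), n_starts = 2, seed = 1)
  fit_sw <- fit_wls(h_spec3(), all_group_moments(twin_data(sw, cb)), n_starts = 2, seed = 1)
  expect_equal(fit_sw$F_min, fit_kept$F_min, tolerance = 1e-8)
  expect_equal(fit_sw$theta, fit_kept$theta, tolerance = 1e-6)
  # phenotype reordering
  perm <- c("i1", "p1", "p2")
  ds_p <- subset_phenotypes(ds, perm)
  spec_p <- build_ipm_spec(twin_codebook_of(ds_p), 1, 0, 1,
    drops = list(specific_a = "i1", specific_c = perm)
  )
  fit_p <- fit_wls(spec_p, all_group_moments(ds_p), n_starts = 2, seed = 1)
  expect_equal(fit_p$F_min, fit0$F_min, tolerance = 1e-8)
  d0 <- fit0$decomposition[match(perm, fit0$decomposition$phenotype), ]
  expect_equal(fit_p$decomposition$general_a, d0$general_a, tolerance = 1e-6)
})

test_that("identification and input checks fail fast", {
  su <- univariate_ace_spec(codebook("x", class_tag = "illicit"))
  thu <- setNames(c(sqrt(.5), sqrt(.1)), su$par_info$name)
  pm <- pop_mom(su, thu)
  expect_error(fit_wls(su, pm[c("MZM", "MZF")]), "MZ and DZ")
  sp5 <- build_ipm_spec(h_codebook3(), 2, 2, 2)
  expect_error(
    fit_wls(sp5, pop_mom(sp5, setNames(
      rep(.2, n_free_params(sp5)), sp5$par_info$name
    ))[c("MZM", "DZM")]),
    "not identified"
  )
})

test_that("sandwich: full-weight identity and analytic univariate jacobian", {
  ds <- h_ds3(101, 1000)
  ds1 <- subset_phenotypes(ds, "p1")
  mom <- all_group_moments(ds1, acov = "bootstrap", B = 300, seed = 3)
  su <- univariate_ace_spec(twin_codebook_of(ds1))
  fit_f <- add_sandwich(fit_wls(su, mom, weight_mode = "full", n_starts = 3, seed = 1))
  # with W = Gamma the sandwich collapses to (D' Gamma^{-1} D)^{-1}
  D <- twinpath:::fit_jacobian(fit_f)
  G <- twinpath:::block_diag(twinpath:::fit_gamma(fit_f))
  V_direct <- solve(t(D) %*% solve(G) %*% D)
  expect_equal(unname(fit_f$vcov), unname(V_direct), tolerance = 1e-6)
  # jacobian of the univariate model: d sigma / d a = 2 a kappa, d/dc = 2c
  a <- fit_f$theta[[1]]; c_ <- fit_f$theta[[2]]
  kap <- ifelse(twinpath:::group_zygosity(fit_f$groups_used) == "MZ", 1, 0.5)
  expect_equal(unname(D[, 1]), unname(2 * a * kap), tolerance = 1e-6)
  expect_equal(unname(D[, 2]), rep(2 * c_, 4), tolerance = 1e-6)
})

test_that("sandwich s.e. tracks sampling variability (univariate)", {
  set.seed(99)
  cbx <- codebook("x", class_tag = "illicit")
  gm <- generating_model(cbx,
    loadings_a = matrix(sqrt(.4)), loadings_c = matrix(sqrt(.2)),
    loadings_e = matrix(0, 1, 0),
    specific_a = 0, specific_c = 0, specific_e = sqrt(.4),
    thresholds = cbind(M = 0, F = 0),
    group_sizes = setNames(rep(1500L, 4), c("MZM", "MZF", "DZM", "DZF"))
  )
  su <- univariate_ace_spec(cbx)
  est <- se_dm <- numeric(120)
  for (i in 1:120) {
    ds <- simulate_twins(gm, seed = 7000 + i)
    mom <- all_group_moments(ds, acov = "bootstrap", B = 120, seed = i)
    fit <- add_sandwich(fit_wls(su, mom, n_starts = 1, seed = i))
    est[i] <- fit$theta[[1]]^2
    se_dm[i] <- 2 * abs(fit$theta[[1]]) * sqrt(fit$vcov[1, 1]) # delta to a^2
  }
  expect_lt(abs(sd(est) / mean(se_dm) - 1), 0.20)
})

test_that("bootstrap intervals: determinism, degenerate hook, and guards", {
  ds <- subset_phenotypes(h_ds3(101, 1000), "i1")
  su <- univariate_ace_spec(twin_codebook_of(ds))
  b1 <- suppressWarnings(bootstrap_ci(ds, su, B = 150, seed = 42))
  b2 <- suppressWarnings(bootstrap_ci(ds, su, B = 150, seed = 42))
  expect_equal(b1$intervals, b2$intervals)
  b3 <- suppressWarnings(bootstrap_ci(ds, su, B = 150, seed = 43))
  expect_false(isTRUE(all.equal(b1$intervals$lower, b3$intervals$lower)))
  expect_error(bootstrap_ci(ds, su, B = 50, seed = 1), "at least 100")
  expect_warning(bootstrap_ci(ds, su, B = 150, seed = 1), "B < 1000")
  b0 <- suppressWarnings(bootstrap_ci(ds, su, B = 100, seed = 1, resample = FALSE))
  expect_equal(b0$intervals$lower, b0$intervals$estimate, tolerance = 1e-10)
  expect_equal(b0$intervals$upper, b0$intervals$estimate, tolerance = 1e-10)
})

test_that("quick univariate solver agrees with the general optimizer", {
  ds <- subset_phenotypes(h_ds3(101, 1000), "p2")
  mom <- all_group_moments(ds)
  su <- univariate_ace_spec(twin_codebook_of(ds))
  fit <- fit_wls(su, mom, n_starts = 3, seed = 1)
  md <- twinpath:::collect_moment_data(su, mom, "diagonal")
  quick <- twinpath:::fit_univariate_closed(su, md)
  expect_equal(unname(quick$theta), unname(fit$theta), tolerance = 1e-6)
})

test_that("diagonal and full weights agree at population moments", {
  sp <- h_spec3()
  pm <- pop_mom(sp, h_theta3())
  # give the population moments a dummy full acov so 'full' mode runs
  for (g in names(pm)) {
    M <- nrow(pm[[g]]$moments)
    pm[[g]]$acov_full <- diag(M) * 1e-4
    pm[[g]]$moments$se <- rep(1e-2, M)
    pm[[g]]$acov_diag <- rep(1e-4, M)
  }
  fd <- fit_wls(sp, pm, weight_mode = "diagonal", n_starts = 2, seed = 1)
  ff <- fit_wls(sp, pm, weight_mode = "full", n_starts = 2, seed = 1)
  expect_lt(max(abs(fd$theta - h_theta3())), 1e-6)
  expect_lt(max(abs(ff$theta - h_theta3())), 1e-6)
})
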