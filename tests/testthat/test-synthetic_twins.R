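test_that("threshold_from_prevalence is the upper-tail normal quantile", {
  expect_equal(threshold_from_prevalence(0.5), 0)
  expect_equal(threshold_from_prevalence(0.0779), qnorm(1 - 0.0779))
  expect_equal(round(threshold_from_prevalence(0.0779), 3), 1.419)
  expect_equal(round(threshold_from_prevalence(0.6181), 4), -0.3005)
  expect_equal(pnorm(threshold_from_prevalence(0.3), lower.tail = FALSE), 0.3)
  expect_error(threshold_from_prevalence(0), "strictly")
  expect_error(threshold_from_prevalence(1), "strictly")
})

test_that("generating_model enforces unit liability variance and cpm identities", {
  cb <- h_codebook3()
  expect_error(
    generating_model(cb,
      loadings_a = matrix(1, 3, 1), loadings_c = matrix(0, 3, 0),
      loadings_e = matrix(0.5, 3, 1),
      specific_a = rep(0, 3), specific_c = rep(0, 3), specific_e = rep(0, 3),
      thresholds = cbind(M = rep(0, 3), F = rep(0, 3)),
      group_sizes = setNames(rep(10L, 4), c("MZM", "MZF", "DZM", "DZF"))
    ),
    "unit liability variance"
  )
  expect_error(
    generating_model(cb,
      specific_a = rep(0, 3), specific_c = rep(0, 3),
      specific_e = sqrt(1 - 0.5),
      thresholds = cbind(M = rep(0, 3), F = rep(0, 3)),
      group_sizes = setNames(rep(10L, 4), c("MZM", "MZF", "DZM", "DZF")),
      cpm = list(a_F = 0.8, c_F = 0.8, e_F = 0.1, lambda = rep(sqrt(0.5), 3))
    ),
    "a_F\\^2"
  )
  gm <- generating_model(cb,
    specific_a = rep(0, 3), specific_c = rep(0, 3),
    specific_e = rep(sqrt(0.5), 3),
    thresholds = cbind(M = rep(0, 3), F = rep(0, 3)),
    group_sizes = setNames(rep(10L, 4), c("MZM", "MZF", "DZM", "DZF")),
    cpm = list(a_F = sqrt(.47), c_F = sqrt(.34), e_F = sqrt(.19),
      lambda = rep(sqrt(0.5), 3))
  )
  td <- true_decomposition(gm)
  expect_equal(td$general_a + td$general_c + td$general_e +
    td$specific_a + td$specific_c + td$specific_e, rep(1, 3))
})

test_that("simulation is deterministic in the seed", {
  gm <- h_gm3(50)
  d1 <- simulate_twins(gm, seed = 7)
  d2 <- simulate_twins(gm, seed = 7)
  d3 <- simulate_twins(gm, seed = 8)
  expect_identical(as.data.frame(d1), as.data.frame(d2))
  expect_false(identical(as.data.frame(d1), as.data.frame(d3)))
})

test_that("registry preset matches its published design numbers", {
  gm <- atr_preset()
  expect_equal(nrow(gm$codebook), 11)
  td <- true_decomposition(gm)
  expect_equal(td$general_a + td$general_c + td$general_e +
    td$specific_a + td$specific_c + td$specific_e, rep(1, 11),
    tolerance = 1e-10
  )
  expect_equal(unname(gm$thresholds["heroin", "F"]), qnorm(1 - 0.0131))
  expect_equal(unname(gm$group_sizes), c(923L, 1344L, 809L, 1075L))
  # expected share of individuals in complete pairs reproduces 84.12%
  exp_complete <- sum(2 * gm$group_sizes * gm$completeness)
  exp_individuals <- sum(gm$group_sizes * (1 + gm$completeness))
  expect_equal(exp_complete / exp_individuals, 0.8412, tolerance = 5e-4)
  # POM general-factor share used in the preset
  expect_equal(td$general_a[td$phenotype == "pom"] +
    td$general_e[td$phenotype == "pom"], 0.55)
  gm10 <- atr_preset(scale = 0.1)
  expect_equal(unname(gm10$group_sizes), as.integer(round(c(923, 1344, 809, 1075) * 0.1)))
})

test_that("pure-E generation gives null cross-twin correlations", {
  cb <- codebook("x", class_tag = "illicit")
  gm <- generating_model(cb,
    loadings_a = matrix(0, 1, 0), loadings_c = matrix(0, 1, 0),
    loadings_e = matrix(0, 1, 0),
    specific_a = 0, specific_c = 0, specific_e = 1,
    thresholds = cbind(M = 0.5, F = 0.5),
    group_sizes = setNames(c(20000L, 0L, 20000L, 0L), c("MZM", "MZF", "DZM", "DZF"))
  )
  ds <- simulate_twins(gm, seed = 3)
  for (g in c("MZM", "DZM")) {
    m <- group_moments(ds, g)
    cross <- m$moments[m$moments$kind == "cross", ]
    expect_lt(abs(cross$r), 3 * cross$se)
  }
})

test_that("ACE generation reproduces closed-form cross-twin expectations", {
  # heroin-like: a2 = .08, c2 = .74 -> r_MZ = .82, r_DZ = .78
  # POM-like: a2 = .37, c2 = .10 -> r_MZ = .47, r_DZ = .285
  cb <- codebook(c("h", "p"), class_tag = c("illicit", "prescription"))
  gm <- generating_model(cb,
    loadings_a = matrix(0, 2, 0), loadings_c = matrix(0, 2, 0),
    loadings_e = matrix(0, 2, 0),
    specific_a = sqrt(c(.08, .37)), specific_c = sqrt(c(.74, .10)),
    specific_e = sqrt(c(.18, .53)),
    thresholds = cbind(M = qnorm(1 - c(.0131, .0779)) * 0, # common traits for power
      F = c(0, 0)),
    group_sizes = setNames(c(30000L, 0L, 30000L, 0L), c("MZM", "MZF", "DZM", "DZF"))
  )
  ds <- simulate_twins(gm, seed = 11)
  expected <- list(MZM = c(.82, .47), DZM = c(.5 * .08 + .74, .5 * .37 + .10))
  for (g in names(expected)) {
    m <- group_moments(ds, g)
    same <- m$moments[m$moments$kind == "cross" & m$moments$j == m$moments$m, ]
    for (j in 1:2) {
      expect_lt(abs(same$r[j] - expected[[g]][j]), 3 * same$se[j])
    }
  }
  # MZ concordance exceeds DZ when a-paths are nonzero
  mz <- group_moments(ds, "MZM")$moments
  dz <- group_moments(ds, "DZM")$moments
  expect_true(all(mz$r[mz$kind == "cross" & mz$j == mz$m] >
    dz$r[dz$kind == "cross" & dz$j == dz$m]))
})

test_that("completeness masking hits its target rate", {
  gm <- atr_preset(scale = 2)
  ds <- simulate_twins(gm, seed = 2)
  sp <- summarize_prevalence(ds)
  expect_equal(sp$completeness, 0.8412, tolerance = 0.015)
})

test_that("twin exchange leaves downstream moments invariant", {
  ds <- h_ds3(55, 400)
  swapped <- as.data.frame(ds)
  cb <- twin_codebook_of(ds)
  for (ph in cb$name) {
    a <- swapped[[paste0(ph, "_t1")]]
    swapped[[paste0(ph, "_t1")]] <- swapped[[paste0(ph, "_t2")]]
    swapped[[paste0(ph, "_t2")]] <- a
  }
  # only complete pairs may be swapped (twin1 must carry data)
  keep <- rowSums(!is.na(swapped[, paste0(cb$name, "_t1")])) > 0
  swapped <- swapped[keep, ]
  orig <- as.data.frame(ds)[keep, ]
  ds_sw <- twin_data(swapped, cb)
  ds_or <- twin_data(orig, cb)
  m1 <- group_moments(ds_or, "MZM")
  m2 <- group_moments(ds_sw, "MZM")
  expect_equal(m1$moments$r, m2$moments$r, tolerance = 1e-12)
  expect_equal(m1$thresholds$tau, m2$thresholds$tau)
})
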