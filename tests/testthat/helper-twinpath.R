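# Shared fixtures: all data are generated in code, seeded.

h_codebook3 <- function() {
  codebook(c("p1", "p2", "i1"),
    class_tag = c("prescription", "prescription", "illicit")
  )
}

# Reduced one-general-a / one-general-e model with two specific-A variance
# components; the workhorse correctly-specified generator for estimation
# and inference tests.
h_gm3 <- function(pairs = 1000) {
  generating_model(
    h_codebook3(),
    loadings_a = matrix(sqrt(c(.4, .5, .45)), 3, 1),
    loadings_c = matrix(0, 3, 0),
    loadings_e = matrix(sqrt(c(.2, .1, .15)), 3, 1),
    specific_a = sqrt(c(.2, .15, 0)), specific_c = rep(0, 3),
    specific_e = sqrt(c(.2, .25, .4)),
    thresholds = cbind(M = stats::qnorm(1 - c(.1, .12, .3)),
      F = stats::qnorm(1 - c(.1, .12, .3))),
    group_sizes = stats::setNames(rep(as.integer(pairs), 4),
      c("MZM", "MZF", "DZM", "DZF"))
  )
}

h_spec3 <- function() {
  build_ipm_spec(h_codebook3(), 1, 0, 1,
    drops = list(specific_a = "i1", specific_c = c("p1", "p2", "i1"))
  )
}

h_theta3 <- function() {
  sp <- h_spec3()
  stats::setNames(
    c(sqrt(.4), sqrt(.5), sqrt(.45), sqrt(.2), sqrt(.1), sqrt(.15), .2, .15),
    sp$par_info$name
  )
}

# Memoized simulated dataset + moments so several test files can share one.
.h_cache <- new.env(parent = emptyenv())

h_ds3 <- function(seed = 101, pairs = 1000) {
  key <- paste0("ds3_", seed, "_", pairs)
  if (is.null(.h_cache[[key]])) {
    .h_cache[[key]] <- simulate_twins(h_gm3(pairs), seed = seed)
  }
  .h_cache[[key]]
}

h_mom3 <- function(seed = 101, pairs = 1000, acov = "diagonal", B = 150) {
  key <- paste0("mom3_", seed, "_", pairs, "_", acov, "_", B)
  if (is.null(.h_cache[[key]])) {
    .h_cache[[key]] <- all_group_moments(h_ds3(seed, pairs),
      acov = acov, B = B, seed = seed
    )
  }
  .h_cache[[key]]
}

# Random 2x2 table with margins in [lo, hi], drawn from a true bivariate
# normal orthant model (used for the oracle-equivalence sweeps).
h_random_table <- function(n = 1000, lo = 0.05, hi = 0.95) {
  repeat {
    pr <- stats::runif(2, lo, hi)
    rho <- stats::runif(1, -0.9, 0.9)
    t1 <- stats::qnorm(1 - pr[1]); t2 <- stats::qnorm(1 - pr[2])
    p11 <- twinpath:::bvn_upper(t1, t2, rho)
    pm <- c(p11, pr[1] - p11, pr[2] - p11, 1 - pr[1] - pr[2] + p11)
    if (all(pm > 0.002)) {
      cn <- as.numeric(stats::rmultinom(1, n, pm))
      if (all(cn > 0)) return(matrix(cn, 2, 2, byrow = TRUE))
    }
  }
}

h_wide_df <- function(cb, rows) {
  # rows: list of c(pair_id, group, t1 values..., t2 values...)
  cols <- c("pair_id", "group", paste0(rep(cb$name, each = 2), c("_t1", "_t2")))
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(df) <- cols
  df
}
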