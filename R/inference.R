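# Test of fit against the saturated stage-1 moments, fit indices with
# conventional cutoffs, Wald tests of parameter restrictions, sex
# difference tests, and sex-covariate adjustment.

#' Mean-adjusted test of model fit
#'
#' Degrees of freedom are the count of distinct fitted moments minus the
#' count of free structural parameters. The statistic is the mean-adjusted
#' weighted least squares statistic `T = df * F_min / trace(U Gamma)`,
#' where `U = W^{-1} - W^{-1} D (D'W^{-1}D)^{-1} D' W^{-1}` is the residual
#' weight operator and `Gamma` the stage-1 asymptotic covariance of the
#' sample moments; `E[F_min] = trace(U Gamma)` under the model, so `T` is
#' referred to the central chi-square upper tail with `df` degrees of
#' freedom.
#'
#' @param fit A converged `twin_fit`.
#' @return List: `T`, `df`, `p_value`, `trace_UG`, `F_min`.
#' @export
test_statistic <- function(fit) {
  if (!fit$converged) stop("fit did not converge", call. = FALSE)
  df <- fit$n_moments - length(fit$theta)
  if (df <= 0) {
    return(list(
      T = 0, df = as.integer(df), p_value = NA_real_,
      trace_UG = NA_real_, F_min = fit$F_min,
      note = "saturated or over-parameterized model; no test available"
    ))
  }
  D <- fit_jacobian(fit)
  Wi <- fit_weight_inverse(fit)
  G <- block_diag(fit_gamma(fit, require_full = TRUE))
  WiD <- block_apply(Wi, D)
  # pseudo-inverse: flat directions at boundary solutions project to zero
  B <- pracma::pinv(crossprod(D, WiD))
  WiG <- block_apply(Wi, G)
  tr_UG <- sum(diag(WiG)) - sum(WiD * (G %*% (WiD %*% B)))
  T_stat <- df * max(fit$F_min, 0) / tr_UG
  list(
    T = T_stat, df = as.integer(df),
    p_value = stats::pchisq(T_stat, df, lower.tail = FALSE),
    trace_UG = tr_UG, F_min = fit$F_min
  )
}

#' Independence-baseline statistic for incremental fit indices
#'
#' The baseline model keeps the stage-1 thresholds and fixes every
#' correlation to zero (no free structural parameters), so its discrepancy
#' is `sum_g s_g' W_g^{-1} s_g`, mean-adjusted the same way as
#' [test_statistic()].
#'
#' @param moments List of `group_moments` (same groups/weights as the fit).
#' @param weight_mode Weight mode matching the fitted model.
#' @return List: `T`, `df`.
#' @export
baseline_statistic <- function(moments, weight_mode = "diagonal") {
  if (inherits(moments, "group_moments")) moments <- list(moments)
  p <- length(moments[[1]]$codebook$name)
  null_spec <- new_model_spec("ipm", moments[[1]]$codebook,
    mask_a = matrix(0, p, 0), mask_c = matrix(0, p, 0),
    mask_e = matrix(0, p, 0),
    smask_a = rep(FALSE, p), smask_c = rep(FALSE, p),
    label = "independence"
  )
  md <- collect_moment_data(null_spec, moments, weight_mode)
  Wi <- purrr::map(md$per_group, function(g) if (is.null(g$Wi)) g$w else g$Wi)
  F0 <- sum(vapply(seq_along(md$groups), function(gi) {
    s <- md$per_group[[gi]]$s
    if (is.matrix(Wi[[gi]])) as.numeric(s %*% Wi[[gi]] %*% s) else sum(Wi[[gi]] * s^2)
  }, numeric(1)))
  G <- block_diag(purrr::map(md$per_group, function(g) {
    if (!is.null(g$acov_full)) psd_smooth(g$acov_full) else diag(g$acov, length(g$acov))
  }))
  WiG <- block_apply(Wi, G)
  tr <- sum(diag(WiG))
  df <- md$n_used
  list(T = df * F0 / tr, df = as.integer(df))
}

#' Fit indices for a multi-group categorical model
#'
#' `RMSEA = sqrt(G * max(T - df, 0) / (df * N))` (multiple-group
#' convention, `N` = individuals), with a 90% interval from the noncentral
#' chi-square; `TLI = ((T_b/df_b) - (T/df)) / ((T_b/df_b) - 1)`;
#' `CFI = 1 - max(T - df, 0) / max(T_b - df_b, T - df, 0)`. Conventional
#' cutoff flags (`RMSEA < 0.05`, `TLI > 0.95`, `CFI > 0.95`) are attached.
#'
#' @param T_stat,df Test statistic and degrees of freedom of the fitted
#'   model.
#' @param N_total Total individuals across groups.
#' @param G Number of groups.
#' @param T_baseline,df_baseline Baseline (independence) statistic.
#' @return List of class `fit_indices`.
#' @export
fit_indices <- function(T_stat, df, N_total, G, T_baseline, df_baseline) {
  if (df <= 0) {
    return(structure(
      list(
        T = T_stat, df = df, p_value = NA_real_, RMSEA = NA_real_,
        RMSEA_lo = NA_real_, RMSEA_hi = NA_real_, TLI = NA_real_,
        CFI = NA_real_, N_total = N_total, G = G,
        acceptable = NA, note = "df = 0: indices undefined"
      ),
      class = "fit_indices"
    ))
  }
  stopifnot(df_baseline >= df)
  rmsea_from_ncp <- function(ncp) sqrt(G * max(ncp, 0) / (df * N_total))
  RMSEA <- rmsea_from_ncp(T_stat - df)
  # 90% interval: noncentrality values at which T sits at the 95th/5th
  # percentile of the noncentral chi-square
  ncp_root <- function(target_p) {
    f <- function(ncp) stats::pchisq(T_stat, df, ncp = ncp) - target_p
    if (f(0) < target_p - 1) return(0)
    hi <- max(T_stat * 2, df * 2, 10)
    while (f(hi) > 0 && hi < 1e8) hi <- hi * 2
    if (f(0) <= 0) 0 else stats::uniroot(f, c(0, hi))$root
  }
  lo <- tryCatch(if (stats::pchisq(T_stat, df) < 0.95) 0 else ncp_root(0.95),
    error = function(e) NA_real_
  )
  hi <- tryCatch(if (stats::pchisq(T_stat, df) < 0.05) 0 else ncp_root(0.05),
    error = function(e) NA_real_
  )
  rb <- T_baseline / df_baseline
  TLI <- (rb - T_stat / df) / (rb - 1)
  CFI <- 1 - max(T_stat - df, 0) / max(T_baseline - df_baseline, T_stat - df, 0)
  if (!is.finite(CFI)) CFI <- 1
  structure(
    list(
      T = T_stat, df = df,
      p_value = stats::pchisq(T_stat, df, lower.tail = FALSE),
      RMSEA = RMSEA,
      RMSEA_lo = rmsea_from_ncp(lo), RMSEA_hi = rmsea_from_ncp(hi),
      TLI = TLI, CFI = CFI, N_total = N_total, G = G,
      acceptable = (RMSEA < 0.05) && (TLI > 0.95) && (CFI > 0.95)
    ),
    class = "fit_indices"
  )
}

#' @export
print.fit_indices <- function(x, ...) {
  cat(sprintf(
    "chi2(%d) = %.3f, p = %.3g; RMSEA = %.3f (%.3f-%.3f); TLI = %.3f; CFI = %.3f\n",
    x$df, x$T, x$p_value, x$RMSEA, x$RMSEA_lo, x$RMSEA_hi, x$TLI, x$CFI
  ))
  invisible(x)
}

#' Wald test of linear parameter restrictions
#'
#' `W = (R theta - r)' (R V R')^{-1} (R theta - r)` with `V` the sandwich
#' covariance of the fuller model's estimates, referred to the central
#' chi-square with `rank(R)` degrees of freedom. Restrictions may be given
#' as a matrix `R` (rows = restrictions) or as a character vector of
#' parameter names to test against zero.
#'
#' @param fit A converged `twin_fit` (its sandwich covariance is computed
#'   if absent).
#' @param restrict Character vector of parameter names (tested = 0) or a
#'   restriction matrix with `length(fit$theta)` columns.
#' @param r Right-hand side (default zeros).
#' @return List: `W`, `df`, `p_value`, plus `boundary_warning` if any
#'   restricted parameter sits at a variance boundary.
#' @export
wald_test <- function(fit, restrict, r = NULL) {
  fit <- add_sandwich(fit)
  theta <- fit$theta
  if (is.character(restrict)) {
    miss <- setdiff(restrict, names(theta))
    if (length(miss) > 0) {
      stop("unknown parameters: ", paste(miss, collapse = ", "), call. = FALSE)
    }
    R <- matrix(0, length(restrict), length(theta),
      dimnames = list(restrict, names(theta))
    )
    R[cbind(seq_along(restrict), match(restrict, names(theta)))] <- 1
  } else {
    R <- as.matrix(restrict)
    stopifnot(ncol(R) == length(theta))
  }
  if (is.null(r)) r <- rep(0, nrow(R))
  if (qr(R)$rank < nrow(R)) stop("restriction matrix is rank deficient", call. = FALSE)
  diff <- as.numeric(R %*% theta - r)
  RVR <- R %*% fit$vcov %*% t(R)
  # a restriction whose variance direction was dropped at a boundary and
  # whose discrepancy is numerically zero is exactly satisfied there; it
  # contributes 0 to W (df unchanged)
  v_tol <- 1e-8 * max(diag(RVR), 1e-8)
  satisfied <- diag(RVR) <= v_tol & abs(diff) < 1e-5
  keep <- which(!satisfied)
  W <- if (length(keep) == 0) {
    0
  } else {
    dk <- diff[keep]
    as.numeric(dk %*% pracma::pinv(RVR[keep, keep, drop = FALSE]) %*% dk)
  }
  df <- nrow(R)
  boundary_warning <- FALSE
  if (isTRUE(fit$boundary)) {
    involved <- colnames(R)[colSums(abs(R)) > 0]
    if (length(involved) > 0) boundary_warning <- TRUE
  }
  out <- list(
    W = W, df = as.integer(df),
    p_value = stats::pchisq(W, df, lower.tail = FALSE),
    boundary_warning = boundary_warning
  )
  if (boundary_warning) {
    out$note <- "restriction touches a boundary solution; test may be conservative"
  }
  out
}

#' Wald test of quantitative sex differences for one phenotype
#'
#' Fits the univariate ACE model with sex-specific structural parameters
#' (thresholds are always sex-specific in stage 1) and Wald-tests the
#' equality of the male and female `a` and `c` path coefficients (2 df;
#' `e` is determined by the unit-variance constraint).
#'
#' @param ds A `twin_data` tibble.
#' @param phenotype Phenotype name.
#' @param B Bootstrap replicates for the stage-1 acov.
#' @param seed Seed.
#' @return List: the Wald test (`W`, `df`, `p_value`), the sex-specific
#'   `fit`, and the per-sex decompositions.
#' @export
sex_difference_test <- function(ds, phenotype, B = 200, seed = 1) {
  cb <- twin_codebook_of(ds)
  if (!phenotype %in% cb$name) stop("unknown phenotype: ", phenotype, call. = FALSE)
  sub <- subset_phenotypes(ds, phenotype)
  groups <- intersect(ZYG_GROUPS, unique(sub$group))
  if (length(unique(group_sex(groups))) < 2) {
    stop("both sexes must be present", call. = FALSE)
  }
  mom <- all_group_moments(sub, acov = "bootstrap", B = B, seed = seed,
    on_degenerate = "error"
  )
  spec <- univariate_ace_spec(twin_codebook_of(sub), sex_specific = TRUE)
  fit <- fit_wls(spec, mom, weight_mode = "diagonal", n_starts = 3, seed = seed)
  if (!fit$converged) {
    return(list(W = NA_real_, df = 2L, p_value = NA_real_, fit = fit))
  }
  fit <- add_sandwich(fit)
  nm <- names(fit$theta)
  R <- matrix(0, 2, length(nm), dimnames = list(c("a_eq", "c_eq"), nm))
  R[1, grep("^a1_.*\\.M$", nm)] <- 1
  R[1, grep("^a1_.*\\.F$", nm)] <- -1
  R[2, grep("^c1_.*\\.M$", nm)] <- 1
  R[2, grep("^c1_.*\\.F$", nm)] <- -1
  wt <- wald_test(fit, R)
  c(wt, list(fit = fit, decomposition = fit$decomposition))
}

#' Subset a twin dataset to selected phenotypes
#'
#' @param ds A `twin_data` tibble.
#' @param phenotypes Phenotype names to keep (order respected).
#' @return A `twin_data` tibble.
#' @export
subset_phenotypes <- function(ds, phenotypes) {
  cb <- twin_codebook_of(ds)
  miss <- setdiff(phenotypes, cb$name)
  if (length(miss) > 0) stop("unknown phenotypes: ", paste(miss, collapse = ", "), call. = FALSE)
  sel <- match(phenotypes, cb$name)
  cb2 <- codebook(cb$name[sel], label = cb$label[sel], class_tag = cb$class_tag[sel])
  cols <- c("pair_id", "group", paste0(rep(phenotypes, each = 2), c("_t1", "_t2")))
  twin_data(tibble::as_tibble(ds)[, cols], cb2)
}

#' Structural fit with sex as a covariate
#'
#' Sex enters the liability model as a per-phenotype threshold shift
#' `beta_j` estimated by probit regression of each phenotype on a sex
#' indicator over all observed individuals. The liability variance
#' explained by sex is `beta_j^2 v_s / (beta_j^2 v_s + 1)` with `v_s` the
#' sex-indicator variance. Because groups are same-sex, the within-group
#' liability correlations already condition on sex, so the structural
#' model is fitted to the group moments unchanged and reported alongside
#' the sex effects.
#'
#' @param ds A `twin_data` tibble.
#' @param spec A `model_spec`.
#' @param ... Passed to [fit_wls()].
#' @return List: `fit`, `sex_effects` tibble (`phenotype`, `beta`,
#'   `var_explained`), `v_s`.
#' @export
sex_covariate_adjustment <- function(ds, spec, ...) {
  cb <- twin_codebook_of(ds)
  m <- twin_matrices(ds)
  sex1 <- as.numeric(group_sex(m$group) == "M")
  y_all <- rbind(m$t1, m$t2)
  sex_all <- c(sex1, sex1)
  obs_person <- rowSums(!is.na(y_all)) > 0
  if (length(unique(sex_all[obs_person])) < 2) {
    stop("both sexes must be present", call. = FALSE)
  }
  v_s <- stats::var(sex_all[obs_person])
  eff <- purrr::map_dfr(seq_len(nrow(cb)), function(j) {
    ok <- !is.na(y_all[, j])
    co <- tryCatch(
      stats::coef(stats::glm(y_all[ok, j] ~ sex_all[ok],
        family = stats::binomial(link = "probit")
      ))[2],
      error = function(e) NA_real_
    )
    beta <- unname(co)
    tibble::tibble(
      phenotype = cb$name[j], beta = beta,
      var_explained = beta^2 * v_s / (beta^2 * v_s + 1)
    )
  })
  mom <- all_group_moments(ds)
  fit <- fit_wls(spec, mom, ...)
  list(fit = fit, sex_effects = eff, v_s = v_s)
}
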