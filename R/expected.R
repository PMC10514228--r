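# Model-implied liability correlation structure and standardized variance
# decompositions.

struct_blocks <- function(spec, st, kappa) {
  # within-twin and cross-twin p x p blocks for one set of path matrices
  A <- tcrossprod(st$La)
  C <- tcrossprod(st$Lc)
  E <- tcrossprod(st$Le) + diag(st$se^2, length(st$se))
  if (spec$kind == "bivariate_cholesky") {
    # E is lower-triangular [[se1, 0], [e21, se2]]: cross term se1 * e21
    e21 <- st$Le[2, 1]
    E[1, 2] <- E[2, 1] <- st$se[1] * e21
  }
  W <- A + C + E + diag(st$v_sa + st$v_sc, length(st$v_sa))
  X <- kappa * (A + diag(st$v_sa, length(st$v_sa))) + C +
    diag(st$v_sc, length(st$v_sc))
  list(W = W, X = X)
}

#' Model-implied liability correlation matrix
#'
#' The expected 2p x 2p within-pair correlation matrix of a structural
#' model at parameter vector `theta`: the within-twin block is
#' `La La' + Lc Lc' + Le Le' + diag(specific variances)` (unit diagonal by
#' the computed specific-E constraint), and the cross-twin block is
#' `kappa (La La' + diag(v_sa)) + Lc Lc' + diag(v_sc)` with `kappa = 1`
#' for MZ and `0.5` for DZ pairs (`v_sa`, `v_sc` are the signed specific
#' A/C variance components). The two same-twin blocks are identical.
#'
#' @param spec A `model_spec`.
#' @param theta Named parameter vector (see `spec$par_info$name`).
#' @param zygosity `"MZ"` or `"DZ"`.
#' @param sex For sex-specific specs, `"M"` or `"F"`.
#' @return A 2p x 2p symmetric matrix with unit diagonal.
#' @export
expected_correlation_matrix <- function(spec, theta, zygosity = c("MZ", "DZ"),
                                        sex = NA) {
  zygosity <- match.arg(zygosity)
  st <- theta_to_struct(spec, theta, sex = sex)
  if (st$pen > 1e-8) {
    stop("theta violates the unit liability variance constraint", call. = FALSE)
  }
  b <- struct_blocks(spec, st, kappa = if (zygosity == "MZ") 1 else 0.5)
  p <- length(spec$phenotypes)
  out <- rbind(cbind(b$W, b$X), cbind(t(b$X), b$W))
  nm <- c(paste0(spec$phenotypes, "_t1"), paste0(spec$phenotypes, "_t2"))
  dimnames(out) <- list(nm, nm)
  out
}

# Moment vector in group_moments order (within j<m, then cross j<=m),
# with soft handling of constraint violations (used inside optimization).
model_implied_moments <- function(spec, theta, zygosity, sex = NA) {
  st <- theta_to_struct(spec, theta, sex = sex)
  b <- struct_blocks(spec, st, kappa = if (zygosity == "MZ") 1 else 0.5)
  p <- length(spec$phenotypes)
  idx <- moment_index(p, spec$phenotypes)
  vals <- numeric(nrow(idx))
  for (k in seq_len(nrow(idx))) {
    vals[k] <- if (idx$kind[k] == "within") {
      b$W[idx$j[k], idx$m[k]]
    } else {
      b$X[idx$j[k], idx$m[k]]
    }
  }
  stats::setNames(vals, idx$name)
}

#' Standardized variance decomposition
#'
#' Proportions of each phenotype's unit liability variance: squared general
#' loadings (summed over general factors), the signed specific A/C variance
#' components (reported raw; a small negative value indicates a boundary
#' solution), and the computed specific-E share. For common pathway models
#' the general proportions are
#' routed through the latent factor (`lambda^2 * a_F^2` etc.) and the
#' factor-level shares are attached as attributes `factor_shares`
#' (`a_F^2, c_F^2, e_F^2`) and a `communality` column (`lambda^2`).
#'
#' @param spec A `model_spec`.
#' @param theta Named parameter vector.
#' @param sex For sex-specific specs, `"M"` or `"F"`.
#' @return Tibble, one row per phenotype; the six proportions sum to 1.
#' @export
standardize <- function(spec, theta, sex = NA) {
  st <- theta_to_struct(spec, theta, sex = sex)
  out <- tibble::tibble(
    phenotype = spec$phenotypes,
    general_a = rowSums(st$La^2),
    general_c = rowSums(st$Lc^2),
    general_e = rowSums(st$Le^2),
    specific_a = st$v_sa,
    specific_c = st$v_sc,
    specific_e = st$se^2
  )
  if (spec$kind == "cpm") {
    # route the floored e_F through the reported proportions so rows
    # still sum to one exactly
    lam2 <- st$lambda^2
    out$general_a <- lam2 * st$aF^2
    out$general_c <- lam2 * st$cF^2
    out$general_e <- lam2 * st$eF^2
    out$communality <- lam2 * (st$aF^2 + st$cF^2 + st$eF^2)
    attr(out, "factor_shares") <- c(
      a_F2 = st$aF^2, c_F2 = st$cF^2, e_F2 = st$eF^2
    )
  }
  out
}

# Analytic (population) moments for a spec + theta: a list shaped like
# all_group_moments() output with exact model-implied correlations and
# unit weights, for self-consistency and oracle tests.
population_moments <- function(spec, theta, se = 1, n_pairs = 1e6) {
  p <- length(spec$phenotypes)
  idx <- moment_index(p, spec$phenotypes)
  out <- purrr::map(ZYG_GROUPS, function(g) {
    zyg <- group_zygosity(g)
    sx <- if (spec$sex_specific) group_sex(g) else NA
    vals <- model_implied_moments(spec, theta, zyg, sex = sx)
    mom <- dplyr::mutate(idx,
      r = as.numeric(vals), se = se, n = n_pairs,
      corrected = FALSE, boundary = FALSE
    )
    structure(
      list(
        group = g, codebook = spec$codebook,
        thresholds = tibble::tibble(
          phenotype = spec$phenotypes, tau = 0, se = se,
          n = 2 * n_pairs, p_obs = 0.5
        ),
        moments = mom, corr = assemble_corr(mom, p, spec$phenotypes),
        acov_diag = stats::setNames(rep(se^2, nrow(mom)), mom$name),
        acov_full = NULL, n_pairs = n_pairs, n_complete = n_pairs,
        n_individuals = 2 * n_pairs, dropped = character(0),
        acov_B = NA_integer_
      ),
      class = "group_moments"
    )
  })
  stats::setNames(out, ZYG_GROUPS)
}
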