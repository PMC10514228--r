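# Declarative structural model specifications: univariate ACE, bivariate
# Cholesky, independent pathway (IPM), and common pathway (CPM) models on
# the liability scale. A spec records which path coefficients are free;
# the per-phenotype specific-E coefficient is never free - it is computed
# from the unit liability variance constraint (and for the CPM the
# factor-level e_F likewise) - so every admissible parameter vector yields
# an exactly standardized solution.

new_model_spec <- function(kind, codebook, mask_a, mask_c, mask_e,
                           smask_a, smask_c, cpm_lambda = NULL,
                           sex_specific = FALSE, label = kind) {
  cb <- assert_codebook(codebook)
  p <- nrow(cb)
  spec <- structure(
    list(
      kind = kind, codebook = cb, phenotypes = cb$name,
      mask_a = mask_a, mask_c = mask_c, mask_e = mask_e,
      smask_a = as.logical(smask_a), smask_c = as.logical(smask_c),
      cpm_lambda = cpm_lambda, sex_specific = sex_specific, label = label
    ),
    class = "model_spec"
  )
  spec$par_info <- build_par_info(spec)
  spec$plan <- build_plan(spec)
  spec
}

# Positional index plan for fast theta decoding (avoids name lookups in
# the optimizer's objective).
build_plan <- function(spec) {
  info <- spec$par_info
  p <- length(spec$phenotypes)
  one_sex <- function(sx) {
    sel <- if (is.na(sx)) seq_len(nrow(info)) else which(info$sex == sx)
    sub <- info[sel, ]
    jrow <- match(sub$phenotype, spec$phenotypes)
    comp_plan <- function(block) {
      i <- which(sub$block == block)
      list(pos = sel[i], row = jrow[i], col = sub$factor[i])
    }
    list(
      ga = comp_plan("ga"), gc = comp_plan("gc"), ge = comp_plan("ge"),
      sa = comp_plan("sa"), sc = comp_plan("sc"),
      lambda = comp_plan("lambda"),
      aF = sel[which(sub$block == "aF")], cF = sel[which(sub$block == "cF")]
    )
  }
  if (spec$sex_specific) {
    list(M = one_sex("M"), F = one_sex("F"))
  } else {
    list(all = one_sex(NA))
  }
}

build_par_info <- function(spec) {
  p <- length(spec$phenotypes)
  nm <- spec$phenotypes
  rows <- list()
  add <- function(name, block, factor = NA_integer_, phenotype = NA_character_) {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      name = name, block = block, factor = factor, phenotype = phenotype
    )
  }
  if (spec$kind == "cpm") {
    for (j in which(spec$cpm_lambda)) {
      add(paste0("lambda_", nm[j]), "lambda", 1L, nm[j])
    }
    add("a_F", "aF"); add("c_F", "cF")
  } else {
    for (comp in c("a", "c", "e")) {
      mask <- spec[[paste0("mask_", comp)]]
      if (ncol(mask) > 0) {
        for (k in seq_len(ncol(mask))) {
          for (j in which(mask[, k] != 0)) {
            add(paste0(comp, k, "_", nm[j]), paste0("g", comp), as.integer(k), nm[j])
          }
        }
      }
    }
  }
  for (j in which(spec$smask_a)) add(paste0("as_", nm[j]), "sa", NA_integer_, nm[j])
  for (j in which(spec$smask_c)) add(paste0("cs_", nm[j]), "sc", NA_integer_, nm[j])
  info <- dplyr::bind_rows(rows)
  if (spec$sex_specific) {
    info <- dplyr::bind_rows(
      dplyr::mutate(info, sex = "M", name = paste0(.data$name, ".M")),
      dplyr::mutate(info, sex = "F", name = paste0(.data$name, ".F"))
    )
  } else {
    info$sex <- NA_character_
  }
  if (anyDuplicated(info$name)) stop("duplicate parameter names", call. = FALSE)
  info
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf(
    "<model_spec %s '%s'> %d phenotypes, %d free parameters%s\n",
    x$kind, x$label, length(x$phenotypes), nrow(x$par_info),
    if (x$sex_specific) " (sex-specific)" else ""
  ))
  invisible(x)
}

#' Number of free parameters of a model spec
#' @param spec A `model_spec`.
#' @return Integer count.
#' @export
n_free_params <- function(spec) nrow(spec$par_info)

echelon_mask <- function(p, k) {
  # full loadings with upper-corner zeros for rotational identification:
  # factor k' has its first (k' - 1) loadings fixed to zero
  m <- matrix(1, p, k)
  if (k > 1) for (kk in 2:k) m[seq_len(kk - 1), kk] <- 0
  m
}

#' Build an independent pathway model specification
#'
#' General A, C, and E factors load on every phenotype (echelon-identified
#' when a component has two factors, or split by codebook `class_tag` with
#' `pattern = "by_class_tag"`), plus phenotype-specific A and C factors;
#' specific E is always present and computed from unit liability variance.
#' `drops` fixes named loadings to zero to form reduced models.
#'
#' @param codebook A [codebook()].
#' @param n_a,n_c,n_e Number of general factors per component (0, 1, or 2).
#' @param pattern `"single"` (factors load on all phenotypes) or
#'   `"by_class_tag"` (two factors split prescription vs illicit; requires
#'   the component count to be 2).
#' @param drops Named list of phenotype-name vectors fixing loadings to
#'   zero: elements `general_a`, `general_c`, `general_e` (drop that
#'   phenotype's loading on every factor of the component), `specific_a`,
#'   `specific_c`. Dropping specific E is an error.
#' @param label Optional display label.
#' @return A `model_spec`.
#' @export
build_ipm_spec <- function(codebook, n_a, n_c, n_e,
                           pattern = c("single", "by_class_tag"),
                           drops = list(), label = NULL) {
  pattern <- match.arg(pattern)
  cb <- assert_codebook(codebook)
  p <- nrow(cb)
  counts <- c(a = n_a, c = n_c, e = n_e)
  if (any(!counts %in% 0:2)) stop("factor counts must be 0, 1, or 2", call. = FALSE)
  if (!is.null(drops$specific_e)) {
    stop("specific E factors cannot be dropped", call. = FALSE)
  }
  bad <- setdiff(names(drops), c("general_a", "general_c", "general_e",
    "specific_a", "specific_c"))
  if (length(bad) > 0) stop("unknown drops: ", paste(bad, collapse = ", "), call. = FALSE)
  mk_mask <- function(k, comp) {
    if (k == 0) return(matrix(0, p, 0))
    if (pattern == "by_class_tag") {
      if (k != 2) stop("pattern 'by_class_tag' requires a factor count of 2", call. = FALSE)
      m <- cbind(
        as.numeric(cb$class_tag == "prescription"),
        as.numeric(cb$class_tag == "illicit")
      )
    } else {
      m <- echelon_mask(p, k)
    }
    dropped <- drops[[paste0("general_", comp)]]
    if (!is.null(dropped)) {
      miss <- setdiff(dropped, cb$name)
      if (length(miss)) stop("unknown phenotype in drops: ", paste(miss, collapse = ", "), call. = FALSE)
      m[match(dropped, cb$name), ] <- 0
    }
    m
  }
  smask <- function(which_comp) {
    s <- rep(TRUE, p)
    dropped <- drops[[paste0("specific_", which_comp)]]
    if (!is.null(dropped)) {
      miss <- setdiff(dropped, cb$name)
      if (length(miss)) stop("unknown phenotype in drops: ", paste(miss, collapse = ", "), call. = FALSE)
      s[match(dropped, cb$name)] <- FALSE
    }
    s
  }
  if (is.null(label)) {
    label <- sprintf("IP %d-%d-%d%s", n_a, n_c, n_e,
      if (pattern == "by_class_tag") " (class)" else ""
    )
  }
  new_model_spec("ipm", cb,
    mask_a = mk_mask(n_a, "a"), mask_c = mk_mask(n_c, "c"),
    mask_e = mk_mask(n_e, "e"),
    smask_a = smask("a"), smask_c = smask("c"), label = label
  )
}

#' Build a common pathway model specification
#'
#' A single latent general phenotype with loadings `lambda` mediates all
#' shared variance; the factor itself decomposes into A, C, E with
#' `a_F^2 + c_F^2 + e_F^2 = 1` (`e_F` computed). Phenotype-specific A and C
#' factors are free unless dropped; specific E is always present.
#'
#' @inheritParams build_ipm_spec
#' @param drops Named list with optional `specific_a`, `specific_c`
#'   phenotype vectors (and `lambda` to fix a loading to zero).
#' @return A `model_spec`.
#' @export
build_cpm_spec <- function(codebook, drops = list(), label = "CP-1") {
  cb <- assert_codebook(codebook)
  p <- nrow(cb)
  if (!is.null(drops$specific_e)) {
    stop("specific E factors cannot be dropped", call. = FALSE)
  }
  lam <- rep(TRUE, p)
  if (!is.null(drops$lambda)) lam[match(drops$lambda, cb$name)] <- FALSE
  sm <- function(comp) {
    s <- rep(TRUE, p)
    d <- drops[[paste0("specific_", comp)]]
    if (!is.null(d)) s[match(d, cb$name)] <- FALSE
    s
  }
  new_model_spec("cpm", cb,
    mask_a = matrix(0, p, 0), mask_c = matrix(0, p, 0),
    mask_e = matrix(0, p, 0),
    smask_a = sm("a"), smask_c = sm("c"),
    cpm_lambda = lam, label = label
  )
}

#' Univariate ACE model specification
#'
#' Free path coefficients `a` and `c`; `e` computed from unit variance.
#' With `sex_specific = TRUE` the structural parameters are duplicated
#' across male and female groups (thresholds are always sex-specific in
#' stage 1).
#'
#' @param codebook A one-phenotype [codebook()] (or a larger one plus
#'   `phenotype` to select).
#' @param phenotype Phenotype name when `codebook` has several.
#' @param sex_specific Duplicate structural parameters by sex.
#' @return A `model_spec`.
#' @export
univariate_ace_spec <- function(codebook, phenotype = NULL, sex_specific = FALSE) {
  cb <- assert_codebook(codebook)
  if (!is.null(phenotype)) {
    cb <- codebook(
      phenotype,
      label = cb$label[match(phenotype, cb$name)],
      class_tag = cb$class_tag[match(phenotype, cb$name)]
    )
  }
  if (nrow(cb) != 1) stop("univariate spec needs exactly one phenotype", call. = FALSE)
  new_model_spec("univariate_ace", cb,
    mask_a = matrix(1, 1, 1), mask_c = matrix(1, 1, 1),
    mask_e = matrix(0, 1, 0),
    smask_a = FALSE, smask_c = FALSE,
    sex_specific = sex_specific,
    label = paste0("ACE ", cb$name)
  )
}

#' Bivariate Cholesky ACE specification
#'
#' Lower-triangular A and C path matrices (three free coefficients each)
#' plus the cross E path `e21`; the diagonal E entries are the computed
#' specific-E coefficients, so the model is exactly identified by the
#' seven distinct liability moments of a two-phenotype twin design.
#'
#' @param codebook A two-phenotype [codebook()].
#' @return A `model_spec`.
#' @export
bivariate_cholesky_spec <- function(codebook) {
  cb <- assert_codebook(codebook)
  if (nrow(cb) != 2) stop("bivariate Cholesky needs exactly two phenotypes", call. = FALSE)
  lower <- matrix(c(1, 1, 0, 1), 2, 2) # a11, a21, a22
  new_model_spec("bivariate_cholesky", cb,
    mask_a = lower, mask_c = lower,
    mask_e = matrix(c(0, 1), 2, 1), # e21 only; e11, e22 computed
    smask_a = c(FALSE, FALSE), smask_c = c(FALSE, FALSE),
    label = paste0("Cholesky ", paste(cb$name, collapse = "+"))
  )
}

# --- parameter vector handling ---------------------------------------------

base_par_names <- function(spec) {
  info <- spec$par_info
  if (spec$sex_specific) unique(sub("\\.(M|F)$", "", info$name)) else info$name
}

# Decode theta (in par_info order) into path matrices for one sex.
# Returns loading matrices, specific coefficients (specific E computed),
# the per-phenotype residual before flooring, and the constraint penalty.
theta_to_struct <- function(spec, theta, sex = NA) {
  nms <- names(theta)
  if (!is.null(nms) && !identical(nms, spec$par_info$name)) {
    theta <- theta[spec$par_info$name]
  }
  pl <- if (spec$sex_specific) spec$plan[[sex]] else spec$plan$all
  p <- length(spec$phenotypes)
  pen <- 0
  if (spec$kind == "cpm") {
    lambda <- rep(0, p)
    lambda[pl$lambda$row] <- theta[pl$lambda$pos]
    aF <- theta[[pl$aF]]; cF <- theta[[pl$cF]]
    fres <- 1 - aF^2 - cF^2
    pen <- pen + max(0, -fres)^2
    eF <- sqrt(max(fres, 0))
    La <- matrix(lambda * aF, p, 1)
    Lc <- matrix(lambda * cF, p, 1)
    Le <- matrix(lambda * eF, p, 1)
    explained_gen <- lambda^2 # lambda^2 * (aF^2+cF^2+eF^2 floored)
  } else {
    load_mat <- function(cp, k) {
      L <- matrix(0, p, k)
      if (length(cp$pos) > 0) L[cbind(cp$row, cp$col)] <- theta[cp$pos]
      L
    }
    La <- load_mat(pl$ga, ncol(spec$mask_a))
    Lc <- load_mat(pl$gc, ncol(spec$mask_c))
    Le <- load_mat(pl$ge, ncol(spec$mask_e))
    lambda <- NULL; aF <- cF <- eF <- NA_real_
    explained_gen <- rowSums(La^2) + rowSums(Lc^2) + rowSums(Le^2)
  }
  # specific A and C are unbounded signed variance components: the moment
  # structure is linear in them, so Wald tests of dropping a specific
  # factor stay chi-square calibrated when the true value is zero
  v_sa <- rep(0, p); v_sc <- rep(0, p)
  v_sa[pl$sa$row] <- theta[pl$sa$pos]
  v_sc[pl$sc$row] <- theta[pl$sc$pos]
  resid <- 1 - explained_gen - v_sa - v_sc
  pen <- pen + sum(pmax(0, -resid)^2)
  # soft box: standardized loadings cannot exceed unit variance, and the
  # signed specific variances may dip only moderately below zero. This
  # bounds the flat ridge (loading^2 + specific variance ~ constant) that
  # opens up when a general loading is truly zero.
  pen <- pen + sum(pmax(La^2 - 1, 0)^2) + sum(pmax(Lc^2 - 1, 0)^2) +
    sum(pmax(Le^2 - 1, 0)^2) +
    sum(pmax(-v_sa - 0.3, 0)^2) + sum(pmax(-v_sc - 0.3, 0)^2)
  # minuscule ridge on the signed variances (see ridge_weight in the
  # objective): selects the v ~ 0 point of an exactly flat
  # loading-vs-specific-variance trade-off without materially biasing
  # identified estimates
  ridge <- sum(v_sa^2) + sum(v_sc^2)
  se <- sqrt(pmax(resid, 0))
  list(
    La = La, Lc = Lc, Le = Le, v_sa = v_sa, v_sc = v_sc, se = se,
    resid = resid, pen = pen, ridge = ridge,
    lambda = lambda, aF = aF, cF = cF, eF = eF
  )
}

#' Falconer closed-form univariate estimates
#'
#' `a2 = 2 (r_MZ - r_DZ)`, `c2 = 2 r_DZ - r_MZ`, `e2 = 1 - r_MZ`. Raw
#' values are reported without truncation; `boundary` flags any negative
#' component.
#'
#' @param r_mz,r_dz Cross-twin same-trait correlations.
#' @return Tibble with columns `a2`, `c2`, `e2`, `boundary`.
#' @examples
#' falconer_estimates(0.8, 0.5) # a2 = .6, c2 = .2, e2 = .2
#' @export
falconer_estimates <- function(r_mz, r_dz) {
  stopifnot(all(abs(r_mz) <= 1), all(abs(r_dz) <= 1))
  a2 <- 2 * (r_mz - r_dz)
  c2 <- 2 * r_dz - r_mz
  e2 <- 1 - r_mz
  tibble::tibble(a2 = a2, c2 = c2, e2 = e2, boundary = a2 < 0 | c2 < 0 | e2 < 0)
}
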