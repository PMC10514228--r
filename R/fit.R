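# Stage 2: fit a structural specification to multi-group liability moments
# by (diagonally) weighted least squares, with multi-start quasi-Newton
# optimization, sandwich covariances, and convergence diagnostics.

# Assemble per-group moment vectors, weights, and bookkeeping for a fit.
collect_moment_data <- function(spec, moments, weight_mode) {
  if (inherits(moments, "group_moments")) moments <- list(moments)
  groups <- vapply(moments, function(m) m$group, character(1))
  names(moments) <- groups
  p <- length(spec$phenotypes)
  for (m in moments) {
    if (!identical(m$codebook$name, spec$phenotypes)) {
      stop("moment phenotypes do not match the model spec", call. = FALSE)
    }
  }
  zyg <- group_zygosity(groups)
  has_a <- any(spec$par_info$block %in% c("ga", "sa", "aF"))
  has_c <- any(spec$par_info$block %in% c("gc", "sc", "cF"))
  if (has_a && has_c && length(unique(zyg)) < 2) {
    stop("need both MZ and DZ groups to separate A from C", call. = FALSE)
  }
  idx <- moment_index(p, spec$phenotypes)
  per_group <- purrr::map(moments, function(m) {
    r <- m$moments$r
    v <- m$moments$se^2
    used <- is.finite(r) & (weight_mode == "identity" | (is.finite(v) & v > 0))
    w <- switch(weight_mode,
      identity = rep(1, sum(used)),
      diagonal = 1 / v[used],
      full = NULL
    )
    Wi <- NULL
    if (weight_mode == "full") {
      if (is.null(m$acov_full)) {
        stop("weight_mode = 'full' needs moments with a bootstrap acov", call. = FALSE)
      }
      Wi <- solve(psd_smooth(m$acov_full[used, used, drop = FALSE]))
    }
    G_full <- if (is.null(m$acov_full)) NULL else m$acov_full[used, used, drop = FALSE]
    list(
      s = r[used], w = w, Wi = Wi, used = used, acov = v[used],
      acov_full = G_full, names = m$moments$name[used]
    )
  })
  n_used <- sum(vapply(per_group, function(g) length(g$s), numeric(1)))
  if (nrow(spec$par_info) > n_used) {
    stop(sprintf(
      "model is not identified: %d free parameters for %d distinct moments",
      nrow(spec$par_info), n_used
    ), call. = FALSE)
  }
  list(
    moments = moments, groups = groups, zyg = zyg,
    sex = group_sex(groups), per_group = per_group, idx = idx,
    n_used = n_used,
    n_total = sum(vapply(moments, function(m) m$n_individuals, numeric(1)))
  )
}

psd_smooth <- function(S, floor_frac = 1e-6) {
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  fl <- floor_frac * mean(diag(S))
  if (all(e$values >= fl)) return(S)
  e$vectors %*% diag(pmax(e$values, fl), nrow(S)) %*% t(e$vectors)
}

# Fast model-implied moment function: decodes theta once per distinct sex
# and builds the within/cross blocks once per (sex, zygosity), with
# precomputed linear indices. Returns per-group sigma vectors + penalty.
make_sigma_all <- function(spec, md) {
  p <- length(spec$phenotypes)
  idx <- md$idx
  li <- (idx$m - 1L) * p + idx$j
  is_w <- idx$kind == "within"
  li_w <- li[is_w]; li_x <- li[!is_w]
  pos_w <- which(is_w); pos_x <- which(!is_w)
  M <- nrow(idx)
  G <- length(md$groups)
  sexes <- if (spec$sex_specific) md$sex else rep("all", G)
  kappas <- ifelse(md$zyg == "MZ", 1, 0.5)
  bkey <- paste0(sexes, "/", md$zyg)
  used <- purrr::map(md$per_group, "used")
  function(theta) {
    structs <- list(); blocks <- list()
    pen <- 0; ridge <- 0
    sig <- vector("list", G)
    for (gi in seq_len(G)) {
      sk <- sexes[gi]
      if (is.null(structs[[sk]])) {
        structs[[sk]] <- theta_to_struct(spec, theta,
          sex = if (spec$sex_specific) sk else NA
        )
        pen <- pen + structs[[sk]]$pen
        ridge <- ridge + structs[[sk]]$ridge
      }
      bk <- bkey[gi]
      if (is.null(blocks[[bk]])) {
        blocks[[bk]] <- struct_blocks(spec, structs[[sk]], kappa = kappas[gi])
      }
      b <- blocks[[bk]]
      vals <- numeric(M)
      vals[pos_w] <- b$W[li_w]
      vals[pos_x] <- b$X[li_x]
      sig[[gi]] <- vals[used[[gi]]]
    }
    list(sigma = sig, pen = pen, ridge = ridge)
  }
}

make_objective <- function(spec, md, pen_w, ridge_w = 0) {
  sigma_all <- make_sigma_all(spec, md)
  G <- length(md$groups)
  s <- purrr::map(md$per_group, "s")
  w <- purrr::map(md$per_group, "w")
  Wi <- purrr::map(md$per_group, "Wi")
  function(theta) {
    sg <- sigma_all(theta)
    total <- 0
    for (gi in seq_len(G)) {
      r <- s[[gi]] - sg$sigma[[gi]]
      total <- total + if (is.null(Wi[[gi]])) {
        sum(w[[gi]] * r * r)
      } else {
        as.numeric(r %*% Wi[[gi]] %*% r)
      }
    }
    total + pen_w * sg$pen + ridge_w * sg$ridge
  }
}

# Crude data-driven start: Falconer components from same-trait cross-twin
# correlations, spread over the free general and specific paths.
crude_start <- function(spec, md) {
  p <- length(spec$phenotypes)
  idx <- md$idx
  same <- which(idx$kind == "cross" & idx$j == idx$m)
  r_by_zyg <- function(z) {
    gs <- which(md$zyg == z)
    if (length(gs) == 0) return(rep(0.3, p))
    vals <- sapply(gs, function(gi) {
      full <- rep(NA_real_, nrow(idx))
      full[md$per_group[[gi]]$used] <- md$per_group[[gi]]$s
      full[same]
    })
    out <- rowMeans(as.matrix(vals), na.rm = TRUE)
    out[!is.finite(out)] <- 0.3
    out
  }
  r_mz <- r_by_zyg("MZ"); r_dz <- r_by_zyg("DZ")
  fal <- falconer_estimates(r_mz, r_dz)
  a2 <- pmin(pmax(fal$a2, 0.05), 0.85)
  c2 <- pmin(pmax(fal$c2, 0.02), 0.85)
  e2 <- pmax(1 - a2 - c2, 0.05)
  nm <- spec$phenotypes
  theta <- stats::setNames(numeric(nrow(spec$par_info)), spec$par_info$name)
  base_val <- function(info_row) {
    j <- match(info_row$phenotype, nm)
    switch(info_row$block,
      ga = sqrt(a2[j] * 0.7 / max(1, ncol(spec$mask_a))),
      gc = sqrt(c2[j] * 0.7 / max(1, ncol(spec$mask_c))),
      ge = sqrt(e2[j] * 0.4 / max(1, ncol(spec$mask_e))),
      sa = a2[j] * 0.3,
      sc = c2[j] * 0.3,
      lambda = sqrt(0.5),
      aF = sqrt(mean(a2)),
      cF = sqrt(mean(c2)),
      0.2
    )
  }
  for (i in seq_len(nrow(spec$par_info))) {
    theta[i] <- base_val(spec$par_info[i, ])
  }
  repair_start(spec, theta)
}

# Scale back any phenotype whose explained variance exceeds 0.9 so the
# start is strictly feasible.
repair_start <- function(spec, theta) {
  for (sx in if (spec$sex_specific) c("M", "F") else NA) {
    st <- theta_to_struct(spec, theta, sex = sx)
    expl <- 1 - st$resid
    for (j in which(expl > 0.9)) {
      f <- sqrt(0.85 / expl[j])
      sel <- spec$par_info$phenotype %in% spec$phenotypes[j]
      if (spec$sex_specific) sel <- sel & spec$par_info$sex == sx
      theta[spec$par_info$name[sel]] <- theta[spec$par_info$name[sel]] * f
    }
    if (spec$kind == "cpm") {
      fvar <- st$aF^2 + st$cF^2
      if (fvar > 0.9) {
        sel <- spec$par_info$block %in% c("aF", "cF")
        if (spec$sex_specific) sel <- sel & spec$par_info$sex == sx
        theta[spec$par_info$name[sel]] <-
          theta[spec$par_info$name[sel]] * sqrt(0.85 / fvar)
      }
    }
  }
  theta
}

canonicalize_theta <- function(spec, theta) {
  info <- spec$par_info
  flip_set <- function(names) theta[names] <<- -theta[names]
  for (sx in if (spec$sex_specific) c("M", "F") else NA) {
    sel_sex <- if (is.na(sx)) rep(TRUE, nrow(info)) else info$sex == sx
    if (spec$kind == "cpm") {
      lam <- info$name[sel_sex & info$block == "lambda"]
      if (length(lam) > 0 && theta[lam[1]] < 0) flip_set(lam)
      for (b in c("aF", "cF")) {
        nmb <- info$name[sel_sex & info$block == b]
        if (length(nmb) > 0 && theta[nmb] < 0) flip_set(nmb)
      }
    } else {
      for (comp in c("a", "c", "e")) {
        mask <- spec[[paste0("mask_", comp)]]
        if (ncol(mask) == 0) next
        if (spec$kind == "bivariate_cholesky" && comp == "e") next
        for (k in seq_len(ncol(mask))) {
          nms <- info$name[sel_sex & info$block == paste0("g", comp) &
            info$factor == k]
          if (length(nms) > 0 && theta[nms[1]] < 0) flip_set(nms)
        }
      }
    }
    # specific A/C are signed variance components; their sign is data, not
    # an identification artifact - leave them untouched
  }
  theta
}

#' Fit a structural model by weighted least squares
#'
#' Minimizes `F(theta) = sum_g (s_g - sigma_g(theta))' W_g^{-1}
#' (s_g - sigma_g(theta))` over the distinct correlation moments of each
#' zygosity-sex group, where `W_g` is the diagonal of the stage-1
#' asymptotic covariance (`"diagonal"`, the robust/DWLS default), the full
#' bootstrap acov (`"full"`), or the identity (`"identity"`). Thresholds
#' are fixed at their stage-1 estimates. Optimization is multi-start
#' quasi-Newton (`nlminb`) from a crude data-driven start plus uniform
#' jitter, with sub-seeds derived from `seed`; the best converged solution
#' is returned with sign-canonicalized factors. Structural parameters are
#' shared across groups (except sex-specific specs, where they are
#' duplicated by sex).
#'
#' Nonconvergence is an ordinary reportable outcome: the returned object
#' has `converged = FALSE` rather than raising, so model ladders can
#' record it.
#'
#' @param spec A `model_spec`.
#' @param moments A `group_moments` object or (named) list of them, e.g.
#'   from [all_group_moments()].
#' @param weight_mode `"diagonal"`, `"full"`, or `"identity"`.
#' @param n_starts Number of jittered starts (default 5).
#' @param seed Seed for start jitter.
#' @param theta_start Optional named start vector (used as the first start).
#' @return A `twin_fit` object.
#' @export
fit_wls <- function(spec, moments, weight_mode = c("diagonal", "full", "identity"),
                    n_starts = 5, seed = 1, theta_start = NULL) {
  weight_mode <- match.arg(weight_mode)
  md <- collect_moment_data(spec, moments, weight_mode)
  max_w <- max(unlist(purrr::map(md$per_group, function(g) {
    if (is.null(g$w)) diag(g$Wi) else g$w
  })))
  pen_w <- 1e5 * max(1, max_w)
  ridge_w <- 1e-6 * max(1, max_w)
  obj <- make_objective(spec, md, pen_w, ridge_w)
  start0 <- crude_start(spec, md)
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  starts <- purrr::map(seq_len(n_starts), function(i) {
    if (i == 1 && !is.null(theta_start)) {
      return(repair_start(spec, theta_start[spec$par_info$name]))
    }
    if (i == 1) return(start0)
    repair_start(spec, start0 + stats::runif(length(start0), -0.2, 0.2))
  })
  runs <- purrr::map(starts, function(s0) {
    fit <- tryCatch(
      stats::nlminb(s0, obj, control = list(
        iter.max = 2000, eval.max = 8000, rel.tol = 1e-12
      )),
      error = function(e) NULL
    )
    if (is.null(fit)) return(NULL)
    # polish from the solution for tight convergence
    fit2 <- tryCatch(
      stats::nlminb(fit$par, obj, control = list(
        iter.max = 300, eval.max = 1500, rel.tol = 1e-14
      )),
      error = function(e) fit
    )
    if (!is.null(fit2$objective) && fit2$objective <= fit$objective) fit2 else fit
  })
  ok <- !vapply(runs, is.null, logical(1))
  if (!any(ok)) {
    return(new_twin_fit(spec, md, theta = start0, converged = FALSE,
      message = "all starts failed", weight_mode = weight_mode,
      starts_f = rep(NA_real_, n_starts)))
  }
  fvals <- vapply(runs, function(r) if (is.null(r)) Inf else r$objective, numeric(1))
  best <- runs[[which.min(fvals)]]
  # final polish with a central-difference gradient: nlminb's internal
  # forward differences stall around 1e-6 in the parameters on large flat
  # problems
  polish <- tryCatch(
    stats::nlminb(best$par, obj,
      gradient = function(th) pracma::grad(obj, th),
      control = list(iter.max = 200, eval.max = 1000, rel.tol = 1e-15)
    ),
    error = function(e) NULL
  )
  if (!is.null(polish) && is.finite(polish$objective) &&
    polish$objective <= best$objective + 1e-12) {
    best <- polish
  }
  # Gauss-Newton refinement: quadratic convergence near the optimum pushes
  # weakly identified directions well past where quasi-Newton stalls
  best_par <- gauss_newton_refine(spec, md, stats::setNames(best$par, spec$par_info$name), obj)
  theta <- canonicalize_theta(spec, best_par)
  f_at <- obj(theta) # canonicalization leaves F unchanged; re-evaluate to be safe
  grad <- tryCatch(pracma::grad(obj, theta), error = function(e) rep(NA_real_, length(theta)))
  grad_norm <- max(abs(grad))
  hess_pd <- NA
  if (length(theta) <= 120) {
    H <- tryCatch(pracma::hessian(obj, theta), error = function(e) NULL)
    if (!is.null(H)) {
      ev <- tryCatch(eigen((H + t(H)) / 2, symmetric = TRUE, only.values = TRUE)$values,
        error = function(e) NA_real_
      )
      hess_pd <- all(is.finite(ev)) && min(ev) > -1e-6 * max(1, max(abs(ev)))
    }
  }
  pen_at <- total_penalty(spec, theta)
  f_min <- f_at - pen_w * pen_at - ridge_w * total_ridge(spec, theta)
  boundary <- boundary_flag(spec, theta)
  tol_grad <- 1e-6 * (1 + max_w) * max(1, f_min)
  converged <- is.finite(grad_norm) && grad_norm <= tol_grad &&
    (is.na(hess_pd) || hess_pd) && pen_at < 1e-10
  msg <- if (converged) "converged" else {
    paste0(
      "not converged:",
      if (!is.finite(grad_norm) || grad_norm > tol_grad) " gradient" else "",
      if (isFALSE(hess_pd)) " hessian" else "",
      if (pen_at >= 1e-10) " constraint-violation" else ""
    )
  }
  new_twin_fit(spec, md, theta = theta, converged = converged, message = msg,
    weight_mode = weight_mode, f_min = f_min, grad_norm = grad_norm,
    hessian_pd = hess_pd, boundary = boundary, starts_f = fvals)
}

# Refine the quasi-Newton solution by Gauss-Newton steps on the pure
# (unpenalized, unridged) WLS discrepancy: quadratic convergence pushes
# weakly identified directions well past where quasi-Newton stalls, and
# removes the ridge's tiny pull on the final estimate. Steps that
# activate the feasibility penalty are rejected.
gauss_newton_refine <- function(spec, md, theta, obj, max_iter = 4L) {
  sigma_all <- make_sigma_all(spec, md)
  s_stack <- unlist(purrr::map(md$per_group, "s"))
  Wi <- fit_weight_inverse(list(md = md))
  wls_f <- function(sg) {
    r <- s_stack - unlist(sg$sigma)
    sum(r * unlist_block_apply(Wi, r))
  }
  sg_cur <- sigma_all(theta)
  if (sg_cur$pen > 0) return(theta)
  f_cur <- wls_f(sg_cur)
  for (it in seq_len(max_iter)) {
    r <- s_stack - unlist(sg_cur$sigma)
    J <- tryCatch(
      pracma::jacobian(function(th) unlist(sigma_all(th)$sigma), theta),
      error = function(e) NULL
    )
    if (is.null(J)) break
    WiJ <- block_apply(Wi, J)
    d <- tryCatch(
      as.numeric(pracma::pinv(crossprod(J, WiJ)) %*% crossprod(WiJ, r)),
      error = function(e) NULL
    )
    if (is.null(d) || !all(is.finite(d))) break
    cand <- theta + d
    sg_new <- sigma_all(cand)
    f_new <- wls_f(sg_new)
    if (sg_new$pen > 0 || !is.finite(f_new) || f_new >= f_cur) break
    theta <- cand; f_cur <- f_new; sg_cur <- sg_new
    if (sqrt(sum(d^2)) < 1e-12) break
  }
  theta
}

unlist_block_apply <- function(Wi_list, v) {
  as.numeric(block_apply(Wi_list, matrix(v, ncol = 1)))
}

total_penalty <- function(spec, theta) {
  sum(vapply(if (spec$sex_specific) c("M", "F") else NA, function(sx) {
    theta_to_struct(spec, theta, sex = sx)$pen
  }, numeric(1)))
}

total_ridge <- function(spec, theta) {
  sum(vapply(if (spec$sex_specific) c("M", "F") else NA, function(sx) {
    theta_to_struct(spec, theta, sex = sx)$ridge
  }, numeric(1)))
}

boundary_flag <- function(spec, theta) {
  any(vapply(if (spec$sex_specific) c("M", "F") else NA, function(sx) {
    st <- theta_to_struct(spec, theta, sex = sx)
    any(st$resid < 1e-6) ||
      (spec$kind == "cpm" && 1 - st$aF^2 - st$cF^2 < 1e-6)
  }, logical(1)))
}

new_twin_fit <- function(spec, md, theta, converged, message, weight_mode,
                         f_min = NA_real_, grad_norm = NA_real_,
                         hessian_pd = NA, boundary = NA, starts_f = NA_real_) {
  dec <- if (spec$sex_specific) {
    dplyr::bind_rows(
      dplyr::mutate(standardize(spec, theta, sex = "M"), sex = "M"),
      dplyr::mutate(standardize(spec, theta, sex = "F"), sex = "F")
    )
  } else {
    standardize(spec, theta)
  }
  structure(
    list(
      spec = spec, theta = theta, F_min = f_min, converged = converged,
      message = message, grad_norm = grad_norm, hessian_pd = hessian_pd,
      boundary = boundary, weight_mode = weight_mode,
      decomposition = dec, n_total = md$n_total,
      groups_used = md$groups, n_moments = md$n_used,
      md = md, vcov = NULL, starts_f = starts_f
    ),
    class = "twin_fit"
  )
}

#' @export
print.twin_fit <- function(x, ...) {
  cat(sprintf(
    "<twin_fit %s '%s'> %s, F_min = %.4g, %d free params, %d moments, groups %s\n",
    x$spec$kind, x$spec$label,
    if (x$converged) "converged" else paste0("NOT converged (", x$message, ")"),
    x$F_min, length(x$theta), x$n_moments, paste(x$groups_used, collapse = "/")
  ))
  if (isTRUE(x$boundary)) cat("  note: solution at a variance boundary\n")
  invisible(x)
}

# Stacked jacobian of the used model moments at theta (central differences).
fit_jacobian <- function(fit) {
  sigma_all <- make_sigma_all(fit$spec, fit$md)
  stack <- function(theta) unlist(sigma_all(theta)$sigma)
  pracma::jacobian(stack, fit$theta)
}

fit_weight_inverse <- function(fit) {
  # block-diagonal W^{-1} as a list of per-group pieces (vector or matrix)
  purrr::map(fit$md$per_group, function(g) if (is.null(g$Wi)) g$w else g$Wi)
}

fit_gamma <- function(fit, require_full = FALSE) {
  purrr::map(fit$md$per_group, function(g) {
    if (!is.null(g$acov_full)) {
      psd_smooth(g$acov_full)
    } else {
      if (require_full) {
        warning(
          "no bootstrap acov available; using the diagonal acov ",
          "(tests may be miscalibrated)",
          call. = FALSE
        )
      }
      diag(g$acov, length(g$acov))
    }
  })
}

block_apply <- function(Wi_list, M) {
  # (block-diagonal W^{-1}) %*% M for stacked row blocks
  sizes <- vapply(Wi_list, function(w) if (is.matrix(w)) nrow(w) else length(w), integer(1))
  stops <- cumsum(sizes); starts <- stops - sizes + 1
  out <- M
  for (i in seq_along(Wi_list)) {
    rows <- starts[i]:stops[i]
    out[rows, ] <- if (is.matrix(Wi_list[[i]])) {
      Wi_list[[i]] %*% M[rows, , drop = FALSE]
    } else {
      Wi_list[[i]] * M[rows, , drop = FALSE]
    }
  }
  out
}

block_diag <- function(blocks) {
  sizes <- vapply(blocks, nrow, integer(1))
  out <- matrix(0, sum(sizes), sum(sizes))
  at <- 0
  for (b in blocks) {
    out[at + seq_len(nrow(b)), at + seq_len(nrow(b))] <- b
    at <- at + nrow(b)
  }
  out
}

#' Sandwich covariance of the structural parameter estimates
#'
#' `(D'W^{-1}D)^{-1} D'W^{-1} Gamma W^{-1} D (D'W^{-1}D)^{-1}` with `D` the
#' Jacobian of the model moments at the estimate and `Gamma` the full
#' stage-1 asymptotic covariance of the sample moments (bootstrap-estimated
#' when available; otherwise the information-based diagonal, with a
#' warning). When `W = Gamma` this reduces to `(D' Gamma^{-1} D)^{-1}`.
#'
#' @param fit A converged `twin_fit`.
#' @return Covariance matrix of `fit$theta` (also cached in `fit$vcov` by
#'   [wald_test()] callers via [add_sandwich()]).
#' @export
sandwich_covariance <- function(fit) {
  if (!fit$converged) stop("fit did not converge", call. = FALSE)
  D <- fit_jacobian(fit)
  Wi <- fit_weight_inverse(fit)
  G <- block_diag(fit_gamma(fit, require_full = TRUE))
  WiD <- block_apply(Wi, D)
  bread_inv <- crossprod(D, WiD)
  ev <- eigen((bread_inv + t(bread_inv)) / 2, symmetric = TRUE)
  tol <- 1e-9 * max(abs(ev$values))
  flat <- which(ev$values <= tol)
  if (length(flat) > 0) {
    # near-zero path coefficients make their Jacobian columns (and the
    # trade-off with the matching specific variance) locally flat - a
    # boundary phenomenon, not a spec defect. Those variance directions
    # are dropped by pseudo-inversion, which makes restrictions touching
    # them conservative. A flat direction carried by a large estimate is
    # genuine non-identification and raises.
    worst_names <- vapply(flat, function(k) {
      fit$spec$par_info$name[which.max(abs(ev$vectors[, k]))]
    }, character(1))
    big <- abs(fit$theta[worst_names]) > 0.2
    if (any(big)) {
      stop(
        "singular information matrix; direction involves parameter '",
        worst_names[which(big)[1]], "'",
        call. = FALSE
      )
    }
    warning(
      "boundary solution: dropping flat variance direction(s) near ",
      paste(unique(worst_names), collapse = ", "), " (pseudo-inverse)",
      call. = FALSE
    )
    bread <- pracma::pinv(bread_inv)
  } else {
    bread <- solve(bread_inv)
  }
  meat <- crossprod(WiD, G %*% WiD)
  V <- bread %*% meat %*% bread
  dimnames(V) <- list(names(fit$theta), names(fit$theta))
  V
}

#' Attach the sandwich covariance to a fit
#'
#' @param fit A converged `twin_fit`.
#' @return The fit with `$vcov` filled.
#' @export
add_sandwich <- function(fit) {
  if (is.null(fit$vcov)) fit$vcov <- sandwich_covariance(fit)
  fit
}
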