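# Bias-corrected accelerated bootstrap confidence intervals for structural
# parameters and variance proportions. Pairs (and singletons) are resampled
# with replacement within each zygosity-sex group; both stages are refitted
# per replicate. The stage-1 refit is computed from resampled pair-level
# cell counts, which is algebraically identical to rebuilding the dataset
# and re-estimating, and vectorizes across replicates.

# Minimal md structure + objective for repeated refits on precomputed
# moment vectors (same shape as collect_moment_data output).
quick_md <- function(spec, groups, s_list, w_list, used_list, n_total) {
  p <- length(spec$phenotypes)
  list(
    moments = NULL, groups = groups, zyg = group_zygosity(groups),
    sex = group_sex(groups),
    per_group = purrr::map(seq_along(groups), function(i) {
      list(
        s = s_list[[i]], w = w_list[[i]], Wi = NULL,
        used = used_list[[i]], acov = 1 / w_list[[i]], acov_full = NULL
      )
    }),
    idx = moment_index(p, spec$phenotypes),
    n_used = sum(lengths(s_list)), n_total = n_total
  )
}

# Closed-form univariate ACE WLS: the objective is linear in (a^2, c^2),
# so the minimizer solves 2x2 normal equations, falling back to the edges
# of the admissible region {x >= 0, y >= 0, x + y <= 1} when violated.
fit_univariate_closed <- function(spec, md) {
  r <- vapply(md$per_group, function(g) g$s[1], numeric(1))
  w <- vapply(md$per_group, function(g) g$w[1], numeric(1))
  kap <- ifelse(md$zyg == "MZ", 1, 0.5)
  obj_xy <- function(x, y) sum(w * (r - kap * x - y)^2)
  A <- rbind(
    c(sum(w * kap^2), sum(w * kap)),
    c(sum(w * kap), sum(w))
  )
  b <- c(sum(w * kap * r), sum(w * r))
  sol <- tryCatch(solve(A, b), error = function(e) c(NA_real_, NA_real_))
  cands <- list()
  if (all(is.finite(sol)) && sol[1] >= 0 && sol[2] >= 0 && sum(sol) <= 1) {
    cands[[1]] <- sol
  } else {
    clip <- function(z) min(max(z, 0), 1)
    x_e <- clip(sum(w * kap * r) / sum(w * kap^2)) # y = 0 edge
    y_e <- clip(sum(w * r) / sum(w)) # x = 0 edge
    x_d <- clip(sum(w * (r - 1) * (kap - 1)) / max(sum(w * (kap - 1)^2), 1e-12))
    cands <- list(
      c(x_e, 0), c(0, y_e), c(x_d, 1 - x_d),
      c(0, 0), c(1, 0), c(0, 1)
    )
    cands <- purrr::keep(cands, function(z) z[1] >= 0 && z[2] >= 0 && sum(z) <= 1)
  }
  vals <- vapply(cands, function(z) obj_xy(z[1], z[2]), numeric(1))
  best <- cands[[which.min(vals)]]
  theta <- stats::setNames(sqrt(best), spec$par_info$name)
  list(theta = theta, objective = min(vals), converged = TRUE)
}

fit_quick <- function(spec, md, theta_start) {
  if (spec$kind == "univariate_ace" && !spec$sex_specific &&
    all(lengths(purrr::map(md$per_group, "s")) == 1)) {
    return(fit_univariate_closed(spec, md))
  }
  max_w <- max(unlist(purrr::map(md$per_group, "w")))
  obj <- make_objective(spec, md,
    pen_w = 1e5 * max(1, max_w), ridge_w = 1e-6 * max(1, max_w)
  )
  res <- tryCatch(
    stats::nlminb(repair_start(spec, theta_start), obj,
      control = list(iter.max = 500, eval.max = 2000, rel.tol = 1e-12)
    ),
    error = function(e) NULL
  )
  if (is.null(res)) return(NULL)
  theta <- canonicalize_theta(spec, stats::setNames(res$par, spec$par_info$name))
  pen <- total_penalty(spec, theta)
  list(theta = theta, objective = res$objective,
    converged = res$convergence == 0 && pen < 1e-8)
}

boot_quantities <- function(spec, theta) {
  dec <- standardize(spec, theta)
  comps <- c("general_a", "general_c", "general_e",
    "specific_a", "specific_c", "specific_e")
  q <- c(
    theta,
    stats::setNames(
      unlist(lapply(comps, function(cc) dec[[cc]])),
      paste0(rep(comps, each = nrow(dec)), ".", rep(dec$phenotype, length(comps)))
    )
  )
  fs <- attr(dec, "factor_shares")
  if (!is.null(fs)) q <- c(q, fs)
  q
}

#' Bias-corrected accelerated bootstrap confidence intervals
#'
#' Resamples pairs (complete and incomplete alike) with replacement within
#' each zygosity-sex group, refits stage 1 and stage 2 per replicate (warm
#' started at the point estimate), and computes BCa intervals for every
#' free parameter and every standardized variance proportion. The
#' acceleration constant comes from a pair-level jackknife, replaced by a
#' grouped (delete-block) jackknife when the dataset exceeds 2000 pairs.
#' Deterministic given `seed`. Intervals are computed from converged
#' replicates only; a reliability warning is attached when more than 10%
#' fail or fewer than 90% of requested replicates are usable.
#'
#' @param ds A `twin_data` tibble.
#' @param spec A `model_spec`.
#' @param B Bootstrap replicates (at least 100; 1000 or more recommended).
#' @param seed Integer seed.
#' @param level Coverage level (default 0.95).
#' @param weight_mode Passed to the fits.
#' @param jack_blocks Blocks for the grouped jackknife fallback.
#' @param resample Test hook: `FALSE` replays the original dataset every
#'   replicate (degenerate resampling; intervals collapse to the point
#'   estimate).
#' @return A `twin_boot` object: tibble `$intervals` (term, estimate,
#'   lower, upper), plus metadata.
#' @export
bootstrap_ci <- function(ds, spec, B = 1000, seed = 1, level = 0.95,
                         weight_mode = "diagonal", jack_blocks = 50,
                         resample = TRUE) {
  if (B < 100) stop("B must be at least 100", call. = FALSE)
  if (B < 1000) warning("B < 1000: BCa intervals may be unstable", call. = FALSE)
  mom0 <- all_group_moments(ds)
  fit0 <- fit_wls(spec, mom0, weight_mode = weight_mode, n_starts = 5, seed = seed)
  if (!fit0$converged) stop("point fit did not converge", call. = FALSE)
  q0 <- boot_quantities(spec, fit0$theta)
  groups <- fit0$groups_used
  p <- length(spec$phenotypes)
  idx <- moment_index(p, spec$phenotypes)
  M <- nrow(idx)
  cells <- purrr::map(groups, function(g) {
    mats <- twin_matrices(ds, g)
    list(
      Z = pair_cell_counts(mats$t1, mats$t2, idx),
      n = nrow(mats$t1), group = g,
      r_hat = mom0[[g]]$moments$r
    )
  })
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  # stage 1 for all replicates at once, per group
  rep_moments <- purrr::map(cells, function(cl) {
    counts <- if (resample) {
      Wts <- stats::rmultinom(B, cl$n, rep(1 / cl$n, cl$n))
      crossprod(Wts, cl$Z)
    } else {
      matrix(colSums(cl$Z), B, ncol(cl$Z), byrow = TRUE)
    }
    quick_moments_from_counts(counts, M, start = cl$r_hat)
  })
  refit_from <- function(extract) {
    s_list <- list(); w_list <- list(); used_list <- list()
    for (i in seq_along(groups)) {
      rv <- extract(rep_moments[[i]]$r, i)
      sev <- extract(rep_moments[[i]]$se, i)
      used <- is.finite(rv) & is.finite(sev) & sev > 0
      s_list[[i]] <- rv[used]; w_list[[i]] <- 1 / sev[used]^2
      used_list[[i]] <- used
    }
    if (sum(lengths(s_list)) < length(fit0$theta)) return(NULL)
    md <- quick_md(spec, groups, s_list, w_list, used_list, fit0$n_total)
    fit_quick(spec, md, fit0$theta)
  }
  reps <- purrr::map(seq_len(B), function(b) refit_from(function(R, i) R[b, ]))
  conv <- vapply(reps, function(r) !is.null(r) && r$converged, logical(1))
  Q <- t(vapply(reps[conv], function(r) boot_quantities(spec, r$theta),
    numeric(length(q0))
  ))
  warn <- character(0)
  if (mean(!conv) > 0.10) {
    warn <- c(warn, sprintf("%.0f%% of replicates failed to converge", 100 * mean(!conv)))
  }
  if (sum(conv) < 0.9 * B) {
    warn <- c(warn, sprintf("only %d of %d replicates usable", sum(conv), B))
  }
  # jackknife for the acceleration constant
  n_tot_pairs <- sum(vapply(cells, function(cl) cl$n, numeric(1)))
  jack_sets <- jackknife_sets(cells, n_tot_pairs, jack_blocks)
  jack_counts <- purrr::map(jack_sets, function(js) {
    purrr::map(seq_along(cells), function(i) {
      di <- js[[i]]
      tot <- colSums(cells[[i]]$Z)
      if (length(di) > 0) tot <- tot - colSums(cells[[i]]$Z[di, , drop = FALSE])
      matrix(tot, 1)
    })
  })
  jack_Q <- purrr::map(jack_counts, function(jc) {
    s_list <- list(); w_list <- list(); used_list <- list()
    for (i in seq_along(groups)) {
      qm <- quick_moments_from_counts(jc[[i]], M, start = cells[[i]]$r_hat)
      used <- is.finite(qm$r[1, ]) & is.finite(qm$se[1, ]) & qm$se[1, ] > 0
      s_list[[i]] <- qm$r[1, used]; w_list[[i]] <- 1 / qm$se[1, used]^2
      used_list[[i]] <- used
    }
    md <- quick_md(spec, groups, s_list, w_list, used_list, fit0$n_total)
    fq <- fit_quick(spec, md, fit0$theta)
    if (is.null(fq) || !fq$converged) return(NULL)
    boot_quantities(spec, fq$theta)
  })
  jack_Q <- do.call(rbind, jack_Q[!vapply(jack_Q, is.null, logical(1))])
  intervals <- bca_intervals(q0, Q, jack_Q, level)
  structure(
    list(
      intervals = intervals, B_requested = B, B_converged = sum(conv),
      seed = seed, level = level, warnings = warn, fit = fit0,
      jack_type = attr(jack_sets, "type")
    ),
    class = "twin_boot"
  )
}

jackknife_sets <- function(cells, n_tot, blocks) {
  if (n_tot <= 2000) {
    sets <- list()
    for (i in seq_along(cells)) {
      for (r in seq_len(cells[[i]]$n)) {
        js <- purrr::map(seq_along(cells), function(k) integer(0))
        js[[i]] <- r
        sets[[length(sets) + 1]] <- js
      }
    }
    attr(sets, "type") <- "pair"
    return(sets)
  }
  # grouped jackknife: contiguous blocks allocated proportionally
  sets <- list()
  for (i in seq_along(cells)) {
    n_i <- cells[[i]]$n
    b_i <- max(2, round(blocks * n_i / n_tot))
    cut_i <- cut(seq_len(n_i), b_i, labels = FALSE)
    for (b in seq_len(b_i)) {
      js <- purrr::map(seq_along(cells), function(k) integer(0))
      js[[i]] <- which(cut_i == b)
      sets[[length(sets) + 1]] <- js
    }
  }
  attr(sets, "type") <- "block"
  sets
}

bca_intervals <- function(q0, Q, jack_Q, level) {
  alpha <- (1 - level) / 2
  z_lo <- stats::qnorm(alpha); z_hi <- stats::qnorm(1 - alpha)
  purrr::map_dfr(seq_along(q0), function(k) {
    th <- q0[[k]]
    qb <- Q[, k]
    qb <- qb[is.finite(qb)]
    if (length(qb) < 10 || stats::sd(qb) < 1e-12) {
      return(tibble::tibble(
        term = names(q0)[k], estimate = th, lower = th, upper = th,
        z0 = 0, accel = 0
      ))
    }
    z0 <- stats::qnorm(pmin(pmax(
      (sum(qb < th) + 0.5 * sum(qb == th)) / length(qb), 1e-6
    ), 1 - 1e-6))
    a <- 0
    if (!is.null(jack_Q) && nrow(jack_Q) > 2) {
      ji <- jack_Q[, k]
      ji <- ji[is.finite(ji)]
      d <- mean(ji) - ji
      denom <- sum(d^2)^1.5
      if (denom > 1e-20) a <- sum(d^3) / (6 * denom)
    }
    adj <- function(z) stats::pnorm(z0 + (z0 + z) / (1 - a * (z0 + z)))
    qs <- stats::quantile(qb, c(adj(z_lo), adj(z_hi)), names = FALSE, type = 6)
    tibble::tibble(
      term = names(q0)[k], estimate = th, lower = qs[1], upper = qs[2],
      z0 = z0, accel = a
    )
  })
}

#' @export
print.twin_boot <- function(x, ...) {
  cat(sprintf(
    "<twin_boot> %d/%d converged replicates, %s jackknife, %.0f%% BCa intervals\n",
    x$B_converged, x$B_requested, x$jack_type, 100 * x$level
  ))
  if (length(x$warnings) > 0) cat("  warning:", paste(x$warnings, collapse = "; "), "\n")
  print(x$intervals, n = 20)
  invisible(x)
}
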