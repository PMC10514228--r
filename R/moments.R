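# Stage 1 of the two-stage weighted least squares: per-group thresholds,
# within- and cross-twin tetrachoric correlation matrices, and the
# asymptotic covariance of the estimated moments.

#' Liability threshold estimate from a binary vector
#'
#' `tau = qnorm(1 - mean(x))` with the delta-method standard error
#' `sqrt(p (1 - p) / n) / dnorm(tau)`.
#'
#' @param x Binary vector (0/1, `NA` allowed).
#' @return List: `tau`, `se`, `n`, `p`.
#' @export
estimate_threshold <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n == 0 || all(x == 0) || all(x == 1)) {
    stop("degenerate phenotype: needs at least one 0 and one 1", call. = FALSE)
  }
  p <- mean(x)
  tau <- stats::qnorm(1 - p)
  se <- sqrt(p * (1 - p) / n) / stats::dnorm(tau)
  list(tau = tau, se = se, n = n, p = p)
}

# Index table of the distinct correlation moments for p phenotypes:
# within-person pairs (j < m), then cross-twin pairs (j <= m).
moment_index <- function(p, names = as.character(seq_len(p))) {
  w <- if (p >= 2) utils::combn(p, 2) else matrix(integer(0), 2, 0)
  cr <- which(upper.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  cr <- cr[order(cr[, 1], cr[, 2]), , drop = FALSE]
  tibble::tibble(
    kind = c(rep("within", ncol(w)), rep("cross", nrow(cr))),
    j = c(w[1, ], cr[, 1]),
    m = c(w[2, ], cr[, 2]),
    name = c(
      if (ncol(w)) paste0("w_", names[w[1, ]], "_", names[w[2, ]]),
      paste0("x_", names[cr[, 1]], "_", names[cr[, 2]])
    )
  )
}

cell_index <- function(x, y) 1L + (1L - x) * 2L + (1L - y)

# Per-pair cell-count matrix: n_pairs x (4 * n_moments). Within-person
# moments receive one unit per observed twin; cross-twin moments receive
# half a unit per ordering (the two orderings are averaged, so table totals
# count pairs once).
pair_cell_counts <- function(t1, t2, idx) {
  n <- nrow(t1)
  Z <- matrix(0, n, 4L * nrow(idx))
  add <- function(col0, x, y, wgt) {
    ok <- which(!is.na(x) & !is.na(y))
    if (length(ok) == 0) return()
    ci <- col0 + cell_index(x[ok], y[ok])
    Z[cbind(ok, ci)] <<- Z[cbind(ok, ci)] + wgt
  }
  for (k in seq_len(nrow(idx))) {
    j <- idx$j[k]; m <- idx$m[k]
    col0 <- 4L * (k - 1L)
    if (idx$kind[k] == "within") {
      add(col0, t1[, j], t1[, m], 1)
      add(col0, t2[, j], t2[, m], 1)
    } else {
      add(col0, t1[, j], t2[, m], 0.5)
      add(col0, t2[, j], t1[, m], 0.5)
    }
  }
  Z
}

#' Group-level liability moments
#'
#' Estimates, for one zygosity-sex group: pooled per-phenotype thresholds
#' (both twins' observed values), the within-person tetrachoric correlation
#' matrix (twins pooled; the twin-1 and twin-2 blocks are constrained equal
#' by construction), and the symmetrized cross-twin tetrachoric block
#' (complete pairs, both twin orderings averaged). Each correlation is
#' estimated by [tetrachoric_ml()] with thresholds fixed at that table's
#' margins, using available cases. The default asymptotic covariance is the
#' per-moment information-based diagonal; `acov = "bootstrap"` adds the
#' full covariance across all moments by pair-level nonparametric bootstrap.
#'
#' @param ds A `twin_data` tibble.
#' @param group Group label (MZM/MZF/DZM/DZF).
#' @param acov `"diagonal"` or `"bootstrap"`.
#' @param B Bootstrap replicates for the full acov (default 200).
#' @param seed Seed for the bootstrap acov.
#' @param on_degenerate `"drop"` (NA out the phenotype for this group, with
#'   a warning) or `"error"`.
#' @return A `group_moments` object.
#' @export
group_moments <- function(ds, group, acov = c("diagonal", "bootstrap"),
                          B = 200, seed = 1,
                          on_degenerate = c("drop", "error")) {
  acov <- match.arg(acov)
  on_degenerate <- match.arg(on_degenerate)
  cb <- twin_codebook_of(ds)
  if (!group %in% ds$group) stop("group not present: ", group, call. = FALSE)
  mats <- twin_matrices(ds, group)
  p <- nrow(cb)
  pooled <- rbind(mats$t1, mats$t2)
  dropped <- character(0)
  thr <- purrr::map_dfr(seq_len(p), function(j) {
    est <- tryCatch(estimate_threshold(pooled[, j]), error = function(e) NULL)
    if (is.null(est)) {
      tibble::tibble(
        phenotype = cb$name[j], tau = NA_real_, se = NA_real_,
        n = sum(!is.na(pooled[, j])), p_obs = NA_real_
      )
    } else {
      tibble::tibble(
        phenotype = cb$name[j], tau = est$tau, se = est$se,
        n = est$n, p_obs = est$p
      )
    }
  })
  dropped <- thr$phenotype[is.na(thr$tau)]
  if (length(dropped) > 0) {
    if (on_degenerate == "error") {
      stop(
        "degenerate phenotype(s) in group ", group, ": ",
        paste(dropped, collapse = ", "),
        call. = FALSE
      )
    }
    warning(
      "group ", group, ": dropping degenerate phenotype(s): ",
      paste(dropped, collapse = ", "),
      call. = FALSE
    )
  }
  idx <- moment_index(p, cb$name)
  Z <- pair_cell_counts(mats$t1, mats$t2, idx)
  totals <- colSums(Z)
  qm <- quick_moments_from_counts(matrix(totals, 1), nrow(idx))
  mom <- dplyr::mutate(idx,
    r = as.numeric(qm$r), se = as.numeric(qm$se), n = as.numeric(qm$n),
    corrected = as.logical(qm$corrected), boundary = as.logical(qm$boundary)
  )
  drop_mom <- cb$name[mom$j] %in% dropped | cb$name[mom$m] %in% dropped
  mom$r[drop_mom] <- NA_real_
  mom$se[drop_mom] <- NA_real_
  corr <- assemble_corr(mom, p, cb$name)
  acov_full <- NULL
  if (acov == "bootstrap") {
    acov_full <- bootstrap_moment_acov(Z, idx, mom$r, B = B, seed = seed)
    dimnames(acov_full) <- list(mom$name, mom$name)
  }
  structure(
    list(
      group = group, codebook = cb, thresholds = thr, moments = mom,
      corr = corr, acov_diag = stats::setNames(mom$se^2, mom$name),
      acov_full = acov_full, n_pairs = nrow(mats$t1),
      n_complete = sum(rowSums(!is.na(mats$t2)) > 0),
      n_individuals = sum(rowSums(!is.na(mats$t1)) > 0) +
        sum(rowSums(!is.na(mats$t2)) > 0),
      dropped = dropped, acov_B = if (acov == "bootstrap") B else NA_integer_
    ),
    class = "group_moments"
  )
}

assemble_corr <- function(mom, p, names) {
  W <- diag(1, p); X <- matrix(NA_real_, p, p)
  for (k in seq_len(nrow(mom))) {
    j <- mom$j[k]; m <- mom$m[k]; r <- mom$r[k]
    if (mom$kind[k] == "within") {
      W[j, m] <- W[m, j] <- r
    } else {
      X[j, m] <- X[m, j] <- r
    }
  }
  full <- rbind(cbind(W, X), cbind(t(X), W))
  dimnames(full) <- list(
    c(paste0(names, "_t1"), paste0(names, "_t2")),
    c(paste0(names, "_t1"), paste0(names, "_t2"))
  )
  full
}

#' @export
print.group_moments <- function(x, ...) {
  cat(sprintf(
    "<group_moments %s> %d pairs (%d complete), %d phenotypes, %d moments%s\n",
    x$group, x$n_pairs, x$n_complete, nrow(x$codebook), nrow(x$moments),
    if (is.null(x$acov_full)) "" else sprintf(" [bootstrap acov, B=%d]", x$acov_B)
  ))
  invisible(x)
}

# Full moment acov by pair-level multinomial-weight bootstrap, vectorized
# across replicates and moments. Point estimates are used as Newton starts.
bootstrap_moment_acov <- function(Z, idx, r_hat, B = 200, seed = 1) {
  n <- nrow(Z)
  M <- nrow(idx)
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  Wts <- stats::rmultinom(B, n, rep(1 / n, n)) # n x B
  counts <- crossprod(Wts, Z) # B x 4M
  qm <- quick_moments_from_counts(counts, M, start = r_hat)
  stats::cov(qm$r, use = "pairwise.complete.obs")
}

#' Moments for every group in a dataset
#'
#' @inheritParams group_moments
#' @param groups Groups to include (default: all present).
#' @return Named list of [group_moments()] objects.
#' @export
all_group_moments <- function(ds, acov = c("diagonal", "bootstrap"), B = 200,
                              seed = 1, groups = NULL,
                              on_degenerate = c("drop", "error")) {
  acov <- match.arg(acov)
  on_degenerate <- match.arg(on_degenerate)
  if (is.null(groups)) groups <- intersect(ZYG_GROUPS, unique(ds$group))
  out <- purrr::map(groups, function(g) {
    group_moments(ds, g,
      acov = acov, B = B, seed = seed + match(g, ZYG_GROUPS),
      on_degenerate = on_degenerate
    )
  })
  stats::setNames(out, groups)
}

#' Tidy the correlation moments of a group
#'
#' @param x A `group_moments` object.
#' @param ... Unused.
#' @return Tibble: phenotype pair, moment kind, estimate, standard error.
#' @export
tidy.group_moments <- function(x, ...) {
  nm <- x$codebook$name
  dplyr::mutate(x$moments,
    group = x$group,
    phenotype1 = nm[.data$j], phenotype2 = nm[.data$m],
    .before = 1
  )
}

#' Serialize group moments to JSON
#'
#' Stores thresholds, correlation moments, diagonal acov, and (when
#' present) the bootstrap acov matrix row-major with phenotype-name
#' indexing, for caching and for refitting from moments alone.
#'
#' @param gm_list A `group_moments` object or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
moments_to_json <- function(gm_list, path) {
  if (inherits(gm_list, "group_moments")) gm_list <- list(gm_list)
  payload <- purrr::map(gm_list, function(g) {
    list(
      group = g$group,
      phenotypes = g$codebook$name,
      class_tag = g$codebook$class_tag,
      thresholds = g$thresholds,
      moments = g$moments,
      acov_full = if (is.null(g$acov_full)) NULL else as.numeric(t(g$acov_full)),
      n_pairs = g$n_pairs, n_complete = g$n_complete,
      n_individuals = g$n_individuals, acov_B = g$acov_B
    )
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read group moments back from JSON
#'
#' @param path Path written by [moments_to_json()].
#' @return Named list of `group_moments` objects.
#' @export
moments_from_json <- function(path) {
  payload <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE, simplifyVector = TRUE)
  if (is.data.frame(payload)) payload <- split(payload, seq_len(nrow(payload)))
  rebuild <- function(rec) {
    if (is.data.frame(rec)) rec <- as.list(rec)
    unwrap <- function(x) if (is.list(x) && length(x) == 1) x[[1]] else x
    phen <- unlist(rec$phenotypes)
    cb <- codebook(phen, class_tag = unlist(rec$class_tag))
    mom <- tibble::as_tibble(unwrap(rec$moments))
    p <- length(phen)
    acov_full <- NULL
    af <- unwrap(rec$acov_full)
    if (!is.null(af) && length(af) > 0 && !all(is.na(af))) {
      M <- nrow(mom)
      acov_full <- matrix(as.numeric(af), M, M, byrow = TRUE,
        dimnames = list(mom$name, mom$name)
      )
    }
    structure(
      list(
        group = unwrap(rec$group)[[1]], codebook = cb,
        thresholds = tibble::as_tibble(unwrap(rec$thresholds)),
        moments = mom, corr = assemble_corr(mom, p, phen),
        acov_diag = stats::setNames(mom$se^2, mom$name),
        acov_full = acov_full,
        n_pairs = unwrap(rec$n_pairs)[[1]],
        n_complete = unwrap(rec$n_complete)[[1]],
        n_individuals = unwrap(rec$n_individuals)[[1]],
        dropped = phen[is.na(tibble::as_tibble(unwrap(rec$thresholds))$tau)],
        acov_B = unwrap(rec$acov_B)[[1]]
      ),
      class = "group_moments"
    )
  }
  out <- purrr::map(payload, rebuild)
  stats::setNames(out, purrr::map_chr(out, "group"))
}
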