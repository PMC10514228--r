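# Bivariate-normal upper-orthant probabilities and tetrachoric correlation
# estimation. All liability-scale moments in the package pass through here.

.gl_cache <- new.env(parent = emptyenv())

gl_rule <- function(n = 64L) {
  key <- as.character(n)
  if (is.null(.gl_cache[[key]])) {
    .gl_cache[[key]] <- pracma::gaussLegendre(n, -1, 1)
  }
  .gl_cache[[key]]
}

BVN_INF <- 8.5 # standard-normal mass beyond is < 1e-17

#' Upper-orthant probability of the standard bivariate normal
#'
#' `P(X > tau1, Y > tau2)` for standard normal `(X, Y)` with correlation
#' `rho`, by Gauss-Legendre quadrature of
#' `integral phi(x) * Phi((rho x - tau2) / sqrt(1 - rho^2)) dx`
#' over `x > tau1`. Vectorized over all three arguments.
#'
#' @param tau1,tau2 Thresholds.
#' @param rho Correlation(s) in `[-1, 1]`.
#' @return Probabilities.
#' @keywords internal
bvn_upper <- function(tau1, tau2, rho) {
  m <- max(length(tau1), length(tau2), length(rho))
  tau1 <- rep_len(tau1, m); tau2 <- rep_len(tau2, m); rho <- rep_len(rho, m)
  # integrate over the larger threshold for a narrower range
  swap <- tau2 > tau1
  tl <- ifelse(swap, tau2, tau1)
  ts <- ifelse(swap, tau1, tau2)
  out <- numeric(m)
  lim <- abs(rho) >= 1 - 1e-12
  if (any(lim)) {
    pos <- lim & rho > 0
    out[pos] <- stats::pnorm(pmax(tl[pos], ts[pos]), lower.tail = FALSE)
    neg <- lim & rho < 0
    out[neg] <- pmax(0, stats::pnorm(-ts[neg]) - stats::pnorm(tl[neg]))
  }
  gen <- !lim
  if (any(gen)) {
    rule <- gl_rule()
    a <- pmax(tl[gen], -BVN_INF)
    half <- (BVN_INF - a) / 2
    mid <- (BVN_INF + a) / 2
    # nodes: length(a) x n
    x <- outer(half, rule$x) + mid
    s <- sqrt(1 - rho[gen]^2)
    z <- (rho[gen] * x - ts[gen]) / s
    f <- stats::dnorm(x) * stats::pnorm(z)
    out[gen] <- half * as.numeric(f %*% rule$w)
  }
  pmin(pmax(out, 0), 1)
}

bvn_density <- function(tau1, tau2, rho) {
  s2 <- 1 - rho^2
  exp(-(tau1^2 - 2 * rho * tau1 * tau2 + tau2^2) / (2 * s2)) /
    (2 * pi * sqrt(s2))
}

RHO_CLAMP <- 1 - 1e-8

# Vectorized safeguarded Newton solver for the margin-fixed tetrachoric:
# finds rho with P(X > tau1, Y > tau2; rho) = p11. Monotone in rho.
# Returns clamped values (with boundary attribute) when p11 sits at or
# beyond the Frechet bounds of the margins.
rho_match <- function(p11, tau1, tau2, tol = 1e-12, max_iter = 60L,
                      start = NULL) {
  m <- max(length(p11), length(tau1), length(tau2))
  p11 <- rep_len(p11, m); tau1 <- rep_len(tau1, m); tau2 <- rep_len(tau2, m)
  if (is.null(start)) start <- rep(0, m) else start <- rep_len(start, m)
  start[!is.finite(start)] <- 0
  start <- pmin(pmax(start, -RHO_CLAMP + 1e-6), RHO_CLAMP - 1e-6)
  p1 <- stats::pnorm(tau1, lower.tail = FALSE)
  p2 <- stats::pnorm(tau2, lower.tail = FALSE)
  lo_b <- pmax(0, p1 + p2 - 1) # rho = -1 orthant mass
  hi_b <- pmin(p1, p2) # rho = +1 orthant mass
  boundary <- rep(FALSE, m)
  rho <- rep(0, m)
  hi_hit <- p11 >= hi_b - 1e-12
  lo_hit <- p11 <= lo_b + 1e-12
  boundary[hi_hit | lo_hit] <- TRUE
  rho[hi_hit] <- RHO_CLAMP
  rho[lo_hit] <- -RHO_CLAMP
  act <- which(!boundary)
  if (length(act) > 0) {
    lo <- rep(-RHO_CLAMP, length(act))
    hi <- rep(RHO_CLAMP, length(act))
    r <- start[act]
    t1 <- tau1[act]; t2 <- tau2[act]; tgt <- p11[act]
    done <- rep(FALSE, length(act))
    for (it in seq_len(max_iter)) {
      f <- bvn_upper(t1, t2, r) - tgt
      done <- done | abs(f) < tol
      lo[!done & f < 0] <- r[!done & f < 0]
      hi[!done & f > 0] <- r[!done & f > 0]
      d <- bvn_density(t1, t2, r)
      rn <- r - f / pmax(d, 1e-300)
      bad <- !is.finite(rn) | rn <= lo | rn >= hi
      rn[bad] <- (lo[bad] + hi[bad]) / 2
      rn[done] <- r[done] # converged roots are frozen
      done <- done | abs(rn - r) < 1e-14
      r <- rn
      if (all(done)) break
    }
    rho[act] <- r
  }
  attr(rho, "boundary") <- boundary
  rho
}

# Closed-form observed-information s.e. of a margin-fixed tetrachoric at an
# interior cell-matching solution: at the MLE the score factor vanishes, so
# -l'' = N * phi2(tau1, tau2; rho)^2 * sum(1/p_ij).
tetra_se_closed <- function(rho, tau1, tau2, p11, p1, p2, n) {
  d <- bvn_density(tau1, tau2, rho)
  pij <- cbind(p11, p1 - p11, p2 - p11, 1 - p1 - p2 + p11)
  pij[pij < 1e-12] <- NA
  1 / (d * sqrt(n * rowSums(1 / pij)))
}

# Moments (r, se, flags) from stacked cell totals: rows = replicates,
# columns = 4 cells per moment. The single engine behind group_moments(),
# the bootstrap acov, and the bootstrap/jackknife refits.
quick_moments_from_counts <- function(counts, M, start = NULL) {
  iM <- seq_len(M)
  c11 <- counts[, 4L * (iM - 1L) + 1L, drop = FALSE]
  c10 <- counts[, 4L * (iM - 1L) + 2L, drop = FALSE]
  c01 <- counts[, 4L * (iM - 1L) + 3L, drop = FALSE]
  c00 <- counts[, 4L * (iM - 1L) + 4L, drop = FALSE]
  n_raw <- c11 + c10 + c01 + c00
  zero <- c11 == 0 | c10 == 0 | c01 == 0 | c00 == 0
  c11 <- c11 + 0.5 * zero; c10 <- c10 + 0.5 * zero
  c01 <- c01 + 0.5 * zero; c00 <- c00 + 0.5 * zero
  n <- c11 + c10 + c01 + c00
  p1 <- (c11 + c10) / n; p2 <- (c11 + c01) / n
  ok <- p1 > 0 & p1 < 1 & p2 > 0 & p2 < 1 & n > 1
  tau1 <- stats::qnorm(1 - p1); tau2 <- stats::qnorm(1 - p2)
  R <- matrix(NA_real_, nrow(counts), M)
  SE <- matrix(NA_real_, nrow(counts), M)
  sel <- which(ok)
  if (length(sel) > 0) {
    st <- if (is.null(start)) NULL else matrix(start, nrow(counts), M, byrow = TRUE)[sel]
    R[sel] <- rho_match((c11 / n)[sel], tau1[sel], tau2[sel], start = st)
    SE[sel] <- tetra_se_closed(R[sel], tau1[sel], tau2[sel],
      (c11 / n)[sel], p1[sel], p2[sel], n[sel]
    )
  }
  bdy <- abs(R) >= RHO_CLAMP - 1e-12
  SE[bdy] <- NA_real_
  list(r = R, se = SE, corrected = zero, boundary = bdy, n = n_raw)
}

prepare_table <- function(table) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2, 2))) stop("expected a 2x2 table", call. = FALSE)
  if (any(tab < 0)) stop("negative cell counts", call. = FALSE)
  corrected <- FALSE
  if (any(tab == 0)) { # continuity correction, flagged
    tab <- tab + 0.5
    corrected <- TRUE
  }
  n <- sum(tab)
  p1 <- sum(tab[1, ]) / n
  p2 <- sum(tab[, 1]) / n
  if (p1 <= 0 || p1 >= 1 || p2 <= 0 || p2 >= 1) {
    stop("degenerate margin in 2x2 table", call. = FALSE)
  }
  list(tab = tab, n = n, p1 = p1, p2 = p2, corrected = corrected)
}

#' Tetrachoric correlation by maximum likelihood
#'
#' Estimates the correlation of the latent bivariate standard normal
#' underlying a 2x2 table, with thresholds fixed at their margin-implied
#' values (two-step). With margin-fixed thresholds the likelihood score is
#' zero exactly where the model `(+,+)` orthant probability matches the
#' observed cell proportion, so the MLE is found by safeguarded Newton
#' root-finding on that monotone equation. Tables containing a zero cell
#' receive a continuity correction of 0.5 added to every cell and are
#' flagged. The estimate is clamped to `|r| <= 1 - 1e-8` with a boundary
#' flag; the standard error comes from the observed information, which at
#' the cell-matching solution has the closed form
#' `-l'' = N * phi2(tau1, tau2; rho)^2 * sum(1 / p_ij)`.
#'
#' Table layout: rows index the first variable (positive, negative), columns
#' the second, so `table[1, 1]` counts pairs endorsing both.
#'
#' @param table 2x2 nonnegative matrix of counts (non-integer weights
#'   allowed).
#' @return A list of class `tetrachoric`: `r`, `se`, `tau1`, `tau2`, `n`,
#'   `corrected`, `boundary`.
#' @examples
#' tetrachoric_ml(matrix(c(400, 200, 200, 400), 2, byrow = TRUE))$r # ~0.5
#' @export
tetrachoric_ml <- function(table) {
  pt <- prepare_table(table)
  tau1 <- stats::qnorm(1 - pt$p1)
  tau2 <- stats::qnorm(1 - pt$p2)
  p11_hat <- pt$tab[1, 1] / pt$n
  r <- rho_match(p11_hat, tau1, tau2)
  boundary <- attr(r, "boundary")[1]
  r <- as.numeric(r)[1]
  se <- NA_real_
  if (!boundary) {
    se <- tetra_se_closed(r, tau1, tau2, p11_hat, pt$p1, pt$p2, pt$n)[1]
  }
  structure(
    list(
      r = r, se = se, tau1 = tau1, tau2 = tau2, n = pt$n,
      corrected = pt$corrected, boundary = boundary
    ),
    class = "tetrachoric"
  )
}

#' @export
print.tetrachoric <- function(x, ...) {
  cat(sprintf(
    "tetrachoric r = %.6f (se %.4f)%s%s\n", x$r, x$se,
    if (x$corrected) " [zero-cell corrected]" else "",
    if (x$boundary) " [boundary]" else ""
  ))
  invisible(x)
}

#' Brute-force tetrachoric oracle
#'
#' Independent verifier for [tetrachoric_ml()]: the upper-orthant
#' probability is computed by two-dimensional tensor-product
#' Gauss-Legendre integration of the raw bivariate-normal density (no
#' shared code with the 1-D estimator), and the multinomial log-likelihood
#' is maximized by staged dense grid search over `rho` with a final
#' parabolic refinement. Intended for tests; slow by design.
#'
#' @param table 2x2 nonnegative matrix of counts.
#' @return The correlation estimate (numeric scalar).
#' @export
tetrachoric_oracle <- function(table) {
  pt <- prepare_table(table)
  tau1 <- stats::qnorm(1 - pt$p1)
  tau2 <- stats::qnorm(1 - pt$p2)
  rule <- gl_rule(72L)
  a1 <- max(tau1, -BVN_INF); a2 <- max(tau2, -BVN_INF)
  h1 <- (BVN_INF - a1) / 2; h2 <- (BVN_INF - a2) / 2
  x1 <- h1 * rule$x + (BVN_INF + a1) / 2
  x2 <- h2 * rule$x + (BVN_INF + a2) / 2
  W <- (rule$w %o% rule$w) * h1 * h2
  X1 <- matrix(x1, length(x1), length(x2))
  X2 <- matrix(x2, length(x1), length(x2), byrow = TRUE)
  Q <- X1^2 + X2^2
  XY <- X1 * X2
  orthant2d <- function(rho) {
    s2 <- 1 - rho^2
    sum(W * exp(-(Q - 2 * rho * XY) / (2 * s2))) / (2 * pi * sqrt(s2))
  }
  counts <- c(pt$tab[1, 1], pt$tab[1, 2], pt$tab[2, 1], pt$tab[2, 2])
  ll <- function(rho) {
    P11 <- orthant2d(rho)
    p <- c(P11, pt$p1 - P11, pt$p2 - P11, 1 - pt$p1 - pt$p2 + P11)
    if (any(p <= 0)) return(-Inf)
    sum(counts * log(p))
  }
  grid_best <- function(lo, hi, step) {
    g <- seq(lo, hi, by = step)
    v <- vapply(g, ll, numeric(1))
    list(g = g, v = v, i = which.max(v))
  }
  s1 <- grid_best(-0.99, 0.99, 0.01)
  r0 <- s1$g[s1$i]
  s2 <- grid_best(max(-RHO_CLAMP, r0 - 0.011), min(RHO_CLAMP, r0 + 0.011), 1e-4)
  r0 <- s2$g[s2$i]
  s3 <- grid_best(max(-RHO_CLAMP, r0 - 1.1e-4), min(RHO_CLAMP, r0 + 1.1e-4), 1e-6)
  i <- s3$i
  if (i > 1 && i < length(s3$g)) { # parabolic refinement on the final grid
    y0 <- s3$v[i - 1]; y1 <- s3$v[i]; y2 <- s3$v[i + 1]
    denom <- y0 - 2 * y1 + y2
    off <- if (abs(denom) > 0) 0.5 * (y0 - y2) / denom else 0
    r_hat <- s3$g[i] + off * 1e-6
  } else {
    r_hat <- s3$g[i]
  }
  max(-RHO_CLAMP, min(RHO_CLAMP, r_hat))
}
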