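# Nested model-comparison ladders: fit an ordered list of structural
# specifications on shared moments, compute fit indices against the
# independence baseline, and Wald-test each reduction on the fuller model.

#' Build a model-comparison ladder entry list
#'
#' Each entry is `list(name, spec, vs)` where `vs` names zero or more
#' fuller models fitted earlier in the ladder; the Wald test restricts the
#' fuller model's parameters that are absent (by name) from the entry's
#' spec to zero.
#'
#' @param ... Entries.
#' @return A list with class `ladder_def`.
#' @export
ladder_def <- function(...) {
  entries <- list(...)
  nms <- vapply(entries, function(e) e$name, character(1))
  if (anyDuplicated(nms)) stop("duplicate ladder entry names", call. = FALSE)
  for (i in seq_along(entries)) {
    bad <- setdiff(entries[[i]]$vs, nms[seq_len(i - 1)])
    if (length(bad) > 0) {
      stop("comparison edge references a later or unknown model: ",
        paste(bad, collapse = ", "),
        call. = FALSE
      )
    }
  }
  structure(entries, class = "ladder_def")
}

#' The packaged factor-count reduction ladder
#'
#' The full 2-2-2 independent pathway model (two echelon-identified
#' general factors per A/C/E component plus all specific A and C factors),
#' the drop-one-general-factor steps, the 1-1-1 and 1-0-1 models, the
#' boundary 0-0-1 / 1-0-0 models, a reduced 1-0-1 model, and one-factor
#' common pathway models. With the 11-phenotype drug (mis)use codebook the
#' reduced entries drop: the cannabis loading on the general E factor;
#' specific A for prescription stimulant misuse and all illicit phenotypes;
#' specific C for all prescription phenotypes and for heroin, cocaine,
#' hallucinogen, and dissociative use (IPM); and for the CPM, specific A
#' for six illicit phenotypes and specific C for the three prescription
#' phenotypes, cannabis, and inhalants. For other codebooks the reduced
#' entries are omitted.
#'
#' @param codebook A [codebook()].
#' @return A `ladder_def`.
#' @export
atr_ladder <- function(codebook = atr_codebook()) {
  cb <- assert_codebook(codebook)
  ip <- function(na, nc, ne, drops = list(), label = NULL) {
    build_ipm_spec(cb, na, nc, ne, pattern = "single", drops = drops, label = label)
  }
  e <- list(
    list(name = "IP 2-2-2", spec = ip(2, 2, 2), vs = character(0)),
    list(name = "IP 2-2-1", spec = ip(2, 2, 1), vs = "IP 2-2-2"),
    list(name = "IP 2-1-2", spec = ip(2, 1, 2), vs = "IP 2-2-2"),
    list(name = "IP 1-2-2", spec = ip(1, 2, 2), vs = "IP 2-2-2"),
    list(name = "IP 1-2-1", spec = ip(1, 2, 1), vs = "IP 1-2-2"),
    list(name = "IP 1-1-2", spec = ip(1, 1, 2), vs = "IP 1-2-2"),
    list(name = "IP 0-2-2", spec = ip(0, 2, 2), vs = "IP 1-2-2"),
    list(name = "IP 1-1-1", spec = ip(1, 1, 1), vs = c("IP 1-2-1", "IP 1-1-2")),
    list(name = "IP 0-1-1", spec = ip(0, 1, 1), vs = "IP 1-1-1"),
    list(name = "IP 1-0-1", spec = ip(1, 0, 1), vs = "IP 1-1-1"),
    list(name = "IP 1-1-0", spec = ip(1, 1, 0), vs = "IP 1-1-1"),
    list(name = "IP 0-0-1", spec = ip(0, 0, 1), vs = "IP 1-0-1"),
    list(name = "IP 1-0-0", spec = ip(1, 0, 0), vs = "IP 1-0-1")
  )
  std11 <- identical(cb$name, atr_codebook()$name)
  if (std11) {
    illicit <- cb$name[cb$class_tag == "illicit"]
    rx <- cb$name[cb$class_tag == "prescription"]
    e <- c(e, list(list(
      name = "IP 1-0-1 (reduced)",
      spec = ip(1, 0, 1,
        drops = list(
          general_e = "cannabis",
          specific_a = c("stimulant_rx", illicit),
          specific_c = c(rx, "heroin", "cocaine", "hallucinogen", "dissociative")
        ),
        label = "IP 1-0-1 (reduced)"
      ),
      vs = "IP 1-0-1"
    )))
  }
  e <- c(e, list(list(name = "CP-1", spec = build_cpm_spec(cb), vs = character(0))))
  if (std11) {
    e <- c(e, list(list(
      name = "CP-1 (reduced)",
      spec = build_cpm_spec(cb,
        drops = list(
          specific_a = c(
            "heroin", "cocaine", "stimulant_illicit",
            "hallucinogen", "solvent", "dissociative"
          ),
          specific_c = c("pom", "stimulant_rx", "sedative_rx", "cannabis", "inhalant")
        ),
        label = "CP-1 (reduced)"
      ),
      vs = "CP-1"
    )))
  }
  do.call(ladder_def, e)
}

#' Fit a ladder of nested models
#'
#' Fits every specification (recording nonconvergence as an outcome, not
#' an error), computes mean-adjusted fit statistics and RMSEA/TLI/CFI
#' against the shared independence baseline, and runs each Wald comparison
#' on the fuller model of the edge (restricting the parameters absent from
#' the reduced spec to zero). An edge whose fuller model did not converge
#' is skipped with a notice.
#'
#' @param moments Named list of `group_moments` (ideally with bootstrap
#'   acov so the mean adjustment and Wald covariances use the full moment
#'   covariance), or a `twin_data` tibble (moments are then computed with
#'   bootstrap acov).
#' @param ladder A `ladder_def` (default [atr_ladder()] on the moments'
#'   codebook).
#' @param weight_mode Passed to [fit_wls()].
#' @param n_starts,seed Passed to [fit_wls()].
#' @param acov_B Bootstrap replicates when `moments` is a dataset.
#' @return A `twin_ladder`: `$table` (one row per model/comparison, shaped
#'   like a model-comparison table), `$fits`, `$baseline`.
#' @export
model_ladder <- function(moments, ladder = NULL,
                         weight_mode = "diagonal", n_starts = 5, seed = 1,
                         acov_B = 200) {
  if (inherits(moments, "twin_data")) {
    moments <- all_group_moments(moments, acov = "bootstrap", B = acov_B, seed = seed)
  }
  if (inherits(moments, "group_moments")) moments <- list(moments)
  cb <- moments[[1]]$codebook
  if (is.null(ladder)) ladder <- atr_ladder(cb)
  base <- baseline_statistic(moments, weight_mode)
  N_total <- sum(vapply(moments, function(m) m$n_individuals, numeric(1)))
  G <- length(moments)
  fits <- list()
  rows <- list()
  for (entry in ladder) {
    fit <- tryCatch(
      fit_wls(entry$spec, moments,
        weight_mode = weight_mode,
        n_starts = n_starts, seed = seed
      ),
      error = function(e) NULL
    )
    fits[[entry$name]] <- fit
    conv <- !is.null(fit) && fit$converged
    fi <- NULL
    if (conv) {
      fi <- tryCatch(
        {
          ts <- test_statistic(fit)
          fit_indices(ts$T, ts$df, N_total, G, base$T, base$df)
        },
        error = function(e) NULL
      )
      if (is.null(fi)) conv <- FALSE
    }
    mk_row <- function(vs_name, wald) {
      tibble::tibble(
        model = entry$name, vs = vs_name %||% NA_character_,
        converged = conv,
        chi2 = if (conv) fi$T else NA_real_,
        df = if (conv) fi$df else NA_integer_,
        p = if (conv) fi$p_value else NA_real_,
        RMSEA = if (conv) fi$RMSEA else NA_real_,
        RMSEA_lo = if (conv) fi$RMSEA_lo else NA_real_,
        RMSEA_hi = if (conv) fi$RMSEA_hi else NA_real_,
        TLI = if (conv) fi$TLI else NA_real_,
        CFI = if (conv) fi$CFI else NA_real_,
        wald_chi2 = if (is.null(wald)) NA_real_ else wald$W,
        wald_df = if (is.null(wald)) NA_integer_ else wald$df,
        wald_p = if (is.null(wald)) NA_real_ else wald$p_value,
        note = if (!conv) "No convergence" else NA_character_
      )
    }
    if (length(entry$vs) == 0) {
      rows[[length(rows) + 1]] <- mk_row(NULL, NULL)
    } else {
      for (vs_name in entry$vs) {
        fuller <- fits[[vs_name]]
        wald <- NULL
        if (is.null(fuller) || !fuller$converged) {
          message(
            "skipping Wald comparison ", entry$name, " vs ", vs_name,
            ": fuller model not converged"
          )
        } else {
          dropped <- setdiff(names(fuller$theta), entry$spec$par_info$name)
          if (length(dropped) == 0) {
            message(
              "no nested restriction from ", vs_name, " to ", entry$name,
              "; skipping Wald test"
            )
          } else {
            wald <- tryCatch(
              {
                fuller <- suppressWarnings(add_sandwich(fuller))
                fits[[vs_name]] <- fuller
                suppressWarnings(wald_test(fuller, dropped))
              },
              error = function(e) {
                message(
                  "Wald comparison ", entry$name, " vs ", vs_name,
                  " failed: ", conditionMessage(e)
                )
                NULL
              }
            )
          }
        }
        rows[[length(rows) + 1]] <- mk_row(vs_name, wald)
      }
    }
  }
  structure(
    list(
      table = dplyr::bind_rows(rows), fits = fits,
      baseline = base, N_total = N_total, G = G
    ),
    class = "twin_ladder"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.twin_ladder <- function(x, ...) {
  cat(format_ladder(x), sep = "\n")
  invisible(x)
}

#' Fixed-layout text rendering of a model ladder
#'
#' Columns: model, chi-square, df, p, RMSEA (90% CI), TLI, CFI, Wald
#' chi-square, df, p.
#'
#' @param ladder A `twin_ladder`.
#' @return Character vector of lines.
#' @export
format_ladder <- function(ladder) {
  tb <- ladder$table
  fmt <- function(x, d = 3) ifelse(is.na(x), "-", formatC(x, digits = d, format = "f"))
  fmt_p <- function(p) {
    ifelse(is.na(p), "-",
      ifelse(p < 0.001, "<0.001", ifelse(p > 0.99, ">0.99", formatC(p, digits = 2, format = "f")))
    )
  }
  header <- sprintf(
    "%-22s %-14s %9s %4s %7s %-15s %6s %6s %9s %4s %7s",
    "Model", "vs", "chi2", "df", "p", "RMSEA (90% CI)", "TLI", "CFI",
    "Wald", "df", "p"
  )
  lines <- vapply(seq_len(nrow(tb)), function(i) {
    r <- tb[i, ]
    rmsea <- if (is.na(r$RMSEA)) {
      if (!is.na(r$note)) r$note else "-"
    } else {
      sprintf("%.3f (%.3f-%.3f)", r$RMSEA, r$RMSEA_lo, r$RMSEA_hi)
    }
    sprintf(
      "%-22s %-14s %9s %4s %7s %-15s %6s %6s %9s %4s %7s",
      r$model, ifelse(is.na(r$vs), "-", r$vs),
      fmt(r$chi2), ifelse(is.na(r$df), "-", r$df), fmt_p(r$p), rmsea,
      fmt(r$TLI), fmt(r$CFI),
      fmt(r$wald_chi2), ifelse(is.na(r$wald_df), "-", r$wald_df), fmt_p(r$wald_p)
    )
  }, character(1))
  c(header, lines)
}

#' Export a ladder table to CSV
#'
#' @param ladder A `twin_ladder`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ladder_csv <- function(ladder, path) {
  utils::write.csv(as.data.frame(ladder$table), path, row.names = FALSE, na = "")
  invisible(path)
}
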