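#' @importFrom rlang .data
NULL

ZYG_GROUPS <- c("MZM", "MZF", "DZM", "DZF")

group_zygosity <- function(group) ifelse(substr(group, 1, 2) == "MZ", "MZ", "DZ")
group_sex <- function(group) ifelse(substr(group, 3, 3) == "M", "M", "F")

#' Construct a twin-pair dataset
#'
#' The canonical storage is one row per twin pair (wide): `pair_id`,
#' `group` (one of MZM/MZF/DZM/DZF), then a pair of columns
#' `<phenotype>_t1` / `<phenotype>_t2` per phenotype, coded 0/1 with `NA`
#' for missing. A pair whose second member is entirely missing is an
#' incomplete pair and is retained; all moment estimators use
#' available-case data. Only same-sex groups exist: the group label implies
#' both zygosity and sex.
#'
#' @param df Data frame in wide layout.
#' @param codebook A [codebook()] describing the phenotype columns.
#' @return A tibble of class `twin_data` with a `codebook` attribute.
#' @export
twin_data <- function(df, codebook) {
  cb <- assert_codebook(codebook)
  df <- tibble::as_tibble(df)
  need <- c("pair_id", "group", paste0(rep(cb$name, each = 2), c("_t1", "_t2")))
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  df <- df[, need]
  df$pair_id <- as.character(df$pair_id)
  df$group <- as.character(df$group)
  bad <- setdiff(unique(df$group), ZYG_GROUPS)
  if (length(bad) > 0) {
    stop("unknown zygosity-sex group: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(df$pair_id)) {
    stop("duplicate pair_id", call. = FALSE)
  }
  phen_cols <- setdiff(need, c("pair_id", "group"))
  for (col in phen_cols) {
    v <- df[[col]]
    if (is.character(v)) {
      v <- trimws(v)
      v[v %in% c("", "NA")] <- NA
      vn <- suppressWarnings(as.numeric(v))
      if (any(!is.na(v) & is.na(vn))) {
        i <- which(!is.na(v) & is.na(vn))[1]
        stop(sprintf(
          "non-binary phenotype value '%s' in column %s, row %d",
          v[i], col, i
        ), call. = FALSE)
      }
      v <- vn
    }
    v <- as.numeric(v)
    ok <- is.na(v) | v %in% c(0, 1)
    if (!all(ok)) {
      i <- which(!ok)[1]
      stop(sprintf(
        "non-binary phenotype value '%s' in column %s, row %d",
        format(df[[col]][i]), col, i
      ), call. = FALSE)
    }
    df[[col]] <- as.integer(v)
  }
  t1 <- as.matrix(df[, paste0(cb$name, "_t1")])
  drop_row <- rowSums(!is.na(t1)) == 0
  if (any(drop_row)) df <- df[!drop_row, , drop = FALSE]
  structure(df, codebook = cb, class = c("twin_data", class(df)))
}

#' @export
print.twin_data <- function(x, ...) {
  cb <- attr(x, "codebook")
  cat(sprintf(
    "<twin_data> %d pairs, %d phenotypes, groups: %s\n",
    nrow(x), nrow(cb),
    paste(sprintf("%s=%d", ZYG_GROUPS, table(factor(x$group, ZYG_GROUPS))),
      collapse = " "
    )
  ))
  NextMethod()
}

#' Codebook attached to a twin dataset
#'
#' @param ds A `twin_data` tibble.
#' @return The `twin_codebook`.
#' @export
twin_codebook_of <- function(ds) {
  cb <- attr(ds, "codebook")
  if (is.null(cb)) stop("not a twin_data object", call. = FALSE)
  cb
}

#' Matrix views of a twin dataset
#'
#' Returns the twin-1 and twin-2 phenotype matrices (pairs x phenotypes,
#' integer 0/1/NA) for a given group or the whole dataset.
#'
#' @param ds A `twin_data` tibble.
#' @param group Optional group label to subset to.
#' @return List with elements `t1`, `t2`, `group`, `pair_id`.
#' @keywords internal
twin_matrices <- function(ds, group = NULL) {
  cb <- twin_codebook_of(ds)
  if (!is.null(group)) ds <- ds[ds$group %in% group, , drop = FALSE]
  list(
    t1 = as.matrix(ds[, paste0(cb$name, "_t1")]),
    t2 = as.matrix(ds[, paste0(cb$name, "_t2")]),
    group = ds$group, pair_id = ds$pair_id
  )
}

pair_complete <- function(ds) {
  m <- twin_matrices(ds)
  rowSums(!is.na(m$t2)) > 0
}

#' Read a twin-pair table from CSV
#'
#' Wide layout: `pair_id, group, <phen>_t1, <phen>_t2, ...`. Long layout:
#' `pair_id, group, twin_index` (1 or 2) plus one column per phenotype;
#' long input is pivoted to one row per pair. A pair present with only one
#' member is retained as an incomplete pair. Empty cells and the token
#' `NA` are treated as missing; any other non-0/1 token is an error.
#'
#' @param path CSV file (UTF-8, header required).
#' @param codebook A [codebook()].
#' @param layout `"wide"` or `"long"`.
#' @return A `twin_data` tibble.
#' @export
read_twin_table <- function(path, codebook, layout = c("wide", "long")) {
  layout <- match.arg(layout)
  cb <- assert_codebook(codebook)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path,
    colClasses = "character", check.names = FALSE,
    fileEncoding = "UTF-8"
  )
  if (layout == "wide") {
    return(twin_data(raw, cb))
  }
  need <- c("pair_id", "group", "twin_index", cb$name)
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) {
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  key <- paste(raw$pair_id, raw$twin_index, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop("duplicate (pair_id, twin_index): ", gsub("\r", "/", d), call. = FALSE)
  }
  if (!all(raw$twin_index %in% c("1", "2"))) {
    stop("twin_index must be 1 or 2", call. = FALSE)
  }
  ids <- unique(raw$pair_id)
  wide <- tibble::tibble(pair_id = ids)
  grp <- tapply(raw$group, raw$pair_id, function(g) {
    if (length(unique(g)) > 1) stop("conflicting group within pair", call. = FALSE)
    g[1]
  })
  wide$group <- as.character(grp[ids])
  for (ph in cb$name) {
    for (ti in c("1", "2")) {
      v <- rep(NA_character_, length(ids))
      sel <- raw$twin_index == ti
      v[match(raw$pair_id[sel], ids)] <- raw[[ph]][sel]
      wide[[paste0(ph, "_t", ti)]] <- v
    }
  }
  twin_data(wide, cb)
}

#' Write a twin-pair table to CSV (wide layout)
#'
#' Missing values are written as empty cells, so a write/read round trip
#' preserves values, groups, and missingness exactly.
#'
#' @param ds A `twin_data` tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_twin_table <- function(ds, path) {
  utils::write.csv(as.data.frame(ds), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Per-phenotype prevalence and pair completeness
#'
#' Endorsement proportions are computed over individuals with an observed
#' value (both twins pooled), per group and overall; a phenotype with no
#' observed values in a stratum is reported as `NA`, not 0. The pair
#' completeness rate is `2 * complete pairs / total individuals`, where an
#' individual is a twin with at least one observed phenotype.
#'
#' @param ds A `twin_data` tibble.
#' @return A list with `prevalence` (tibble: phenotype, group incl.
#'   `"overall"`, n_observed, proportion) and `completeness` (scalar).
#' @export
summarize_prevalence <- function(ds) {
  cb <- twin_codebook_of(ds)
  if (nrow(ds) == 0) stop("empty dataset", call. = FALSE)
  m <- twin_matrices(ds)
  present1 <- rowSums(!is.na(m$t1)) > 0
  present2 <- rowSums(!is.na(m$t2)) > 0
  n_ind <- sum(present1) + sum(present2)
  n_complete <- sum(present1 & present2)
  strata <- c(ZYG_GROUPS, "overall")
  rows <- purrr::map_dfr(strata, function(g) {
    sel <- if (g == "overall") rep(TRUE, nrow(ds)) else m$group == g
    x <- rbind(m$t1[sel, , drop = FALSE], m$t2[sel, , drop = FALSE])
    n_obs <- colSums(!is.na(x))
    prop <- ifelse(n_obs > 0, colMeans(x, na.rm = TRUE), NA_real_)
    tibble::tibble(
      phenotype = cb$name, group = g,
      n_observed = as.integer(n_obs), proportion = as.numeric(prop)
    )
  })
  list(
    prevalence = rows,
    completeness = 2 * n_complete / n_ind,
    n_individuals = n_ind,
    n_pairs = nrow(ds)
  )
}
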