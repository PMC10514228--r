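#' Phenotype codebooks
#'
#' A codebook is a tibble with one row per binary phenotype: its `name`
#' (unique identifier used in column headers), a display `label`, and a
#' `class_tag` in `{"prescription", "illicit"}`. The class tag drives the
#' two-factor loading pattern of independent pathway models in which
#' prescription misuse phenotypes load on one general factor and illicit
#' use phenotypes on the other.
#'
#' @param name Character vector of unique phenotype identifiers.
#' @param label Display labels (defaults to `name`).
#' @param class_tag Per-phenotype tag, `"prescription"` or `"illicit"`.
#' @return A tibble of class `twin_codebook`.
#' @examples
#' codebook(c("pom", "cannabis"), class_tag = c("prescription", "illicit"))
#' @export
codebook <- function(name, label = name, class_tag) {
  stopifnot(is.character(name), length(name) > 0)
  if (anyDuplicated(name)) {
    stop("codebook phenotype names must be unique", call. = FALSE)
  }
  if (any(!nzchar(name))) stop("codebook names must be non-empty", call. = FALSE)
  class_tag <- match_class_tag(class_tag, length(name))
  out <- tibble::tibble(name = name, label = label, class_tag = class_tag)
  class(out) <- c("twin_codebook", class(out))
  out
}

match_class_tag <- function(class_tag, n) {
  allowed <- c("prescription", "illicit")
  if (length(class_tag) == 1) class_tag <- rep(class_tag, n)
  if (length(class_tag) != n || !all(class_tag %in% allowed)) {
    stop("class_tag must be 'prescription' or 'illicit' for every phenotype",
      call. = FALSE
    )
  }
  class_tag
}

#' Read a codebook from YAML or JSON
#'
#' The file holds a list of records with fields `name`, `label` (optional),
#' and `class_tag`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `twin_codebook` tibble.
#' @export
read_codebook <- function(path) {
  stopifnot(file.exists(path))
  recs <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  name <- vapply(recs, function(r) as.character(r$name), character(1))
  label <- vapply(recs, function(r) {
    as.character(if (is.null(r$label)) r$name else r$label)
  }, character(1))
  tag <- vapply(recs, function(r) as.character(r$class_tag), character(1))
  codebook(name, label, tag)
}

#' The 11-phenotype drug (mis)use codebook
#'
#' Lifetime misuse of three prescription drug classes and lifetime use of
#' eight illicit drug classes, as assessed by structured interview in large
#' volunteer twin registries. Order is fixed and used throughout the
#' packaged presets.
#'
#' @return A `twin_codebook` tibble with 11 rows.
#' @export
atr_codebook <- function() {
  codebook(
    name = c(
      "pom", "stimulant_rx", "sedative_rx",
      "heroin", "cannabis", "cocaine", "stimulant_illicit",
      "hallucinogen", "inhalant", "solvent", "dissociative"
    ),
    label = c(
      "Prescription opioid misuse", "Prescription stimulant misuse",
      "Prescription sedative misuse", "Heroin use", "Cannabis use",
      "Cocaine/crack use", "Illicit stimulant use", "Hallucinogen use",
      "Inhalant use", "Solvent use", "Dissociative use"
    ),
    class_tag = c(rep("prescription", 3), rep("illicit", 8))
  )
}

assert_codebook <- function(cb) {
  if (!inherits(cb, "twin_codebook")) {
    if (is.data.frame(cb) && all(c("name", "class_tag") %in% names(cb))) {
      return(codebook(cb$name,
        label = if ("label" %in% names(cb)) cb$label else cb$name,
        class_tag = cb$class_tag
      ))
    }
    stop("expected a twin_codebook (see codebook())", call. = FALSE)
  }
  cb
}
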