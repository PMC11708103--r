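#' Two-level policy evaluation indicator schemas
#'
#' A `pmc_schema` describes the measurement frame of a PMC (Policy Modeling
#' Consistency) index model: an ordered set of main indicators, each holding
#' an ordered (possibly empty) set of binary sub-indicators. A main indicator
#' with no declared sub-indicators (the bundled system's X10, policy
#' disclosure) is itself a single binary variable: `sub_counts()` reports 0
#' declared subs for it, while the scoring layer treats it as one implicit
#' variable so it still contributes a 0/1 score.
#'
#' The bundled default system for traditional-Chinese-medicine emergency
#' policies has 10 main indicators (policy nature, time, release agency,
#' function, guarantees, perspective, evaluation, receptors, instrument,
#' disclosure) subdivided into 44 sub-indicators, all equally weighted.
#'
#' @name pmc_schema
NULL

new_pmc_schema <- function(name, version, mains) {
  structure(list(name = name, version = version, mains = mains),
            class = "pmc_schema")
}

#' Validate an indicator schema
#'
#' Checks structural invariants: unique main ids, unique sub ids, every sub id
#' prefixed by its parent main id, non-empty labels.
#'
#' @param schema a `pmc_schema`.
#' @return the schema, invisibly, if valid; otherwise an error naming the
#'   offending id.
#' @export
validate_schema <- function(schema) {
  if (!inherits(schema, "pmc_schema"))
    stop("not a pmc_schema object", call. = FALSE)
  main_ids <- vapply(schema$mains, `[[`, character(1), "id")
  dup <- unique(main_ids[duplicated(main_ids)])
  if (length(dup))
    stop("duplicate main indicator id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  sub_ids <- character(0)
  for (m in schema$mains) {
    if (!nzchar(m$id) || !nzchar(m$label))
      stop("main indicator with empty id or label", call. = FALSE)
    for (s in m$subs) {
      if (!startsWith(s$id, paste0(m$id, ":")))
        stop("sub-indicator '", s$id, "' does not belong to main '", m$id,
             "' (id must be prefixed '", m$id, ":')", call. = FALSE)
      sub_ids <- c(sub_ids, s$id)
    }
  }
  dup <- unique(sub_ids[duplicated(sub_ids)])
  if (length(dup))
    stop("duplicate sub-indicator id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  invisible(schema)
}

#' Read an indicator schema from a YAML or JSON file
#'
#' The file holds keys `name`, `version` and an ordered list `mains`, each
#' main with `id`, `label`, optional `source`, and a list `subs` of
#' `{id, label}` entries (empty list for a sub-less main). Ordering is
#' significant: the PMC surface is position-based.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` schema file.
#' @return a validated `pmc_schema`.
#' @seealso [default_schema()] for the bundled system, [write_schema()] for
#'   the inverse.
#' @export
read_schema <- function(path) {
  if (!file.exists(path)) stop("schema file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw$mains)) stop("schema file has no 'mains' list", call. = FALSE)
  mains <- lapply(raw$mains, function(m) {
    subs <- lapply(m$subs, function(s)
      list(id = as.character(s$id), label = as.character(s$label),
           source_note = if (is.null(s$source_note)) m$source else s$source_note))
    list(id = as.character(m$id), label = as.character(m$label),
         source = if (is.null(m$source)) "" else as.character(m$source),
         subs = subs)
  })
  schema <- new_pmc_schema(
    name = if (is.null(raw$name)) "" else raw$name,
    version = if (is.null(raw$version)) "" else as.character(raw$version),
    mains = mains)
  validate_schema(schema)
  schema
}

#' Write an indicator schema to YAML
#'
#' Serializes so that `read_schema(write_schema(s, f))` reproduces `s`
#' (round-trip identity up to the source-note inheritance rule).
#'
#' @param schema a `pmc_schema`.
#' @param path output file path (`.yaml`).
#' @return `path`, invisibly.
#' @export
write_schema <- function(schema, path) {
  validate_schema(schema)
  out <- list(
    name = schema$name, version = schema$version,
    mains = lapply(schema$mains, function(m)
      list(id = m$id, label = m$label, source = m$source,
           subs = lapply(m$subs, function(s) list(id = s$id, label = s$label)))))
  yaml::write_yaml(out, path)
  invisible(path)
}

#' The bundled default indicator system
#'
#' Loads the 10-main / 44-sub evaluation system for traditional-medicine
#' emergency-health policies shipped with the package.
#'
#' @return a `pmc_schema` with per-main sub counts 4, 3, 3, 12, 8, 2, 4, 4,
#'   4, 0.
#' @export
default_schema <- function() {
  read_schema(system.file("extdata", "tcm_emergency_schema.yaml",
                          package = "pmcindex", mustWork = TRUE))
}

#' Declared sub-indicator counts per main indicator
#'
#' Returns T(X_t), the number of declared sub-indicators of each main
#' indicator, in schema order. A sub-less main reports 0 here even though the
#' scoring layer gives it one implicit binary variable.
#'
#' @param schema a `pmc_schema`.
#' @return integer vector named by main indicator id.
#' @export
sub_counts <- function(schema) {
  validate_schema(schema)
  n <- vapply(schema$mains, function(m) length(m$subs), integer(1))
  names(n) <- vapply(schema$mains, `[[`, character(1), "id")
  n
}

#' Binary variable ids of a schema
#'
#' The full ordered set of 0/1 variables a score matrix must contain: all
#' declared sub-indicator ids, plus the main id itself for each sub-less main
#' (its implicit single variable).
#'
#' @param schema a `pmc_schema`.
#' @return character vector of column ids in schema order.
#' @export
binary_ids <- function(schema) {
  validate_schema(schema)
  unlist(lapply(schema$mains, function(m) {
    if (length(m$subs) == 0) m$id
    else vapply(m$subs, `[[`, character(1), "id")
  }))
}

#' @export
print.pmc_schema <- function(x, ...) {
  n <- sub_counts(x)
  cat("<pmc_schema> ", x$name,
      if (nzchar(x$version)) paste0(" (v", x$version, ")"), "\n", sep = "")
  cat("  ", length(x$mains), " main indicators, ",
      sum(n), " sub-indicators\n", sep = "")
  for (m in x$mains)
    cat(sprintf("  %-4s %-28s %d sub(s)\n", m$id, m$label, length(m$subs)))
  invisible(x)
}

#' Schema as a tidy table
#'
#' One row per binary variable with its parent main indicator, in schema
#' order; a sub-less main appears as its own single row.
#'
#' @param schema a `pmc_schema`.
#' @return a tibble with columns `main_id`, `main_label`, `sub_id`,
#'   `sub_label`.
#' @export
schema_table <- function(schema) {
  validate_schema(schema)
  rows <- lapply(schema$mains, function(m) {
    if (length(m$subs) == 0)
      return(tibble::tibble(main_id = m$id, main_label = m$label,
                            sub_id = m$id, sub_label = m$label))
    tibble::tibble(
      main_id = m$id, main_label = m$label,
      sub_id = vapply(m$subs, `[[`, character(1), "id"),
      sub_label = vapply(m$subs, `[[`, character(1), "label"))
  })
  dplyr::bind_rows(rows)
}
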