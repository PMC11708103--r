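#' PMC index scoring
#'
#' The scoring layer turns a binary policy-by-variable matrix into the
#' Policy Modeling Consistency (PMC) index. Each binary variable records
#' whether a policy text exhibits a feature (1) or not (0), all variables
#' within a main indicator are equally weighted, and
#'
#' * the main-indicator score is the mean of its binary variables,
#'   X_t = sum_j X_tj / T(X_tj), rounded half-up to 2 decimals;
#' * the PMC index is the sum of all main-indicator scores (again rounded
#'   half-up to 2 decimals), ranging from 0 to the number of main
#'   indicators (10 for the bundled system);
#' * the depression index is the shortfall from the maximum, M - PMC;
#' * policies are classified Excellent (7-10), Good (6-7), Acceptable (5-6)
#'   or Poor (< 5) and ranked by descending PMC.
#'
#' @name pmc-scoring
NULL

check_binary <- function(x, what = "score") {
  if (length(x) == 0) stop("empty ", what, " vector", call. = FALSE)
  bad <- !(x %in% c(0, 1)) | is.na(x)
  if (any(bad))
    stop("non-binary ", what, " value(s): ",
         paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  invisible(x)
}

#' Score one main indicator from its binary sub-indicator codings
#'
#' @param binary_row vector of 0/1 codings, one per sub-indicator of the main.
#' @param round logical; round half-up to 2 decimals (the published
#'   convention). `FALSE` returns the raw mean, useful for diagnostics.
#' @return the main-indicator score in \[0, 1\].
#' @examples
#' score_main(c(1, 1, 1, 1, 1, 1, 1, 0)) # 7/8 -> 0.88
#' @export
score_main <- function(binary_row, round = TRUE) {
  check_binary(binary_row)
  x <- sum(binary_row) / length(binary_row)
  if (round) round_half_up(x) else x
}

# check a score-matrix data frame against a schema; returns the matrix with
# columns pid + binary variables in schema order
check_score_matrix <- function(m, schema) {
  if (!is.data.frame(m) || !"pid" %in% names(m))
    stop("score matrix must be a data frame with a 'pid' column", call. = FALSE)
  if (anyDuplicated(m$pid))
    stop("duplicate policy id(s): ",
         paste(unique(m$pid[duplicated(m$pid)]), collapse = ", "),
         call. = FALSE)
  ids <- binary_ids(schema)
  have <- setdiff(names(m), "pid")
  missing <- setdiff(ids, have)
  extra <- setdiff(have, ids)
  if (length(missing) || length(extra))
    stop("score matrix columns do not match schema",
         if (length(missing)) paste0("; missing: ",
                                     paste(missing, collapse = ", ")),
         if (length(extra)) paste0("; extra: ",
                                   paste(extra, collapse = ", ")),
         call. = FALSE)
  for (id in ids) check_binary(m[[id]], paste0("'", id, "'"))
  m[, c("pid", ids)]
}

#' Main-indicator score table from a binary score matrix
#'
#' Applies [score_main()] per policy and main indicator: the analogue of the
#' published per-policy score tables.
#'
#' @param m data frame: column `pid` plus one 0/1 column per binary variable
#'   of `schema` (sub-indicator ids; the main id itself for a sub-less main).
#' @param schema a `pmc_schema`.
#' @param round round half-up at 2 decimals (default) or keep raw means.
#' @return tibble: `pid` plus one score column per main indicator, values in
#'   \[0, 1\].
#' @export
main_score_table <- function(m, schema, round = TRUE) {
  m <- check_score_matrix(m, schema)
  out <- tibble::tibble(pid = m$pid)
  for (main in schema$mains) {
    cols <- if (length(main$subs) == 0) main$id
            else vapply(main$subs, `[[`, character(1), "id")
    sub <- as.matrix(m[, cols, drop = FALSE])
    x <- rowSums(sub) / length(cols)
    out[[main$id]] <- if (round) round_half_up(x) else x
  }
  out
}

check_main_scores <- function(scores, main_ids = NULL) {
  if (!is.data.frame(scores) || !"pid" %in% names(scores))
    stop("main score table must be a data frame with a 'pid' column",
         call. = FALSE)
  cols <- setdiff(names(scores), "pid")
  if (!is.null(main_ids)) {
    missing <- setdiff(main_ids, cols)
    if (length(missing))
      stop("missing main indicator column(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    cols <- main_ids
  }
  vals <- as.matrix(scores[, cols, drop = FALSE])
  if (anyNA(vals))
    stop("missing main-indicator score(s) in column(s): ",
         paste(cols[colSums(is.na(vals)) > 0], collapse = ", "),
         call. = FALSE)
  if (any(vals < 0 | vals > 1))
    stop("main-indicator scores must lie in [0, 1]", call. = FALSE)
  scores[, c("pid", cols)]
}

#' PMC index of each policy
#'
#' Sums the main-indicator scores of every row — all main indicators
#' contribute, including a sub-less disclosure-type indicator — and rounds
#' half-up to 2 decimals.
#'
#' @param scores main-indicator score table (`pid` + one column per main).
#' @param round round the sum half-up at 2 decimals (default).
#' @return numeric vector of PMC indices, one per policy row.
#' @export
pmc_index <- function(scores, round = TRUE) {
  scores <- check_main_scores(scores)
  x <- rowSums(as.matrix(scores[, setdiff(names(scores), "pid"), drop = FALSE]))
  if (round) round_half_up(x) else x
}

#' PMC depression index
#'
#' The shortfall of a policy's PMC index from the maximum attainable score
#' M (the number of main indicators): depression = M - PMC. Lower is better.
#'
#' @param pmc numeric vector of PMC indices.
#' @param max_score maximum attainable PMC (default 10).
#' @return numeric vector, rounded half-up at 2 decimals.
#' @export
depression_index <- function(pmc, max_score = 10) {
  stopifnot(is.numeric(pmc), max_score >= 1)
  if (any(is.na(pmc) | pmc < 0 | pmc > max_score))
    stop("PMC index out of [0, ", max_score, "]", call. = FALSE)
  round_half_up(max_score - pmc)
}

#' Classify policies into consistency levels
#'
#' Thresholds on the 10-point scale: Excellent for PMC in \[7, 10\], Good in
#' \[6, 7), Acceptable in \[5, 6), Poor in \[0, 5). The four intervals
#' partition \[0, 10\]; boundaries belong to the higher level.
#'
#' @param pmc numeric vector of PMC indices in \[0, 10\].
#' @return factor with levels Excellent, Good, Acceptable, Poor.
#' @export
classify_level <- function(pmc) {
  stopifnot(is.numeric(pmc))
  if (any(is.na(pmc) | pmc < 0 | pmc > 10))
    stop("PMC index out of [0, 10]", call. = FALSE)
  lv <- c("Excellent", "Good", "Acceptable", "Poor")
  out <- ifelse(pmc >= 7, "Excellent",
         ifelse(pmc >= 6, "Good",
         ifelse(pmc >= 5, "Acceptable", "Poor")))
  factor(out, levels = lv)
}

#' Rank policies by PMC index
#'
#' Descending ranks. `ties = "competition"` gives each tied policy one plus
#' the number of strictly greater values (pattern 1-2-2-4); `ties = "first"`
#' gives a strict 1..n ordering, breaking ties by position in the input —
#' the convention the bundled study tables use.
#'
#' @param pmc numeric vector of PMC indices.
#' @param ties `"competition"` (default) or `"first"`.
#' @return integer vector of ranks, aligned with `pmc`.
#' @export
rank_policies <- function(pmc, ties = c("competition", "first")) {
  stopifnot(is.numeric(pmc), length(pmc) >= 1)
  ties <- match.arg(ties)
  method <- if (ties == "competition") "min" else "first"
  as.integer(rank(-pmc, ties.method = method))
}

#' Average each binary variable across policies
#'
#' The per-sub-indicator mean coding (detailed-scoring table analogue):
#' the fraction of policies exhibiting each feature, rounded half-up at 2
#' decimals.
#'
#' @param m binary score matrix (`pid` + 0/1 columns).
#' @param schema optional `pmc_schema`; when given, columns are validated and
#'   ordered against it.
#' @return tibble with columns `sub_id`, `score`.
#' @export
sub_indicator_averages <- function(m, schema = NULL) {
  if (!is.null(schema)) m <- check_score_matrix(m, schema)
  if (!is.data.frame(m) || !"pid" %in% names(m) || nrow(m) < 1)
    stop("need a score matrix with a 'pid' column and at least one policy",
         call. = FALSE)
  cols <- setdiff(names(m), "pid")
  for (id in cols) check_binary(m[[id]], paste0("'", id, "'"))
  tibble::tibble(
    sub_id = cols,
    score = unname(round_half_up(colMeans(as.matrix(m[, cols, drop = FALSE])))))
}

#' Evaluate policies from a main-indicator score table
#'
#' Computes PMC index, depression index, level and rank for each row of an
#' already-aggregated main-score table.
#'
#' @param scores main-indicator score table (`pid` + one column per main).
#' @param max_score maximum attainable PMC; defaults to the number of main
#'   indicator columns.
#' @param rank_ties tie convention passed to [rank_policies()]; the default
#'   `"first"` reproduces study tables that print a strict 1..n ordering.
#' @return tibble: `pid`, `pmc`, `depression`, `level`, `rank`.
#' @export
evaluate_scores <- function(scores, max_score = NULL,
                            rank_ties = c("first", "competition")) {
  rank_ties <- match.arg(rank_ties)
  scores <- check_main_scores(scores)
  if (is.null(max_score)) max_score <- length(setdiff(names(scores), "pid"))
  pmc <- pmc_index(scores)
  tibble::tibble(
    pid = scores$pid,
    pmc = pmc,
    depression = depression_index(pmc, max_score),
    level = classify_level(pmc),
    rank = rank_policies(pmc, ties = rank_ties))
}

#' Evaluate policies from a binary score matrix
#'
#' Full pipeline: binary codings -> main-indicator scores -> PMC index ->
#' depression, level, rank. Deterministic; errors from any stage propagate.
#'
#' @inheritParams main_score_table
#' @inheritParams evaluate_scores
#' @return tibble: `pid`, `pmc`, `depression`, `level`, `rank`.
#' @examples
#' s <- default_schema()
#' m <- gen_score_matrix(generator_config(n_policies = 3, p = 1, seed = 1), s)
#' evaluate_policies(m, s) # every policy scores the maximum, PMC = 10
#' @export
evaluate_policies <- function(m, schema, max_score = NULL,
                              rank_ties = c("first", "competition")) {
  evaluate_scores(main_score_table(m, schema), max_score = max_score,
                  rank_ties = match.arg(rank_ties))
}
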