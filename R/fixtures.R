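#' Bundled study fixtures
#'
#' Typed, validated versions of the study's printed tables, shipped as CSV:
#'
#' * `"table1"` — the 13 national policy documents: id, title, ISO release
#'   date, issuing agencies;
#' * `"table4"` — per-policy main-indicator scores (printed for P1-P12 only;
#'   the 13th policy's decomposition was never published);
#' * `"table5"` — PMC index, depression index, level and rank for all 13
#'   policies;
#' * `"table6"` — per-sub-indicator average codings across the 13 policies.
#'
#' @param name one of `"table1"`, `"table4"`, `"table5"`, `"table6"`.
#' @return a tibble; see Details for the columns of each fixture.
#' @examples
#' load_fixture("table5")[2, ] # P2: PMC 7.63, depression 2.37, Excellent, 1
#' @export
load_fixture <- function(name) {
  valid <- c("table1", "table4", "table5", "table6")
  if (!is.character(name) || length(name) != 1 || !name %in% valid)
    stop("unknown fixture '", name, "'; valid names: ",
         paste(valid, collapse = ", "), call. = FALSE)
  file <- c(table1 = "table1_policies.csv",
            table4 = "table4_main_scores.csv",
            table5 = "table5_results.csv",
            table6 = "table6_sub_averages.csv")[[name]]
  path <- system.file("extdata", file, package = "pmcindex", mustWork = TRUE)
  out <- tibble::as_tibble(
    utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                    encoding = "UTF-8"))
  switch(name,
    table1 = {
      out$release_date <- as.Date(out$release_date)
      out$agencies <- strsplit(out$agencies, ";\\s*")
      stopifnot(nrow(out) == 13, !anyNA(out$release_date),
                all(lengths(out$agencies) >= 1))
    },
    table4 = {
      stopifnot(all(as.matrix(out[, -1]) >= 0), all(as.matrix(out[, -1]) <= 1))
    },
    table5 = {
      out$level <- factor(out$level,
                          levels = c("Excellent", "Good", "Acceptable", "Poor"))
      stopifnot(nrow(out) == 13, !anyNA(out$level),
                all(abs(out$pmc + out$depression - 10) < 1e-9))
    },
    table6 = {
      stopifnot(all(out$score >= 0), all(out$score <= 1))
    })
  out
}
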