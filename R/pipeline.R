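#' End-to-end evaluation pipeline
#'
#' Runs the full PMC evaluation on file inputs and writes the result tables
#' (and optionally figures) to an output directory. All CSVs are UTF-8,
#' comma-delimited, with scores fixed at 2 decimals, so repeated runs on
#' identical inputs are byte-identical. On any error, partial outputs
#' created by the failing run are removed before the error propagates.
#'
#' Written artifacts: `main_scores.csv` (per-policy main-indicator scores),
#' `results.csv` (PMC, depression, level, rank), `sub_averages.csv`
#' (per-variable mean codings), `radar.csv` (mean indicator profile), and,
#' when metadata is supplied, `timeline.csv`; with `figures = TRUE` also
#' `radar.png`, `timeline.png` and one `surface_<pid>.png` per policy.
#'
#' @param matrix_path CSV with column `pid` and one 0/1 column per binary
#'   variable of the schema, in schema order.
#' @param output_dir directory to write into (created if absent).
#' @param schema_path optional schema YAML/JSON; default the bundled system.
#' @param meta_path optional policy-metadata CSV (`pid`, `title`,
#'   `release_date`, `agencies`) enabling the release timeline.
#' @param max_score maximum attainable PMC for the depression index; default
#'   the number of main indicators.
#' @param rank_ties rank tie convention, see [rank_policies()].
#' @param figures also write PNG figures (default `FALSE`).
#' @return invisibly, a named character vector of the files written.
#' @export
run_pipeline <- function(matrix_path, output_dir, schema_path = NULL,
                         meta_path = NULL, max_score = NULL,
                         rank_ties = c("first", "competition"),
                         figures = FALSE) {
  rank_ties <- match.arg(rank_ties)
  if (!file.exists(matrix_path))
    stop("score matrix file not found: ", matrix_path, call. = FALSE)
  if (!is.null(meta_path) && !file.exists(meta_path))
    stop("metadata file not found: ", meta_path, call. = FALSE)
  schema <- if (is.null(schema_path)) default_schema()
            else read_schema(schema_path)
  m <- tibble::as_tibble(utils::read.csv(matrix_path, check.names = FALSE,
                                         encoding = "UTF-8"))
  meta <- if (!is.null(meta_path))
    tibble::as_tibble(utils::read.csv(meta_path, check.names = FALSE,
                                      encoding = "UTF-8"))

  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  on_fail <- function(e) {
    unlink(written)
    stop(e)
  }
  tryCatch({
    scores <- main_score_table(m, schema)
    results <- evaluate_scores(scores, max_score = max_score,
                               rank_ties = rank_ties)
    averages <- sub_indicator_averages(m, schema)
    radar <- radar_series(scores)

    written <- c(written, write_score_csv(
      scores, file.path(output_dir, "main_scores.csv"),
      score_cols = setdiff(names(scores), "pid")))
    written <- c(written, write_score_csv(
      results, file.path(output_dir, "results.csv"),
      score_cols = c("pmc", "depression")))
    written <- c(written, write_score_csv(
      averages, file.path(output_dir, "sub_averages.csv"),
      score_cols = "score"))
    written <- c(written, write_score_csv(
      radar, file.path(output_dir, "radar.csv"), score_cols = "mean_score"))

    tl <- NULL
    if (!is.null(meta)) {
      tl <- timeline(meta)
      written <- c(written, write_score_csv(
        tl, file.path(output_dir, "timeline.csv"), score_cols = character(0)))
    }

    if (figures) {
      f <- file.path(output_dir, "radar.png")
      ggplot2::ggsave(f, plot_radar(radar), width = 5, height = 5, dpi = 96)
      written <- c(written, f)
      if (!is.null(tl)) {
        f <- file.path(output_dir, "timeline.png")
        ggplot2::ggsave(f, plot_timeline(tl), width = 6, height = 4, dpi = 96)
        written <- c(written, f)
      }
      for (i in seq_len(nrow(scores))) {
        pid <- scores$pid[i]
        f <- file.path(output_dir, paste0("surface_", pid, ".png"))
        ggplot2::ggsave(f, plot_surface(build_surface(scores[i, ]),
                                        title = pid),
                        width = 4, height = 4, dpi = 96)
        written <- c(written, f)
      }
    }
  }, error = on_fail)
  invisible(written)
}

# fixed-format CSV writer: named score columns at 2 decimals, UTF-8, LF
write_score_csv <- function(df, path, score_cols) {
  df <- as.data.frame(df)
  for (col in score_cols) df[[col]] <- format_score(df[[col]])
  for (col in names(df)) if (is.list(df[[col]]))
    df[[col]] <- vapply(df[[col]], paste, character(1), collapse = "; ")
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.csv(df, con, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8", eol = "\n")
  path
}
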