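#' PMC surface, radar and timeline summaries
#'
#' Visual-summary data objects: the 3x3 PMC surface matrix of one policy
#' (disclosure indicator removed for symmetry), the per-indicator mean
#' profile behind a radar chart, and per-year policy release counts.
#'
#' @name pmc-reporting
NULL

#' PMC surface matrix of one policy
#'
#' Arranges a policy's first nine main-indicator scores row-major into a
#' 3x3 matrix: (X1 X2 X3 / X4 X5 X6 / X7 X8 X9). The tenth (disclosure)
#' indicator is dropped so the matrix is square.
#'
#' @param row one row of a main-indicator score table (data frame with one
#'   row, or a named/plain numeric vector of at least 9 scores in indicator
#'   order; a `pid` column is ignored).
#' @return 3x3 numeric matrix with values in \[0, 1\].
#' @export
build_surface <- function(row) {
  if (is.data.frame(row)) {
    if (nrow(row) != 1)
      stop("expected a single policy row", call. = FALSE)
    row <- unlist(row[, setdiff(names(row), "pid"), drop = FALSE])
  }
  if (!is.numeric(row) || length(row) < 9)
    stop("need at least 9 main-indicator scores to build a surface",
         call. = FALSE)
  v <- as.numeric(row[1:9])
  if (anyNA(v) || any(v < 0 | v > 1))
    stop("surface scores must lie in [0, 1]", call. = FALSE)
  matrix(v, nrow = 3, byrow = TRUE)
}

#' Mean main-indicator profile (radar-chart series)
#'
#' Column means of a main-indicator score table over all policies present,
#' unrounded internally and reported at 2 decimals. Invariant to the order
#' of policy rows.
#'
#' @param scores main-indicator score table (`pid` + one column per main).
#' @return tibble with columns `indicator`, `mean_score`.
#' @export
radar_series <- function(scores) {
  scores <- check_main_scores(scores)
  if (nrow(scores) < 1) stop("need at least one policy", call. = FALSE)
  cols <- setdiff(names(scores), "pid")
  tibble::tibble(
    indicator = cols,
    mean_score = unname(round_half_up(
      colMeans(as.matrix(scores[, cols, drop = FALSE])))))
}

#' Policy releases per year
#'
#' Counts policies by release year, zero-filling every year in the observed
#' span so release-intensity line charts have a continuous axis.
#'
#' @param meta policy metadata: data frame with columns `pid` and
#'   `release_date` (Date or ISO-8601 string).
#' @return tibble with columns `year`, `n`; empty for an empty input.
#' @export
timeline <- function(meta) {
  if (!is.data.frame(meta) || !all(c("pid", "release_date") %in% names(meta)))
    stop("meta must have columns 'pid' and 'release_date'", call. = FALSE)
  if (nrow(meta) == 0)
    return(tibble::tibble(year = integer(0), n = integer(0)))
  dates <- as.Date(meta$release_date, format = "%Y-%m-%d")
  if (anyNA(dates))
    stop("unparseable release date for policy id(s): ",
         paste(meta$pid[is.na(dates)], collapse = ", "), call. = FALSE)
  yr <- as.integer(format(dates, "%Y"))
  span <- seq(min(yr), max(yr))
  counts <- table(factor(yr, levels = span))
  tibble::tibble(year = span, n = as.integer(counts))
}

#' Plot a PMC surface
#'
#' Renders the 3x3 surface grid as a filled tile map with a fixed \[0, 1\]
#' fill range so surfaces of different policies are directly comparable.
#' The rendering is presentation only; the data artifact is the exact grid.
#'
#' @param surface 3x3 matrix from [build_surface()].
#' @param title optional plot title.
#' @return a ggplot object.
#' @export
plot_surface <- function(surface, title = NULL) {
  stopifnot(is.matrix(surface), all(dim(surface) == c(3, 3)))
  df <- expand.grid(col = 1:3, row = 1:3)
  df$score <- as.vector(t(surface))
  df$label <- paste0("X", (df$row - 1) * 3 + df$col)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$score)) +
    ggplot2::geom_tile(color = "grey30") +
    ggplot2::geom_text(ggplot2::aes(
      label = paste0(.data$label, "\n", format_score(.data$score)))) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 1)) +
    ggplot2::labs(title = title, fill = "score", x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}

#' Plot the mean main-indicator radar profile
#'
#' @param series tibble from [radar_series()].
#' @return a ggplot object (polar bar rendering of the radar data).
#' @export
plot_radar <- function(series) {
  stopifnot(all(c("indicator", "mean_score") %in% names(series)))
  series$indicator <- factor(series$indicator, levels = series$indicator)
  ggplot2::ggplot(series, ggplot2::aes(x = .data$indicator,
                                       y = .data$mean_score)) +
    ggplot2::geom_col(fill = "steelblue", width = 1, color = "white") +
    ggplot2::coord_polar() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "mean score") +
    ggplot2::theme_minimal()
}

#' Plot policy releases over time
#'
#' @param counts tibble from [timeline()].
#' @return a ggplot object.
#' @export
plot_timeline <- function(counts) {
  stopifnot(all(c("year", "n") %in% names(counts)))
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$year, y = .data$n)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "release year", y = "policies released") +
    ggplot2::theme_minimal()
}
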