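#' Tidy an exam result
#'
#' @param x An `exam_result`.
#' @param ... Unused.
#' @return The per-point threshold tibble (`x`, `y`, `eye`, `threshold`,
#'   `floored`, `ceilinged`, `n_presentations`).
#' @exportS3Method generics::tidy
tidy.exam_result <- function(x, ...) {
  x$thresholds
}

#' @rdname tidy.exam_result
#' @return `glance()`: a one-row exam summary (central threshold, mean
#'   threshold, floored/ceilinged counts, presentations, duration).
#' @exportS3Method generics::glance
glance.exam_result <- function(x, ...) {
  tibble::tibble(
    n_points = nrow(x$thresholds),
    central_db = x$central$threshold,
    mean_db = mean(x$thresholds$threshold),
    n_floored = sum(x$thresholds$floored),
    n_ceilinged = sum(x$thresholds$ceilinged),
    total_presentations = x$total_presentations,
    duration_s = x$duration_s,
    tracking = x$config$tracking
  )
}

#' Tidy a correlation or comparison report
#'
#' @param x A `correlation_report` or `comparison_report`.
#' @param type `"regions"` or `"points"`.
#' @param ... Unused.
#' @return The requested tibble of correlations.
#' @exportS3Method generics::tidy
tidy.correlation_report <- function(x, type = c("regions", "points"), ...) {
  type <- match.arg(type)
  x[[type]]
}

#' @rdname tidy.correlation_report
#' @exportS3Method generics::tidy
tidy.comparison_report <- tidy.correlation_report

#' @rdname tidy.correlation_report
#' @return `glance()`: one row with eyes analyzed, global r and class, and
#'   the strength-class census over the 76 points.
#' @exportS3Method generics::glance
glance.comparison_report <- function(x, ...) {
  g <- x$regions[x$regions$region == "global", ]
  tibble::tibble(
    n_eyes = x$n_eyes,
    n_excluded = x$filter_counts$n_excluded,
    global_r = g$r,
    global_class = g$class,
    n_strong = sum(x$points$class == "strong", na.rm = TRUE),
    n_moderate = sum(x$points$class == "moderate", na.rm = TRUE),
    n_weak = sum(x$points$class == "weak", na.rm = TRUE),
    global_t_p = x$global_t$p
  )
}
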