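#' Default sector map for the 30-2 grid
#'
#' Assigns every test location to a hemifield and quadrant, and locations in
#' the paracentral/arcuate zone to one of five glaucoma-hemifield-test (GHT)
#' sector pairs mirrored across the horizontal meridian. The default GHT
#' assignment is the package's approximation of the canonical published
#' clusters: five sectors per hemifield sweeping the nasal step, paracentral
#' and arcuate regions (`|x| <= 21`, `|y| <= 21`); the peripheral ring and
#' the two blind-spot-adjacent points are unassigned (`NA`). Override with a
#' CSV via [read_sector_map()] and the `ght` argument.
#'
#' Sector names are `S1`-`S5` (superior) and `I1`-`I5` (inferior); `Sk` and
#' `Ik` are mirror images.
#'
#' @param eye Laterality.
#' @param ght Optional tibble `x`, `y`, `ght_sector` overriding the default
#'   GHT assignment (e.g. from [read_sector_map()]).
#' @return The grid tibble with an added `ght_sector` column.
#' @export
sector_map_30_2 <- function(eye = "OD", ght = NULL) {
  grid <- build_grid_30_2(eye)
  nasal_sign <- if (eye == "OD") -1 else 1
  nx <- grid$x * nasal_sign          # nasal-positive abscissa
  ay <- abs(grid$y)
  sec <- rep(NA_character_, nrow(grid))
  band <- function(cond) cond & !grid$blind_spot
  sec[band(nx %in% c(15, 21) & ay <= 9)] <- "1"  # nasal step region
  sec[band(nx %in% c(3, 9) & ay <= 9)] <- "2"    # paracentral nasal
  sec[band(nx %in% c(-3, -9) & ay <= 9)] <- "3"  # paracentral temporal
  sec[band(abs(grid$x) <= 15 & ay == 15)] <- "4" # arcuate inner
  sec[band(abs(grid$x) <= 15 & ay == 21)] <- "5" # arcuate outer
  grid$ght_sector <- ifelse(
    is.na(sec), NA_character_,
    paste0(ifelse(grid$hemifield == "superior", "S", "I"), sec)
  )
  if (!is.null(ght)) {
    grid <- grid |>
      dplyr::select(-"ght_sector") |>
      dplyr::left_join(dplyr::select(ght, "x", "y", "ght_sector"),
                       by = c("x", "y"))
  }
  grid
}

# region labels available on a sector map: global, hemifields, quadrants, GHT
region_labels <- function(sector_map) {
  c("global", "superior", "inferior", sort(unique(sector_map$quadrant)),
    sort(unique(sector_map$ght_sector[!is.na(sector_map$ght_sector)])))
}

# logical selector for a region label on a sector map
region_selector <- function(sector_map, region) {
  if (region == "global") rep(TRUE, nrow(sector_map))
  else if (region %in% c("superior", "inferior")) sector_map$hemifield == region
  else if (region %in% sector_map$quadrant) sector_map$quadrant == region
  else if (region %in% sector_map$ght_sector) {
    !is.na(sector_map$ght_sector) & sector_map$ght_sector == region
  } else abort(sprintf("unknown region label: %s", region))
}

#' Regional mean sensitivity
#'
#' Arithmetic mean of sensitivities over a region of the field: `"global"`,
#' a hemifield (`"superior"`/`"inferior"`), a quadrant (`"SN"`, `"ST"`,
#' `"IN"`, `"IT"`) or a GHT sector label. The two blind-spot-adjacent points
#' are excluded from every regional mean by default, following perimetric
#' convention.
#'
#' @param field Tibble with `x`, `y` and a sensitivity column (`sens` or
#'   `threshold`).
#' @param region Region label.
#' @param sector_map From [sector_map_30_2()] (must match the field's eye).
#' @param exclude_blind_spot Drop the blind-spot pair from the mean?
#' @return One-row tibble `region`, `mean_db`, `n`.
#' @export
region_mean <- function(field, region, sector_map = sector_map_30_2(),
                        exclude_blind_spot = TRUE) {
  val <- if ("sens" %in% names(field)) field$sens else field$threshold
  key <- paste(field$x, field$y)
  mkey <- paste(sector_map$x, sector_map$y)
  idx <- match(mkey, key)
  if (anyNA(idx)) abort("field does not cover the sector map's grid")
  sel <- region_selector(sector_map, region)
  if (exclude_blind_spot) sel <- sel & !sector_map$blind_spot
  if (!any(sel)) abort(sprintf("region %s selects no points", region))
  tibble::tibble(region = region, mean_db = mean(val[idx[sel]]),
                 n = sum(sel))
}

#' Classify a Pearson correlation by strength
#'
#' Strength cut-offs: strong if `r >= 0.7`; moderate if `0.4 <= r < 0.7`;
#' weak if `r < 0.4` (boundaries inclusive on the stronger side).
#'
#' @param r Correlation coefficient(s) in `[-1, 1]`; `NA` allowed
#'   (undefined correlations) and returned as `NA`.
#' @return Character vector: `"strong"`, `"moderate"` or `"weak"`.
#' @examples
#' classify_r(c(0.81, 0.7, 0.4, 0.39, -0.2))
#' @export
classify_r <- function(r) {
  if (any(abs(r) > 1, na.rm = TRUE)) abort("|r| cannot exceed 1")
  dplyr::case_when(
    is.na(r) ~ NA_character_,
    r >= 0.7 ~ "strong",
    r >= 0.4 ~ "moderate",
    .default = "weak"
  )
}

# Pearson r with two-sided p; zero-variance series flagged as undefined
pearson_or_na <- function(a, b) {
  if (sd(a) == 0 || sd(b) == 0) {
    return(tibble::tibble(r = NA_real_, p = NA_real_, undefined = TRUE))
  }
  ct <- cor.test(a, b, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p = ct$p.value, undefined = FALSE)
}

#' Device-agreement correlations over a cohort
#'
#' For each region (global, hemifields, quadrants, GHT sectors) computes the
#' Pearson correlation across eyes between the two devices' regional mean
#' sensitivities, and for each of the 76 test locations the point-wise
#' correlation across eyes; every `r` carries its strength class and
#' two-sided p-value. Zero-variance series are flagged undefined rather than
#' coerced.
#'
#' @param cohort A `paired_cohort` (already reliability-filtered if desired).
#' @param sector_map From [sector_map_30_2()].
#' @param exclude_blind_spot Exclude the blind-spot pair from regional means?
#' @return A `correlation_report`: list with `regions` and `points` tibbles
#'   (`r`, `n`, `class`, `p`, `undefined`) and `n_eyes`.
#' @export
cohort_correlations <- function(cohort, sector_map = sector_map_30_2(),
                                exclude_blind_spot = TRUE) {
  stopifnot(inherits(cohort, "paired_cohort"))
  n_eyes <- nrow(cohort$manifest)
  if (n_eyes < 3) abort("correlation analysis requires at least 3 eyes")
  f <- cohort$fields
  regions <- purrr::map(region_labels(sector_map), function(reg) {
    means <- f |>
      dplyr::group_by(.data$eye_id) |>
      dplyr::group_map(function(df, key) {
        tibble::tibble(
          eye_id = key$eye_id,
          a = region_mean(dplyr::rename(df, sens = "sens_a"), reg,
                          sector_map, exclude_blind_spot)$mean_db,
          b = region_mean(dplyr::rename(df, sens = "sens_b"), reg,
                          sector_map, exclude_blind_spot)$mean_db
        )
      }) |> purrr::list_rbind()
    dplyr::bind_cols(tibble::tibble(region = reg),
                     pearson_or_na(means$a, means$b),
                     tibble::tibble(n = n_eyes))
  }) |> purrr::list_rbind()
  points <- f |>
    dplyr::group_by(.data$x, .data$y) |>
    dplyr::group_map(function(df, key) {
      dplyr::bind_cols(key, pearson_or_na(df$sens_a, df$sens_b),
                       tibble::tibble(n = nrow(df)))
    }) |> purrr::list_rbind()
  regions$class <- classify_r(regions$r)
  points$class <- classify_r(points$r)
  structure(
    list(regions = regions, points = points, n_eyes = n_eyes,
         eye = cohort$manifest$laterality[1]),
    class = "correlation_report"
  )
}

#' Reliability-based exclusion of unreliable exams
#'
#' Excludes a record iff `fl > fl_max` OR `fp > fp_max` OR `fn > fn_max`
#' (strict inequalities: a record exactly at a threshold is kept). A record
#' with a missing index is an error, never a silent inclusion.
#'
#' @param records Tibble with columns `fl`, `fp`, `fn` (proportions), e.g. a
#'   cohort manifest.
#' @param fl_max,fp_max,fn_max Exclusion thresholds (fixation loss 20%,
#'   false positives 15%, false negatives 30% by default).
#' @return A list: `kept` (tibble), `excluded` (tibble with a `reasons`
#'   column naming the violated indices).
#' @examples
#' reliability_filter(tibble::tibble(fl = c(0.25, 0.20), fp = 0, fn = 0))
#' @export
reliability_filter <- function(records, fl_max = 0.20, fp_max = 0.15,
                               fn_max = 0.30) {
  need <- c("fl", "fp", "fn")
  missing_col <- setdiff(need, names(records))
  if (length(missing_col) > 0) {
    abort(paste0("records lack reliability column(s): ",
                 paste(missing_col, collapse = ", ")))
  }
  bad <- which(!stats::complete.cases(records[need]))
  if (length(bad) > 0) {
    abort(sprintf("record %d has a missing reliability index", bad[1]))
  }
  reasons <- purrr::pmap_chr(records[need], function(fl, fp, fn) {
    r <- c(if (fl > fl_max) "FL", if (fp > fp_max) "FP", if (fn > fn_max) "FN")
    paste(r, collapse = "+")
  })
  list(
    kept = records[reasons == "", , drop = FALSE],
    excluded = dplyr::bind_cols(records[reasons != "", , drop = FALSE],
                                tibble::tibble(reasons = reasons[reasons != ""]))
  )
}

#' Apply the reliability filter to a cohort
#'
#' @param cohort A `paired_cohort`.
#' @inheritParams reliability_filter
#' @return The filtered cohort with attribute `"filter_counts"`
#'   (`n_input`, `n_excluded`, `n_analyzed`).
#' @export
filter_cohort <- function(cohort, fl_max = 0.20, fp_max = 0.15,
                          fn_max = 0.30) {
  flt <- reliability_filter(cohort$manifest, fl_max, fp_max, fn_max)
  out <- cohort
  out$manifest <- flt$kept
  out$fields <- dplyr::filter(cohort$fields,
                              .data$eye_id %in% flt$kept$eye_id)
  attr(out, "filter_counts") <- tibble::tibble(
    n_input = nrow(cohort$manifest), n_excluded = nrow(flt$excluded),
    n_analyzed = nrow(flt$kept))
  attr(out, "excluded") <- flt$excluded
  out
}

#' Paired-sample t-test
#'
#' Standard paired t on the differences with a two-sided p from the t
#' distribution on n - 1 degrees of freedom. Zero variance of the
#' differences (including identical vectors) yields an undefined-statistic
#' flag instead of a number.
#'
#' @param xs,ys Paired numeric vectors of equal length >= 2.
#' @return One-row tibble `t`, df`, `p`, `mean_diff`, `undefined`.
#' @examples
#' paired_t(c(1, 2, 3, 4), c(2, 2, 4, 5))  # t = -3, df = 3
#' @export
paired_t <- function(xs, ys) {
  if (length(xs) != length(ys)) abort("paired vectors must have equal length")
  if (length(xs) < 2) abort("paired t requires at least 2 pairs")
  d <- xs - ys
  if (sd(d) == 0) {
    return(tibble::tibble(t = NA_real_, df = length(d) - 1, p = NA_real_,
                          mean_diff = mean(d), undefined = TRUE))
  }
  ht <- t.test(xs, ys, paired = TRUE)
  tibble::tibble(t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value, mean_diff = unname(ht$estimate),
                 undefined = FALSE)
}

#' Full device-comparison report
#'
#' Runs the reliability filter, the regional and point-wise correlation
#' analysis and a paired t-test on the global means, and assembles a
#' machine-readable report mirroring the shape of a two-device agreement
#' study: filter counts, per-region correlations with strength classes, the
#' 76-point classification grid, and the global paired t.
#'
#' @param cohort A `paired_cohort`.
#' @param sector_map From [sector_map_30_2()].
#' @param filter Apply the reliability filter first?
#' @return A `comparison_report` list: `filter_counts`, `regions`, `points`,
#'   `global_t`, `n_eyes`.
#' @export
comparison_report <- function(cohort, sector_map = sector_map_30_2(),
                              filter = TRUE) {
  analyzed <- if (filter) filter_cohort(cohort) else cohort
  counts <- attr(analyzed, "filter_counts") %||% tibble::tibble(
    n_input = nrow(cohort$manifest), n_excluded = 0L,
    n_analyzed = nrow(cohort$manifest))
  corr <- cohort_correlations(analyzed, sector_map)
  gm <- analyzed$fields |>
    dplyr::group_by(.data$eye_id) |>
    dplyr::summarise(a = mean(.data$sens_a), b = mean(.data$sens_b))
  structure(
    list(filter_counts = counts, regions = corr$regions,
         points = corr$points, global_t = paired_t(gm$a, gm$b),
         n_eyes = corr$n_eyes, eye = corr$eye),
    class = "comparison_report"
  )
}

#' Write / read a comparison report as JSON
#'
#' @param report A `comparison_report`.
#' @param path File path.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "comparison_report"))
  doc <- list(format = "perisim-comparison-report", version = 1L,
              filter_counts = report$filter_counts, regions = report$regions,
              points = report$points, global_t = report$global_t,
              n_eyes = report$n_eyes, eye = report$eye)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "perisim-comparison-report")) {
    abort("not a perisim comparison-report document")
  }
  structure(
    list(filter_counts = tibble::as_tibble(doc$filter_counts),
         regions = tibble::as_tibble(doc$regions),
         points = tibble::as_tibble(doc$points),
         global_t = tibble::as_tibble(doc$global_t),
         n_eyes = doc$n_eyes, eye = doc$eye),
    class = "comparison_report"
  )
}

#' Render the per-point classification grid
#'
#' Three-level raster of the point-wise correlation classes (strong,
#' moderate, weak), mirroring a point-by-point agreement figure: each test
#' location's 6 x 6 degree cell painted white (strong, 255), mid-gray
#' (moderate, 170) or dark (weak, 85); undefined correlations render at the
#' background level.
#'
#' @param report A `correlation_report` or `comparison_report`.
#' @param px_per_deg Raster resolution.
#' @return A `gray_map` integer matrix.
#' @export
render_classification_grid <- function(report, px_per_deg = 4) {
  pts <- report$points
  lev <- c(strong = 255L, moderate = 170L, weak = 85L)
  vals <- dplyr::coalesce(lev[pts$class], 200L)
  df <- tibble::tibble(x = pts$x, y = pts$y, gray = as.integer(vals))
  half <- 30.5
  n <- as.integer(2 * half * px_per_deg)
  cx <- -half + (seq_len(n) - 0.5) / px_per_deg
  cy <- half - (seq_len(n) - 0.5) / px_per_deg
  img <- matrix(200L, n, n)
  for (k in seq_len(nrow(df))) {
    xi <- which(cx >= df$x[k] - 3 & cx < df$x[k] + 3)
    yi <- which(cy <= df$y[k] + 3 & cy > df$y[k] - 3)
    img[yi, xi] <- df$gray[k]
  }
  structure(img, class = c("gray_map", "matrix", "array"))
}

#' @export
print.comparison_report <- function(x, ...) {
  g <- x$regions[x$regions$region == "global", ]
  cat(sprintf(
    "<comparison_report> %d eyes analyzed (%d excluded); global r = %.2f (%s)\n",
    x$filter_counts$n_analyzed, x$filter_counts$n_excluded, g$r, g$class))
  invisible(x)
}
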