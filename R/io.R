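#' Write / read an exam result as JSON
#'
#' The JSON document embeds the per-point thresholds, the central (fixation)
#' threshold, the presentation log, the echoed configuration (grid included)
#' and the observer descriptor hash. `read_exam_result()` validates the
#' structure: required keys, grid completeness (76 locations, no duplicates)
#' and flag types, with descriptive errors.
#'
#' @param result An `exam_result`.
#' @param path File path.
#' @return `write_exam_result()`: `path` invisibly; `read_exam_result()`: an
#'   `exam_result`.
#' @export
write_exam_result <- function(result, path) {
  stopifnot(inherits(result, "exam_result"))
  cfg <- result$config
  doc <- list(
    format = "perisim-exam-result", version = 1L,
    thresholds = result$thresholds,
    central = result$central,
    log = result$log,
    total_presentations = result$total_presentations,
    duration_s = result$duration_s,
    config = list(
      grid = dplyr::select(cfg$grid, "x", "y", "eye"),
      luminance = unclass(cfg$luminance),
      stimulus_ms = cfg$stimulus_ms,
      response_window_ms = cfg$response_window_ms,
      inter_stimulus_ms = cfg$inter_stimulus_ms,
      tracking = cfg$tracking, seeding = cfg$seeding,
      order_seed = cfg$order_seed, bowl_radius_mm = cfg$bowl_radius_mm
    ),
    observer_hash = result$observer_hash
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_exam_result
#' @export
read_exam_result <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("format", "thresholds", "central", "log", "config",
            "total_presentations", "duration_s", "observer_hash")
  missing <- setdiff(need, names(doc))
  if (length(missing) > 0) {
    abort(paste0("result JSON missing keys: ", paste(missing, collapse = ", ")))
  }
  if (!identical(doc$format, "perisim-exam-result")) {
    abort("not a perisim exam-result document")
  }
  th <- tibble::as_tibble(doc$thresholds)
  validate_grid_points(th, "thresholds")
  cfgd <- doc$config
  config <- exam_config(
    grid = build_grid_30_2(cfgd$grid$eye[1]),
    luminance = do.call(luminance_spec, cfgd$luminance),
    stimulus_ms = cfgd$stimulus_ms,
    response_window_ms = cfgd$response_window_ms,
    inter_stimulus_ms = cfgd$inter_stimulus_ms,
    tracking = cfgd$tracking, seeding = cfgd$seeding,
    order_seed = cfgd$order_seed, bowl_radius_mm = cfgd$bowl_radius_mm
  )
  structure(
    list(thresholds = th,
         central = tibble::as_tibble(doc$central),
         log = tibble::as_tibble(doc$log),
         total_presentations = doc$total_presentations,
         duration_s = doc$duration_s,
         config = config,
         observer_hash = doc$observer_hash),
    class = "exam_result"
  )
}

# a complete 30-2 point set: 76 unique locations on the canonical grid
validate_grid_points <- function(df, what, eye = df$eye[1]) {
  ref <- build_grid_30_2(if (is.null(eye) || is.na(eye)) "OD" else eye)
  key <- paste(df$x, df$y)
  refkey <- paste(ref$x, ref$y)
  dup <- key[duplicated(key)]
  if (length(dup) > 0) {
    abort(sprintf("%s: duplicate location(s): %s", what,
                  paste(unique(dup), collapse = "; ")))
  }
  miss <- setdiff(refkey, key)
  if (length(miss) > 0) {
    abort(sprintf("%s: missing %d of 76 locations, first absent (x, y) = (%s)",
                  what, length(miss), sub(" ", ", ", miss[1])))
  }
  extra <- setdiff(key, refkey)
  if (length(extra) > 0) {
    abort(sprintf("%s: location(s) not on the 30-2 grid: %s", what,
                  paste(extra, collapse = "; ")))
  }
  invisible(df)
}

#' Write / read a 30-2 field table as CSV
#'
#' Columns `x_deg`, `y_deg`, `sens_db` (plus any extra columns, preserved).
#' The reader validates completeness of the 76-point pattern and reports
#' missing or duplicate locations with line context.
#'
#' @param field Tibble with `x`, `y`, `sens` (or `threshold`).
#' @param path File path.
#' @param eye Laterality used to validate the pattern on read.
#' @return `read_field_csv()`: tibble `x`, `y`, `sens` (+ extras).
#' @export
write_field_csv <- function(field, path) {
  val <- if ("sens" %in% names(field)) field$sens else field$threshold
  extra <- field[setdiff(names(field),
                         c("x", "y", "sens", "threshold", "eye", "ecc",
                           "side", "hemifield", "quadrant", "blind_spot"))]
  out <- tibble::tibble(x_deg = field$x, y_deg = field$y, sens_db = val)
  readr::write_csv(dplyr::bind_cols(out, extra), path)
  invisible(path)
}

#' @rdname write_field_csv
#' @export
read_field_csv <- function(path, eye = "OD") {
  df <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("x_deg", "y_deg", "sens_db")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    abort(sprintf("field CSV %s missing column(s): %s", path,
                  paste(missing, collapse = ", ")))
  }
  bad <- which(!is.finite(df$sens_db))
  if (length(bad) > 0) {
    abort(sprintf("field CSV %s: non-numeric sensitivity at data row %d",
                  path, bad[1]))
  }
  out <- tibble::tibble(x = df$x_deg, y = df$y_deg, sens = df$sens_db,
                        eye = eye)
  validate_grid_points(out, sprintf("field CSV %s", path), eye = eye)
  dplyr::bind_cols(out, df[setdiff(names(df), need)])
}

#' Read a sector-map CSV
#'
#' Columns `x_deg`, `y_deg`, `sector_id`; every coordinate must lie on the
#' 30-2 grid. Used to override the default glaucoma-hemifield-test sector
#' assignment of [sector_map_30_2()].
#'
#' @param path File path.
#' @param eye Laterality for grid validation.
#' @return Tibble `x`, `y`, `ght_sector`.
#' @export
read_sector_map <- function(path, eye = "OD") {
  df <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("x_deg", "y_deg", "sector_id")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    abort(sprintf("sector map %s missing column(s): %s", path,
                  paste(missing, collapse = ", ")))
  }
  ref <- build_grid_30_2(eye)
  off <- !(paste(df$x_deg, df$y_deg) %in% paste(ref$x, ref$y))
  if (any(off)) {
    abort(sprintf(
      "sector map %s: coordinate not on the 30-2 grid at data row %d: (%g, %g)",
      path, which(off)[1], df$x_deg[which(off)[1]], df$y_deg[which(off)[1]]))
  }
  tibble::tibble(x = df$x_deg, y = df$y_deg,
                 ght_sector = as.character(df$sector_id))
}

#' Write / read a paired cohort
#'
#' A cohort directory holds `manifest.csv` (one row per eye: id, laterality,
#' FL/FP/FN reliability indices, MD/PSD/VFI metadata) and one
#' `<eye_id>.csv` per eye with columns `x_deg`, `y_deg`, `sens_a_db`,
#' `sens_b_db`.
#'
#' @param cohort A `paired_cohort` from [make_paired_cohort()].
#' @param dir Directory path (created if needed).
#' @return `read_cohort()`: a `paired_cohort` (without generator params).
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "paired_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(cohort$manifest, file.path(dir, "manifest.csv"))
  cohort$fields |>
    dplyr::group_by(.data$eye_id) |>
    dplyr::group_walk(function(df, key) {
      df |>
        dplyr::select(x_deg = "x", y_deg = "y", sens_a_db = "sens_a",
                      sens_b_db = "sens_b") |>
        readr::write_csv(file.path(dir, paste0(key$eye_id, ".csv")))
    })
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  man_path <- file.path(dir, "manifest.csv")
  if (!file.exists(man_path)) {
    abort(sprintf("cohort directory %s has no manifest.csv", dir))
  }
  manifest <- readr::read_csv(man_path, show_col_types = FALSE)
  need <- c("eye_id", "laterality", "fl", "fp", "fn")
  missing <- setdiff(need, names(manifest))
  if (length(missing) > 0) {
    abort(paste0("cohort manifest missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  fields <- purrr::map(seq_len(nrow(manifest)), function(i) {
    p <- file.path(dir, paste0(manifest$eye_id[i], ".csv"))
    if (!file.exists(p)) abort(sprintf("cohort eye file missing: %s", p))
    df <- readr::read_csv(p, show_col_types = FALSE)
    chk <- tibble::tibble(x = df$x_deg, y = df$y_deg,
                          eye = manifest$laterality[i])
    validate_grid_points(chk, p, eye = manifest$laterality[i])
    tibble::tibble(eye_id = manifest$eye_id[i], x = df$x_deg, y = df$y_deg,
                   sens_a = df$sens_a_db, sens_b = df$sens_b_db)
  }) |> purrr::list_rbind()
  structure(
    list(manifest = tibble::as_tibble(manifest), fields = fields,
         grid = build_grid_30_2(manifest$laterality[1]), params = NULL),
    class = "paired_cohort"
  )
}
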