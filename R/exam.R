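#' Exam configuration
#'
#' Collects everything a simulated exam needs besides the observer: the test
#' grid, photometric spec, stimulus timing (200 ms presentation, 1 s response
#' window, plus an inter-stimulus gap), whether gaze-contingent tracking is
#' active, the seeding policy for non-fixation staircases, and the seed
#' controlling the random testing order.
#'
#' @param grid Test grid from [build_grid_30_2()].
#' @param luminance A [luminance_spec()].
#' @param stimulus_ms Stimulus presentation time, ms.
#' @param response_window_ms Response window, ms (>= `stimulus_ms`).
#' @param inter_stimulus_ms Inter-stimulus interval, ms.
#' @param tracking `"on"` (gaze-contingent repositioning) or `"off"`.
#' @param seeding `"central"` (all points seeded by the fixation threshold,
#'   the default policy) or `"neighbour"` (each point seeded by the mean
#'   threshold of already-completed points within 8.5 degrees, falling back to
#'   the central threshold; an extension) or `"none"`.
#' @param order_seed Integer seed for the random testing order.
#' @param bowl_radius_mm Virtual bowl radius, mm.
#' @return An `exam_config` list.
#' @export
exam_config <- function(grid = build_grid_30_2("OD"),
                        luminance = luminance_spec(),
                        stimulus_ms = 200, response_window_ms = 1000,
                        inter_stimulus_ms = 500,
                        tracking = c("on", "off"),
                        seeding = c("central", "neighbour", "none"),
                        order_seed = 1L, bowl_radius_mm = 330) {
  tracking <- match.arg(tracking)
  seeding <- match.arg(seeding)
  if (stimulus_ms <= 0 || response_window_ms <= 0 || inter_stimulus_ms < 0) {
    abort("durations must be positive")
  }
  if (stimulus_ms > response_window_ms) {
    abort("stimulus_ms must not exceed response_window_ms")
  }
  structure(
    list(grid = grid, luminance = luminance, stimulus_ms = stimulus_ms,
         response_window_ms = response_window_ms,
         inter_stimulus_ms = inter_stimulus_ms, tracking = tracking,
         seeding = seeding, order_seed = as.integer(order_seed),
         bowl_radius_mm = bowl_radius_mm),
    class = "exam_config"
  )
}

# polynomial rolling hash of a deparsed object; stable run-to-run identifier
descriptor_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run a complete simulated exam
#'
#' Orchestrates a full threshold exam against a simulated observer:
#' \enumerate{
#'   \item The fixation point (0, 0) is thresholded first, unseeded, so the
#'     first stimulus is 27 dB (the midpoint of the 14-40 dB range); its
#'     result is the central threshold.
#'   \item The 76 grid points are visited in a random order drawn from
#'     `order_seed`, each with a bisection staircase seeded per the config
#'     (by default, by the central threshold).
#'   \item Each presentation draws a gaze sample from the observer's wander
#'     distribution, places the stimulus gaze-contingently (tracking on) or
#'     at the uncorrected bowl position (tracking off), queries the
#'     frequency-of-seeing observer, and updates the staircase.
#'   \item Simulated time accrues as stimulus + response window +
#'     inter-stimulus interval per presentation.
#' }
#'
#' The observer's response stream is seeded from `observer$rng_seed`, so an
#' identical (observer seed, order seed) pair reproduces the exam exactly.
#'
#' @param observer An [observer_model()]; its field must be on the same grid
#'   as the config.
#' @param config An [exam_config()].
#' @return An `exam_result` list: `thresholds` (tibble, one row per grid
#'   point: `x`, `y`, `eye`, `threshold`, `floored`, `ceilinged`,
#'   `n_presentations`), `central` (fixation-point threshold row),
#'   `log` (per-presentation tibble), `total_presentations`, `duration_s`,
#'   `config`, `observer_hash`.
#' @examples
#' obs <- observer_model(make_normal_field(build_grid_30_2("OD"), seed = 7),
#'                       rng_seed = 7)
#' res <- run_exam(obs, exam_config(order_seed = 7))
#' res$central$threshold
#' @export
run_exam <- function(observer, config = exam_config()) {
  stopifnot(inherits(observer, "observer_model"),
            inherits(config, "exam_config"))
  grid <- config$grid
  tf <- observer$true_field
  if (!identical(tf$x, grid$x) || !identical(tf$y, grid$y) ||
      !identical(tf$eye, grid$eye)) {
    abort("observer field grid does not match the exam config grid")
  }
  tracking_on <- config$tracking == "on"
  floor_db <- 14
  log_rows <- vector("list", 0)
  presentation_s <- (config$stimulus_ms + config$response_window_ms +
                       config$inter_stimulus_ms) / 1000

  ecc_target <- sqrt(config$grid$x^2 + config$grid$y^2)
  max_ecc <- max(ecc_target)

  run_one <- function(idx, x, y, seed_db) {
    st <- init_state(floor_db, 40, seed_db)
    presented <- numeric(0)
    seen_v <- logical(0)
    gxs <- numeric(0)
    gys <- numeric(0)
    while (!st$terminated) {
      intensity <- next_intensity(st)
      gx <- rnorm(1, 0, observer$gaze_sd)
      gy <- rnorm(1, 0, observer$gaze_sd)
      if (tracking_on && sqrt(gx^2 + gy^2) + max_ecc >= 90) {
        # gaze so eccentric the repositioned stimulus may leave the display:
        # skip and retry with the next gaze sample
        ok <- tryCatch({
          gaze_contingent_position(x, y, gx, gy, config$bowl_radius_mm)
          TRUE
        }, perisim_out_of_display = function(e) FALSE)
        if (!ok) next
      }
      seen <- respond(observer, x, y, intensity, gx, gy, tracking_on)
      st <- stair_update(st, intensity, seen)
      presented <- c(presented, intensity)
      seen_v <- c(seen_v, seen)
      gxs <- c(gxs, gx)
      gys <- c(gys, gy)
    }
    list(
      final = final_threshold(st),
      log = tibble::tibble(
        location = idx, x = x, y = y, presented = presented, seen = seen_v,
        gaze_x = gxs, gaze_y = gys, elapsed_ms = 1000 * presentation_s
      )
    )
  }

  order_idx <- with_local_seed(config$order_seed, sample.int(nrow(grid)))

  result <- with_local_seed(observer$rng_seed, {
    central <- run_one(0L, 0, 0, NULL)
    done_x <- numeric(0)
    done_y <- numeric(0)
    done_th <- numeric(0)
    th_rows <- vector("list", nrow(grid))
    logs <- vector("list", nrow(grid) + 1)
    logs[[1]] <- central$log
    for (k in seq_along(order_idx)) {
      idx <- order_idx[k]
      seed_db <- switch(
        config$seeding,
        none = NULL,
        central = central$final$threshold,
        neighbour = {
          near <- sqrt((done_x - grid$x[idx])^2 +
                         (done_y - grid$y[idx])^2) <= 8.5
          if (any(near)) mean(done_th[near]) else central$final$threshold
        }
      )
      one <- run_one(idx, grid$x[idx], grid$y[idx], seed_db)
      th_rows[[idx]] <- dplyr::bind_cols(
        grid[idx, c("x", "y", "eye")], one$final
      )
      done_x <- c(done_x, grid$x[idx])
      done_y <- c(done_y, grid$y[idx])
      done_th <- c(done_th, one$final$threshold)
      logs[[k + 1]] <- one$log
    }
    list(thresholds = purrr::list_rbind(th_rows),
         central = dplyr::bind_cols(tibble::tibble(x = 0, y = 0),
                                    central$final),
         log = purrr::list_rbind(logs))
  })

  total <- nrow(result$log)
  structure(
    list(
      thresholds = result$thresholds,
      central = result$central,
      log = result$log,
      total_presentations = total,
      duration_s = total * presentation_s,
      config = config,
      observer_hash = descriptor_hash(
        observer[c("fos_slope", "fp_rate", "fn_rate", "gaze_sd", "rng_seed")]
      )
    ),
    class = "exam_result"
  )
}

#' Simulated exam duration
#'
#' Total simulated wall time: presentations x (stimulus + response window +
#' inter-stimulus interval). Early-response truncation is not modelled.
#'
#' @param result An `exam_result`.
#' @return Duration in seconds.
#' @export
simulated_duration <- function(result) {
  stopifnot(inherits(result, "exam_result"))
  cfg <- result$config
  result$total_presentations *
    (cfg$stimulus_ms + cfg$response_window_ms + cfg$inter_stimulus_ms) / 1000
}

#' @export
print.exam_result <- function(x, ...) {
  cat(sprintf(
    "<exam_result> %d locations, central threshold %.2f dB,\n  %d presentations, simulated duration %.1f s (%.1f min), tracking %s\n",
    nrow(x$thresholds), x$central$threshold, x$total_presentations,
    x$duration_s, x$duration_s / 60, x$config$tracking
  ))
  invisible(x)
}
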