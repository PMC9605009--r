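#' Generate a normal "hill of vision" true sensitivity field
#'
#' True (ground-truth) sensitivity at each grid point follows the normal hill
#' of vision: an apex sensitivity `s0` at fixation declining linearly with
#' eccentricity, plus independent Gaussian point scatter. Defaults (33 dB
#' apex, 0.3 dB/degree decline, 1 dB scatter) are conventional normative
#' values for a healthy mid-adult eye. Truth is allowed outside the 14-40 dB
#' testable range (clipped to [0, 50]).
#'
#' @param grid A grid tibble from [build_grid_30_2()].
#' @param s0 Apex sensitivity, dB (in `[20, 45]`).
#' @param slope Decline, dB per degree of eccentricity (>= 0).
#' @param noise_sd Point scatter SD, dB.
#' @param seed Optional integer seed for reproducible scatter.
#' @return The grid tibble with a `sens` column (true sensitivity, dB) and a
#'   `lesions` attribute (character description of injected defects).
#' @examples
#' f <- make_normal_field(build_grid_30_2("OD"), noise_sd = 0)
#' f$sens[f$x == 3 & f$y == 3]  # 33 - 0.3 * sqrt(18)
#' @export
make_normal_field <- function(grid, s0 = 33, slope = 0.3, noise_sd = 1,
                              seed = NULL) {
  if (s0 < 20 || s0 > 45) abort("s0 must lie in [20, 45] dB")
  if (slope < 0) abort("slope must be non-negative")
  if (!is.null(seed)) {
    noise <- with_local_seed(seed, rnorm(nrow(grid), 0, noise_sd))
  } else {
    noise <- rnorm(nrow(grid), 0, noise_sd)
  }
  out <- grid |>
    dplyr::mutate(sens = pmin(pmax(s0 - slope * .data$ecc + noise, 0), 50))
  attr(out, "lesions") <- character()
  out
}

# evaluate an expression with a temporary RNG seed, restoring global state
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Inject a visual-field defect into a true field
#'
#' Subtracts `depth` dB (floored at 0 dB) over a lesion-shaped set of grid
#' points. Available defects mirror those seen clinically and in head-mounted
#' testing:
#' \describe{
#'   \item{blind_spot}{the two points adjacent to the physiologic blind spot,
#'     (temporal 15, +/-3).}
#'   \item{nasal_step}{nasal points with `|y| <= 9` in one hemifield.}
#'   \item{arcuate}{an arcuate bundle defect: points at eccentricity 9-21
#'     degrees in one hemifield, on the nasal side through to the blind spot
#'     (i.e. excluding the far temporal wedge beyond the blind spot).}
#'   \item{quadrantanopia}{one full quadrant (`"SN"`, `"ST"`, `"IN"`, `"IT"`).}
#'   \item{rim_artifact}{all points at eccentricity >= 21 degrees on a chosen
#'     side — the signature of an eyeglasses frame displaced over the field.}
#' }
#'
#' @param field A field tibble with a `sens` column.
#' @param kind Lesion kind, one of the names above.
#' @param depth Sensitivity loss, dB (>= 0).
#' @param hemifield For `nasal_step`/`arcuate`: `"superior"` or `"inferior"`.
#' @param quadrant For `quadrantanopia`: quadrant label.
#' @param rim_side For `rim_artifact`: `"superior"`, `"inferior"`, `"nasal"`
#'   or `"temporal"`.
#' @return The field with reduced `sens` over the lesion; the `lesions`
#'   attribute is extended.
#' @export
inject_lesion <- function(field,
                          kind = c("blind_spot", "nasal_step", "arcuate",
                                   "quadrantanopia", "rim_artifact"),
                          depth = 20, hemifield = "superior",
                          quadrant = "ST", rim_side = "inferior") {
  kind <- match.arg(kind)
  if (depth < 0) abort("lesion depth must be non-negative")
  sel <- switch(
    kind,
    blind_spot = field$blind_spot,
    nasal_step = field$side == "nasal" & field$hemifield == hemifield &
      abs(field$y) <= 9,
    arcuate = field$hemifield == hemifield & field$ecc >= 9 &
      field$ecc <= 21 &
      !(field$side == "temporal" & abs(field$x) > 15),
    quadrantanopia = field$quadrant == quadrant,
    rim_artifact = field$ecc >= 21 & switch(
      rim_side,
      superior = field$y > 0, inferior = field$y < 0,
      nasal = field$side == "nasal", temporal = field$side == "temporal",
      abort("unknown rim_side")
    )
  )
  field$sens[sel] <- pmax(field$sens[sel] - depth, 0)
  attr(field, "lesions") <- c(attr(field, "lesions") %||% character(),
                              sprintf("%s(depth=%g)", kind, depth))
  field
}

#' Construct a simulated observer
#'
#' A frequency-of-seeing observer over a true sensitivity field. The
#' probability of reporting a stimulus of intensity `presented` dB at a
#' location with effective true sensitivity `t` is
#' `p = fp + (1 - fp - fn) * pnorm((t - presented) / fos_slope)`:
#' false positives floor the curve (responses to invisible stimuli), false
#' negatives cap it (missed visible stimuli), and `fos_slope` is the spread
#' of the psychometric function in dB. Gaze wander is Gaussian per axis with
#' SD `gaze_sd` degrees, within the accuracy bracket of a headset eye tracker
#' (0.5-1.1 degrees).
#'
#' @param true_field Field tibble with `sens` (see [make_normal_field()]).
#' @param fos_slope Psychometric spread, dB (> 0).
#' @param fp_rate,fn_rate False-positive / false-negative response rates, each
#'   in `[0, 0.5)`.
#' @param gaze_sd Per-axis gaze wander SD, degrees (>= 0).
#' @param rng_seed Integer seed identifying the observer's response stream.
#' @return An `observer_model` object.
#' @export
observer_model <- function(true_field, fos_slope = 1.0, fp_rate = 0.03,
                           fn_rate = 0.03, gaze_sd = 1.0, rng_seed = 1L) {
  stopifnot(is.data.frame(true_field), "sens" %in% names(true_field))
  if (fos_slope <= 0) abort("fos_slope must be positive")
  if (fp_rate < 0 || fp_rate >= 0.5 || fn_rate < 0 || fn_rate >= 0.5) {
    abort("fp_rate and fn_rate must lie in [0, 0.5)")
  }
  if (gaze_sd < 0) abort("gaze_sd must be non-negative")
  structure(
    list(true_field = true_field, fos_slope = fos_slope, fp_rate = fp_rate,
         fn_rate = fn_rate, gaze_sd = gaze_sd, rng_seed = as.integer(rng_seed)),
    class = "observer_model"
  )
}

#' True sensitivity at an arbitrary field location
#'
#' Truth is defined on the test lattice; off-lattice locations (e.g. the
#' displaced retinal position when gaze tracking is off) are evaluated by
#' inverse-distance-weighted interpolation over the four nearest grid points,
#' with an exact-hit shortcut. This avoids step artifacts at cell borders
#' while staying defined everywhere, including outside the grid hull (where
#' it decays to a nearest-points average).
#'
#' @param field Field tibble with `x`, `y`, `sens`.
#' @param x,y Query location, degrees (scalars).
#' @return Interpolated sensitivity, dB.
#' @export
field_sensitivity_at <- function(field, x, y) {
  d2 <- (field$x - x)^2 + (field$y - y)^2
  hit <- which(d2 < 1e-12)
  if (length(hit) > 0) return(field$sens[hit[1]])
  nn <- order(d2)[1:4]
  w <- 1 / sqrt(d2[nn])
  sum(w * field$sens[nn]) / sum(w)
}

#' Simulated seen/not-seen response
#'
#' Draws one Bernoulli response from the observer's frequency-of-seeing model
#' at a grid location. With gaze tracking on, the stimulus lands on the
#' intended retinal location; with tracking off, the effective location is the
#' intended one displaced by the current gaze error and truth is interpolated
#' there via [field_sensitivity_at()]. Uses the current RNG stream; seed it
#' (e.g. via the observer's `rng_seed`) for reproducibility.
#'
#' @param observer An [observer_model()].
#' @param x,y Intended field location, degrees.
#' @param presented Stimulus intensity, dB.
#' @param gaze_x,gaze_y Current gaze error, degrees.
#' @param tracking Logical: gaze-contingent repositioning active?
#' @return Logical seen flag.
#' @export
respond <- function(observer, x, y, presented, gaze_x = 0, gaze_y = 0,
                    tracking = TRUE) {
  stopifnot(inherits(observer, "observer_model"))
  t_eff <- if (tracking) {
    field_sensitivity_at(observer$true_field, x, y)
  } else {
    field_sensitivity_at(observer$true_field, x - gaze_x, y - gaze_y)
  }
  p <- seen_probability(t_eff, presented, observer$fos_slope,
                        observer$fp_rate, observer$fn_rate)
  runif(1) < p
}

#' @rdname respond
#' @param t_true True sensitivity at the effective location, dB.
#' @param fos_slope,fp_rate,fn_rate Psychometric parameters.
#' @export
seen_probability <- function(t_true, presented, fos_slope = 1.0,
                             fp_rate = 0.03, fn_rate = 0.03) {
  fp_rate + (1 - fp_rate - fn_rate) * pnorm((t_true - presented) / fos_slope)
}

#' Simulated gaze-wander trace
#'
#' First-order autoregressive gaze wander per axis, sampled at the eye
#' tracker's rate (default 120 Hz): `g[k+1] = phi * g[k] + e`, with the
#' innovation variance chosen so the stationary SD equals `gaze_sd`. The
#' persistence `phi = 0.95` per sample gives a ~0.16 s drift time constant,
#' a plausible slow fixational wander.
#'
#' @param duration Trace length, seconds (> 0).
#' @param gaze_sd Stationary per-axis SD, degrees.
#' @param rate Sampling rate, Hz.
#' @param seed Optional integer seed.
#' @param phi AR(1) persistence per sample, in `[0, 1)`.
#' @return A tibble `t` (s), `gx`, `gy` (degrees), strictly increasing in `t`.
#' @export
gaze_trace <- function(duration, gaze_sd = 1.0, rate = 120, seed = NULL,
                       phi = 0.95) {
  if (duration <= 0) abort("duration must be positive")
  if (phi < 0 || phi >= 1) abort("phi must lie in [0, 1)")
  n <- ceiling(duration * rate)
  sim <- function() {
    if (gaze_sd == 0) return(matrix(0, n, 2))
    innov_sd <- gaze_sd * sqrt(1 - phi^2)
    vapply(1:2, function(i) {
      g <- numeric(n)
      g[1] <- rnorm(1, 0, gaze_sd)
      eps <- rnorm(n - 1, 0, innov_sd)
      for (k in seq_len(n - 1)) g[k + 1] <- phi * g[k] + eps[k]
      g
    }, numeric(n))
  }
  gm <- if (!is.null(seed)) with_local_seed(seed, sim()) else sim()
  tibble::tibble(t = (seq_len(n) - 1) / rate, gx = gm[, 1], gy = gm[, 2])
}

#' Generate a synthetic paired-device cohort
#'
#' Simulates a cohort of eyes measured on two perimetric devices (A and B)
#' for agreement analysis. Per eye, a true field is drawn (apex sensitivity
#' varying between eyes with SD `between_sd`, plus per-point scatter); each
#' device then measures truth plus a shared per-point distortion (common to
#' both devices, SD `shared_sd`), a per-eye device bias (SD `eye_bias_sd_*`;
#' the dominant driver of disagreement between global means), and independent
#' per-point noise (SD `indep_sd_*`). Reliability indices (FL/FP/FN) are
#' drawn uniformly within `reliability_ranges`; MD/PSD/VFI metadata are
#' derived summaries carried as passthrough.
#'
#' The expected correlation of paired global means is computed analytically
#' by [nominal_global_r()]; [eye_bias_for_r()] inverts it.
#'
#' @param n_eyes Number of eyes (>= 3).
#' @param shared_sd Shared per-point distortion SD, dB.
#' @param indep_sd_a,indep_sd_b Independent per-point noise SD per device, dB.
#' @param eye_bias_sd_a,eye_bias_sd_b Per-eye device bias SD, dB.
#' @param between_sd Between-eye SD of the apex sensitivity, dB.
#' @param point_sd Per-point truth scatter SD, dB.
#' @param seed Integer seed.
#' @param eye Laterality for the grid.
#' @param reliability_ranges Named list of `c(min, max)` for `fl`, `fp`, `fn`.
#' @return A list with `manifest` (one row per eye: `eye_id`, `laterality`,
#'   `fl`, `fp`, `fn`, `md`, `psd`, `vfi`) and `fields` (one row per eye x
#'   point: `eye_id`, `x`, `y`, `sens_a`, `sens_b`), of class `paired_cohort`.
#' @examples
#' coh <- make_paired_cohort(10, seed = 1)
#' nrow(coh$fields)  # 10 * 76
#' @export
make_paired_cohort <- function(n_eyes, shared_sd = 1, indep_sd_a = 2,
                               indep_sd_b = 2, eye_bias_sd_a = 0,
                               eye_bias_sd_b = 0, between_sd = 4,
                               point_sd = 2, seed = 1L, eye = "OD",
                               reliability_ranges = list(
                                 fl = c(0, 0.15), fp = c(0, 0.10),
                                 fn = c(0, 0.20))) {
  if (n_eyes < 3) abort("n_eyes must be at least 3")
  if (min(shared_sd, indep_sd_a, indep_sd_b, eye_bias_sd_a, eye_bias_sd_b,
          between_sd, point_sd) < 0) {
    abort("all SDs must be non-negative")
  }
  grid <- build_grid_30_2(eye)
  m <- nrow(grid)
  gen <- function() {
    purrr::map(seq_len(n_eyes), function(i) {
      s0 <- min(max(rnorm(1, 33, between_sd), 20), 45)
      truth <- make_normal_field(grid, s0 = s0, slope = 0.3,
                                 noise_sd = point_sd)
      shared <- rnorm(m, 0, shared_sd)
      a <- truth$sens + shared + rnorm(1, 0, eye_bias_sd_a) +
        rnorm(m, 0, indep_sd_a)
      b <- truth$sens + shared + rnorm(1, 0, eye_bias_sd_b) +
        rnorm(m, 0, indep_sd_b)
      rel <- purrr::map_dbl(reliability_ranges, ~ runif(1, .x[1], .x[2]))
      md <- mean(truth$sens) - mean(33 - 0.3 * grid$ecc)
      list(
        manifest = tibble::tibble(
          eye_id = sprintf("eye%03d", i), laterality = eye,
          fl = rel[["fl"]], fp = rel[["fp"]], fn = rel[["fn"]],
          md = md, psd = sd(truth$sens - (33 - 0.3 * grid$ecc)),
          vfi = max(0, min(100, 100 + 2.5 * md))
        ),
        fields = tibble::tibble(
          eye_id = sprintf("eye%03d", i), x = grid$x, y = grid$y,
          sens_a = a, sens_b = b
        )
      )
    })
  }
  eyes <- with_local_seed(as.integer(seed), gen())
  structure(
    list(
      manifest = purrr::list_rbind(purrr::map(eyes, "manifest")),
      fields = purrr::list_rbind(purrr::map(eyes, "fields")),
      grid = grid,
      params = list(n_eyes = n_eyes, shared_sd = shared_sd,
                    indep_sd_a = indep_sd_a, indep_sd_b = indep_sd_b,
                    eye_bias_sd_a = eye_bias_sd_a,
                    eye_bias_sd_b = eye_bias_sd_b, between_sd = between_sd,
                    point_sd = point_sd, seed = as.integer(seed))
    ),
    class = "paired_cohort"
  )
}

#' Expected correlation of paired global means
#'
#' Analytic Pearson correlation, across eyes, of the two devices' global mean
#' sensitivities under the [make_paired_cohort()] generative model. With `m`
#' points averaged, between-eye variance `B = between_sd^2 + (point_sd^2 +
#' shared_sd^2) / m` is common to both devices while each device adds
#' `u_x = eye_bias_sd_x^2 + indep_sd_x^2 / m`, giving
#' `r = B / sqrt((B + u_a) * (B + u_b))`.
#'
#' @param shared_sd,indep_sd_a,indep_sd_b,eye_bias_sd_a,eye_bias_sd_b,between_sd,point_sd
#'   Generator SDs as in [make_paired_cohort()].
#' @param m Number of points averaged per eye (76, or 74 with the blind-spot
#'   pair excluded).
#' @return The nominal correlation.
#' @export
nominal_global_r <- function(shared_sd = 1, indep_sd_a = 2, indep_sd_b = 2,
                             eye_bias_sd_a = 0, eye_bias_sd_b = 0,
                             between_sd = 4, point_sd = 2, m = 76) {
  B <- between_sd^2 + (point_sd^2 + shared_sd^2) / m
  ua <- eye_bias_sd_a^2 + indep_sd_a^2 / m
  ub <- eye_bias_sd_b^2 + indep_sd_b^2 / m
  B / sqrt((B + ua) * (B + ub))
}

#' @rdname nominal_global_r
#' @param r Target nominal global-mean correlation, in (0, 1].
#' @return `eye_bias_for_r()`: the common per-eye device bias SD (applied to
#'   both devices) that achieves nominal correlation `r`, holding the other
#'   SDs fixed.
#' @export
eye_bias_for_r <- function(r, shared_sd = 1, indep_sd_a = 2, indep_sd_b = 2,
                           between_sd = 4, point_sd = 2, m = 76) {
  if (r <= 0 || r > 1) abort("target r must lie in (0, 1]")
  B <- between_sd^2 + (point_sd^2 + shared_sd^2) / m
  u <- B * (1 - r) / r  # symmetric case: r = B / (B + u)
  bias2 <- u - mean(c(indep_sd_a^2, indep_sd_b^2)) / m
  if (bias2 < 0) {
    abort("target r unreachable: per-point noise alone already exceeds it")
  }
  sqrt(bias2)
}
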