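# Shared fixtures, all built in code.

# deterministic step-function observer: sees iff the stimulus is at least as
# bright as the true threshold (attenuation <= t)
step_responder <- function(t) function(db) db <= t

# flat true field at a constant sensitivity
flat_field <- function(db, eye = "OD") {
  grid <- build_grid_30_2(eye)
  grid$sens <- rep(db, nrow(grid))
  grid
}

# RMSE between exam thresholds and truth clamped to the testable range
exam_rmse <- function(result, truth) {
  sqrt(mean((result$thresholds$threshold - pmin(pmax(truth, 14), 40))^2))
}

# a glaucomatous true field: superior arcuate defect + inferior nasal step,
# the defect pattern whose steep edges make gaze error consequential
glaucoma_field <- function(seed, eye = "OD") {
  make_normal_field(build_grid_30_2(eye), noise_sd = 1, seed = seed) |>
    inject_lesion("arcuate", depth = 15, hemifield = "superior") |>
    inject_lesion("nasal_step", depth = 10, hemifield = "inferior")
}
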