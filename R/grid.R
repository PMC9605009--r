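#' Build the 30-2 test grid
#'
#' Constructs the 76-point test pattern covering the central 30 degrees of the
#' visual field: a square lattice with 6 degree spacing, offset 3 degrees from
#' both meridians (coordinates in \{-27, -21, ..., -3, 3, ..., 27\}), keeping
#' every lattice point whose eccentricity is at most 28.5 degrees. That
#' inclusion radius reproduces the canonical pattern of 4/6/8/10/10 points per
#' row in each hemifield (76 total, 38 per hemifield, 19 per quadrant).
#'
#' Laterality fixes the nasal/temporal convention: positive x is the patient's
#' right, which is the temporal field for a right eye (OD) and the nasal field
#' for a left eye (OS). The physiologic blind spot sits temporally at
#' approximately 15 degrees, so its two adjacent grid points are
#' (temporal 15, +/-3).
#'
#' @param eye `"OD"` (right) or `"OS"` (left).
#' @return A tibble with one row per test location, in row-major order (top
#'   row first, x ascending within a row): columns `x`, `y` (field angles,
#'   degrees), `eye`, `ecc` (eccentricity, degrees), `side`
#'   (`"nasal"`/`"temporal"`), `hemifield` (`"superior"`/`"inferior"`),
#'   `quadrant` (`"SN"`, `"ST"`, `"IN"`, `"IT"`) and `blind_spot` (`TRUE` for
#'   the two points adjacent to the physiologic blind spot).
#' @examples
#' g <- build_grid_30_2("OD")
#' nrow(g)                     # 76
#' dplyr::count(g, quadrant)   # 19 per quadrant
#' @export
build_grid_30_2 <- function(eye = c("OD", "OS")) {
  eye <- match.arg(eye)
  coords <- c(-27, -21, -15, -9, -3, 3, 9, 15, 21, 27)
  grid <- tidyr::expand_grid(y = rev(coords), x = coords) |>
    dplyr::mutate(ecc = sqrt(.data$x^2 + .data$y^2)) |>
    dplyr::filter(.data$ecc <= 28.5)
  temporal_sign <- if (eye == "OD") 1 else -1
  grid |>
    dplyr::mutate(
      eye = eye,
      side = ifelse(sign(.data$x) == temporal_sign, "temporal", "nasal"),
      hemifield = ifelse(.data$y > 0, "superior", "inferior"),
      quadrant = paste0(
        substr(.data$hemifield, 1, 1) |> toupper(),
        ifelse(.data$side == "nasal", "N", "T")
      ),
      blind_spot = .data$x == 15 * temporal_sign & abs(.data$y) == 3
    ) |>
    dplyr::select("x", "y", "eye", "ecc", "side", "hemifield", "quadrant",
                  "blind_spot")
}

#' Project field angles onto the virtual bowl
#'
#' Maps visual-field direction angles to a 3-D point on a sphere ("virtual
#' bowl") centred at the eye. The direction vector is
#' `normalize(tan x, tan y, 1)` scaled by the bowl radius, so a stimulus keeps
#' a constant angular subtense regardless of eccentricity. Coordinates are
#' eye-centred, right-handed, z toward the bowl apex, millimetres.
#'
#' @param x,y Field azimuth/elevation in degrees (vectorised); each must lie
#'   strictly within (-90, 90).
#' @param radius Bowl radius in millimetres (default 330).
#' @return A tibble with columns `px`, `py`, `pz` (mm) and `radius`.
#' @examples
#' field_to_bowl(27, 0)  # ~ (149.8, 0, 294.0)
#' @export
field_to_bowl <- function(x, y, radius = 330) {
  if (any(abs(x) >= 90) || any(abs(y) >= 90)) {
    abort("field angles must be strictly within (-90, 90) degrees")
  }
  if (radius <= 0) abort("bowl radius must be positive")
  dx <- tan(deg2rad(x))
  dy <- tan(deg2rad(y))
  nrm <- sqrt(dx^2 + dy^2 + 1)
  tibble::tibble(
    px = radius * dx / nrm,
    py = radius * dy / nrm,
    pz = radius / nrm,
    radius = radius
  )
}

# unit direction vector for field angles; rows of a 3-column matrix
field_direction <- function(x, y) {
  dx <- tan(deg2rad(x))
  dy <- tan(deg2rad(y))
  nrm <- sqrt(dx^2 + dy^2 + 1)
  cbind(dx / nrm, dy / nrm, 1 / nrm)
}

# rotation matrix carrying unit vector a onto unit vector b (Rodrigues)
rotation_between <- function(a, b) {
  v <- c(a[2] * b[3] - a[3] * b[2],
         a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  c_ <- sum(a * b)
  s2 <- sum(v^2)
  if (s2 < 1e-30) {
    if (c_ > 0) return(diag(3))
    abort("gaze direction is antipodal to straight-ahead; rotation undefined")
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx * ((1 - c_) / s2)
}

#' Gaze-contingent stimulus placement
#'
#' Repositions a stimulus so that it lands on the intended retinal location
#' despite eye movement: the target direction is rotated by the rotation that
#' carries the straight-ahead axis onto the current gaze direction, then
#' projected onto the bowl. The angle between the gaze direction and the
#' repositioned stimulus equals the target's eccentricity exactly, which is
#' what eliminates fixation loss in an eye-tracked perimeter.
#'
#' @param target_x,target_y Intended field location of the stimulus (degrees).
#' @param gaze_x,gaze_y Current gaze direction (degrees, same convention).
#' @param radius Bowl radius in millimetres.
#' @return A one-row tibble `px`, `py`, `pz`, `radius` on the bowl.
#' @examples
#' gaze_contingent_position(9, 0, 0, 0)   # identical to field_to_bowl(9, 0)
#' @export
gaze_contingent_position <- function(target_x, target_y, gaze_x, gaze_y,
                                     radius = 330) {
  tdir <- drop(field_direction(target_x, target_y))
  gdir <- drop(field_direction(gaze_x, gaze_y))
  rot <- rotation_between(c(0, 0, 1), gdir)
  d <- drop(rot %*% tdir)
  if (d[3] <= 1e-12) {
    abort("combined gaze + target angle reaches 90 degrees: off the display",
          class = "perisim_out_of_display")
  }
  tibble::tibble(px = radius * d[1], py = radius * d[2], pz = radius * d[3],
                 radius = radius)
}

#' Angular diameter of the Goldmann size III stimulus
#'
#' The Goldmann size III target is a circle of area 4 mm^2 presented at the
#' standard 300 mm Goldmann bowl distance; its angular diameter is
#' `2 * atan(sqrt(4 / pi) / 300)`, approximately 0.43 degrees. This angular
#' size is treated as normative; the physical extent on any bowl is derived
#' from it via [stimulus_extent_on_bowl()].
#'
#' @return Angular diameter in degrees (~0.431).
#' @examples
#' round(goldmann_iii_angle(), 2)  # 0.43
#' @export
goldmann_iii_angle <- function() {
  2 * rad2deg(atan(sqrt(4 / pi) / 300))
}

#' Physical extent of a stimulus on the bowl
#'
#' Chord diameter, in millimetres, of a stimulus of given angular diameter
#' rendered on a bowl of given radius: `2 * radius * tan(angle / 2)`.
#'
#' @param angular_diameter Angular diameter in degrees, in (0, 90).
#' @param radius Bowl radius in millimetres, positive.
#' @return Extent in millimetres.
#' @examples
#' stimulus_extent_on_bowl(goldmann_iii_angle(), 330)  # ~2.48 mm
#' @export
stimulus_extent_on_bowl <- function(angular_diameter, radius = 330) {
  if (any(angular_diameter <= 0) || any(angular_diameter >= 90)) {
    abort("angular_diameter must lie in (0, 90) degrees")
  }
  if (any(radius <= 0)) abort("radius must be positive")
  2 * radius * tan(deg2rad(angular_diameter) / 2)
}

#' Write a test grid to CSV
#'
#' @param grid A grid tibble from [build_grid_30_2()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_grid_csv <- function(grid, path) {
  grid |>
    dplyr::select(x_deg = "x", y_deg = "y", "eye") |>
    readr::write_csv(path)
  invisible(path)
}
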