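#' Map a threshold in dB to a grayscale level
#'
#' The grayscale map convention: 14 dB renders as black (0) and 40 dB as
#' white (255); values strictly between are mapped linearly onto gray levels
#' 1-254 as `round_half_up(1 + 253 * (db - 14) / 26)`. Out-of-range input is
#' clamped to the nearest endpoint with a warning.
#'
#' @param db Sensitivity in dB (vectorised).
#' @return Integer gray levels in `[0, 255]`.
#' @examples
#' db_to_gray(c(14, 27, 40))  # 0, 128, 255
#' @export
db_to_gray <- function(db) {
  if (any(db < 14 | db > 40)) {
    warn("dB values outside [14, 40] clamped to the endpoint gray level")
    db <- pmin(pmax(db, 14), 40)
  }
  out <- ifelse(db == 14, 0,
                ifelse(db == 40, 255,
                       floor(1 + 253 * (db - 14) / 26 + 0.5)))
  as.integer(out)
}

# bilinear-style interpolation of point values onto canvas; IDW over the
# four nearest grid points (exact-hit shortcut), same scheme as truth lookup
idw4 <- function(px, py, qx, qy, v) {
  vapply(seq_along(qx), function(i) {
    d2 <- (px - qx[i])^2 + (py - qy[i])^2
    hit <- which(d2 < 1e-12)
    if (length(hit) > 0) return(v[hit[1]])
    nn <- order(d2)[1:4]
    w <- 1 / sqrt(d2[nn])
    sum(w * v[nn]) / sum(w)
  }, numeric(1))
}

#' Render a grayscale visual-field map
#'
#' Rasterises per-point thresholds onto a square canvas spanning -30.5 to
#' +30.5 degrees (61 degrees) on both axes, y increasing upward.
#' \describe{
#'   \item{tiles}{each test location paints its 6 x 6 degree cell with the
#'     point's gray level — an integer-only pipeline, bit-exact across
#'     platforms.}
#'   \item{interpolated}{gray varies smoothly, interpolating thresholds over
#'     the four nearest grid points inside the tested region.}
#' }
#' Pixels outside every tested cell are background gray (level 200).
#'
#' @param result An `exam_result`, or any tibble with `x`, `y` and a
#'   threshold column.
#' @param style `"tiles"` or `"interpolated"`.
#' @param px_per_deg Raster resolution, pixels per degree.
#' @param value_col Name of the threshold column (default `"threshold"`).
#' @param background Background gray level.
#' @return An integer matrix of gray levels (rows = raster rows, top first),
#'   class `gray_map`.
#' @export
render_map <- function(result, style = c("tiles", "interpolated"),
                       px_per_deg = 4, value_col = "threshold",
                       background = 200L) {
  style <- match.arg(style)
  pts <- if (inherits(result, "exam_result")) result$thresholds else result
  stopifnot(all(c("x", "y", value_col) %in% names(pts)))
  half <- 30.5
  n <- as.integer(2 * half * px_per_deg)
  # pixel-centre coordinates in degrees
  cx <- -half + (seq_len(n) - 0.5) / px_per_deg
  cy <- half - (seq_len(n) - 0.5) / px_per_deg  # top row first
  img <- matrix(as.integer(background), n, n)
  db <- pmin(pmax(pts[[value_col]], 14), 40)
  gray <- db_to_gray(db)
  if (style == "tiles") {
    for (k in seq_len(nrow(pts))) {
      xi <- which(cx >= pts$x[k] - 3 & cx < pts$x[k] + 3)
      yi <- which(cy <= pts$y[k] + 3 & cy > pts$y[k] - 3)
      img[yi, xi] <- gray[k]
    }
  } else {
    # tested region = union of the 6x6 cells, smooth gray inside
    pix <- expand.grid(row = seq_len(n), col = seq_len(n))
    qx <- cx[pix$col]
    qy <- cy[pix$row]
    inside <- vapply(seq_len(nrow(pix)), function(i) {
      any(abs(pts$x - qx[i]) < 3 & abs(pts$y - qy[i]) < 3)
    }, logical(1))
    vals <- idw4(pts$x, pts$y, qx[inside], qy[inside], db)
    img[cbind(pix$row[inside], pix$col[inside])] <- db_to_gray(vals)
  }
  structure(img, class = c("gray_map", class(img)))
}

#' Write / read a plain (P2) PGM image
#'
#' The plain-text PGM format is the package's bit-exact raster reference:
#' integer gray levels, ASCII encoding, no platform-dependent compression.
#'
#' @param img Integer matrix of gray levels in `[0, 255]` (rows top-first).
#' @param path File path.
#' @return `write_pgm()`: `path` invisibly; `read_pgm()`: integer matrix.
#' @export
write_pgm <- function(img, path) {
  stopifnot(is.matrix(img), all(img >= 0), all(img <= 255))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(img), nrow(img)), "255"), con)
  apply(img, 1, function(r) writeLines(paste(r, collapse = " "), con))
  invisible(path)
}

#' @rdname write_pgm
#' @export
read_pgm <- function(path) {
  toks <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  if (toks[1] != "P2") abort("not a plain (P2) PGM file")
  w <- as.integer(toks[2]); h <- as.integer(toks[3])
  vals <- as.integer(toks[-(1:4)])
  if (length(vals) != w * h) abort("PGM pixel count does not match header")
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

#' Write a gray map as PNG (convenience)
#'
#' Requires the `png` package; the PGM writer is the bit-exact reference.
#'
#' @param img Integer gray matrix.
#' @param path Output path.
#' @export
write_png_map <- function(img, path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    abort("the 'png' package is required for PNG output")
  }
  png::writePNG(unclass(img) / 255, path)
  invisible(path)
}
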