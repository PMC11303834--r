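#' Ordered 3-D landmark curve
#'
#' An ordered list of world-space points (µm) with an optional per-point
#' angle annotation — the representation of valve-hinge and myocardial-crest
#' loci used by the mitral-annular-disjunction analysis.
#'
#' @param x_um,y_um,z_um numeric point coordinates (µm), equal length >= 2.
#' @param angle_deg optional per-point angular position (degrees).
#' @return A data frame of class `landmark_curve` with columns
#'   `angle_deg` (possibly NA), `x_um`, `y_um`, `z_um`.
#' @export
landmark_curve <- function(x_um, y_um, z_um, angle_deg = NULL) {
  n <- length(x_um)
  if (n < 2L || length(y_um) != n || length(z_um) != n)
    stop("a curve needs >= 2 points with equal-length coordinates",
         call. = FALSE)
  if (is.null(angle_deg)) angle_deg <- rep(NA_real_, n)
  if (length(angle_deg) != n)
    stop("`angle_deg` must match the number of points", call. = FALSE)
  pts <- cbind(x_um, y_um, z_um)
  if (any(rowSums(abs(diff(pts))) == 0))
    stop("duplicate consecutive points are not allowed", call. = FALSE)
  structure(
    data.frame(angle_deg = as.numeric(angle_deg), x_um = as.numeric(x_um),
               y_um = as.numeric(y_um), z_um = as.numeric(z_um)),
    class = c("landmark_curve", "data.frame")
  )
}

curve_points <- function(curve) {
  as.matrix(curve[, c("x_um", "y_um", "z_um")])
}

#' Read and write landmark curves as CSV
#'
#' Curves are stored as plain CSV with columns `angle_deg, x_um, y_um,
#' z_um` (angle may be empty).
#'
#' @param path file path.
#' @param curve a [landmark_curve()].
#' @return `read_curve` returns a [landmark_curve()]; `write_curve`
#'   invisibly returns `path`.
#' @export
read_curve <- function(path) {
  df <- read.csv(path)
  need <- c("x_um", "y_um", "z_um")
  if (!all(need %in% names(df)))
    stop("curve CSV must have columns x_um, y_um, z_um", call. = FALSE)
  ang <- if ("angle_deg" %in% names(df)) df$angle_deg else NULL
  landmark_curve(df$x_um, df$y_um, df$z_um, angle_deg = ang)
}

#' @rdname read_curve
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "landmark_curve"))
  write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}
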