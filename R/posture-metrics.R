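#' Spinal curvature index of a marked curve
#'
#' Computes the curvature index used in planar posture photogrammetry:
#' \deqn{CI = 100 \cdot f / x}
#' where \eqn{x} (the "straight") is the chord length between the upper and
#' lower limit vertebrae of a spinal curve, and \eqn{f} (the "arrow") is the
#' perpendicular distance from the apex of the curve to that chord. All
#' three points are world coordinates in centimetres, so CI is a
#' dimensionless percentage-scale index invariant under rigid motion and
#' uniform scaling.
#'
#' @param upper,lower world coordinates (cm) of the limit vertebrae bounding
#'   the curve; order is irrelevant.
#' @param apex world coordinates (cm) of the curve apex.
#' @param clamp_to_segment if \code{TRUE}, \eqn{f} is the distance to the
#'   chord \emph{segment} rather than the infinite line through the limit
#'   vertebrae. For realistic anatomy the apex projects inside the chord and
#'   both agree; the infinite-line "arrow" is the default, matching
#'   flexicurve-style indices.
#' @return An object of class \code{curvature_result}: list with \code{x}
#'   (chord, cm), \code{f} (arrow, cm) and \code{ci}.
#' @examples
#' curvature_index(c(0, 0), c(2, 5), c(0, 10))   # ci = 20
#' @export
curvature_index <- function(upper, apex, lower, clamp_to_segment = FALSE) {
  u <- as.numeric(upper); a <- as.numeric(apex); l <- as.numeric(lower)
  stopifnot(length(u) == 2L, length(a) == 2L, length(l) == 2L)
  chord <- l - u
  x <- sqrt(sum(chord^2))
  if (x < 1e-12) {
    stop("degenerate chord: upper and lower limit vertebrae coincide")
  }
  if (clamp_to_segment) {
    t <- sum((a - u) * chord) / sum(chord^2)
    t <- min(max(t, 0), 1)
    f <- sqrt(sum((a - (u + t * chord))^2))
  } else {
    # twice the triangle area over the base
    f <- abs((l[1L] - u[1L]) * (a[2L] - u[2L]) -
             (l[2L] - u[2L]) * (a[1L] - u[1L])) / x
  }
  structure(list(x = x, f = f, ci = 100 * f / x), class = "curvature_result")
}

#' @export
print.curvature_result <- function(x, ...) {
  cat(sprintf("curvature: chord x = %.3f cm, arrow f = %.3f cm, CI = %.2f\n",
              x$x, x$f, x$ci))
  invisible(x)
}

#' Euclidean distance between two world points
#'
#' @param a,b world coordinates (cm).
#' @return distance in cm.
#' @export
point_distance <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  stopifnot(length(a) == 2L, length(b) == 2L)
  sqrt(sum((a - b)^2))
}

#' Interior angle at a vertex
#'
#' Unsigned angle in degrees between the rays \code{vertex -> a} and
#' \code{vertex -> c}, in [0, 180], as reported clinically.
#'
#' @param a,c world coordinates (cm) of the ray endpoints.
#' @param vertex world coordinates (cm) of the vertex.
#' @return angle in degrees.
#' @export
segment_angle <- function(a, vertex, c) {
  a <- as.numeric(a); v <- as.numeric(vertex); c <- as.numeric(c)
  r1 <- a - v; r2 <- c - v
  n1 <- sqrt(sum(r1^2)); n2 <- sqrt(sum(r2^2))
  if (n1 < 1e-12 || n2 < 1e-12) {
    stop("degenerate angle: a ray of the angle has zero length")
  }
  cosang <- sum(r1 * r2) / (n1 * n2)
  cosang <- min(max(cosang, -1), 1)
  acos(cosang) * 180 / pi
}

#' Area of a closed polygon
#'
#' Absolute shoelace area of the polygon whose vertices are given in order
#' (either orientation).
#'
#' @param vertices an n x 2 matrix (or data frame) of world coordinates (cm),
#'   n >= 3; the polygon is closed implicitly.
#' @return area in cm^2.
#' @export
polygon_area <- function(vertices) {
  V <- as.matrix(vertices)
  storage.mode(V) <- "double"
  if (nrow(V) < 3L) {
    stop("insufficient vertices: a polygon needs at least 3, got ", nrow(V))
  }
  x <- V[, 1L]; y <- V[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  abs(sum(x * yn - xn * y)) / 2
}

#' Construct a landmark frame
#'
#' One annotated video frame: an ordinal index, the platform rotation angle
#' at acquisition (if known), and named landmark pixel coordinates.
#'
#' @param frame_index non-negative ordinal of the frame.
#' @param landmarks named list of length-2 numeric vectors \code{c(u, v)}
#'   (pixel coordinates); names must be unique.
#' @param rotation_angle platform angle in degrees, or \code{NA} if unknown.
#' @return an object of class \code{landmark_frame}.
#' @export
landmark_frame <- function(frame_index, landmarks, rotation_angle = NA_real_) {
  frame_index <- as.integer(frame_index)
  stopifnot(length(frame_index) == 1L, frame_index >= 0L)
  if (length(landmarks) > 0L) {
    nm <- names(landmarks)
    if (is.null(nm) || anyDuplicated(nm) > 0L || any(!nzchar(nm))) {
      stop("landmarks must be uniquely named")
    }
    landmarks <- lapply(landmarks, function(p) {
      p <- as.numeric(p)
      stopifnot(length(p) == 2L)
      p
    })
  }
  structure(
    list(frame_index = frame_index,
         rotation_angle = as.numeric(rotation_angle),
         landmarks = landmarks),
    class = "landmark_frame"
  )
}

#' Measure all configured posture metrics on one frame
#'
#' Converts every landmark to world centimetres through the calibration
#' model, then evaluates each metric defined in the protocol: one curvature
#' index per region, plus any configured distances, angles and polygon
#' areas. A metric whose landmarks are absent from the frame is flagged
#' missing rather than silently dropped, so downstream aggregation can
#' report skip counts.
#'
#' @param frame a [landmark_frame()].
#' @param model a [calibration model][fit_calibration].
#' @param protocol a [protocol_config()] defining the metrics.
#' @return data frame with one row per metric: \code{metric}, \code{value}
#'   (NA when missing) and \code{missing} (logical).
#' @export
measure_frame <- function(frame, model, protocol) {
  stopifnot(inherits(frame, "landmark_frame"),
            inherits(model, "calibration_model"),
            inherits(protocol, "protocol_config"))
  world <- lapply(frame$landmarks, function(p) pixel_to_world(model, p))

  have <- function(names) all(names %in% names(world))
  rows <- list()
  emit <- function(metric, value, missing) {
    rows[[length(rows) + 1L]] <<- data.frame(
      metric = metric, value = value, missing = missing,
      stringsAsFactors = FALSE)
  }

  for (rg in protocol$regions) {
    nm <- paste0(rg$label, "_ci")
    pts <- c(rg$upper, rg$apex, rg$lower)
    if (have(pts)) {
      res <- curvature_index(world[[rg$upper]], world[[rg$apex]],
                             world[[rg$lower]],
                             clamp_to_segment = protocol$clamp_to_segment)
      emit(nm, res$ci, FALSE)
    } else emit(nm, NA_real_, TRUE)
  }
  for (d in protocol$distances) {
    pts <- c(d$from, d$to)
    if (have(pts)) emit(d$name, point_distance(world[[d$from]], world[[d$to]]), FALSE)
    else emit(d$name, NA_real_, TRUE)
  }
  for (an in protocol$angles) {
    pts <- c(an$a, an$vertex, an$c)
    if (have(pts)) emit(an$name, segment_angle(world[[an$a]], world[[an$vertex]],
                                               world[[an$c]]), FALSE)
    else emit(an$name, NA_real_, TRUE)
  }
  for (ar in protocol$areas) {
    if (have(ar$vertices)) {
      V <- do.call(rbind, world[ar$vertices])
      emit(ar$name, polygon_area(V), FALSE)
    } else emit(ar$name, NA_real_, TRUE)
  }

  if (length(rows) == 0L) {
    return(data.frame(metric = character(), value = numeric(),
                      missing = logical(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out$frame_index <- frame$frame_index
  out[, c("frame_index", "metric", "value", "missing")]
}
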