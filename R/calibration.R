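#' Fit a pixel-to-centimetre calibration model from fiducial marks
#'
#' Estimates the planar map taking image pixel coordinates to real-world
#' centimetre coordinates from points marked on a calibration support of
#' known dimensions placed in the subject's plane. The map is
#' \code{world = linear \%*\% pixel + offset}, fitted by least squares in
#' world space.
#'
#' Two transform families are supported. The default (\code{"auto"}) fits a
#' full 2D affine map (6 parameters) when three or more non-collinear marks
#' are available; an affine map is the weakest family that accommodates a
#' tilted camera and independent horizontal/vertical scales. With exactly two
#' marks, or when \code{family = "similarity"} is forced, a similarity
#' transform (rotation + isotropic scale + translation, 4 parameters) is
#' fitted instead.
#'
#' Pixel coordinates follow the image convention: origin at the top-left
#' corner, \code{u} increasing rightwards and \code{v} increasing downwards,
#' continuous and 0-based. World \code{y} increases upwards; the sign flip is
#' absorbed by the fitted linear block, so no axis juggling is needed by the
#' caller.
#'
#' @param marks data frame of calibration marks with columns \code{u_px},
#'   \code{v_px} (pixel coordinates) and \code{x_cm}, \code{y_cm} (known
#'   world coordinates); an optional \code{mark_id} column is ignored.
#'   See [read_calibration_marks()].
#' @param family transform family: \code{"auto"} (affine when >= 3 marks,
#'   similarity when 2), \code{"affine"}, or \code{"similarity"}.
#' @return An object of class \code{calibration_model}: a list with
#'   \code{linear} (2x2 matrix, cm/px), \code{offset} (length-2 vector, cm),
#'   \code{residual_rms} (root-mean-square world-space residual, cm),
#'   \code{n_marks} and \code{family}.
#' @details Collinearity is declared when the smallest singular value of the
#'   centred pixel-mark matrix is below 1e-8 times the largest, a scale-free
#'   criterion. The least-squares problem is solved by QR decomposition.
#' @examples
#' marks <- data.frame(u_px = c(0, 100, 0), v_px = c(0, 0, 100),
#'                     x_cm = c(0, 10, 0),  y_cm = c(0, 0, -10))
#' m <- fit_calibration(marks)
#' pixel_to_world(m, c(50, 50))
#' @seealso [pixel_to_world()], [world_to_pixel()], [write_calibration_model()]
#' @export
fit_calibration <- function(marks, family = c("auto", "affine", "similarity")) {
  family <- match.arg(family)
  marks <- as.data.frame(marks)
  need <- c("u_px", "v_px", "x_cm", "y_cm")
  miss <- setdiff(need, names(marks))
  if (length(miss) > 0L) {
    stop("calibration marks lack column(s): ", paste(miss, collapse = ", "))
  }
  P <- as.matrix(marks[, c("u_px", "v_px")])
  W <- as.matrix(marks[, c("x_cm", "y_cm")])
  storage.mode(P) <- "double"
  storage.mode(W) <- "double"
  n <- nrow(P)
  if (n < 2L) {
    stop("insufficient data: at least 2 calibration marks are required, got ", n)
  }
  if (!all(is.finite(P)) || !all(is.finite(W))) {
    stop("calibration marks must have finite coordinates")
  }
  if (anyDuplicated(round(P, 9L)) > 0L) {
    stop("degenerate configuration: duplicate pixel points among calibration marks")
  }

  if (family == "auto") family <- if (n >= 3L) "affine" else "similarity"

  if (family == "affine") {
    if (n < 3L) {
      stop("insufficient data: the affine family requires at least 3 marks, got ", n)
    }
    Pc <- sweep(P, 2L, colMeans(P))
    sv <- svd(Pc, nu = 0L, nv = 0L)$d
    if (sv[2L] < 1e-8 * sv[1L]) {
      stop("degenerate configuration: pixel marks are collinear; ",
           "affine calibration is underdetermined")
    }
    X <- cbind(P, 1)
    beta <- qr.coef(qr(X), W)          # 3 x 2: rows u, v, intercept
    linear <- t(beta[1:2, , drop = FALSE])
    offset <- as.numeric(beta[3L, ])
  } else {
    # similarity: x = a*u - b*v + tx ; y = b*u + a*v + ty
    A <- rbind(
      cbind(P[, 1L], -P[, 2L], 1, 0),
      cbind(P[, 2L],  P[, 1L], 0, 1)
    )
    rhs <- c(W[, 1L], W[, 2L])
    th <- qr.coef(qr(A), rhs)
    linear <- matrix(c(th[1L], th[2L], -th[2L], th[1L]), 2L, 2L)
    offset <- c(th[3L], th[4L])
  }

  dimnames(linear) <- NULL
  names(offset) <- NULL
  if (!all(is.finite(linear)) || abs(det(linear)) < 1e-12) {
    stop("degenerate configuration: fitted calibration map is not invertible")
  }
  pred <- t(linear %*% t(P)) + matrix(offset, n, 2L, byrow = TRUE)
  residual_rms <- sqrt(mean(rowSums((pred - W)^2)))

  structure(
    list(linear = linear, offset = offset, residual_rms = residual_rms,
         n_marks = n, family = family),
    class = "calibration_model"
  )
}

#' @export
print.calibration_model <- function(x, ...) {
  cat("Pixel-to-world calibration model (", x$family, ", ",
      x$n_marks, " marks)\n", sep = "")
  cat("  linear block (cm/px):\n")
  print(signif(x$linear, 6L))
  cat("  offset (cm): ", paste(signif(x$offset, 6L), collapse = ", "), "\n",
      sep = "")
  cat("  residual RMS (cm): ", signif(x$residual_rms, 4L), "\n", sep = "")
  invisible(x)
}

as_point_matrix <- function(p) {
  if (is.null(dim(p))) {
    if (length(p) != 2L) stop("a point must have exactly 2 coordinates")
    matrix(as.numeric(p), 1L, 2L)
  } else {
    p <- as.matrix(p)
    if (ncol(p) != 2L) stop("point matrix must have 2 columns")
    storage.mode(p) <- "double"
    p
  }
}

#' Convert pixel coordinates to world centimetres
#'
#' Applies a fitted [calibration model][fit_calibration] so that any pixel in
#' the image receives an (x, y) coordinate in centimetres relative to the
#' axes defined on the calibration support.
#'
#' @param model a \code{calibration_model}.
#' @param p a length-2 numeric vector \code{c(u, v)} or an n x 2 matrix of
#'   pixel coordinates.
#' @return World coordinates in cm, in the same shape as the input.
#' @export
pixel_to_world <- function(model, p) {
  stopifnot(inherits(model, "calibration_model"))
  P <- as_point_matrix(p)
  out <- t(model$linear %*% t(P)) +
    matrix(model$offset, nrow(P), 2L, byrow = TRUE)
  colnames(out) <- c("x", "y")
  if (is.null(dim(p))) c(x = out[1L, 1L], y = out[1L, 2L]) else out
}

#' Convert world centimetres back to pixel coordinates
#'
#' Exact inverse of [pixel_to_world()]; used by the turntable simulator and
#' for overlay rendering.
#'
#' @inheritParams pixel_to_world
#' @param w a length-2 numeric vector \code{c(x, y)} or an n x 2 matrix of
#'   world coordinates (cm).
#' @return Pixel coordinates, in the same shape as the input.
#' @export
world_to_pixel <- function(model, w) {
  stopifnot(inherits(model, "calibration_model"))
  W <- as_point_matrix(w)
  shifted <- sweep(W, 2L, model$offset)
  out <- t(solve(model$linear, t(shifted)))
  colnames(out) <- c("u", "v")
  if (is.null(dim(w))) c(u = out[1L, 1L], v = out[1L, 2L]) else out
}

#' Read calibration marks from CSV
#'
#' Expects the header \code{mark_id,u_px,v_px,x_cm,y_cm}.
#'
#' @param path path to the marks file.
#' @return data frame of marks suitable for [fit_calibration()].
#' @export
read_calibration_marks <- function(path) {
  if (!file.exists(path)) stop("calibration marks file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("mark_id", "u_px", "v_px", "x_cm", "y_cm")
  if (!identical(sort(names(df)), sort(need))) {
    stop("format error: expected header '", paste(need, collapse = ","),
         "' in ", path)
  }
  df[, need]
}

#' Write calibration marks to CSV
#'
#' @param marks data frame with columns \code{u_px,v_px,x_cm,y_cm} and
#'   optionally \code{mark_id} (generated if absent).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_calibration_marks <- function(marks, path) {
  marks <- as.data.frame(marks)
  if (is.null(marks$mark_id)) marks$mark_id <- seq_len(nrow(marks))
  utils::write.csv(marks[, c("mark_id", "u_px", "v_px", "x_cm", "y_cm")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize a calibration model to JSON
#'
#' The document has fields \code{linear} (row-major 2x2), \code{offset},
#' \code{residual_rms_cm} and \code{n_marks}.
#'
#' @param model a \code{calibration_model}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_calibration_model <- function(model, path) {
  stopifnot(inherits(model, "calibration_model"))
  doc <- list(
    linear = lapply(seq_len(2L), function(i) as.numeric(model$linear[i, ])),
    offset = as.numeric(model$offset),
    residual_rms_cm = model$residual_rms,
    n_marks = model$n_marks,
    family = model$family
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a calibration model from JSON
#'
#' @param path path written by [write_calibration_model()].
#' @return a \code{calibration_model}.
#' @export
read_calibration_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  linear <- if (is.matrix(doc$linear)) doc$linear
            else matrix(unlist(doc$linear), 2L, 2L, byrow = TRUE)
  dimnames(linear) <- NULL
  if (abs(det(linear)) < 1e-12) stop("calibration model in ", path,
                                     " is not invertible")
  structure(
    list(linear = linear, offset = as.numeric(doc$offset),
         residual_rms = as.numeric(doc$residual_rms_cm),
         n_marks = as.integer(doc$n_marks),
         family = if (is.null(doc$family)) "affine" else doc$family),
    class = "calibration_model"
  )
}

#' Identity calibration model
#'
#' Convenience model mapping pixels 1:1 to centimetres, for data already
#' expressed in world units (e.g. digitised tables of measurements).
#'
#' @return a \code{calibration_model} with unit linear block and zero offset.
#' @export
identity_calibration <- function() {
  structure(
    list(linear = diag(2L), offset = c(0, 0), residual_rms = 0,
         n_marks = 0L, family = "identity"),
    class = "calibration_model"
  )
}
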