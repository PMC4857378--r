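#' Define a turntable acquisition scene
#'
#' Geometric model of the acquisition rig: a rigid set of 3D landmarks in a
#' body-fixed frame rotating about a vertical axis at constant platform
#' speed, filmed by a fixed pinhole camera. The body frame has its origin
#' on the rotation axis at platform height, Y up (cm); the Z axis points
#' toward the camera at platform angle 0, so angle 0 is the subject facing
#' the camera and 90 degrees is the right profile, angles increasing
#' counter-clockwise seen from above.
#'
#' The camera is a pinhole with principal point at the image centre and
#' square pixels — the minimal model that produces the parallax and
#' foreshortening the averaging protocol is designed to control. Annotation
#' error is modelled as isotropic Gaussian jitter in pixel space.
#'
#' @param landmarks3d named list of length-3 numeric vectors (X, Y, Z), cm.
#' @param platform_rpm platform angular speed, revolutions per minute
#'   (default 0.7, a speed slow enough for comfortable standing).
#' @param camera_distance rotation-axis-to-pinhole distance, cm; must
#'   exceed the largest radial landmark extent.
#' @param focal_px focal length in pixels.
#' @param image_size c(width, height) in pixels; the principal point is at
#'   \code{image_size / 2}.
#' @param frame_rate acquisition frequency, Hz (default 30, typical of a
#'   consumer CCD camcorder).
#' @param noise_sd_px landmark jitter SD in pixels (>= 0).
#' @param occlusion_depth surface landmarks are treated as self-occluded
#'   once their rotated position lies more than this many cm behind the
#'   plane through the rotation axis (half-space visibility heuristic);
#'   set it to roughly the body half-depth so that e.g. both ends of a
#'   sagittal chord stay visible at profile. Default 0 (strict half-space).
#' @param seed RNG seed for the jitter.
#' @return an object of class \code{turntable_scene}.
#' @export
turntable_scene <- function(landmarks3d,
                            platform_rpm = 0.7,
                            camera_distance = 300,
                            focal_px = 1500,
                            image_size = c(2048, 1536),
                            frame_rate = 30,
                            noise_sd_px = 0,
                            occlusion_depth = 0,
                            seed = 1L) {
  stopifnot(platform_rpm > 0, frame_rate > 0, noise_sd_px >= 0,
            length(image_size) == 2L, focal_px > 0, occlusion_depth >= 0)
  nm <- names(landmarks3d)
  if (is.null(nm) || anyDuplicated(nm) > 0L || any(!nzchar(nm))) {
    stop("landmarks3d must be uniquely named")
  }
  landmarks3d <- lapply(landmarks3d, function(p) {
    p <- as.numeric(p)
    stopifnot(length(p) == 3L, all(is.finite(p)))
    p
  })
  radial <- vapply(landmarks3d, function(p) sqrt(p[1L]^2 + p[3L]^2),
                   numeric(1L))
  if (camera_distance <= max(radial)) {
    stop("camera_distance must exceed the largest radial landmark extent (",
         signif(max(radial), 4L), " cm)")
  }
  structure(
    list(landmarks3d = landmarks3d, platform_rpm = platform_rpm,
         camera_distance = camera_distance, focal_px = focal_px,
         image_size = as.numeric(image_size), frame_rate = frame_rate,
         noise_sd_px = noise_sd_px, occlusion_depth = occlusion_depth,
         seed = as.integer(seed)),
    class = "turntable_scene"
  )
}

# rotate a body-frame point about the vertical axis and return camera-frame
# (lateral, vertical, depth-from-pinhole, depth-behind-axis-plane)
rotate_to_camera <- function(scene, p, angle_deg) {
  th <- angle_deg * pi / 180
  xw <- p[1L] * cos(th) + p[3L] * sin(th)
  zw <- -p[1L] * sin(th) + p[3L] * cos(th)
  c(lateral = xw, vertical = p[2L],
    depth = scene$camera_distance - zw, zw = zw)
}

#' Project a body-frame point through the turntable camera
#'
#' Rotates the point about the vertical axis by the platform angle,
#' translates into the camera frame and applies the pinhole projection.
#' Image \code{v} grows downward while body \code{Y} grows up.
#'
#' @param scene a [turntable_scene()].
#' @param point3d length-3 numeric (X, Y, Z) body-frame coordinates, cm.
#' @param angle_deg platform rotation angle, degrees.
#' @return named numeric \code{c(u, v)} pixel coordinates (noise-free).
#' @export
project_point <- function(scene, point3d, angle_deg) {
  stopifnot(inherits(scene, "turntable_scene"))
  p <- as.numeric(point3d)
  stopifnot(length(p) == 3L)
  cam <- rotate_to_camera(scene, p, angle_deg)
  if (cam[["depth"]] <= 0) {
    stop("projection domain error: point lies at or behind the pinhole plane")
  }
  cx <- scene$image_size[1L] / 2
  cy <- scene$image_size[2L] / 2
  c(u = cx + scene$focal_px * cam[["lateral"]] / cam[["depth"]],
    v = cy - scene$focal_px * cam[["vertical"]] / cam[["depth"]])
}

# evaluate expr with a temporary seed, leaving the session RNG untouched
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Simulate frames over full platform revolutions
#'
#' Generates the landmark table a perfect annotator would produce from the
#' video: one frame every \code{1 / frame_rate} seconds with the platform
#' angle advancing at \code{platform_rpm}, each visible landmark projected
#' through the pinhole camera and jittered by seeded Gaussian pixel noise.
#' Landmarks whose rotated position falls on the far side of the rotation
#' axis (depth beyond the axis plane) are dropped, a simple stand-in for
#' body self-occlusion.
#'
#' @param scene a [turntable_scene()].
#' @param n_revolutions number of full platform turns (>= 1; the acquisition
#'   protocol recommends two).
#' @return data frame with columns \code{frame_index} (1-based),
#'   \code{time_s}, \code{rotation_angle_deg} (in [0, 360)),
#'   \code{landmark}, \code{u_px}, \code{v_px} — the same long dialect as
#'   [read_landmark_frames()] consumes.
#' @export
simulate_rotation <- function(scene, n_revolutions = 1L) {
  stopifnot(inherits(scene, "turntable_scene"), n_revolutions >= 1)
  sec_per_rev <- 60 / scene$platform_rpm
  n_frames <- floor(scene$frame_rate * sec_per_rev * n_revolutions)
  times <- (seq_len(n_frames) - 1L) / scene$frame_rate
  angles <- (scene$platform_rpm * 6 * times) %% 360  # deg/s = rpm*360/60

  nm <- names(scene$landmarks3d)
  rows <- vector("list", n_frames)
  with_seed(scene$seed, {
    for (i in seq_len(n_frames)) {
      vis_u <- numeric(0); vis_v <- numeric(0); vis_n <- character(0)
      for (j in seq_along(nm)) {
        cam <- rotate_to_camera(scene, scene$landmarks3d[[j]], angles[i])
        if (cam[["zw"]] < -scene$occlusion_depth || cam[["depth"]] <= 0) next
        cx <- scene$image_size[1L] / 2
        cy <- scene$image_size[2L] / 2
        vis_n <- c(vis_n, nm[j])
        vis_u <- c(vis_u, cx + scene$focal_px * cam[["lateral"]] / cam[["depth"]])
        vis_v <- c(vis_v, cy - scene$focal_px * cam[["vertical"]] / cam[["depth"]])
      }
      k <- length(vis_n)
      if (k > 0L && scene$noise_sd_px > 0) {
        vis_u <- vis_u + stats::rnorm(k, 0, scene$noise_sd_px)
        vis_v <- vis_v + stats::rnorm(k, 0, scene$noise_sd_px)
      }
      rows[[i]] <- data.frame(
        frame_index = rep.int(i, k), time_s = rep.int(times[i], k),
        rotation_angle_deg = rep.int(angles[i], k),
        landmark = vis_n, u_px = vis_u, v_px = vis_v,
        stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

circular_distance <- function(a, b) {
  d <- abs(((a - b + 180) %% 360) - 180)
  d
}

#' Select frames near a target platform angle
#'
#' Implements the protocol's frame selection: keep the frames whose platform
#' angle lies within \code{tolerance} degrees (circular distance) of the
#' target angle — e.g. 90 degrees for sagittal-plane curvature measurement —
#' ordered nearest-first with ties broken by the earlier frame, truncated to
#' \code{max_frames}.
#'
#' @param frames long landmark data frame with columns \code{frame_index}
#'   and \code{rotation_angle_deg} (as produced by [simulate_rotation()] or
#'   [read_landmark_frames()]'s table form).
#' @param target_angle target platform angle, degrees.
#' @param tolerance half-width of the selection window, degrees (> 0).
#' @param max_frames maximum number of frames to keep (default 26, the
#'   number the measurement protocol averages).
#' @return the rows of \code{frames} belonging to the selected frames, in
#'   selection order; carries attributes \code{selected_frames} (ordered
#'   frame indices) and \code{empty_selection} (TRUE, with a warning, when
#'   no frame falls inside the window).
#' @export
select_frames <- function(frames, target_angle = 90, tolerance = 2,
                          max_frames = 26L) {
  stopifnot(tolerance > 0)
  per_frame <- unique(frames[, c("frame_index", "rotation_angle_deg")])
  d <- circular_distance(per_frame$rotation_angle_deg, target_angle)
  keep <- which(d <= tolerance)
  if (length(keep) == 0L) {
    warning("empty selection: no frame within ", tolerance,
            " degrees of target angle ", target_angle)
    out <- frames[0L, , drop = FALSE]
    attr(out, "selected_frames") <- integer(0)
    attr(out, "empty_selection") <- TRUE
    return(out)
  }
  ord <- keep[order(d[keep], per_frame$frame_index[keep])]
  sel <- utils::head(per_frame$frame_index[ord], max_frames)
  pieces <- lapply(sel, function(fi) frames[frames$frame_index == fi, ,
                                            drop = FALSE])
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  attr(out, "selected_frames") <- sel
  attr(out, "empty_selection") <- FALSE
  out
}

#' Generate a synthetic known-rectangle acquisition
#'
#' Emulates the criterion-validity experiment: a planar rectangle of known
#' width and height facing the camera, filmed over \code{n_frames} frames in
#' practically the same position, with seeded Gaussian annotation noise on
#' the corner pixels. Four noise-free calibration marks on the same plane
#' are generated alongside, so the fixture can be pushed through the full
#' calibrate-measure-aggregate pipeline and the recovered dimensions
#' compared with the ground truth.
#'
#' The rectangle is centred on the rotation axis in the plane Z = 0 (the
#' plane through the axis parallel to the image plane), where the pinhole
#' projection is an exact similarity: with zero noise the fitted calibration
#' reproduces the true dimensions exactly.
#'
#' @param width,height true rectangle dimensions, cm (defaults 25 x 15).
#' @param camera_distance,focal_px,image_size camera geometry, as in
#'   [turntable_scene()].
#' @param noise_sd_px annotation jitter SD in pixels.
#' @param n_frames number of frames (default 30).
#' @param seed RNG seed.
#' @return list of class \code{rectangle_fixture} with \code{frames} (long
#'   landmark data frame; corners named \code{tl}, \code{tr}, \code{br},
#'   \code{bl}), \code{marks} (calibration marks data frame),
#'   \code{protocol} (a [protocol_config()] measuring \code{width} = tl-tr
#'   and \code{height} = tr-br) and \code{truth} (list with \code{width},
#'   \code{height}).
#' @export
generate_rectangle_fixture <- function(width = 25, height = 15,
                                       camera_distance = 300,
                                       focal_px = 1500,
                                       image_size = c(2048, 1536),
                                       noise_sd_px = 0,
                                       n_frames = 30L,
                                       seed = 1L) {
  stopifnot(width > 0, height > 0, n_frames >= 1L, noise_sd_px >= 0)
  corners <- list(
    tl = c(-width / 2,  height / 2, 0),
    tr = c( width / 2,  height / 2, 0),
    br = c( width / 2, -height / 2, 0),
    bl = c(-width / 2, -height / 2, 0)
  )
  scene <- turntable_scene(corners, camera_distance = camera_distance,
                           focal_px = focal_px, image_size = image_size,
                           noise_sd_px = 0, seed = seed)
  proj <- function(p) project_point(scene, p, 0)

  # calibration support: four marks spanning the target plane, marked once
  # and carefully, hence noise-free
  ext <- max(width, height)
  mark_world <- list(c(-ext, -ext), c(ext, -ext), c(ext, ext), c(-ext, ext))
  marks <- do.call(rbind, lapply(seq_along(mark_world), function(i) {
    w <- mark_world[[i]]
    px <- proj(c(w[1L], w[2L], 0))
    data.frame(mark_id = i, u_px = px[["u"]], v_px = px[["v"]],
               x_cm = w[1L], y_cm = w[2L])
  }))

  base <- lapply(corners, proj)
  rows <- with_seed(seed, {
    lapply(seq_len(n_frames), function(i) {
      u <- vapply(base, `[[`, numeric(1L), "u")
      v <- vapply(base, `[[`, numeric(1L), "v")
      if (noise_sd_px > 0) {
        u <- u + stats::rnorm(4L, 0, noise_sd_px)
        v <- v + stats::rnorm(4L, 0, noise_sd_px)
      }
      data.frame(frame_index = i, rotation_angle_deg = 0,
                 landmark = names(corners), u_px = unname(u),
                 v_px = unname(v), stringsAsFactors = FALSE)
    })
  })

  protocol <- protocol_config(
    distances = list(list(name = "width", from = "tl", to = "tr"),
                     list(name = "height", from = "tr", to = "br")),
    frame_selection = list(target_angle = 0, tolerance = 2,
                           max_frames = as.integer(n_frames))
  )
  structure(
    list(frames = do.call(rbind, rows), marks = marks, protocol = protocol,
         truth = list(width = width, height = height)),
    class = "rectangle_fixture"
  )
}
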