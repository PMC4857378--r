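# numeric parser tolerant of comma decimal separators (annotation files from
# pt-BR locales); writers always emit dots
parse_decimal <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  as.numeric(sub(",", ".", trimws(as.character(x)), fixed = TRUE))
}

#' Read annotated landmark frames from CSV
#'
#' Long-format dialect, one landmark per row, with header
#' \code{frame_index,rotation_angle_deg,landmark,u_px,v_px};
#' \code{rotation_angle_deg} may be empty when the platform angle is
#' unknown. Decimal commas are accepted on input; writers emit dots.
#'
#' @param path path to the CSV file.
#' @param as how to return the data: \code{"frames"} for a list of
#'   [landmark_frame()] objects sorted by frame index, or \code{"table"}
#'   for the raw long data frame.
#' @return see \code{as}.
#' @export
read_landmark_frames <- function(path, as = c("frames", "table")) {
  as <- match.arg(as)
  if (!file.exists(path)) stop("landmark file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("frame_index", "rotation_angle_deg", "landmark", "u_px", "v_px")
  if (!identical(names(df), need)) {
    stop("format error: expected header '", paste(need, collapse = ","),
         "' in ", path)
  }
  df$frame_index <- suppressWarnings(as.integer(df$frame_index))
  df$rotation_angle_deg <- suppressWarnings(parse_decimal(df$rotation_angle_deg))
  df$u_px <- suppressWarnings(parse_decimal(df$u_px))
  df$v_px <- suppressWarnings(parse_decimal(df$v_px))
  bad <- which(is.na(df$frame_index) | !nzchar(df$landmark) |
                 is.na(df$u_px) | is.na(df$v_px))
  if (length(bad) > 0L) {
    stop("malformed row(s) at line(s) ",
         paste(bad + 1L, collapse = ", "), " of ", path)
  }
  dup <- which(duplicated(df[, c("frame_index", "landmark")]))
  if (length(dup) > 0L) {
    stop("duplicate record: frame ", df$frame_index[dup[1L]],
         ", landmark '", df$landmark[dup[1L]], "' at line ", dup[1L] + 1L,
         " of ", path)
  }
  df <- df[order(df$frame_index), , drop = FALSE]
  rownames(df) <- NULL
  if (as == "table") df else as_landmark_frames(df)
}

#' Convert a long landmark table to a list of frames
#'
#' @param df data frame with columns \code{frame_index}, \code{landmark},
#'   \code{u_px}, \code{v_px} and optionally \code{rotation_angle_deg} (as
#'   produced by [simulate_rotation()] or [read_landmark_frames()]).
#' @return list of [landmark_frame()] objects sorted by frame index.
#' @export
as_landmark_frames <- function(df) {
  if (inherits(df, "landmark_frame")) return(list(df))
  if (is.list(df) && !is.data.frame(df) &&
      all(vapply(df, inherits, logical(1L), "landmark_frame"))) {
    return(df)
  }
  df <- as.data.frame(df)
  if (is.null(df$rotation_angle_deg)) df$rotation_angle_deg <- NA_real_
  idx <- sort(unique(df$frame_index))
  lapply(idx, function(fi) {
    sub <- df[df$frame_index == fi, , drop = FALSE]
    lm <- lapply(seq_len(nrow(sub)), function(i) c(sub$u_px[i], sub$v_px[i]))
    names(lm) <- sub$landmark
    landmark_frame(fi, lm, rotation_angle = sub$rotation_angle_deg[1L])
  })
}

#' Convert a list of frames to the long landmark table
#'
#' @param frames list of [landmark_frame()] objects.
#' @return long data frame in the [read_landmark_frames()] dialect.
#' @export
frames_to_table <- function(frames) {
  frames <- as_landmark_frames(frames)
  do.call(rbind, lapply(frames, function(fr) {
    if (length(fr$landmarks) == 0L) return(NULL)
    data.frame(frame_index = fr$frame_index,
               rotation_angle_deg = fr$rotation_angle,
               landmark = names(fr$landmarks),
               u_px = vapply(fr$landmarks, `[[`, numeric(1L), 1L),
               v_px = vapply(fr$landmarks, `[[`, numeric(1L), 2L),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}

fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else formatC(v, digits = 17, format = "g")
  }, character(1L))
  out
}

#' Write landmark frames to CSV
#'
#' Inverse of [read_landmark_frames()]; numbers are written with enough
#' digits for a lossless round trip.
#'
#' @param frames a list of [landmark_frame()] objects or a long table.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_landmark_frames <- function(frames, path) {
  df <- if (is.data.frame(frames)) frames else frames_to_table(frames)
  out <- data.frame(frame_index = df$frame_index,
                    rotation_angle_deg = fmt_num(df$rotation_angle_deg),
                    landmark = df$landmark,
                    u_px = fmt_num(df$u_px), v_px = fmt_num(df$v_px),
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Published 30-frame validation measurements of a known rectangle
#'
#' Per-frame width and height measurements of a printed 25 cm x 15 cm
#' rectangle filmed on the rotating platform over 30 near-identical frontal
#' frames, as published in the validation of the rotating-platform posture
#' system. These series are the benchmark for the accumulated-statistics
#' machinery: their summary rows (width 24.99 +/- 0.22, CV 0.88; height
#' 14.99 +/- 0.35, CV 2.33) and accumulated checkpoints are reproduced by
#' [summary_stats()] and [accumulated_stats()] under the
#' \code{"printed-table"} policy.
#'
#' The per-frame values are transcribed as printed, including the published
#' table's internal oddities (its summary narrative quotes a width range of
#' 24.83-25.2 while the per-frame extremes are 24.75 and 25.8); the
#' transcription is authoritative here and is guarded by a checksum test.
#'
#' @return list of class \code{rectangle_validation} with \code{widths} and
#'   \code{heights} (30 values each, cm), \code{true_width} (25),
#'   \code{true_height} (15) and \code{n} (30).
#' @export
rectangle_validation <- function() {
  path <- system.file("extdata", "rectangle_validation.csv",
                      package = "rotapose", mustWork = TRUE)
  df <- utils::read.csv(path)
  stopifnot(nrow(df) == 30L,
            identical(names(df), c("frame", "width_cm", "height_cm")))
  structure(
    list(widths = df$width_cm, heights = df$height_cm,
         true_width = 25, true_height = 15, n = nrow(df)),
    class = "rectangle_validation"
  )
}

#' Landmark frames reproducing the rectangle validation series
#'
#' Rebuilds, for each of the 30 published frames, four rectangle-corner
#' landmarks (\code{tl}, \code{tr}, \code{br}, \code{bl}) whose measured
#' width and height under an identity calibration equal that frame's
#' published values — so the whole pipeline (measure, aggregate, stabilize)
#' can be exercised end-to-end against the published summary rows.
#'
#' @return list with \code{frames} (list of [landmark_frame()]),
#'   \code{protocol} (measuring \code{width} = tl-tr, \code{height} =
#'   tr-br) and \code{truth}.
#' @export
rectangle_validation_frames <- function() {
  fx <- rectangle_validation()
  frames <- lapply(seq_len(fx$n), function(i) {
    w <- fx$widths[i]; h <- fx$heights[i]
    landmark_frame(i, list(tl = c(0, 0), tr = c(w, 0),
                           br = c(w, h), bl = c(0, h)))
  })
  protocol <- protocol_config(
    distances = list(list(name = "width", from = "tl", to = "tr"),
                     list(name = "height", from = "tr", to = "br"))
  )
  list(frames = frames, protocol = protocol,
       truth = list(width = fx$true_width, height = fx$true_height))
}

summary_table <- function(metrics, rounding) {
  rows <- lapply(names(metrics), function(m) {
    mt <- metrics[[m]]
    if (mt$insufficient) return(NULL)
    s <- mt$summary
    if (rounding == "printed-table") {
      data.frame(metric = m, n = s$n, mean = round_half_up(s$mean, 2L),
                 sd = round_half_up(s$sd, 2L), cv = s$cv,
                 min = s$min, max = s$max, stringsAsFactors = FALSE)
    } else {
      data.frame(metric = m, n = s$n, mean = s$mean, sd = s$sd, cv = s$cv,
                 min = s$min, max = s$max, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

accumulated_table <- function(metrics) {
  rows <- lapply(names(metrics), function(m) {
    mt <- metrics[[m]]
    if (mt$insufficient) return(NULL)
    cbind(metric = m, as.data.frame(mt$accumulated))
  })
  do.call(rbind, rows)
}

#' Write / read an accumulated-statistics table
#'
#' CSV with columns \code{metric,k,mean_accum,sd_accum,cv_accum}; numbers
#' carry full precision so the round trip is lossless.
#'
#' @param accum data frame as produced by the pipeline (or
#'   [accumulated_stats()] with a \code{metric} column added).
#' @param path file path.
#' @return \code{path} invisibly / the parsed data frame.
#' @export
write_accumulated_csv <- function(accum, path) {
  out <- data.frame(metric = accum$metric, k = accum$k,
                    mean_accum = fmt_num(accum$mean_accum),
                    sd_accum = fmt_num(accum$sd_accum),
                    cv_accum = fmt_num(accum$cv_accum),
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_accumulated_csv
#' @export
read_accumulated_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("metric", "k", "mean_accum", "sd_accum", "cv_accum")
  if (!identical(names(df), need)) {
    stop("format error: expected header '", paste(need, collapse = ","),
         "' in ", path)
  }
  for (col in c("mean_accum", "sd_accum", "cv_accum")) {
    df[[col]] <- parse_decimal(df[[col]])
  }
  df
}

stage <- function(name, quiet, expr) {
  if (!quiet) message("[", name, "] starting")
  tryCatch(force(expr), error = function(e) {
    stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full posture-evaluation pipeline
#'
#' Calibrate, measure every selected frame, aggregate across frames and
#' apply the stabilization rule — the complete workflow from annotated
#' video frames to a posture report. Frame selection (nearest frames to the
#' protocol's target platform angle) is applied only when the annotations
#' carry rotation angles; otherwise all frames are used, which matches
#' manually pre-selected frame sets.
#'
#' @param landmarks landmark annotations: a path to a landmark CSV, a long
#'   data frame, or a list of [landmark_frame()] objects.
#' @param calibration a fitted \code{calibration_model}, a path to a marks
#'   CSV or a model JSON, a marks data frame, or \code{NULL} for the
#'   identity calibration.
#' @param protocol a [protocol_config()] or a path readable by
#'   [read_protocol()].
#' @param out_dir if non-NULL, writes \code{summary.csv},
#'   \code{accumulated.csv}, \code{stabilization.json} and a human-readable
#'   \code{report.txt} there.
#' @param quiet suppress per-stage log messages.
#' @return An object of class \code{posture_report}: list with
#'   \code{model}, \code{n_frames_used}, \code{metrics} (per-metric
#'   aggregate), \code{summary} (data frame), \code{accumulated} (long data
#'   frame), \code{stabilization} (per-metric [repetitions_needed()]
#'   results) and \code{skipped} (per-metric skip counts).
#' @export
run_pipeline <- function(landmarks, calibration = NULL, protocol,
                         out_dir = NULL, quiet = TRUE) {
  if (is.character(protocol)) protocol <- read_protocol(protocol)
  stopifnot(inherits(protocol, "protocol_config"))

  model <- stage("calibrate", quiet, {
    if (is.null(calibration)) {
      identity_calibration()
    } else if (inherits(calibration, "calibration_model")) {
      calibration
    } else if (is.character(calibration)) {
      if (grepl("\\.json$", calibration, ignore.case = TRUE)) {
        read_calibration_model(calibration)
      } else {
        fit_calibration(read_calibration_marks(calibration),
                        family = protocol$calibration_family)
      }
    } else {
      fit_calibration(as.data.frame(calibration),
                      family = protocol$calibration_family)
    }
  })

  frames <- stage("load", quiet, {
    if (is.character(landmarks)) read_landmark_frames(landmarks)
    else as_landmark_frames(landmarks)
  })

  frames <- stage("select", quiet, {
    angles <- vapply(frames, `[[`, numeric(1L), "rotation_angle")
    if (all(is.na(angles))) {
      if (!quiet) message("[select] no rotation angles; using all ",
                          length(frames), " frames")
      frames
    } else {
      fs <- protocol$frame_selection
      tab <- select_frames(frames_to_table(frames),
                           target_angle = fs$target_angle,
                           tolerance = fs$tolerance,
                           max_frames = fs$max_frames)
      if (isTRUE(attr(tab, "empty_selection"))) {
        stop("no frames within ", fs$tolerance, " degrees of ",
             fs$target_angle)
      }
      as_landmark_frames(tab)
    }
  })

  per_frame <- stage("measure", quiet, {
    if (length(frames) < 2L) {
      stop("insufficient data: need at least 2 frames, got ", length(frames))
    }
    known <- unique(unlist(lapply(frames, function(f) names(f$landmarks))))
    validate_protocol(protocol, known)
    lapply(frames, measure_frame, model = model, protocol = protocol)
  })

  metrics <- stage("aggregate", quiet,
                   aggregate_metrics(per_frame, rounding = protocol$rounding))

  stab <- stage("stabilize", quiet, {
    st <- protocol$stabilization
    res <- lapply(metrics, function(mt) {
      if (mt$insufficient) return(NULL)
      repetitions_needed(mt$accumulated, rule = st$rule,
                         epsilon = st$epsilon, window = st$window)
    })
    res[!vapply(res, is.null, logical(1L))]
  })

  skipped <- vapply(metrics, `[[`, numeric(1L), "n_skipped")
  if (!quiet && any(skipped > 0)) {
    message("[aggregate] skipped frames per metric: ",
            paste(names(skipped)[skipped > 0], skipped[skipped > 0],
                  sep = "=", collapse = ", "))
  }

  report <- structure(
    list(model = model, n_frames_used = length(frames), metrics = metrics,
         summary = summary_table(metrics, protocol$rounding),
         accumulated = accumulated_table(metrics),
         stabilization = stab, skipped = skipped),
    class = "posture_report"
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(report$summary, file.path(out_dir, "summary.csv"),
                     row.names = FALSE, quote = FALSE)
    write_accumulated_csv(report$accumulated,
                          file.path(out_dir, "accumulated.csv"))
    stab_doc <- lapply(names(stab), function(m) {
      s <- stab[[m]]
      list(metric = m,
           k_stable = if (s$stabilized) s$k_stable else NULL,
           rule = s$rule, params = s$params, stabilized = s$stabilized)
    })
    jsonlite::write_json(stab_doc, file.path(out_dir, "stabilization.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    writeLines(utils::capture.output(print(report)),
               file.path(out_dir, "report.txt"))
  }
  report
}

#' @export
print.posture_report <- function(x, ...) {
  cat("Posture evaluation report —", x$n_frames_used, "frames\n\n")
  if (!is.null(x$summary)) {
    print(x$summary, row.names = FALSE)
  }
  cat("\nStabilization:\n")
  for (m in names(x$stabilization)) {
    s <- x$stabilization[[m]]
    if (s$stabilized) {
      cat(sprintf("  %s: stable after %d frames (%s)\n", m, s$k_stable,
                  s$rule))
    } else {
      cat(sprintf("  %s: not stabilized (%s)\n", m, s$rule))
    }
  }
  if (any(x$skipped > 0)) {
    cat("\nFrames skipped per metric:\n")
    for (m in names(x$skipped)[x$skipped > 0]) {
      cat("  ", m, ": ", x$skipped[[m]], "\n", sep = "")
    }
  }
  invisible(x)
}
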