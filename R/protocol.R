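#' Define a measurement protocol
#'
#' The protocol bundles everything the pipeline needs beyond the raw
#' annotations: the metric definitions (curvature regions, distance pairs,
#' angle triples, area vertex lists), the frame-selection window used to
#' pick near-identical views, the rounding policy for reported statistics,
#' and the stabilization rule.
#'
#' @param regions list of curvature regions, each a list with \code{label}
#'   and landmark names \code{upper}, \code{apex}, \code{lower} (three
#'   distinct names). Each region yields a metric named
#'   \code{<label>_ci}.
#' @param distances list of \code{list(name, from, to)} landmark pairs.
#' @param angles list of \code{list(name, a, vertex, c)} landmark triples.
#' @param areas list of \code{list(name, vertices)} where \code{vertices} is
#'   a character vector of >= 3 landmark names in polygon order.
#' @param frame_selection list with \code{target_angle} (degrees),
#'   \code{tolerance} (degrees, > 0) and \code{max_frames} (>= 2; default 26,
#'   the number of near-identical frames the acquisition protocol selects
#'   per evaluation).
#' @param rounding \code{"printed-table"} (mean and SD each rounded half-up
#'   to two decimals before forming the coefficient of variation, matching
#'   how results tables are conventionally printed) or \code{"exact"}.
#' @param stabilization list with \code{rule}
#'   (\code{"terminal-plateau"} or \code{"delta-threshold"}) and, for the
#'   latter, \code{epsilon} and \code{window}.
#' @param clamp_to_segment passed to [curvature_index()].
#' @param calibration_family passed to [fit_calibration()].
#' @return an object of class \code{protocol_config}.
#' @export
protocol_config <- function(regions = list(),
                            distances = list(),
                            angles = list(),
                            areas = list(),
                            frame_selection = list(target_angle = 90,
                                                   tolerance = 5,
                                                   max_frames = 26L),
                            rounding = c("printed-table", "exact"),
                            stabilization = list(rule = "terminal-plateau",
                                                 epsilon = 0.05,
                                                 window = 4L),
                            clamp_to_segment = FALSE,
                            calibration_family = "auto") {
  rounding <- match.arg(rounding)

  for (rg in regions) {
    if (!all(c("label", "upper", "apex", "lower") %in% names(rg))) {
      stop("each region needs fields label, upper, apex, lower")
    }
    if (anyDuplicated(c(rg$upper, rg$apex, rg$lower)) > 0L) {
      stop("region '", rg$label, "' must name three distinct landmarks")
    }
  }
  for (d in distances) {
    if (!all(c("name", "from", "to") %in% names(d))) {
      stop("each distance needs fields name, from, to")
    }
  }
  for (an in angles) {
    if (!all(c("name", "a", "vertex", "c") %in% names(an))) {
      stop("each angle needs fields name, a, vertex, c")
    }
  }
  for (ar in areas) {
    if (!all(c("name", "vertices") %in% names(ar)) ||
        length(ar$vertices) < 3L) {
      stop("each area needs a name and at least 3 vertex landmark names")
    }
  }

  fs <- utils::modifyList(list(target_angle = 90, tolerance = 5,
                               max_frames = 26L), frame_selection)
  if (fs$max_frames < 2L) stop("frame_selection$max_frames must be >= 2")
  if (fs$tolerance <= 0) stop("frame_selection$tolerance must be > 0")

  st <- utils::modifyList(list(rule = "terminal-plateau", epsilon = 0.05,
                               window = 4L), stabilization)
  if (!st$rule %in% c("terminal-plateau", "delta-threshold")) {
    stop("unknown stabilization rule: ", st$rule)
  }

  structure(
    list(regions = regions, distances = distances, angles = angles,
         areas = areas, frame_selection = fs, rounding = rounding,
         stabilization = st, clamp_to_segment = isTRUE(clamp_to_segment),
         calibration_family = calibration_family),
    class = "protocol_config"
  )
}

#' Check that a protocol only references known landmarks
#'
#' @param protocol a [protocol_config()].
#' @param known_landmarks character vector of landmark names present in the
#'   annotation data (typically the union over frames).
#' @return \code{protocol}, invisibly; errors naming the first unknown
#'   landmark otherwise.
#' @export
validate_protocol <- function(protocol, known_landmarks) {
  stopifnot(inherits(protocol, "protocol_config"))
  referenced <- c(
    unlist(lapply(protocol$regions, function(r) c(r$upper, r$apex, r$lower))),
    unlist(lapply(protocol$distances, function(d) c(d$from, d$to))),
    unlist(lapply(protocol$angles, function(a) c(a$a, a$vertex, a$c))),
    unlist(lapply(protocol$areas, function(a) a$vertices))
  )
  unknown <- setdiff(referenced, known_landmarks)
  if (length(unknown) > 0L) {
    stop("configuration error: protocol references unknown landmark(s): ",
         paste(unknown, collapse = ", "))
  }
  invisible(protocol)
}

#' Read a protocol configuration from YAML or JSON
#'
#' The document mirrors the arguments of [protocol_config()]; unspecified
#' fields take their defaults.
#'
#' @param path path to a \code{.yaml}/\code{.yml} or \code{.json} file.
#' @return a [protocol_config()].
#' @export
read_protocol <- function(path) {
  if (!file.exists(path)) stop("protocol file not found: ", path)
  doc <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  args <- doc[intersect(names(doc),
                        names(formals(protocol_config)))]
  # yaml may hand areas$vertices in as a list; flatten to character
  if (!is.null(args$areas)) {
    args$areas <- lapply(args$areas, function(a) {
      a$vertices <- as.character(unlist(a$vertices)); a
    })
  }
  do.call(protocol_config, args)
}
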