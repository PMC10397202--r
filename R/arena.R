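#' Describe an object placed in the arena
#'
#' @param centre length-2 numeric, x/y of the object centre (mm).
#' @param footprint_radius object footprint radius (mm).
#' @param top_height height of the object's top above the floor (mm); used by
#'   the climb rule of investigation detection.
#' @param role `"familiar"` or `"novel"`.
#' @return An object of class `object_spec`.
#' @export
object_spec <- function(centre, footprint_radius = 30, top_height = 60,
                        role = c("familiar", "novel")) {
  role <- match.arg(role)
  stopifnot(length(centre) == 2L, is.finite(centre))
  if (footprint_radius <= 0) stop("footprint_radius must be > 0", call. = FALSE)
  if (top_height <= 0) stop("top_height must be > 0", call. = FALSE)
  structure(list(centre = as.numeric(centre),
                 footprint_radius = footprint_radius,
                 top_height = top_height, role = role),
            class = "object_spec")
}

#' Describe the behavioural arena
#'
#' Defaults describe the two apparatus used for this assay: a circular open
#' field of diameter 50 cm, and a 40 x 40 cm square box for the novel-object
#' task.
#'
#' @param shape `"circle"` or `"square"`.
#' @param size diameter (circle) or side length (square), mm.
#' @param height wall height, mm.
#' @param objects list of [object_spec()] (0-2 objects).
#' @return An object of class `arena_spec`.
#' @export
arena_spec <- function(shape = c("circle", "square"), size = 500,
                       height = 500, objects = list()) {
  shape <- match.arg(shape)
  if (size <= 0) stop("arena size must be > 0", call. = FALSE)
  if (length(objects) > 2L) stop("at most 2 objects supported", call. = FALSE)
  for (o in objects)
    if (!inherits(o, "object_spec")) stop("objects must be object_spec",
                                          call. = FALSE)
  structure(list(shape = shape, size = size, height = height,
                 objects = objects),
            class = "arena_spec")
}

#' Open-field arena preset (50 cm diameter circle)
#' @return An [arena_spec()].
#' @export
open_field_arena <- function() arena_spec("circle", size = 500, height = 500)

#' Novel-object arena preset (40 x 40 cm box, two objects)
#'
#' Objects sit near one wall, mirrored left/right.
#'
#' @param top_height object top height, mm.
#' @return An [arena_spec()].
#' @export
nor_arena <- function(top_height = 60) {
  arena_spec("square", size = 400, height = 500, objects = list(
    object_spec(c(100, 80), top_height = top_height, role = "familiar"),
    object_spec(c(300, 80), top_height = top_height, role = "novel")))
}

#' Arena centre coordinates
#' @param arena an [arena_spec()].
#' @return length-2 numeric (mm). Square arenas have origin at a corner, so
#'   the centre is `size/2`; circular arenas are centred on the origin.
#' @export
arena_centre <- function(arena) {
  if (arena$shape == "circle") c(0, 0) else c(arena$size / 2, arena$size / 2)
}

#' Bundle a session's data and metadata
#'
#' @param animal_id identifier string.
#' @param group `"control"`, `"model"` or `"dex"`.
#' @param paradigm `"OFT"`, `"NOR_train"` or `"NOR_test"`.
#' @param trajectory a [skeleton_trajectory()] or NULL.
#' @param labels a [movement_labels()] or NULL.
#' @param arena an [arena_spec()].
#' @param timepoint_h postoperative timepoint in hours (6, 30, 54 or 78), or
#'   NULL.
#' @param ground_truth optional list of generator ground truth (kept verbatim
#'   in the metadata sidecar).
#' @return An object of class `session_record`.
#' @export
session_record <- function(animal_id, group = c("control", "model", "dex"),
                           paradigm = c("OFT", "NOR_train", "NOR_test"),
                           trajectory = NULL, labels = NULL,
                           arena = open_field_arena(), timepoint_h = NULL,
                           ground_truth = NULL) {
  group <- match.arg(group)
  paradigm <- match.arg(paradigm)
  if (!is.null(timepoint_h) && !timepoint_h %in% c(6, 30, 54, 78))
    stop("timepoint_h must be one of 6, 30, 54, 78", call. = FALSE)
  if (paradigm != "OFT" && length(arena$objects) == 0L)
    stop("NOR paradigms require an arena with objects", call. = FALSE)
  structure(list(animal_id = animal_id, group = group, paradigm = paradigm,
                 trajectory = trajectory, labels = labels, arena = arena,
                 timepoint_h = timepoint_h, ground_truth = ground_truth),
            class = "session_record")
}

#' Write session metadata (and ground truth) to a JSON sidecar
#'
#' The trajectory and labels themselves go to CSV via [write_trajectory()]
#' and [write_labels()]; the sidecar carries everything else, including any
#' generator ground truth, and round-trips through [read_session_meta()].
#'
#' @param session a [session_record()].
#' @param path output path for the JSON file.
#' @return `path`, invisibly.
#' @export
write_session_meta <- function(session, path) {
  arena <- session$arena
  meta <- list(
    animal_id = session$animal_id, group = session$group,
    paradigm = session$paradigm, timepoint_h = session$timepoint_h,
    arena = list(shape = arena$shape, size = arena$size,
                 height = arena$height,
                 objects = lapply(arena$objects, unclass)),
    ground_truth = session$ground_truth)
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       null = "null", dataframe = "columns")
  invisible(path)
}

#' Read session metadata from a JSON sidecar
#'
#' @param path path written by [write_session_meta()].
#' @return A [session_record()] (trajectory/labels slots empty).
#' @export
read_session_meta <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = FALSE)
  objects <- lapply(m$arena$objects, function(o)
    object_spec(unlist(o$centre), o$footprint_radius, o$top_height, o$role))
  arena <- arena_spec(m$arena$shape, m$arena$size, m$arena$height, objects)
  session_record(m$animal_id, m$group, m$paradigm, arena = arena,
                 timepoint_h = m$timepoint_h,
                 ground_truth = .simplify_json(m$ground_truth))
}

# collapse unnamed lists of scalars (JSON arrays) back into vectors
.simplify_json <- function(x) {
  if (!is.list(x)) return(x)
  if (is.null(names(x)) && length(x) && !any(vapply(x, is.list, TRUE)))
    return(unlist(x))
  lapply(x, .simplify_json)
}
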