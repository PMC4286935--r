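# Renderer-agnostic scene serialization: an apms_diagram round-trips
# through a documented JSON file so alternative renderers (or the CLI's
# renderer-only mode) can consume the geometry without recomputing it.

#' Serialize a diagram to a scene JSON file
#'
#' The scene file carries the resolved geometry only — segments (kind,
#' label, angular extent, colors), arcs (endpoint angles, Bezier control
#' geometry in normalized canvas coordinates, class, color), the legend,
#' the bait label and the layout options. Indices are 1-based. Numbers
#' are written at full precision, so identical diagrams serialize to
#' identical bytes and round-trip exactly.
#'
#' @param diagram An `apms_diagram` object.
#' @param path Output path; when `NULL` the JSON text is returned.
#' @return The JSON text, invisibly when `path` is given.
#' @seealso [diagram_from_json()]
#' @export
diagram_to_json <- function(diagram, path = NULL) {
  scene <- list(
    format = "baitring-scene",
    version = 1L,
    bait_label = diagram$bait_label,
    options = unclass(diagram$options),
    segments = as.data.frame(diagram$segments),
    arcs = as.data.frame(diagram$arcs),
    legend = as.data.frame(diagram$legend),
    unmatched = as.data.frame(diagram$mapping$unmatched),
    unit_angle = attr(diagram$segments, "unit_angle")
  )
  txt <- jsonlite::toJSON(scene, dataframe = "columns", auto_unbox = TRUE,
                          digits = NA, pretty = TRUE, na = "null")
  if (is.null(path)) return(as.character(txt))
  writeLines(txt, path)
  invisible(as.character(txt))
}

#' Rebuild a diagram from a scene JSON file
#'
#' Reconstructs an `apms_diagram` sufficient for rendering. The mapping
#' component holds only what the scene preserves (arcs and the unmatched
#' report).
#'
#' @param path Path to a scene JSON file, or a JSON string.
#' @return An `apms_diagram` object.
#' @export
diagram_from_json <- function(path) {
  scene <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(scene$format, "baitring-scene")) {
    abort("not a baitring scene file", class = "baitring_error")
  }
  o <- scene$options
  opts <- layout_options(
    spacer_units = o$spacer_units, bait_units = o$bait_units,
    radius = o$radius, ring_thickness = o$ring_thickness,
    bait_center_angle = o$bait_center_angle, clockwise = o$clockwise,
    arc_tension = o$arc_tension
  )
  seg <- as_tibble(as.data.frame(scene$segments, stringsAsFactors = FALSE))
  seg$set_index <- as.integer(seg$set_index)
  segments <- structure(seg,
                        unit_angle = scene$unit_angle,
                        clockwise = opts$clockwise,
                        bait_center_angle = opts$bait_center_angle,
                        class = c("apms_segments", class(tibble())))
  arcs <- as_tibble(as.data.frame(scene$arcs, stringsAsFactors = FALSE))
  if (ncol(arcs) == 0L) {
    arcs <- tibble(record_index = integer(), arc_class = character(),
                   prey_id = character(), set_index = integer(),
                   entry_index = integer(), from_angle = double(),
                   to_angle = double(), x0 = double(), y0 = double(),
                   cx = double(), cy = double(), x1 = double(),
                   y1 = double(), degenerate = logical(),
                   red = integer(), green = integer(), blue = integer())
  }
  unmatched <- as_tibble(as.data.frame(scene$unmatched, stringsAsFactors = FALSE))
  if (ncol(unmatched) == 0L) {
    unmatched <- tibble(record_index = integer(), prey_id = character())
  }
  structure(
    list(segments = segments, arcs = arcs,
         legend = as_tibble(as.data.frame(scene$legend, stringsAsFactors = FALSE)),
         mapping = structure(list(arcs = arcs, unmatched = unmatched,
                                  removals = NULL,
                                  reappearance = NA, n_records = NA_integer_),
                             class = "apms_mapping"),
         bait_label = scene$bait_label, options = opts),
    class = "apms_diagram"
  )
}
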