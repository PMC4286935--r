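# Angular layout: proportional segment allocation around the ring and
# arc geometry, independent of any rendering backend. Angles are in
# degrees, mathematical convention (counterclockwise positive,
# 0 = east, 90 = top); the clockwise option is a sign flip applied at
# layout time, and all stored angles are normalized to [0, 360).

normalize_angle <- function(a) ((a %% 360) + 360) %% 360

#' Layout options for the circular diagram
#'
#' All widths on the outer circle are measured in *protein units*: one
#' unit is the slot width of a single reference protein, so segment
#' widths stay proportional to set sizes and the white spacers double as
#' a visual scale bar.
#'
#' @param spacer_units Width of each of the two white spacers flanking
#'   the bait, in protein units (default 3: each spacer spans exactly
#'   three proteins).
#' @param bait_units Width of the black bait segment, in protein units
#'   (default 3, matching a spacer).
#' @param radius Outer ring radius as a fraction of the canvas
#'   half-extent, in (0, 1] (default 0.85).
#' @param ring_thickness Radial thickness of the ring as a fraction of
#'   `radius` (default 0.06). Arcs attach to the ring's inner edge.
#' @param bait_center_angle Angle (degrees) at which the bait segment is
#'   centered; default 90 puts the bait at the top.
#' @param clockwise Lay sets out clockwise from the bait (default
#'   `TRUE`).
#' @param arc_tension In `[0, 1]`: 0 (default) places the quadratic
#'   Bezier control point of every arc at the circle center; 1 places it
#'   at the chord midpoint, flattening the arc toward the chord.
#' @return A validated list of class `layout_options`.
#' @export
layout_options <- function(spacer_units = 3, bait_units = 3, radius = 0.85,
                           ring_thickness = 0.06, bait_center_angle = 90,
                           clockwise = TRUE, arc_tension = 0) {
  stopifnot(
    is.numeric(spacer_units), length(spacer_units) == 1L, spacer_units > 0,
    is.numeric(bait_units), length(bait_units) == 1L, bait_units > 0,
    is.numeric(radius), length(radius) == 1L, radius > 0, radius <= 1,
    is.numeric(ring_thickness), ring_thickness > 0, ring_thickness < 1,
    is.numeric(bait_center_angle), length(bait_center_angle) == 1L,
    is.logical(clockwise), length(clockwise) == 1L,
    is.numeric(arc_tension), arc_tension >= 0, arc_tension <= 1
  )
  structure(
    list(spacer_units = spacer_units, bait_units = bait_units,
         radius = radius, ring_thickness = ring_thickness,
         bait_center_angle = bait_center_angle, clockwise = clockwise,
         arc_tension = arc_tension),
    class = "layout_options"
  )
}

#' Angular width of one protein slot
#'
#' The circle is divided into `sum(set sizes) + bait_units +
#' 2 * spacer_units` equal protein units; every segment's width is its
#' unit count times this angle, which makes colored set widths
#' proportional to the number of proteins they encompass.
#'
#' @param reference An `apms_reference` tibble with at least one entry.
#' @param opts A [layout_options()] list.
#' @return Degrees per protein unit.
#' @examples
#' r <- parse_reference(paste0(">A\n", paste(rep("-,P,-\n", 6), collapse = ""),
#'                             ">B\n-,Q1,-\n-,Q2,-\n-,Q3,-\n"))
#' unit_angle(r, layout_options())  # 360 / (9 + 3 + 6) = 20
#' @export
unit_angle <- function(reference, opts = layout_options()) {
  n <- nrow(reference)
  if (n == 0L) {
    abort("reference has no protein entries; cannot lay out a circle",
          class = "baitring_error")
  }
  360 / (n + opts$bait_units + 2 * opts$spacer_units)
}

#' Compute the outer-circle segments
#'
#' Tiles the full circle, starting from the black bait segment centered
#' at `bait_center_angle` and proceeding in the layout direction:
#' bait, white spacer, the protein sets in reference order, white
#' spacer (which closes back onto the bait). Widths are `n_units` times
#' the [unit_angle()]; an empty protein set occupies a zero-width
#' segment (with a warning) so set indices stay aligned.
#'
#' @param reference An `apms_reference` tibble.
#' @param bait_label Text label for the bait segment.
#' @param set_colors Per-set colors from [assign_set_colors()].
#' @param opts A [layout_options()] list.
#' @return A tibble of class `apms_segments` with columns `kind`
#'   (`"bait"`, `"spacer"`, `"set"`), `label`, `set_index` (`NA` for
#'   bait/spacers), `n_units`, `width_deg`, `start_offset` (degrees
#'   traversed from the bait segment start, along the layout direction),
#'   `start_angle`, `end_angle` (normalized degrees; traversal from
#'   start to end follows the layout direction), `red`, `green`, `blue`.
#'   The unit angle, direction and bait center are kept as attributes.
#' @export
compute_segments <- function(reference, bait_label, set_colors,
                             opts = layout_options()) {
  sets <- reference_sets(reference)
  stopifnot(nrow(set_colors) == nrow(sets))
  unit <- unit_angle(reference, opts)
  empty <- sets$set_name[sets$n_entries == 0L]
  for (nm in empty) {
    warn(sprintf("protein set '%s' is empty and occupies zero width", nm),
         class = "baitring_warn_empty_set")
  }
  seg <- tibble(
    kind = c("bait", "spacer", rep("set", nrow(sets)), "spacer"),
    label = c(bait_label, "", sets$set_name, ""),
    set_index = c(NA_integer_, NA_integer_, sets$set_index, NA_integer_),
    n_units = c(opts$bait_units, opts$spacer_units, sets$n_entries,
                opts$spacer_units),
    red = c(0L, 255L, set_colors$red, 255L),
    green = c(0L, 255L, set_colors$green, 255L),
    blue = c(0L, 255L, set_colors$blue, 255L)
  )
  seg$width_deg <- seg$n_units * unit
  seg$start_offset <- cumsum(c(0, seg$width_deg))[seq_len(nrow(seg))]
  dir <- if (opts$clockwise) -1 else 1
  start0 <- opts$bait_center_angle - dir * seg$width_deg[1] / 2
  seg$start_angle <- normalize_angle(start0 + dir * seg$start_offset)
  seg$end_angle <- normalize_angle(start0 + dir * (seg$start_offset + seg$width_deg))
  structure(seg,
            unit_angle = unit, clockwise = opts$clockwise,
            bait_center_angle = opts$bait_center_angle,
            class = c("apms_segments", class(tibble())))
}

segment_direction <- function(segments) {
  if (isTRUE(attr(segments, "clockwise"))) -1 else 1
}

#' Anchor angle of one reference entry
#'
#' Each protein occupies a one-unit slot inside its set segment; its arc
#' anchors at the slot midpoint, so anchors advance strictly along the
#' layout direction and never touch the segment boundaries.
#'
#' @param segments An `apms_segments` tibble from [compute_segments()].
#' @param set_index 1-based protein set index.
#' @param entry_index 1-based entry index within the set.
#' @return Anchor angle in degrees, normalized to `[0, 360)`.
#' @export
anchor_angle <- function(segments, set_index, entry_index) {
  row <- which(segments$kind == "set" & segments$set_index == set_index)
  if (length(row) != 1L) {
    abort(sprintf("no protein set with index %s", set_index),
          class = "baitring_error")
  }
  if (entry_index < 1L || entry_index > segments$n_units[row]) {
    abort(sprintf("entry index %s out of range for set %s (size %d)",
                  entry_index, set_index, segments$n_units[row]),
          class = "baitring_error")
  }
  unit <- attr(segments, "unit_angle")
  dir <- segment_direction(segments)
  normalize_angle(segments$start_angle[row] + dir * (entry_index - 0.5) * unit)
}

#' Anchor angle of the bait segment
#'
#' All arcs originate here: the midpoint of the black bait segment
#' (equal to `bait_center_angle`, 90 degrees with defaults).
#'
#' @param segments An `apms_segments` tibble.
#' @return Degrees, normalized to `[0, 360)`.
#' @export
bait_anchor <- function(segments) {
  normalize_angle(attr(segments, "bait_center_angle"))
}

angular_separation <- function(a, b) {
  d <- abs(normalize_angle(a) - normalize_angle(b))
  min(d, 360 - d)
}

#' Quadratic Bezier geometry of one interaction arc
#'
#' Arcs run through the middle of the circle: a quadratic Bezier from
#' the ring inner-edge point at `from_angle` to the point at `to_angle`,
#' with the control point at the circle center displaced toward the
#' chord midpoint by the fraction `arc_tension` (tension 0 puts the
#' control exactly at the center). Coincident endpoints (angular
#' separation below 1e-3 degrees) degenerate to a short stub toward the
#' center, with a `baitring_warn_degenerate_arc` warning.
#'
#' @param from_angle,to_angle Endpoint angles in degrees.
#' @param opts A [layout_options()] list (supplies `arc_tension`).
#' @param center Numeric length-2 circle center.
#' @param radius Radius of the attachment circle (the ring inner edge).
#' @return A list `x0, y0, cx, cy, x1, y1, degenerate`.
#' @export
arc_path <- function(from_angle, to_angle, opts = layout_options(),
                     center = c(0, 0), radius = 1) {
  p0 <- center + radius * c(cospi(from_angle / 180), sinpi(from_angle / 180))
  p1 <- center + radius * c(cospi(to_angle / 180), sinpi(to_angle / 180))
  degenerate <- angular_separation(from_angle, to_angle) < 1e-3
  if (degenerate) {
    warn(sprintf("degenerate arc at %.4f degrees drawn as a stub", from_angle),
         class = "baitring_warn_degenerate_arc")
    p1 <- p0 + 0.2 * (center - p0)
    ctrl <- (p0 + p1) / 2
  } else {
    mid <- (p0 + p1) / 2
    ctrl <- center + opts$arc_tension * (mid - center)
  }
  list(x0 = p0[1], y0 = p0[2], cx = ctrl[1], cy = ctrl[2],
       x1 = p1[1], y1 = p1[2], degenerate = degenerate)
}

# Evaluate the quadratic Bezier at parameter t (vectorized over t).
bezier_point <- function(path, t) {
  list(
    x = (1 - t)^2 * path$x0 + 2 * (1 - t) * t * path$cx + t^2 * path$x1,
    y = (1 - t)^2 * path$y0 + 2 * (1 - t) * t * path$cy + t^2 * path$y1
  )
}

#' Build the full circular diagram
#'
#' Composes the pipeline: duplicate-row removal, occurrence mapping
#' (reappearance ON or OFF), color cycling, segment layout and per-arc
#' geometry. Arc color follows the arc class: `ppi` arcs take the color
#' of the protein set they land in, `ivtk` (kinase substrate) arcs are
#' black and are ordered after all `ppi` arcs so they draw on top.
#'
#' @param experiment An `apms_experiment` tibble.
#' @param reference An `apms_reference` tibble.
#' @param scheme An `apms_colors` tibble.
#' @param reappearance Redundant mapping flag; see [map_experiment()].
#' @param opts A [layout_options()] list.
#' @param dedupe Collapse exact duplicate rows first (default `TRUE`).
#' @return An object of class `apms_diagram`: a list with `segments`
#'   (the [compute_segments()] tibble), `arcs` (a tibble with mapping
#'   columns plus `from_angle`, `to_angle`, `x0, y0, cx, cy, x1, y1`,
#'   `degenerate`, `red, green, blue` in normalized canvas coordinates,
#'   center `(0, 0)`, half-extent 1), `legend` (set name to color),
#'   `mapping` (the full [map_experiment()] result), `bait_label` and
#'   `options`.
#' @export
build_diagram <- function(experiment, reference, scheme, reappearance = TRUE,
                          opts = layout_options(), dedupe = TRUE) {
  mapping <- map_experiment(experiment, reference, reappearance = reappearance,
                            dedupe = dedupe)
  set_colors <- assign_set_colors(reference, scheme)
  bait <- experiment_bait(experiment)
  segments <- compute_segments(reference, bait, set_colors, opts)
  r_in <- opts$radius * (1 - opts$ring_thickness)
  from <- bait_anchor(segments)

  arcs <- mapping$arcs
  arcs <- arcs[order(match(arcs$arc_class, c("ppi", "ivtk"))), ]
  geom <- purrr::pmap(
    list(arcs$set_index, arcs$entry_index, arcs$arc_class),
    function(si, ei, cls) {
      to <- anchor_angle(segments, si, ei)
      path <- arc_path(from, to, opts, center = c(0, 0), radius = r_in)
      col <- if (cls == "ivtk") {
        c(0L, 0L, 0L)
      } else {
        k <- match(si, set_colors$set_index)
        c(set_colors$red[k], set_colors$green[k], set_colors$blue[k])
      }
      tibble(from_angle = from, to_angle = to,
             x0 = path$x0, y0 = path$y0, cx = path$cx, cy = path$cy,
             x1 = path$x1, y1 = path$y1, degenerate = path$degenerate,
             red = col[1], green = col[2], blue = col[3])
    }
  )
  empty_geom <- tibble(from_angle = double(), to_angle = double(),
                       x0 = double(), y0 = double(), cx = double(),
                       cy = double(), x1 = double(), y1 = double(),
                       degenerate = logical(), red = integer(),
                       green = integer(), blue = integer())
  arcs <- dplyr::bind_cols(arcs, dplyr::bind_rows(empty_geom, !!!geom))
  structure(
    list(segments = segments, arcs = arcs,
         legend = set_colors, mapping = mapping,
         bait_label = bait, options = opts),
    class = "apms_diagram"
  )
}

#' @export
print.apms_diagram <- function(x, ...) {
  cat(sprintf(
    "<apms_diagram> bait '%s': %d segments (%d protein sets), %d arcs, %d unmatched prey\n",
    x$bait_label, nrow(x$segments), sum(x$segments$kind == "set"),
    nrow(x$arcs), nrow(x$mapping$unmatched)
  ))
  invisible(x)
}

#' Tidy a circular diagram
#'
#' `tidy()` returns the arc table (one row per drawn arc with its full
#' geometry); `glance()` a one-row summary of the diagram.
#'
#' @param x An `apms_diagram` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy apms_diagram
#' @export
tidy.apms_diagram <- function(x, ...) x$arcs

#' @rdname tidy.apms_diagram
#' @method glance apms_diagram
#' @export
glance.apms_diagram <- function(x, ...) {
  tibble(
    bait = x$bait_label,
    n_sets = sum(x$segments$kind == "set"),
    n_segments = nrow(x$segments),
    n_arcs = nrow(x$arcs),
    n_ppi_arcs = sum(x$arcs$arc_class == "ppi"),
    n_ivtk_arcs = sum(x$arcs$arc_class == "ivtk"),
    n_unmatched = nrow(x$mapping$unmatched),
    reappearance = x$mapping$reappearance
  )
}
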