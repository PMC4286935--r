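# Vector-graphics backends. SVG is the canonical backend and is emitted
# directly (deterministic bytes, one element per scene object, so tests
# can count and compare against the geometry). PDF draws the same scene
# through grid onto grDevices::pdf(), never by converting the SVG file.

#' Rendering options
#'
#' @param canvas_size Square canvas edge in points (default 800).
#' @param arc_stroke Arc stroke width in points (default 1.2).
#' @param ring_outline Draw a thin outline around ring sectors (default
#'   `FALSE`).
#' @param label_font_size Label size in points (default 10).
#' @param draw_labels Draw the bait label and set names (default
#'   `TRUE`).
#' @param background Canvas background: an R color name, `"white"` by
#'   default; `"none"` leaves the canvas transparent (SVG only).
#' @param fill_spacers Fill the two spacer sectors white instead of
#'   leaving gaps (default `FALSE`, so diagrams composite cleanly onto
#'   slides).
#' @param arc_opacity Stroke opacity of arcs in `[0, 1]` (default 0.8),
#'   which keeps overdrawn arcs legible.
#' @return A validated list of class `render_options`.
#' @export
render_options <- function(canvas_size = 800, arc_stroke = 1.2,
                           ring_outline = FALSE, label_font_size = 10,
                           draw_labels = TRUE, background = "white",
                           fill_spacers = FALSE, arc_opacity = 0.8) {
  stopifnot(
    is.numeric(canvas_size), length(canvas_size) == 1L, canvas_size > 0,
    is.numeric(arc_stroke), length(arc_stroke) == 1L, arc_stroke > 0,
    is.logical(ring_outline), is.numeric(label_font_size),
    label_font_size > 0, is.logical(draw_labels),
    is.character(background), length(background) == 1L,
    is.logical(fill_spacers),
    is.numeric(arc_opacity), arc_opacity >= 0, arc_opacity <= 1
  )
  structure(
    list(canvas_size = canvas_size, arc_stroke = arc_stroke,
         ring_outline = ring_outline, label_font_size = label_font_size,
         draw_labels = draw_labels, background = background,
         fill_spacers = fill_spacers, arc_opacity = arc_opacity),
    class = "render_options"
  )
}

#' Polar to Cartesian conversion
#'
#' Mathematical convention: angle measured counterclockwise from east,
#' y up, so 90 degrees maps to the top of the circle.
#'
#' @param angle Angle(s) in degrees.
#' @param radius Radius (canvas units); recycled against `angle`.
#' @param center Numeric length-2 center point.
#' @return A list with numeric vectors `x` and `y`.
#' @export
polar_to_cartesian <- function(angle, radius, center = c(0, 0)) {
  list(x = center[1] + radius * cospi(angle / 180),
       y = center[2] + radius * sinpi(angle / 180))
}

# Fixed-width decimal formatting so renders are byte-stable; -0 folded
# into 0 to keep output independent of sign-of-zero quirks.
fmt_num <- function(x) {
  x <- round(x, 4)
  x[x == 0] <- 0
  sprintf("%.4f", x)
}

rgb_css <- function(r, g, b) sprintf("rgb(%d,%d,%d)", r, g, b)

# Screen coordinates: SVG y grows downward; scene coordinates are
# normalized (center 0,0, half-extent 1, y up).
scene_to_screen <- function(x, y, canvas) {
  list(x = canvas / 2 + canvas / 2 * x, y = canvas / 2 - canvas / 2 * y)
}

# SVG path data for an annular sector between two radii, traversed from
# start_angle to end_angle along the layout direction.
sector_path_d <- function(start_angle, end_angle, width_deg, clockwise,
                          r_in, r_out, canvas) {
  sweep <- if (clockwise) 1L else 0L
  large <- if (width_deg > 180) 1L else 0L
  po0 <- scene_to_screen_polar(start_angle, r_out, canvas)
  po1 <- scene_to_screen_polar(end_angle, r_out, canvas)
  pi1 <- scene_to_screen_polar(end_angle, r_in, canvas)
  pi0 <- scene_to_screen_polar(start_angle, r_in, canvas)
  ro <- fmt_num(canvas / 2 * r_out)
  ri <- fmt_num(canvas / 2 * r_in)
  paste0(
    "M", fmt_num(po0$x), " ", fmt_num(po0$y),
    " A", ro, " ", ro, " 0 ", large, " ", sweep, " ",
    fmt_num(po1$x), " ", fmt_num(po1$y),
    " L", fmt_num(pi1$x), " ", fmt_num(pi1$y),
    " A", ri, " ", ri, " 0 ", large, " ", 1L - sweep, " ",
    fmt_num(pi0$x), " ", fmt_num(pi0$y),
    " Z"
  )
}

scene_to_screen_polar <- function(angle, radius, canvas) {
  p <- polar_to_cartesian(angle, radius)
  scene_to_screen(p$x, p$y, canvas)
}

segment_mid_angle <- function(segments, row) {
  dir <- segment_direction(segments)
  normalize_angle(segments$start_angle[row] + dir * segments$width_deg[row] / 2)
}

# Which segments get a filled sector: bait and non-empty sets always,
# spacers only on request.
drawn_segment_rows <- function(diagram, opts) {
  seg <- diagram$segments
  drawn <- (seg$kind != "spacer" | opts$fill_spacers) & seg$width_deg > 0
  which(drawn)
}

#' Render a diagram to SVG
#'
#' Emits one filled annular-sector `<path>` per drawn segment (spacers
#' are gaps unless `fill_spacers`), one stroked quadratic-Bezier
#' `<path>` per arc (`ppi` arcs in their set's color, `ivtk` arcs
#' black, drawn last so they sit on top), and optional labels. Output
#' is byte-identical across repeated renders of the same diagram.
#'
#' @param diagram An `apms_diagram` object.
#' @param path Output file path; when `NULL` the SVG text is returned.
#' @param opts A [render_options()] list.
#' @return The SVG text, invisibly when `path` is given.
#' @export
render_svg <- function(diagram, path = NULL, opts = render_options()) {
  canvas <- opts$canvas_size
  lopt <- diagram$options
  seg <- diagram$segments
  r_out <- lopt$radius
  r_in <- lopt$radius * (1 - lopt$ring_thickness)
  cw <- isTRUE(attr(seg, "clockwise"))

  out <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    sprintf(paste0("<svg xmlns=\"http://www.w3.org/2000/svg\" width=\"%s\" ",
                   "height=\"%s\" viewBox=\"0 0 %s %s\">"),
            fmt_num(canvas), fmt_num(canvas), fmt_num(canvas), fmt_num(canvas))
  )
  if (!identical(opts$background, "none")) {
    bg <- grDevices::col2rgb(opts$background)
    out <- c(out, sprintf(
      "<rect class=\"background\" x=\"0\" y=\"0\" width=\"%s\" height=\"%s\" fill=\"%s\"/>",
      fmt_num(canvas), fmt_num(canvas), rgb_css(bg[1], bg[2], bg[3])))
  }

  stroke_attr <- if (opts$ring_outline) {
    " stroke=\"rgb(80,80,80)\" stroke-width=\"0.5\""
  } else {
    ""
  }
  for (i in drawn_segment_rows(diagram, opts)) {
    d <- sector_path_d(seg$start_angle[i], seg$end_angle[i], seg$width_deg[i],
                       cw, r_in, r_out, canvas)
    out <- c(out, sprintf(
      "<path class=\"segment segment-%s\" d=\"%s\" fill=\"%s\"%s/>",
      seg$kind[i], d, rgb_css(seg$red[i], seg$green[i], seg$blue[i]),
      stroke_attr))
  }

  arcs <- diagram$arcs
  for (i in seq_len(nrow(arcs))) {
    p0 <- scene_to_screen(arcs$x0[i], arcs$y0[i], canvas)
    pc <- scene_to_screen(arcs$cx[i], arcs$cy[i], canvas)
    p1 <- scene_to_screen(arcs$x1[i], arcs$y1[i], canvas)
    out <- c(out, sprintf(
      paste0("<path class=\"arc arc-%s\" d=\"M%s %s Q%s %s %s %s\" ",
             "fill=\"none\" stroke=\"%s\" stroke-width=\"%s\" ",
             "stroke-opacity=\"%s\" stroke-linecap=\"round\"/>"),
      arcs$arc_class[i],
      fmt_num(p0$x), fmt_num(p0$y), fmt_num(pc$x), fmt_num(pc$y),
      fmt_num(p1$x), fmt_num(p1$y),
      rgb_css(arcs$red[i], arcs$green[i], arcs$blue[i]),
      fmt_num(opts$arc_stroke), fmt_num(opts$arc_opacity)))
  }

  if (opts$draw_labels) {
    out <- c(out, svg_labels(diagram, opts, canvas, r_in, r_out))
  }
  out <- c(out, "</svg>")
  txt <- paste0(paste0(out, collapse = "\n"), "\n")
  emit_text(txt, path)
}

xml_escape <- function(s) {
  s <- gsub("&", "&amp;", s, fixed = TRUE)
  s <- gsub("<", "&lt;", s, fixed = TRUE)
  gsub(">", "&gt;", s, fixed = TRUE)
}

svg_labels <- function(diagram, opts, canvas, r_in, r_out) {
  seg <- diagram$segments
  out <- character()
  for (i in seq_len(nrow(seg))) {
    if (seg$kind[i] == "spacer" || seg$width_deg[i] <= 0) next
    mid <- segment_mid_angle(seg, i)
    if (seg$kind[i] == "bait") {
      p <- scene_to_screen_polar(mid, (r_in + r_out) / 2, canvas)
      fill <- "rgb(255,255,255)"
    } else {
      p <- scene_to_screen_polar(mid, r_out + 0.03, canvas)
      fill <- "rgb(0,0,0)"
    }
    rot <- normalize_angle(90 - mid)
    if (rot > 90 && rot < 270) rot <- normalize_angle(rot + 180)
    rot <- round(rot, 4) %% 360
    out <- c(out, sprintf(
      paste0("<text class=\"label label-%s\" x=\"%s\" y=\"%s\" ",
             "font-size=\"%s\" font-family=\"Helvetica\" ",
             "text-anchor=\"middle\" transform=\"rotate(%s %s %s)\" ",
             "fill=\"%s\">%s</text>"),
      seg$kind[i], fmt_num(p$x), fmt_num(p$y), fmt_num(opts$label_font_size),
      fmt_num(rot), fmt_num(p$x), fmt_num(p$y), fill,
      xml_escape(seg$label[i])))
  }
  out
}

#' Render a diagram to a single-page vector PDF
#'
#' Draws the same scene as [render_svg()] through the grid graphics
#' system onto an uncompressed [grDevices::pdf()] device: sectors as
#' densely sampled polygons, arcs as densely sampled Bezier polylines
#' (all vector, nothing rasterized). The PDF creation and modification
#' dates are fixed to an epoch constant so repeated renders are
#' byte-identical.
#'
#' @param diagram An `apms_diagram` object.
#' @param path Output PDF path.
#' @param opts A [render_options()] list.
#' @return `path`, invisibly.
#' @export
render_pdf <- function(diagram, path, opts = render_options()) {
  canvas <- opts$canvas_size
  lopt <- diagram$options
  seg <- diagram$segments
  r_out <- lopt$radius
  r_in <- lopt$radius * (1 - lopt$ring_thickness)

  grDevices::pdf(path, width = canvas / 72, height = canvas / 72,
                 onefile = TRUE, paper = "special", compress = FALSE,
                 useDingbats = FALSE, title = "baitring diagram")
  on.exit(grDevices::dev.off(), add = TRUE)
  grid::grid.newpage()
  vp <- grid::viewport(xscale = c(0, canvas), yscale = c(canvas, 0))
  grid::pushViewport(vp)

  if (!identical(opts$background, "none")) {
    grid::grid.rect(gp = grid::gpar(fill = opts$background, col = NA))
  }
  for (i in drawn_segment_rows(diagram, opts)) {
    dir <- segment_direction(seg)
    a0 <- seg$start_angle[i]
    n_steps <- max(2L, ceiling(seg$width_deg[i] * 2))
    ang <- a0 + dir * seq(0, seg$width_deg[i], length.out = n_steps)
    outer <- scene_to_screen_polar(ang, r_out, canvas)
    inner <- scene_to_screen_polar(rev(ang), r_in, canvas)
    border <- if (opts$ring_outline) "grey30" else NA
    grid::grid.polygon(
      x = c(outer$x, inner$x), y = c(outer$y, inner$y),
      default.units = "native",
      gp = grid::gpar(
        fill = grDevices::rgb(seg$red[i], seg$green[i], seg$blue[i],
                              maxColorValue = 255),
        col = border, lwd = 0.5))
  }

  arcs <- diagram$arcs
  tt <- seq(0, 1, length.out = 65)
  for (i in seq_len(nrow(arcs))) {
    b <- bezier_point(arcs[i, ], tt)
    p <- scene_to_screen(b$x, b$y, canvas)
    grid::grid.lines(
      x = p$x, y = p$y, default.units = "native",
      gp = grid::gpar(
        col = grDevices::rgb(arcs$red[i], arcs$green[i], arcs$blue[i],
                             alpha = round(opts$arc_opacity * 255),
                             maxColorValue = 255),
        lwd = opts$arc_stroke, lineend = "round"))
  }

  if (opts$draw_labels) {
    for (i in seq_len(nrow(seg))) {
      if (seg$kind[i] == "spacer" || seg$width_deg[i] <= 0) next
      mid <- segment_mid_angle(seg, i)
      if (seg$kind[i] == "bait") {
        p <- scene_to_screen_polar(mid, (r_in + r_out) / 2, canvas)
        col <- "white"
      } else {
        p <- scene_to_screen_polar(mid, r_out + 0.03, canvas)
        col <- "black"
      }
      rot <- normalize_angle(90 - mid)
      if (rot > 90 && rot < 270) rot <- normalize_angle(rot + 180)
      grid::grid.text(
        seg$label[i], x = p$x, y = p$y, default.units = "native",
        rot = -rot,
        gp = grid::gpar(fontsize = opts$label_font_size, col = col,
                        fontfamily = "Helvetica"))
    }
  }
  grid::popViewport()
  grDevices::dev.off()
  on.exit()
  normalize_pdf_dates(path)
  invisible(path)
}

# Fix /CreationDate and /ModDate to the epoch so re-renders are
# byte-identical; the replacement has the same length as the original,
# so xref byte offsets stay valid.
normalize_pdf_dates <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  txt <- rawToChar(raw)
  txt <- gsub("D:[0-9]{14}", "D:19700101000000", txt, useBytes = TRUE)
  writeBin(charToRaw(txt), path)
  invisible(path)
}

#' Plot a circular diagram with ggplot2
#'
#' Builds the same scene as the file renderers as a ggplot: sampled
#' annular sectors, sampled Bezier arcs and labels, on a fixed-aspect
#' blank canvas.
#'
#' @param object An `apms_diagram` object.
#' @param draw_labels Draw bait and set labels (default `TRUE`).
#' @param arc_opacity Arc stroke opacity (default 0.8).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot apms_diagram
#' @export
autoplot.apms_diagram <- function(object, draw_labels = TRUE,
                                  arc_opacity = 0.8, ...) {
  lopt <- object$options
  seg <- object$segments
  r_out <- lopt$radius
  r_in <- lopt$radius * (1 - lopt$ring_thickness)
  dir <- segment_direction(seg)

  sector_rows <- which(seg$kind != "spacer" & seg$width_deg > 0)
  sectors <- purrr::map(sector_rows, function(i) {
    ang <- seg$start_angle[i] +
      dir * seq(0, seg$width_deg[i], length.out = max(2L, ceiling(seg$width_deg[i] * 2)))
    po <- polar_to_cartesian(ang, r_out)
    pin <- polar_to_cartesian(rev(ang), r_in)
    tibble(x = c(po$x, pin$x), y = c(po$y, pin$y), id = i,
           fill = grDevices::rgb(seg$red[i], seg$green[i], seg$blue[i],
                                 maxColorValue = 255))
  })
  sectors <- dplyr::bind_rows(sectors)

  tt <- seq(0, 1, length.out = 65)
  arcs <- purrr::map(seq_len(nrow(object$arcs)), function(i) {
    b <- bezier_point(object$arcs[i, ], tt)
    tibble(x = b$x, y = b$y, id = i,
           colour = grDevices::rgb(object$arcs$red[i], object$arcs$green[i],
                                   object$arcs$blue[i], maxColorValue = 255))
  })
  arcs <- dplyr::bind_rows(arcs)

  p <- ggplot2::ggplot() +
    ggplot2::coord_fixed(xlim = c(-1, 1), ylim = c(-1, 1), expand = FALSE) +
    ggplot2::theme_void()
  if (nrow(sectors) > 0) {
    p <- p + ggplot2::geom_polygon(
      data = sectors,
      ggplot2::aes(x = .data$x, y = .data$y, group = .data$id,
                   fill = I(.data$fill)))
  }
  if (nrow(arcs) > 0) {
    p <- p + ggplot2::geom_path(
      data = arcs,
      ggplot2::aes(x = .data$x, y = .data$y, group = .data$id,
                   colour = I(.data$colour)),
      linewidth = 0.4, alpha = arc_opacity, lineend = "round")
  }
  if (draw_labels) {
    lab_rows <- which(seg$kind != "spacer" & seg$width_deg > 0)
    labs <- purrr::map(lab_rows, function(i) {
      mid <- segment_mid_angle(seg, i)
      r <- if (seg$kind[i] == "bait") (r_in + r_out) / 2 else r_out + 0.06
      pt <- polar_to_cartesian(mid, r)
      tibble(x = pt$x, y = pt$y, label = seg$label[i],
             colour = if (seg$kind[i] == "bait") "white" else "black")
    })
    labs <- dplyr::bind_rows(labs)
    p <- p + ggplot2::geom_text(
      data = labs,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$label,
                   colour = I(.data$colour)),
      size = 3)
  }
  p
}

#' @export
plot.apms_diagram <- function(x, ...) print(autoplot.apms_diagram(x, ...))

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
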