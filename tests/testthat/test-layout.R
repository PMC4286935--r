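ref_of_sizes <- function(sizes) {
  ids <- split(sprintf("Q%04d", seq_len(sum(sizes))),
               rep(seq_along(sizes), times = sizes))
  names(ids) <- sprintf("S%d", seq_along(sizes))
  parse_reference(ref_text(ids))
}

colors_for <- function(reference) {
  assign_set_colors(reference, parse_color_scheme("200,10,10\n10,10,200\n60,160,60\n"))
}

test_that("unit angle divides the circle by total protein units", {
  expect_equal(unit_angle(ref_of_sizes(c(6, 3))), 20)
  expect_equal(unit_angle(ref_of_sizes(351)), 1)
  expect_equal(unit_angle(ref_of_sizes(c(10, 5, 5))), 360 / 29)
  expect_error(unit_angle(ref_of_sizes(c(6, 3))[0, ]), class = "baitring_error")
})

test_that("the {6,3} worked example lays out exactly", {
  r <- ref_of_sizes(c(6, 3))
  seg <- compute_segments(r, "K", colors_for(r))
  expect_equal(seg$kind, c("bait", "spacer", "set", "set", "spacer"))
  expect_equal(seg$width_deg, c(60, 60, 120, 60, 60))
  expect_equal(sum(seg$width_deg), 360)
  # bait centered at 90, clockwise: bait spans [120 -> 60]
  expect_equal(seg$start_angle[1], 120)
  expect_equal(seg$end_angle[1], 60)
  expect_equal(bait_anchor(seg), 90)
  # colors: bait black, spacers white, sets from the cycled scheme
  expect_equal(seg$red, c(0L, 255L, 200L, 10L, 255L))
})

test_that("segments tile the circle without overlap for random size vectors", {
  set.seed(5)
  for (i in 1:7) {
    sizes <- sample(1:30, sample(2:6, 1))
    r <- ref_of_sizes(sizes)
    seg <- compute_segments(r, "K", colors_for(r))
    expect_equal(sum(seg$width_deg), 360, tolerance = 1e-9)
    # consecutive offsets abut exactly: no gaps, no overlaps
    expect_equal(seg$start_offset,
                 cumsum(c(0, seg$width_deg))[seq_len(nrow(seg))],
                 tolerance = 1e-12)
    # widths proportional to set sizes
    widths <- seg$width_deg[seg$kind == "set"]
    expect_equal(widths / sum(widths), sizes / sum(sizes), tolerance = 1e-9)
    # angular width matches n_units * unit within 1e-9 degrees
    expect_equal(seg$width_deg, seg$n_units * attr(seg, "unit_angle"),
                 tolerance = 1e-12)
    # spacer is exactly spacer_units protein widths
    expect_equal(seg$width_deg[seg$kind == "spacer"][1] / attr(seg, "unit_angle"), 3)
  }
})

test_that("anchors sit at slot midpoints, strictly inside their segment", {
  r <- ref_of_sizes(c(6, 3))
  seg <- compute_segments(r, "K", colors_for(r))
  unit <- attr(seg, "unit_angle")
  # set 1 starts at 0 degrees (after bait [120->60] and spacer [60->0]);
  # first slot midpoint is half a unit into the segment, clockwise
  row1 <- which(seg$kind == "set" & seg$set_index == 1)
  expect_equal(anchor_angle(seg, 1, 1),
               (seg$start_angle[row1] - unit / 2) %% 360)
  # anchors advance strictly along the layout direction within each set
  for (s in 1:2) {
    n <- reference_sets(r)$n_entries[s]
    anchors <- vapply(seq_len(n), function(j) anchor_angle(seg, s, j), numeric(1))
    # clockwise layout: strictly decreasing (no wrap inside these sets)
    expect_true(all(diff(anchors) < 0))
    row <- which(seg$kind == "set" & seg$set_index == s)
    width <- seg$width_deg[row]
    start <- seg$start_angle[row]
    offs <- (start - anchors) %% 360  # degrees traversed clockwise from start
    expect_true(all(offs > 0 & offs < width))
  }
  expect_error(anchor_angle(seg, 1, 7), class = "baitring_error")
  expect_error(anchor_angle(seg, 3, 1), class = "baitring_error")
})

test_that("bait anchor follows bait_center_angle and stays inside the bait segment", {
  r <- ref_of_sizes(c(6, 3))
  seg0 <- compute_segments(r, "K", colors_for(r),
                           layout_options(bait_center_angle = 0))
  expect_equal(bait_anchor(seg0), 0)
  seg <- compute_segments(r, "K", colors_for(r))
  off <- (seg$start_angle[1] - bait_anchor(seg)) %% 360
  expect_true(off > 0 && off < seg$width_deg[1])
})

test_that("counterclockwise layout mirrors the clockwise one", {
  r <- ref_of_sizes(c(6, 3))
  seg <- compute_segments(r, "K", colors_for(r),
                          layout_options(clockwise = FALSE))
  expect_equal(seg$start_angle[1], 60)
  expect_equal(seg$end_angle[1], 120)
  expect_equal(sum(seg$width_deg), 360)
})

test_that("arc paths are quadratic Beziers controlled by tension", {
  # tension 0, diametrically opposite endpoints: curve midpoint at center
  p <- arc_path(90, 270, layout_options(), radius = 1)
  mid <- bezier_point(p, 0.5)
  expect_equal(mid$x, 0, tolerance = 1e-12)
  expect_equal(mid$y, 0, tolerance = 1e-12)

  # near-coincident endpoints degenerate to a stub, with a warning
  expect_warning(pd <- arc_path(90, 90.0001), class = "baitring_warn_degenerate_arc")
  expect_true(pd$degenerate)

  # tension 1 pulls the curve midpoint strictly closer to the chord
  p0 <- arc_path(90, 200, layout_options(arc_tension = 0))
  p1 <- arc_path(90, 200, layout_options(arc_tension = 1))
  chord_mid <- c((p0$x0 + p0$x1) / 2, (p0$y0 + p0$y1) / 2)
  d0 <- bezier_point(p0, 0.5); d1 <- bezier_point(p1, 0.5)
  dist0 <- sqrt((d0$x - chord_mid[1])^2 + (d0$y - chord_mid[2])^2)
  dist1 <- sqrt((d1$x - chord_mid[1])^2 + (d1$y - chord_mid[2])^2)
  expect_lt(dist1, dist0)
  expect_equal(dist1, 0, tolerance = 1e-12)
})

test_that("build_diagram composes mapping, colors and geometry", {
  e <- parse_experiment("K,ppi,P1\n")
  r <- parse_reference(ref_text(list(A = "P1")))
  s <- parse_color_scheme("255,0,0\n")
  d <- build_diagram(e, r, s)
  expect_equal(nrow(d$arcs), 1L)
  expect_equal(c(d$arcs$red, d$arcs$green, d$arcs$blue), c(255L, 0L, 0L))
  expect_equal(d$arcs$from_angle, 90)

  # same interaction classed ivtk: black arc
  e2 <- parse_experiment("K,ivtk,P1\n")
  d2 <- build_diagram(e2, r, s)
  expect_equal(c(d2$arcs$red, d2$arcs$green, d2$arcs$blue), c(0L, 0L, 0L))

  # ivtk arcs are ordered after ppi arcs so they draw on top
  e3 <- parse_experiment("K,ivtk,P1\nK,ppi,P2\n")
  r3 <- parse_reference(ref_text(list(A = c("P1", "P2"))))
  d3 <- build_diagram(e3, r3, s)
  expect_equal(d3$arcs$arc_class, c("ppi", "ivtk"))
})

test_that("diagram arc counts equal mapping arc counts for ON and OFF", {
  fx <- generate_fixture(fixture_spec(seed = 17, cross_set_duplication = 0.3))
  e <- parse_experiment(fx$experiment_text)
  r <- parse_reference(fx$reference_text)
  s <- parse_color_scheme(fx$colors_text)
  for (reapp in c(TRUE, FALSE)) {
    d <- quiet_diagram(e, r, s, reappearance = reapp)
    m <- quiet_map(e, r, reappearance = reapp)
    expect_equal(nrow(d$arcs), nrow(m$arcs))
    # every prey anchor lies strictly inside its set segment
    for (i in seq_len(nrow(d$arcs))) {
      row <- which(d$segments$kind == "set" &
                     d$segments$set_index == d$arcs$set_index[i])
      off <- (d$segments$start_angle[row] - d$arcs$to_angle[i]) %% 360
      expect_true(off > 0 && off < d$segments$width_deg[row])
    }
  }
})

test_that("identical inputs and options give identical geometry", {
  fx <- generate_fixture(fixture_spec(seed = 19))
  e <- parse_experiment(fx$experiment_text)
  r <- parse_reference(fx$reference_text)
  s <- parse_color_scheme(fx$colors_text)
  d1 <- quiet_diagram(e, r, s)
  d2 <- quiet_diagram(e, r, s)
  expect_identical(d1$segments, d2$segments)
  expect_identical(d1$arcs, d2$arcs)
})

test_that("empty sets occupy zero width but keep set indices aligned", {
  r <- suppressWarnings(parse_reference(">A\nl,P1,r\n>EMPTY\n>C\nl,P2,r\n"))
  expect_warning(seg <- compute_segments(r, "K", colors_for(r)),
                 class = "baitring_warn_empty_set")
  unit <- 360 / 11  # 1 + 0 + 1 entries + 3 bait + 6 spacer units
  expect_equal(seg$width_deg[seg$kind == "set"], c(unit, 0, unit))
  expect_equal(seg$set_index[seg$kind == "set"], 1:3)
  expect_equal(sum(seg$width_deg), 360)
})

test_that("scene JSON round-trips to an identical rendering", {
  fx <- generate_fixture(fixture_spec(seed = 23))
  e <- parse_experiment(fx$experiment_text)
  r <- parse_reference(fx$reference_text)
  s <- parse_color_scheme(fx$colors_text)
  d <- quiet_diagram(e, r, s)
  json <- diagram_to_json(d)
  d2 <- diagram_from_json(json)
  expect_identical(render_svg(d2), render_svg(d))
  expect_equal(nrow(d2$arcs), nrow(d$arcs))
  expect_equal(d2$segments$width_deg, d$segments$width_deg)
})
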