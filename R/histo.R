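# Histology quantification -----------------------------------------------------

#' Barrel wall/hollow geometry
#'
#' The hollow is the closed disc of radius `r_hollow` about `center_xy`; the
#' wall is the half-open annulus `(r_hollow, r_wall]`.
#'
#' @param center_xy Barrel centre (um), length-2 numeric.
#' @param r_hollow,r_wall Hollow radius and wall outer radius (um).
#' @return A `barrel_annulus` object.
#' @export
barrel_annulus <- function(center_xy = c(0, 0), r_hollow = 100, r_wall = 150) {
  if (!is.numeric(center_xy) || length(center_xy) != 2L || anyNA(center_xy))
    abort_config("center_xy", "must be a length-2 numeric")
  check_pos(r_hollow, "r_hollow")
  if (!is.numeric(r_wall) || length(r_wall) != 1L || r_wall <= r_hollow)
    abort_config("r_wall", "must exceed r_hollow")
  structure(list(center_xy = center_xy, r_hollow = r_hollow, r_wall = r_wall),
            class = "barrel_annulus")
}

#' Barrel segregation score from a nuclei point field
#'
#' Per optical section, the cell density (points per um^2) of the wall
#' annulus and of the hollow disc are computed from the point counts and the
#' analytic region areas; the section score is the wall/hollow density ratio.
#' Sections with an empty hollow are undefined and skipped. The stack score
#' is the maximum per-section ratio, matching the convention of scoring each
#' animal by its best optical section.
#'
#' @param field A [point_field()].
#' @param geom A [barrel_annulus()].
#' @return A `segregation_score`: list with `per_section` (data frame:
#'   section, n_wall, n_hollow, density_wall, density_hollow, ratio),
#'   `best_ratio`, `best_section_index`.
#' @export
segregation_ratio <- function(field, geom) {
  stopifnot(inherits(field, "point_field"), inherits(geom, "barrel_annulus"))
  pts <- field$points
  if (nrow(pts) == 0L)
    abort_insufficient("point field is empty: cannot score segregation")
  area_hollow <- pi * geom$r_hollow^2
  area_wall <- pi * (geom$r_wall^2 - geom$r_hollow^2)
  d2 <- (pts$x_um - geom$center_xy[1])^2 + (pts$y_um - geom$center_xy[2])^2
  in_hollow <- d2 <= geom$r_hollow^2
  in_wall <- d2 > geom$r_hollow^2 & d2 <= geom$r_wall^2
  secs <- sort(unique(pts$section))
  per <- do.call(rbind, lapply(secs, function(s) {
    sel <- pts$section == s
    nh <- sum(in_hollow & sel); nw <- sum(in_wall & sel)
    data.frame(section = s, n_wall = nw, n_hollow = nh,
               density_wall = nw / area_wall,
               density_hollow = nh / area_hollow,
               ratio = if (nh > 0) (nw / area_wall) / (nh / area_hollow)
                       else NA_real_)
  }))
  if (all(is.na(per$ratio)))
    abort_insufficient("no section has points in the barrel hollow: segregation undefined")
  i_best <- which.max(per$ratio)
  structure(list(per_section = per,
                 best_ratio = per$ratio[i_best],
                 best_section_index = per$section[i_best]),
            class = "segregation_score")
}

#' Rectangular region of interest
#'
#' @param center_xy ROI centre (um).
#' @param length_um,width_um Long and short dimensions (um); defaults 100 x 30.
#' @param angle_deg Orientation of the long axis, degrees counter-clockwise
#'   from the x axis.
#' @return An `roi_rect` object.
#' @export
roi_rect <- function(center_xy = c(0, 0), length_um = 100, width_um = 30,
                     angle_deg = 0) {
  if (!is.numeric(center_xy) || length(center_xy) != 2L || anyNA(center_xy))
    abort_config("center_xy", "must be a length-2 numeric")
  check_pos(length_um, "length_um")
  check_pos(width_um, "width_um")
  if (!is.numeric(angle_deg) || length(angle_deg) != 1L || is.na(angle_deg))
    abort_config("angle_deg", "must be a single number")
  structure(list(center_xy = center_xy, length_um = length_um,
                 width_um = width_um, angle_deg = angle_deg),
            class = "roi_rect")
}

# Does segment p1-p2 intersect segment q1-q2 (inclusive of endpoints)?
# Standard orientation/straddle test, robust to collinear overlap.
segs_intersect <- function(p1x, p1y, p2x, p2y, q1x, q1y, q2x, q2y) {
  orient <- function(ax, ay, bx, by, cx, cy)
    sign((bx - ax) * (cy - ay) - (by - ay) * (cx - ax))
  d1 <- orient(q1x, q1y, q2x, q2y, p1x, p1y)
  d2 <- orient(q1x, q1y, q2x, q2y, p2x, p2y)
  d3 <- orient(p1x, p1y, p2x, p2y, q1x, q1y)
  d4 <- orient(p1x, p1y, p2x, p2y, q2x, q2y)
  gen <- (d1 * d2 < 0) & (d3 * d4 < 0)
  on_seg <- function(ax, ay, bx, by, cx, cy)
    pmin(ax, bx) - 1e-12 <= cx & cx <= pmax(ax, bx) + 1e-12 &
    pmin(ay, by) - 1e-12 <= cy & cy <= pmax(ay, by) + 1e-12
  col <- (d1 == 0 & on_seg(q1x, q1y, q2x, q2y, p1x, p1y)) |
         (d2 == 0 & on_seg(q1x, q1y, q2x, q2y, p2x, p2y)) |
         (d3 == 0 & on_seg(p1x, p1y, p2x, p2y, q1x, q1y)) |
         (d4 == 0 & on_seg(p1x, p1y, p2x, p2y, q2x, q2y))
  gen | col
}

#' Count axon segments crossing a region of interest
#'
#' Under the default `"traverse"` rule a segment is counted iff it intersects
#' both long edges of the rectangle, i.e. it runs all the way across the
#' short (30 um) dimension; fragments that merely enter or lie inside the ROI
#' are not counted. The `"any"` rule counts every segment that touches the
#' rectangle at all. Each segment is counted at most once.
#'
#' @param segments Data frame with columns `x1_um`, `y1_um`, `x2_um`, `y2_um`.
#' @param roi An [roi_rect()].
#' @param rule `"traverse"` (default) or `"any"`.
#' @return Integer crossing count.
#' @export
count_crossings <- function(segments, roi, rule = c("traverse", "any")) {
  rule <- match.arg(rule)
  stopifnot(inherits(roi, "roi_rect"))
  need <- c("x1_um", "y1_um", "x2_um", "y2_um")
  if (!all(need %in% names(segments)))
    abort_schema("segment table must have columns x1_um, y1_um, x2_um, y2_um")
  if (nrow(segments) == 0L) return(0L)
  # transform segment endpoints into the ROI frame (long axis = x)
  a <- -roi$angle_deg * pi / 180
  rot <- function(x, y) list(x = cos(a) * x - sin(a) * y,
                             y = sin(a) * x + cos(a) * y)
  e1 <- rot(segments$x1_um - roi$center_xy[1], segments$y1_um - roi$center_xy[2])
  e2 <- rot(segments$x2_um - roi$center_xy[1], segments$y2_um - roi$center_xy[2])
  l2 <- roi$length_um / 2; w2 <- roi$width_um / 2
  top <- segs_intersect(e1$x, e1$y, e2$x, e2$y, -l2, w2, l2, w2)
  bot <- segs_intersect(e1$x, e1$y, e2$x, e2$y, -l2, -w2, l2, -w2)
  if (rule == "traverse") return(sum(top & bot))
  lef <- segs_intersect(e1$x, e1$y, e2$x, e2$y, -l2, -w2, -l2, w2)
  rig <- segs_intersect(e1$x, e1$y, e2$x, e2$y, l2, -w2, l2, w2)
  inside <- abs(e1$x) <= l2 & abs(e1$y) <= w2
  sum(top | bot | lef | rig | inside)
}

#' Crossing counts per compartment
#'
#' @param centre_rois,septa_rois Lists of [roi_rect()]s placed in barrel
#'   centres and septal regions.
#' @param segments Segment table (see [count_crossings()]); if it has a
#'   `compartment` column, centre ROIs only see `"centre"` segments and
#'   septal ROIs only `"septa"` segments.
#' @param rule Counting rule, see [count_crossings()].
#' @return A `crossing_counts` list: `centre`, `septa`, `total`
#'   (= centre + septa) summed over ROIs.
#' @export
crossing_report <- function(centre_rois, septa_rois, segments,
                            rule = "traverse") {
  if (length(centre_rois) < 1L || length(septa_rois) < 1L)
    abort_insufficient("need at least one ROI per compartment")
  pick <- function(comp) {
    if ("compartment" %in% names(segments))
      segments[segments$compartment == comp, , drop = FALSE]
    else segments
  }
  centre <- sum(vapply(centre_rois, function(r)
    count_crossings(pick("centre"), r, rule), integer(1)))
  septa <- sum(vapply(septa_rois, function(r)
    count_crossings(pick("septa"), r, rule), integer(1)))
  structure(list(centre = as.integer(centre), septa = as.integer(septa),
                 total = as.integer(centre + septa)),
            class = "crossing_counts")
}

#' Area of a traced region
#'
#' Shoelace area of a simple polygon with vertices in um, reported in mm^2.
#'
#' @param vertices Two-column matrix or data frame of (x_um, y_um) vertices
#'   in order (open or closed ring).
#' @return An `area_measure`: list with `vertices`, `area_um2`, `area_mm2`.
#' @export
polygon_area <- function(vertices) {
  v <- as.matrix(vertices)
  if (ncol(v) != 2L) abort_geometry("vertices must be a two-column table")
  # drop an explicitly repeated closing vertex
  if (nrow(v) > 1L && all(v[1, ] == v[nrow(v), ])) v <- v[-nrow(v), , drop = FALSE]
  n <- nrow(v)
  if (n < 3L) abort_geometry("a polygon needs at least 3 distinct vertices")
  if (any(!is.finite(v))) abort_geometry("vertex coordinates must be finite")
  # simplicity check: no two non-adjacent edges may intersect
  nxt <- c(2:n, 1L)
  for (i in seq_len(n - 2L)) {
    js <- (i + 2L):n
    js <- js[!(i == 1L & js == n)]  # edges sharing the wrap-around vertex
    if (length(js) == 0L) next
    hit <- segs_intersect(v[i, 1], v[i, 2], v[nxt[i], 1], v[nxt[i], 2],
                          v[js, 1], v[js, 2], v[nxt[js], 1], v[nxt[js], 2])
    if (any(hit)) abort_geometry("polygon is self-intersecting")
  }
  area_um2 <- abs(sum(v[, 1] * v[nxt, 2] - v[nxt, 1] * v[, 2])) / 2
  structure(list(vertices = v, area_um2 = area_um2,
                 area_mm2 = area_um2 * 1e-6),
            class = "area_measure")
}

#' Proportion of a barrel field covered by axon patches
#'
#' @param patch_areas List of `area_measure` objects (or numeric mm^2 values)
#'   for individual axon patches.
#' @param pmbsf An `area_measure` (or numeric mm^2) for the whole barrel
#'   subfield.
#' @return `sum(patch areas) / pmbsf area` (dimensionless).
#' @export
patch_proportion <- function(patch_areas, pmbsf) {
  as_mm2 <- function(x) if (inherits(x, "area_measure")) x$area_mm2 else as.numeric(x)
  total <- sum(vapply(patch_areas, as_mm2, numeric(1)))
  denom <- as_mm2(pmbsf)
  if (!is.finite(denom) || denom <= 0)
    abort_data("reference (PMBSF) area must be positive")
  total / denom
}
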