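# Segregation scoring, crossing counts and area measures.

test_that("segregation_ratio estimates the density ratio and skips empty sections", {
  geom <- barrel_annulus(r_hollow = 80, r_wall = 140)
  # hand-built field: section 0 has hollow and wall points, section 1 only wall
  hollow_pts <- data.frame(section = 0L, x_um = c(0, 10, -20), y_um = c(0, 5, 3))
  wall_pts <- data.frame(section = 0L, x_um = c(100, -110, 0, 0),
                         y_um = c(0, 0, 120, -100))
  only_wall <- data.frame(section = 1L, x_um = 100, y_um = 20)
  f <- point_field(rbind(hollow_pts, wall_pts, only_wall))
  sc <- segregation_ratio(f, geom)
  expect_identical(nrow(sc$per_section), 2L)
  expect_true(is.na(sc$per_section$ratio[sc$per_section$section == 1]))
  area_h <- pi * 80^2; area_w <- pi * (140^2 - 80^2)
  expect_equal(sc$best_ratio, (4 / area_w) / (3 / area_h), tolerance = 1e-12)
  expect_identical(sc$best_section_index, 0L)

  # no hollow points anywhere -> insufficient data
  expect_error(segregation_ratio(point_field(only_wall), geom),
               class = "barreldev_insufficient_data_error")
})

test_that("best-of-stack maximum bias is small at high point counts", {
  # per-section ratio is consistent; max over 5 sections biases high by <10%
  cfg <- barrel_gen_config(r_hollow = 100, r_wall = 150, rho_hollow = 0.25,
                           rho_wall = 0.4, rho_outside = 0.05,
                           n_sections = 5, seed = 41)
  f <- gen_barrel_points(cfg)
  expect_gt(min(table(f$points$section)), 1e4)
  sc <- segregation_ratio(f, barrel_annulus(r_hollow = 100, r_wall = 150))
  expect_lt(abs(sc$best_ratio - 1.6) / 1.6, 0.10)
  expect_gte(sc$best_ratio, min(sc$per_section$ratio))
})

test_that("count_crossings applies the traversal rule", {
  roi <- roi_rect(center_xy = c(0, 0), length_um = 100, width_um = 30)
  expect_identical(count_crossings(data.frame(x1_um = numeric(0),
                                              y1_um = numeric(0),
                                              x2_um = numeric(0),
                                              y2_um = numeric(0)), roi), 0L)
  # one perpendicular segment spanning the short dimension
  one <- data.frame(x1_um = 0, y1_um = -40, x2_um = 0, y2_um = 40)
  expect_identical(count_crossings(one, roi), 1L)

  # 12 parallel traversing segments + 5 interior fragments -> 12
  trav <- data.frame(x1_um = seq(-44, 44, length.out = 12), y1_um = -20,
                     x2_um = seq(-44, 44, length.out = 12), y2_um = 20)
  frag <- data.frame(x1_um = seq(-30, 30, length.out = 5), y1_um = -5,
                     x2_um = seq(-30, 30, length.out = 5) + 4, y2_um = 5)
  expect_identical(count_crossings(rbind(trav, frag), roi), 12L)
  # the permissive rule counts the fragments too
  expect_identical(count_crossings(rbind(trav, frag), roi, rule = "any"), 17L)
})

test_that("crossing counts are invariant under joint rigid motion", {
  roi <- roi_rect(center_xy = c(0, 0))
  set.seed(42)
  segs <- gen_axon_segments(axon_field_config(lambda_centre = 14,
                                              n_distractors = 4, seed = 43),
                            roi, "centre")
  n0 <- count_crossings(segs, roi)
  th <- 37 * pi / 180; shift <- c(123, -77)
  rot <- function(x, y) list(x = cos(th) * x - sin(th) * y + shift[1],
                             y = sin(th) * x + cos(th) * y + shift[2])
  a <- rot(segs$x1_um, segs$y1_um); b <- rot(segs$x2_um, segs$y2_um)
  segs2 <- data.frame(x1_um = a$x, y1_um = a$y, x2_um = b$x, y2_um = b$y)
  roi2 <- roi_rect(center_xy = shift, angle_deg = 37)
  expect_identical(count_crossings(segs2, roi2), n0)
})

test_that("crossing_report sums compartments additively", {
  roi_c <- roi_rect(center_xy = c(0, 0))
  roi_s <- roi_rect(center_xy = c(500, 0))
  mk <- function(n, cx) data.frame(
    x1_um = cx + seq(-40, 40, length.out = n), y1_um = rep(-20, n),
    x2_um = cx + seq(-40, 40, length.out = n), y2_um = rep(20, n),
    compartment = rep(NA_character_, n))
  segs <- rbind(transform(mk(12, 0), compartment = "centre"),
                transform(mk(10, 500), compartment = "septa"))
  rep_ <- crossing_report(list(roi_c), list(roi_s), segs)
  expect_identical(rep_$centre, 12L)
  expect_identical(rep_$septa, 10L)
  expect_identical(rep_$total, 22L)

  empty <- mk(0, 0)
  rep0 <- crossing_report(list(roi_c), list(roi_s), empty)
  expect_identical(c(rep0$centre, rep0$septa, rep0$total), c(0L, 0L, 0L))
  expect_error(crossing_report(list(), list(roi_s), segs),
               class = "barreldev_insufficient_data_error")
})

test_that("Poisson crossing totals converge to the sum of intensities", {
  roi_c <- roi_rect(center_xy = c(0, 0))
  roi_s <- roi_rect(center_xy = c(500, 0))
  totals <- vapply(1:300, function(i) {
    cfg <- axon_field_config(lambda_centre = 12, lambda_septa = 10,
                             seed = 7000 + i)
    segs <- rbind(gen_axon_segments(cfg, roi_c, "centre"),
                  gen_axon_segments(axon_field_config(
                    lambda_centre = 12, lambda_septa = 10,
                    seed = 17000 + i), roi_s, "septa"))
    crossing_report(list(roi_c), list(roi_s), segs)$total
  }, integer(1))
  expect_lt(abs(mean(totals) - 22), 4 * sqrt(22 / 300))
})

test_that("polygon_area matches closed forms, symmetries and a Monte-Carlo oracle", {
  sq <- rbind(c(0, 0), c(1000, 0), c(1000, 1000), c(0, 1000))
  expect_equal(polygon_area(sq)$area_mm2, 1.0, tolerance = 1e-12)
  tri <- rbind(c(0, 0), c(1000, 0), c(0, 2000))
  expect_equal(polygon_area(tri)$area_mm2, 1.0, tolerance = 1e-12)

  # invariance under vertex reversal and cyclic shift
  poly <- rbind(c(0, 0), c(800, 100), c(900, 700), c(400, 900), c(-100, 500))
  a0 <- polygon_area(poly)$area_um2
  expect_equal(polygon_area(poly[nrow(poly):1, ])$area_um2, a0)
  expect_equal(polygon_area(poly[c(3:5, 1:2), ])$area_um2, a0)

  # rejection-sampling oracle on a random simple (star-shaped) polygon
  set.seed(44)
  ang <- sort(runif(9, 0, 2 * pi))
  rad <- runif(9, 200, 600)
  star <- cbind(rad * cos(ang), rad * sin(ang))
  a_star <- polygon_area(star)$area_um2
  n_mc <- 2e5
  px <- runif(n_mc, -600, 600); py <- runif(n_mc, -600, 600)
  # point-in-polygon by ray casting
  inside <- rep(FALSE, n_mc)
  j <- nrow(star)
  for (i in seq_len(nrow(star))) {
    xi <- star[i, 1]; yi <- star[i, 2]; xj <- star[j, 1]; yj <- star[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  a_mc <- mean(inside) * 1200^2
  se <- sqrt(mean(inside) * (1 - mean(inside)) / n_mc) * 1200^2
  expect_lt(abs(a_star - a_mc), 4 * se)

  # self-intersecting bow-tie is rejected
  bow <- rbind(c(0, 0), c(10, 10), c(10, 0), c(0, 10))
  expect_error(polygon_area(bow), class = "barreldev_geometry_error")
  expect_error(polygon_area(rbind(c(0, 0), c(1, 1))),
               class = "barreldev_geometry_error")
})

test_that("patch_proportion follows its arithmetic definition", {
  expect_equal(patch_proportion(list(0.165), 1.21), 0.165 / 1.21,
               tolerance = 1e-12)
  expect_equal(round(patch_proportion(list(0.165), 1.21), 4), 0.1364)
  expect_identical(patch_proportion(list(), 1.21), 0)
  # patches tiling the field exactly
  sq <- polygon_area(rbind(c(0, 0), c(1000, 0), c(1000, 1000), c(0, 1000)))
  halves <- list(
    polygon_area(rbind(c(0, 0), c(1000, 0), c(1000, 500), c(0, 500))),
    polygon_area(rbind(c(0, 500), c(1000, 500), c(1000, 1000), c(0, 1000))))
  expect_equal(patch_proportion(halves, sq), 1, tolerance = 1e-12)
  expect_error(patch_proportion(list(0.1), 0), class = "barreldev_data_error")
})
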