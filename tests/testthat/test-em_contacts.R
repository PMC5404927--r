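test_that("perimeter sums polyline edges, closing only closed contours", {
  square <- tibble::tibble(contour_id = "sq", organelle = "mito",
                           er_class = NA, closed = TRUE, point_index = 1:4,
                           x_nm = c(0, 100, 100, 0), y_nm = c(0, 0, 100, 100),
                           condition_label = "t")
  expect_equal(perimeter(square), 400)
  seg <- line_contour("l", 0, 0, 0, 300)
  expect_equal(perimeter(seg), 300)
  circ <- circle_contour("c", 500, n = 360)
  expect_equal(perimeter(circ), 2 * pi * 500, tolerance = 1e-3)
  expect_error(perimeter(seg[1, ]), "2 points")
})

test_that("a parallel ER line yields one segment with the membrane gap as mean distance", {
  mito <- line_contour("m", 0, 0, 2000, 0, n = 3, organelle = "mito",
                       er_class = NA)
  er <- line_contour("e", 750, 45, 1250, 45)
  segs <- contact_segments(mito, er, threshold = 80, spacing = 15)
  expect_equal(nrow(segs), 1)
  # contact covers the 500 nm overlap plus the stretch still within 80 nm of
  # each ER terminus: sqrt(80^2 - 45^2) per side
  spill <- sqrt(80^2 - 45^2)
  expect_lt(abs(segs$length - (500 + 2 * spill)), 2 * 15)
  # oracle mean distance: 45 over the overlap, sqrt(45^2 + x^2) over the spill
  mean_exp <- (500 * 45 + 2 * integrate(function(x) sqrt(45^2 + x^2),
                                        0, spill)$value) / (500 + 2 * spill)
  expect_lt(abs(segs$mean_distance - mean_exp), 1)
  prof <- distance_profile(segs, 1)
  expect_equal(mean(prof), segs$mean_distance)
  expect_true(all(prof >= 44.9 & prof < 80))
  expect_lt(abs(median(prof) - 45), 0.5)  # the bulk of the run sits at the gap

  # ER beyond the threshold produces nothing
  far <- line_contour("f", 0, 100, 2000, 100)
  expect_equal(nrow(contact_segments(mito, far)), 0)
  expect_error(contact_segments(mito, er, spacing = 0), "positive")
})

test_that("a tilted ER line gives a monotone distance profile", {
  mito <- line_contour("m", 0, 0, 1000, 0, n = 3, organelle = "mito",
                       er_class = NA)
  wedge <- line_contour("w", 0, 20, 1000, 75)
  segs <- contact_segments(mito, wedge)
  prof <- distance_profile(segs, 1)
  expect_true(all(diff(prof) > 0))
})

test_that("a mitochondrion enclosed by ER at sub-threshold gap is fully in contact", {
  mito <- circle_contour("m", 500, n = 360)
  er <- circle_contour("e", 560, n = 360, organelle = "er", er_class = "smooth")
  segs <- contact_segments(mito, er, threshold = 80)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$length, perimeter(mito))
  expect_equal(segs$mean_distance, 60, tolerance = 0.1)
  rep <- contact_report(dplyr::bind_rows(mito, er))
  expect_equal(rep$per_mito$fraction_total, 1)
  expect_equal(rep$aggregate$fraction_smooth, 1)
})

test_that("contact runs crossing the trace start point merge into one wrapped segment", {
  mito <- circle_contour("m", 500, n = 360)  # starts at angle 0
  # ER arc spanning -40 to +40 degrees, crossing the start point
  theta <- seq(-40, 40, by = 2) * pi / 180
  er <- tibble::tibble(contour_id = "e", organelle = "er", er_class = "rough",
                       closed = FALSE, point_index = seq_along(theta),
                       x_nm = 545 * cos(theta), y_nm = 545 * sin(theta),
                       condition_label = "t")
  segs <- contact_segments(mito, er)
  expect_equal(nrow(segs), 1)
  expected <- 2 * (40 * pi / 180 + acos((500^2 + 545^2 - 80^2) /
                                          (2 * 500 * 545))) * 500
  expect_equal(segs$length, expected, tolerance = 15)
})

test_that("report fractions follow the summed-length arithmetic", {
  # mito A: open trace 1000 nm with a 100 nm contact; mito B: 3000 nm, none
  mA <- line_contour("mA", 0, 0, 1000, 0, n = 3, organelle = "mito", er_class = NA)
  mB <- line_contour("mB", 0, 5000, 3000, 5000, n = 3, organelle = "mito",
                     er_class = NA)
  er <- line_contour("e", 450, 40, 550, 40)
  rep <- contact_report(dplyr::bind_rows(mA, mB, er))
  pm <- rep$per_mito[order(rep$per_mito$mito_id), ]
  expect_equal(pm$perimeter, c(1000, 3000))
  contact_exp <- 100 + 2 * sqrt(80^2 - 40^2)  # overlap + terminus spill-over
  expect_lt(abs(pm$fraction_total[1] - contact_exp / 1000), 2 * 15 / 1000)
  expect_equal(pm$fraction_total[2], 0)
  agg <- rep$aggregate
  expect_equal(agg$fraction_total, sum(pm$contact_total) / sum(pm$perimeter))
  # consistency identity: aggregate = perimeter-weighted mean of fractions
  expect_equal(agg$fraction_total,
               sum(pm$fraction_total * pm$perimeter) / sum(pm$perimeter),
               tolerance = 1e-9)
  # no ER at all
  rep0 <- contact_report(dplyr::bind_rows(mA, mB))
  expect_true(all(rep0$per_mito$fraction_total == 0))
})

test_that("overlapping ER contours are unioned, never double-counted", {
  mito <- circle_contour("m", 500, n = 360)
  er1 <- circle_contour("e1", 560, n = 360, organelle = "er", er_class = "rough")
  er2 <- circle_contour("e2", 570, n = 360, organelle = "er", er_class = "rough")
  rep <- contact_report(dplyr::bind_rows(mito, er1, er2))
  expect_equal(rep$per_mito$fraction_total, 1)  # not 2
  expect_equal(rep$per_mito$fraction_rough, 1)
  expect_equal(nrow(rep$segments), 2)  # both kept for distance statistics
})

test_that("mitochondria touching unclassified ER leave the stratified metrics only", {
  m1 <- circle_contour("m1", 500, n = 180)
  e1 <- circle_contour("e1", 560, n = 180, organelle = "er", er_class = "rough")
  m2 <- circle_contour("m2", 500, n = 180, cx = 5000)
  e2 <- circle_contour("e2", 560, n = 180, cx = 5000, organelle = "er",
                       er_class = "unclassified")
  rep <- contact_report(dplyr::bind_rows(m1, e1, m2, e2))
  expect_equal(rep$aggregate$fraction_total, 1)       # both mitochondria count
  expect_equal(rep$aggregate$fraction_rough, 1)       # only m1 enters, fully rough
  expect_equal(rep$aggregate$stratified_perimeter, rep$per_mito$perimeter[1],
               tolerance = 1e-9)
})

test_that("contact metrics are invariant under rigid motion", {
  field <- simulate_contour_field(
    n_mito = 3, contact_spec = data.frame(er_class = c("rough", "smooth"),
                                          gap_nm = c(45, 70),
                                          arc_fraction = c(0.2, 0.15)),
    seed = 8)
  rep1 <- contact_report(field$contours)
  a <- 0.7
  moved <- dplyr::mutate(field$contours,
                         x2 = cos(a) * x_nm - sin(a) * y_nm + 12345,
                         y2 = sin(a) * x_nm + cos(a) * y_nm - 999,
                         x_nm = x2, y_nm = y2, x2 = NULL, y2 = NULL)
  rep2 <- contact_report(moved)
  expect_equal(rep1$per_mito$fraction_total, rep2$per_mito$fraction_total,
               tolerance = 1e-9)
  expect_equal(rep1$segments$mean_distance, rep2$segments$mean_distance,
               tolerance = 1e-9)
})

test_that("halving the sample spacing moves fractions only within the sampling tolerance", {
  field <- simulate_contour_field(n_mito = 2, seed = 3)
  r15 <- contact_report(field$contours, spacing = 15)
  r7 <- contact_report(field$contours, spacing = 7.5)
  per <- r15$per_mito$perimeter
  expect_true(all(abs(r15$per_mito$fraction_total - r7$per_mito$fraction_total)
                  <= 2 * 15 / per))
})
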