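test_that("line constructions and intersections match hand geometry", {
  l <- line_through(c(0, 0), c(1, 0))
  expect_equal(l$anchor, c(0, 0))
  expect_equal(l$direction, c(1, 0))
  expect_equal(line_through(c(0, 0), c(3, 4))$direction, c(0.6, 0.8))

  # parallel through a point keeps direction, contains the point
  xaxis <- line_through(c(0, 0), c(1, 0))
  par <- line_parallel_through(c(-20, 40), xaxis)
  expect_equal(par$direction, xaxis$direction)
  expect_equal(par$anchor, c(-20, 40))
  diag_ref <- line_through(c(5, 5), c(5 + 0.6, 5 + 0.8))
  through_origin <- line_parallel_through(c(0, 0), diag_ref)
  expect_equal(through_origin$direction, c(0.6, 0.8))
  expect_equal(through_origin$anchor, c(0, 0))

  # intersections
  expect_equal(intersect_lines(line_through(c(0, 0), c(1, 0)),
                               line_through(c(0, 0), c(0, 1))), c(0, 0))
  pm <- line_through(c(0, 50), c(5, 10))
  ref40 <- line_parallel_through(c(0, 40), xaxis)
  expect_equal(intersect_lines(pm, ref40), c(1.25, 40))

  # orthogonal projection
  expect_equal(project_point_onto_line(c(42, -15), ref40), c(42, 40))
  expect_equal(project_point_onto_line(c(3, 4), xaxis), c(3, 0))
  on_line <- c(7, 40)
  expect_equal(project_point_onto_line(on_line, ref40), on_line)
})

test_that("degenerate 2D constructions raise named geometry errors", {
  expect_error(line_through(c(0, 0), c(0, 0), what = c("Poc", "Aoc")),
               class = "counterpart3d_degenerate_geometry")
  expect_error(line_through(c(0, 0), c(0, 0), what = c("Poc", "Aoc")),
               regexp = "Poc.*Aoc")
  h1 <- line_through(c(0, 0), c(1, 0))
  h2 <- line_through(c(0, 5), c(1, 5))
  expect_error(intersect_lines(h1, h2), class = "counterpart3d_degenerate_geometry")
  expect_error(intersect_lines(h1, h1), class = "counterpart3d_degenerate_geometry")
})

test_that("plane construction rules reproduce hand examples", {
  p <- plane_from_three_points(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_equal(abs(p$normal), c(0, 0, 1))
  expect_equal(p$provenance, "three_points")
  p5 <- plane_from_three_points(c(0, 0, 5), c(1, 0, 5), c(0, 1, 5))
  expect_equal(point_plane_distance(c(3, -2, 5), p5), 0)
  expect_equal(point_plane_distance(c(0, 0, 0), p5), 5)
  expect_error(plane_from_three_points(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2)),
               class = "counterpart3d_degenerate_geometry")

  axial <- plane_from_three_points(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  lt <- plane_from_two_points_normal(c(20, -15, -10), c(-20, -15, -10), axial)
  expect_equal(abs(lt$normal), c(0, 1, 0))           # the plane y = -15
  expect_equal(point_plane_distance(c(0, 33, -25), lt), 48)
  expect_equal(lt$provenance, "two_points_normal")
  cl <- plane_from_two_points_normal(c(12, 5, 20), c(-12, 5, 20), axial)
  expect_equal(point_plane_distance(c(7, 5, -3), cl), 0)  # y = 5
  expect_error(plane_from_two_points_normal(c(0, 0, 0), c(0, 0, 7), axial),
               class = "counterpart3d_degenerate_geometry")
  expect_error(plane_from_two_points_normal(c(1, 2, 3), c(1, 2, 3), axial,
                                            what = c("rLT", "lLT")),
               regexp = "rLT.*lLT")

  coronal <- plane_from_three_points(c(0, 0, 0), c(0, 0, 1), c(1, 0, 0))
  pns <- plane_parallel_through_point(c(0, -10, 0), coronal)
  expect_equal(point_plane_distance(c(0, 35, -5), pns), 45)
  expect_equal(pns$provenance, "point_parallel")
  expect_equal(plane_parallel_through_point(c(0, 0, 9), axial)$anchor, c(0, 0, 9))

  expect_equal(point_plane_distance(c(0, 0, 5), axial), 5)
  expect_equal(point_plane_distance(c(0, 0, 5), axial, signed = TRUE), 5)
  expect_equal(point_plane_distance(c(0, 0, -5), axial, signed = TRUE), -5)
})

test_that("plane constructions satisfy their defining contracts on random inputs", {
  set.seed(101)
  for (i in 1:100) {
    pts <- matrix(stats::runif(9, -50, 50), 3)
    tri <- try(plane_from_three_points(pts[1, ], pts[2, ], pts[3, ]), silent = TRUE)
    if (inherits(tri, "try-error")) next
    expect_lt(max(abs(apply(pts, 1, function(q)
      point_plane_distance(q, tri)))), 1e-9)
    expect_equal(sqrt(sum(tri$normal^2)), 1, tolerance = 1e-12)

    ref <- tri
    p1 <- stats::runif(3, -50, 50); p2 <- stats::runif(3, -50, 50)
    two <- plane_from_two_points_normal(p1, p2, ref)
    expect_lt(point_plane_distance(p1, two), 1e-9)
    expect_lt(point_plane_distance(p2, two), 1e-9)
    expect_lt(abs(sum(two$normal * ref$normal)), 1e-9)

    q <- stats::runif(3, -50, 50)
    par <- plane_parallel_through_point(q, ref)
    expect_lt(point_plane_distance(q, par), 1e-9)
    expect_identical(par$normal, ref$normal)
    # offset between ref and result is the same at many sampled ref points
    e <- if (abs(ref$normal[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    u <- c(ref$normal[2] * e[3] - ref$normal[3] * e[2],
           ref$normal[3] * e[1] - ref$normal[1] * e[3],
           ref$normal[1] * e[2] - ref$normal[2] * e[1])
    u <- u / sqrt(sum(u^2))
    smp <- sapply(stats::runif(25, -60, 60), function(t)
      point_plane_distance(ref$anchor + t * u, par))
    expect_lt(diff(range(smp)), 1e-9)
  }
})

test_that("projection onto a line is idempotent and distance-minimizing", {
  set.seed(202)
  for (i in 1:50) {
    l <- line_through(stats::runif(2, -40, 40), stats::runif(2, -40, 40))
    p <- stats::runif(2, -40, 40)
    f <- project_point_onto_line(p, l)
    expect_lt(abs(sum((p - f) * l$direction)), 1e-9)       # residual is perpendicular
    expect_equal(project_point_onto_line(f, l), f, tolerance = 1e-12)
    # no sampled point of the line is closer than the foot
    t <- stats::runif(40, -100, 100)
    on_line <- cbind(l$anchor[1] + t * l$direction[1],
                     l$anchor[2] + t * l$direction[2])
    d_all <- sqrt((on_line[, 1] - p[1])^2 + (on_line[, 2] - p[2])^2)
    expect_true(all(d_all >= sqrt(sum((p - f)^2)) - 1e-9))
  }
})

test_that("constructions are rigid-motion invariant", {
  set.seed(303)
  base_pts <- matrix(stats::runif(15, -40, 40), 5)
  for (i in 1:30) {
    R <- rand_rotation3(); tr <- stats::runif(3, -30, 30)
    m <- apply_rigid(base_pts, R, tr)
    ref0 <- plane_from_three_points(base_pts[1, ], base_pts[2, ], base_pts[3, ])
    ref1 <- plane_from_three_points(m[1, ], m[2, ], m[3, ])
    expect_equal(point_plane_distance(m[4, ], ref1),
                 point_plane_distance(base_pts[4, ], ref0), tolerance = 1e-9)
    two0 <- plane_from_two_points_normal(base_pts[4, ], base_pts[5, ], ref0)
    two1 <- plane_from_two_points_normal(m[4, ], m[5, ], ref1)
    expect_equal(point_plane_distance(m[1, ], two1),
                 point_plane_distance(base_pts[1, ], two0), tolerance = 1e-9)
  }
})

test_that("geometry tolerances are configurable and restorable", {
  old <- geometry_tolerance()
  expect_equal(old$point, 1e-9)
  geometry_tolerance(point = 1e-3)
  # a 0.5 mm separation now counts as coincident
  expect_error(line_through(c(0, 0), c(5e-4, 0)),
               class = "counterpart3d_degenerate_geometry")
  geometry_tolerance(point = old$point, angle = old$angle)
  expect_silent(line_through(c(0, 0), c(5e-4, 0)))
  expect_error(geometry_tolerance(point = -1), class = "error")
})
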