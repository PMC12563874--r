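test_that("line_from_points passes through both points and canonicalizes", {
  l <- line_from_points(c(0, 0), c(0, 1))
  expect_equal(c(l$A, l$B, l$C), c(1, 0, 0))

  l2 <- line_from_points(c(0, 0), c(1, 1))
  expect_equal(line_direction_deg(l2), 45)
  expect_lt(abs(line_eval(l2, c(0, 0))), 1e-9)

  l3 <- line_from_points(c(1, 2), c(3, 6))
  expect_lt(abs(line_eval(l3, c(1, 2))), 1e-9)
  expect_lt(abs(line_eval(l3, c(3, 6))), 1e-9)
  expect_equal(l3$A^2 + l3$B^2, 1, tolerance = 1e-12)

  expect_error(line_from_points(c(1, 1), c(1, 1)), "degenerate")
})

test_that("canonicalize fixes scale and sign and is idempotent", {
  mk <- function(A, B, C) structure(list(A = A, B = B, C = C), class = "ipath_line")
  expect_equal(unclass(canonicalize_line(mk(2, 0, 4)))[1:3],
               list(A = 1, B = 0, C = 2))
  expect_equal(unclass(canonicalize_line(mk(0, -3, 6)))[1:3],
               list(A = 0, B = 1, C = -2))
  expect_equal(unclass(canonicalize_line(mk(3, 4, 10)))[1:3],
               list(A = 0.6, B = 0.8, C = 2))
  expect_error(canonicalize_line(mk(0, 0, 1)), "invalid line")

  set.seed(11)
  for (i in 1:50) {
    l <- rand_line()
    expect_line_equal(canonicalize_line(l), l, tol = 1e-12)
  }
})

test_that("obb corners follow the fixed convention and invariants", {
  expect_equal(obb_corners(oriented_box(0, 0, 2, 4, 0)),
               matrix(c(-1, -2, 1, -2, 1, 2, -1, 2), 4, 2, byrow = TRUE))
  # quarter turn swaps the apparent extents
  c90 <- obb_corners(oriented_box(0, 0, 2, 4, 90))
  expect_equal(sort(abs(c90[, 1])), c(2, 2, 2, 2))
  expect_equal(sort(abs(c90[, 2])), c(1, 1, 1, 1))
  # rotated square: corners land on the axes at radius sqrt(2)
  c45 <- obb_corners(oriented_box(0, 0, 2, 2, 45))
  r <- sqrt(rowSums(c45^2))
  expect_equal(r, rep(sqrt(2), 4), tolerance = 1e-12)
  expect_equal(sort(round(abs(c45[, 1]), 9)), c(0, 0, sqrt(2), sqrt(2)),
               tolerance = 1e-9)

  set.seed(12)
  for (i in 1:25) {
    b <- rand_obb()
    corners <- obb_corners(b)
    expect_equal(colMeans(corners), c(b$cx, b$cy), tolerance = 1e-9)
    d <- sqrt(rowSums((corners - corners[c(2, 3, 4, 1), ])^2))
    expect_equal(d, c(b$w, b$h, b$w, b$h), tolerance = 1e-9)
  }
})

test_that("a box refitted from its corners recovers the parameters", {
  set.seed(13)
  for (i in 1:25) {
    b <- rand_obb()
    fit <- min_area_rect(obb_corners(b))
    expect_equal(c(fit$cx, fit$cy, fit$w, fit$h), c(b$cx, b$cy, b$w, b$h),
                 tolerance = 1e-6)
    dtheta <- abs(fit$theta - b$theta) %% 180
    expect_lt(min(dtheta, 180 - dtheta), 1e-6)
  }
  expect_error(min_area_rect(cbind(0:3, 0:3)), "collinear")
})

test_that("long axis runs along the greater extent", {
  expect_line_equal(long_axis(oriented_box(0, 0, 10, 40, 0)),
                    ipath_line(1, 0, 0))                      # vertical x = 0
  expect_line_equal(long_axis(oriented_box(5, 5, 10, 40, 90)),
                    ipath_line(0, 1, -5))                     # horizontal y = 5
  ax30 <- long_axis(oriented_box(0, 0, 10, 40, 30))
  expect_line_equal(ax30, line_from_point_direction(c(0, 0), 120), tol = 1e-9)
  expect_warning(long_axis(oriented_box(0, 0, 5, 5, 10)), "square")
})

test_that("lateral edge lines are parallel offsets with the long axis as midline", {
  b <- oriented_box(0, 0, 10, 40, 0)
  edges <- lateral_edge_lines(b)
  cs <- sort(vapply(edges, function(l) -l$C / l$A, numeric(1)))
  expect_equal(cs, c(-5, 5))                                   # x = -5 and x = +5
  mid <- angle_bisectors(edges[[1]], edges[[2]])
  expect_true(isTRUE(attr(mid, "parallel")))
  expect_line_equal(mid, long_axis(b))

  b30 <- oriented_box(0, 0, 10, 40, 30)
  ax <- long_axis(b30)
  for (l in lateral_edge_lines(b30)) {
    expect_equal(angle_between(l, ax), 0, tolerance = 1e-9)
    p <- c(-l$C * l$A, -l$C * l$B)                            # a point on l
    expect_equal(abs(line_eval(ax, p)), 5, tolerance = 1e-9)
  }
})

test_that("angle bisectors: symmetric examples", {
  bb <- angle_bisectors(ipath_line(1, 0, 0), ipath_line(0, 1, 0))
  dirs <- sort(vapply(bb, line_direction_deg, numeric(1)))
  expect_equal(dirs, c(45, 135), tolerance = 1e-9)

  l1 <- line_from_point_direction(c(0, 0), 60)   # +30 deg from vertical
  l2 <- line_from_point_direction(c(0, 0), 120)  # -30 deg from vertical
  bb2 <- angle_bisectors(l1, l2)
  dirs2 <- sort(vapply(bb2, line_direction_deg, numeric(1)))
  expect_equal(dirs2, c(0, 90), tolerance = 1e-9)

  bb3 <- angle_bisectors(ipath_line(3, 4, 0), ipath_line(1, 0, 0))
  for (b in bb3) {
    expect_equal(angle_between(b, ipath_line(3, 4, 0)),
                 angle_between(b, ipath_line(1, 0, 0)), tolerance = 1e-9)
    expect_lt(abs(line_eval(b, c(0, 0))), 1e-9)
  }

  expect_error(angle_bisectors(ipath_line(1, 0, 0), ipath_line(2, 0, 0)),
               "degenerate")
})

test_that("bisector equal-angle, perpendicularity and rotation equivariance", {
  set.seed(14)
  for (i in 1:300) {
    l1 <- rand_line(); l2 <- rand_line()
    if (angle_between(l1, l2) < 1e-6) next
    bb <- angle_bisectors(l1, l2)
    for (b in bb)
      expect_lt(abs(angle_between(b, l1) - angle_between(b, l2)), 1e-9)
    expect_lt(abs(angle_between(bb[[1]], bb[[2]]) - 90), 1e-9)
  }
  # rotating both inputs by phi rotates both bisectors by phi (mod 180)
  rot_line <- function(l, phi) {
    t <- phi * pi / 180
    ipath_line(cos(t) * l$A - sin(t) * l$B, sin(t) * l$A + cos(t) * l$B, l$C)
  }
  set.seed(15)
  for (i in 1:50) {
    l1 <- rand_line(); l2 <- rand_line(); phi <- stats::runif(1, 0, 180)
    if (angle_between(l1, l2) < 1e-6) next
    d0 <- sort(vapply(angle_bisectors(l1, l2), line_direction_deg, numeric(1)))
    d1 <- sort(vapply(angle_bisectors(rot_line(l1, phi), rot_line(l2, phi)),
                      line_direction_deg, numeric(1)))
    shift <- sort((d0 + phi) %% 180)
    expect_lt(max(pmin(abs(d1 - shift), 180 - abs(d1 - shift))), 1e-9)
  }
})

test_that("angle_between and line_direction_deg behave as direction arithmetic", {
  expect_equal(angle_between(ipath_line(1, 0, 0), ipath_line(1, 0, -3)), 0)
  expect_equal(angle_between(ipath_line(1, 0, 0), ipath_line(0, 1, 0)), 90)
  a <- line_from_point_direction(c(0, 0), 10)
  b <- line_from_point_direction(c(5, -2), 13)
  expect_equal(angle_between(a, b), 3, tolerance = 1e-9)

  expect_equal(line_direction_deg(ipath_line(0, 1, 0)), 0)
  expect_equal(line_direction_deg(ipath_line(1, 0, 0)), 90)
  expect_equal(line_direction_deg(ipath_line(1, -1, 0)), 45)
})

test_that("convex polygon clipping matches the vertex-enumeration oracle", {
  set.seed(16)
  for (i in 1:100) {
    a <- rand_obb(4); b <- rand_obb(4)
    inter <- polygon_area(convex_clip(obb_corners(a), obb_corners(b)))
    expect_equal(inter, poly_intersection_area_oracle(obb_corners(a), obb_corners(b)),
                 tolerance = 1e-9)
  }
})
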