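test_that("euler_to_rotation yields proper rotations that preserve norms", {
  expect_equal(euler_to_rotation(c(0, 0, 0)), diag(3))
  expect_error(euler_to_rotation(c(0, NA, 0)), "finite")
  set.seed(1)
  for (i in 1:100) {
    a <- runif(3, -2 * pi, 2 * pi)
    R <- euler_to_rotation(a)
    expect_rotation_matrix(R)
    v <- rnorm(3)
    expect_equal(sqrt(sum((R %*% v)^2)), sqrt(sum(v^2)), tolerance = 1e-12)
  }
})

test_that("rotation_to_euler round-trips the rotation matrix", {
  set.seed(2)
  for (i in 1:50) {
    R <- euler_to_rotation(runif(3, -pi, pi))
    expect_equal(euler_to_rotation(rotation_to_euler(R)), R, tolerance = 1e-9)
  }
  # gimbal-lock boundary
  Rz <- euler_to_rotation(c(0.7, 0, 0))
  expect_equal(euler_to_rotation(rotation_to_euler(Rz)), Rz, tolerance = 1e-9)
})

test_that("quaternion rotation agrees with matrix rotation and is Haar-uniform", {
  set.seed(3)
  q <- polycorr:::runif_quat(200)
  v <- c(1.5, -2, 0.5)
  Vq <- polycorr:::quat_rotate_vec(q, v)
  for (i in c(1, 57, 200)) {
    R <- polycorr:::quat_to_matrix(q[i, ])
    expect_rotation_matrix(R)
    expect_equal(as.numeric(R %*% v), Vq[i, ], tolerance = 1e-12)
  }
  # Haar measure: the mean rotation matrix converges to the zero matrix
  set.seed(4)
  qs <- polycorr:::runif_quat(20000)
  M <- matrix(0, 3, 3)
  for (k in 1:3) {
    e <- numeric(3); e[k] <- 1
    M[, k] <- colMeans(polycorr:::quat_rotate_vec(qs, e))
  }
  expect_lt(max(abs(M)), 0.03)
})

test_that("apply_perspective preserves congruence and decouples T from R", {
  tri <- triangle_template(50, 60, 15)
  expect_equal(apply_perspective(tri), tri$positions, ignore_attr = TRUE)
  shifted <- apply_perspective(tri, translation = c(10, 0, 0))
  expect_equal(shifted, tri$positions + rep(c(10, 0, 0), each = 3),
               ignore_attr = TRUE)
  set.seed(5)
  for (i in 1:20) {
    P <- apply_perspective(tri, translation = rnorm(3, 0, 100),
                           angles = runif(3, -pi, pi))
    expect_equal(unname(dist(P)[1:3]),
                 unname(dist(tri$positions)[1:3]), tolerance = 1e-9)
    # node 1 lands at X1 + T
    P2 <- apply_perspective(tri, translation = c(3, 4, 5), angles = runif(3))
    expect_equal(P2[1, ], c(3, 4, 5), tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("standardize_polygon inverts apply_perspective", {
  set.seed(6)
  for (i in 1:20) {
    tri <- random_triangle()
    tr <- rnorm(3, 0, 50); an <- runif(3, -pi, pi)
    P <- apply_perspective(tri, tr, an)
    sp <- standardize_polygon(P)
    expect_equal(sp$template$positions, tri$positions, tolerance = 1e-8,
                 ignore_attr = TRUE)
    back <- apply_perspective(sp$template, sp$translation, sp$angles)
    expect_equal(back, P, tolerance = 1e-8, ignore_attr = TRUE)
  }
  # already canonical: identity perspective
  tri <- triangle_template(45, 85, 45)
  sp <- standardize_polygon(tri$positions)
  expect_equal(sp$translation, c(0, 0, 0), ignore_attr = TRUE)
  expect_equal(sp$template$positions, tri$positions, tolerance = 1e-12)
})

test_that("standardize_polygon handles degenerate configurations by convention", {
  # collinear points: valid template with y3 = 0
  sp <- standardize_polygon(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)))
  expect_equal(sp$template$positions[3, 2], 0)
  expect_equal(edge_lengths(sp$template), c(l12 = 1, l13 = 2, l23 = 1))
  # node 2 coincident with node 1
  sp2 <- standardize_polygon(rbind(c(5, 5, 5), c(5, 5, 5), c(5, 8, 5)))
  expect_equal(unname(edge_lengths(sp2$template)), c(0, 3, 3))
  # J = 2 segment
  sp3 <- standardize_polygon(rbind(c(1, 2, 3), c(4, 2, 3)))
  expect_equal(unname(edge_lengths(sp3$template)), 3)
})

test_that("internal angles follow the law of cosines and sum to 180", {
  expect_equal(unname(internal_angles(c(10, 10, 10))), rep(60, 3))
  # right angle opposite the 5-side (at node 1, between sides 3 and 4)
  expect_equal(unname(internal_angles(c(3, 4, 5)))[1], 90)
  set.seed(7)
  for (i in 1:30) {
    tri <- random_triangle()
    l <- edge_lengths(tri)
    ang <- internal_angles(tri)
    expect_equal(sum(ang), 180, tolerance = 1e-9)
    # brute force via position vectors
    X <- tri$positions
    cosv <- function(u, v) sum(u * v) / sqrt(sum(u^2) * sum(v^2))
    a1 <- acos(cosv(X[2, ] - X[1, ], X[3, ] - X[1, ])) * 180 / pi
    expect_equal(unname(ang[1]), a1, tolerance = 1e-9)
  }
  expect_warning(a <- internal_angles(c(0, 5, 5)), "undefined")
  expect_true(is.na(a[1]))
})

test_that("triangle inequality counts the boundary as satisfied", {
  expect_true(triangle_inequality_holds(c(3, 4, 5)))
  expect_false(triangle_inequality_holds(c(3, 4, 8)))
  expect_true(triangle_inequality_holds(c(50, 60, 110)))
  expect_identical(triangle_inequality_holds(rbind(c(1, 1, 1), c(1, 1, 3))),
                   c(TRUE, FALSE))
})

test_that("length and angle descriptors are rigid-motion invariant", {
  set.seed(8)
  tri <- random_triangle()
  for (i in 1:10) {
    P <- apply_perspective(tri, rnorm(3, 0, 30), runif(3, -pi, pi))
    tpl <- standardize_polygon(P)$template
    expect_equal(edge_lengths(tpl), edge_lengths(tri), tolerance = 1e-8)
    expect_equal(internal_angles(tpl), internal_angles(tri), tolerance = 1e-6)
  }
})
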