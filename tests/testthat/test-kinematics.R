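test_that("law-of-cosines angles match their closed forms and the vector formulation", {
  expect_equal(angle_from_sides(1, 1, 1), 60)
  expect_equal(angle_from_sides(5, 3, 4), 90)
  expect_equal(angle_from_sides(sqrt(2), 1, 1), 90)
  expect_error(angle_from_sides(10, 1, 1), class = "rehabmm_domain_error")
  expect_error(angle_from_sides(-1, 1, 1), class = "rehabmm_domain_error")

  expect_equal(angle_at_joint(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0)), 90)
  expect_equal(angle_at_joint(c(2, 0, 0), c(1, 0, 0), c(0, 0, 0)), 180)
  expect_error(angle_at_joint(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)),
               class = "rehabmm_domain_error")

  # dual-formula oracle: direct arccos of normalized dot products
  set.seed(101)
  for (i in 1:1000) {
    p <- matrix(rnorm(9), 3)
    if (min(dist(p)) < 1e-3) next
    u <- p[1, ] - p[2, ]; v <- p[3, ] - p[2, ]
    direct <- acos(pmin(1, pmax(-1, sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
    expect_equal(angle_at_joint(p[1, ], p[2, ], p[3, ]), direct, tolerance = 1e-9)
  }
})

test_that("cross product follows the component formula", {
  expect_equal(cross_product(c(1, 0, 0), c(0, 1, 0)), c(0, 0, 1))
  expect_equal(cross_product(c(1, 2, 3), c(4, 5, 6)), c(-3, 6, -3))
  expect_equal(cross_product(c(2, -1, 5), c(2, -1, 5)), c(0, 0, 0))
})

test_that("the personal coordinate system is orthonormal, right-handed and equivariant", {
  pcs <- build_pcs(c(-0.1, 1, 2), c(0.1, 1, 2), c(0, 1, 0, 0))
  expect_equal(pcs$origin, c(0, 0, 2))
  expect_equal(pcs$axis_ud, c(0, 1, 0))
  expect_equal(abs(pcs$axis_lr), c(1, 0, 0))
  A <- cbind(pcs$axis_lr, pcs$axis_ud, pcs$axis_fb)
  expect_equal(crossprod(A), diag(3), tolerance = 1e-6)
  expect_equal(det(A), 1, tolerance = 1e-6)  # right-handed

  # rotating hips and floor about the vertical axis rotates all axes alike
  ang <- 37 * pi / 180
  R <- matrix(c(cos(ang), 0, sin(ang), 0, 1, 0, -sin(ang), 0, cos(ang)), 3, byrow = TRUE)
  hl <- c(-0.13, 0.97, 1.8); hr <- c(0.09, 1.02, 2.2)
  p1 <- build_pcs(hl, hr, c(0, 1, 0, 0))
  p2 <- build_pcs(as.vector(R %*% hl), as.vector(R %*% hr), c(0, 1, 0, 0))
  for (ax in c("axis_lr", "axis_ud", "axis_fb"))
    expect_equal(p2[[ax]], as.vector(R %*% p1[[ax]]), tolerance = 1e-9)

  expect_error(build_pcs(c(0, 1, 2), c(0, 1, 2), c(0, 1, 0, 0)),
               class = "rehabmm_degenerate_error")
  expect_error(build_pcs(c(0, 1, 2), c(0, 2, 2), c(0, 1, 0, -0.5)),
               class = "rehabmm_degenerate_error")  # vertically stacked hips
})

test_that("PCS expression is invariant to rotation about the floor normal and floor translation", {
  sim <- simulate_abduction(short_spec(seed = 6))
  seq1 <- sim$sequence
  ang <- 90 * pi / 180
  R <- matrix(c(cos(ang), 0, sin(ang), 0, 1, 0, -sin(ang), 0, cos(ang)), 3, byrow = TRUE)
  seq2 <- seq1
  for (i in seq_len(length(seq1$timestamps)))
    seq2$positions[i, , ] <- seq1$positions[i, , ] %*% t(R)
  seq3 <- seq1
  seq3$positions[, , "x"] <- seq3$positions[, , "x"] + 1  # 1 m along the floor

  pcs1 <- to_personal_coords(seq1)
  expect_identical(pcs1$coords, "pcs")
  expect_equal(to_personal_coords(seq2)$positions, pcs1$positions, tolerance = 1e-6)
  expect_equal(to_personal_coords(seq3)$positions, pcs1$positions, tolerance = 1e-6)
  # hips straddle the origin with equal and opposite left/right components
  expect_equal(pcs1$positions[, "hip_left", "lr"],
               -pcs1$positions[, "hip_right", "lr"], tolerance = 1e-6)
})

test_that("buffered speed matches its closed forms and the naive windowed oracle", {
  const <- matrix(1.5, 100, 3)
  out <- buffered_speed(const, 15, 60)
  expect_identical(sum(is.na(out)), 14L)  # masked prefix is buffer_len - 1
  expect_equal(out[15:100], rep(0, 86))

  uniform <- cbind(seq(0, 0.99, by = 0.01), 0)
  out <- buffered_speed(uniform, 15, 60)
  expect_equal(out[15:100], rep(0.6, 86))  # 0.01 m/frame at 60 Hz

  set.seed(7)
  walk <- apply(matrix(rnorm(3 * 80, sd = 0.01), ncol = 3), 2, cumsum)
  expect_equal(buffered_speed(walk, 15, 60),
               oracle_buffered_speed(walk, 15, 60), tolerance = 1e-12)
  expect_true(all(buffered_speed(walk, 15, 60)[15:80] >= 0))

  expect_error(buffered_speed(walk[1:10, ], 15, 60), class = "rehabmm_config_error")
  expect_error(buffered_speed(walk, 1, 60), class = "rehabmm_config_error")
})

test_that("quaternion decomposition recovers intrinsic rotations", {
  expect_equal(as.numeric(quaternion_to_rotations(c(1, 0, 0, 0))), c(0, 0, 0))
  r <- quaternion_to_rotations(c(sqrt(2) / 2, sqrt(2) / 2, 0, 0))
  expect_equal(as.numeric(r), c(90, 0, 0), tolerance = 1e-9)
  expect_false(attr(r, "gimbal_lock"))
  expect_error(quaternion_to_rotations(c(1, 1, 0, 0)), class = "rehabmm_domain_error")

  # compose-then-decompose round trip away from lock
  qmul <- function(a, b) c(
    a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
  axis_q <- function(angle_deg, axis) {
    a <- angle_deg * pi / 360
    q <- c(cos(a), 0, 0, 0); q[1 + axis] <- sin(a); q
  }
  set.seed(42)
  for (i in 1:200) {
    ang <- c(runif(1, -170, 170), runif(1, -80, 80), runif(1, -170, 170))
    q <- qmul(axis_q(ang[1], 1), qmul(axis_q(ang[2], 2), axis_q(ang[3], 3)))
    expect_equal(as.numeric(quaternion_to_rotations(q)), ang, tolerance = 1e-6)
  }
  # gimbal lock is flagged and handled canonically
  qlock <- qmul(axis_q(30, 1), axis_q(90, 2))
  rl <- quaternion_to_rotations(qlock)
  expect_true(attr(rl, "gimbal_lock"))
  expect_equal(rl[["yaw"]], 90, tolerance = 1e-6)
})
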