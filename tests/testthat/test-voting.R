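# Vote accumulation, direction refinement, schedule, and the full loop.

single_voter_field <- function(shape, at, angle, m = 2) {
  mag <- array(0, shape)
  mag[at[1], at[2]] <- m
  dir <- array(NA_real_, shape)
  dir[at[1], at[2]] <- angle
  make_gradient_field(mag, dir)
}

test_that("a single voter stamps its magnitude onto exactly its cone members", {
  f <- single_voter_field(c(6, 6), c(2, 2), 0, m = 2)
  v <- cast_votes(f, r = 2.5, phi = pi / 2)
  expected <- array(0, c(6, 6))
  for (s in list(c(3, 2), c(4, 2), c(4, 3), c(4, 1))) expected[s[1], s[2]] <- 2
  expect_equal(v$scores, expected, ignore_attr = TRUE)
  expect_equal(sum(v$scores), attr(v$scores, "mass"))
})

test_that("vote mass bookkeeping matches an independent member count", {
  set.seed(5)
  for (shape in list(c(12, 12), c(6, 6, 6))) {
    f <- random_gradient_field(shape, density = 0.6)
    r <- 3; phi <- pi / 3
    v <- cast_votes(f, r, phi)
    expect_equal(sum(v$scores), attr(v$scores, "mass"), tolerance = 1e-12)
    # independent path: enumerate each voter's members via cone_member_sites
    dm <- radvote:::direction_matrix(f)
    voters <- which(f$magnitude > 0)
    total <- 0
    for (t in voters) {
      pos <- arrayInd(t, shape)[1, ]
      cn <- cone_spec(pos, dm[t, ], r, phi)
      total <- total + f$magnitude[t] * nrow(cone_member_sites(cn, shape))
    }
    expect_equal(sum(v$scores), total, tolerance = 1e-9)
  }
})

test_that("project and collect vote formulations agree", {
  set.seed(23)
  f2 <- random_gradient_field(c(16, 16))
  f3 <- random_gradient_field(c(8, 8, 8))
  for (f in list(f2, f3)) {
    a <- cast_votes(f, r = 4, phi = pi / 2)
    b <- collect_votes_oracle(f, r = 4, phi = pi / 2)
    expect_lt(max(abs(a$scores - b$scores)), 1e-9)
  }
  # single-voter case agrees too
  f <- single_voter_field(c(6, 6), c(2, 2), 0)
  expect_equal(cast_votes(f, 2.5, pi / 2)$scores,
               collect_votes_oracle(f, 2.5, pi / 2)$scores,
               ignore_attr = TRUE)
})

test_that("voters re-orient toward the cone vote maximum", {
  # voter at (1, 1), direction +x; plant the max at offset (2, 1)
  f <- single_voter_field(c(8, 8), c(1, 1), 0, m = 1.5)
  votes <- radvote:::new_vote_field(array(0, c(8, 8)), f$spacing)
  votes$scores[3, 2] <- 7
  up <- update_directions(f, votes, r = 4, phi = pi / 2)
  expect_equal(up$direction[1, 1], atan2(1, 2), tolerance = 1e-12)
  expect_equal(up$magnitude, f$magnitude)  # Eq-style magnitude preservation

  # constant positive score over the cone: tie goes to the first member in
  # storage order, here offset (2, -1) from a voter at (2, 2)
  f2 <- single_voter_field(c(6, 6), c(2, 2), 0)
  votes2 <- radvote:::new_vote_field(array(1, c(6, 6)), f2$spacing)
  up2 <- update_directions(f2, votes2, r = 2.5, phi = pi / 2)
  expect_equal(up2$direction[2, 2], atan2(-1, 2) %% (2 * pi),
               tolerance = 1e-12)
})

test_that("3D direction update is the unit offset with magnitude embedded", {
  mag <- array(0, c(8, 8, 8)); mag[1, 1, 1] <- 5
  dir <- array(NA_real_, c(8, 8, 8, 3))
  dir[1, 1, 1, ] <- c(0, 0, 1)
  f <- make_gradient_field(mag, dir)
  votes <- radvote:::new_vote_field(array(0, c(8, 8, 8)), f$spacing)
  votes$scores[1, 4, 5] <- 2      # offset (0, 3, 4), angle ~36.9 deg < 45
  up <- update_directions(f, votes, r = 6, phi = pi / 2)
  expect_equal(up$direction[1, 1, 1, ], c(0, 0.6, 0.8), tolerance = 1e-12)
  expect_equal(up$magnitude[1, 1, 1], 5)
})

test_that("zero cone evidence leaves directions unchanged", {
  f <- single_voter_field(c(8, 8), c(4, 4), pi / 3)
  votes <- radvote:::new_vote_field(array(0, c(8, 8)), f$spacing)
  up <- update_directions(f, votes, r = 3, phi = pi / 2)
  expect_equal(up$direction[4, 4], pi / 3)
  # magnitudes preserved on a random field as well
  set.seed(7)
  f3 <- random_gradient_field(c(7, 7, 7))
  v3 <- cast_votes(f3, 3, pi / 2)
  expect_equal(update_directions(f3, v3, 3, pi / 2)$magnitude, f3$magnitude)
})

test_that("the aperture schedule halves from pi/2 to below one pixel arc", {
  s10 <- make_schedule(10)
  expect_equal(s10$phis, pi / 2 * 0.5^(0:4), tolerance = 1e-12)
  expect_equal(s10$n_iterations, 5)
  expect_equal(s10$phi_t, 0.1)
  expect_lt(s10$phis[5], 0.1)

  s1 <- make_schedule(1)
  expect_equal(s1$n_iterations, 2)
  expect_equal(s1$phis, c(pi / 2, pi / 4), tolerance = 1e-12)

  for (r in c(1, 2.5, 7, 100)) {
    s <- make_schedule(r)
    expect_true(all(diff(s$phis) < 0))            # strictly decreasing
    expect_lt(s$phis[s$n_iterations], s$phi_t)    # terminates below phi_t
    expect_gte(s$phis[s$n_iterations - 1], s$phi_t)
  }
  expect_error(make_schedule(0.5), ">= 1")
})

test_that("iterative voting recovers a 2D disk center", {
  img <- render_dark_blob(c(64, 64), c(32, 32), 5)
  v <- iterative_vote(img, 6, "dark")
  d <- find_local_maxima(v, 6)
  expect_equal(d$count, 1)
  expect_lte(sqrt(sum((d$centers[1, ] - c(32, 32))^2)), 1)
})

test_that("a blank image yields a zero vote field and no detections", {
  img <- image_grid(array(0.5, c(16, 16, 8)), 1)
  v <- iterative_vote(img, 3, "dark")
  expect_true(all(v$scores == 0))
  expect_equal(find_local_maxima(v, 3)$count, 0)
})

test_that("the vote maximum of a symmetric blob is stationary across iterations", {
  img <- gaussian_blur(render_dark_blob(c(48, 48), c(24, 24), 5), 2)
  f <- compute_gradient(img, "dark")
  sched <- make_schedule(6)
  for (phi in sched$phis) {
    v <- cast_votes(f, 6, phi)
    am <- arrayInd(which.max(v$scores), dim(v$scores))[1, ]
    expect_lte(sqrt(sum((am - c(24, 24))^2)), 1)
    f <- update_directions(f, v, 6, phi)
  }
})

test_that("detection is equivariant to 90-degree rotation of the input", {
  img <- render_dark_blob(c(48, 48), c(20, 28), 5)
  rimg <- image_grid(rot90_mat(img$values), 1)
  d1 <- find_local_maxima(iterative_vote(img, 6, "dark"), 6)
  d2 <- find_local_maxima(iterative_vote(rimg, 6, "dark"), 6)
  # site (x, y) maps to (y, n + 1 - x) under this rotation
  mapped <- c(d1$centers[1, 2], 48 + 1 - d1$centers[1, 1])
  expect_lte(sqrt(sum((d2$centers[1, ] - mapped)^2)), 1.5)
})

test_that("vote parameters are validated", {
  f <- random_gradient_field(c(8, 8))
  expect_error(cast_votes(f, r = 0.5, phi = pi / 2), "smaller than one pixel")
  img <- image_grid(matrix(0.5, 8, 8), 2)
  expect_error(iterative_vote(img, 1.5), "exceed")
  v <- cast_votes(f, 3, pi / 2)
  f3 <- random_gradient_field(c(9, 9))
  expect_error(update_directions(f3, v, 3, pi / 2), "shapes")
})
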