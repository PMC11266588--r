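test_that("smoothed Heaviside/Dirac pair has the stated closed forms", {
  for (eps in c(0.5, 1, 2)) {
    expect_equal(lgdf_heaviside(0, eps), 0.5)
    expect_equal(lgdf_delta(0, eps), 1 / (pi * eps))
    x <- seq(-5, 5, by = 0.25)
    expect_equal(lgdf_heaviside(x, eps) + lgdf_heaviside(-x, eps),
                 rep(1, length(x)))
    # central difference of H matches delta to O(h^2)
    h <- 1e-4
    num <- (lgdf_heaviside(x + h, eps) - lgdf_heaviside(x - h, eps)) / (2 * h)
    expect_equal(num, lgdf_delta(x, eps), tolerance = 1e-6)
  }
})

test_that("level-set initialization rasterizes the seed disc", {
  phi <- init_level_set(c(64, 64), c(32, 32), 10)
  want <- 0L
  for (r in 1:64) for (c in 1:64) {
    if ((r - 32)^2 + (c - 32)^2 <= 100) want <- want + 1L
  }
  expect_equal(sum(phi < 0), want)
  expect_equal(sort(unique(as.vector(phi))), c(-2, 2))
  expect_error(init_level_set(c(64, 64), c(32, 32), 0), "positive")
  expect_error(init_level_set(c(64, 64), c(5, 32), 10), "inside")
})

test_that("local statistics match the brute-force evaluation", {
  set.seed(41)
  img <- matrix(runif(81, 0, 255), 9, 9)
  phi <- matrix(runif(81, -3, 3), 9, 9)
  p <- small_params()
  got <- local_gaussian_stats(img, phi, p)
  want <- oracle_local_stats(img, phi, p$kernel_sigma, p$kernel_radius,
                             p$epsilon, p$var_floor)
  for (f in names(want)) expect_equal(got[[f]], want[[f]], tolerance = 1e-8)
})

test_that("constant images yield equal means and floored variances", {
  img <- matrix(77, 12, 12)
  phi <- init_level_set(c(12, 12), c(6, 6), 3)
  p <- small_params()
  st <- local_gaussian_stats(img, phi, p)
  expect_equal(st$u1, matrix(77, 12, 12), tolerance = 1e-9)
  expect_equal(st$u2, matrix(77, 12, 12), tolerance = 1e-9)
  expect_equal(st$var1, matrix(p$var_floor, 12, 12))
  expect_equal(st$var2, matrix(p$var_floor, 12, 12))
})

test_that("two-region statistics recover the region means away from the edge", {
  fx <- two_region_fixture(c(40, 40), radius = 10)
  phi <- init_level_set(c(40, 40), c(20.5, 20.5), 10)
  p <- lgdf_params()
  st <- local_gaussian_stats(fx$image, phi, p)
  # u2 models the inside (phi < 0), u1 the outside
  expect_equal(st$u2[20, 20], fx$image[20, 20], tolerance = 3)
  expect_equal(st$u1[3, 3], fx$image[3, 3], tolerance = 3)
})

test_that("data force matches brute force and vanishes for identical regions", {
  set.seed(42)
  img <- matrix(runif(81, 0, 255), 9, 9)
  p <- small_params()
  st <- list(u1 = matrix(100, 9, 9), u2 = matrix(100, 9, 9),
             var1 = matrix(50, 9, 9), var2 = matrix(50, 9, 9))
  expect_equal(lgdf_data_force(img, st, p), matrix(0, 9, 9), tolerance = 1e-10)
  st2 <- list(u1 = matrix(runif(81, 50, 200), 9, 9),
              u2 = matrix(runif(81, 50, 200), 9, 9),
              var1 = matrix(runif(81, 10, 400), 9, 9),
              var2 = matrix(runif(81, 10, 400), 9, 9))
  got <- lgdf_data_force(img, st2, p)
  want <- oracle_data_force(img, st2, p$kernel_sigma, p$kernel_radius)
  expect_equal(got, want, tolerance = 1e-8)
})

test_that("the force is invariant to a joint intensity rescaling", {
  set.seed(43)
  img <- matrix(runif(81, 20, 230), 9, 9)
  st <- list(u1 = matrix(runif(81, 50, 200), 9, 9),
             u2 = matrix(runif(81, 50, 200), 9, 9),
             var1 = matrix(runif(81, 10, 400), 9, 9),
             var2 = matrix(runif(81, 10, 400), 9, 9))
  p <- small_params()
  base <- lgdf_data_force(img, st, p)
  b <- 3
  st_b <- list(u1 = b * st$u1, u2 = b * st$u2,
               var1 = b^2 * st$var1, var2 = b^2 * st$var2)
  scaled <- lgdf_data_force(b * img, st_b, p)
  expect_lt(max(abs(scaled - base)), 1e-8)
})

test_that("one evolution step equals the independent stencil evaluation", {
  set.seed(44)
  img <- matrix(runif(256, 0, 255), 16, 16)
  phi <- init_level_set(c(16, 16), c(8, 8), 4)
  p <- small_params()
  got <- lgdf_evolve_step(img, phi, p)
  want <- oracle_evolve_step(img, phi, p)
  expect_equal(got$phi, want, tolerance = 1e-8)
  expect_equal(got$iteration, 1L)
  # variance floors hold after the refresh
  expect_true(all(got$var1 >= p$var_floor) && all(got$var2 >= p$var_floor))
})

test_that("a signed distance function is a regularizer fixed point", {
  # phi = |row - edge| style 1-D distance: |grad| = 1 so the mu-term and
  # curvature vanish; with matched flat stats the whole update is ~0
  n <- 24
  phi <- matrix(rep(seq_len(n) - 12.5, n), n, n)
  img <- matrix(150, n, n)
  p <- small_params()
  st <- lgdf_evolve_step(img, phi, p)
  delta <- st$phi - phi
  inner <- delta[3:(n - 2), 3:(n - 2)]
  expect_lt(max(abs(inner)), p$dt * p$nu * 0.1 + 1e-6)
})

test_that("total energy matches the brute-force double integral", {
  set.seed(45)
  img <- matrix(runif(81, 0, 255), 9, 9)
  phi <- matrix(runif(81, -2, 2), 9, 9)
  p <- small_params()
  got <- lgdf_energy(img, phi, p)
  want <- oracle_energy(img, phi, p)
  expect_equal(got, want, tolerance = 1e-6 * abs(want))
})

test_that("length term measures a straight zero crossing", {
  n <- 32
  phi <- matrix(rep(seq_len(n) - 16.5, each = n), n, n)  # vertical contour
  img <- matrix(100, n, n)
  p <- lgdf_params()
  ctx <- fundusseg:::lgdf_context(img, p)
  M1 <- lgdf_heaviside(phi, p$epsilon)
  g <- fundusseg:::grad_central(M1)
  len <- sum(sqrt(g$gx^2 + g$gy^2))
  expect_equal(len, n, tolerance = 0.1 * n)
  # mu-term of an exact SDF is ~0
  gphi <- fundusseg:::grad_central(phi)
  pen <- sum(0.5 * (sqrt(gphi$gx^2 + gphi$gy^2) - 1)^2)
  expect_lt(pen / (n * n), 1e-2)
})

test_that("energy is non-increasing over 50 steps on the two-region fixture", {
  fx <- two_region_fixture(c(48, 48), radius = 12)
  p <- lgdf_params()
  ctx <- fundusseg:::lgdf_context(fx$image, p)
  state <- init_level_set(c(48, 48), c(24.5, 24.5), 9)
  e_prev <- lgdf_energy(fx$image, state, p, ctx)
  state <- lgdf_evolve_step(fx$image, state, p, ctx)
  for (i in 1:50) {
    state <- lgdf_evolve_step(fx$image, state, p, ctx)
    e <- lgdf_energy(fx$image, state, p, ctx)
    expect_lte(e, e_prev * (1 + 1e-6) + 1e-6)
    e_prev <- e
  }
})

test_that("segmentation recovers the two-region disc and is deterministic", {
  fx <- two_region_fixture(c(64, 64), radius = 14)
  p <- lgdf_params(iterations = 200)
  seg1 <- segment_lesion(fx$image, p, seed_center = c(32, 32),
                         seed_radius = 11, preprocess = FALSE, trace_every = 0)
  seg2 <- segment_lesion(fx$image, p, seed_center = c(32, 32),
                         seed_radius = 11, preprocess = FALSE, trace_every = 0)
  expect_identical(seg1$mask, seg2$mask)
  expect_gt(dice_coefficient(seg1$mask, fx$mask), 0.9)
  expect_true(all(is.finite(seg1$state$phi)))
})

test_that("a uniform image leaves the seed circle nearly untouched", {
  u <- matrix(120, 96, 96)
  seg <- segment_lesion(u, lgdf_params(iterations = 50),
                        seed_center = c(48, 48), seed_radius = 20,
                        preprocess = FALSE, trace_every = 0)
  seed_disc <- fundusseg:::disc_mask(c(96, 96), c(48, 48), 20)
  expect_gt(dice_coefficient(seg$mask, seed_disc), 0.8)
})

test_that("masks are unchanged under global intensity scaling", {
  fx <- two_region_fixture(c(64, 64), radius = 14)
  p <- lgdf_params(iterations = 150)
  seg1 <- segment_lesion(fx$image, p, seed_center = c(32, 32),
                         seed_radius = 11, preprocess = FALSE, trace_every = 0)
  seg3 <- segment_lesion(3 * fx$image, p, seed_center = c(32, 32),
                         seed_radius = 11, preprocess = FALSE, trace_every = 0)
  expect_identical(seg1$mask, seg3$mask)
})

test_that("segmentation trace and tidiers expose the run", {
  fx <- two_region_fixture(c(48, 48), radius = 10)
  seg <- segment_lesion(fx$image, lgdf_params(iterations = 60),
                        seed_center = c(24, 24), seed_radius = 8,
                        preprocess = FALSE, trace_every = 20)
  expect_equal(seg$trace$iteration, c(20, 40, 60))
  expect_true(all(diff(seg$trace$energy) <= 1e-6 * abs(seg$trace$energy[-3])))
  td <- tidy(seg)
  expect_equal(td$area_px, sum(seg$mask))
  gl <- glance(seg)
  expect_equal(gl$iterations, 60L)
  expect_s3_class(autoplot(seg), "ggplot")
  expect_s3_class(plot_energy_trace(seg), "ggplot")
})
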