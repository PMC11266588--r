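const_rgb <- function(v, dims = c(32, 32)) {
  array(v, c(dims, 3))
}

test_that("geometric-mean brightness matches hand arithmetic", {
  expect_equal(as.numeric(geometric_mean_brightness(matrix(128, 16, 16))),
               128 / 255)
  two <- matrix(c(64, 255), 1, 2)
  expect_equal(as.numeric(geometric_mean_brightness(two, within_field = FALSE)),
               sqrt((64 / 255) * (255 / 255)))
  expect_warning(b <- geometric_mean_brightness(matrix(0, 8, 8)), "black")
  expect_equal(as.numeric(b), 1 / 255)
})

test_that("brightness adjustment is a clipped linear scale", {
  bright <- matrix(200, 16, 16)
  expect_equal(adjust_brightness(bright, b_min = 0.35), bright,
               ignore_attr = TRUE)
  dim50 <- matrix(50, 16, 16)
  out <- adjust_brightness(dim50, b_min = 100 / 255)
  expect_equal(out, matrix(100, 16, 16), ignore_attr = TRUE)
  # corrected output reaches b_min (no clipping engaged here)
  expect_gte(as.numeric(geometric_mean_brightness(out)), 100 / 255 - 1e-9)
  # reverse standardization darkens bright images on request
  std <- adjust_brightness(bright, b_min = 0.35, standardize = TRUE)
  expect_lt(mean(std), mean(bright))
})

test_that("dark synthetic fundus triggers correction", {
  sm <- generate_sample(synth_spec(seed = 4, background_level = 60,
                                   noise_sigma = 5))
  b <- as.numeric(geometric_mean_brightness(sm$image_rgb))
  expect_lt(b, 0.35)
  out <- adjust_brightness(sm$image_rgb, b_min = 0.35)
  expect_gt(attr(out, "brightness_scale"), 1)
})

test_that("circle crop produces the square bounding the inscribed disc", {
  img <- matrix(0, 120, 200)
  img[disc_mask(c(120, 200), c(60, 100), 50)] <- 200
  out <- circle_crop(img)
  expect_equal(dim(out)[1], dim(out)[2])       # aspect ratio exactly 1
  expect_equal(dim(out)[1], 101)               # the rasterized disc spans 101 px
  expect_equal(sum(out > 0), sum(img > 0))     # full disc retained
  # idempotence and square contract
  again <- circle_crop(out)
  expect_equal(dim(again), dim(out))
  expect_equal(again, out)
  expect_error(circle_crop(matrix(0, 20, 20)), "background")
})

test_that("smooth blend cancels on constants and localizes at edges", {
  expect_equal(smooth_blend(const_rgb(77)), const_rgb(128))
  expect_equal(smooth_blend(const_rgb(200)), const_rgb(128))
  # degenerate parameters give the identity
  p_id <- enhancement_params(alpha = 1, beta = 0, gamma_offset = 0)
  img <- const_rgb(90); img[10:20, 10:20, ] <- 150
  expect_equal(smooth_blend(img, p_id), img)
  # step edge: response deviates from 128 only near the edge
  step <- matrix(60, 64, 64); step[, 33:64] <- 180
  out <- smooth_blend(step, enhancement_params(smooth_sigma_x = 4))
  expect_equal(out[32, 2], 128, tolerance = 1e-6)
  expect_equal(out[32, 62], 128, tolerance = 1e-6)
  expect_gt(max(abs(out[32, 28:38] - 128)), 20)
  # symmetric overshoot/undershoot across the edge
  expect_gt(out[32, 34], 128); expect_lt(out[32, 31], 128)
})

test_that("gaussian smoothing agrees with a direct convolution oracle", {
  set.seed(8)
  img <- matrix(runif(15 * 15, 0, 255), 15, 15)
  sig <- 1.2; k <- ceiling(4 * sig)
  g <- exp(-(-k:k)^2 / (2 * sig^2)); g <- g / sum(g)
  ker <- outer(g, g)
  reflect <- function(i, n) { while (i < 1 || i > n) { if (i < 1) i <- 1 - i; if (i > n) i <- 2 * n + 1 - i }; i }
  want <- img
  for (r in 1:15) for (c in 1:15) {
    acc <- 0
    for (dr in -k:k) for (dc in -k:k) {
      acc <- acc + ker[dr + k + 1, dc + k + 1] *
        img[reflect(r + dr, 15), reflect(c + dc, 15)]
    }
    want[r, c] <- acc
  }
  got <- fundusseg:::gaussian_smooth(img, sig)
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("CLAHE increases local contrast and respects channels", {
  expect_equal(clahe_enhance(const_rgb(120), "gray"), matrix(120, 32, 32),
               tolerance = 1)
  # low-contrast two-band image: global std strictly increases
  set.seed(5)
  img <- matrix(118, 64, 64); img[, 33:64] <- 138
  img <- img + matrix(rnorm(64 * 64, 0, 2), 64, 64)
  out <- clahe_enhance(pmin(pmax(img, 0), 255), "gray")
  expect_gt(sd(out), sd(img))
  # hsv_v mode preserves hue within quantization tolerance
  sm <- generate_sample(synth_spec(seed = 6, noise_sigma = 5))
  rgb <- sm$image_rgb
  out_v <- clahe_enhance(rgb, "hsv_v")
  h_in <- fundusseg:::rgb_to_hsv_img(rgb)["h", ]
  h_out <- fundusseg:::rgb_to_hsv_img(out_v)["h", ]
  keep <- h_in > 0.02 & h_in < 0.98   # hue is meaningless near the wrap/grey axis
  dh <- abs(h_out - h_in)[keep]
  expect_lt(median(dh), 0.02)
  expect_error(clahe_enhance(matrix(300, 8, 8), "gray"), "8-bit")
})

test_that("channel operations split, restack and swap consistently", {
  sm <- generate_sample(synth_spec(seed = 2, noise_sigma = 5))
  img <- sm$image_rgb
  pl <- channel_ops(img, "split")
  restack <- array(0, dim(img))
  restack[, , 1] <- pl$r; restack[, , 2] <- pl$g; restack[, , 3] <- pl$b
  expect_equal(restack, img)
  expect_equal(channel_ops(channel_ops(img, "swap_rgb_bgr"), "swap_rgb_bgr"),
               img)
  expect_error(channel_ops(matrix(1, 4, 4), "split"), "3-channel")
  # vessels are built strongest in green: green vessel contrast >= blue
  clean <- generate_sample(synth_spec(seed = 3, noise_sigma = 0,
                                      inhomogeneity_amplitude = 0,
                                      lesion_count = 0))
  vm <- fundusseg:::with_seed_local(3, {
    # vessel pixels: where green drops below its field median
    g <- clean$image_rgb[, , 2]
    fld <- clean$field_mask
    g < 0.8 * median(g[fld]) & fld
  })
  fld <- clean$field_mask & !vm
  g_con <- median(clean$image_rgb[, , 2][fld]) - median(clean$image_rgb[, , 2][vm])
  b_con <- median(clean$image_rgb[, , 3][fld]) - median(clean$image_rgb[, , 3][vm])
  expect_gte(g_con, b_con)
})

test_that("enhancement outputs stay in range and shape", {
  sm <- generate_sample(synth_spec(seed = 9))
  img <- sm$image_rgb
  for (out in list(smooth_blend(img), clahe_enhance(img, "hsv_v"),
                   adjust_brightness(img))) {
    expect_true(min(out) >= 0 && max(out) <= 255)
    expect_equal(dim(out)[1:2], dim(img)[1:2])
  }
})
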