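# Shared fixtures built in code.

# Random valid metadata rows for round-trip properties.
random_metadata_tbl <- function(n, seed = 1) {
  set.seed(seed)
  ga <- sample(23:41, n, replace = TRUE)
  tok <- sample(c("RC3", "RE", "ICON", "1", "2", "3"), n, replace = TRUE)
  tibble::tibble(
    patient_id = sample(1:999, n, replace = TRUE),
    sex = sample(c("F", "M"), n, replace = TRUE),
    gestational_age_weeks = ga,
    birth_weight_g = sample(480:4080, n, replace = TRUE),
    postconceptual_age_weeks = ga + sample(0:40, n, replace = TRUE),
    diagnosis_code = sample(0:13, n, replace = TRUE),
    plus_form = sample(0:2, n, replace = TRUE),
    device = c(RC3 = 1L, RE = 2L, ICON = 3L, `1` = 1L, `2` = 2L, `3` = 3L)[tok],
    device_token = tok,
    series = sample(1:12, n, replace = TRUE),
    image_index = sample(1:9, n, replace = TRUE)
  )
}

# Two-region fixture: dark disc on bright background with a faint smooth
# deterministic ramp so local variances stay informative, no random noise.
two_region_fixture <- function(dims = c(64, 64), radius = 14) {
  msk <- outer((seq_len(dims[1]) - (dims[1] + 1) / 2)^2,
               rep(1, dims[2])) +
    outer(rep(1, dims[1]), (seq_len(dims[2]) - (dims[2] + 1) / 2)^2)
  msk <- msk <= radius^2
  ramp <- outer(seq_len(dims[1]), seq_len(dims[2]),
                function(i, j) 0.2 * i + 0.15 * j)
  img <- matrix(160, dims[1], dims[2]) + ramp
  img[msk] <- 60 + ramp[msk]
  list(image = img, mask = msk)
}

small_params <- function(...) {
  lgdf_params(kernel_sigma = 1.5, kernel_radius = 3, ...)
}
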