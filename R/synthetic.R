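# Seeded synthetic fundus generator: the test substrate standing in for the
# downloadable image dataset.  Not a photorealistic retina simulator -- it
# emulates the features the segmentation pipeline is sensitive to: a dark
# circular field with vignetting, vessel-like curves strongest in the green
# channel, an optic-disc blob, hemorrhage-like dark lesions with known
# masks, a smooth multiplicative inhomogeneity field, and additive noise.

# Evaluate code under a fixed, named RNG without disturbing the caller's
# stream.  Mersenne-Twister / Inversion are pinned so fixtures are stable
# across sessions and releases.
with_seed_local <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

#' Specification of a synthetic fundus sample
#'
#' Defaults are the stress conditions the segmentation engine is validated
#' under: one hemorrhage-like dark lesion of contrast 100 on a background of
#' 160 within a 128 x 128 field, up to ±30% smooth multiplicative
#' intensity inhomogeneity and additive Gaussian noise of sigma 10.
#'
#' @param seed RNG seed (integer).
#' @param size Image dimensions `c(rows, cols)`; overridden by
#'   `device_profile`.
#' @param background_level Mean fundus intensity of the fused red/green
#'   field (0--255).
#' @param lesion_count Number of disjoint lesions.
#' @param lesion_radius_range Range `c(min, max)` of lesion radii, pixels
#'   (>= 3).
#' @param lesion_contrast Intensity drop of lesions below the background
#'   (must exceed `noise_sigma`).
#' @param vessel_count,vessel_contrast Number and intensity drop of
#'   vessel-like curves (strongest in the green channel).
#' @param inhomogeneity_amplitude Amplitude of the multiplicative
#'   low-frequency shading field `b(x) = 1 + a f(x)` with `|f| <= 1`.
#' @param noise_sigma Additive Gaussian noise standard deviation.
#' @param device_profile Optional device preset 1/2/3 selecting the native
#'   resolutions 640 x 480, 1440 x 1080 or 1240 x 1240.
#' @return A `synth_spec` list.
#' @export
synth_spec <- function(seed = 1, size = c(128, 128), background_level = 160,
                       lesion_count = 1, lesion_radius_range = c(10, 20),
                       lesion_contrast = 100, vessel_count = 4,
                       vessel_contrast = 60, inhomogeneity_amplitude = 0.3,
                       noise_sigma = 10, device_profile = NULL) {
  if (!is.null(device_profile)) {
    size <- switch(as.character(device_profile),
      "1" = c(480, 640), "2" = c(1080, 1440), "3" = c(1240, 1240),
      abort("device_profile must be 1, 2 or 3"))
  }
  stopifnot(all(size > 0), lesion_radius_range[1] >= 3,
            lesion_radius_range[2] >= lesion_radius_range[1],
            lesion_contrast > noise_sigma, lesion_count >= 0,
            inhomogeneity_amplitude >= 0, noise_sigma >= 0)
  structure(list(seed = as.integer(seed), size = as.integer(size),
                 background_level = background_level,
                 lesion_count = lesion_count,
                 lesion_radius_range = lesion_radius_range,
                 lesion_contrast = lesion_contrast,
                 vessel_count = vessel_count, vessel_contrast = vessel_contrast,
                 inhomogeneity_amplitude = inhomogeneity_amplitude,
                 noise_sigma = noise_sigma,
                 device_profile = device_profile %||% NA_integer_),
            class = "synth_spec")
}

# Smoothly deformed ellipse-ish lesion mask: boundary radius
# r(theta) = r0 (1 + sum_k a_k cos(k theta + phase_k)).
deformed_blob <- function(dims, center, r0) {
  a <- runif(2, 0.05, 0.15)
  ph <- runif(2, 0, 2 * pi)
  elong <- runif(1, 0, 0.25)
  ang <- runif(1, 0, pi)
  rr <- outer(seq_len(dims[1]) - center[1], rep(1, dims[2]))
  cc <- outer(rep(1, dims[1]), seq_len(dims[2]) - center[2])
  th <- atan2(rr, cc)
  rmax <- r0 * (1 + a[1] * cos(2 * th + ph[1]) + a[2] * cos(3 * th + ph[2]) +
                  elong * cos(2 * (th - ang)))
  sqrt(rr^2 + cc^2) <= rmax
}

# Stamp a polyline of (row, col) points into a map with round brushes.
stamp_curve <- function(map, pts, width) {
  n <- nrow(map); p <- ncol(map)
  w <- ceiling(width)
  off <- expand.grid(dr = -w:w, dc = -w:w)
  off <- off[off$dr^2 + off$dc^2 <= width^2 + 0.5, ]
  for (i in seq_len(nrow(pts))) {
    r <- round(pts[i, 1] + off$dr); c <- round(pts[i, 2] + off$dc)
    ok <- r >= 1 & r <= n & c >= 1 & c <= p
    map[cbind(r[ok], c[ok])] <- 1
  }
  map
}

#' Generate one synthetic fundus sample
#'
#' Deterministic given `spec$seed`.  Construction order: base fundus colour
#' (red/green fused level equals `background_level`), optic-disc blob,
#' vessel curves, lesions (which overwrite what is beneath them, so that in
#' the noise-free homogeneous case the lesion interior of the fused field
#' equals `background_level - lesion_contrast` exactly), radial vignetting
#' near the field rim, multiplicative inhomogeneity, additive noise,
#' clipping to \[0, 255\].  Lesions are placed in the flat interior of the
#' field (inside 65% of the field radius) so the vignette does not touch
#' them.
#'
#' @param spec A [synth_spec()].
#' @return A `synthetic_fundus` list: `image_rgb` (H x W x 3), `lesion_masks`
#'   (list of logical matrices, disjoint), `metadata` (one-row tibble in the
#'   naming-convention vocabulary), `truth` (the spec), `field_mask`.
#' @export
generate_sample <- function(spec = synth_spec()) {
  with_seed_local(spec$seed, generate_sample_impl(spec))
}

generate_sample_impl <- function(spec) {
  H <- spec$size[1]; W <- spec$size[2]
  ctr <- c((H + 1) / 2, (W + 1) / 2)
  R <- 0.47 * min(H, W)
  rr <- outer(seq_len(H) - ctr[1], rep(1, W))
  cc <- outer(rep(1, H), seq_len(W) - ctr[2])
  dist <- sqrt(rr^2 + cc^2)
  field <- dist <= R

  bg <- spec$background_level
  chR <- matrix(bg + 30, H, W)
  chG <- matrix(bg - 30, H, W)
  chB <- matrix(0.45 * bg, H, W)

  # optic disc: bright blob off-centre
  oang <- runif(1, 0, 2 * pi)
  octr <- ctr + 0.45 * R * c(sin(oang), cos(oang))
  oprof <- exp(-((rr - (octr[1] - ctr[1]))^2 + (cc - (octr[2] - ctr[2]))^2) /
                 (2 * (0.1 * min(H, W))^2))
  chR <- chR + 50 * oprof; chG <- chG + 45 * oprof; chB <- chB + 25 * oprof

  # vessels: gently curving strokes radiating from the optic disc
  vmap <- matrix(0, H, W)
  for (v in seq_len(spec$vessel_count)) {
    ang <- runif(1, 0, 2 * pi)
    curv <- runif(1, -0.02, 0.02)
    len <- runif(1, 0.8, 1.6) * R
    steps <- ceiling(len / 0.7)
    pts <- matrix(0, steps, 2)
    pos <- octr
    for (s in seq_len(steps)) {
      pos <- pos + 0.7 * c(sin(ang), cos(ang))
      ang <- ang + curv
      pts[s, ] <- pos
    }
    vmap <- stamp_curve(vmap, pts, width = runif(1, 1.2, 2.2))
  }
  chR <- chR - 0.55 * spec$vessel_contrast * vmap
  chG <- chG - spec$vessel_contrast * vmap
  chB <- chB - 0.2 * spec$vessel_contrast * vmap

  # lesions: disjoint deformed blobs in the flat interior of the field
  masks <- list()
  occupied <- matrix(FALSE, H, W)
  for (l in seq_len(spec$lesion_count)) {
    placed <- FALSE
    for (att in seq_len(100)) {
      r0 <- runif(1, spec$lesion_radius_range[1], spec$lesion_radius_range[2])
      maxd <- 0.65 * R - 1.2 * r0
      if (maxd <= 0) next
      d <- sqrt(runif(1)) * maxd
      a <- runif(1, 0, 2 * pi)
      lctr <- ctr + d * c(sin(a), cos(a))
      m <- deformed_blob(c(H, W), lctr, r0)
      if (!any(m & occupied)) {
        masks[[l]] <- m
        occupied <- occupied | m
        placed <- TRUE
        break
      }
    }
    if (!placed) abort("could not place a lesion inside the field after 100 attempts")
  }
  if (length(masks)) {
    lesR <- bg + 30 - spec$lesion_contrast
    lesG <- bg - 30 - spec$lesion_contrast
    lesB <- 0.45 * bg - 0.3 * spec$lesion_contrast
    chR[occupied] <- lesR; chG[occupied] <- lesG; chB[occupied] <- lesB
  }

  # vignette: flat (exactly 1) inside 80% of the field radius, cosine
  # rolloff to 0.55 at the rim, black outside the field
  vgn <- matrix(0, H, W)
  vgn[field] <- 1
  rim <- field & dist > 0.8 * R
  t <- (dist[rim] - 0.8 * R) / (0.2 * R)
  vgn[rim] <- 1 - 0.45 * (1 - cos(pi * t)) / 2

  # multiplicative low-frequency inhomogeneity, max |f| = 1
  if (spec$inhomogeneity_amplitude > 0) {
    fr <- runif(2, 0.5, 1.5); ph <- runif(2, 0, 2 * pi); mix <- runif(1, 0.3, 0.7)
    f <- mix * sin(2 * pi * fr[1] * (rr / H) + ph[1]) +
      (1 - mix) * sin(2 * pi * fr[2] * (cc / W) + ph[2])
    f <- f / max(abs(f))
    b <- 1 + spec$inhomogeneity_amplitude * f
  } else {
    b <- matrix(1, H, W)
  }

  img <- array(0, c(H, W, 3))
  img[, , 1] <- chR * vgn * b
  img[, , 2] <- chG * vgn * b
  img[, , 3] <- chB * vgn * b
  if (spec$noise_sigma > 0) {
    img <- img + array(rnorm(length(img), 0, spec$noise_sigma), dim(img))
  }
  img <- clip255(img)

  structure(
    list(image_rgb = img, lesion_masks = masks,
         metadata = random_patient_metadata(1),
         truth = spec, field_mask = field),
    class = "synthetic_fundus"
  )
}

# Plausible cohort attributes mirroring the published population: GA ~
# N(33, 5) truncated to [23, 41], BW ~ N(2017, 1024) truncated to
# [480, 4080], diagnoses dominated by physiological findings and
# haemorrhages, plus form almost always normal.
random_patient_metadata <- function(n, patient_id = seq_len(n)) {
  rtrunc <- function(n, mean, sd, lo, hi) {
    x <- round(rnorm(n, mean, sd))
    pmin(pmax(x, lo), hi)
  }
  ga <- rtrunc(n, 33, 5, 23, 41)
  tibble(
    patient_id = as.integer(patient_id),
    sex = sample(c("F", "M"), n, replace = TRUE),
    gestational_age_weeks = as.integer(ga),
    birth_weight_g = as.integer(rtrunc(n, 2017, 1024, 480, 4080)),
    postconceptual_age_weeks = as.integer(ga + sample(1:12, n, replace = TRUE)),
    diagnosis_code = sample(c(0L, 11L, 2L, 3L, 9L), n, replace = TRUE,
                            prob = c(0.45, 0.35, 0.08, 0.06, 0.06)),
    plus_form = sample(c(0L, 2L), n, replace = TRUE, prob = c(0.97, 0.03)),
    device = sample(1:3, n, replace = TRUE),
    device_token = NA_character_,
    series = 1L,
    image_index = 1L
  ) |>
    dplyr::mutate(device_token = names(.device_tokens)[.data$device])
}

#' Generate a convention-compliant synthetic dataset tree
#'
#' Writes a folder tree mirroring the published dataset layouts — an
#' `images/<ID>/<series>/` hierarchy plus a flat `images_stack/` mirror of
#' the same files — with convention-compliant filenames, ground-truth
#' lesion masks under `masks/`, and a metadata table
#' (`infant_retinal_database_info.csv`) consistent with the files.
#'
#' @param n_patients Number of patients (0 gives an empty tree).
#' @param spec A [synth_spec()]; per-image seeds are derived from
#'   `spec$seed`.
#' @param out_root Output directory.
#' @param series_per_patient,images_per_series Tree shape (defaults 2, 3).
#' @return Tibble of the generated metadata (one row per image, with
#'   `name` and `path`), invisibly.
#' @export
generate_dataset_tree <- function(n_patients, spec = synth_spec(), out_root,
                                  series_per_patient = 2,
                                  images_per_series = 3) {
  dir.create(file.path(out_root, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_root, "images_stack"), showWarnings = FALSE)
  dir.create(file.path(out_root, "masks"), showWarnings = FALSE)
  if (n_patients == 0) {
    warn("empty tree requested: no images generated")
    readr::write_csv(random_patient_metadata(0),
                     file.path(out_root, "infant_retinal_database_info.csv"))
    return(invisible(tibble()))
  }
  meta <- with_seed_local(spec$seed, random_patient_metadata(n_patients))
  rows <- list()
  img_seed <- spec$seed
  for (i in seq_len(n_patients)) {
    for (s in seq_len(series_per_patient)) {
      pa <- meta$postconceptual_age_weeks[i] + 4L * (s - 1L)
      for (k in seq_len(images_per_series)) {
        row <- meta[i, ]
        row$series <- as.integer(s)
        row$image_index <- as.integer(k)
        row$postconceptual_age_weeks <- pa
        name <- format_fundus_filename(row, ext = ".jpg")
        img_seed <- (img_seed * 69069 + 1013904223) %% 2147483647
        sm <- spec; sm$seed <- as.integer(img_seed)
        samp <- generate_sample(sm)
        dir1 <- file.path(out_root, "images", sprintf("%03d", row$patient_id),
                          sprintf("S%02d", s))
        dir.create(dir1, recursive = TRUE, showWarnings = FALSE)
        write_fundus(samp$image_rgb, file.path(dir1, name))
        write_fundus(samp$image_rgb, file.path(out_root, "images_stack", name))
        for (m in seq_along(samp$lesion_masks)) {
          write_fundus(samp$lesion_masks[[m]],
                       file.path(out_root, "masks",
                                 sub("\\.jpg$", sprintf("_mask%d.png", m), name)))
        }
        row$name <- name
        row$path <- file.path(dir1, name)
        rows[[length(rows) + 1]] <- row
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  wb <- dplyr::select(out, ID = "patient_id", SEX = "sex",
                      GESTATIONAL_AGE = "gestational_age_weeks",
                      BIRTH_WEIGHT = "birth_weight_g",
                      POSTCONCEPTUAL_AGE = "postconceptual_age_weeks",
                      DIAGNOSIS_CODE = "diagnosis_code", PLUS_FORM = "plus_form",
                      DEVICE = "device", DEVICE_TOKEN = "device_token",
                      SERIES_NUMBER = "series", IMAGE_NUMBER = "image_index",
                      NAME = "name")
  readr::write_csv(wb, file.path(out_root, "infant_retinal_database_info.csv"))
  invisible(out)
}

#' Monochrome disc-lesion fixture
#'
#' The canonical recovery benchmark: a dark disc of known radius on a
#' uniform background, optionally shaded by a smooth multiplicative field
#' and corrupted by Gaussian noise.  Returns the image together with the
#' exact ground-truth mask.
#'
#' @param dims Image dimensions (default `c(128, 128)`).
#' @param center,radius Disc geometry (defaults: image centre, radius 20).
#' @param background,lesion_intensity Intensities (defaults 160 and 60).
#' @param noise_sigma Additive Gaussian noise sd (default 0).
#' @param inhomogeneity_amplitude Amplitude of a smooth multiplicative
#'   shading field (default 0).
#' @param seed RNG seed for noise/shading.
#' @return List with `image` (matrix) and `mask` (logical matrix).
#' @export
synth_disc_image <- function(dims = c(128, 128), center = (dims + 1) / 2,
                             radius = 20, background = 160,
                             lesion_intensity = 60, noise_sigma = 0,
                             inhomogeneity_amplitude = 0, seed = 1) {
  with_seed_local(seed, {
    mask <- disc_mask(dims, center, radius)
    img <- matrix(background, dims[1], dims[2])
    img[mask] <- lesion_intensity
    if (inhomogeneity_amplitude > 0) {
      rr <- outer(seq_len(dims[1]) / dims[1], rep(1, dims[2]))
      cc <- outer(rep(1, dims[1]), seq_len(dims[2]) / dims[2])
      ph <- runif(2, 0, 2 * pi)
      f <- 0.6 * sin(2 * pi * 0.9 * rr + ph[1]) + 0.4 * sin(2 * pi * 1.1 * cc + ph[2])
      f <- f / max(abs(f))
      img <- img * (1 + inhomogeneity_amplitude * f)
    }
    if (noise_sigma > 0) {
      img <- img + matrix(rnorm(length(img), 0, noise_sigma), dims[1], dims[2])
    }
    list(image = img, mask = mask)
  })
}
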