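#' Parameters of the local Gaussian distribution fitting contour
#'
#' All tunables of the segmentation model.  The region energy models local
#' intensities inside and outside the contour as Gaussians with spatially
#' varying mean and variance, estimated within a truncated Gaussian window
#' \eqn{\omega} of dispersion `kernel_sigma` and support radius
#' `kernel_radius`; the level-set field is evolved by explicit gradient
#' descent with a length penalty `nu` and a signed-distance regularizer
#' `mu`.
#'
#' @param kernel_sigma Dispersion of the localization window, pixels
#'   (default 3).
#' @param kernel_radius Truncation radius of the window (default
#'   `ceiling(2 * kernel_sigma)`).
#' @param epsilon Width of the smoothed Heaviside/Dirac pair (default 1).
#' @param nu Contour length penalty weight (default 1).  The data force of
#'   this model is normalized by the local variances and is therefore O(1)
#'   and invariant to the intensity scale, so the length weight must be
#'   O(1) as well; the `0.001 * 255^2` convention of the un-normalized
#'   local fitting models would overwhelm the force and collapse the
#'   contour.
#' @param mu Distance-regularization weight (default 1).
#' @param dt Explicit gradient-descent time step (default 0.1).
#' @param iterations Number of evolution steps (default 400, the setting
#'   used for all reported lesion segmentations).
#' @param seed_center Seed point `c(row, col)` inside the lesion.
#' @param seed_radius Radius of the initial circle, pixels.
#' @param c0 Magnitude of the binary level-set initialization (default 2).
#' @param var_floor Lower bound applied to the local variance fields
#'   (default 1e-6).
#' @return An `lgdf_params` list.
#' @export
lgdf_params <- function(kernel_sigma = 3,
                        kernel_radius = ceiling(2 * kernel_sigma),
                        epsilon = 1, nu = 1, mu = 1,
                        dt = 0.1, iterations = 400,
                        seed_center = NULL, seed_radius = NULL,
                        c0 = 2, var_floor = 1e-6) {
  stopifnot(kernel_sigma > 0, kernel_radius >= kernel_sigma, epsilon > 0,
            nu > 0, mu > 0, dt > 0, iterations >= 1, c0 > 0, var_floor > 0)
  structure(list(kernel_sigma = kernel_sigma,
                 kernel_radius = as.integer(ceiling(kernel_radius)),
                 epsilon = epsilon, nu = nu, mu = mu, dt = dt,
                 iterations = as.integer(iterations),
                 seed_center = seed_center, seed_radius = seed_radius,
                 c0 = c0, var_floor = var_floor),
            class = "lgdf_params")
}

#' Smoothed Heaviside and Dirac surrogates
#'
#' Differentiable region-membership and contour-localization functions used
#' by the level-set energy:
#' \eqn{H_\varepsilon(x) = \tfrac12[1 + \tfrac{2}{\pi}\arctan(x/\varepsilon)]}
#' and its derivative
#' \eqn{\delta_\varepsilon(x) = \tfrac{1}{\pi}\,\varepsilon/(\varepsilon^2 + x^2)}.
#'
#' @param x Numeric vector/matrix (typically the level-set field).
#' @param epsilon Smoothing width (> 0).
#' @return Same shape as `x`.
#' @export
lgdf_heaviside <- function(x, epsilon = 1) {
  0.5 * (1 + (2 / pi) * atan(x / epsilon))
}

#' @rdname lgdf_heaviside
#' @export
lgdf_delta <- function(x, epsilon = 1) {
  (1 / pi) * epsilon / (epsilon^2 + x^2)
}

#' Initialize the level-set field from a seed circle
#'
#' Binary step initialization: \eqn{\Phi = -c_0} inside the seed circle,
#' \eqn{+c_0} outside.  The lesion is reported as the region sharing the
#' seed's (negative) sign.
#'
#' @param dims Image dimensions `c(rows, cols)`.
#' @param center Seed centre `c(row, col)`.
#' @param radius Seed circle radius in pixels (> 0).
#' @param c0 Initialization magnitude.
#' @return Numeric matrix `phi`.
#' @export
init_level_set <- function(dims, center, radius, c0 = 2) {
  if (length(center) != 2 || anyNA(center)) abort("seed center must be c(row, col)")
  if (is.null(radius) || radius <= 0) abort("seed radius must be positive")
  if (center[1] - radius < 1 || center[1] + radius > dims[1] ||
      center[2] - radius < 1 || center[2] + radius > dims[2]) {
    abort("seed circle must lie fully inside the image")
  }
  inside <- disc_mask(dims, center, radius)
  phi <- matrix(c0, dims[1], dims[2])
  phi[inside] <- -c0
  phi
}

# Convolution context shared across the evolution loop: the cached-FFT
# window convolution plus the image moments it never has to recompute.
lgdf_context <- function(image, params) {
  kern <- gaussian_window(params$kernel_sigma, params$kernel_radius)
  cv <- make_conv(dim(image), kern)
  ones <- matrix(1, nrow(image), ncol(image))
  mom <- cv$pair(ones, image)
  list(conv = cv, w1 = mom[[1]], wI = mom[[2]], wI2 = cv$one(image^2),
       kernel = kern)
}

#' Local Gaussian statistics of the two regions
#'
#' Window-weighted means and variances of the image inside and outside the
#' contour, using the smoothed memberships
#' \eqn{M_{1,\varepsilon} = H_\varepsilon(\Phi)} (region \eqn{\Phi > 0}) and
#' \eqn{M_{2,\varepsilon} = 1 - H_\varepsilon(\Phi)}:
#' \deqn{u_i(x) = \frac{\omega * (I M_i)}{\omega * M_i}, \qquad
#'   \sigma_i^2(x) = \frac{\omega * (I^2 M_i)}{\omega * M_i} - u_i(x)^2.}
#' Denominators are floored at 1e-10 and variances at `var_floor`.
#'
#' @param image Monochrome matrix.
#' @param phi Level-set field.
#' @param params An [lgdf_params()] list.
#' @param ctx Internal convolution context (built automatically).
#' @return List with matrices `u1`, `u2`, `var1`, `var2`.
#' @export
local_gaussian_stats <- function(image, phi, params = lgdf_params(), ctx = NULL) {
  if (is.null(ctx)) ctx <- lgdf_context(image, params)
  M1 <- lgdf_heaviside(phi, params$epsilon)
  p <- ctx$conv$pair(M1, image * M1)
  wM1 <- p[[1]]; wIM1 <- p[[2]]
  wI2M1 <- ctx$conv$one(image^2 * M1)
  wM2 <- ctx$w1 - wM1
  wIM2 <- ctx$wI - wIM1
  wI2M2 <- ctx$wI2 - wI2M1
  floor_den <- function(x) pmax(x, 1e-10)
  u1 <- wIM1 / floor_den(wM1)
  u2 <- wIM2 / floor_den(wM2)
  # local residual: u^2 (w*M) - 2 u (w*IM) + w*I^2M, normalized by w*M
  var1 <- (u1^2 * wM1 - 2 * u1 * wIM1 + wI2M1) / floor_den(wM1)
  var2 <- (u2^2 * wM2 - 2 * u2 * wIM2 + wI2M2) / floor_den(wM2)
  list(u1 = u1, u2 = u2,
       var1 = pmax(var1, params$var_floor),
       var2 = pmax(var2, params$var_floor))
}

#' Data force of the LGDF contour
#'
#' The image-driven term \eqn{e_1 - e_2} of the gradient-descent flow,
#' \deqn{e_i(x) = \int \omega(y - x)\Big[\log \sigma_i(y) +
#'   \frac{(u_i(y) - I(x))^2}{2\sigma_i(y)^2}\Big] dy,}
#' evaluated through the convolution identity
#' \eqn{e_i = \omega * A_i - I\, (\omega * B_i) + \tfrac{I^2}{2} (\omega * C_i)}
#' with \eqn{A_i = \log\sigma_i + u_i^2 / (2\sigma_i^2)},
#' \eqn{B_i = u_i/\sigma_i^2}, \eqn{C_i = 1/\sigma_i^2}.  Because means and
#' standard deviations enter only through these ratios, the force is
#' invariant to a multiplicative rescaling of image and statistics — the
#' property that makes the model robust to smooth intensity inhomogeneity.
#'
#' @inheritParams local_gaussian_stats
#' @param stats Result of [local_gaussian_stats()].
#' @return Matrix `e1 - e2`.
#' @export
lgdf_data_force <- function(image, stats, params = lgdf_params(), ctx = NULL) {
  if (is.null(ctx)) ctx <- lgdf_context(image, params)
  A <- (0.5 * log(stats$var1) + stats$u1^2 / (2 * stats$var1)) -
       (0.5 * log(stats$var2) + stats$u2^2 / (2 * stats$var2))
  B <- stats$u1 / stats$var1 - stats$u2 / stats$var2
  C <- 1 / stats$var1 - 1 / stats$var2
  p <- ctx$conv$pair(A, B)
  wC <- ctx$conv$one(C)
  p[[1]] - image * p[[2]] + (image^2 / 2) * wC
}

# Central-difference gradient, curvature and Laplacian with replicate
# (Neumann) boundary.
grad_central <- function(phi) {
  gx <- (shift_clamp(phi, 0L, 1L) - shift_clamp(phi, 0L, -1L)) / 2
  gy <- (shift_clamp(phi, 1L, 0L) - shift_clamp(phi, -1L, 0L)) / 2
  list(gx = gx, gy = gy)
}

curvature <- function(phi) {
  g <- grad_central(phi)
  raw <- sqrt(g$gx^2 + g$gy^2)
  nrm <- pmax(raw, 1e-10)
  # on numerically flat plateaus the gradient direction is pure round-off;
  # force the curvature to its continuum value 0 there instead of
  # amplifying noise through the 0/0 normalization
  flat <- raw < 1e-6
  nx <- g$gx / nrm
  ny <- g$gy / nrm
  nx[flat] <- 0
  ny[flat] <- 0
  dnx <- (shift_clamp(nx, 0L, 1L) - shift_clamp(nx, 0L, -1L)) / 2
  dny <- (shift_clamp(ny, 1L, 0L) - shift_clamp(ny, -1L, 0L)) / 2
  dnx + dny
}

laplacian5 <- function(phi) {
  shift_clamp(phi, 0L, 1L) + shift_clamp(phi, 0L, -1L) +
    shift_clamp(phi, 1L, 0L) + shift_clamp(phi, -1L, 0L) - 4 * phi
}

new_lgdf_state <- function(phi, stats, iteration = 0L) {
  structure(c(list(phi = phi), stats, list(iteration = as.integer(iteration))),
            class = "lgdf_state")
}

#' One explicit gradient-descent step of the level-set flow
#'
#' Refreshes the local statistics, then performs one explicit Euler update
#' \deqn{\Phi \leftarrow \Phi + \Delta t\,[\, -\delta_\varepsilon(\Phi)(e_1 - e_2)
#'   + \nu\,\delta_\varepsilon(\Phi)\,\kappa
#'   + \mu(\nabla^2\Phi - \kappa)\,],}
#' where \eqn{\kappa = \mathrm{div}(\nabla\Phi/|\nabla\Phi|)} is computed by
#' central differences with \eqn{|\nabla\Phi|} floored at 1e-10, the
#' Laplacian by the 5-point stencil, and borders are replicate (Neumann).
#'
#' @inheritParams local_gaussian_stats
#' @param state An `lgdf_state` (from [init_level_set()] wrapped by
#'   [segment_lesion()], or a previous step).  A bare `phi` matrix is also
#'   accepted.
#' @return Updated `lgdf_state`.
#' @export
lgdf_evolve_step <- function(image, state, params = lgdf_params(), ctx = NULL) {
  if (is.null(ctx)) ctx <- lgdf_context(image, params)
  phi <- if (is.matrix(state)) state else state$phi
  iter <- if (is.matrix(state)) 0L else state$iteration
  stats <- local_gaussian_stats(image, phi, params, ctx)
  force <- lgdf_data_force(image, stats, params, ctx)
  dlt <- lgdf_delta(phi, params$epsilon)
  kap <- curvature(phi)
  phi_new <- phi + params$dt * (
    -dlt * force + params$nu * dlt * kap +
      params$mu * (laplacian5(phi) - kap)
  )
  if (!all(is.finite(phi_new))) {
    abort("level-set update produced non-finite values: numerical instability, try a smaller dt")
  }
  new_lgdf_state(phi_new, stats, iter + 1L)
}

#' Total level-set energy
#'
#' The \eqn{\varepsilon}-smoothed objective
#' \eqn{F_\varepsilon = E^{LGDF}_\varepsilon + \nu L_\varepsilon(\Phi) + \mu P(\Phi)}:
#' the local Gaussian fitting energy (double window integral, evaluated by
#' the same convolution algebra as the force), the contour length
#' \eqn{L_\varepsilon = \sum |\nabla H_\varepsilon(\Phi)|}, and the
#' signed-distance penalty \eqn{P = \sum \tfrac12(|\nabla\Phi| - 1)^2}.
#'
#' @inheritParams lgdf_evolve_step
#' @return Scalar energy.
#' @export
lgdf_energy <- function(image, state, params = lgdf_params(), ctx = NULL) {
  if (is.null(ctx)) ctx <- lgdf_context(image, params)
  phi <- if (is.matrix(state)) state else state$phi
  stats <- if (is.matrix(state) || is.null(state$u1)) {
    local_gaussian_stats(image, phi, params, ctx)
  } else {
    state[c("u1", "u2", "var1", "var2")]
  }
  M1 <- lgdf_heaviside(phi, params$epsilon)
  M2 <- 1 - M1
  ehat <- function(u, v) {
    A <- 0.5 * log(2 * pi * v) + u^2 / (2 * v)
    B <- u / v
    C <- 1 / v
    p <- ctx$conv$pair(A, B)
    p[[1]] - image * p[[2]] + (image^2 / 2) * ctx$conv$one(C)
  }
  e_lgdf <- sum(M1 * ehat(stats$u1, stats$var1) + M2 * ehat(stats$u2, stats$var2))
  gH <- grad_central(M1)
  g <- grad_central(phi)
  nrm <- sqrt(g$gx^2 + g$gy^2)
  len <- sum(sqrt(gH$gx^2 + gH$gy^2))
  pen <- sum(0.5 * (nrm - 1)^2)
  e_lgdf + params$nu * len + params$mu * pen
}

#' Segment a retinal lesion with the LGDF active contour
#'
#' End-to-end segmentation of one seed-selected lesion: optional
#' preprocessing (red/green fusion, adaptive equalization, edge-preserving
#' smoothing), binary seed-circle initialization, `iterations` explicit
#' gradient-descent steps of the level-set flow, and extraction of the
#' connected component of \eqn{\{\Phi < 0\}} containing the seed.  The
#' procedure is fully deterministic.
#'
#' @param image RGB array or monochrome matrix on \[0, 255\].
#' @param params An [lgdf_params()] list; `seed_center` and `seed_radius`
#'   must be set (or passed here).
#' @param seed_center,seed_radius Convenience overrides of the
#'   corresponding `params` entries.
#' @param preprocess Run the preprocessing pipeline first (default TRUE).
#' @param filter Smoother used by preprocessing: `"bilateral"` (default),
#'   `"median"` or `"none"`.
#' @param fparams,enh Filter/CLAHE parameter lists for preprocessing.
#' @param trace_every Record the total energy every this many iterations
#'   (0 disables the trace; default 50).
#' @return A `fundus_seg` object: `mask` (logical matrix), `state` (final
#'   `lgdf_state`), `trace` (tibble of iteration/energy), `input`
#'   (monochrome field segmented), `params`.
#' @examples
#' img <- synth_disc_image(dims = c(64, 64), radius = 12, noise_sigma = 5,
#'                         seed = 1)
#' seg <- segment_lesion(img$image, lgdf_params(iterations = 150),
#'                       seed_center = c(32, 32), seed_radius = 6,
#'                       preprocess = FALSE)
#' dice_coefficient(seg$mask, img$mask)
#' @export
segment_lesion <- function(image, params = lgdf_params(),
                           seed_center = NULL, seed_radius = NULL,
                           preprocess = TRUE,
                           filter = c("bilateral", "median", "none"),
                           fparams = filter_params(),
                           enh = enhancement_params(),
                           trace_every = 50) {
  filter <- match.arg(filter)
  if (!is.null(seed_center)) params$seed_center <- seed_center
  if (!is.null(seed_radius)) params$seed_radius <- seed_radius
  if (is.null(params$seed_center) || is.null(params$seed_radius)) {
    abort("a seed circle (seed_center, seed_radius) is required")
  }
  mono <- if (is_rgb(image)) {
    if (preprocess) preprocess_fundus(image, filter = filter,
                                      params = fparams, enh = enh)
    else fuse_red_green(image)
  } else {
    if (preprocess) preprocess_fundus(image, filter = filter,
                                      params = fparams, enh = enh)
    else image
  }
  ctx <- lgdf_context(mono, params)
  phi <- init_level_set(dim(mono), params$seed_center, params$seed_radius,
                        params$c0)
  state <- structure(list(phi = phi, iteration = 0L), class = "lgdf_state")
  trace <- list()
  for (it in seq_len(params$iterations)) {
    state <- lgdf_evolve_step(mono, state, params, ctx)
    if (trace_every > 0 && (it %% trace_every == 0 || it == params$iterations)) {
      trace[[length(trace) + 1]] <-
        tibble(iteration = it, energy = lgdf_energy(mono, state, params, ctx))
    }
  }
  mask <- seed_component(state$phi < 0, params$seed_center)
  if (!any(mask)) warn("segmentation collapsed: empty final region")
  structure(
    list(mask = mask, state = state,
         trace = if (length(trace)) dplyr::bind_rows(trace)
                 else tibble(iteration = integer(), energy = double()),
         input = mono, params = params, filter = if (preprocess) filter else "none"),
    class = "fundus_seg"
  )
}

# Connected component (8-connectivity) of a logical mask containing the
# seed; everything else is discarded.
seed_component <- function(mask, seed_center) {
  if (!any(mask)) return(mask)
  lab <- EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
  id <- lab[round(seed_center[1]), round(seed_center[2])]
  if (id == 0) {
    return(matrix(FALSE, nrow(mask), ncol(mask)))
  }
  lab == id
}

#' @export
print.fundus_seg <- function(x, ...) {
  cat(sprintf(
    "LGDF lesion segmentation: %d px lesion on a %d x %d field (%d iterations, %s filter)\n",
    sum(x$mask), nrow(x$mask), ncol(x$mask), x$state$iteration, x$filter))
  invisible(x)
}
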