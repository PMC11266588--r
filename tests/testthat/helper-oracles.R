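# Independent brute-force oracles: direct per-pixel evaluations of the
# model equations, written without reusing any of the package's internal
# convolution/padding machinery.

# Gaussian window w(d) = exp(-|d|^2 / 2 sigma^2) on |d| <= rho, else 0,
# normalized to sum 1 over its discrete support.
oracle_window <- function(sigma, rho) {
  w <- matrix(0, 2 * rho + 1, 2 * rho + 1)
  for (i in -rho:rho) for (j in -rho:rho) {
    if (i^2 + j^2 <= rho^2) {
      w[i + rho + 1, j + rho + 1] <- exp(-(i^2 + j^2) / (2 * sigma^2))
    }
  }
  w / sum(w)
}

oracle_heaviside <- function(x, eps) 0.5 * (1 + (2 / pi) * atan(x / eps))
oracle_delta <- function(x, eps) (1 / pi) * eps / (eps^2 + x^2)

# Bilateral filter: literal double loop with mirror ("symmetric") padding.
oracle_bilateral <- function(img, sigma_r, sigma_s, w) {
  n <- nrow(img); p <- ncol(img)
  reflect <- function(i, n) {
    while (i < 1 || i > n) {
      if (i < 1) i <- 1 - i
      if (i > n) i <- 2 * n + 1 - i
    }
    i
  }
  out <- img
  for (r in 1:n) for (c in 1:p) {
    num <- 0; den <- 0
    for (dr in -w:w) for (dc in -w:w) {
      v <- img[reflect(r + dr, n), reflect(c + dc, p)]
      wt <- exp(-(v - img[r, c])^2 / (2 * sigma_r^2)) *
        exp(-(dr^2 + dc^2) / (2 * sigma_s^2))
      num <- num + v * wt
      den <- den + wt
    }
    out[r, c] <- num / den
  }
  out
}

oracle_median <- function(img, kernel) {
  w <- (kernel - 1) / 2
  n <- nrow(img); p <- ncol(img)
  reflect <- function(i, n) {
    while (i < 1 || i > n) {
      if (i < 1) i <- 1 - i
      if (i > n) i <- 2 * n + 1 - i
    }
    i
  }
  out <- img
  for (r in 1:n) for (c in 1:p) {
    vals <- numeric(0)
    for (dr in -w:w) for (dc in -w:w) {
      vals <- c(vals, img[reflect(r + dr, n), reflect(c + dc, p)])
    }
    out[r, c] <- median(vals)
  }
  out
}

# Local means and variances: direct double loop over in-image neighbours.
oracle_local_stats <- function(img, phi, sigma, rho, eps, var_floor) {
  w <- oracle_window(sigma, rho)
  n <- nrow(img); p <- ncol(img)
  M1 <- oracle_heaviside(phi, eps); M2 <- 1 - M1
  u1 <- u2 <- v1 <- v2 <- matrix(0, n, p)
  for (r in 1:n) for (c in 1:p) {
    s1 <- s2 <- si1 <- si2 <- 0
    for (dr in -rho:rho) for (dc in -rho:rho) {
      rr <- r + dr; cc <- c + dc
      if (rr < 1 || rr > n || cc < 1 || cc > p) next
      wt <- w[dr + rho + 1, dc + rho + 1]
      s1 <- s1 + wt * M1[rr, cc];  si1 <- si1 + wt * img[rr, cc] * M1[rr, cc]
      s2 <- s2 + wt * M2[rr, cc];  si2 <- si2 + wt * img[rr, cc] * M2[rr, cc]
    }
    u1[r, c] <- si1 / max(s1, 1e-10)
    u2[r, c] <- si2 / max(s2, 1e-10)
    q1 <- q2 <- 0
    for (dr in -rho:rho) for (dc in -rho:rho) {
      rr <- r + dr; cc <- c + dc
      if (rr < 1 || rr > n || cc < 1 || cc > p) next
      wt <- w[dr + rho + 1, dc + rho + 1]
      q1 <- q1 + wt * (u1[r, c] - img[rr, cc])^2 * M1[rr, cc]
      q2 <- q2 + wt * (u2[r, c] - img[rr, cc])^2 * M2[rr, cc]
    }
    v1[r, c] <- max(q1 / max(s1, 1e-10), var_floor)
    v2[r, c] <- max(q2 / max(s2, 1e-10), var_floor)
  }
  list(u1 = u1, u2 = u2, var1 = v1, var2 = v2)
}

# e1 - e2: direct double loop.
oracle_data_force <- function(img, st, sigma, rho) {
  w <- oracle_window(sigma, rho)
  n <- nrow(img); p <- ncol(img)
  out <- matrix(0, n, p)
  for (r in 1:n) for (c in 1:p) {
    e1 <- e2 <- 0
    for (dr in -rho:rho) for (dc in -rho:rho) {
      rr <- r + dr; cc <- c + dc
      if (rr < 1 || rr > n || cc < 1 || cc > p) next
      wt <- w[dr + rho + 1, dc + rho + 1]
      e1 <- e1 + wt * (log(sqrt(st$var1[rr, cc])) +
                         (st$u1[rr, cc] - img[r, c])^2 / (2 * st$var1[rr, cc]))
      e2 <- e2 + wt * (log(sqrt(st$var2[rr, cc])) +
                         (st$u2[rr, cc] - img[r, c])^2 / (2 * st$var2[rr, cc]))
    }
    out[r, c] <- e1 - e2
  }
  out
}

# One explicit Euler step, finite differences coded from scratch with
# clamped (replicate) borders.
oracle_evolve_step <- function(img, phi, par) {
  st <- oracle_local_stats(img, phi, par$kernel_sigma, par$kernel_radius,
                           par$epsilon, par$var_floor)
  f <- oracle_data_force(img, st, par$kernel_sigma, par$kernel_radius)
  n <- nrow(phi); p <- ncol(phi)
  at <- function(m, r, c) m[min(max(r, 1), n), min(max(c, 1), p)]
  gx <- gy <- nx <- ny <- lap <- matrix(0, n, p)
  for (r in 1:n) for (c in 1:p) {
    gx[r, c] <- (at(phi, r, c + 1) - at(phi, r, c - 1)) / 2
    gy[r, c] <- (at(phi, r + 1, c) - at(phi, r - 1, c)) / 2
    lap[r, c] <- at(phi, r, c + 1) + at(phi, r, c - 1) +
      at(phi, r + 1, c) + at(phi, r - 1, c) - 4 * phi[r, c]
  }
  nrm <- pmax(sqrt(gx^2 + gy^2), 1e-10)
  nx <- gx / nrm; ny <- gy / nrm
  kap <- matrix(0, n, p)
  for (r in 1:n) for (c in 1:p) {
    kap[r, c] <- (at(nx, r, c + 1) - at(nx, r, c - 1)) / 2 +
      (at(ny, r + 1, c) - at(ny, r - 1, c)) / 2
  }
  dlt <- oracle_delta(phi, par$epsilon)
  phi + par$dt * (-dlt * f + par$nu * dlt * kap + par$mu * (lap - kap))
}

# Total energy: double integral of the fitting term plus length and
# distance penalties, all by direct loops.
oracle_energy <- function(img, phi, par) {
  st <- oracle_local_stats(img, phi, par$kernel_sigma, par$kernel_radius,
                           par$epsilon, par$var_floor)
  w <- oracle_window(par$kernel_sigma, par$kernel_radius)
  rho <- par$kernel_radius
  n <- nrow(img); p <- ncol(img)
  M1 <- oracle_heaviside(phi, par$epsilon); M2 <- 1 - M1
  e <- 0
  for (x1 in 1:n) for (x2 in 1:p) {         # centre of the window
    for (dr in -rho:rho) for (dc in -rho:rho) {
      y1 <- x1 + dr; y2 <- x2 + dc
      if (y1 < 1 || y1 > n || y2 < 1 || y2 > p) next
      wt <- w[dr + rho + 1, dc + rho + 1]
      lp1 <- -log(sqrt(2 * pi) * sqrt(st$var1[x1, x2])) -
        (st$u1[x1, x2] - img[y1, y2])^2 / (2 * st$var1[x1, x2])
      lp2 <- -log(sqrt(2 * pi) * sqrt(st$var2[x1, x2])) -
        (st$u2[x1, x2] - img[y1, y2])^2 / (2 * st$var2[x1, x2])
      e <- e - wt * (lp1 * M1[y1, y2] + lp2 * M2[y1, y2])
    }
  }
  at <- function(m, r, c) m[min(max(r, 1), n), min(max(c, 1), p)]
  len <- 0; pen <- 0
  for (r in 1:n) for (c in 1:p) {
    hx <- (at(M1, r, c + 1) - at(M1, r, c - 1)) / 2
    hy <- (at(M1, r + 1, c) - at(M1, r - 1, c)) / 2
    len <- len + sqrt(hx^2 + hy^2)
    gx <- (at(phi, r, c + 1) - at(phi, r, c - 1)) / 2
    gy <- (at(phi, r + 1, c) - at(phi, r - 1, c)) / 2
    pen <- pen + 0.5 * (sqrt(gx^2 + gy^2) - 1)^2
  }
  e + par$nu * len + par$mu * pen
}
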