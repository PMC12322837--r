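# Independent brute-force oracles: explicit-loop implementations of the
# quantities the package computes with vectorized / recurrence-based code.
# These deliberately share no code path with the implementation.

# Cox-de Boor by direct recursion on an integer knot grid: N_{i,k}(s).
oracle_bspline_N <- function(i, k, s) {
  if (k == 0L) return(as.numeric(s >= i & s < i + 1))
  (s - i) / k * oracle_bspline_N(i, k - 1L, s) +
    (i + k + 1 - s) / k * oracle_bspline_N(i + 1L, k - 1L, s)
}

# Displacement of a B-spline field at one point by the explicit
# double tensor-product sum over every control point.
oracle_ffd_point <- function(field, pt) {
  k <- field$degree
  ux <- pt[1] / field$spacing[1]
  uy <- pt[2] / field$spacing[2]
  d <- c(0, 0)
  for (m in seq_len(ncol(field$cx)) - 1L) {      # x control index (0-based)
    wm <- oracle_bspline_N(m - k, k, ux)
    if (wm == 0) next
    for (n in seq_len(nrow(field$cx)) - 1L) {    # y control index
      wn <- oracle_bspline_N(n - k, k, uy)
      d <- d + c(field$cx[n + 1, m + 1], field$cy[n + 1, m + 1]) * wm * wn
    }
  }
  pt + d
}

# Local squared-NCC loss by explicit loops over window centres and offsets.
oracle_ncc <- function(f, w, r, normalize = TRUE, eps_rel = 1e-6) {
  ny <- nrow(f)
  nx <- ncol(f)
  n <- (2 * r + 1)^2
  eps <- (eps_rel * n * diff(range(f)) * diff(range(w)))^2
  total <- 0
  count <- 0
  for (cy in (r + 1):(ny - r)) for (cx in (r + 1):(nx - r)) {
    fv <- wv <- numeric(0)
    for (dy in -r:r) for (dx in -r:r) {
      fv <- c(fv, f[cy + dy, cx + dx])
      wv <- c(wv, w[cy + dy, cx + dx])
    }
    s_num <- sum((fv - mean(fv)) * (wv - mean(wv)))
    d1 <- sum((fv - mean(fv))^2)
    d2 <- sum((wv - mean(wv))^2)
    total <- total + s_num^2 / (d1 * d2 + eps)
    count <- count + 1
  }
  if (normalize) -total / count else -total
}

# Diffusion regularizer by explicit loops over forward differences.
oracle_diffusion <- function(ux, uy) {
  ny <- nrow(ux)
  nx <- ncol(ux)
  sx2 <- nx^2
  sy2 <- ny^2
  ex <- c()
  ey <- c()
  for (y in 1:ny) for (x in 1:(nx - 1))
    ex <- c(ex, (ux[y, x + 1] - ux[y, x])^2 + (uy[y, x + 1] - uy[y, x])^2)
  for (y in 1:(ny - 1)) for (x in 1:nx)
    ey <- c(ey, (ux[y + 1, x] - ux[y, x])^2 + (uy[y + 1, x] - uy[y, x])^2)
  0.5 * (sx2 * mean(ex) + sy2 * mean(ey))
}

# Per-landmark rTRE by an explicit loop.
oracle_rtre <- function(est, truth, dims) {
  d <- sqrt(dims[1]^2 + dims[2]^2)
  out <- numeric(nrow(est))
  for (l in seq_len(nrow(est)))
    out[l] <- sqrt(sum((est[l, ] - truth[l, ])^2)) / d
  out
}

# Suite aggregates recomputed from the raw per-landmark vectors.
oracle_summary <- function(evals) {
  med <- mx <- mn <- rb <- md <- numeric(length(evals))
  for (i in seq_along(evals)) {
    e <- evals[[i]]
    med[i] <- median(e$rtre)
    mx[i] <- max(e$rtre)
    mn[i] <- mean(e$rtre)
    rb[i] <- sum(e$rtre < e$rire) / length(e$rtre)
    md[i] <- mean(e$dist_px)
  }
  c(AMrTRE = mean(med), MMrTRE = median(med), AMean_rTRE = mean(mn),
    AMxrTRE = mean(mx), R_avg = mean(rb), AMean_D = mean(md))
}

# Matches generated exactly by a known affine, with optional planted
# outliers forced to sit far outside the inlier band.
planted_matches <- function(n_inliers, n_outliers = 0, threshold = 3,
                            extent = 200) {
  theta <- runif(1, -30, 30) * pi / 180
  s <- runif(1, 0.9, 1.1)
  A <- s * matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  tr <- runif(2, -20, 20)
  tf <- affine2d(A, tr)
  q <- cbind(runif(n_inliers + n_outliers, 0, extent),
             runif(n_inliers + n_outliers, 0, extent))
  p <- affine_apply(tf, q)
  if (n_outliers > 0) {
    out_idx <- seq_len(n_outliers) + n_inliers
    ang <- runif(n_outliers, 0, 2 * pi)
    rad <- runif(n_outliers, 5 * threshold, 15 * threshold)
    p[out_idx, ] <- p[out_idx, ] + cbind(rad * cos(ang), rad * sin(ang))
  }
  list(matches = serialreg:::new_match_set(p, q, rep(0, nrow(p))),
       transform = tf, inliers = seq_len(n_inliers))
}

# Small, fast configuration for pipeline-level tests.
fast_config <- function() {
  cfg <- default_config()
  cfg$search_iters <- 300L
  cfg$ransac_iters <- 800L
  cfg$max_iters <- 120L
  cfg$background <- 0.15
  cfg
}
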