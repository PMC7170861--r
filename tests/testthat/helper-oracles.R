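# Independent oracles: deliberately separate, straightforward
# re-implementations used to cross-check the package's code paths.

# Second implementation of the biased persistent random walk with the
# same documented draw order (per track: n_steps + 1 angles, then
# n_steps truncated-normal speeds drawn vectorized with redraws).
oracle_simulate_tracks <- function(params) {
  p <- params
  n_steps <- floor(p$duration / p$dt)
  mu <- p$speed_mean * if (p$chemokine) p$chemokinesis_factor else 1
  sdv <- p$speed_sd * if (p$chemokine) p$chemokinesis_factor else 1
  g <- p$gradient_axis
  out <- vector("list", p$n_cells)
  withr::with_seed(p$seed, {
    for (i in seq_len(p$n_cells)) {
      ang <- runif(n_steps + 1, 0, 2 * pi)
      sp <- rnorm(n_steps, mu, sdv)
      while (length(neg <- which(sp < 0))) sp[neg] <- rnorm(length(neg), mu, sdv)
      pos <- matrix(0, n_steps + 1, 2)
      dprev <- c(cos(ang[1]), sin(ang[1]))
      for (k in 1:n_steps) {
        v <- p$persistence * dprev +
          p$bias * g +
          (1 - p$persistence - p$bias) * c(cos(ang[k + 1]), sin(ang[k + 1]))
        if (sqrt(sum(v^2)) > 0) dprev <- v / sqrt(sum(v^2))
        pos[k + 1, ] <- pos[k, ] + sp[k] * p$dt * dprev
      }
      out[[i]] <- pos
    }
  })
  out
}

# Brute-force per-segment path length.
oracle_path_length <- function(x, y) {
  total <- 0
  for (k in 2:length(x)) {
    total <- total + sqrt((x[k] - x[k - 1])^2 + (y[k] - y[k - 1])^2)
  }
  total
}

# Exact two-sided rank-sum p-value by full enumeration of group
# assignments (midranks, so ties are handled).
oracle_ranksum_p <- function(a, b) {
  r <- rank(c(a, b))
  na <- length(a)
  mu <- na * (length(r) + 1) / 2
  obs <- abs(sum(r[1:na]) - mu)
  sums <- combn(length(r), na, function(idx) sum(r[idx]))
  mean(abs(sums - mu) >= obs - 1e-12)
}

# First-moment centroid of a weighted pixel set, computed longhand.
oracle_centroid <- function(mask, weights = NULL) {
  sx <- sy <- sw <- 0
  for (i in seq_len(nrow(mask))) {
    for (j in seq_len(ncol(mask))) {
      if (mask[i, j] != 0) {
        w <- if (is.null(weights)) 1 else weights[i, j]
        sx <- sx + w * j; sy <- sy + w * i; sw <- sw + w
      }
    }
  }
  c(x = sx / sw, y = sy / sw)
}

# Sort-and-take-half front selection on an arbitrary pixel index set.
oracle_front_half <- function(mask, indices, direction) {
  rc <- arrayInd(which(mask != 0), dim(mask))
  cx <- mean(rc[, 2]); cy <- mean(rc[, 1])
  rc_sub <- arrayInd(indices, dim(mask))
  score <- (rc_sub[, 2] - cx) * direction[1] + (rc_sub[, 1] - cy) * direction[2]
  ord <- order(-score, indices)
  sort(indices[ord][seq_len(ceiling(length(indices) / 2))])
}

# Mask of a filled ellipse rotated by `theta`, for shape-invariance
# checks (falls back to regenerating until >= 5 pixels).
rand_rotated_ellipse <- function(seed, grid = 48) {
  withr::with_seed(seed, {
    repeat {
      a <- runif(1, 4, grid / 3)
      b <- runif(1, 2, a)
      th <- runif(1, 0, pi)
      cx <- runif(1, grid / 3, 2 * grid / 3)
      cy <- runif(1, grid / 3, 2 * grid / 3)
      xs <- matrix(seq_len(grid), grid, grid, byrow = TRUE)
      ys <- matrix(seq_len(grid), grid, grid)
      u <- (xs - cx) * cos(th) + (ys - cy) * sin(th)
      v <- -(xs - cx) * sin(th) + (ys - cy) * cos(th)
      m <- ((u / a)^2 + (v / b)^2 <= 1) * 1L
      if (sum(m) >= 5) return(m)
    }
  })
}

# Random non-degenerate track for property tests.
rand_track <- function(seed, n_points = 10) {
  withr::with_seed(seed, {
    track(paste0("r", seed),
          t = cumsum(runif(n_points, 0.5, 1.5)),
          x = cumsum(rnorm(n_points)), y = cumsum(rnorm(n_points)))
  })
}

# A straight-line track with the given net displacement over `dur` min.
line_track <- function(dx, dy, dur = 60, id = "line", volume = NA_real_) {
  track(id, t = c(0, dur), x = c(0, dx), y = c(0, dy), volume = volume)
}
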