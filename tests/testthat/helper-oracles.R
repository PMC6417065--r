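# Independent naive-enumeration oracles for the texture matrices and the
# ANOVA/concordance statistics.  Deliberately slow and literal: plain
# loops over voxels, no shared code with the package internals.

in_grid <- function(z, y, x, d)
  z >= 1 && z <= d[1] && y >= 1 && y <= d[2] && x >= 1 && x <= d[3]

# Symmetric GLCM counts for one direction: ordered pairs over +d and -d.
oracle_glcm <- function(arr, dir, L) {
  d <- dim(arr)
  M <- matrix(0, L, L)
  for (x in 1:d[3]) for (y in 1:d[2]) for (z in 1:d[1]) {
    a <- arr[z, y, x]
    if (a == 0) next
    for (s in c(1, -1)) {
      z2 <- z + s * dir[1]; y2 <- y + s * dir[2]; x2 <- x + s * dir[3]
      if (!in_grid(z2, y2, x2, d)) next
      b <- arr[z2, y2, x2]
      if (b > 0) M[a, b] <- M[a, b] + 1
    }
  }
  M
}

# Run-length counts for one direction, via explicit line traversals.
oracle_glrlm <- function(arr, dir, L) {
  d <- dim(arr)
  maxlen <- sum(d)
  M <- matrix(0, L, maxlen)
  for (x in 1:d[3]) for (y in 1:d[2]) for (z in 1:d[1]) {
    # line starts: cells whose predecessor along -dir leaves the grid
    zp <- z - dir[1]; yp <- y - dir[2]; xp <- x - dir[3]
    if (in_grid(zp, yp, xp, d)) next
    lev <- integer(0)
    cz <- z; cy <- y; cx <- x
    while (in_grid(cz, cy, cx, d)) {
      lev <- c(lev, arr[cz, cy, cx])
      cz <- cz + dir[1]; cy <- cy + dir[2]; cx <- cx + dir[3]
    }
    r <- rle(lev)
    for (i in seq_along(r$values))
      if (r$values[i] > 0)
        M[r$values[i], r$lengths[i]] <- M[r$values[i], r$lengths[i]] + 1
  }
  M
}

# Zones (level, size) via naive BFS over the full neighborhood.
oracle_glszm <- function(arr, neigh) {
  d <- dim(arr)
  seen <- array(FALSE, d)
  zones <- NULL
  idx <- which(arr > 0, arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    v <- idx[k, ]
    if (seen[v[1], v[2], v[3]]) next
    lev <- arr[v[1], v[2], v[3]]
    queue <- list(v)
    seen[v[1], v[2], v[3]] <- TRUE
    size <- 0
    while (length(queue)) {
      c0 <- queue[[1]]; queue <- queue[-1]
      size <- size + 1
      for (r in seq_len(nrow(neigh))) {
        w <- c0 + neigh[r, ]
        if (!in_grid(w[1], w[2], w[3], d)) next
        if (!seen[w[1], w[2], w[3]] && arr[w[1], w[2], w[3]] == lev) {
          seen[w[1], w[2], w[3]] <- TRUE
          queue[[length(queue) + 1]] <- w
        }
      }
    }
    zones <- rbind(zones, c(lev, size))
  }
  zones[order(zones[, 1], zones[, 2]), , drop = FALSE]
}

# Per-level (n_i, s_i) with in-mask neighborhood means.
oracle_ngtdm <- function(arr, neigh, L) {
  d <- dim(arr)
  out <- matrix(0, L, 2)
  for (x in 1:d[3]) for (y in 1:d[2]) for (z in 1:d[1]) {
    a <- arr[z, y, x]
    if (a == 0) next
    nb <- numeric(0)
    for (r in seq_len(nrow(neigh))) {
      z2 <- z + neigh[r, 1]; y2 <- y + neigh[r, 2]; x2 <- x + neigh[r, 3]
      if (!in_grid(z2, y2, x2, d)) next
      b <- arr[z2, y2, x2]
      if (b > 0) nb <- c(nb, b)
    }
    if (length(nb)) {
      out[a, 1] <- out[a, 1] + 1
      out[a, 2] <- out[a, 2] + abs(a - mean(nb))
    }
  }
  out
}

# One-way ANOVA ICC(1,1) spelled out.
oracle_icc <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  ssb <- 0; ssw <- 0
  for (i in 1:n) {
    mi <- mean(m[i, ])
    ssb <- ssb + k * (mi - grand)^2
    for (j in 1:k) ssw <- ssw + (m[i, j] - mi)^2
  }
  msb <- ssb / (n - 1); msw <- ssw / (n * (k - 1))
  (msb - msw) / (msb + (k - 1) * msw)
}

# Harrell C by explicit pair enumeration.
oracle_c_index <- function(scores, time, event) {
  num <- den <- 0
  n <- length(scores)
  for (i in 1:n) for (j in 1:n) {
    if (i == j || event[i] != 1) next
    comparable <- time[i] < time[j] || (time[i] == time[j] && event[j] == 0)
    if (!comparable) next
    den <- den + 1
    if (scores[i] > scores[j]) num <- num + 1
    else if (scores[i] == scores[j]) num <- num + 0.5
  }
  num / den
}

# Random small quantized ROI on its own grid (levels 1..L, 0 outside).
random_roi <- function(shape = c(5, 5, 5), L = 6, p_mask = 0.7) {
  arr <- array(0L, shape)
  mask <- array(runif(prod(shape)) < p_mask, shape)
  if (!any(mask)) mask[1] <- TRUE
  arr[mask] <- sample.int(L, sum(mask), replace = TRUE)
  arr
}

# Wrap a bare level array as a quantized_roi (intensities = levels / L).
roi_from_levels <- function(arr, L = max(arr), dims = "3D",
                            spacing = c(1, 1, 1)) {
  if (length(dim(arr)) == 2L) arr <- array(arr, c(1L, dim(arr)))
  storage.mode(arr) <- "integer"
  quantized_roi(arr, arr > 0, arr / L, spacing, L, dims)
}
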