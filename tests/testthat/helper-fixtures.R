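# fixtures built in code: voxelised analytic solids and tiny hand masks

ball_mask <- function(r = 3, h = 0.1, margin = 1) {
  n <- ceiling((2 * r + 2 * margin) / h)
  cx <- (seq_len(n) - 0.5) * h - (r + margin)
  arr <- array(FALSE, c(n, n, n))
  X <- rep(cx, times = n); Y <- rep(cx, each = n)
  for (k in seq_len(n))
    arr[, , k] <- matrix(X^2 + Y^2 + cx[k]^2 < r^2, n, n)
  VoxelGrid(arr, rep(h, 3))
}

box_mask <- function(ext = c(4, 4, 2), h = 0.2, margin = 1) {
  n <- ceiling((ext + 2 * margin) / h)
  arr <- array(FALSE, n)
  idx <- lapply(1:3, function(a) {
    cx <- (seq_len(n[a]) - 0.5) * h - (ext[a] / 2 + margin)
    which(abs(cx) < ext[a] / 2)
  })
  arr[idx[[1]], idx[[2]], idx[[3]]] <- TRUE
  VoxelGrid(arr, rep(h, 3))
}

# small hand mask in an 8-voxel cube corner of a larger array
hand_mask <- function(which_voxels, dims = c(6, 6, 6), spacing = c(1, 1, 1)) {
  arr <- array(FALSE, dims)
  arr[which_voxels] <- TRUE
  VoxelGrid(arr, spacing)
}

# brute-force truncated-Gaussian convolution with mirror padding (oracle)
brute_gauss3 <- function(arr, sigma, support) {
  i <- seq.int(-support, support)
  w1 <- exp(-i^2 / (2 * sigma^2)); w1 <- w1 / sum(w1)
  d <- dim(arr)
  mirror <- function(j, n) ifelse(j < 1, 1 - j, ifelse(j > n, 2 * n + 1 - j, j))
  out <- array(0, d)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    acc <- 0
    for (a in i) for (b in i) for (cc in i) {
      acc <- acc + w1[a + support + 1] * w1[b + support + 1] *
        w1[cc + support + 1] *
        arr[mirror(x + a, d[1]), mirror(y + b, d[2]), mirror(z + cc, d[3])]
    }
    out[x, y, z] <- acc
  }
  out
}

# from-definition precision error (oracle, independent of precisionError)
pe_oracle <- function(v) {
  sds <- apply(v, 1, function(row) sqrt(sum((row - mean(row))^2) /
                                          (length(row) - 1)))
  list(pe_sd = sqrt(sum(sds^2) / nrow(v)),
       pe_pct_cv = 100 * sqrt(sum((sds / rowMeans(v))^2) / nrow(v)))
}

# aov-based ICC(A,1) (oracle, independent of iccAbsoluteSingle)
icc_oracle <- function(v) {
  d <- data.frame(y = as.vector(v),
                  s = factor(rep(seq_len(nrow(v)), ncol(v))),
                  r = factor(rep(seq_len(ncol(v)), each = nrow(v))))
  ms <- stats::anova(stats::lm(y ~ s + r, d))[["Mean Sq"]]
  n <- nrow(v); k <- ncol(v)
  (ms[1] - ms[3]) / (ms[1] + (k - 1) * ms[3] + (k / n) * (ms[2] - ms[3]))
}

# brute-force local thickness oracle on a tiny mask: sphere centres on the
# half-voxel grid, radius = distance to the nearest background voxel cube
# (the foreground solid is the union of foreground voxel cubes)
thickness_oracle <- function(mask, h) {
  d <- dim(mask)
  fg <- which(mask, arr.ind = TRUE)
  bg <- which(!mask, arr.ind = TRUE)
  bg_lo <- (bg - 1) * h          # cube corners
  bg_hi <- bg * h
  fg_pos <- (fg - 0.5) * h       # voxel centres
  # candidate centres: half-voxel grid over the foreground bounding box
  rng <- lapply(1:3, function(a)
    seq((min(fg[, a]) - 1) * h, max(fg[, a]) * h, by = h / 2))
  cand <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
  th <- numeric(nrow(fg))
  for (ci in seq_len(nrow(cand))) {
    c0 <- cand[ci, ]
    # distance from c0 to nearest background cube
    dx <- pmax(pmax(bg_lo[, 1] - c0[1], c0[1] - bg_hi[, 1]), 0)
    dy <- pmax(pmax(bg_lo[, 2] - c0[2], c0[2] - bg_hi[, 2]), 0)
    dz <- pmax(pmax(bg_lo[, 3] - c0[3], c0[3] - bg_hi[, 3]), 0)
    # array borders count as background too
    border <- min(c0, dim(mask) * h - c0)
    r <- min(sqrt(dx^2 + dy^2 + dz^2), border)
    if (r <= 0) next
    covered <- (fg_pos[, 1] - c0[1])^2 + (fg_pos[, 2] - c0[2])^2 +
      (fg_pos[, 3] - c0[3])^2 <= r^2 + 1e-12
    th[covered] <- pmax(th[covered], 2 * r)
  }
  out <- array(0, d)
  out[fg] <- th
  out
}
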