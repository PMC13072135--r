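# Independent naive-loop recomputations of every behavioral measure.
# Deliberately dumb: element-by-element loops, no vectorization, no reuse
# of package internals, so they stay an independent oracle.

oracle_velocity <- function(traj) {
  pos <- traj$positions
  n <- nrow(pos)
  dt <- (traj$times[n] - traj$times[1]) / (n - 1)
  speeds <- numeric(n - 1)
  for (i in seq_len(n - 1)) {
    d2 <- 0
    for (ax in 1:3) d2 <- d2 + (pos[i + 1, ax] - pos[i, ax])^2
    speeds[i] <- sqrt(d2) * 10 / dt
  }
  speeds
}

oracle_distance <- function(traj) {
  pos <- traj$positions
  total <- 0
  for (i in seq_len(nrow(pos) - 1)) {
    d2 <- 0
    for (ax in 1:3) d2 <- d2 + (pos[i + 1, ax] - pos[i, ax])^2
    total <- total + sqrt(d2)
  }
  total
}

oracle_bottom <- function(traj) {
  z <- traj$positions[, 3]
  s <- 0
  for (i in seq_along(z)) s <- s + z[i]
  s / length(z)
}

oracle_center <- function(traj) {
  cx <- traj$geometry$width_x / 2
  cy <- traj$geometry$depth_y / 2
  pos <- traj$positions
  s <- 0
  for (i in seq_len(nrow(pos)))
    s <- s + sqrt((pos[i, 1] - cx)^2 + (pos[i, 2] - cy)^2)
  s / nrow(pos)
}

# brute-force voxel-set counting: a character set of "ix,iy,iz" keys
oracle_explored <- function(traj) {
  g <- traj$geometry
  ext <- c(g$width_x, g$depth_y, g$height_z)
  k <- g$grid_divisions
  seen <- character(0)
  pos <- traj$positions
  for (i in seq_len(nrow(pos))) {
    idx <- integer(3)
    for (ax in 1:3) {
      j <- floor(pos[i, ax] / (ext[ax] / k))
      if (j > k - 1) j <- k - 1
      idx[ax] <- j
    }
    seen <- union(seen, paste(idx, collapse = ","))
  }
  100 * length(seen) / k^3
}

oracle_immobile <- function(speeds, threshold = 1.5) {
  cnt <- 0
  for (s in speeds) if (s < threshold) cnt <- cnt + 1
  100 * cnt / length(speeds)
}

oracle_max_velocity <- function(speeds) {
  k <- ceiling(0.05 * length(speeds))
  top <- sort(speeds, decreasing = TRUE)[1:k]
  median(top)
}

# random but valid trajectory: clipped random walk on a uniform clock
random_trajectory <- function(seed, n = 200, geometry = tank_geometry(),
                              dt = 1 / 30) {
  set.seed(seed)
  ext <- c(geometry$width_x, geometry$depth_y, geometry$height_z)
  pos <- sapply(1:3, function(ax) {
    p <- cumsum(c(runif(1, 0, ext[ax]), rnorm(n - 1, 0, ext[ax] / 20)))
    pmin(pmax(p, 0), ext[ax])
  })
  trajectory3d((seq_len(n) - 1) * dt, pos[, 1], pos[, 2], pos[, 3],
               geometry, fish_id = paste0("rand", seed))
}

# centers of `m` distinct voxels of the default 10x10x10 grid, in order
voxel_center_waypoints <- function(m, geometry = tank_geometry()) {
  k <- geometry$grid_divisions
  stopifnot(m <= k^3)
  idx <- seq_len(m) - 1L
  ix <- idx %% k
  iy <- (idx %/% k) %% k
  iz <- idx %/% (k * k)
  cbind((ix + 0.5) * geometry$width_x / k,
        (iy + 0.5) * geometry$depth_y / k,
        (iz + 0.5) * geometry$height_z / k)
}

# exact Mann-Whitney null via full enumeration of group labelings
enumerate_mw_p <- function(y1, y2, alternative = "less") {
  pooled <- c(y1, y2)
  n1 <- length(y1)
  u_stat <- function(g1, g2) sum(outer(g1, g2, ">")) +
    0.5 * sum(outer(g1, g2, "=="))
  obs <- u_stat(y1, y2)
  combos <- combn(length(pooled), n1)
  us <- apply(combos, 2, function(ix)
    u_stat(pooled[ix], pooled[-ix]))
  switch(alternative,
         less = mean(us <= obs),
         greater = mean(us >= obs),
         two.sided = min(1, 2 * min(mean(us <= obs), mean(us >= obs))))
}

# exact Wilcoxon signed-rank null via enumeration of all 2^n sign flips
enumerate_signed_rank_p <- function(d, alternative = "two.sided") {
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- as.vector(signs %*% r)
  p_less <- mean(vs <= v_obs)
  p_greater <- mean(vs >= v_obs)
  switch(alternative,
         less = p_less, greater = p_greater,
         two.sided = min(1, 2 * min(p_less, p_greater)))
}

# brute-force balanced two-way ANOVA decomposition (cell-mean formulas)
oracle_balanced_ss <- function(y, a, b) {
  a <- factor(a); b <- factor(b)
  gm <- mean(y)
  ssa <- 0
  for (la in levels(a)) {
    ya <- y[a == la]
    ssa <- ssa + length(ya) * (mean(ya) - gm)^2
  }
  ssb <- 0
  for (lb in levels(b)) {
    yb <- y[b == lb]
    ssb <- ssb + length(yb) * (mean(yb) - gm)^2
  }
  ssab <- 0
  for (la in levels(a)) for (lb in levels(b)) {
    yc <- y[a == la & b == lb]
    ma <- mean(y[a == la]); mb <- mean(y[b == lb])
    ssab <- ssab + length(yc) * (mean(yc) - ma - mb + gm)^2
  }
  list(A = ssa, B = ssb, AB = ssab, total = sum((y - gm)^2))
}
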