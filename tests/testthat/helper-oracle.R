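# Brute-force texture oracles: direct enumeration of pixel pairs and runs
# with explicit loops, written solely from the feature formulas. They share
# no code with the package implementation.

oracle_quantize <- function(values, Q) {
  mn <- min(values); mx <- max(values)
  if (mx == mn) return(rep(1L, length(values)))
  q <- floor((values - mn) / (mx - mn) * Q) + 1
  as.integer(ifelse(q > Q, Q, q))
}

# Levels laid out on the full plane grid, NA off-region.
oracle_level_grid <- function(plane, region_mask, Q) {
  lev <- matrix(NA_integer_, nrow(plane), ncol(plane))
  vals <- plane[region_mask]
  lev[region_mask] <- oracle_quantize(vals, Q)
  lev
}

oracle_glcm <- function(plane, region_mask, Q) {
  lev <- oracle_level_grid(plane, region_mask, Q)
  counts <- matrix(0, Q, Q)
  offs <- list(c(0, 1), c(1, 1), c(1, 0), c(1, -1))
  for (r in seq_len(nrow(lev))) for (cc in seq_len(ncol(lev))) {
    if (is.na(lev[r, cc])) next
    for (o in offs) {
      r2 <- r + o[1]; c2 <- cc + o[2]
      if (r2 < 1 || r2 > nrow(lev) || c2 < 1 || c2 > ncol(lev)) next
      if (is.na(lev[r2, c2])) next
      i <- lev[r, cc]; j <- lev[r2, c2]
      counts[i, j] <- counts[i, j] + 1
      counts[j, i] <- counts[j, i] + 1
    }
  }
  p <- counts / sum(counts)
  px <- rowSums(p)
  mu <- 0; for (i in 1:Q) mu <- mu + i * px[i]
  s2 <- 0; for (i in 1:Q) s2 <- s2 + (i - mu)^2 * px[i]
  energy <- 0; entropy <- 0; inertia <- 0; idm <- 0
  corr_num <- 0; har_num <- 0; shade <- 0; prom <- 0
  for (i in 1:Q) for (j in 1:Q) {
    v <- p[i, j]
    energy <- energy + v^2
    if (v > 0) entropy <- entropy - v * log(v)
    inertia <- inertia + (i - j)^2 * v
    idm <- idm + v / (1 + (i - j)^2)
    corr_num <- corr_num + (i - mu) * (j - mu) * v
    har_num <- har_num + i * j * v
    shade <- shade + (i + j - 2 * mu)^3 * v
    prom <- prom + (i + j - 2 * mu)^4 * v
  }
  c(correlation = if (s2 > 0) corr_num / s2 else 0,
    cluster_shade = shade, cluster_prominence = prom,
    energy = energy, entropy = entropy,
    haralick_correlation = if (s2 > 0) (har_num - mu^2) / s2 else 0,
    inertia = inertia, inverse_difference_moment = idm)
}

# Walk one line of (row, col) positions, collecting maximal runs.
oracle_walk_runs <- function(lev, positions) {
  runs_i <- integer(0); runs_j <- integer(0)
  cur <- NA_integer_; len <- 0L
  flush <- function() {
    if (!is.na(cur) && len > 0L) {
      runs_i <<- c(runs_i, cur); runs_j <<- c(runs_j, len)
    }
  }
  for (k in seq_len(nrow(positions))) {
    v <- lev[positions[k, 1], positions[k, 2]]
    if (is.na(v)) { flush(); cur <- NA_integer_; len <- 0L }
    else if (!is.na(cur) && v == cur) len <- len + 1L
    else { flush(); cur <- v; len <- 1L }
  }
  flush()
  cbind(runs_i, runs_j)
}

oracle_rlm <- function(plane, region_mask, Q) {
  lev <- oracle_level_grid(plane, region_mask, Q)
  nr <- nrow(lev); nc <- ncol(lev)
  runs <- matrix(integer(0), 0, 2)
  for (r in 1:nr)                      # horizontal
    runs <- rbind(runs, oracle_walk_runs(lev, cbind(r, 1:nc)))
  for (cc in 1:nc)                     # vertical
    runs <- rbind(runs, oracle_walk_runs(lev, cbind(1:nr, cc)))
  for (d in (1 - nc):(nr - 1)) {       # down-right diagonals (r - c = d)
    r <- max(1, 1 + d):min(nr, nc + d)
    runs <- rbind(runs, oracle_walk_runs(lev, cbind(r, r - d)))
  }
  for (s in 2:(nr + nc)) {             # down-left diagonals (r + c = s)
    r <- max(1, s - nc):min(nr, s - 1)
    runs <- rbind(runs, oracle_walk_runs(lev, cbind(r, s - r)))
  }
  i <- runs[, 1]; j <- runs[, 2]
  n_r <- length(i)
  gln <- 0
  for (lv in unique(i)) gln <- gln + sum(i == lv)^2
  rln <- 0
  for (ln in unique(j)) rln <- rln + sum(j == ln)^2
  c(gln = gln / n_r, rln = rln / n_r,
    lgre = sum(1 / i^2) / n_r, hgre = sum(i^2) / n_r,
    srlge = sum(1 / (i^2 * j^2)) / n_r, srhge = sum(i^2 / j^2) / n_r,
    lrlge = sum(j^2 / i^2) / n_r, lrhge = sum(i^2 * j^2) / n_r)
}

random_region <- function(seed, nr = 16L, nc = 16L, p = 0.6) {
  withr::with_seed(seed, {
    repeat {
      m <- matrix(runif(nr * nc) < p, nr, nc)
      # need at least one distance-1 in-region pair
      pairs <- sum(m[, -1] & m[, -nc]) + sum(m[-1, ] & m[-nr, ])
      if (sum(m) >= 4 && pairs > 0) break
    }
    list(mask = m, plane = matrix(runif(nr * nc), nr, nc))
  })
}
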