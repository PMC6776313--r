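clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Exact box-filter local mean with edge-clipped (shrinking) windows,
# computed from an integral image. `w` must be odd.
local_mean <- function(x, w) {
  if (w %% 2 == 0 || w < 3) stopf("window must be odd and >= 3, got %d", w)
  nr <- nrow(x); nc <- ncol(x)
  if (w > min(nr, nc)) stopf("window (%d) exceeds image extent (%d x %d)", w, nr, nc)
  h <- (w - 1L) %/% 2L
  # integral image with zero padding row/col
  S <- matrix(0, nr + 1L, nc + 1L)
  S[-1L, -1L] <- t(apply(apply(x, 2L, cumsum), 1L, cumsum))
  r1 <- pmax(seq_len(nr) - h, 1L); r2 <- pmin(seq_len(nr) + h, nr)
  c1 <- pmax(seq_len(nc) - h, 1L); c2 <- pmin(seq_len(nc) + h, nc)
  A <- S[r2 + 1L, c2 + 1L] + S[r1, c1] - S[r1, c2 + 1L] - S[r2 + 1L, c1]
  n <- outer(r2 - r1 + 1L, c2 - c1 + 1L)
  A / n
}

# Monotone quantile mapping of `src` values onto the distribution of `ref`.
# Tied source values map to a single output value (mean of the matched
# reference order statistics), so the map is a well-defined monotone function.
quantile_map <- function(src, ref) {
  u <- sort(unique(src))
  if (length(u) == 1L) {
    out <- rep(median(ref), length(src))
    return(out)
  }
  rk <- rank(src, ties.method = "average")          # average rank per value
  p <- (tapply(rk, match(src, u), mean) - 0.5) / length(src)
  mapped <- as.numeric(quantile(ref, probs = clamp(p, 0, 1), type = 7, names = FALSE))
  mapped <- cummax(mapped)                          # guard monotonicity
  mapped[match(src, u)]
}

as_patch <- function(x) {
  if (is.array(x) && length(dim(x)) == 3L && dim(x)[3L] == 3L) {
    storage.mode(x) <- "integer"
    return(x)
  }
  stopf("expected an H x W x 3 RGB array")
}

check_patch <- function(patch) {
  d <- dim(patch)
  if (is.null(d) || length(d) != 3L || d[3L] != 3L)
    stopf("patch must be an H x W x 3 array (got dims: %s)",
          paste(d, collapse = " x "))
  if (d[1L] < 1L || d[2L] < 1L) stopf("patch must be at least 1 x 1")
  invisible(patch)
}
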