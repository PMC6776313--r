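# Shared in-code fixtures.

disk_mask <- function(r, pad = 4L) {
  n <- 2L * ceiling(r) + 1L + 2L * pad
  ctr <- (n + 1) / 2
  rr <- matrix(seq_len(n), n, n) - ctr
  cc <- t(rr)
  rr^2 + cc^2 <= r^2
}

# A flat gray patch (no stain signal) of a given level.
gray_patch <- function(h, w, level = 230L) {
  array(as.integer(level), dim = c(h, w, 3L))
}

# Render a standard multi-nucleus fixture patch used across tests.
fixture_patch <- function(n = 12L, size = c(400L, 400L), seed = 42L,
                          radius = c(9, 20), noise_sd = 0.01) {
  specs <- random_nucleus_specs(n, size = size, radius = radius, seed = seed)
  render_patch(specs, size = size, noise_sd = noise_sd, seed = seed)
}

# Match segmentation labels to truth labels by maximal overlap; returns a
# data.frame with one row per truth label.
match_labels <- function(seg, truth) {
  out <- lapply(sort(unique(truth[truth > 0])), function(tl) {
    tmask <- truth == tl
    labs <- seg[tmask]
    labs <- labs[labs > 0]
    if (!length(labs))
      return(data.frame(truth = tl, seg = NA_integer_, iou = 0))
    sl <- as.integer(names(sort(table(labs), decreasing = TRUE))[1])
    smask <- seg == sl
    data.frame(truth = tl, seg = sl,
               iou = sum(smask & tmask) / sum(smask | tmask))
  })
  do.call(rbind, out)
}
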