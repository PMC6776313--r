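#' Specify one synthetic nucleus
#'
#' @param center numeric (row, col) center in pixels (1-based)
#' @param semi_axes numeric (a, b) semi-axes in pixels, a >= b > 0
#' @param orientation major-axis angle in radians (0 = along columns)
#' @param chromatin_contrast multiplicative texture amplitude in `[0, 1]`
#' @param base_stain hematoxylin optical density inside the nucleus (>= 0)
#' @return object of class `nucleus_spec`
#' @export
nucleus_spec <- function(center, semi_axes, orientation = 0,
                         chromatin_contrast = 0.3, base_stain = 0.8) {
  a <- semi_axes[1L]; b <- semi_axes[2L]
  if (!(a >= b && b > 0)) stopf("semi-axes must satisfy a >= b > 0 (got %g, %g)", a, b)
  if (chromatin_contrast < 0 || chromatin_contrast > 1)
    stopf("chromatin_contrast must lie in [0, 1]")
  if (base_stain < 0) stopf("base_stain must be >= 0")
  structure(list(center = as.numeric(center), semi_axes = c(a, b),
                 orientation = orientation,
                 chromatin_contrast = chromatin_contrast,
                 base_stain = base_stain),
            class = "nucleus_spec")
}

# Axis-aligned bounding half-extents of a rotated ellipse (rows, cols).
ellipse_extent <- function(spec) {
  a <- spec$semi_axes[1L]; b <- spec$semi_axes[2L]; th <- spec$orientation
  c(row = sqrt((a * sin(th))^2 + (b * cos(th))^2),
    col = sqrt((a * cos(th))^2 + (b * sin(th))^2))
}

# Logical matrix of pixels (centers at integer coordinates) inside the
# ellipse.
rasterize_ellipse <- function(spec, size) {
  ctr <- spec$center; a <- spec$semi_axes[1L]; b <- spec$semi_axes[2L]
  th <- spec$orientation
  rr <- matrix(seq_len(size[1L]), size[1L], size[2L]) - ctr[1L]
  cc <- matrix(seq_len(size[2L]), size[1L], size[2L], byrow = TRUE) - ctr[2L]
  u <- cc * cos(th) + rr * sin(th)
  v <- -cc * sin(th) + rr * cos(th)
  (u / a)^2 + (v / b)^2 <= 1
}

#' Render a synthetic H&E-like patch with ground-truth nuclei
#'
#' Nuclei are elliptical regions of hematoxylin optical density with
#' band-limited multiplicative chromatin texture, composited over a uniform
#' eosin background via the inverse Beer-Lambert transform with the
#' standard H&E stain vectors. Deconvolution is therefore an (almost) exact
#' inverse on noiseless patches.
#'
#' @param specs list of [nucleus_spec()] objects
#' @param size integer (H, W) patch size in pixels
#' @param background_eosin eosin optical density of the background
#' @param noise_sd standard deviation of additive OD noise
#' @param seed integer seed; rendering is deterministic given it
#' @param allow_overlap if `FALSE` (default), overlapping nuclei raise an
#'   error
#' @return list of class `synthetic_patch` with elements `image` (integer
#'   H x W x 3), `truth_mask` (integer label matrix, labels 1..n in spec
#'   order), `specs`, and `seed`
#' @export
render_patch <- function(specs, size = c(256L, 256L), background_eosin = 0.25,
                         noise_sd = 0.01, seed = 1L, allow_overlap = FALSE) {
  size <- as.integer(size)
  for (sp in specs) {
    if (!inherits(sp, "nucleus_spec")) stopf("specs must be nucleus_spec objects")
    ext <- ellipse_extent(sp)
    if (sp$center[1L] - ext["row"] < 1 || sp$center[1L] + ext["row"] > size[1L] ||
        sp$center[2L] - ext["col"] < 1 || sp$center[2L] + ext["col"] > size[2L])
      stopf("nucleus at (%g, %g) extends outside the %d x %d patch",
            sp$center[1L], sp$center[2L], size[1L], size[2L])
  }
  withr::with_seed(seed, {
    truth <- matrix(0L, size[1L], size[2L])
    hem <- matrix(0, size[1L], size[2L])
    for (i in seq_along(specs)) {
      sp <- specs[[i]]
      inside <- rasterize_ellipse(sp, size)
      if (!allow_overlap && any(truth[inside] != 0L))
        stopf("nucleus %d overlaps an earlier nucleus", i)
      truth[inside] <- i
      od <- sp$base_stain
      if (sp$chromatin_contrast > 0) {
        tex <- matrix(rnorm(prod(size)), size[1L], size[2L])
        tex <- EBImage::gblur(tex, sigma = 1.5)
        tex <- (tex - mean(tex)) / sd(tex)
        tex <- clamp(tex / 2.5, -1, 1)
        hem[inside] <- od * (1 + sp$chromatin_contrast * tex[inside])
      } else {
        hem[inside] <- od
      }
    }
    eos <- matrix(background_eosin, size[1L], size[2L])
    if (noise_sd > 0) {
      hem <- hem + matrix(rnorm(prod(size), sd = noise_sd), size[1L], size[2L])
      eos <- eos + matrix(rnorm(prod(size), sd = noise_sd), size[1L], size[2L])
    }
    hem[hem < 0] <- 0; eos[eos < 0] <- 0
    m <- he_stain_matrix()
    od <- array(0, c(size, 3L))
    for (k in 1:3) od[, , k] <- hem * m["hematoxylin", k] + eos * m["eosin", k]
    img <- od_to_rgb(od)
    structure(list(image = img, truth_mask = truth, specs = specs, seed = seed),
              class = "synthetic_patch")
  })
}

# Canonical set of summarized feature names for cohort simulation.
default_cohort_features <- function(n_features) {
  nm <- summary_feature_names()
  if (n_features == length(nm)) return(nm)
  sprintf("f%03d", seq_len(n_features))
}

#' Simulate a case cohort with grade-linked features and survival
#'
#' Features are drawn from a Gaussian class-conditional model: every
#' feature is standard normal, and each informative feature's mean is
#' shifted by its effect size in high-grade cases. Survival times are
#' exponential, with the high-grade hazard multiplied by `hazard_ratio`;
#' censoring is independent exponential with its rate chosen so the
#' expected censoring fraction equals `censor_rate`.
#'
#' @param n_cases number of cases (>= 2)
#' @param informative_features named numeric vector of effect sizes
#'   (feature mean shift, in SD units, for high vs low grade); names must
#'   be feature names. `NULL` for no informative features.
#' @param hazard_ratio true high/low hazard ratio (> 0)
#' @param censor_rate expected fraction of censored cases in `[0, 1)`
#' @param n_features total number of features (default the 144 summarized
#'   histomics names)
#' @param prob_high marginal probability of a high-grade case
#' @param baseline_median_months median survival of low-grade cases
#' @param seed integer seed
#' @return data.frame of class `synthetic_cohort` with columns `case_id`,
#'   `grade_true` ("low"/"high"), `age`, `gender`, `stage`, `time`
#'   (months), `event` (0/1), and one column per feature
#' @export
generate_cohort <- function(n_cases = 160L, informative_features = NULL,
                            hazard_ratio = 2, censor_rate = 0.6,
                            n_features = 144L, prob_high = 0.5,
                            baseline_median_months = 60, seed = 1L) {
  if (n_cases < 2L) stopf("n_cases must be >= 2")
  if (hazard_ratio <= 0) stopf("hazard_ratio must be positive")
  if (censor_rate < 0 || censor_rate >= 1) stopf("censor_rate must be in [0, 1)")
  feat_names <- default_cohort_features(n_features)
  eff <- setNames(numeric(n_features), feat_names)
  if (length(informative_features)) {
    bad <- setdiff(names(informative_features), feat_names)
    if (length(bad)) stopf("unknown informative features: %s",
                           paste(bad, collapse = ", "))
    eff[names(informative_features)] <- informative_features
  }
  withr::with_seed(seed, {
    grade <- ifelse(runif(n_cases) < prob_high, "high", "low")
    x <- matrix(rnorm(n_cases * n_features), n_cases, n_features,
                dimnames = list(NULL, feat_names))
    hi <- grade == "high"
    if (any(eff != 0))
      x[hi, ] <- sweep(x[hi, , drop = FALSE], 2L, eff, `+`)
    lambda0 <- log(2) / baseline_median_months
    rate <- lambda0 * ifelse(hi, hazard_ratio, 1)
    t_event <- rexp(n_cases, rate = rate)
    if (censor_rate > 0) {
      mu <- mean(rate) * censor_rate / (1 - censor_rate)
      t_cens <- rexp(n_cases, rate = mu)
    } else {
      t_cens <- rep(Inf, n_cases)
    }
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
    age <- clamp(round(rnorm(n_cases, 60, 12)), 30, 90)
    gender <- sample(c("male", "female"), n_cases, replace = TRUE,
                     prob = c(0.67, 0.33))
    stage <- sample(c("I", "II", "III", "IV"), n_cases, replace = TRUE,
                    prob = c(0.52, 0.11, 0.23, 0.14))
    out <- data.frame(case_id = sprintf("case%04d", seq_len(n_cases)),
                      grade_true = grade, age = age, gender = gender,
                      stage = stage, time = time, event = event,
                      stringsAsFactors = FALSE)
    out <- cbind(out, as.data.frame(x))
    attr(out, "effect_sizes") <- eff
    attr(out, "hazard_ratio") <- hazard_ratio
    attr(out, "seed") <- seed
    class(out) <- c("synthetic_cohort", "data.frame")
    out
  })
}

#' Randomly place non-overlapping nucleus specs in a patch
#'
#' Rejection-samples ellipse centers so that axis-aligned bounding boxes
#' (with a 2 px margin) do not overlap and every ellipse lies fully inside
#' the patch.
#'
#' @param n number of nuclei requested
#' @param size integer (H, W) patch size
#' @param radius numeric (lo, hi) range for the major semi-axis in pixels
#' @param eccentricity numeric (lo, hi) range for the a/b axis ratio
#' @param chromatin_contrast texture amplitude passed to [nucleus_spec()]
#' @param base_stain hematoxylin OD passed to [nucleus_spec()]
#' @param seed integer seed
#' @return list of [nucleus_spec()] objects (length may be < `n` if the
#'   patch is too crowded; a warning is raised in that case)
#' @export
random_nucleus_specs <- function(n, size = c(256L, 256L), radius = c(9, 16),
                                 eccentricity = c(1, 1.8),
                                 chromatin_contrast = 0.3, base_stain = 0.8,
                                 seed = 1L) {
  withr::with_seed(seed, {
    specs <- list()
    boxes <- matrix(numeric(0), 0L, 4L)  # r1, r2, c1, c2
    tries <- 0L
    while (length(specs) < n && tries < n * 200L) {
      tries <- tries + 1L
      a <- runif(1L, radius[1L], radius[2L])
      b <- clamp(a / runif(1L, eccentricity[1L], eccentricity[2L]), 1, a)
      th <- runif(1L, 0, pi)
      sp <- nucleus_spec(center = c(0, 0), semi_axes = c(a, b),
                         orientation = th,
                         chromatin_contrast = chromatin_contrast,
                         base_stain = base_stain)
      ext <- ellipse_extent(sp)
      ctr <- c(runif(1L, ext["row"] + 2, size[1L] - ext["row"] - 1),
               runif(1L, ext["col"] + 2, size[2L] - ext["col"] - 1))
      box <- c(ctr[1L] - ext["row"] - 2, ctr[1L] + ext["row"] + 2,
               ctr[2L] - ext["col"] - 2, ctr[2L] + ext["col"] + 2)
      clash <- nrow(boxes) > 0 &&
        any(box[1L] <= boxes[, 2L] & box[2L] >= boxes[, 1L] &
            box[3L] <= boxes[, 4L] & box[4L] >= boxes[, 3L])
      if (clash) next
      sp$center <- ctr
      specs[[length(specs) + 1L]] <- sp
      boxes <- rbind(boxes, box)
    }
    if (length(specs) < n)
      warning(sprintf("placed only %d of %d nuclei", length(specs), n))
    specs
  })
}
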