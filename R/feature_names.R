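# Canonical naming of the 72 per-patch histomics features:
#   morphology (9):  morph_<name>
#   intensity (15):  int_<stat>_<channel>
#   texture   (48):  tex_<name>_<channel>
# with channels hsv (HSV value), lab (Lab lightness), he (hematoxylin OD).
# ROI summaries append _median / _mad, giving the 144-name space.

morph_feature_names <- c("area", "roundness", "elongation", "flatness",
                         "perimeter", "equivalent_spherical_perimeter",
                         "equivalent_spherical_radius", "ellipse_minor_axis",
                         "ellipse_major_axis")

intensity_stat_names <- c("mean", "median", "sd", "skewness", "kurtosis")

texture_stat_names <- c("correlation", "cluster_shade", "cluster_prominence",
                        "energy", "entropy", "haralick_correlation", "inertia",
                        "inverse_difference_moment", "gln", "rln", "lgre",
                        "hgre", "srlge", "srhge", "lrlge", "lrhge")

channel_codes <- c(hsv = "hsv_value", lab = "lab_lightness", he = "hematoxylin")

#' Canonical names of the 72 per-patch histomics features
#'
#' @return character vector of length 72 in canonical order: 9 morphology,
#'   15 intensity (5 statistics x 3 channels), 48 texture (16 statistics x
#'   3 channels)
#' @export
feature_names <- function() {
  c(paste0("morph_", morph_feature_names),
    as.vector(t(outer(intensity_stat_names, names(channel_codes),
                      function(s, ch) paste0("int_", s, "_", ch)))),
    as.vector(t(outer(texture_stat_names, names(channel_codes),
                      function(s, ch) paste0("tex_", s, "_", ch)))))
}

#' Canonical names of the 144 ROI-summarized features
#'
#' Each per-patch feature is summarized across a region of interest's
#' patches by its median and raw median absolute deviation.
#'
#' @return character vector of length 144
#' @export
summary_feature_names <- function() {
  fn <- feature_names()
  as.vector(rbind(paste0(fn, "_median"), paste0(fn, "_mad")))
}

#' Machine-readable manifest of the histomics features
#'
#' @return data.frame with columns `name`, `family` (morphology, intensity,
#'   texture), `base` (statistic name), and `channel` (`hsv`, `lab`, `he`,
#'   or `NA` for morphology)
#' @export
feature_manifest <- function() {
  nm <- feature_names()
  family <- ifelse(startsWith(nm, "morph_"), "morphology",
                   ifelse(startsWith(nm, "int_"), "intensity", "texture"))
  strip <- sub("^(morph|int|tex)_", "", nm)
  channel <- ifelse(family == "morphology", NA_character_,
                    sub(".*_(hsv|lab|he)$", "\\1", strip))
  base <- ifelse(family == "morphology", strip,
                 sub("_(hsv|lab|he)$", "", strip))
  data.frame(name = nm, family = family, base = base, channel = channel,
             stringsAsFactors = FALSE)
}
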