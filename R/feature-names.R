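#' Registry of the 31 lesion-level plaque features
#'
#' Returns the canonical feature table used throughout the package: one row
#' per feature in the standard reporting order, with the internal key (a
#' syntactic column name), the display label used in CSV headers and printed
#' tables, and the feature type (`"continuous"` or `"binary"`).
#'
#' The ordering is fixed: lesion length; four lumen features; six calcium
#' features; fifteen fibrous-cap (FC) features across the four thickness
#' classes (1, 2, 3, T); five vulnerable-plaque flags. All downstream
#' tie-breaks (e.g. in redundancy pruning) fall back on this order.
#'
#' @return A data.frame with columns `key`, `label`, `type`, in feature order.
#' @export
#' @examples
#' oct_features()$key
oct_features <- function() {
  f <- function(key, label, type) data.frame(key = key, label = label,
                                             type = type,
                                             stringsAsFactors = FALSE)
  rbind(
    f("lesion_length",           "Lesion length (mm)",            "continuous"),
    f("min_lumen_area",          "Minimum lumen area (mm^2)",     "continuous"),
    f("avg_lumen_area",          "Average lumen area (mm^2)",     "continuous"),
    f("min_lumen_diameter",      "Minimum lumen diameter (mm)",   "continuous"),
    f("avg_lumen_diameter",      "Average lumen diameter (mm)",   "continuous"),
    f("max_calcium_angle",       "Maximum calcium angle (deg)",   "continuous"),
    f("min_calcium_angle",       "Minimum calcium angle (deg)",   "continuous"),
    f("max_calcium_thickness",   "Maximum calcium thickness (mm)", "continuous"),
    f("min_calcium_thickness",   "Minimum calcium thickness (mm)", "continuous"),
    f("max_calcium_depth",       "Maximum calcium depth (mm)",    "continuous"),
    f("min_calcium_depth",       "Minimum calcium depth (mm)",    "continuous"),
    f("max_fc_angle",            "Maximum FC angle (deg)",        "continuous"),
    f("min_fc_angle",            "Minimum FC angle (deg)",        "continuous"),
    f("min_fc_thickness",        "Minimum FC thickness (mm)",     "continuous"),
    f("max_fc_area_1",           "Maximum FC area-1 (mm^2)",      "continuous"),
    f("max_fc_area_2",           "Maximum FC area-2 (mm^2)",      "continuous"),
    f("max_fc_area_3",           "Maximum FC area-3 (mm^2)",      "continuous"),
    f("max_fc_area_t",           "Maximum FC area-T (mm^2)",      "continuous"),
    f("fc_surface_area_1",       "FC Surface area-1 (mm^2)",      "continuous"),
    f("fc_surface_area_2",       "FC Surface area-2 (mm^2)",      "continuous"),
    f("fc_surface_area_3",       "FC Surface area-3 (mm^2)",      "continuous"),
    f("fc_surface_area_t",       "FC Surface area-T (mm^2)",      "continuous"),
    f("fc_burden_1",             "FC burden-1",                   "continuous"),
    f("fc_burden_2",             "FC burden-2",                   "continuous"),
    f("fc_burden_3",             "FC burden-3",                   "continuous"),
    f("fc_burden_t",             "FC burden-T",                   "continuous"),
    f("microchannel",            "Microchannel",                  "binary"),
    f("macrophage_infiltration", "Macrophage Infiltration",       "binary"),
    f("cholesterol_crystal",     "Cholesterol Crystal",           "binary"),
    f("layered_plaque",          "Layered Plaque",                "binary"),
    f("calcium_nodule",          "Calcium Nodule",                "binary")
  )
}

#' @rdname oct_features
#' @export
oct_feature_keys <- function() oct_features()$key

# label <-> key translation used by the CSV readers/writers
.key_to_label <- function(keys) {
  reg <- oct_features()
  out <- reg$label[match(keys, reg$key)]
  out[is.na(out)] <- keys[is.na(out)]
  out
}

.label_to_key <- function(labels) {
  reg <- oct_features()
  out <- reg$key[match(labels, reg$label)]
  out[is.na(out)] <- labels[is.na(out)]
  out
}

#' Names of the five vulnerable-plaque flags
#' @return Character vector of flag keys (frame-level presence indicators).
#' @export
oct_vp_flags <- function() {
  c("microchannel", "macrophage_infiltration", "cholesterol_crystal",
    "layered_plaque", "calcium_nodule")
}

# integer labels used in segmentation masks
OCT_LABELS <- c(background = 0L, lumen = 1L, calcium = 2L, lipid = 3L,
                fibrous_cap = 4L)
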