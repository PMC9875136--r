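#' Lesion-versus-NAWM elevation
#'
#' Difference between the mean of a quantitative map over a lesion ROI and
#' over its normal-appearing white-matter (NAWM) reference ROI. Sentinel
#' (`NaN`/`NA`) voxels are excluded; a lesion with fewer than `min_voxels`
#' valid voxels in either ROI is flagged unevaluable.
#'
#' @param map Quantitative map (matrix), or a `kex_map` /
#'   `susceptibility_map` object.
#' @param lesion_mask,nawm_mask Disjoint, nonempty logical masks.
#' @param min_voxels Minimum valid voxels per ROI.
#'
#' @return One-row tibble: `delta`, `lesion_mean`, `nawm_mean`, `nawm_sd`,
#'   `n_lesion`, `n_nawm`, `n_excluded`, `evaluable`.
#' @export
roi_delta <- function(map, lesion_mask, nawm_mask, min_voxels = 5) {
  m <- map_values(map)
  stop_if(!any(lesion_mask) || !any(nawm_mask), "masks must be nonempty")
  stop_if(any(lesion_mask & nawm_mask), "lesion and NAWM masks must be disjoint")
  lv <- m[lesion_mask]; nv <- m[nawm_mask]
  lv_ok <- lv[is.finite(lv)]; nv_ok <- nv[is.finite(nv)]
  n_excluded <- (length(lv) - length(lv_ok)) + (length(nv) - length(nv_ok))
  evaluable <- length(lv_ok) >= min_voxels && length(nv_ok) >= min_voxels
  tibble::tibble(
    delta = if (evaluable) mean(lv_ok) - mean(nv_ok) else NA_real_,
    lesion_mean = if (length(lv_ok)) mean(lv_ok) else NA_real_,
    nawm_mean = if (length(nv_ok)) mean(nv_ok) else NA_real_,
    nawm_sd = if (length(nv_ok) > 1) sd(nv_ok) else NA_real_,
    n_lesion = length(lv_ok), n_nawm = length(nv_ok),
    n_excluded = n_excluded, evaluable = evaluable
  )
}

map_values <- function(map) {
  if (inherits(map, "kex_map")) return(map$kex)
  if (inherits(map, "susceptibility_map")) return(map$chi)
  if (inherits(map, "field_map")) return(map$field)
  map
}

#' Positivity rule for an elevation
#'
#' A lesion is positive when its elevation exceeds `tau` and exceeds
#' `z_min` NAWM standard deviations. The defaults (`tau = 0`, `z_min = 0`)
#' reduce to the strict sign rule — elevation above zero — the numeric
#' surrogate for the radiologists' visual call.
#'
#' @param delta Elevation (map units); vectorized.
#' @param nawm_sd NAWM standard deviation (same units).
#' @param tau Absolute threshold.
#' @param z_min Multiplier on `nawm_sd`.
#'
#' @return Logical.
#' @export
positivity <- function(delta, nawm_sd = 0, tau = 0, z_min = 0) {
  stop_if(any(nawm_sd < 0, na.rm = TRUE), "nawm_sd must be >= 0")
  delta > tau & delta > z_min * nawm_sd
}

#' Nodular-versus-ring shape of a lesion on a map
#'
#' Splits the lesion mask into a rim (the outer `rim_fraction` of the
#' effective radius, obtained by binary erosion) and a core, and calls the
#' lesion ring-shaped when the NAWM-referenced rim mean is at least
#' `ring_ratio` times the referenced core mean and both are positive
#' (hyperintensity concentrated at the lesion edge). Masks too small to
#' erode are nodular by convention and flagged.
#'
#' @param map Quantitative map (matrix or map object).
#' @param mask Logical lesion mask.
#' @param nawm_mean Reference level subtracted before comparison.
#' @param rim_fraction Fraction of the effective radius forming the rim.
#' @param ring_ratio Rim/core contrast at or above which the lesion is ring.
#'
#' @return List: `shape` (`"ring"` or `"nodular"`), `rim_mean`, `core_mean`,
#'   `flagged` (mask too small to erode).
#' @export
shape_classify <- function(map, mask, nawm_mean = 0, rim_fraction = 0.3,
                           ring_ratio = 1.2) {
  m <- map_values(map)
  stop_if(!any(mask), "empty lesion mask")
  r_eff <- sqrt(sum(mask) / pi)
  n_iter <- max(1L, round(rim_fraction * r_eff))
  core <- erode_mask(mask, n_iter)
  if (!any(core)) {
    return(list(shape = "nodular", rim_mean = mean(m[mask], na.rm = TRUE),
                core_mean = NA_real_, flagged = TRUE))
  }
  rim <- mask & !core
  rim_mean <- mean(m[rim], na.rm = TRUE) - nawm_mean
  core_mean <- mean(m[core], na.rm = TRUE) - nawm_mean
  ring <- is.finite(rim_mean) && is.finite(core_mean) &&
    rim_mean > 0 && core_mean > 0 && rim_mean >= ring_ratio * core_mean
  list(shape = if (ring) "ring" else "nodular",
       rim_mean = rim_mean, core_mean = core_mean, flagged = FALSE)
}

#' Assign stratification patterns from positivity flags
#'
#' All gadolinium-enhancing lesions form one category (`GdPlus`);
#' non-enhancing lesions are stratified by joint exchange-rate/QSM
#' positivity: Pattern I (both positive), IIa (exchange-rate positive only),
#' IIb (QSM positive only), III (both negative).
#'
#' @param gd_positive,kex_positive,qsm_positive Logical vectors.
#'
#' @return Factor with levels `GdPlus, I, IIa, IIb, III`.
#' @export
#' @examples
#' assign_pattern(FALSE, TRUE, TRUE)    # I
#' assign_pattern(FALSE, FALSE, TRUE)   # IIb
assign_pattern <- function(gd_positive, kex_positive, qsm_positive) {
  stop_if(any(is.na(gd_positive)), "gd_positive must be resolved")
  out <- ifelse(gd_positive, "GdPlus",
         ifelse(kex_positive & qsm_positive, "I",
         ifelse(kex_positive & !qsm_positive, "IIa",
         ifelse(!kex_positive & qsm_positive, "IIb", "III"))))
  factor(out, levels = c("GdPlus", "I", "IIa", "IIb", "III"))
}

#' Classify a lesion record table
#'
#' Adds `pattern` (GdPlus/I/IIa/IIb/III) and `pattern_merged`
#' (GdPlus/I/II/III, the IIa/IIb subtypes merged) columns. If positivity
#' flags are absent but elevations (`delta_kex`, `delta_chi`) are present,
#' flags are derived with [positivity()] first.
#'
#' @param records Tibble with `gd_positive` and either positivity flags
#'   (`kex_positive`, `qsm_positive`) or elevations (`delta_kex`,
#'   `delta_chi`).
#' @param tau,z_min Passed to [positivity()] when flags are derived.
#'
#' @return The records tibble with added columns.
#' @export
classify_lesions <- function(records, tau = 0, z_min = 0) {
  if (!all(c("kex_positive", "qsm_positive") %in% names(records))) {
    stop_if(!all(c("delta_kex", "delta_chi") %in% names(records)),
            "records need positivity flags or delta_kex/delta_chi columns")
    sd_k <- if ("nawm_sd_kex" %in% names(records)) records$nawm_sd_kex else 0
    sd_c <- if ("nawm_sd_chi" %in% names(records)) records$nawm_sd_chi else 0
    records$kex_positive <- positivity(records$delta_kex, sd_k, tau, z_min)
    records$qsm_positive <- positivity(records$delta_chi, sd_c, tau, z_min)
  }
  records$pattern <- assign_pattern(records$gd_positive,
                                    records$kex_positive,
                                    records$qsm_positive)
  records$pattern_merged <- factor(
    ifelse(records$pattern %in% c("IIa", "IIb"), "II",
           as.character(records$pattern)),
    levels = c("GdPlus", "I", "II", "III"))
  records
}

#' Per-patient pattern summary
#'
#' Counts and percentages of each pattern among a patient's
#' gadolinium-negative lesions (the percentage denominators); patients with
#' no gadolinium-negative lesion are flagged and carry `NA` percentages so
#' they drop out of duration correlations.
#'
#' @param records Classified lesion tibble (see [classify_lesions()]).
#'
#' @return Tibble, one row per patient: `n_lesions`, `n_gd_pos`, `n_gd_neg`,
#'   `n_I`, `n_IIa`, `n_IIb`, `n_III`, `pct_I`, `pct_II`, `pct_III`,
#'   `no_gd_neg` flag.
#' @export
patient_summary <- function(records) {
  stop_if(!"pattern" %in% names(records), "records must be classified first")
  records |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      n_lesions = dplyr::n(),
      n_gd_pos = sum(.data$pattern == "GdPlus"),
      n_gd_neg = sum(.data$pattern != "GdPlus"),
      n_I = sum(.data$pattern == "I"),
      n_IIa = sum(.data$pattern == "IIa"),
      n_IIb = sum(.data$pattern == "IIb"),
      n_III = sum(.data$pattern == "III"),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      pct_I = 100 * .data$n_I / dplyr::na_if(.data$n_gd_neg, 0L),
      pct_II = 100 * (.data$n_IIa + .data$n_IIb) / dplyr::na_if(.data$n_gd_neg, 0L),
      pct_III = 100 * .data$n_III / dplyr::na_if(.data$n_gd_neg, 0L),
      no_gd_neg = .data$n_gd_neg == 0L
    )
}

#' Measure and classify lesions on quantitative maps
#'
#' For each lesion ROI: exchange-rate and susceptibility elevations against
#' its NAWM reference ([roi_delta()]), positivity flags, QSM shape
#' (ring/nodular; exchange-rate maps are never shape-classified), an
#' eligibility filter on the long axis, and the pattern assignment.
#'
#' @param kmap `kex_map` (or matrix, s^-1).
#' @param qmap `susceptibility_map` (or matrix, ppb).
#' @param rois List of ROI entries: `lesion_id`, `patient_id`, `mask`,
#'   `nawm_mask`, `gd_positive`, `gd_shape`.
#' @param voxel_mm In-plane voxel size, mm.
#' @param min_long_axis_mm Minimum lesion long axis, mm.
#' @param tau,z_min Positivity rule parameters.
#'
#' @return Classified lesion tibble with one row per eligible, evaluable
#'   lesion; ineligible/unevaluable lesions are retained with
#'   `eligible`/`evaluable` set `FALSE` and `NA` pattern.
#' @export
measure_lesions <- function(kmap, qmap, rois, voxel_mm = 1.875,
                            min_long_axis_mm = 3, tau = 0, z_min = 0) {
  rows <- purrr::map_dfr(rois, function(roi) {
    long_axis <- mask_long_axis(roi$mask) * voxel_mm
    eligible <- long_axis >= min_long_axis_mm
    dk <- roi_delta(kmap, roi$mask, roi$nawm_mask)
    dc <- roi_delta(qmap, roi$mask, roi$nawm_mask)
    qsm_shape <- "none"
    qsm_pos <- positivity(dc$delta, dc$nawm_sd, tau, z_min)
    if (isTRUE(qsm_pos)) {
      qsm_shape <- shape_classify(qmap, roi$mask, nawm_mean = dc$nawm_mean)$shape
    }
    tibble::tibble(
      lesion_id = roi$lesion_id, patient_id = roi$patient_id,
      gd_positive = roi$gd_positive,
      gd_shape = if (!is.null(roi$gd_shape)) roi$gd_shape else
        if (roi$gd_positive) "nodular" else "none",
      long_axis_mm = long_axis, eligible = eligible,
      evaluable = dk$evaluable && dc$evaluable,
      delta_kex = dk$delta, delta_chi = dc$delta,
      nawm_sd_kex = dk$nawm_sd, nawm_sd_chi = dc$nawm_sd,
      kex_positive = positivity(dk$delta, dk$nawm_sd, tau, z_min),
      qsm_positive = qsm_pos, qsm_shape = qsm_shape
    )
  })
  out <- classify_lesions(rows, tau = tau, z_min = z_min)
  out$pattern[!(out$eligible & out$evaluable)] <- NA
  out$pattern_merged[!(out$eligible & out$evaluable)] <- NA
  out
}

# longest voxel-to-voxel extent of a mask (+1 voxel for voxel width)
mask_long_axis <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) return(0)
  if (nrow(idx) == 1) return(1)
  max(stats::dist(idx)) + 1
}
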