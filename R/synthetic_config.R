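#' Synthetic-data configuration
#'
#' Bundles every tunable of the synthetic generators with defaults emulating
#' the signal structure of a MERFISH olfactory-receptor experiment: somas
#' expressing exactly one receptor whose 4 on-bit channels carry correlated
#' signal above background; ring-structured receptor zones with a
#' basal-apical sub-gradient in the epithelium; glomeruli with one dominant
#' receptor in mirrored medial/lateral pairs across hemispheres; serial
#' sections related by rigid transforms plus a smooth deformation; and
#' per-cell Egr1 counts drawn from planted per-receptor response fractions.
#'
#' Image-scale defaults (the `image_*` and soma parameters) describe a single
#' decoding field of view at 0.5 um lateral / 1 um axial voxels; atlas-scale
#' defaults (`atlas_*`) describe millimetre-scale cell tables used for
#' spatial statistics, where images are not rendered.
#'
#' @param ... Named overrides of any default listed below.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(...) {
  cfg <- list(
    # image-scale MOE section (decoding tests)
    image_shape = c(ny = 400L, nx = 400L, nz = 5L),
    pixel_um = c(x = 0.5, y = 0.5, z = 1.0),
    n_cells = 200L,
    n_receptors = 50L,
    soma_radius_um = 2.5,
    soma_z_radius_um = 1.6,
    min_separation_um = 8,
    image_ring_range_um = c(30, 92),
    ring_sd_um = 6,
    amplitude = 20,
    background = 2,
    noise_sd = 1,
    texture_sd = 0.5,
    gain_range = c(0.8, 1.2),
    max_place_tries = 300L,
    # Egr1 spot model
    egr1_lambda_high = 3,    # responders: count = 6 + Poisson(lambda_high)
    egr1_lambda_low = 0.3,   # non-responders: Poisson(lambda_low)
    egr1_amplitude = 30,
    egr1_background = 1,
    egr1_noise_sd = 0.5,
    egr1_min_spot_sep_um = 1.6,
    # atlas-scale MOE cell tables
    atlas_n_receptors = 46L,
    atlas_n_unusual = 4L,
    atlas_cells_per_type = 40L,
    atlas_n_sections = 4L,
    atlas_ring_range_um = c(450, 1400),
    atlas_ring_sd_um = 40,
    atlas_unusual_radius_um = 100,
    atlas_thickness_um = 60,
    ba_offset_range = c(0.2, 0.8),
    ba_depth_sd = 0.1,
    # olfactory bulb series
    ob_extent_um = c(x = 1600, y = 1000),
    ob_midline_um = 800,
    ob_n_sections = 10L,
    ob_z_step_um = 16,
    ob_n_receptors = 30L,
    glom_radius_um = 40,
    glom_dominant_count = 30L,
    glom_background_rate = 0.3,
    glom_jitter_um = 30,
    spot_jitter_um = 0.04,
    spot_brightness_meanlog = log(10),
    spot_bg_brightness_meanlog = log(3),
    spot_brightness_sdlog = 0.25,
    alternate_pools = FALSE,
    # section deformation model
    deform_theta_max_deg = 8,
    deform_shift_max_px = 20,
    deform_amplitude_px = 5,
    deform_period_um = 1500
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad))
    stop_orfish("unknown config fields: ", paste(bad, collapse = ", "),
                class = "orfish_config_error")
  cfg[names(over)] <- over
  geom <- c("soma_radius_um", "soma_z_radius_um", "min_separation_um",
            "ring_sd_um", "glom_radius_um", "atlas_thickness_um")
  for (f in geom) if (any(cfg[[f]] <= 0))
    stop_orfish(f, " must be positive", class = "orfish_config_error")
  structure(cfg, class = "synthetic_config")
}
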