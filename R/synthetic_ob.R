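#' Simulate a serial-section olfactory bulb series
#'
#' Generates per-section glomerulus label masks, bit-level spot tables and
#' ground truth for a bilateral bulb: each receptor in the panel projects to
#' one medial and one lateral glomerulus per hemisphere, mirror-symmetric
#' about the midline up to positional jitter. Each glomerulus carries
#' point-like transcript spots of its dominant receptor (4 co-localized
#' bit-spots per molecule, following the receptor's code) plus uniform
#' background molecules of random untargeted receptors at lower brightness.
#' Optionally alternating sections carry only half the receptor panel,
#' emulating two probe pools hybridized in alternation.
#'
#' @param config A [synthetic_config()].
#' @param codebook An `or_codebook` covering at least `ob_n_receptors`
#'   receptors plus some untargeted ones used for background.
#' @param seed Integer seed.
#' @param jitter_um Positional jitter of mirrored glomeruli (defaults to
#'   `config$glom_jitter_um`; 0 gives exactly mirrored placements).
#' @param emit_spots If `FALSE`, skip spot tables (masks and truth only).
#' @return A list with `glomeruli` (data.frame: glom_id, section, hemisphere,
#'   side, label, x_um, y_um, z_um, radius_um, receptor, planted_count),
#'   `spots` (data.frame: section, bit, x_um, y_um, z_um, brightness,
#'   molecule_id, receptor, background), `masks` (list of integer label
#'   matrices, one per section, at `mask_pixel_um` resolution),
#'   `mask_pixel_um`, and `panel` (targeted receptor ids; `pool` column in
#'   `glomeruli` when `alternate_pools`).
#' @export
simulate_ob_series <- function(config = synthetic_config(),
                               codebook = build_codebook(
                                 sprintf("OR%03d", 1:60), seed = 1),
                               seed = 1, jitter_um = NULL,
                               emit_spots = TRUE) {
  jitter_um <- jitter_um %||% config$glom_jitter_um
  with_seed(seed, {
    nrec <- config$ob_n_receptors
    all_ids <- rownames(codebook$entries)
    if (length(all_ids) < nrec)
      stop_orfish("codebook smaller than ob_n_receptors",
                  class = "orfish_input_error")
    panel <- all_ids[seq_len(nrec)]
    untargeted <- setdiff(all_ids, panel)
    if (!length(untargeted)) untargeted <- panel
    mid <- config$ob_midline_um
    ext <- config$ob_extent_um
    nsec <- config$ob_n_sections
    rad <- config$glom_radius_um
    # per-receptor geometry: 1 medial + 1 lateral glomerulus per hemisphere,
    # mirrored about the midline, placed with rejection to avoid overlap
    placed <- lapply(seq_len(nsec), function(s) matrix(numeric(0), 0, 2))
    glom <- list(); gi <- 0L
    min_gap <- 2 * rad + 5
    for (r in seq_len(nrec)) {
      ok <- FALSE
      for (try in seq_len(300L)) {
        # medial and lateral pairs sit in different sections (as in real
        # bulbs, where they occupy different anterior-posterior positions);
        # bilateral twins share a section and mirror exactly at zero jitter
        ss <- sample.int(nsec, 2)
        y0 <- stats::runif(1, rad + 10, ext[["y"]] - rad - 10)
        dxm <- stats::runif(1, 120, 320)
        dxl <- stats::runif(1, 450, mid - rad - 10)
        cand <- rbind(
          c(mid - dxm, y0), c(mid + dxm, y0),
          c(mid - dxl, y0), c(mid + dxl, y0)) +
          matrix(stats::rnorm(8, 0, jitter_um), 4, 2)
        sec4 <- ss[c(1, 1, 2, 2)]
        clash <- FALSE
        for (k in 1:4) {
          same <- which(sec4 == sec4[k]); same <- setdiff(same, k)
          if (length(same) &&
              min(cross_dist(cand[k, , drop = FALSE],
                             cand[same, , drop = FALSE])) < min_gap) clash <- TRUE
          if (nrow(placed[[sec4[k]]]) &&
              min(cross_dist(cand[k, , drop = FALSE],
                             placed[[sec4[k]]])) < min_gap) clash <- TRUE
        }
        if (clash) next
        ok <- TRUE
        break
      }
      if (!ok)
        stop_orfish("could not place glomeruli for receptor ", panel[r],
                    " without overlap", class = "orfish_placement_error")
      hemi_side <- cbind(hemi = c("left", "right", "left", "right"),
                         side = c("medial", "medial", "lateral", "lateral"))
      for (k in 1:4) {
        placed[[sec4[k]]] <- rbind(placed[[sec4[k]]], cand[k, , drop = FALSE])
        gi <- gi + 1L
        glom[[gi]] <- data.frame(
          glom_id = gi, section = sec4[k], hemisphere = hemi_side[k, 1],
          side = hemi_side[k, 2], x_um = cand[k, 1], y_um = cand[k, 2],
          radius_um = rad, receptor = panel[r], stringsAsFactors = FALSE)
      }
    }
    glomeruli <- do.call(rbind, glom)
    glomeruli$z_um <- (glomeruli$section - 1L) * config$ob_z_step_um
    # pools
    if (config$alternate_pools) {
      poolA <- panel[seq_len(ceiling(nrec / 2))]
      glomeruli$pool <- ifelse(glomeruli$section %% 2L == 1L, "A", "B")
      in_pool <- ifelse(glomeruli$pool == "A", glomeruli$receptor %in% poolA,
                        !(glomeruli$receptor %in% poolA))
    } else in_pool <- rep(TRUE, nrow(glomeruli))
    glomeruli$planted_count <- ifelse(in_pool, config$glom_dominant_count, 0L)
    # masks: label images on a coarse grid
    mask_px <- 8
    mny <- ceiling(ext[["y"]] / mask_px); mnx <- ceiling(ext[["x"]] / mask_px)
    xs <- (seq_len(mnx) - 0.5) * mask_px
    ys <- (seq_len(mny) - 0.5) * mask_px
    masks <- lapply(seq_len(nsec), function(s) {
      m <- matrix(0L, mny, mnx)
      gs <- glomeruli[glomeruli$section == s, ]
      for (k in seq_len(nrow(gs))) {
        ix <- which(abs(xs - gs$x_um[k]) <= rad)
        iy <- which(abs(ys - gs$y_um[k]) <= rad)
        g <- expand.grid(iy = iy, ix = ix)
        inside <- (xs[g$ix] - gs$x_um[k])^2 + (ys[g$iy] - gs$y_um[k])^2 <= rad^2
        m[cbind(g$iy[inside], g$ix[inside])] <- gs$glom_id[k]
      }
      m
    })
    spots <- NULL
    if (emit_spots) {
      mol <- list(); mi <- 0L
      for (k in seq_len(nrow(glomeruli))) {
        nk <- glomeruli$planted_count[k]
        if (nk <= 0) next
        rr <- rad * sqrt(stats::runif(nk)); aa <- stats::runif(nk, 0, 2 * pi)
        mol[[length(mol) + 1L]] <- data.frame(
          molecule_id = mi + seq_len(nk), section = glomeruli$section[k],
          x_um = glomeruli$x_um[k] + rr * cos(aa),
          y_um = glomeruli$y_um[k] + rr * sin(aa),
          z_um = stats::runif(nk, 0, 10),
          receptor = glomeruli$receptor[k], background = FALSE,
          stringsAsFactors = FALSE)
        mi <- mi + nk
      }
      n_bg <- stats::rpois(1, config$glom_background_rate * nrow(glomeruli))
      if (n_bg > 0) {
        mol[[length(mol) + 1L]] <- data.frame(
          molecule_id = mi + seq_len(n_bg),
          section = sample(seq_len(nsec), n_bg, replace = TRUE),
          x_um = stats::runif(n_bg, 0, ext[["x"]]),
          y_um = stats::runif(n_bg, 0, ext[["y"]]),
          z_um = stats::runif(n_bg, 0, 10),
          receptor = sample(untargeted, n_bg, replace = TRUE),
          background = TRUE, stringsAsFactors = FALSE)
      }
      molecules <- do.call(rbind, mol)
      # expand each molecule into its 4 bit-spots
      code <- codebook$entries[molecules$receptor, , drop = FALSE]
      nmol <- nrow(molecules)
      ob <- codebook$on_bits
      bright_mean <- ifelse(molecules$background,
                            config$spot_bg_brightness_meanlog,
                            config$spot_brightness_meanlog)
      spots <- data.frame(
        section = rep(molecules$section, each = ob),
        bit = as.integer(t(code)),
        x_um = rep(molecules$x_um, each = ob) +
          stats::runif(nmol * ob, -1, 1) * config$spot_jitter_um,
        y_um = rep(molecules$y_um, each = ob) +
          stats::runif(nmol * ob, -1, 1) * config$spot_jitter_um,
        z_um = rep(molecules$z_um, each = ob) +
          stats::runif(nmol * ob, -1, 1) * config$spot_jitter_um,
        brightness = stats::rlnorm(nmol * ob, rep(bright_mean, each = ob),
                                   config$spot_brightness_sdlog),
        molecule_id = rep(molecules$molecule_id, each = ob),
        receptor = rep(molecules$receptor, each = ob),
        background = rep(molecules$background, each = ob),
        stringsAsFactors = FALSE)
    }
    list(glomeruli = glomeruli, spots = spots, masks = masks,
         mask_pixel_um = mask_px, panel = panel, untargeted = untargeted)
  })
}

#' Simulate aligned projection maps for several animals
#'
#' Produces per-animal glomerular projection maps in a common frame: each
#' receptor has a true medial and lateral position per hemisphere, mirrored
#' about the midline; every observed glomerulus position is the truth plus
#' isotropic 3D jitter. Optional planted monotone mappings tie the
#' dorsal-ventral (y) position to a central-peripheral coordinate and the
#' anterior-posterior (z) position to a basal-apical coordinate.
#'
#' @param n_receptors Number of receptors.
#' @param n_animals Number of animals (maps).
#' @param jitter_um Isotropic per-glomerulus jitter standard deviation.
#' @param cp,ba Optional per-receptor coordinates in `[0, 1]` driving the
#'   planted DV / AP mappings (default uniform draws).
#' @param dv_range,ap_range Ranges (um) the cp / ba coordinates map onto.
#' @param extent_um Named extent `(x, y, z)` of the volume.
#' @param midline_um Midsagittal plane x position.
#' @param seed Integer seed.
#' @return A list of projection-map data.frames (`receptor`, `animal`,
#'   `hemisphere`, `side`, `x_um`, `y_um`, `z_um`, `tier`, `count`), with
#'   attribute `truth` (per-receptor true positions and the cp/ba used).
#' @export
simulate_projection_maps <- function(n_receptors = 100L, n_animals = 2L,
                                     jitter_um = 30, cp = NULL, ba = NULL,
                                     dv_range = c(100, 900),
                                     ap_range = c(100, 900),
                                     extent_um = c(x = 1600, y = 1000, z = 1000),
                                     midline_um = 800, seed = 1) {
  with_seed(seed, {
    receptors <- sprintf("OR%03d", seq_len(n_receptors))
    cp <- cp %||% stats::runif(n_receptors)
    ba <- ba %||% stats::runif(n_receptors)
    y0 <- dv_range[1] + cp * diff(dv_range)
    z0 <- ap_range[1] + ba * diff(ap_range)
    dx_med <- stats::runif(n_receptors, 120, 320)
    dx_lat <- stats::runif(n_receptors, 450, midline_um - 60)
    truth <- data.frame(receptor = receptors, cp = cp, ba = ba,
                        y_um = y0, z_um = z0, dx_medial = dx_med,
                        dx_lateral = dx_lat, stringsAsFactors = FALSE)
    maps <- lapply(seq_len(n_animals), function(a) {
      rows <- list(); k <- 0L
      for (r in seq_len(n_receptors)) {
        for (hemi in c("left", "right")) {
          for (side in c("medial", "lateral")) {
            dx <- if (side == "medial") dx_med[r] else dx_lat[r]
            x0 <- if (hemi == "left") midline_um - dx else midline_um + dx
            k <- k + 1L
            rows[[k]] <- data.frame(
              receptor = receptors[r], animal = a, hemisphere = hemi,
              side = side,
              x_um = x0 + stats::rnorm(1, 0, jitter_um),
              y_um = y0[r] + stats::rnorm(1, 0, jitter_um),
              z_um = z0[r] + stats::rnorm(1, 0, jitter_um),
              tier = "strict", count = 30L, stringsAsFactors = FALSE)
          }
        }
      }
      do.call(rbind, rows)
    })
    attr(maps, "truth") <- truth
    attr(maps, "midline_um") <- midline_um
    maps
  })
}

#' Simulate a nuclear-stain section image
#'
#' A field of Gaussian nuclei blobs on a dark background, used as the
#' landmark signal for section alignment tests.
#'
#' @param ny,nx Image size in pixels.
#' @param n_blobs Number of nuclei.
#' @param radius_px Gaussian sigma of a nucleus in pixels.
#' @param seed Integer seed.
#' @param noise_sd Additive Gaussian noise sd.
#' @return A numeric `ny x nx` matrix.
#' @export
simulate_nuclei_image <- function(ny = 400L, nx = 400L, n_blobs = 400L,
                                  radius_px = 3, seed = 1, noise_sd = 0.02) {
  with_seed(seed, {
    img <- matrix(0, ny, nx)
    cx <- stats::runif(n_blobs, 1, nx)
    cy <- stats::runif(n_blobs, 1, ny)
    amp <- stats::runif(n_blobs, 0.5, 1)
    w <- ceiling(3 * radius_px)
    for (i in seq_len(n_blobs)) {
      ix <- max(1, floor(cx[i] - w)):min(nx, ceiling(cx[i] + w))
      iy <- max(1, floor(cy[i] - w)):min(ny, ceiling(cy[i] + w))
      img[iy, ix] <- img[iy, ix] + amp[i] *
        exp(-(outer((iy - cy[i])^2, (ix - cx[i])^2, "+")) / (2 * radius_px^2))
    }
    img + matrix(stats::rnorm(ny * nx, 0, noise_sd), ny, nx)
  })
}

#' Warp an image through an inverse coordinate map
#'
#' Resamples `img` so that `out[p] = img[inv_map(p)]` by bilinear
#' interpolation, with pixel coordinates `(x = column, y = row)` and zero
#' outside the source. `inv_map` maps output-frame points to source-frame
#' points, e.g. the inverse of a `rigid2d` for a forward rigid motion.
#'
#' @param img Numeric matrix.
#' @param inv_map Function taking an `n x 2` matrix of `(x, y)` points and
#'   returning same-shape source coordinates, or a `rigid2d` (used as the
#'   map from output to source directly).
#' @return Warped matrix, same size as `img`.
#' @export
warp_image <- function(img, inv_map) {
  if (inherits(inv_map, "rigid2d")) {
    rt <- inv_map
    inv_map <- function(p) rigid_apply(rt, p)
  }
  ny <- nrow(img); nx <- ncol(img)
  g <- cbind(x = rep(seq_len(nx), each = ny), y = rep(seq_len(ny), times = nx))
  src <- inv_map(g)
  x <- src[, 1]; y <- src[, 2]
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  val <- function(xx, yy) {
    ok <- xx >= 1 & xx <= nx & yy >= 1 & yy <= ny
    v <- numeric(length(xx))
    v[ok] <- img[cbind(yy[ok], xx[ok])]
    v
  }
  out <- (1 - fx) * (1 - fy) * val(x0, y0) + fx * (1 - fy) * val(x0 + 1, y0) +
    (1 - fx) * fy * val(x0, y0 + 1) + fx * fy * val(x0 + 1, y0 + 1)
  matrix(out, ny, nx)
}
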