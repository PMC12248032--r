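#' Simulate atlas-scale MOE cell tables
#'
#' Generates olfactory sensory neuron positions over several coronal sections
#' at millimetre scale, with the spatial structure the atlas statistics
#' assume: each receptor occupies a concentric ring zone (radius drawn per
#' cell around the receptor's planted ring radius), a small group of
#' "unusual zone" receptors is confined to a central patch detached from the
#' rings, and every receptor carries a planted basal-apical depth offset
#' realised as the cell's normalized depth in a slab of thickness
#' `atlas_thickness_um`.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed.
#' @param n_animals Number of animals (sections are split across animals).
#' @return A data.frame of cells (`cell_id`, `animal`, `section`, `receptor`,
#'   `x_um`, `y_um`, `depth`, `z_um`, `brightness`) with attribute
#'   `receptor_truth`: per-receptor planted `ring_radius_um`, `cp_true`
#'   (normalized ring order, 0 = most central), `ba_offset`, `is_unusual`.
#' @export
simulate_moe_cells <- function(config = synthetic_config(), seed = 1,
                               n_animals = 2L) {
  with_seed(seed, {
    nr <- config$atlas_n_receptors
    nu <- config$atlas_n_unusual
    ring <- seq(config$atlas_ring_range_um[1], config$atlas_ring_range_um[2],
                length.out = nr)
    receptors <- sprintf("OR%03d", seq_len(nr + nu))
    ring_receptors <- receptors[seq_len(nr)]
    unusual <- if (nu > 0) receptors[nr + seq_len(nu)] else character()
    cp_true <- (ring - min(ring)) / diff(range(ring))
    ba_offset <- stats::runif(nr + nu, config$ba_offset_range[1],
                              config$ba_offset_range[2])
    names(ba_offset) <- receptors
    truth <- data.frame(
      receptor = receptors,
      ring_radius_um = c(ring, rep(NA_real_, nu)),
      cp_true = c(cp_true, rep(NA_real_, nu)),
      ba_offset = as.numeric(ba_offset),
      is_unusual = c(rep(FALSE, nr), rep(TRUE, nu)),
      stringsAsFactors = FALSE
    )
    n_sec <- config$atlas_n_sections
    per <- config$atlas_cells_per_type
    out <- vector("list", n_sec)
    for (s in seq_len(n_sec)) {
      rec <- rep(receptors, each = per)
      n <- length(rec)
      r_ring <- rep(c(ring, rep(NA_real_, nu)), each = per)
      is_unu <- is.na(r_ring)
      rad <- numeric(n)
      rad[!is_unu] <- pmax(stats::rnorm(sum(!is_unu), r_ring[!is_unu],
                                        config$atlas_ring_sd_um), 0)
      rad[is_unu] <- config$atlas_unusual_radius_um *
        sqrt(stats::runif(sum(is_unu)))
      ang <- stats::runif(n, 0, 2 * pi)
      depth <- pmin(pmax(stats::rnorm(n, ba_offset[rec], config$ba_depth_sd),
                         0), 1)
      out[[s]] <- data.frame(
        animal = ((s - 1L) %% n_animals) + 1L,
        section = s,
        receptor = rec,
        x_um = rad * cos(ang),
        y_um = rad * sin(ang),
        depth = depth,
        z_um = depth * config$atlas_thickness_um,
        brightness = stats::rlnorm(n, meanlog = 0, sdlog = 0.3),
        stringsAsFactors = FALSE
      )
    }
    cells <- do.call(rbind, out)
    cells <- cbind(cell_id = seq_len(nrow(cells)), cells)
    attr(cells, "receptor_truth") <- truth
    cells
  })
}

#' Epithelium slab geometry
#'
#' Analytic basal/apical surfaces for synthetic epithelium ribbons: the
#' basal lamina is the plane `z = basal_z` and the apical (lumenal) surface
#' the plane `z = apical_z`, so every depth is exact by construction.
#'
#' @param basal_z,apical_z Plane positions in micrometres.
#' @return An object of class `epithelium_geometry` with functions
#'   `d_basal(z)` and `d_apical(z)` returning signed distances.
#' @export
slab_geometry <- function(basal_z = 0, apical_z = 60) {
  structure(list(type = "slab", basal_z = basal_z, apical_z = apical_z,
                 d_basal = function(z) z - basal_z,
                 d_apical = function(z) apical_z - z),
            class = "epithelium_geometry")
}

#' Simulate one image-scale MOE section
#'
#' Renders a multi-channel 3D stack (one channel per readout bit, plus Egr1
#' and nuclear channels) containing `n_cells` somas. Each soma expresses one
#' receptor and carries elevated, spatially correlated signal in exactly the
#' receptor's 4 on-bit channels: the four channels share a common soma
#' profile and voxel-level texture, differing only in a per-channel gain,
#' while all other channels stay at background. Egr1 spot counts per cell
#' are drawn from the planted response model and rendered as point-like
#' local maxima inside the soma.
#'
#' @param config A [synthetic_config()].
#' @param codebook An `or_codebook`; the first `n_receptors` entries form
#'   the receptor panel.
#' @param seed Integer seed.
#' @param response_fractions Optional named vector (receptor -> probability a
#'   cell responds). Default: drawn once per call, a few strong (0.6), some
#'   partial (0.2), the rest near zero (0.02).
#' @param render If `FALSE`, skip image rendering (ground truth only).
#' @return A list with `stack` (class `readout_stack`: `bits` array
#'   `[y, x, z, bit]`, `egr1`, `nuclear`, `pixel_um`), and `truth`:
#'   `cells` data.frame (positions in um, receptor, planted Egr1 count),
#'   `cell_voxels` (list of linear voxel indices per cell), and the
#'   `response_fractions` used.
#' @export
simulate_moe_section <- function(config = synthetic_config(),
                                 codebook = build_codebook(
                                   sprintf("OR%03d", 1:50), seed = 1),
                                 seed = 1, response_fractions = NULL,
                                 render = TRUE) {
  if (config$n_receptors > nrow(codebook$entries))
    stop_orfish("codebook smaller than n_receptors",
                class = "orfish_input_error")
  with_seed(seed, {
    sh <- config$image_shape
    px <- config$pixel_um
    receptors <- rownames(codebook$entries)[seq_len(config$n_receptors)]
    if (is.null(response_fractions)) {
      cls <- sample(c("strong", "partial", "none"), length(receptors),
                    replace = TRUE, prob = c(0.05, 0.2, 0.75))
      response_fractions <- stats::setNames(
        c(strong = 0.6, partial = 0.2, none = 0.02)[cls], receptors)
    }
    ring <- seq(config$image_ring_range_um[1], config$image_ring_range_um[2],
                length.out = length(receptors))
    names(ring) <- receptors
    fov <- c(x = sh[["nx"]] * px[["x"]], y = sh[["ny"]] * px[["y"]],
             z = sh[["nz"]] * px[["z"]])
    center <- c(fov[["x"]], fov[["y"]]) / 2
    # place somas: ring-constrained, minimum separation enforced
    n <- config$n_cells
    rec <- sort(sample(receptors, n, replace = TRUE))
    pos <- matrix(NA_real_, n, 2)
    zc <- numeric(n)
    margin <- config$soma_radius_um + 1
    placed <- 0L
    for (i in seq_len(n)) {
      ok <- FALSE
      for (try in seq_len(config$max_place_tries)) {
        rad <- stats::rnorm(1, ring[[rec[i]]], config$ring_sd_um)
        rad <- min(max(rad, 10), min(center) - margin)
        ang <- stats::runif(1, 0, 2 * pi)
        p <- center + rad * c(cos(ang), sin(ang))
        if (placed == 0L ||
            min(cross_dist(matrix(p, 1), pos[seq_len(placed), , drop = FALSE])) >=
            config$min_separation_um) { ok <- TRUE; break }
      }
      if (!ok)
        stop_orfish("could not place soma ", i, " without overlap",
                    class = "orfish_placement_error")
      placed <- placed + 1L
      pos[i, ] <- p
      zc[i] <- fov[["z"]] / 2 + stats::runif(1, -0.5, 0.5)
    }
    responding <- stats::runif(n) < response_fractions[rec]
    egr1_true <- ifelse(responding,
                        6L + stats::rpois(n, config$egr1_lambda_high),
                        stats::rpois(n, config$egr1_lambda_low))
    cells <- data.frame(cell_id = seq_len(n), receptor = rec,
                        x_um = pos[, 1], y_um = pos[, 2], z_um = zc,
                        responding = responding, egr1_true = egr1_true,
                        stringsAsFactors = FALSE)
    # voxel centers in um
    xs <- (seq_len(sh[["nx"]]) - 0.5) * px[["x"]]
    ys <- (seq_len(sh[["ny"]]) - 0.5) * px[["y"]]
    zs <- (seq_len(sh[["nz"]]) - 0.5) * px[["z"]]
    cell_voxels <- vector("list", n)
    stack <- NULL
    if (render) {
      nb <- codebook$n_bits
      bits <- array(stats::rnorm(prod(sh) * nb, config$background,
                                 config$noise_sd),
                    dim = c(sh[["ny"]], sh[["nx"]], sh[["nz"]], nb))
      egr1 <- array(stats::rnorm(prod(sh), config$egr1_background,
                                 config$egr1_noise_sd),
                    dim = sh[c("ny", "nx", "nz")])
      nuclear <- array(stats::rnorm(prod(sh), 1, 0.3),
                       dim = sh[c("ny", "nx", "nz")])
    }
    r_xy <- config$soma_radius_um
    r_z <- config$soma_z_radius_um
    for (i in seq_len(n)) {
      ix <- which(abs(xs - pos[i, 1]) <= r_xy)
      iy <- which(abs(ys - pos[i, 2]) <= r_xy)
      iz <- which(abs(zs - zc[i]) <= r_z)
      g <- expand.grid(iy = iy, ix = ix, iz = iz)
      m2 <- ((xs[g$ix] - pos[i, 1]) / r_xy)^2 +
        ((ys[g$iy] - pos[i, 2]) / r_xy)^2 +
        ((zs[g$iz] - zc[i]) / r_z)^2
      keep <- m2 <= 1
      g <- g[keep, ]; m2 <- m2[keep]
      lin <- g$iy + (g$ix - 1L) * sh[["ny"]] +
        (g$iz - 1L) * sh[["ny"]] * sh[["nx"]]
      cell_voxels[[i]] <- lin
      if (render) {
        profile <- config$amplitude * exp(-m2) *
          exp(stats::rnorm(length(m2), 0, config$texture_sd))
        code <- codebook$entries[rec[i], ]
        gains <- stats::runif(codebook$on_bits, config$gain_range[1],
                              config$gain_range[2])
        plane <- sh[["ny"]] * sh[["nx"]] * sh[["nz"]]
        for (b in seq_along(code)) {
          bits[lin + plane * code[b]] <- bits[lin + plane * code[b]] +
            gains[b] * profile
        }
        nuclear[lin] <- nuclear[lin] + 8 * exp(-m2)
        # Egr1 spots: separated point-like maxima inside the soma
        k <- egr1_true[i]
        if (k > 0) {
          cand <- sample(length(lin))
          chosen <- integer(0)
          cx <- xs[g$ix]; cy <- ys[g$iy]; czv <- zs[g$iz]
          for (j in cand) {
            if (length(chosen) >= k) break
            if (length(chosen) == 0L ||
                min(sqrt((cx[j] - cx[chosen])^2 + (cy[j] - cy[chosen])^2 +
                           (czv[j] - czv[chosen])^2)) >=
                config$egr1_min_spot_sep_um)
              chosen <- c(chosen, j)
          }
          cells$egr1_true[i] <- length(chosen)
          spot_lin <- lin[chosen]
          egr1[spot_lin] <- egr1[spot_lin] + config$egr1_amplitude
          # shoulder on in-plane 4-neighbourhood keeps the peak strict
          for (d in c(-1L, 1L, -sh[["ny"]], sh[["ny"]])) {
            nb_lin <- spot_lin + d
            ok <- nb_lin >= 1L & nb_lin <= prod(sh)
            egr1[nb_lin[ok]] <- egr1[nb_lin[ok]] + 0.3 * config$egr1_amplitude
          }
        }
      }
    }
    if (render) {
      stack <- structure(list(bits = bits, egr1 = egr1, nuclear = nuclear,
                              pixel_um = px), class = "readout_stack")
    }
    list(stack = stack,
         truth = list(cells = cells, cell_voxels = cell_voxels,
                      response_fractions = response_fractions,
                      receptors = receptors))
  })
}

#' Planted per-receptor response fractions
#'
#' Draws a receptor-by-condition matrix of planted responding fractions:
#' for each condition a few receptors respond strongly (fraction ~0.55-0.8),
#' a moderate set partially (~0.12-0.45), and the rest barely (~0-0.04),
#' mirroring the graded response structure of immediate-early-gene screens.
#'
#' @param receptors Character vector of receptor ids.
#' @param conditions Character vector of condition names.
#' @param seed Integer seed.
#' @param p_strong,p_partial Probabilities of the strong / partial classes.
#' @return Numeric matrix receptors x conditions of planted fractions.
#' @export
simulate_response_truth <- function(receptors, conditions, seed = 1,
                                    p_strong = 0.05, p_partial = 0.2) {
  with_seed(seed, {
    m <- matrix(0, length(receptors), length(conditions),
                dimnames = list(receptors, conditions))
    for (j in seq_along(conditions)) {
      cls <- sample(c("s", "p", "n"), length(receptors), replace = TRUE,
                    prob = c(p_strong, p_partial, 1 - p_strong - p_partial))
      m[, j] <- ifelse(cls == "s", stats::runif(length(receptors), 0.55, 0.8),
                ifelse(cls == "p", stats::runif(length(receptors), 0.12, 0.45),
                       stats::runif(length(receptors), 0, 0.04)))
    }
    m
  })
}

#' Simulate per-cell Egr1 count tables
#'
#' Draws cell-level Egr1 transcript counts from planted response fractions:
#' responder cells get `6 + Poisson(lambda_high)` counts (always above the
#' activity threshold of 5), non-responders `Poisson(lambda_low)`.
#'
#' @param fractions Receptor x condition matrix of planted fractions (e.g.
#'   from [simulate_response_truth()]).
#' @param cells_per_receptor Cells drawn per receptor per animal.
#' @param n_animals Animals per condition.
#' @param lambda_high,lambda_low Poisson means of the two count modes.
#' @param seed Integer seed.
#' @return A data.frame with `receptor`, `condition`, `animal`, `egr1`.
#' @export
simulate_egr1_cells <- function(fractions, cells_per_receptor = 50L,
                                n_animals = 3L, lambda_high = 3,
                                lambda_low = 0.3, seed = 1) {
  with_seed(seed, {
    grid <- expand.grid(receptor = rownames(fractions),
                        condition = colnames(fractions),
                        animal = seq_len(n_animals),
                        stringsAsFactors = FALSE)
    out <- vector("list", nrow(grid))
    for (i in seq_len(nrow(grid))) {
      f <- fractions[grid$receptor[i], grid$condition[i]]
      resp <- stats::runif(cells_per_receptor) < f
      counts <- ifelse(resp, 6L + stats::rpois(cells_per_receptor, lambda_high),
                       stats::rpois(cells_per_receptor, lambda_low))
      out[[i]] <- data.frame(receptor = grid$receptor[i],
                             condition = grid$condition[i],
                             animal = grid$animal[i],
                             egr1 = counts, stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
}
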