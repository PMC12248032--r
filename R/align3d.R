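#' Serial-section alignment and cross-bulb registration
#'
#' Serial 16-18 um sections are aligned pairwise from the nuclear signal:
#' small subimages (~100 um) are rigidly matched across adjacent sections
#' by correlation maximization, a robust consensus rigid transform is taken
#' over the subimage estimates, and the remaining sectioning distortion is
#' corrected from the residual displacements of the matched features,
#' Gaussian-weighted with a ~75 um bandwidth. Chained transforms assemble
#' the sections into a 3D volume, in which bilateral and cross-animal
#' glomerular maps are compared by rigid point-set registration.
#'
#' @name align3d
NULL

# cross-correlation shift between equal-size images: returns the shift s
# (x, y) such that b(p) ~ a(p - s), with subpixel parabolic refinement and
# a normalized peak score.
phase_corr <- function(a, b) {
  am <- a - mean(a); bm <- b - mean(b)
  n <- length(a)
  cc <- Re(stats::fft(stats::fft(bm) * Conj(stats::fft(am)), inverse = TRUE)) / n
  pk <- which.max(cc)
  sub <- arrayInd(pk, dim(cc))
  d <- dim(cc)
  wrap <- function(i, n) ifelse(i > n / 2, i - n, i)  # 1-based index -> shift
  ix <- function(i, n) ((i - 1) %% n) + 1
  para <- function(cm, c0, cp) {
    den <- 2 * (2 * c0 - cm - cp)
    if (abs(den) < 1e-12) 0 else (cp - cm) / den
  }
  dy <- para(cc[ix(sub[1] - 1, d[1]), sub[2]], cc[sub[1], sub[2]],
             cc[ix(sub[1] + 1, d[1]), sub[2]])
  dx <- para(cc[sub[1], ix(sub[2] - 1, d[2])], cc[sub[1], sub[2]],
             cc[sub[1], ix(sub[2] + 1, d[2])])
  shift <- c(x = wrap(sub[2], d[2]) - 1 + dx, y = wrap(sub[1], d[1]) - 1 + dy)
  score <- max(cc) / (stats::sd(am) * stats::sd(bm) * (n - 1) / n) / n
  list(shift = shift, score = score)
}

#' Rigidly align a pair of sections
#'
#' Estimates the rigid transform `T` (rotation about the image center plus
#' translation, in pixels) such that `B(p) ~ A(T^{-1}(p))`, i.e. `T` maps
#' A-frame coordinates to B-frame coordinates. A coarse global angle grid
#' with per-angle translation by Fourier cross-correlation is refined
#' locally, then subimages of ~`feature_size_um` are matched individually
#' as features; the consensus transform is re-fitted from the feature
#' matches by least squares with robust (3 x MAD) outlier rejection.
#'
#' @param a,b Numeric matrices (nuclear images of adjacent sections).
#' @param pixel_um Pixel size in micrometres (isotropic in-plane).
#' @param feature_size_um Subimage size (default 100).
#' @param angle_range_deg,angle_step_deg Coarse angle grid (default +-10,
#'   step 0.5).
#' @param refine_step_deg Fine angle step (default 0.05).
#' @param min_features Minimum usable subimages (default 3).
#' @return A list: `transform` (`rigid2d`, pixels, center = image center),
#'   `matches` (data.frame of feature positions in A, matched positions in
#'   B, and residuals in pixels after the rigid fit), `angle_scores`,
#'   `n_dropped`.
#' @export
rigid_align_pair <- function(a, b, pixel_um = 1, feature_size_um = 100,
                             angle_range_deg = 10, angle_step_deg = 0.5,
                             refine_step_deg = 0.05, min_features = 3L) {
  d <- dim(a)
  ctr <- c((ncol(a) + 1) / 2, (nrow(a) + 1) / 2)
  score_angle <- function(theta) {
    bu <- warp_image(b, function(p) rigid_apply(rigid2d(theta, center = ctr), p))
    pc <- phase_corr(a, bu)
    list(theta = theta, shift = pc$shift, score = pc$score)
  }
  grid <- seq(-angle_range_deg, angle_range_deg, by = angle_step_deg)
  coarse <- lapply(grid, score_angle)
  sc <- vapply(coarse, `[[`, numeric(1), "score")
  th0 <- grid[which.max(sc)]
  fine_grid <- seq(th0 - angle_step_deg, th0 + angle_step_deg,
                   by = refine_step_deg)
  fine <- lapply(fine_grid, score_angle)
  fsc <- vapply(fine, `[[`, numeric(1), "score")
  best <- fine[[which.max(fsc)]]
  # coarse estimate: un-rotating b by theta leaves b(p) ~ a(p - s);
  # feature at p in A appears at rot_theta(p + s) in B
  theta0 <- best$theta; s0 <- best$shift
  t0 <- rigid2d(theta0, 0, 0, center = ctr)
  to_b <- function(p) rigid_apply(t0, sweep(matrix(p, ncol = 2), 2, s0, "+"))
  # feature matching on subimages of the coarse-aligned pair
  fpx <- max(8L, round(feature_size_um / pixel_um))
  b_aligned <- warp_image(b, function(p) {
    rigid_apply(t0, sweep(p, 2, s0, "+"))
  })
  cy <- seq(fpx %/% 2 + 1, nrow(a) - fpx %/% 2, by = fpx)
  cx <- seq(fpx %/% 2 + 1, ncol(a) - fpx %/% 2, by = fpx)
  feats <- list()
  for (yy in cy) for (xx in cx) {
    iy <- (yy - fpx %/% 2):(yy + fpx %/% 2 - 1)
    ix <- (xx - fpx %/% 2):(xx + fpx %/% 2 - 1)
    ta <- a[iy, ix]; tb <- b_aligned[iy, ix]
    if (stats::sd(ta) < 1e-8 || stats::sd(tb) < 1e-8) next
    pc <- phase_corr(ta, tb)
    if (pc$score < 0.2 || any(abs(pc$shift) > fpx / 4)) next
    # local residual shift delta: tb(p) ~ ta(p - delta), so the feature at
    # (xx, yy) in A sits at (xx, yy) + delta in the aligned B frame
    feats[[length(feats) + 1L]] <- c(xx, yy, pc$shift)
  }
  if (length(feats) < min_features)
    stop_orfish("alignment failure: only ", length(feats),
                " usable subimages", class = "orfish_alignment_error")
  fm <- do.call(rbind, feats)
  pa <- fm[, 1:2, drop = FALSE]
  pb <- to_b(pa + fm[, 3:4, drop = FALSE])
  # robust rigid re-fit A -> B
  fit <- kabsch(pa, pb)
  res <- pb - fit$apply(pa)
  rn <- sqrt(rowSums(res^2))
  madn <- stats::mad(rn, center = 0)
  keep <- rn <= max(3 * madn, 1e-6) | rn <= stats::median(rn)
  n_dropped <- sum(!keep)
  if (sum(keep) >= min_features) {
    fit <- kabsch(pa[keep, , drop = FALSE], pb[keep, , drop = FALSE])
    res <- pb - fit$apply(pa)
  }
  theta_hat <- atan2(fit$R[2, 1], fit$R[1, 1]) * 180 / pi
  # express as rotation about the image center
  t_ctr <- fit$apply(matrix(ctr, 1)) - ctr
  transform <- rigid2d(theta_hat, t_ctr[1], t_ctr[2], center = ctr)
  matches <- data.frame(x_a = pa[, 1], y_a = pa[, 2],
                        x_b = pb[, 1], y_b = pb[, 2],
                        res_x = res[, 1], res_y = res[, 2],
                        kept = keep)
  list(transform = transform, matches = matches,
       angle_scores = data.frame(theta = c(grid, fine_grid), score = c(sc, fsc)),
       n_dropped = n_dropped)
}

#' Least-squares rigid point-set registration
#'
#' Finds rotation `R` and translation `t` minimizing `sum |R p_i + t - q_i|^2`
#' (Kabsch algorithm). Reflections are excluded unless `allow_reflection`.
#'
#' @param p,q Matched point matrices (rows = points, 2 or 3 columns).
#' @param allow_reflection Permit `det(R) = -1` solutions.
#' @return A list with `R`, `t`, `apply(x)`, and `rmsd`.
#' @export
kabsch <- function(p, q, allow_reflection = FALSE) {
  p <- as.matrix(p); q <- as.matrix(q)
  cp <- colMeans(p); cq <- colMeans(q)
  pc <- sweep(p, 2, cp); qc <- sweep(q, 2, cq)
  s <- svd(crossprod(pc, qc))
  d <- diag(ncol(p))
  if (!allow_reflection)
    d[ncol(p), ncol(p)] <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% d %*% t(s$u)
  t_vec <- cq - drop(R %*% cp)
  f <- function(x) sweep(tcrossprod(as.matrix(x), R), 2, t_vec, "+")
  list(R = R, t = t_vec, apply = f,
       rmsd = sqrt(mean(rowSums((f(p) - q)^2))))
}

#' Gaussian residual-field correction
#'
#' Builds the smooth displacement field interpolating feature residuals:
#' the displacement at point `p` is `sum w_i r_i / sum w_i` with
#' `w_i = exp(-|p - f_i|^2 / (2 sigma^2))` over features `f_i` carrying
#' residuals `r_i`. Corrected coordinates subtract the interpolated
#' displacement.
#'
#' The kernel is truncated at `truncate_sigmas` standard deviations: points
#' with no feature inside the truncation radius get zero displacement, so
#' the correction vanishes far from any matched feature.
#'
#' @param features Matrix of feature positions (rows, 2 columns).
#' @param residuals Matrix of residual displacement vectors at the features.
#' @param sigma_um Gaussian bandwidth (default 75).
#' @param truncate_sigmas Kernel support radius in sigmas (default 5).
#' @return A list: `field(points)` returning interpolated displacements and
#'   `correct(points)` returning `points - field(points)`.
#' @export
residual_correction <- function(features, residuals, sigma_um = 75,
                                truncate_sigmas = 5) {
  features <- as.matrix(features); residuals <- as.matrix(residuals)
  if (nrow(features) < 1L)
    stop_orfish("at least one feature required", class = "orfish_input_error")
  field <- function(points) {
    points <- matrix(as.numeric(points), ncol = 2)
    d <- cross_dist(points, features)
    w <- exp(-d^2 / (2 * sigma_um^2))
    w[d > truncate_sigmas * sigma_um] <- 0
    sw <- rowSums(w)
    out <- (w %*% residuals) / pmax(sw, .Machine$double.xmin)
    out[sw == 0, ] <- 0
    out
  }
  correct <- function(points) {
    pm <- matrix(as.numeric(points), ncol = 2)
    out <- pm - field(pm)
    if (is.null(dim(points))) drop(out) else out
  }
  list(field = field, correct = correct, sigma_um = sigma_um,
       features = features, residuals = residuals)
}

#' Assemble pairwise transforms into a section stack
#'
#' Composes a chain of pairwise rigid transforms (element `i` maps section
#' `i + 1` coordinates into section `i` coordinates) into per-section
#' transforms to the reference (first) section, and attaches the axial
#' coordinate `z = (index - 1) * z_step_um`.
#'
#' @param transforms List of `n - 1` `rigid2d` transforms (a `NULL` element
#'   is a broken chain and raises an error naming the gap).
#' @param z_step_um Section thickness / z increment.
#' @return A list with `to_reference` (list of composed `rigid2d`, identity
#'   for the first section) and `z_um` (numeric vector).
#' @export
assemble_stack <- function(transforms, z_step_um = 16) {
  n <- length(transforms) + 1L
  gaps <- which(vapply(transforms, is.null, logical(1)))
  if (length(gaps))
    stop_orfish("broken transform chain between sections ", gaps[1], " and ",
                gaps[1] + 1L, class = "orfish_assembly_error")
  to_ref <- vector("list", n)
  to_ref[[1]] <- rigid2d()
  for (i in seq_len(n - 1L))
    to_ref[[i + 1L]] <- rigid_compose(to_ref[[i]], transforms[[i]])
  list(to_reference = to_ref, z_um = (seq_len(n) - 1) * z_step_um)
}

# per (receptor, hemisphere, side) centroid of a projection map
map_centroids <- function(map) {
  ag <- stats::aggregate(map[, c("x_um", "y_um", "z_um")],
                         by = list(receptor = map$receptor,
                                   hemisphere = map$hemisphere,
                                   side = map$side), FUN = mean)
  ag
}

#' Bilateral glomerular matching
#'
#' Reflects the right hemisphere about the midsagittal plane, rigidly
#' registers it onto the left hemisphere by least squares over matched
#' receptor centroids, and reports the per-receptor matched distances
#' (medial and lateral sides separately) and their medians.
#'
#' @param map Projection-map data.frame (`receptor`, `hemisphere`, `side`,
#'   `x_um`, `y_um`, `z_um`).
#' @param midline_um Midsagittal plane position (default: mean x).
#' @return A list: `distances` (data.frame `receptor`, `side`, `distance_um`),
#'   `median_um`, `median_by_side`, `n_excluded` (receptors present in only
#'   one hemisphere), `registration` (kabsch fit).
#' @export
match_bilateral <- function(map, midline_um = NULL) {
  if (length(unique(map$hemisphere)) < 2L)
    stop_orfish("both hemispheres required", class = "orfish_matching_error")
  midline_um <- midline_um %||% mean(map$x_um)
  cen <- map_centroids(map)
  right <- cen[cen$hemisphere == "right", , drop = FALSE]
  right$x_um <- 2 * midline_um - right$x_um
  left <- cen[cen$hemisphere == "left", , drop = FALSE]
  key <- function(d) paste(d$receptor, d$side)
  shared <- intersect(key(left), key(right))
  if (!length(shared))
    stop_orfish("no shared receptors across hemispheres",
                class = "orfish_matching_error")
  li <- match(shared, key(left)); ri <- match(shared, key(right))
  P <- as.matrix(right[ri, c("x_um", "y_um", "z_um")])
  Q <- as.matrix(left[li, c("x_um", "y_um", "z_um")])
  fit <- kabsch(P, Q)
  dd <- sqrt(rowSums((fit$apply(P) - Q)^2))
  distances <- data.frame(receptor = left$receptor[li], side = left$side[li],
                          distance_um = dd, stringsAsFactors = FALSE)
  list(distances = distances,
       median_um = stats::median(dd),
       median_by_side = tapply(dd, distances$side, stats::median),
       n_excluded = length(unique(c(setdiff(key(left), shared),
                                    setdiff(key(right), shared)))),
       registration = fit)
}

#' Align projection maps across animals
#'
#' Registers each animal's map onto the first by least-squares rigid motion
#' (optionally with reflection) over shared (receptor, hemisphere, side)
#' centroids and reports the cross-animal matched distance distribution.
#'
#' @param maps List of projection-map data.frames.
#' @param allow_reflection Permit reflections in the registration.
#' @return A list: `maps` (transformed copies in the common frame),
#'   `distances` (data.frame `receptor`, `side`, `animal`, `distance_um`
#'   to the reference map), `median_um`.
#' @export
align_maps_across_animals <- function(maps, allow_reflection = TRUE) {
  if (length(maps) < 2L)
    stop_orfish("at least two maps required", class = "orfish_matching_error")
  ref <- map_centroids(maps[[1]])
  key <- function(d) paste(d$receptor, d$hemisphere, d$side)
  out_maps <- maps
  dist_rows <- list()
  for (i in seq_along(maps)[-1]) {
    cen <- map_centroids(maps[[i]])
    shared <- intersect(key(ref), key(cen))
    if (length(unique(sub(" .*", "", shared))) < 3L)
      stop_orfish("fewer than 3 shared receptors with map 1",
                  class = "orfish_matching_error")
    ri <- match(shared, key(ref)); ci <- match(shared, key(cen))
    P <- as.matrix(cen[ci, c("x_um", "y_um", "z_um")])
    Q <- as.matrix(ref[ri, c("x_um", "y_um", "z_um")])
    fit <- kabsch(P, Q, allow_reflection = allow_reflection)
    m <- maps[[i]]
    m[, c("x_um", "y_um", "z_um")] <-
      fit$apply(as.matrix(m[, c("x_um", "y_um", "z_um")]))
    out_maps[[i]] <- m
    dd <- sqrt(rowSums((fit$apply(P) - Q)^2))
    dist_rows[[length(dist_rows) + 1L]] <- data.frame(
      receptor = ref$receptor[ri], side = ref$side[ri], animal = i,
      distance_um = dd, stringsAsFactors = FALSE)
  }
  distances <- do.call(rbind, dist_rows)
  list(maps = out_maps, distances = distances,
       median_um = stats::median(distances$distance_um))
}
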