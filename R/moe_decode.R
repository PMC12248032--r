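#' Soma-level decoding of receptor identity from readout stacks
#'
#' In epithelium sections every sensory neuron expresses a single receptor,
#' so its soma lights up in exactly the 4 readout channels of that
#' receptor's code, with strongly correlated intensity across those
#' channels. Decoding proceeds by scanning ~2.5 um cubes over the stack,
#' computing all pairwise Pearson correlations between readout channels in
#' each cube, selecting the 4-bit combination with the highest mean internal
#' correlation, thresholding (> 0.6), density-clustering the surviving
#' voxels into cells, and matching each cell's bit quadruple against the
#' codebook.
#'
#' @name moe_decode
NULL

# sum over non-overlapping blocks of size s = c(sy, sx, sz); returns array
# of block sums with dim floor(dim(a) / s)
block_reduce <- function(a, s) {
  d <- dim(a)
  nb <- d %/% s
  a <- a[seq_len(nb[1] * s[1]), seq_len(nb[2] * s[2]), seq_len(nb[3] * s[3]),
         drop = FALSE]
  r <- colSums(matrix(a, nrow = s[1]))
  dim(r) <- c(nb[1], nb[2] * s[2], nb[3] * s[3])
  r <- aperm(r, c(2, 1, 3))
  r <- colSums(matrix(r, nrow = s[2]))
  dim(r) <- c(nb[2], nb[1], nb[3] * s[3])
  r <- aperm(r, c(3, 2, 1))
  r <- colSums(matrix(r, nrow = s[3]))
  dim(r) <- c(nb[3], nb[1], nb[2])
  aperm(r, c(2, 3, 1))
}

# sum of 2x2x2 (or fewer along degenerate axes) neighbouring blocks ->
# overlapping cube sums at stride resolution
cube_from_blocks <- function(b, e) {
  d <- dim(b)
  n <- d - e + 1L
  out <- array(0, n)
  for (dy in seq_len(e[1]) - 1L)
    for (dx in seq_len(e[2]) - 1L)
      for (dz in seq_len(e[3]) - 1L)
        out <- out + b[dy + seq_len(n[1]), dx + seq_len(n[2]),
                       dz + seq_len(n[3]), drop = FALSE]
  out
}

#' Cube-wise pairwise correlation map
#'
#' Scans overlapping cubes (stride = half the cube size) across the stack
#' and computes, for every cube, the Pearson correlation between every pair
#' of readout channels over the cube's voxels, plus the 4-bit combination
#' maximizing the mean of its 6 internal pairwise correlations (exhaustive
#' search over all C(n_bits, 4) quadruples). Channels with (near-)constant
#' signal in a cube yield undefined correlations, which are flagged and
#' treated as 0. To bound the exhaustive search, quadruples are only scored
#' for cubes whose maximum pairwise correlation exceeds `min_corr`; since
#' the mean of 6 pair correlations can never exceed their maximum, any
#' `min_corr` at or below the downstream candidate threshold is lossless.
#'
#' @param stack A `readout_stack`.
#' @param cube_um Cube edge length in micrometres (default 2.5).
#' @param min_corr Prefilter on the maximum pairwise correlation per cube
#'   before quadruple scoring (default 0.3).
#' @return A `cube_map` list: `pair_corr` (cubes x pairs matrix), `pairs`
#'   (0-based bit pairs), `max_pair`, `best_score` / `best_quad`
#'   (NA outside the prefilter), cube geometry (`origin`, 1-based voxel
#'   origins; `size_px`; `stride_px`), `undefined` flag matrix, `n_vox`.
#' @export
cube_correlation_map <- function(stack, cube_um = 2.5, min_corr = 0.3) {
  px <- stack$pixel_um
  d <- dim(stack$bits)
  n_bits <- d[4]
  stride <- pmax(1L, round(cube_um / c(px[["y"]], px[["x"]], px[["z"]]) / 2))
  size <- 2L * stride
  size <- pmin(size, d[1:3])
  e <- ifelse(d[1:3] %/% stride >= 2L, 2L, 1L)
  if (any(size > d[1:3]))
    stop_orfish("cube larger than image", class = "orfish_geometry_error")
  if (any(size < 2L))
    stop_orfish("cube must span at least 2 voxels per axis",
                class = "orfish_geometry_error")
  nb <- d[1:3] %/% stride
  ncube <- nb - e + 1L
  n_cubes <- prod(ncube)
  n_vox <- prod(stride * e)
  # per-channel block sums of x and x^2
  Sx <- matrix(0, n_cubes, n_bits)
  Sxx <- matrix(0, n_cubes, n_bits)
  for (b in seq_len(n_bits)) {
    ch <- stack$bits[, , , b, drop = FALSE]
    dim(ch) <- d[1:3]
    Sx[, b] <- as.numeric(cube_from_blocks(block_reduce(ch, stride), e))
    Sxx[, b] <- as.numeric(cube_from_blocks(block_reduce(ch * ch, stride), e))
  }
  varn <- n_vox * Sxx - Sx^2  # n^2 * variance
  undefined <- varn <= 1e-9 * pmax(Sxx, 1)
  pairs <- t(utils::combn(n_bits, 2L)) - 1L
  n_pairs <- nrow(pairs)
  pair_corr <- matrix(0, n_cubes, n_pairs)
  for (p in seq_len(n_pairs)) {
    i <- pairs[p, 1] + 1L; j <- pairs[p, 2] + 1L
    chi <- stack$bits[, , , i, drop = FALSE]; dim(chi) <- d[1:3]
    chj <- stack$bits[, , , j, drop = FALSE]; dim(chj) <- d[1:3]
    Sxy <- as.numeric(cube_from_blocks(block_reduce(chi * chj, stride), e))
    num <- n_vox * Sxy - Sx[, i] * Sx[, j]
    den <- sqrt(pmax(varn[, i], 0) * pmax(varn[, j], 0))
    r <- ifelse(den > 0, num / den, 0)
    r[undefined[, i] | undefined[, j]] <- 0
    pair_corr[, p] <- pmin(pmax(r, -1), 1)
  }
  max_pair <- do.call(pmax, as.data.frame(pair_corr))
  # exhaustive quadruple scoring on prefiltered cubes
  quads <- t(utils::combn(n_bits, 4L)) - 1L
  pair_index <- matrix(0L, n_bits, n_bits)
  pair_index[cbind(pairs[, 1] + 1L, pairs[, 2] + 1L)] <- seq_len(n_pairs)
  quad_pairs <- t(apply(quads, 1L, function(q) {
    pr <- utils::combn(q, 2L)
    pair_index[cbind(pmin(pr[1, ], pr[2, ]) + 1L, pmax(pr[1, ], pr[2, ]) + 1L)]
  }))
  M <- matrix(0, n_pairs, nrow(quads))
  M[cbind(as.integer(t(quad_pairs)), rep(seq_len(nrow(quads)), each = 6L))] <- 1 / 6
  sel <- which(max_pair > min_corr)
  best_score <- rep(NA_real_, n_cubes)
  best_quad <- matrix(NA_integer_, n_cubes, 4L)
  if (length(sel)) {
    scores <- pair_corr[sel, , drop = FALSE] %*% M
    wb <- max.col(scores, ties.method = "first")
    best_score[sel] <- scores[cbind(seq_along(sel), wb)]
    best_quad[sel, ] <- quads[wb, , drop = FALSE]
  }
  origin <- cbind(
    y = rep(seq_len(ncube[1]), times = prod(ncube[2:3])),
    x = rep(rep(seq_len(ncube[2]), each = ncube[1]), times = ncube[3]),
    z = rep(seq_len(ncube[3]), each = prod(ncube[1:2]))
  )
  origin <- sweep(origin - 1L, 2L, as.integer(stride), "*") + 1L
  structure(list(pair_corr = pair_corr, pairs = pairs, max_pair = max_pair,
                 best_score = best_score, best_quad = best_quad,
                 origin = origin, size_px = as.integer(stride * e),
                 stride_px = as.integer(stride), dim = d[1:3],
                 undefined = undefined, n_vox = n_vox, pixel_um = px,
                 min_corr = min_corr),
            class = "cube_map")
}

#' Extract candidate voxels above the correlation threshold
#'
#' Keeps the voxels of cubes whose best-quadruple mean correlation strictly
#' exceeds `threshold`, grouped by quadruple. A voxel covered by several
#' passing cubes takes the quadruple of its best-scoring cube.
#'
#' @param cmap A `cube_map`.
#' @param threshold Correlation threshold in `(0, 1)` (default 0.6).
#' @return A data.frame (`y`, `x`, `z` 1-based voxel indices, `quad_key`,
#'   `score`) with attribute `quads` (named list quad_key -> 0-based bits);
#'   zero rows when nothing passes.
#' @export
extract_candidate_voxels <- function(cmap, threshold = 0.6) {
  if (threshold <= 0 || threshold > 1)
    stop_orfish("threshold must be in (0, 1]", class = "orfish_input_error")
  pass <- which(!is.na(cmap$best_score) & cmap$best_score > threshold)
  d <- cmap$dim
  empty <- data.frame(y = integer(), x = integer(), z = integer(),
                      quad_key = character(), score = numeric(),
                      stringsAsFactors = FALSE)
  attr(empty, "quads") <- list()
  if (!length(pass)) return(empty)
  pass <- pass[order(cmap$best_score[pass])]
  score_arr <- array(-Inf, d)
  quad_arr <- array(0L, d)
  keys <- apply(cmap$best_quad[pass, , drop = FALSE], 1L, bit_key)
  ukeys <- unique(keys)
  key_id <- match(keys, ukeys)
  sz <- cmap$size_px
  for (k in seq_along(pass)) {
    o <- cmap$origin[pass[k], ]
    iy <- o[1]:min(o[1] + sz[1] - 1L, d[1])
    ix <- o[2]:min(o[2] + sz[2] - 1L, d[2])
    iz <- o[3]:min(o[3] + sz[3] - 1L, d[3])
    score_arr[iy, ix, iz] <- cmap$best_score[pass[k]]
    quad_arr[iy, ix, iz] <- key_id[k]
  }
  lin <- which(quad_arr > 0L)
  sub <- arrayInd(lin, d)
  out <- data.frame(y = sub[, 1], x = sub[, 2], z = sub[, 3],
                    quad_key = ukeys[quad_arr[lin]], score = score_arr[lin],
                    stringsAsFactors = FALSE)
  quads <- lapply(ukeys, function(k) as.integer(strsplit(k, "-")[[1]]))
  names(quads) <- ukeys
  attr(out, "quads") <- quads
  out
}

#' Density-based clustering (DBSCAN)
#'
#' Groups points into density-reachable clusters: core points have at least
#' `min_pts` neighbours (self included) within `eps`; clusters are the
#' connected components of core points under the eps-neighbour relation;
#' non-core points adjacent to a core point join the cluster of their
#' nearest core neighbour; remaining points are noise (label 0).
#'
#' @param x Numeric matrix of point coordinates (rows = points).
#' @param eps Neighbourhood radius.
#' @param min_pts Minimum neighbourhood size for a core point.
#' @return Integer cluster labels (0 = noise), deterministic in input order.
#' @export
dbscan_cluster <- function(x, eps, min_pts) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n == 0L) return(integer())
  d <- cross_dist(x, x)
  adj <- d <= eps
  core <- rowSums(adj) >= min_pts
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != 0L) next
    cl <- cl + 1L
    queue <- i
    labels[i] <- cl
    while (length(queue)) {
      j <- queue[[1]]; queue <- queue[-1]
      nb <- which(adj[j, ] & core & labels == 0L)
      labels[nb] <- cl
      queue <- c(queue, nb)
    }
  }
  # border points: nearest core neighbour's cluster
  border <- which(!core & labels == 0L)
  for (i in border) {
    nb <- which(adj[i, ] & core)
    if (length(nb)) labels[i] <- labels[nb[which.min(d[i, nb])]]
  }
  labels
}

#' Cluster candidate voxels into cells
#'
#' Applies density-based clustering separately within each bit-quadruple
#' group of candidate voxels (voxel coordinates converted to micrometres),
#' discarding clusters smaller than `min_pts`.
#'
#' @param candidates Output of [extract_candidate_voxels()].
#' @param pixel_um Named voxel size `(x, y, z)` in micrometres.
#' @param eps_um Density radius in micrometres (default 1.5).
#' @param min_pts Minimum voxels per cell (default 10).
#' @return A list of clusters, each a list with `quad` (0-based bits),
#'   `quad_key`, `voxels` (data.frame y, x, z, score), `coords_um`.
#' @export
density_cluster_cells <- function(candidates, pixel_um, eps_um = 1.5,
                                  min_pts = 10L) {
  if (eps_um <= max(pixel_um))
    stop_orfish("eps_um must exceed the voxel size", class = "orfish_input_error")
  quads <- attr(candidates, "quads")
  out <- list()
  for (key in names(quads)) {
    g <- candidates[candidates$quad_key == key, , drop = FALSE]
    if (!nrow(g)) next
    co <- cbind((g$x - 0.5) * pixel_um[["x"]],
                (g$y - 0.5) * pixel_um[["y"]],
                (g$z - 0.5) * pixel_um[["z"]])
    lab <- dbscan_cluster(co, eps_um, min_pts)
    for (cl in setdiff(unique(lab), 0L)) {
      idx <- lab == cl
      if (sum(idx) < min_pts) next
      out[[length(out) + 1L]] <- list(
        quad = quads[[key]], quad_key = key,
        voxels = g[idx, c("y", "x", "z", "score")],
        coords_um = co[idx, , drop = FALSE])
    }
  }
  out
}

#' Assign a decoded cell its receptor identity
#'
#' Matches the cluster's bit quadruple against the codebook by exact lookup
#' and summarizes the cell: intensity-weighted centroid (weights = mean
#' on-bit intensity per voxel), voxel volume, mean candidate correlation
#' score and mean on-bit brightness.
#'
#' @param cluster One element of [density_cluster_cells()] output.
#' @param codebook An `or_codebook`.
#' @param stack The `readout_stack` the cluster came from.
#' @return A one-row data.frame (`receptor` is `NA` when the quadruple is
#'   not in the codebook).
#' @export
assign_cell_identity <- function(cluster, codebook, stack) {
  d <- dim(stack$bits)
  lin <- cluster$voxels$y + (cluster$voxels$x - 1L) * d[1] +
    (cluster$voxels$z - 1L) * d[1] * d[2]
  plane <- prod(d[1:3])
  inten <- rowMeans(vapply(cluster$quad,
                           function(b) stack$bits[lin + plane * b],
                           numeric(length(lin))))
  w <- pmax(inten, 0)
  if (sum(w) == 0) w <- rep(1, length(lin))
  px <- stack$pixel_um
  centroid <- c(
    x = sum(w * (cluster$voxels$x - 0.5) * px[["x"]]) / sum(w),
    y = sum(w * (cluster$voxels$y - 0.5) * px[["y"]]) / sum(w),
    z = sum(w * (cluster$voxels$z - 0.5) * px[["z"]]) / sum(w))
  data.frame(receptor = receptor_for_code(codebook, cluster$quad),
             quad_key = cluster$quad_key,
             x_um = centroid[["x"]], y_um = centroid[["y"]],
             z_um = centroid[["z"]],
             n_vox = length(lin),
             volume_um3 = length(lin) * prod(px),
             mean_corr = mean(cluster$voxels$score),
             brightness = mean(inten),
             stringsAsFactors = FALSE)
}

# strict 3D local maxima of arr above threshold, restricted to mask
local_maxima_3d <- function(arr, threshold, mask = NULL) {
  d <- dim(arr)
  pad <- array(-Inf, d + 2L)
  pad[1L + seq_len(d[1]), 1L + seq_len(d[2]), 1L + seq_len(d[3])] <- arr
  is_max <- arr > threshold
  for (dy in -1:1) for (dx in -1:1) for (dz in -1:1) {
    if (dy == 0 && dx == 0 && dz == 0) next
    nbv <- pad[1L + dy + seq_len(d[1]), 1L + dx + seq_len(d[2]),
               1L + dz + seq_len(d[3]), drop = FALSE]
    dim(nbv) <- d
    is_max <- is_max & (arr > nbv)
  }
  if (!is.null(mask)) is_max <- is_max & mask
  which(is_max)
}

#' Count Egr1 transcripts in a cell
#'
#' Counts strict 3D local maxima of the Egr1 channel above an intensity
#' threshold within the cell's voxel set dilated by one voxel ring.
#'
#' @param voxels Data.frame with 1-based `y`, `x`, `z` voxel indices of the
#'   cell (e.g. a cluster's `voxels`).
#' @param egr1 3D Egr1 intensity array.
#' @param threshold Intensity threshold; default `NULL` uses a robust
#'   image-wide estimate, `median + 5 * mad`.
#' @param dilate Dilation radius in voxels (default 1).
#' @return Integer spot count.
#' @export
count_egr1 <- function(voxels, egr1, threshold = NULL, dilate = 1L) {
  if (is.null(threshold))
    threshold <- stats::median(egr1) + 5 * stats::mad(egr1)
  d <- dim(egr1)
  if (nrow(voxels) == 0L) return(0L)
  lo <- pmax(c(min(voxels$y), min(voxels$x), min(voxels$z)) - dilate - 1L, 1L)
  hi <- pmin(c(max(voxels$y), max(voxels$x), max(voxels$z)) + dilate + 1L, d)
  sub <- egr1[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  dim(sub) <- hi - lo + 1L
  mask <- array(FALSE, dim(sub))
  mask[cbind(voxels$y - lo[1] + 1L, voxels$x - lo[2] + 1L,
             voxels$z - lo[3] + 1L)] <- TRUE
  if (dilate > 0L) {
    dl <- mask
    for (dy in -dilate:dilate) for (dx in -dilate:dilate)
      for (dz in -dilate:dilate) {
        if (dy == 0 && dx == 0 && dz == 0) next
        src_y <- seq_len(dim(mask)[1]) - dy
        src_x <- seq_len(dim(mask)[2]) - dx
        src_z <- seq_len(dim(mask)[3]) - dz
        ok_y <- src_y >= 1 & src_y <= dim(mask)[1]
        ok_x <- src_x >= 1 & src_x <= dim(mask)[2]
        ok_z <- src_z >= 1 & src_z <= dim(mask)[3]
        sh <- array(FALSE, dim(mask))
        sh[ok_y, ok_x, ok_z] <- mask[src_y[ok_y], src_x[ok_x], src_z[ok_z],
                                     drop = FALSE]
        dl <- dl | sh
      }
    mask <- dl
  }
  length(local_maxima_3d(sub, threshold, mask))
}

#' Decode one epithelium section end to end
#'
#' Runs the full soma pipeline: cube correlation map, candidate extraction,
#' density clustering, identity assignment, and per-cell Egr1 counting.
#'
#' @param stack A `readout_stack`.
#' @param codebook An `or_codebook`.
#' @param cube_um Scan cube size (default 2.5 um).
#' @param corr_threshold Candidate threshold on the best-quadruple mean
#'   correlation (default 0.6).
#' @param eps_um,min_pts Density-clustering parameters.
#' @param egr1_threshold Egr1 spot intensity threshold (`NULL` = robust
#'   image-wide default).
#' @param section Section id stored in the output.
#' @return A data.frame of cell records (one row per decoded cell):
#'   `cell_id`, `section`, `receptor` (NA if the quadruple is not in the
#'   book), positions in um, `n_vox`, `volume_um3`, `mean_corr`,
#'   `brightness`, `egr1`.
#' @export
decode_moe_section <- function(stack, codebook, cube_um = 2.5,
                               corr_threshold = 0.6, eps_um = 1.5,
                               min_pts = 10L, egr1_threshold = NULL,
                               section = 1L) {
  cmap <- cube_correlation_map(stack, cube_um = cube_um,
                               min_corr = min(0.3, corr_threshold))
  cand <- extract_candidate_voxels(cmap, threshold = corr_threshold)
  clusters <- density_cluster_cells(cand, stack$pixel_um, eps_um = eps_um,
                                    min_pts = min_pts)
  if (!length(clusters)) {
    return(data.frame(cell_id = integer(), section = integer(),
                      receptor = character(), quad_key = character(),
                      x_um = numeric(), y_um = numeric(), z_um = numeric(),
                      n_vox = integer(), volume_um3 = numeric(),
                      mean_corr = numeric(), brightness = numeric(),
                      egr1 = integer(), stringsAsFactors = FALSE))
  }
  recs <- do.call(rbind, lapply(clusters, assign_cell_identity,
                                codebook = codebook, stack = stack))
  if (is.null(egr1_threshold))
    egr1_threshold <- stats::median(stack$egr1) + 5 * stats::mad(stack$egr1)
  recs$egr1 <- vapply(clusters, function(cl)
    count_egr1(cl$voxels, stack$egr1, threshold = egr1_threshold),
    integer(1))
  cbind(cell_id = seq_len(nrow(recs)), section = section, recs)
}

#' Score decoded cells against ground truth
#'
#' Matches each decoded, codebook-assigned cell to the nearest ground-truth
#' soma within `max_dist_um` (greedy, best-distance first, one-to-one) and
#' reports detection recall and identity precision.
#'
#' @param cells Decoded cell table ([decode_moe_section()]).
#' @param truth_cells Ground-truth cell table with `receptor`, `x_um`,
#'   `y_um`, `z_um`.
#' @param max_dist_um Match radius (default 4 um).
#' @return A list with `recall` (fraction of true somas recovered with the
#'   correct identity), `precision` (fraction of assigned cells whose
#'   identity matches their matched soma), `n_assigned`, `n_unassigned`,
#'   `matches` data.frame.
#' @export
score_decoding <- function(cells, truth_cells, max_dist_um = 4) {
  asn <- cells[!is.na(cells$receptor), , drop = FALSE]
  if (!nrow(asn) || !nrow(truth_cells))
    return(list(recall = 0, precision = NA_real_, n_assigned = nrow(asn),
                n_unassigned = sum(is.na(cells$receptor)),
                matches = data.frame()))
  d <- cross_dist(asn[, c("x_um", "y_um", "z_um")],
                  truth_cells[, c("x_um", "y_um", "z_um")])
  cand <- which(d <= max_dist_um, arr.ind = TRUE)
  cand <- cand[order(d[cand]), , drop = FALSE]
  used_c <- logical(nrow(asn)); used_t <- logical(nrow(truth_cells))
  mi <- integer(0); mj <- integer(0)
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (used_c[i] || used_t[j]) next
    used_c[i] <- TRUE; used_t[j] <- TRUE
    mi <- c(mi, i); mj <- c(mj, j)
  }
  correct <- asn$receptor[mi] == truth_cells$receptor[mj]
  list(recall = sum(correct) / nrow(truth_cells),
       precision = if (nrow(asn)) sum(correct) / nrow(asn) else NA_real_,
       n_assigned = nrow(asn),
       n_unassigned = sum(is.na(cells$receptor)),
       matches = data.frame(cell = mi, truth = mj, correct = correct,
                            dist = d[cbind(mi, mj)]))
}
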