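#' Spatial organization statistics of the receptor repertoire
#'
#' Receptor expression in the epithelium is organized along two axes:
#' concentric ring zones running central to peripheral, and a finer
#' basal-apical depth gradient across the epithelial sheet. This module
#' quantifies both: a pairwise spatial-overlap matrix between receptor
#' types, a central-peripheral index obtained by embedding the overlap
#' structure and reading receptor positions off the resulting 1D
#' trajectory, a basal-apical index from cell depths between the two
#' epithelial surfaces, projection coordinates along the bulb axes, and
#' association statistics with genomic position and sequence phylogeny.
#'
#' @name spatial_atlas
NULL

#' Summarize per-receptor abundance and expression level
#'
#' Counts are averaged over sections within each animal, then over animals;
#' per-cell brightness is first normalized by the mean cell brightness of
#' its section, then averaged per receptor the same way.
#'
#' @param cells Cell table with `receptor`, `section`, `animal`, and
#'   optionally `brightness`.
#' @return A data.frame: `receptor`, `cells_per_section`,
#'   `norm_brightness` (NA without a brightness column), `n_cells`.
#' @export
summarize_repertoire <- function(cells) {
  receptors <- sort(unique(cells$receptor))
  animals <- unique(cells$animal)
  cnt_by_animal <- sapply(animals, function(a) {
    ca <- cells[cells$animal == a, , drop = FALSE]
    secs <- unique(ca$section)
    tab <- table(factor(ca$receptor, levels = receptors))
    as.numeric(tab) / length(secs)
  })
  cnt <- rowMeans(as.matrix(cnt_by_animal))
  nb <- rep(NA_real_, length(receptors))
  if ("brightness" %in% names(cells)) {
    cells$norm_b <- cells$brightness
    for (s in unique(paste(cells$animal, cells$section))) {
      idx <- paste(cells$animal, cells$section) == s
      cells$norm_b[idx] <- cells$brightness[idx] / mean(cells$brightness[idx])
    }
    nb_by_animal <- sapply(animals, function(a) {
      ca <- cells[cells$animal == a, , drop = FALSE]
      vapply(receptors, function(r) {
        v <- ca$norm_b[ca$receptor == r]
        if (length(v)) mean(v) else NA_real_
      }, numeric(1))
    })
    nb <- rowMeans(as.matrix(nb_by_animal), na.rm = TRUE)
  }
  data.frame(receptor = receptors, cells_per_section = cnt,
             norm_brightness = nb,
             n_cells = as.integer(table(factor(cells$receptor,
                                               levels = receptors))),
             stringsAsFactors = FALSE)
}

#' Pairwise spatial-overlap matrix
#'
#' For each section and each pair of receptor types A, B the overlap is the
#' fraction of cells with a neighbour of the other type within the cutoff:
#' `(#A-cells with a B within cutoff + #B-cells with an A within cutoff) /
#' (|A| + |B|)`, averaged over the sections where both types occur. The
#' matrix is symmetric with unit diagonal by convention; types absent
#' everywhere give undefined (NA) rows.
#'
#' @param cells Cell table with `receptor`, `section`, `x_um`, `y_um`.
#' @param cutoff_um Neighbour cutoff distance (default 200).
#' @param receptors Optional receptor universe (default: those observed).
#' @return A list of class `overlap_matrix`: `overlap` (receptors x
#'   receptors), `support` (number of sections contributing per pair).
#' @export
overlap_matrix <- function(cells, cutoff_um = 200, receptors = NULL) {
  if (cutoff_um <= 0)
    stop_orfish("cutoff_um must be positive", class = "orfish_input_error")
  receptors <- receptors %||% sort(unique(cells$receptor))
  K <- length(receptors)
  acc <- matrix(0, K, K, dimnames = list(receptors, receptors))
  supp <- matrix(0L, K, K, dimnames = list(receptors, receptors))
  for (s in unique(cells$section)) {
    cs <- cells[cells$section == s, , drop = FALSE]
    pres <- intersect(receptors, unique(cs$receptor))
    if (length(pres) < 1L) next
    xy <- as.matrix(cs[, c("x_um", "y_um")])
    f <- factor(cs$receptor, levels = receptors)
    D <- cross_dist(xy, xy)
    near <- D <= cutoff_um
    # counts[i, B]: cell i has a neighbour of type B (self counts for own type)
    hasnb <- matrix(FALSE, nrow(cs), K)
    for (r in pres) {
      cols <- which(f == r)
      hasnb[, match(r, receptors)] <-
        rowSums(near[, cols, drop = FALSE]) > 0
    }
    cnt <- rowsum(hasnb + 0, f)  # type A rows: #A-cells with B-neighbour
    nA <- as.integer(table(f))[match(rownames(cnt), receptors)]
    ia <- match(rownames(cnt), receptors)
    for (u in seq_along(ia)) for (v in seq_along(ia)) {
      A <- ia[u]; B <- ia[v]
      if (A > B) next
      ov <- (cnt[u, B] + cnt[v, A]) / (nA[u] + nA[v])
      acc[A, B] <- acc[A, B] + ov
      supp[A, B] <- supp[A, B] + 1L
    }
  }
  ov <- ifelse(supp > 0, acc / supp, NA_real_)
  ov[lower.tri(ov)] <- t(ov)[lower.tri(ov)]
  diag(ov) <- ifelse(receptors %in% cells$receptor, 1, NA_real_)
  supp[lower.tri(supp)] <- t(supp)[lower.tri(supp)]
  structure(list(overlap = ov, support = supp, cutoff_um = cutoff_um),
            class = "overlap_matrix")
}

#' Central-peripheral index from the overlap matrix
#'
#' Embeds receptors in 2D from the dissimilarity `1 - overlap` (classical
#' multidimensional scaling), identifies detached groups (connected
#' components of the graph joining receptor pairs with overlap above
#' `min_overlap`; everything outside the largest component is flagged
#' "unusual zone" and excluded), fits a 1D trajectory through the main
#' component as geodesic distances along a k-nearest-neighbour graph
#' between its two farthest nodes, and normalizes each receptor's position
#' along that trajectory to `[0, 1]`.
#'
#' The embedding and ordering are deterministic; `seed` is accepted for
#' interface stability and does not change the result. With `orient_by`
#' (e.g. a mean radial coordinate per receptor) the index is flipped if
#' needed so that 0 is the central end; otherwise the first receptor (row
#' order) is placed in the lower half.
#'
#' @param om An `overlap_matrix` (or plain overlap matrix).
#' @param k Nearest-neighbour graph degree (default 10).
#' @param min_overlap Minimum overlap for graph connectivity (default 0.02).
#' @param min_support Minimum cells for a defined index (informational).
#' @param orient_by Optional named numeric used to orient the index.
#' @param seed Unused (deterministic); kept for interface stability.
#' @return A list of class `cp_index`: `index` (data.frame `receptor`,
#'   `cp_index`, `unusual_zone`), `embedding` (2D coordinates), `endpoints`.
#' @export
central_peripheral_index <- function(om, k = 10L, min_overlap = 0.02,
                                     min_support = 5L, orient_by = NULL,
                                     seed = 1L) {
  ov <- if (inherits(om, "overlap_matrix")) om$overlap else om
  ok <- rowSums(!is.na(ov)) > 0
  ov <- ov[ok, ok, drop = FALSE]
  n <- nrow(ov)
  if (n < 10L)
    stop_orfish("overlap matrix defined for fewer than 10 receptors",
                class = "orfish_input_error")
  ov0 <- ov; ov0[is.na(ov0)] <- 0
  if (stats::sd(ov0[upper.tri(ov0)]) < 1e-12)
    stop_orfish("degenerate overlap matrix: index undefined",
                class = "orfish_degenerate_error")
  # detached components on the overlap graph
  adj <- ov0 > min_overlap
  diag(adj) <- FALSE
  g_all <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g_all)
  main <- which.max(comp$csize)
  unusual <- comp$membership != main
  receptors <- rownames(ov)
  idx <- rep(NA_real_, n)
  main_i <- which(!unusual)
  D <- 1 - ov0[main_i, main_i, drop = FALSE]
  diag(D) <- 0
  emb <- stats::cmdscale(stats::as.dist(D), k = 2)
  if (ncol(emb) < 2) emb <- cbind(emb, 0)
  # kNN graph on the embedding, geodesic trajectory between extremes
  m <- nrow(emb)
  kk <- min(k, m - 1L)
  Ed <- cross_dist(emb, emb)
  A <- matrix(FALSE, m, m)
  for (i in seq_len(m)) {
    nb <- order(Ed[i, ])[2:(kk + 1L)]
    A[i, nb] <- TRUE
  }
  A <- A | t(A)
  W <- ifelse(A, Ed, 0)
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE)
  if (igraph::components(g)$no > 1L) {
    # bridge disconnected embedding parts with their closest pair
    cmp <- igraph::components(g)$membership
    while (length(unique(cmp)) > 1L) {
      c1 <- which(cmp == cmp[1]); c2 <- which(cmp != cmp[1])
      sub <- Ed[c1, c2, drop = FALSE]
      w <- which(sub == min(sub), arr.ind = TRUE)[1, ]
      g <- igraph::add_edges(g, c(c1[w[1]], c2[w[2]]),
                             weight = min(sub))
      cmp <- igraph::components(g)$membership
    }
  }
  d1 <- igraph::distances(g, v = 1)
  u <- which.max(d1)
  du <- igraph::distances(g, v = u)
  v <- which.max(du)
  pos <- as.numeric(du)
  pos <- (pos - min(pos)) / (max(pos) - min(pos))
  # canonical orientation
  flip <- FALSE
  if (!is.null(orient_by)) {
    ob <- orient_by[receptors[main_i]]
    if (sum(!is.na(ob)) >= 3 &&
        isTRUE(stats::cor(pos, ob, use = "complete.obs") < 0)) flip <- TRUE
  } else if (pos[1] > 0.5) flip <- TRUE
  if (flip) pos <- 1 - pos
  idx[main_i] <- pos
  out <- data.frame(receptor = receptors, cp_index = idx,
                    unusual_zone = unusual, stringsAsFactors = FALSE)
  rownames(emb) <- receptors[main_i]
  structure(list(index = out, embedding = emb,
                 endpoints = receptors[main_i][c(u, v)]),
            class = "cp_index")
}

#' Basal-apical index from cell depths
#'
#' Each cell's depth is `d_basal / (d_basal + d_apical)` between the two
#' epithelial surfaces (0 = on the basal lamina, 1 = at the apical
#' surface); a receptor's index is the mean depth of its cells. Cells
#' outside the ribbon (negative distance to either surface) are excluded
#' and counted.
#'
#' @param cells Cell table with `receptor` and `z_um` (or `depth`).
#' @param geometry An `epithelium_geometry` (e.g. [slab_geometry()]).
#' @param min_support Minimum cells for a defined index (default 5).
#' @return A data.frame `receptor`, `ba_index`, `n_cells`, plus attribute
#'   `n_excluded`.
#' @export
basal_apical_index <- function(cells, geometry, min_support = 5L) {
  db <- geometry$d_basal(cells$z_um)
  da <- geometry$d_apical(cells$z_um)
  inside <- db >= 0 & da >= 0
  depth <- db[inside] / (db[inside] + da[inside])
  rec <- cells$receptor[inside]
  receptors <- sort(unique(cells$receptor))
  ba <- vapply(receptors, function(r) {
    v <- depth[rec == r]
    if (length(v) >= min_support) mean(v) else NA_real_
  }, numeric(1))
  n <- vapply(receptors, function(r) sum(rec == r), integer(1))
  out <- data.frame(receptor = receptors, ba_index = as.numeric(ba),
                    n_cells = n, stringsAsFactors = FALSE)
  attr(out, "n_excluded") <- sum(!inside)
  out
}

#' Bulb axis coordinates of receptor projections
#'
#' Assigns each receptor a dorsal-ventral coordinate (the center of its
#' 150 um DV bin, bins half-open `(lo, hi]` so y = 300 falls in the bin
#' centered at 225) and an anterior-posterior coordinate (mean z),
#' separately for medial and lateral projections, and computes
#' sliding-window mean-position tracks over receptors ordered by the
#' central-peripheral index.
#'
#' @param map Projection-map data.frame.
#' @param dv_bin_um DV bin width (default 150).
#' @param window Sliding window size in receptors (default 70).
#' @param cp Optional named central-peripheral index for track ordering.
#' @return A list: `coordinates` (data.frame `receptor`, `side`, `dv_um`
#'   (bin center), `dv_raw_um`, `ap_um`), `tracks` (per side, data.frame of
#'   window-mean 3D positions along the cp ordering; NULL without `cp`).
#' @export
ob_axis_coordinates <- function(map, dv_bin_um = 150, window = 70L, cp = NULL) {
  ag <- stats::aggregate(map[, c("x_um", "y_um", "z_um")],
                         by = list(receptor = map$receptor, side = map$side),
                         FUN = mean)
  dv_bin <- (pmax(ceiling(ag$y_um / dv_bin_um), 1) - 0.5) * dv_bin_um
  coords <- data.frame(receptor = ag$receptor, side = ag$side,
                       dv_um = dv_bin, dv_raw_um = ag$y_um, ap_um = ag$z_um,
                       stringsAsFactors = FALSE)
  tracks <- NULL
  if (!is.null(cp)) {
    tracks <- list()
    for (sd_ in unique(coords$side)) {
      as_ <- ag[ag$side == sd_, , drop = FALSE]
      cpv <- cp[as_$receptor]
      keep <- !is.na(cpv)
      as_ <- as_[keep, , drop = FALSE][order(cpv[keep]), , drop = FALSE]
      nr <- nrow(as_)
      w <- min(window, nr)
      if (nr >= 1 && w >= 1) {
        nwin <- nr - w + 1L
        pos <- t(vapply(seq_len(nwin), function(i)
          colMeans(as_[i:(i + w - 1L), c("x_um", "y_um", "z_um")]),
          numeric(3)))
        tracks[[sd_]] <- data.frame(window = seq_len(nwin), pos)
      }
    }
  }
  list(coordinates = coords, tracks = tracks)
}

#' Genomic clustering and enhancer-proximity statistics
#'
#' Single-linkage clustering of receptor genes along the genome (genes on
#' the same chromosome join a cluster when their interval gap is at most
#' `cluster_gap_bp`), the mean pairwise spatial overlap as a function of
#' genomic distance, and a rank-sum test comparing the abundance of
#' receptors within `enhancer_window_bp` of a known enhancer against the
#' rest.
#'
#' @param metadata Data.frame `receptor`, `chrom`, `start`, `end` (bp).
#' @param abundance Named per-receptor abundance (e.g. cells/section).
#' @param om Optional `overlap_matrix` for the distance curve.
#' @param enhancers Optional data.frame `chrom`, `pos` (bp) of enhancer
#'   elements; when missing the proximity test is skipped with a notice.
#' @param cluster_gap_bp Single-linkage gap (default 1e5).
#' @param enhancer_window_bp Proximity window (default 5e4).
#' @param distance_breaks_bp Bin edges for the overlap-distance curve.
#' @return A list: `clusters` (metadata plus `cluster` id),
#'   `overlap_by_distance` (data.frame `bin_lo`, `bin_hi`, `mean_overlap`,
#'   `n_pairs`), `enhancer_test` (htest or NULL), `n_near_enhancer`.
#' @export
genomic_cluster_analysis <- function(metadata, abundance = NULL, om = NULL,
                                     enhancers = NULL, cluster_gap_bp = 1e5,
                                     enhancer_window_bp = 5e4,
                                     distance_breaks_bp =
                                       c(0, 1e5, 3e5, 1e6, 3e6, 1e7, Inf)) {
  md <- metadata[order(metadata$chrom, metadata$start), , drop = FALSE]
  cl <- integer(nrow(md)); cur <- 0L
  for (i in seq_len(nrow(md))) {
    newc <- i == 1L || md$chrom[i] != md$chrom[i - 1L] ||
      (md$start[i] - md$end[i - 1L]) > cluster_gap_bp
    if (newc) cur <- cur + 1L
    cl[i] <- cur
  }
  md$cluster <- cl
  curve <- NULL
  if (!is.null(om)) {
    ov <- if (inherits(om, "overlap_matrix")) om$overlap else om
    shared <- intersect(rownames(ov), md$receptor)
    mi <- md[match(shared, md$receptor), ]
    pr <- utils::combn(length(shared), 2)
    same <- mi$chrom[pr[1, ]] == mi$chrom[pr[2, ]]
    gd <- abs((mi$start[pr[1, ]] + mi$end[pr[1, ]]) / 2 -
                (mi$start[pr[2, ]] + mi$end[pr[2, ]]) / 2)
    ovv <- ov[cbind(match(shared, rownames(ov))[pr[1, ]],
                    match(shared, rownames(ov))[pr[2, ]])]
    keep <- same & !is.na(ovv)
    b <- cut(gd[keep], distance_breaks_bp, right = FALSE)
    curve <- data.frame(
      bin = levels(b),
      mean_overlap = as.numeric(tapply(ovv[keep], b, mean)),
      n_pairs = as.integer(table(b)))
  }
  test <- NULL; near <- NULL
  if (!is.null(enhancers) && !is.null(abundance)) {
    dist_to_enh <- vapply(seq_len(nrow(md)), function(i) {
      e <- enhancers[enhancers$chrom == md$chrom[i], , drop = FALSE]
      if (!nrow(e)) return(Inf)
      min(pmax(e$pos - md$end[i], md$start[i] - e$pos, 0))
    }, numeric(1))
    near <- dist_to_enh <= enhancer_window_bp
    ab <- abundance[md$receptor]
    if (any(near) && any(!near))
      test <- stats::wilcox.test(ab[near], ab[!near], exact = FALSE)
  } else if (is.null(enhancers)) {
    message("no enhancers supplied; proximity test skipped")
  }
  list(clusters = md, overlap_by_distance = curve, enhancer_test = test,
       n_near_enhancer = if (is.null(near)) NA_integer_ else sum(near))
}

#' Phylogenetic association of spatial overlap or receptor sets
#'
#' Patristic distances are taken from the branch lengths of the supplied
#' tree. Mode A bins pairwise spatial overlap by patristic distance
#' (quartile summaries per bin); mode B asks whether a receptor set (e.g.
#' the responders to one cue) is more similar in sequence than chance,
#' comparing within-set pairwise distances to all remaining pairwise
#' distances by rank-sum and to size-matched random sets by permutation.
#'
#' @param tree An `ape::phylo` tree with branch lengths, tips = receptors.
#' @param om Optional overlap matrix (mode A).
#' @param receptor_set Optional character vector (mode B).
#' @param n_bins Patristic-distance bins for mode A (default 5).
#' @param n_perm Permutation resamples for mode B (default 1000).
#' @param seed Seed for the permutation draw.
#' @return A list with `dropped` (queried receptors missing from the tree),
#'   and per mode: `overlap_by_distance` (data.frame with quartiles) and/or
#'   `set_test` (`p_ranksum`, `p_perm`, `mean_within`, `null_means`).
#' @export
phylo_association <- function(tree, om = NULL, receptor_set = NULL,
                              n_bins = 5L, n_perm = 1000L, seed = 1L) {
  pd <- ape::cophenetic.phylo(tree)
  out <- list(dropped = character())
  if (!is.null(om)) {
    ov <- if (inherits(om, "overlap_matrix")) om$overlap else om
    shared <- intersect(rownames(ov), rownames(pd))
    out$dropped <- union(out$dropped, setdiff(rownames(ov), shared))
    po <- pd[shared, shared]
    oo <- ov[shared, shared]
    ut <- upper.tri(po)
    keep <- ut & !is.na(oo)
    b <- cut(po[keep], stats::quantile(po[keep], seq(0, 1, length.out = n_bins + 1)),
             include.lowest = TRUE)
    qs <- tapply(oo[keep], b, function(v)
      stats::quantile(v, c(0.25, 0.5, 0.75)))
    out$overlap_by_distance <- data.frame(
      bin = levels(b),
      q25 = vapply(qs, `[[`, numeric(1), 1),
      median = vapply(qs, `[[`, numeric(1), 2),
      q75 = vapply(qs, `[[`, numeric(1), 3),
      n_pairs = as.integer(table(b)))
  }
  if (!is.null(receptor_set)) {
    present <- intersect(receptor_set, rownames(pd))
    out$dropped <- union(out$dropped, setdiff(receptor_set, present))
    if (length(present) < 2L)
      stop_orfish("receptor set has fewer than 2 tips on the tree",
                  class = "orfish_input_error")
    ii <- match(present, rownames(pd))
    within <- pd[ii, ii][upper.tri(matrix(0, length(ii), length(ii)))]
    all_ut <- pd[upper.tri(pd)]
    other_mask <- upper.tri(pd)
    other_mask[ii, ii] <- FALSE
    others <- pd[other_mask & upper.tri(pd)]
    p_rs <- tryCatch(
      stats::wilcox.test(within, others, alternative = "less",
                         exact = FALSE)$p.value,
      error = function(e) NA_real_)
    obs <- mean(within)
    null_means <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
      jj <- sample(nrow(pd), length(ii))
      mean(pd[jj, jj][upper.tri(matrix(0, length(jj), length(jj)))])
    }, numeric(1)))
    p_perm <- (1 + sum(null_means <= obs)) / (n_perm + 1)
    out$set_test <- list(p_ranksum = p_rs, p_perm = p_perm,
                         mean_within = obs, null_means = null_means,
                         n_set = length(present))
  }
  out
}
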