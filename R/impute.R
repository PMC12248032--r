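#' Spatial imputation of type-averaged expression
#'
#' Type-averaged expression from single-cell sequencing is transferred onto
#' spatial coordinates measured by imaging: every decoded cell (epithelium)
#' or glomerular projection (bulb) inherits the expression vector of its
#' receptor type, values are averaged over all entities within a radius of
#' each surface point (50 um for the epithelium, 400 um for the bulb), and
#' each gene's surface is normalized by its 99th-percentile value and
#' capped at 1.
#'
#' @name impute
NULL

surface_grid <- function(positions, spacing_um, radius_um) {
  xr <- range(positions$x_um); yr <- range(positions$y_um)
  gx <- seq(xr[1], xr[2], by = spacing_um)
  gy <- seq(yr[1], yr[2], by = spacing_um)
  g <- expand.grid(x_um = gx, y_um = gy)
  d <- cross_dist(g, positions[, c("x_um", "y_um")])
  g[apply(d, 1, min) <= radius_um, , drop = FALSE]
}

#' Impute expression onto a spatial surface
#'
#' The value of gene g at surface point p is the mean of
#' `expr[receptor(e), g]` over all entities e within `radius_um` of p;
#' points with no contributor are undefined (NA). Normalized values divide
#' by the `norm_percentile` (type-1) quantile of the defined raw values per
#' gene and are capped at 1, so the percentile of the normalized surface is
#' exactly 1.
#'
#' @param expr Types x genes expression matrix (rownames = receptors).
#' @param positions Data.frame of entities: `receptor`, `x_um`, `y_um`,
#'   optionally `region` (e.g. medial / lateral; surfaces are built per
#'   region) and other columns carried through.
#' @param radius_um Averaging radius (50 for MOE, 400 for OB).
#' @param norm_percentile Normalization percentile (default 99).
#' @param surface_points `"cells"` (the entity positions themselves; MOE
#'   convention) or `"grid"` (uniform grid at `grid_spacing_um` over the
#'   region within `radius_um` of any entity; OB convention).
#' @param grid_spacing_um Grid spacing for `surface_points = "grid"`.
#' @param genes Genes to impute (default all columns of `expr`).
#' @param exclude_receptor Optional receptor whose entities are left out
#'   (leave-one-out support).
#' @return A list of class `imputed_surface`: `points` (data.frame with
#'   `x_um`, `y_um`, `region`, `n_contrib`), `raw` and `norm` (points x
#'   genes matrices), `radius_um`, `norm_percentile`.
#' @export
impute_surface <- function(expr, positions, radius_um = 50,
                           norm_percentile = 99, surface_points = "cells",
                           grid_spacing_um = 50, genes = colnames(expr),
                           exclude_receptor = NULL) {
  if (radius_um <= 0)
    stop_orfish("radius_um must be positive", class = "orfish_input_error")
  if (norm_percentile <= 0 || norm_percentile > 100)
    stop_orfish("norm_percentile must be in (0, 100]",
                class = "orfish_input_error")
  missing_g <- setdiff(genes, colnames(expr))
  if (length(missing_g))
    stop_orfish("genes absent from expression matrix: ",
                paste(missing_g, collapse = ", "),
                class = "orfish_input_error")
  bad <- setdiff(unique(positions$receptor), rownames(expr))
  if (length(bad))
    stop_orfish("receptors absent from expression matrix: ",
                paste(utils::head(bad, 5), collapse = ", "),
                class = "orfish_input_error")
  if (!is.null(exclude_receptor))
    positions <- positions[positions$receptor != exclude_receptor, ,
                           drop = FALSE]
  if (!"region" %in% names(positions)) positions$region <- "n/a"
  pts_list <- list(); raw_list <- list()
  for (rg in unique(positions$region)) {
    po <- positions[positions$region == rg, , drop = FALSE]
    pts <- switch(surface_points,
                  cells = po[, c("x_um", "y_um")],
                  grid = surface_grid(po, grid_spacing_um, radius_um),
                  stop_orfish("unknown surface_points", class = "orfish_input_error"))
    A <- cross_dist(pts, po[, c("x_um", "y_um")]) <= radius_um
    counts <- rowSums(A)
    E <- expr[po$receptor, genes, drop = FALSE]
    raw <- (A %*% E) / pmax(counts, 1)
    raw[counts == 0, ] <- NA_real_
    pts$region <- rg
    pts$n_contrib <- counts
    pts_list[[rg]] <- pts
    raw_list[[rg]] <- raw
  }
  points <- do.call(rbind, pts_list)
  raw <- do.call(rbind, raw_list)
  rownames(points) <- rownames(raw) <- NULL
  norm <- raw
  for (j in seq_len(ncol(raw))) {
    v <- raw[, j][!is.na(raw[, j])]
    if (!length(v)) next
    q <- stats::quantile(v, norm_percentile / 100, type = 1, names = FALSE)
    norm[, j] <- if (q > 0) pmin(raw[, j] / q, 1) else raw[, j] * 0
  }
  structure(list(points = points, raw = raw, norm = norm,
                 radius_um = radius_um, norm_percentile = norm_percentile,
                 surface_points = surface_points,
                 grid_spacing_um = grid_spacing_um),
            class = "imputed_surface")
}

#' Leave-one-out prediction of projection positions from expression
#'
#' For each receptor, the bulb surface is re-imputed from all other
#' receptors' projections; the predicted position is the surface point
#' (per region, medial and lateral) where the Pearson correlation between
#' the imputed gene vector and the receptor's own expression profile is
#' highest, and the error is the distance to the receptor's true
#' projection in that region. With `shuffle = TRUE` the receptor-to-
#' expression assignment is permuted first, giving the chance baseline.
#'
#' @param expr Types x genes expression matrix.
#' @param map Projection positions: data.frame `receptor`, `x_um`, `y_um`,
#'   optionally `region`.
#' @param radius_um Imputation radius (default 400).
#' @param grid_spacing_um Surface grid spacing (default 50).
#' @param genes Genes used (default all).
#' @param shuffle Permute the receptor -> expression assignment first.
#' @param seed Seed for the shuffle.
#' @return A data.frame, one row per (receptor, region): `receptor`,
#'   `region`, `pred_x_um`, `pred_y_um`, `true_x_um`, `true_y_um`,
#'   `error_um`, `best_cor`.
#' @export
loo_predict_projection <- function(expr, map, radius_um = 400,
                                   grid_spacing_um = 50,
                                   genes = colnames(expr), shuffle = FALSE,
                                   seed = 1) {
  receptors <- intersect(rownames(expr), unique(map$receptor))
  if (length(receptors) < 2L)
    stop_orfish("need at least 2 receptor types in the map",
                class = "orfish_input_error")
  if (shuffle) {
    perm <- with_seed(seed, sample(receptors))
    rownames(expr)[match(receptors, rownames(expr))] <- perm
  }
  if (!"region" %in% names(map)) map$region <- "n/a"
  map <- map[map$receptor %in% receptors, , drop = FALSE]
  out <- list()
  for (rg in unique(map$region)) {
    mr <- map[map$region == rg, , drop = FALSE]
    pts <- surface_grid(mr, grid_spacing_um, radius_um)
    A <- cross_dist(pts, mr[, c("x_um", "y_um")]) <= radius_um
    E <- expr[mr$receptor, genes, drop = FALSE]
    S_all <- A %*% E
    n_all <- rowSums(A)
    for (r in unique(mr$receptor)) {
      own <- mr$receptor == r
      S <- S_all - A[, own, drop = FALSE] %*% E[own, , drop = FALSE]
      n <- n_all - rowSums(A[, own, drop = FALSE])
      ok <- n > 0
      V <- S[ok, , drop = FALSE] / n[ok]
      prof <- expr[r, genes]
      cc <- suppressWarnings(stats::cor(t(V), prof))
      cc[is.na(cc)] <- -Inf
      best <- which.max(cc)
      pi_ <- which(ok)[best]
      true_xy <- colMeans(mr[own, c("x_um", "y_um"), drop = FALSE])
      out[[length(out) + 1L]] <- data.frame(
        receptor = r, region = rg,
        pred_x_um = pts$x_um[pi_], pred_y_um = pts$y_um[pi_],
        true_x_um = true_xy[1], true_y_um = true_xy[2],
        error_um = sqrt(sum((c(pts$x_um[pi_], pts$y_um[pi_]) - true_xy)^2)),
        best_cor = max(cc), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Rank genes by axis gradient strength
#'
#' Correlates each gene's imputed surface values with a spatial axis
#' coordinate and ranks genes by absolute Pearson correlation; genes with
#' constant surfaces are excluded with a notice. Under the package's axis
#' convention the DV coordinate is the surface `y_um` (increasing
#' ventrally, so a gene increasing dorsally has negative r against `y_um`;
#' pass `orientation = -1` to report dorsal-positive correlations) and the
#' AP coordinate is `z_um` when present.
#'
#' @param surface An `imputed_surface` whose points carry the axis column.
#' @param axis Column of `surface$points` to correlate against (default
#'   `"y_um"`).
#' @param use `"norm"` or `"raw"` values.
#' @param orientation +1 or -1 sign flip applied to the reported r.
#' @return A data.frame `gene`, `r`, `abs_r`, `rank`, sorted by `abs_r`
#'   descending; attribute `excluded` lists constant genes.
#' @export
rank_axis_gradients <- function(surface, axis = "y_um", use = "norm",
                                orientation = 1) {
  if (!axis %in% names(surface$points))
    stop_orfish("axis column ", axis, " not present on the surface",
                class = "orfish_input_error")
  V <- surface[[use]]
  coord <- surface$points[[axis]]
  ok_pt <- rowSums(is.na(V)) == 0
  V <- V[ok_pt, , drop = FALSE]; coord <- coord[ok_pt]
  sds <- apply(V, 2, stats::sd)
  excluded <- colnames(V)[sds < 1e-12]
  if (length(excluded))
    message(length(excluded), " constant gene surface(s) excluded")
  keep <- sds >= 1e-12
  r <- orientation * as.numeric(stats::cor(V[, keep, drop = FALSE], coord))
  out <- data.frame(gene = colnames(V)[keep], r = r, abs_r = abs(r),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$abs_r), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Embed genes by spatial-pattern correlation
#'
#' Embeds genes in 2D from the dissimilarity `1 - Pearson r` between their
#' imputed spatial patterns (classical MDS) and groups them by Leiden
#' community detection on a k-nearest-neighbour graph of the patterns.
#' Deterministic given `seed`.
#'
#' @param surface An `imputed_surface` (at least 20 genes).
#' @param k Nearest-neighbour graph degree (default 10).
#' @param resolution Leiden resolution (default 1).
#' @param use `"norm"` or `"raw"` values.
#' @param seed Integer seed.
#' @return A data.frame `gene`, `dim1`, `dim2`, `cluster`.
#' @export
embed_gene_patterns <- function(surface, k = 10L, resolution = 1,
                                use = "norm", seed = 1) {
  V <- surface[[use]]
  ok_pt <- rowSums(is.na(V)) == 0
  V <- V[ok_pt, , drop = FALSE]
  if (ncol(V) < 20L)
    stop_orfish("need at least 20 genes with defined surfaces",
                class = "orfish_input_error")
  C <- suppressWarnings(stats::cor(V))
  C[is.na(C)] <- 0
  D <- 1 - C
  diag(D) <- 0
  emb <- stats::cmdscale(stats::as.dist(D), k = 2)
  n <- ncol(V)
  kk <- min(k, n - 1L)
  A <- matrix(FALSE, n, n)
  for (i in seq_len(n)) A[i, order(D[i, ])[2:(kk + 1L)]] <- TRUE
  A <- A | t(A)
  W <- ifelse(A, pmax(C, 1e-6), 0)
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE)
  cl <- with_seed(seed, igraph::cluster_leiden(
    g, objective_function = "modularity", resolution = resolution,
    n_iterations = 5))
  data.frame(gene = colnames(V), dim1 = emb[, 1], dim2 = emb[, 2],
             cluster = as.integer(igraph::membership(cl)),
             stringsAsFactors = FALSE)
}
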