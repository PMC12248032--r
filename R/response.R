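#' Odor-response catalogs from Egr1 counts
#'
#' A sensory neuron is scored active when it carries more than 5 Egr1
#' transcripts; the response of a receptor type to a cue is the fraction of
#' its neurons that are active, averaged across animals. Responses are
#' classified as strong (fraction > 0.5), partial (> 0.1) or none, compared
#' across cues to derive selectivity sets, screened for concentration-
#' dependent shifts against replicate variability, and mapped back onto the
#' epithelium and bulb atlases.
#'
#' @name response
NULL

#' Per-receptor responding fractions
#'
#' For each receptor and condition, the fraction of cells with an Egr1
#' count strictly above `egr1_threshold`, computed per animal and averaged
#' (unweighted) across animals; pooled cell support below `min_cells`
#' leaves the fraction undefined.
#'
#' @param cells Data.frame `receptor`, `condition`, `animal`, `egr1`.
#' @param egr1_threshold Activity threshold, strict (default 5).
#' @param min_cells Minimum pooled cells for a defined fraction (default 10).
#' @param pooled If `TRUE`, compute the pooled-cell fraction instead of the
#'   per-animal mean.
#' @return A data.frame of class `response_catalog`: `receptor`,
#'   `condition`, `fraction`, `n_cells`, `n_animals`; attribute
#'   `by_animal` holds the per-animal fractions.
#' @export
response_fractions <- function(cells, egr1_threshold = 5, min_cells = 10L,
                               pooled = FALSE) {
  if (any(cells$egr1 < 0))
    stop_orfish("Egr1 counts must be non-negative",
                class = "orfish_input_error")
  cells$active <- cells$egr1 > egr1_threshold
  grp <- list(receptor = cells$receptor, condition = cells$condition,
              animal = cells$animal)
  by_an <- stats::aggregate(list(fraction = cells$active), by = grp,
                            FUN = mean)
  by_an$n_cells <- stats::aggregate(list(n = cells$active), by = grp,
                                    FUN = length)$n
  key <- paste(by_an$receptor, by_an$condition)
  out <- list()
  for (kk in unique(key)) {
    rows <- by_an[key == kk, , drop = FALSE]
    n_tot <- sum(rows$n_cells)
    frac <- if (n_tot < min_cells) NA_real_
    else if (pooled) sum(rows$fraction * rows$n_cells) / n_tot
    else mean(rows$fraction)
    out[[kk]] <- data.frame(receptor = rows$receptor[1],
                            condition = rows$condition[1],
                            fraction = frac, n_cells = n_tot,
                            n_animals = nrow(rows), stringsAsFactors = FALSE)
  }
  cat_ <- do.call(rbind, out)
  cat_ <- cat_[order(cat_$condition, cat_$receptor), ]
  rownames(cat_) <- NULL
  attr(cat_, "by_animal") <- by_an
  class(cat_) <- c("response_catalog", class(cat_))
  cat_
}

#' Classify responses
#'
#' Strong if fraction > `strong_threshold`, partial if strictly above
#' `partial_threshold` (and at most strong), none otherwise; undefined
#' fractions stay unclassified.
#'
#' @param catalog A `response_catalog`.
#' @param partial_threshold Default 0.10 (strict).
#' @param strong_threshold Default 0.50 (strict).
#' @return The catalog with a `class` column
#'   (`"strong"`/`"partial"`/`"none"`/`NA`).
#' @export
classify_responses <- function(catalog, partial_threshold = 0.10,
                               strong_threshold = 0.50) {
  catalog$class <- ifelse(is.na(catalog$fraction), NA_character_,
                   ifelse(catalog$fraction > strong_threshold, "strong",
                   ifelse(catalog$fraction > partial_threshold, "partial",
                          "none")))
  catalog
}

#' Compare responding sets across cues
#'
#' The responding set of a condition contains the receptors with fraction
#' strictly above `respond_threshold`. Pairwise sharing is reported either
#' row-conditionally (`|A intersect B| / |A|`, the default, read row ->
#' column) or as Jaccard (`|A intersect B| / |A union B|`); only receptors
#' with defined fractions in both conditions enter each pairwise entry.
#'
#' @param catalog A `response_catalog` covering >= 2 conditions.
#' @param respond_threshold Responding threshold (default 0.1, strict).
#' @param method `"conditional"` or `"jaccard"`.
#' @return A list: `sets` (named list of responding receptor sets),
#'   `shared` (conditions x conditions matrix), `n_shared_receptors`.
#' @export
compare_cues <- function(catalog, respond_threshold = 0.1,
                         method = c("conditional", "jaccard")) {
  method <- match.arg(method)
  conds <- unique(catalog$condition)
  if (length(conds) < 2L)
    stop_orfish("need at least 2 conditions", class = "orfish_input_error")
  sets <- lapply(conds, function(cn) {
    cc <- catalog[catalog$condition == cn & !is.na(catalog$fraction), ]
    cc$receptor[cc$fraction > respond_threshold]
  })
  names(sets) <- conds
  defined <- lapply(conds, function(cn)
    catalog$receptor[catalog$condition == cn & !is.na(catalog$fraction)])
  names(defined) <- conds
  M <- matrix(NA_real_, length(conds), length(conds),
              dimnames = list(conds, conds))
  Nsh <- M
  for (i in conds) for (j in conds) {
    shared_def <- intersect(defined[[i]], defined[[j]])
    A <- intersect(sets[[i]], shared_def)
    B <- intersect(sets[[j]], shared_def)
    Nsh[i, j] <- length(shared_def)
    M[i, j] <- if (method == "conditional") {
      if (length(A)) length(intersect(A, B)) / length(A) else NA_real_
    } else {
      u <- length(union(A, B))
      if (u) length(intersect(A, B)) / u else NA_real_
    }
  }
  list(sets = sets, shared = M, n_shared_receptors = Nsh)
}

#' Cue-selective receptor set
#'
#' Receptors responding to `pos_condition` (fraction > `threshold`) but not
#' to `neg_condition` (fraction < `threshold`), e.g. male-selective =
#' responding to male but not female cue.
#'
#' @param catalog A `response_catalog`.
#' @param pos_condition,neg_condition Condition names.
#' @param threshold Response threshold (default 0.1).
#' @return Character vector of receptor ids.
#' @export
selective_set <- function(catalog, pos_condition, neg_condition,
                          threshold = 0.1) {
  pos <- catalog[catalog$condition == pos_condition, ]
  neg <- catalog[catalog$condition == neg_condition, ]
  m <- merge(pos[, c("receptor", "fraction")],
             neg[, c("receptor", "fraction")], by = "receptor",
             suffixes = c("_pos", "_neg"))
  m <- m[!is.na(m$fraction_pos) & !is.na(m$fraction_neg), ]
  m$receptor[m$fraction_pos > threshold & m$fraction_neg < threshold]
}

#' Concentration-dependent response shifts
#'
#' Flags receptors whose response to the high condition exceeds the low
#' condition by more than replicate-to-replicate variation: the empirical
#' band (5th-95th percentile of replicate-pair differences, by default) is
#' estimated in `n_bins` equal-count bins of the pair mean, and a receptor
#' is flagged when `high - low` exceeds the upper band at its mean
#' response. Flagging is monotone in `high - low` at fixed mean by
#' construction.
#'
#' @param catalog_high,catalog_low `response_catalog`s for the two
#'   concentrations (same receptors).
#' @param replicates Data.frame `receptor`, `f1`, `f2`: responding
#'   fractions of two replicate animals under the same condition.
#' @param band Central band mass (default 0.90: 5th-95th percentiles).
#' @param n_bins Equal-count bins of the mean response (default 5).
#' @return A data.frame `receptor`, `high`, `low`, `diff`, `mean`,
#'   `upper_band`, `flagged`; attribute `band_table`.
#' @export
concentration_shift <- function(catalog_high, catalog_low, replicates,
                                band = 0.90, n_bins = 5L) {
  if (is.null(replicates) || !nrow(replicates))
    stop_orfish("replicate pairs required to estimate the variability band",
                class = "orfish_input_error")
  rd <- replicates$f1 - replicates$f2
  rm_ <- (replicates$f1 + replicates$f2) / 2
  qs <- stats::quantile(rm_, probs = seq(0, 1, length.out = n_bins + 1))
  qs[1] <- -Inf; qs[n_bins + 1] <- Inf
  bin <- cut(rm_, qs, labels = FALSE, include.lowest = TRUE)
  hi_p <- 1 - (1 - band) / 2
  upper <- vapply(seq_len(n_bins), function(b) {
    v <- rd[bin == b]
    if (length(v) < 2) stats::quantile(rd, hi_p, names = FALSE)
    else stats::quantile(v, hi_p, names = FALSE)
  }, numeric(1))
  m <- merge(catalog_high[, c("receptor", "fraction")],
             catalog_low[, c("receptor", "fraction")], by = "receptor",
             suffixes = c("_high", "_low"))
  m <- m[!is.na(m$fraction_high) & !is.na(m$fraction_low), ]
  mean_r <- (m$fraction_high + m$fraction_low) / 2
  b_of <- cut(mean_r, qs, labels = FALSE, include.lowest = TRUE)
  ub <- upper[b_of]
  out <- data.frame(receptor = m$receptor, high = m$fraction_high,
                    low = m$fraction_low, diff = m$fraction_high - m$fraction_low,
                    mean = mean_r, upper_band = ub,
                    flagged = (m$fraction_high - m$fraction_low) > ub,
                    stringsAsFactors = FALSE)
  attr(out, "band_table") <- data.frame(bin = seq_len(n_bins),
                                        lo = qs[-(n_bins + 1)],
                                        hi = qs[-1], upper = upper)
  out
}

#' Mother-selective receptor types
#'
#' Receptors with a response above `floor` in mothers and more than `fold`
#' times their response in virgin females.
#'
#' @param catalog_mother,catalog_virgin `response_catalog`s (one condition
#'   each, shared receptors).
#' @param floor Minimum mother response (default 0.05, strict).
#' @param fold Fold-change over virgins (default 2, strict).
#' @return Character vector of receptor ids.
#' @export
mother_selective_types <- function(catalog_mother, catalog_virgin,
                                   floor = 0.05, fold = 2) {
  m <- merge(catalog_mother[, c("receptor", "fraction")],
             catalog_virgin[, c("receptor", "fraction")], by = "receptor",
             suffixes = c("_m", "_v"))
  m <- m[!is.na(m$fraction_m) & !is.na(m$fraction_v), ]
  m$receptor[m$fraction_m > floor & m$fraction_m > fold * m$fraction_v]
}

#' Differential gene expression in selected receptor types
#'
#' Compares each gene between cells of the selected types and all other
#' cells by a two-sided rank-sum test, after optionally restricting to
#' cells from female animals (Y-marker expression must be zero and X-marker
#' expression above `x_threshold`). Raw p-values are thresholded; a
#' Benjamini-Hochberg column is reported alongside.
#'
#' @param expr Cells x genes expression matrix.
#' @param cell_types Character vector, receptor type per cell (row).
#' @param selected_types Receptor types defining the selected group.
#' @param p_threshold Significance threshold on raw p (default 0.01).
#' @param sex_filter Apply the female-cell filter.
#' @param y_genes,x_genes Marker gene columns for the sex filter.
#' @param x_threshold Minimum summed X-marker expression (default 0).
#' @return A data.frame `gene`, `p`, `p_bh`, `direction` (+1 higher in the
#'   selected group), `significant` (p < threshold and direction +1),
#'   plus attribute `n_cells` (selected / other after filtering).
#' @export
differential_genes <- function(expr, cell_types, selected_types,
                               p_threshold = 0.01, sex_filter = FALSE,
                               y_genes = character(), x_genes = character(),
                               x_threshold = 0) {
  keep <- rep(TRUE, nrow(expr))
  if (sex_filter) {
    if (length(y_genes))
      keep <- keep & rowSums(expr[, y_genes, drop = FALSE]) == 0
    if (length(x_genes))
      keep <- keep & rowSums(expr[, x_genes, drop = FALSE]) > x_threshold
  }
  expr <- expr[keep, , drop = FALSE]
  cell_types <- cell_types[keep]
  sel <- cell_types %in% selected_types
  if (sum(sel) < 2L || sum(!sel) < 2L)
    stop_orfish("need at least 2 cells per group after filtering",
                class = "orfish_input_error")
  genes <- setdiff(colnames(expr), c(y_genes, x_genes))
  p <- numeric(length(genes)); dir_ <- integer(length(genes))
  for (i in seq_along(genes)) {
    a <- expr[sel, genes[i]]; b <- expr[!sel, genes[i]]
    p[i] <- tryCatch(
      stats::wilcox.test(a, b, exact = FALSE)$p.value,
      error = function(e) NA_real_)
    dir_[i] <- sign(stats::median(a) - stats::median(b))
  }
  out <- data.frame(gene = genes, p = p, p_bh = stats::p.adjust(p, "BH"),
                    direction = dir_,
                    significant = !is.na(p) & p < p_threshold & dir_ > 0,
                    stringsAsFactors = FALSE)
  attr(out, "n_cells") <- c(selected = sum(sel), other = sum(!sel))
  out
}

#' Map responses onto the spatial atlases
#'
#' Gives every epithelium cell-type entry and every glomerular projection a
#' weight equal to its receptor's responding fraction, and computes the
#' density of responding projections along the bulb DV and AP axes in
#' half-open bins of `axis_bin_um`, normalized to unit area.
#'
#' @param catalog A `response_catalog` (one condition).
#' @param spatial_index Data.frame with `receptor`, `cp_index` (and
#'   optionally `ba_index`).
#' @param map Projection-map data.frame (`receptor`, `y_um`, `z_um`).
#' @param axis_bin_um Axis bin width (default 200).
#' @param respond_threshold Receptors above this fraction enter the
#'   densities (default 0.1).
#' @return A list: `moe` (index table with `weight`), `ob` (map with
#'   `weight`), `density_dv` and `density_ap` (data.frames `bin_center_um`,
#'   `density`), `n_dropped` (catalog receptors absent from the atlases).
#' @export
map_responses_to_atlas <- function(catalog, spatial_index, map,
                                   axis_bin_um = 200,
                                   respond_threshold = 0.1) {
  fr <- stats::setNames(catalog$fraction, catalog$receptor)
  moe <- spatial_index
  moe$weight <- as.numeric(fr[moe$receptor])
  ob <- map
  ob$weight <- as.numeric(fr[ob$receptor])
  n_dropped <- sum(!(names(fr) %in% c(spatial_index$receptor, map$receptor)))
  resp <- ob[!is.na(ob$weight) & ob$weight > respond_threshold, , drop = FALSE]
  dens <- function(coord, w) {
    if (!length(coord))
      return(data.frame(bin_center_um = numeric(), density = numeric()))
    b <- floor(coord / axis_bin_um)
    agg <- tapply(w, b, sum)
    centers <- (as.numeric(names(agg)) + 0.5) * axis_bin_um
    d <- as.numeric(agg)
    d <- d / (sum(d) * axis_bin_um)  # unit area
    data.frame(bin_center_um = centers, density = d)
  }
  list(moe = moe, ob = ob,
       density_dv = dens(resp$y_um, resp$weight),
       density_ap = dens(resp$z_um, resp$weight),
       n_dropped = n_dropped)
}
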