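#' Transcript-level decoding in the olfactory bulb
#'
#' In the bulb, receptor transcripts sit in axon terminals rather than
#' somas, so decoding works at single-molecule level: 3D local maxima are
#' detected per readout image, spots co-localizing within ~160 nm per axis
#' in at least 4 readout bits form molecules, and each segmented glomerulus
#' is assigned the receptor whose molecule count passes strict
#' count-and-enrichment rules (count > 10 and > 10x any other glomerulus in
#' the section), with a relaxed cross-bulb consensus tier (count > 5,
#' co-located within 500 um in at least two bulbs).
#'
#' @name ob_decode
NULL

#' Detect 3D spots in a single readout image
#'
#' Finds strict 3D local maxima above `threshold` and refines each position
#' by intensity center-of-mass over its 3x3x3 neighbourhood.
#'
#' @param image 3D intensity array `[y, x, z]`.
#' @param threshold Intensity threshold (>= 0).
#' @param pixel_um Named voxel size `(x, y, z)` in micrometres.
#' @param bit Optional bit index attached to the detections.
#' @return A data.frame (`bit`, `x_um`, `y_um`, `z_um`, `brightness`).
#' @export
detect_spots <- function(image, threshold, pixel_um = c(x = 0.1, y = 0.1, z = 0.1),
                         bit = NA_integer_) {
  if (threshold < 0)
    stop_orfish("threshold must be >= 0", class = "orfish_input_error")
  d <- dim(image)
  idx <- local_maxima_3d(image, threshold)
  if (!length(idx))
    return(data.frame(bit = integer(), x_um = numeric(), y_um = numeric(),
                      z_um = numeric(), brightness = numeric()))
  sub <- arrayInd(idx, d)
  n <- nrow(sub)
  pos <- matrix(0, n, 3)
  for (k in seq_len(n)) {
    iy <- max(1, sub[k, 1] - 1):min(d[1], sub[k, 1] + 1)
    ix <- max(1, sub[k, 2] - 1):min(d[2], sub[k, 2] + 1)
    iz <- max(1, sub[k, 3] - 1):min(d[3], sub[k, 3] + 1)
    w <- image[iy, ix, iz, drop = FALSE]
    dim(w) <- c(length(iy), length(ix), length(iz))
    w <- pmax(w, 0)
    sw <- sum(w)
    pos[k, ] <- c(
      sum(apply(w, 2, sum) * (ix - 0.5)) / sw,
      sum(apply(w, 1, sum) * (iy - 0.5)) / sw,
      sum(apply(w, 3, sum) * (iz - 0.5)) / sw)
  }
  data.frame(bit = bit,
             x_um = pos[, 1] * pixel_um[["x"]],
             y_um = pos[, 2] * pixel_um[["y"]],
             z_um = pos[, 3] * pixel_um[["z"]],
             brightness = image[idx])
}

#' Co-localize spots across readout bits into molecules
#'
#' Groups spots into molecules by per-axis box co-localization: spots are
#' visited in order of decreasing brightness (ties broken by bit then input
#' order); each unused spot seeds a molecule from the unused spots within
#' `radius_um` of it along every axis, keeping the brightest spot per bit;
#' if at least `min_bits` distinct bits co-localize, the `min_bits`
#' brightest of those per-bit representatives form the molecule (when more
#' than 4 bits co-localize, only the brightest 4 are kept) and are removed
#' from the pool, so each spot belongs to at most one molecule.
#'
#' @param spots Data.frame with `bit`, `x_um`, `y_um`, `z_um`, `brightness`.
#' @param radius_um Per-axis co-localization radius (default 0.16 = 160 nm).
#' @param min_bits Minimum number of distinct bits (default 4).
#' @return A data.frame of molecules: `x_um`, `y_um`, `z_um` (means of the
#'   member spots), `brightness` (mean), `bits` (sorted key string),
#'   `member_rows` (list column of member row indices in `spots`).
#' @export
colocalize <- function(spots, radius_um = 0.16, min_bits = 4L) {
  if (radius_um <= 0)
    stop_orfish("radius_um must be positive", class = "orfish_input_error")
  n <- nrow(spots)
  empty <- data.frame(x_um = numeric(), y_um = numeric(), z_um = numeric(),
                      brightness = numeric(), bits = character(),
                      stringsAsFactors = FALSE)
  empty$member_rows <- list()
  if (!n) return(empty)
  ord <- order(-spots$brightness, spots$bit, seq_len(n))
  rank_of <- integer(n); rank_of[ord] <- seq_len(n)
  used <- logical(n)
  mols <- list()
  for (s in ord) {
    if (used[s]) next
    near <- !used &
      abs(spots$x_um - spots$x_um[s]) <= radius_um &
      abs(spots$y_um - spots$y_um[s]) <= radius_um &
      abs(spots$z_um - spots$z_um[s]) <= radius_um
    cand <- which(near)
    if (!length(cand)) next
    # brightest spot per distinct bit (ties by global order)
    cand <- cand[order(rank_of[cand])]
    reps <- cand[!duplicated(spots$bit[cand])]
    if (length(reps) < min_bits) next
    members <- reps[seq_len(min_bits)]  # already brightness-ordered
    used[members] <- TRUE
    mols[[length(mols) + 1L]] <- list(
      x_um = mean(spots$x_um[members]), y_um = mean(spots$y_um[members]),
      z_um = mean(spots$z_um[members]),
      brightness = mean(spots$brightness[members]),
      bits = bit_key(spots$bit[members]), members = sort(members))
  }
  if (!length(mols)) return(empty)
  out <- data.frame(
    x_um = vapply(mols, `[[`, numeric(1), "x_um"),
    y_um = vapply(mols, `[[`, numeric(1), "y_um"),
    z_um = vapply(mols, `[[`, numeric(1), "z_um"),
    brightness = vapply(mols, `[[`, numeric(1), "brightness"),
    bits = vapply(mols, `[[`, character(1), "bits"),
    stringsAsFactors = FALSE)
  out$member_rows <- lapply(mols, `[[`, "members")
  out
}

#' Assign receptor identities to molecules via the codebook
#'
#' @param molecules Output of [colocalize()].
#' @param codebook An `or_codebook`.
#' @return `molecules` with a `receptor` column (`NA` when the bit set is
#'   not in the book).
#' @export
identify_molecules <- function(molecules, codebook) {
  keys <- apply(codebook$entries, 1L, bit_key)
  molecules$receptor <- rownames(codebook$entries)[match(molecules$bits, keys)]
  molecules
}

#' Fit the brightness threshold separating targeted from untargeted molecules
#'
#' Molecules decoding to receptors outside the experiment's targeted panel
#' are noise; their brightness distribution sits below that of genuine
#' molecules. The threshold is the 1-D split minimizing total
#' misclassification (targeted below + untargeted at or above), and
#' molecules dimmer than the threshold are removed.
#'
#' @param molecules Data.frame with `brightness` and `receptor`.
#' @param targeted Character vector of targeted receptor ids.
#' @return A list: `threshold` (NA with a warning when either population is
#'   empty, in which case nothing is filtered), `molecules` (filtered),
#'   `accuracy` (training misclassification accuracy at the threshold).
#' @export
fit_brightness_threshold <- function(molecules, targeted) {
  is_t <- molecules$receptor %in% targeted
  if (!any(is_t) || all(is_t)) {
    warning("one brightness population is empty; no threshold fitted")
    return(list(threshold = NA_real_, molecules = molecules,
                accuracy = NA_real_))
  }
  b <- molecules$brightness
  o <- order(b)
  bs <- b[o]; ts <- is_t[o]
  n <- length(bs)
  # candidate cuts between consecutive distinct values (and the extremes);
  # classify as targeted iff brightness >= cut
  cuts <- c(bs[1] - 1, (bs[-n] + bs[-1]) / 2, bs[n] + 1)
  n_t_below <- c(0, cumsum(ts))        # targeted strictly below cut k
  n_u_below <- c(0, cumsum(!ts))
  errs <- n_t_below + (sum(!ts) - n_u_below)
  k <- which.min(errs)
  thr <- cuts[k]
  list(threshold = thr,
       molecules = molecules[molecules$brightness >= thr, , drop = FALSE],
       accuracy = 1 - errs[k] / n)
}

#' Count molecules per glomerulus
#'
#' Maps molecule positions into per-section glomerulus label masks and
#' tabulates counts per (glomerulus, receptor).
#'
#' @param molecules Data.frame with `section`, `x_um`, `y_um`, `receptor`
#'   (rows with `NA` receptor are dropped).
#' @param masks List of integer label matrices, one per section (0 =
#'   outside any glomerulus).
#' @param mask_pixel_um Mask pixel size in micrometres.
#' @return A data.frame `glom_id`, `section`, `receptor`, `count`.
#' @export
glomerulus_count_table <- function(molecules, masks, mask_pixel_um) {
  m <- molecules[!is.na(molecules$receptor), , drop = FALSE]
  if (!nrow(m))
    return(data.frame(glom_id = integer(), section = integer(),
                      receptor = character(), count = integer(),
                      stringsAsFactors = FALSE))
  lab <- integer(nrow(m))
  for (s in unique(m$section)) {
    msk <- masks[[s]]
    idx <- which(m$section == s)
    row <- pmin(pmax(ceiling(m$y_um[idx] / mask_pixel_um), 1L), nrow(msk))
    col <- pmin(pmax(ceiling(m$x_um[idx] / mask_pixel_um), 1L), ncol(msk))
    lab[idx] <- msk[cbind(row, col)]
  }
  keep <- lab > 0L
  if (!any(keep))
    return(data.frame(glom_id = integer(), section = integer(),
                      receptor = character(), count = integer(),
                      stringsAsFactors = FALSE))
  tab <- stats::aggregate(
    list(count = rep.int(1L, sum(keep))),
    by = list(glom_id = lab[keep], section = m$section[keep],
              receptor = m$receptor[keep]), FUN = sum)
  tab[order(tab$glom_id, -tab$count), ]
}

#' Glomerulus centroids and hemispheres from label masks
#'
#' Computes each glomerulus's centroid from its mask pixels and classifies
#' its hemisphere by the midline (`x < midline_um` = left). Useful for
#' running the assignment rule per hemi-bulb: bilateral twin glomeruli of
#' one receptor lie in the same coronal section, so comparing enrichment
#' within hemi-sections (paste hemisphere into the section key) keeps the
#' strict rule meaningful.
#'
#' @param masks List of integer label matrices (one per section).
#' @param mask_pixel_um Mask pixel size.
#' @param midline_um Midsagittal x position (default: half the mask width).
#' @return A data.frame `glom_id`, `section`, `x_um`, `y_um`, `hemisphere`.
#' @export
glomerulus_centroids <- function(masks, mask_pixel_um, midline_um = NULL) {
  midline_um <- midline_um %||% (ncol(masks[[1]]) * mask_pixel_um / 2)
  out <- list()
  for (s in seq_along(masks)) {
    m <- masks[[s]]
    labs <- setdiff(unique(as.integer(m)), 0L)
    for (g in labs) {
      idx <- which(m == g, arr.ind = TRUE)
      x <- mean((idx[, 2] - 0.5) * mask_pixel_um)
      y <- mean((idx[, 1] - 0.5) * mask_pixel_um)
      out[[length(out) + 1L]] <- data.frame(
        glom_id = g, section = s, x_um = x, y_um = y,
        hemisphere = if (x < midline_um) "left" else "right",
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Assign glomerulus identities by the strict count-enrichment rule
#'
#' A glomerulus is assigned its most-counted receptor if and only if that
#' count is strictly greater than `min_count` and strictly greater than
#' `enrichment` times the highest count of the same receptor in any other
#' glomerulus of the same section (treated as 1 when no other glomerulus
#' carries it, so a count above `min_count` always passes).
#'
#' @param counts Count table ([glomerulus_count_table()]): `glom_id`,
#'   `section`, `receptor`, `count`.
#' @param min_count Strict lower bound on the dominant count (default 10).
#' @param enrichment Strict enrichment factor over other glomeruli
#'   (default 10).
#' @return A data.frame, one row per glomerulus: `glom_id`, `section`,
#'   `receptor` (top receptor), `count`, `assigned` (receptor or NA),
#'   `tier` (`"strict"` or `"none"`).
#' @export
assign_glomerulus_identity <- function(counts, min_count = 10, enrichment = 10) {
  if (!nrow(counts))
    return(data.frame(glom_id = integer(), section = integer(),
                      receptor = character(), count = integer(),
                      assigned = character(), tier = character(),
                      stringsAsFactors = FALSE))
  if (any(counts$count < 0))
    stop_orfish("counts must be non-negative", class = "orfish_input_error")
  out <- list()
  for (s in unique(counts$section)) {
    cs <- counts[counts$section == s, , drop = FALSE]
    for (g in unique(cs$glom_id)) {
      cg <- cs[cs$glom_id == g, , drop = FALSE]
      top <- which.max(cg$count)
      rec <- cg$receptor[top]; cnt <- cg$count[top]
      other <- cs$count[cs$receptor == rec & cs$glom_id != g]
      denom <- if (length(other)) max(other) else 1
      denom <- max(denom, 1)
      ok <- (cnt > min_count) && (cnt > enrichment * denom)
      out[[length(out) + 1L]] <- data.frame(
        glom_id = g, section = s, receptor = rec, count = cnt,
        assigned = if (ok) rec else NA_character_,
        tier = if (ok) "strict" else "none", stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Relaxed cross-bulb consensus assignment
#'
#' Glomeruli failing the strict rule but with more than `relaxed_min`
#' molecules are assigned their top receptor when at least one other bulb
#' shows the same receptor (strictly assigned, or itself a relaxed
#' candidate) within `consensus_radius_um` in the common aligned frame;
#' such glomeruli get tier `"relaxed"`. Consensus positions are cross-bulb
#' means over the supporting glomeruli of each receptor.
#'
#' @param bulbs List of per-bulb glomerulus tables in a common reference
#'   frame; each needs `glom_id`, `receptor` (top receptor), `count`,
#'   `assigned`, `tier`, `x_um`, `y_um`, `z_um`.
#' @param relaxed_min Strict lower bound for relaxed candidates (default 5).
#' @param consensus_radius_um Co-location radius across bulbs (default 500).
#' @return A list: `glomeruli` (all bulbs stacked, with `bulb`, updated
#'   `assigned`/`tier`), `consensus` (per receptor/position-group means:
#'   `receptor`, `x_um`, `y_um`, `z_um`, `n_bulbs`, `tier`).
#' @export
relaxed_consensus <- function(bulbs, relaxed_min = 5, consensus_radius_um = 500) {
  if (length(bulbs) < 2L) {
    warning("fewer than 2 bulbs: consensus impossible, strict-only output")
    g <- if (length(bulbs)) cbind(bulb = 1L, bulbs[[1]]) else NULL
    return(list(glomeruli = g, consensus = NULL))
  }
  all_g <- do.call(rbind, lapply(seq_along(bulbs), function(i)
    cbind(bulb = i, bulbs[[i]])))
  cand <- all_g$tier == "none" & all_g$count > relaxed_min
  support <- all_g$tier == "strict" | cand
  for (i in which(cand)) {
    others <- which(support & all_g$bulb != all_g$bulb[i] &
                      all_g$receptor == all_g$receptor[i])
    if (!length(others)) next
    d <- sqrt((all_g$x_um[others] - all_g$x_um[i])^2 +
                (all_g$y_um[others] - all_g$y_um[i])^2 +
                (all_g$z_um[others] - all_g$z_um[i])^2)
    if (any(d <= consensus_radius_um)) {
      all_g$assigned[i] <- all_g$receptor[i]
      all_g$tier[i] <- "relaxed"
    }
  }
  asn <- all_g[!is.na(all_g$assigned), , drop = FALSE]
  cons <- NULL
  if (nrow(asn)) {
    rows <- list()
    for (rec in unique(asn$receptor)) {
      ar <- asn[asn$receptor == rec, , drop = FALSE]
      # group same-receptor glomeruli across bulbs by single linkage
      grp <- seq_len(nrow(ar))
      if (nrow(ar) > 1) {
        d <- cross_dist(ar[, c("x_um", "y_um", "z_um")],
                        ar[, c("x_um", "y_um", "z_um")])
        g_graph <- igraph::graph_from_adjacency_matrix(
          d <= consensus_radius_um, mode = "undirected")
        grp <- igraph::components(g_graph)$membership
      }
      for (k in unique(grp)) {
        ak <- ar[grp == k, , drop = FALSE]
        rows[[length(rows) + 1L]] <- data.frame(
          receptor = rec, x_um = mean(ak$x_um), y_um = mean(ak$y_um),
          z_um = mean(ak$z_um), n_bulbs = length(unique(ak$bulb)),
          tier = if (any(ak$tier == "strict")) "strict" else "relaxed",
          stringsAsFactors = FALSE)
      }
    }
    cons <- do.call(rbind, rows)
  }
  list(glomeruli = all_g, consensus = cons)
}
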