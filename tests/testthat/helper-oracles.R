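# Independent brute-force oracles used across tests. These deliberately
# avoid the package's implementation paths.

# O(n^2) Hamming distances between code rows via explicit bit vectors
oracle_min_hamming <- function(codes, n_bits) {
  n <- nrow(codes)
  tobin <- function(row) {
    v <- rep(0L, n_bits); v[row + 1L] <- 1L; v
  }
  best <- Inf
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    best <- min(best, sum(tobin(codes[i, ]) != tobin(codes[j, ])))
  as.integer(best)
}

# greedy brightest-first box colocalization, written independently:
# global which.max over a masked brightness vector, explicit per-bit
# selection, returns a list of sorted member index vectors
oracle_colocalize <- function(spots, radius, min_bits = 4L) {
  n <- nrow(spots)
  avail <- rep(TRUE, n)   # not yet absorbed into a molecule
  tried <- rep(FALSE, n)  # already visited as a seed
  pr <- order(-spots$brightness, spots$bit, seq_len(n))
  prio <- integer(n); prio[pr] <- seq_len(n)
  mols <- list()
  repeat {
    todo <- which(avail & !tried)
    if (!length(todo)) break
    seed <- todo[which.min(prio[todo])]
    tried[seed] <- TRUE
    pool <- which(avail)
    inbox <- pool[abs(spots$x_um[pool] - spots$x_um[seed]) <= radius &
                    abs(spots$y_um[pool] - spots$y_um[seed]) <= radius &
                    abs(spots$z_um[pool] - spots$z_um[seed]) <= radius]
    # brightest per bit
    byb <- split(inbox, spots$bit[inbox])
    reps <- vapply(byb, function(ii) ii[which.min(prio[ii])], integer(1))
    if (length(reps) >= min_bits) {
      members <- reps[order(prio[reps])][seq_len(min_bits)]
      avail[members] <- FALSE
      mols[[length(mols) + 1L]] <- sort(unname(members))
    }
  }
  mols
}

# one-pass strict + relaxed glomerulus rule oracle over a count table
oracle_glom_rule <- function(counts, min_count = 10, enrichment = 10) {
  res <- list()
  for (s in unique(counts$section)) {
    cs <- counts[counts$section == s, ]
    for (g in unique(cs$glom_id)) {
      cg <- cs[cs$glom_id == g, ]
      i <- which.max(cg$count)
      rec <- cg$receptor[i]; cnt <- cg$count[i]
      oth <- cs$count[cs$glom_id != g & cs$receptor == rec]
      den <- max(c(oth, 1))
      res[[paste(s, g)]] <- data.frame(
        glom_id = g, section = s,
        assigned = if (cnt > min_count && cnt > enrichment * den) rec
        else NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, res)
}

# direct double-loop overlap matrix
oracle_overlap <- function(cells, cutoff) {
  recs <- sort(unique(cells$receptor))
  K <- length(recs)
  acc <- matrix(0, K, K, dimnames = list(recs, recs))
  supp <- matrix(0, K, K, dimnames = list(recs, recs))
  for (s in unique(cells$section)) {
    cs <- cells[cells$section == s, ]
    for (a in seq_len(K)) for (b in seq_len(K)) {
      if (a > b) next
      A <- cs[cs$receptor == recs[a], c("x_um", "y_um")]
      B <- cs[cs$receptor == recs[b], c("x_um", "y_um")]
      if (!nrow(A) || !nrow(B)) next
      cntA <- 0
      for (i in seq_len(nrow(A)))
        if (any(sqrt((B$x_um - A$x_um[i])^2 + (B$y_um - A$y_um[i])^2) <=
                cutoff)) cntA <- cntA + 1
      cntB <- 0
      for (i in seq_len(nrow(B)))
        if (any(sqrt((A$x_um - B$x_um[i])^2 + (A$y_um - B$y_um[i])^2) <=
                cutoff)) cntB <- cntB + 1
      acc[a, b] <- acc[a, b] + (cntA + cntB) / (nrow(A) + nrow(B))
      supp[a, b] <- supp[a, b] + 1
    }
  }
  ov <- ifelse(supp > 0, acc / supp, NA_real_)
  ov[lower.tri(ov)] <- t(ov)[lower.tri(ov)]
  diag(ov) <- 1
  ov
}

# brute-force neighbourhood-average imputation
oracle_impute <- function(expr, positions, points, radius) {
  out <- matrix(NA_real_, nrow(points), ncol(expr))
  for (i in seq_len(nrow(points))) {
    d <- sqrt((positions$x_um - points$x_um[i])^2 +
                (positions$y_um - points$y_um[i])^2)
    nb <- which(d <= radius)
    if (length(nb))
      out[i, ] <- colMeans(expr[positions$receptor[nb], , drop = FALSE])
  }
  out
}

# igraph connected-components DBSCAN oracle
oracle_dbscan <- function(x, eps, min_pts) {
  n <- nrow(x)
  d <- as.matrix(dist(x))
  core <- rowSums(d <= eps) >= min_pts
  labels <- integer(n)
  if (any(core)) {
    adj <- (d <= eps) & outer(core, core, "&")
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                             diag = FALSE)
    comp <- igraph::components(g)$membership
    # relabel components by order of first appearance among core points
    first <- order(match(comp[core], unique(comp[core])))
    lab_map <- match(comp, unique(comp[core]))
    labels[core] <- lab_map[core]
    for (i in which(!core)) {
      nb <- which(d[i, ] <= eps & core)
      if (length(nb)) labels[i] <- labels[nb[which.min(d[i, nb])]]
    }
  }
  labels
}

# small default codebook shared by tests
test_codebook <- function(n = 50L, seed = 1L)
  build_codebook(sprintf("OR%03d", seq_len(n)), n_bits = 15, on_bits = 4,
                 seed = seed)

# compact image config for fast decoding tests
small_image_config <- function(...)
  synthetic_config(image_shape = c(ny = 200L, nx = 200L, nz = 5L),
                   n_cells = 40L, n_receptors = 20L,
                   image_ring_range_um = c(15, 42), ...)
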