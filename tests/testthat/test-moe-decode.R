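# a tiny stack with controllable channels for correlation tests
tiny_stack <- function(arrs, pixel_um = c(x = 0.5, y = 0.5, z = 1)) {
  d <- dim(arrs[[1]])
  bits <- array(0, c(d, length(arrs)))
  for (b in seq_along(arrs)) bits[, , , b] <- arrs[[b]]
  structure(list(bits = bits, egr1 = array(0, d), nuclear = array(0, d),
                 pixel_um = pixel_um), class = "readout_stack")
}

test_that("cube correlations: affine copies give 1, independent noise stays near 0", {
  set.seed(1)
  d <- c(24, 24, 4)
  base <- array(rnorm(prod(d)), d)
  st <- tiny_stack(list(base, 3 * base + 7, array(rnorm(prod(d)), d),
                        array(rnorm(prod(d)), d)))
  cm <- cube_correlation_map(st, cube_um = 2.5, min_corr = -1)
  # pair (0,1) is an affine copy: correlation 1 in every cube
  p01 <- which(cm$pairs[, 1] == 0 & cm$pairs[, 2] == 1)
  expect_true(all(abs(cm$pair_corr[, p01] - 1) < 1e-8))
  # independent pairs: |r| < 3/sqrt(n) for at least 95% of cubes
  p23 <- which(cm$pairs[, 1] == 2 & cm$pairs[, 2] == 3)
  expect_gte(mean(abs(cm$pair_corr[, p23]) < 3 / sqrt(cm$n_vox)), 0.95)
})

test_that("constant channels are flagged undefined and treated as zero", {
  d <- c(8, 8, 4)
  st <- tiny_stack(list(array(5, d), array(rnorm(prod(d)), d),
                        array(rnorm(prod(d)), d), array(rnorm(prod(d)), d)))
  cm <- cube_correlation_map(st, cube_um = 2.5, min_corr = -1)
  expect_true(all(cm$undefined[, 1]))
  p01 <- which(cm$pairs[, 1] == 0)
  expect_true(all(cm$pair_corr[, p01] == 0))
})

test_that("a planted soma's on-bits win the exhaustive quadruple search", {
  cb <- test_codebook(20)
  cfg <- small_image_config(n_cells = 1L)
  sim <- simulate_moe_section(cfg, cb, seed = 11)
  cm <- cube_correlation_map(sim$stack)
  truth <- sim$truth$cells
  code <- sort(cb$entries[truth$receptor, ])
  # cubes covering the soma center
  cvx <- truth$x_um / cfg$pixel_um[["x"]]
  cvy <- truth$y_um / cfg$pixel_um[["y"]]
  cover <- cm$origin[, "x"] <= cvx & cm$origin[, "x"] + cm$size_px[2] > cvx &
    cm$origin[, "y"] <= cvy & cm$origin[, "y"] + cm$size_px[1] > cvy
  hit <- which(cover & !is.na(cm$best_score))
  expect_gt(length(hit), 0)
  best_keys <- apply(cm$best_quad[hit, , drop = FALSE], 1, paste, collapse = "-")
  expect_true(any(best_keys == paste(code, collapse = "-")))
  # cross-check one covered cube against a manual exhaustive quadruple scan
  i <- hit[which.max(cm$best_score[hit])]
  quads <- t(utils::combn(15, 4)) - 1L
  score_of <- function(q) {
    pr <- utils::combn(q, 2)
    cols <- vapply(seq_len(ncol(pr)), function(k)
      which(cm$pairs[, 1] == min(pr[, k]) & cm$pairs[, 2] == max(pr[, k])),
      integer(1))
    mean(cm$pair_corr[i, cols])
  }
  sc <- apply(quads, 1, score_of)
  expect_equal(sort(cm$best_quad[i, ]), sort(quads[which.max(sc), ]))
  expect_equal(cm$best_score[i], max(sc), tolerance = 1e-10)
})

test_that("candidate extraction respects the strict threshold", {
  set.seed(2)
  d <- c(24, 24, 4)
  noise <- replicate(15, array(rnorm(prod(d), 2, 1), d), simplify = FALSE)
  st <- tiny_stack(noise)
  cm <- cube_correlation_map(st, min_corr = -1)
  expect_equal(nrow(extract_candidate_voxels(cm, 0.6)), 0)
  expect_equal(nrow(extract_candidate_voxels(cm, 1.0)), 0)

  cb <- test_codebook(20)
  sim <- simulate_moe_section(small_image_config(n_cells = 10L), cb, seed = 3)
  cand <- extract_candidate_voxels(cube_correlation_map(sim$stack), 0.6)
  # candidate mask covers at least 80% of each soma's voxels
  d2 <- dim(sim$stack$bits)[1:3]
  cand_lin <- cand$y + (cand$x - 1L) * d2[1] + (cand$z - 1L) * d2[1] * d2[2]
  cover <- vapply(sim$truth$cell_voxels, function(v)
    mean(v %in% cand_lin), numeric(1))
  expect_true(all(cover >= 0.8))
})

test_that("density clustering matches an independent graph-components oracle", {
  set.seed(4)
  # two blobs separated by > 2x radius -> 2 clusters; one blob -> 1
  b1 <- matrix(rnorm(60, 0, 0.5), ncol = 3)
  b2 <- sweep(matrix(rnorm(60, 0, 0.5), ncol = 3), 2, c(10, 0, 0), "+")
  expect_equal(length(unique(dbscan_cluster(rbind(b1, b2), 1.5, 5))), 2)
  expect_equal(unique(dbscan_cluster(b1, 1.5, 5)), 1L)

  for (rep in 1:5) {
    n_blob <- sample(2:4, 1)
    pts <- do.call(rbind, lapply(seq_len(n_blob), function(i)
      sweep(matrix(rnorm(40 * 3, 0, 0.6), ncol = 3), 2,
            runif(3, 0, 20), "+")))
    lab <- dbscan_cluster(pts, 1.2, 8)
    ref <- oracle_dbscan(pts, 1.2, 8)
    # same partition up to label permutation, same noise set
    expect_equal(lab == 0, ref == 0)
    keep <- lab != 0
    tab <- table(lab[keep], ref[keep])
    expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
  }
})

test_that("identity assignment is exact codebook lookup", {
  cb <- build_codebook(c("hit"), n_bits = 15, on_bits = 4, seed = 1)
  cb$entries[1, ] <- 0:3
  st <- tiny_stack(replicate(15, array(1, c(4, 4, 2)), simplify = FALSE))
  cl <- list(quad = 0:3, quad_key = "0-1-2-3",
             voxels = data.frame(y = 1:3, x = 1:3, z = 1L, score = 0.9))
  rec <- assign_cell_identity(cl, cb, st)
  expect_identical(rec$receptor, "hit")
  cl$quad <- c(0, 1, 2, 4); cl$quad_key <- "0-1-2-4"
  expect_true(is.na(assign_cell_identity(cl, cb, st)$receptor))
})

test_that("Egr1 spot counting recovers planted counts", {
  d <- c(20, 20, 4)
  egr <- array(0, d)
  vox <- expand.grid(y = 5:15, x = 5:15, z = 2:3)
  expect_identical(count_egr1(vox, egr, threshold = 1), 0L)
  # 3 well-separated planted spots
  spots <- rbind(c(6, 6, 2), c(12, 6, 3), c(9, 13, 2))
  for (k in 1:3) egr[spots[k, 1], spots[k, 2], spots[k, 3]] <- 10
  expect_identical(count_egr1(vox, egr, threshold = 1), 3L)
})

test_that("decoding on a synthetic section is accurate and codebook-closed", {
  cb <- test_codebook(20)
  sim <- simulate_moe_section(small_image_config(), cb, seed = 21)
  cells <- decode_moe_section(sim$stack, cb)
  # no assignment outside the codebook; quadruple lookup equals hash oracle
  keys <- apply(cb$entries, 1, function(b) paste(sort(b), collapse = "-"))
  lookup <- stats::setNames(rownames(cb$entries), keys)
  expect_identical(cells$receptor, unname(lookup[cells$quad_key]))
  sc <- score_decoding(cells, sim$truth$cells)
  expect_gte(sc$recall, 0.9)
  expect_gte(sc$precision, 0.95)
  # per-cell Egr1 counts within +-1 of planted for >= 95% of matched cells
  asn <- cells[!is.na(cells$receptor), ]
  diffs <- abs(asn$egr1[sc$matches$cell] -
                 sim$truth$cells$egr1_true[sc$matches$truth])
  expect_gte(mean(diffs <= 1), 0.95)
})

test_that("decoding is invariant to bit relabeling with a matching codebook permutation", {
  cb <- test_codebook(20)
  sim <- simulate_moe_section(small_image_config(n_cells = 15L), cb, seed = 31)
  cells <- decode_moe_section(sim$stack, cb)
  perm <- rev(seq_len(15))  # channel b -> position perm[b]
  st2 <- sim$stack
  st2$bits <- st2$bits[, , , perm]
  cb2 <- cb
  cb2$entries <- matrix(match(cb$entries + 1L, perm) - 1L,
                        nrow = nrow(cb$entries),
                        dimnames = dimnames(cb$entries))
  cb2$entries <- t(apply(cb2$entries, 1, sort))
  cells2 <- decode_moe_section(st2, cb2)
  ord1 <- order(cells$x_um, cells$y_um)
  ord2 <- order(cells2$x_um, cells2$y_um)
  expect_identical(cells$receptor[ord1], cells2$receptor[ord2])
  expect_equal(cells$x_um[ord1], cells2$x_um[ord2])
})
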