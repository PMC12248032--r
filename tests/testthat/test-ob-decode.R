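test_that("spot detection finds planted 3D maxima with subvoxel accuracy", {
  px <- c(x = 0.1, y = 0.1, z = 0.1)
  blank <- array(0, c(30, 30, 10))
  expect_equal(nrow(detect_spots(blank, 1, px)), 0)

  # one planted Gaussian spot
  img <- blank
  ctr <- c(y = 14.2, x = 17.6, z = 5.3)
  for (y in 1:30) for (x in 1:30) for (z in 1:10)
    img[y, x, z] <- exp(-((y - ctr[1])^2 + (x - ctr[2])^2 + (z - ctr[3])^2) / 3)
  sp <- detect_spots(img, 0.5, px)
  expect_equal(nrow(sp), 1)
  expect_lt(abs(sp$x_um / px[["x"]] + 0.5 - ctr[["x"]]), 1)
  expect_lt(abs(sp$y_um / px[["y"]] + 0.5 - ctr[["y"]]), 1)

  # 100 planted spots with >= 5 voxel spacing: all recovered, RMS < 0.5 vox
  set.seed(5)
  big <- array(0, c(120, 120, 12))
  pos <- NULL
  while (is.null(pos) || nrow(pos) < 100) {
    cand <- c(runif(1, 4, 117), runif(1, 4, 117), runif(1, 3, 10))
    if (is.null(pos) ||
        min(sqrt(rowSums(sweep(pos, 2, cand)^2))) >= 5)
      pos <- rbind(pos, cand)
  }
  for (k in seq_len(100)) {
    yy <- max(1, floor(pos[k, 1] - 2)):min(120, ceiling(pos[k, 1] + 2))
    xx <- max(1, floor(pos[k, 2] - 2)):min(120, ceiling(pos[k, 2] + 2))
    zz <- max(1, floor(pos[k, 3] - 2)):min(12, ceiling(pos[k, 3] + 2))
    for (y in yy) for (x in xx) for (z in zz)
      big[y, x, z] <- big[y, x, z] +
        exp(-((y - pos[k, 1])^2 + (x - pos[k, 2])^2 + (z - pos[k, 3])^2) / 1.2)
  }
  det <- detect_spots(big, 0.3, px)
  expect_equal(nrow(det), 100)
  dv <- cbind(det$y_um / px[["y"]] + 0.5, det$x_um / px[["x"]] + 0.5,
              det$z_um / px[["z"]] + 0.5)
  err <- vapply(seq_len(100), function(k)
    min(sqrt(rowSums(sweep(dv, 2, pos[k, ])^2))), numeric(1))
  expect_lt(sqrt(mean(err^2)), 0.5)
})

test_that("colocalization follows the 4-of-15 box rule with brightest-4 selection", {
  base <- data.frame(bit = 0:3, x_um = 1, y_um = 1, z_um = 1,
                     brightness = c(5, 4, 3, 2))
  m4 <- colocalize(base, radius_um = 0.16)
  expect_equal(nrow(m4), 1)
  expect_identical(m4$bits, "0-1-2-3")

  expect_equal(nrow(colocalize(base[1:3, ], radius_um = 0.16)), 0)

  five <- rbind(base, data.frame(bit = 9, x_um = 1, y_um = 1, z_um = 1,
                                 brightness = 10))
  m5 <- colocalize(five, radius_um = 0.16)
  expect_equal(nrow(m5), 1)
  expect_identical(m5$bits, "0-1-2-9")  # brightest 4 of the 5
})

test_that("colocalization equals the brute-force oracle and is order-invariant", {
  set.seed(6)
  for (rep in 1:8) {
    n <- sample(c(50, 150, 300), 1)
    sp <- data.frame(bit = sample(0:14, n, replace = TRUE),
                     x_um = runif(n, 0, 3), y_um = runif(n, 0, 3),
                     z_um = runif(n, 0, 1), brightness = rlnorm(n))
    got <- colocalize(sp, radius_um = 0.16)
    ref <- oracle_colocalize(sp, 0.16)
    expect_equal(unname(lapply(got$member_rows, as.integer)), ref)
    # permutation invariance of the molecule set
    perm <- sample(n)
    sp2 <- sp[perm, ]
    got2 <- colocalize(sp2, radius_um = 0.16)
    sets1 <- sort(vapply(got$member_rows, function(m)
      paste(sort(m), collapse = ","), character(1)))
    sets2 <- sort(vapply(got2$member_rows, function(m)
      paste(sort(perm[m]), collapse = ","), character(1)))
    expect_identical(sets1, sets2)
  }
})

test_that("brightness threshold separates the two molecule populations", {
  set.seed(7)
  mols <- data.frame(
    brightness = c(rnorm(2000, 10, 1), rnorm(2000, 2, 1)),
    receptor = c(rep("t", 2000), rep("u", 2000)))
  ft <- fit_brightness_threshold(mols, targeted = "t")
  expect_gt(ft$threshold, 2)
  expect_lt(ft$threshold, 10)
  expect_gt(ft$accuracy, 0.99)
  expect_true(all(ft$molecules$brightness >= ft$threshold))

  # indistinguishable populations: warning-free near-chance separation is
  # allowed, but degenerate populations must warn and leave data intact
  same <- data.frame(brightness = rnorm(500, 5, 1),
                     receptor = rep("t", 500))
  expect_warning(res <- fit_brightness_threshold(same, targeted = "t"))
  expect_identical(res$molecules, same)
  expect_true(is.na(res$threshold))
})

test_that("the strict assignment rule applies exact boundaries", {
  mk <- function(...) {
    df <- data.frame(...)
    df
  }
  # {A:12}, other glomeruli <= 1 -> strict
  ct <- mk(glom_id = c(1, 2), section = 1, receptor = "A", count = c(12, 1))
  asn <- assign_glomerulus_identity(ct)
  expect_identical(asn$assigned[asn$glom_id == 1], "A")
  expect_identical(asn$tier[asn$glom_id == 1], "strict")
  # two glomeruli both A:12 in one section -> neither assigned
  ct2 <- mk(glom_id = c(1, 2), section = 1, receptor = "A", count = c(12, 12))
  expect_true(all(is.na(assign_glomerulus_identity(ct2)$assigned)))
  # exactly 10 -> not assigned (strict inequality)
  ct3 <- mk(glom_id = 1, section = 1, receptor = "A", count = 10)
  expect_true(is.na(assign_glomerulus_identity(ct3)$assigned))
  ct4 <- mk(glom_id = 1, section = 1, receptor = "A", count = 11)
  expect_identical(assign_glomerulus_identity(ct4)$assigned, "A")
})

test_that("assignment matches the rule oracle on randomized tables", {
  set.seed(8)
  for (rep in 1:20) {
    n_glom <- sample(3:8, 1)
    rows <- do.call(rbind, lapply(seq_len(n_glom), function(g)
      data.frame(glom_id = g, section = sample(1:2, 1),
                 receptor = sample(LETTERS[1:5], sample(1:4, 1)),
                 stringsAsFactors = FALSE)))
    rows$count <- sample(c(0:15, 10, 5), nrow(rows), replace = TRUE)
    got <- assign_glomerulus_identity(rows)
    ref <- oracle_glom_rule(rows)
    key <- paste(got$section, got$glom_id)
    refkey <- paste(ref$section, ref$glom_id)
    expect_identical(got$assigned[order(key)], ref$assigned[order(refkey)])
  }
})

test_that("assignment is monotone in the dominant count", {
  set.seed(9)
  base <- data.frame(glom_id = c(1, 1, 2), section = 1,
                     receptor = c("A", "B", "A"), count = c(8, 3, 0))
  was_assigned <- FALSE
  for (cnt in 5:40) {
    b <- base; b$count[1] <- cnt
    now <- !is.na(assign_glomerulus_identity(b)$assigned[1])
    expect_false(was_assigned && !now)
    was_assigned <- now
  }
  expect_true(was_assigned)
})

test_that("relaxed consensus recovers co-located sub-threshold glomeruli", {
  mk_bulb <- function(count, x, receptor = "A", tier = "none") {
    data.frame(glom_id = 1, receptor = receptor, count = count,
               assigned = if (tier == "strict") receptor else NA_character_,
               tier = tier, x_um = x, y_um = 0, z_um = 0,
               stringsAsFactors = FALSE)
  }
  # counts 7 and 6 at 300 um, same receptor -> both relaxed
  res <- relaxed_consensus(list(mk_bulb(7, 0), mk_bulb(6, 300)))
  expect_identical(res$glomeruli$tier, c("relaxed", "relaxed"))
  expect_identical(res$consensus$receptor, "A")
  expect_equal(res$consensus$x_um, 150)
  # no counterpart within 500 um -> unassigned
  res2 <- relaxed_consensus(list(mk_bulb(7, 0), mk_bulb(6, 800)))
  expect_true(all(res2$glomeruli$tier == "none"))
  # count 5 is never assigned (strictly more than 5 required)
  res3 <- relaxed_consensus(list(mk_bulb(5, 0), mk_bulb(7, 100)))
  expect_identical(res3$glomeruli$tier[1], "none")
  # fewer than 2 bulbs: warning, strict-only
  expect_warning(res4 <- relaxed_consensus(list(mk_bulb(7, 0))))
  expect_null(res4$consensus)
})

test_that("planted bulbs: strict tier at high counts, relaxed recovers (5, 10]", {
  cb <- test_codebook(60)
  cfg <- synthetic_config(glom_dominant_count = 8L, glom_background_rate = 0,
                          ob_n_receptors = 12L)
  decode_bulb <- function(seed) {
    ob <- simulate_ob_series(cfg, cb, seed = seed)
    sp <- ob$spots
    mol <- identify_molecules(
      colocalize(sp[, c("bit", "x_um", "y_um", "z_um", "brightness")]), cb)
    mol$section <- sp$section[vapply(mol$member_rows, `[`, 1L, 1)]
    ct <- glomerulus_count_table(mol, ob$masks, ob$mask_pixel_um)
    cen <- glomerulus_centroids(ob$masks, ob$mask_pixel_um,
                                midline_um = cfg$ob_midline_um)
    ct$section <- paste(ct$section, cen$hemisphere[match(ct$glom_id,
                                                         cen$glom_id)])
    asn <- assign_glomerulus_identity(ct)
    tr <- ob$glomeruli
    asn$x_um <- tr$x_um[match(asn$glom_id, tr$glom_id)]
    asn$y_um <- tr$y_um[match(asn$glom_id, tr$glom_id)]
    asn$z_um <- tr$z_um[match(asn$glom_id, tr$glom_id)]
    list(asn = asn, truth = tr)
  }
  b1 <- decode_bulb(41)
  # second bulb: same true map observed with 100 um cross-bulb jitter
  b2 <- b1
  set.seed(42)
  b2$asn[, c("x_um", "y_um", "z_um")] <-
    b2$asn[, c("x_um", "y_um", "z_um")] + rnorm(3 * nrow(b2$asn), 0, 100)
  # dominant count 8 (in (5, 10]): strict assignment must be empty
  expect_true(all(is.na(b1$asn$assigned)))
  res <- relaxed_consensus(list(b1$asn, b2$asn), relaxed_min = 5,
                           consensus_radius_um = 500)
  rel <- res$glomeruli[res$glomeruli$tier == "relaxed", ]
  expect_gt(nrow(rel), 0)
  # every relaxed assignment matches the planted identity
  truth_rec <- b1$truth$receptor[match(rel$glom_id, b1$truth$glom_id)]
  expect_identical(rel$assigned, truth_rec)
})
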