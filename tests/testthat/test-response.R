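test_that("responding fractions apply the strict Egr1 threshold", {
  cells <- data.frame(receptor = "A", condition = "cue", animal = 1,
                      egr1 = c(6, 7, 0))
  cat_ <- response_fractions(cells, min_cells = 1)
  expect_equal(cat_$fraction, 2 / 3)
  # a count of exactly 5 is inactive
  cells5 <- data.frame(receptor = "A", condition = "cue", animal = 1,
                       egr1 = c(5, 5, 5, 6))
  expect_equal(response_fractions(cells5, min_cells = 1)$fraction, 1 / 4)
  # support floor: below min_cells the fraction is undefined
  expect_true(is.na(response_fractions(cells, min_cells = 10)$fraction))
})

test_that("catalog values are invariant to row order and animal relabeling", {
  fr <- simulate_response_truth(sprintf("OR%02d", 1:10), "cue", seed = 31)
  cells <- simulate_egr1_cells(fr, cells_per_receptor = 30, n_animals = 2,
                               seed = 32)
  c1 <- response_fractions(cells)
  c2 <- response_fractions(cells[sample(nrow(cells)), ])
  expect_equal(c1$fraction, c2$fraction)
  cells3 <- cells
  cells3$animal <- 3 - cells3$animal
  c3 <- response_fractions(cells3)
  expect_equal(c1$fraction, c3$fraction)
})

test_that("classification thresholds are strict and match a one-line oracle", {
  cat_ <- data.frame(receptor = letters[1:5], condition = "c",
                     fraction = c(0.6, 0.10, 0.101, 0.5, NA),
                     n_cells = 50, n_animals = 2)
  cl <- classify_responses(cat_)
  expect_identical(cl$class, c("strong", "none", "partial", "partial", NA))
  # oracle on a simulated catalog
  fr <- simulate_response_truth(sprintf("OR%02d", 1:30),
                                c("a", "b"), seed = 33)
  cells <- simulate_egr1_cells(fr, 60, 2, seed = 34)
  cl2 <- classify_responses(response_fractions(cells))
  oracle <- ifelse(cl2$fraction > 0.5, "strong",
                   ifelse(cl2$fraction > 0.1, "partial", "none"))
  expect_identical(cl2$class, oracle)
})

test_that("cue comparison recovers planted sharing structure exactly", {
  cat_ <- data.frame(
    receptor = rep(sprintf("r%02d", 1:20), 2),
    condition = rep(c("male", "female"), each = 20),
    fraction = c(c(rep(0.3, 10), rep(0.02, 10)),     # male: r01-r10
                 c(rep(0.3, 6), rep(0.02, 14))),     # female: r01-r06
    n_cells = 50, n_animals = 2)
  cc <- compare_cues(cat_)
  expect_setequal(cc$sets$male, sprintf("r%02d", 1:10))
  expect_setequal(cc$sets$female, sprintf("r%02d", 1:6))
  expect_equal(cc$shared["male", "female"], 6 / 10)
  expect_equal(cc$shared["female", "male"], 1)
  jc <- compare_cues(cat_, method = "jaccard")
  expect_equal(jc$shared["male", "female"], 6 / 10)
  # identical catalogs share everything
  half <- cat_[cat_$condition == "male", ]
  cat_b <- rbind(transform(half, condition = "x"),
                 transform(half, condition = "y"))
  sh <- compare_cues(cat_b)$shared
  expect_true(all(sh[!is.na(sh)] == 1))
  # male-selective rule
  sel <- selective_set(cat_, "male", "female")
  expect_setequal(sel, sprintf("r%02d", 7:10))
})

test_that("concentration shifts are flagged against the replicate band", {
  set.seed(35)
  n <- 100
  recs <- sprintf("r%03d", 1:n)
  base <- runif(n, 0, 0.4)
  reps <- data.frame(receptor = recs,
                     f1 = pmin(pmax(base + rnorm(n, 0, 0.05), 0), 1),
                     f2 = pmin(pmax(base + rnorm(n, 0, 0.05), 0), 1))
  mkcat <- function(f) data.frame(receptor = recs, condition = "c",
                                  fraction = f, n_cells = 100, n_animals = 2)
  # identical catalogs: nothing flagged
  same <- concentration_shift(mkcat(base), mkcat(base), reps)
  expect_equal(sum(same$flagged), 0)
  # planted shift of 0.4 on 20 receptors over replicate noise 0.05
  shift <- rep(0, n); shift[1:20] <- 0.4
  high <- pmin(base + shift + rnorm(n, 0, 0.05), 1)
  low <- pmin(pmax(base + rnorm(n, 0, 0.05), 0), 1)
  cs <- concentration_shift(mkcat(high), mkcat(low), reps)
  expect_gte(sum(cs$flagged[1:20]), 19)
  expect_lte(mean(cs$flagged[21:n]), 0.10)
  # monotone in (high - low) at fixed mean: within a band bin, every flagged
  # difference exceeds every unflagged one
  band <- attr(cs, "band_table")
  bin_of <- cut(cs$mean, c(band$lo[1], band$hi), labels = FALSE,
                include.lowest = TRUE)
  for (b in unique(bin_of)) {
    fl <- cs$diff[bin_of == b & cs$flagged]
    un <- cs$diff[bin_of == b & !cs$flagged]
    if (length(fl) && length(un)) expect_gt(min(fl), max(un))
  }
  expect_equal(nrow(band), 5)
  # no replicates: error
  expect_error(concentration_shift(mkcat(high), mkcat(low),
                                   reps[0, ]),
               class = "orfish_input_error")
})

test_that("mother-selective rule applies the floor and fold thresholds", {
  mk <- function(f) data.frame(receptor = c("a", "b", "c"), condition = "pup",
                               fraction = f, n_cells = 50, n_animals = 2)
  mother <- mk(c(0.2, 0.04, 0.10))
  virgin <- mk(c(0.05, 0.0, 0.06))
  sel <- mother_selective_types(mother, virgin)
  expect_identical(sel, "a")  # b fails the floor, c fails the 2x fold
})

test_that("differential genes reach planted power with a calibrated null", {
  set.seed(36)
  n_cells <- 400
  types <- sample(sprintf("T%02d", 1:20), n_cells, TRUE)
  sel_types <- sprintf("T%02d", 1:4)
  n_genes <- 60
  expr <- matrix(rpois(n_cells * n_genes, 5), n_cells, n_genes,
                 dimnames = list(NULL, sprintf("g%02d", 1:n_genes)))
  up <- 1:10  # planted 2x upshift in the selected types
  expr[types %in% sel_types, up] <-
    rpois(sum(types %in% sel_types) * 10, 10)
  dg <- differential_genes(expr, types, sel_types)
  expect_gt(mean(dg$significant[up]), 0.9)
  expect_lt(mean(dg$significant[-up]), 0.05)
  # null calibration: no signal, flag rate near the nominal 1%
  expr0 <- matrix(rpois(n_cells * n_genes, 5), n_cells, n_genes,
                  dimnames = dimnames(expr))
  dg0 <- differential_genes(expr0, types, sel_types)
  expect_lt(mean(dg0$p < 0.01, na.rm = TRUE), 0.05)
  # Y-marker expressing cells are excluded by the sex filter
  expr_y <- cbind(expr0, Ddx3y = 0L)
  expr_y[1:50, "Ddx3y"] <- 3L
  dg_y <- differential_genes(expr_y, types, sel_types, sex_filter = TRUE,
                             y_genes = "Ddx3y")
  expect_equal(sum(attr(dg_y, "n_cells")), n_cells - 50)
})

test_that("responses map onto the atlases with unit-area densities", {
  cat_ <- data.frame(receptor = c("a", "b"), condition = "cue",
                     fraction = c(0.4, 0.02), n_cells = 50, n_animals = 2)
  idx <- data.frame(receptor = c("a", "b"), cp_index = c(0.2, 0.8))
  map <- data.frame(receptor = c("a", "b"), y_um = c(110, 700),
                    z_um = c(50, 300))
  res <- map_responses_to_atlas(cat_, idx, map, axis_bin_um = 200)
  # single responding receptor with one glomerulus: one occupied DV bin
  expect_equal(nrow(res$density_dv), 1)
  expect_equal(res$density_dv$bin_center_um, 100)
  expect_equal(sum(res$density_dv$density) * 200, 1)
  # planted ventral-band responders put the density mode in the ventral third
  set.seed(37)
  n <- 60
  recs <- sprintf("r%02d", 1:n)
  frac <- rep(0.02, n); frac[41:60] <- 0.5  # responders
  cat2 <- data.frame(receptor = recs, condition = "cue", fraction = frac,
                     n_cells = 50, n_animals = 2)
  y <- c(runif(40, 0, 900), runif(20, 700, 900))  # responders ventral
  map2 <- data.frame(receptor = recs, y_um = y, z_um = runif(n, 0, 900))
  res2 <- map_responses_to_atlas(cat2, data.frame(receptor = recs,
                                                  cp_index = runif(n)),
                                 map2, axis_bin_um = 200)
  mode_bin <- res2$density_dv$bin_center_um[which.max(res2$density_dv$density)]
  expect_gte(mode_bin, 600)
})
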