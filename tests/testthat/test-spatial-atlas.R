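test_that("repertoire summaries count and normalize as defined", {
  cells <- data.frame(receptor = c("A", "A", "A", "B"), section = 1,
                      animal = 1, x_um = 0, y_um = 0,
                      brightness = c(2, 2, 2, 2))
  s <- summarize_repertoire(cells)
  expect_equal(s$cells_per_section[s$receptor == "A"], 3)
  # equal brightness: normalized brightness is exactly 1 for every receptor
  expect_equal(s$norm_brightness, c(1, 1))

  # planted multinomial proportions recovered within a binomial CI
  set.seed(20)
  probs <- c(A = 0.5, B = 0.3, C = 0.2)
  n <- 2000
  cells2 <- data.frame(
    receptor = sample(names(probs), n, TRUE, probs),
    section = sample(1:4, n, TRUE), animal = 1, x_um = 0, y_um = 0)
  s2 <- summarize_repertoire(cells2)
  prop <- s2$cells_per_section / sum(s2$cells_per_section)
  for (r in names(probs))
    expect_lt(abs(prop[s2$receptor == r] - probs[r]),
              3 * sqrt(probs[r] * (1 - probs[r]) / n))
})

test_that("overlap matrix matches definitions and the exhaustive oracle", {
  cells <- data.frame(receptor = c("A", "B"), section = 1,
                      x_um = c(0, 100), y_um = 0)
  ov <- overlap_matrix(cells, cutoff_um = 200)$overlap
  expect_equal(ov["A", "B"], 1)
  cells2 <- data.frame(receptor = c("A", "B"), section = 1,
                       x_um = c(0, 300), y_um = 0)
  expect_equal(overlap_matrix(cells2, 200)$overlap["A", "B"], 0)

  set.seed(21)
  rc <- data.frame(
    receptor = rep(c("A", "B", "C"), each = 50),
    section = sample(1:2, 150, TRUE),
    x_um = runif(150, 0, 600), y_um = runif(150, 0, 600))
  got <- overlap_matrix(rc, cutoff_um = 150)$overlap
  ref <- oracle_overlap(rc, 150)
  expect_equal(got, ref[rownames(got), colnames(got)], tolerance = 1e-12)
  expect_identical(got, t(got))
})

test_that("cp index recovers planted ring order and flags the detached zone", {
  cfg <- synthetic_config(atlas_n_receptors = 30L, atlas_cells_per_type = 30L,
                          atlas_n_sections = 2L)
  cells <- simulate_moe_cells(cfg, seed = 22)
  truth <- attr(cells, "receptor_truth")
  om <- overlap_matrix(cells, cutoff_um = 200)
  cp <- central_peripheral_index(
    om, orient_by = stats::setNames(truth$ring_radius_um, truth$receptor))
  ix <- merge(cp$index, truth, by = "receptor")
  expect_setequal(ix$receptor[ix$unusual_zone],
                  truth$receptor[truth$is_unusual])
  keep <- !ix$unusual_zone
  expect_gt(stats::cor(ix$cp_index[keep], ix$cp_true[keep],
                       method = "spearman"), 0.95)
  # endpoints are exactly 0 and 1
  expect_equal(min(ix$cp_index[keep]), 0)
  expect_equal(max(ix$cp_index[keep]), 1)
  # deterministic across seeds (interface stability)
  cp2 <- central_peripheral_index(
    om, seed = 99,
    orient_by = stats::setNames(truth$ring_radius_um, truth$receptor))
  expect_identical(cp$index, cp2$index)
  # degenerate matrix errors
  flat <- matrix(0.5, 12, 12, dimnames = list(letters[1:12], letters[1:12]))
  diag(flat) <- 1
  expect_error(central_peripheral_index(flat),
               class = "orfish_degenerate_error")
})

test_that("basal-apical depth is the normalized distance between surfaces", {
  geom <- slab_geometry(0, 60)
  cells <- data.frame(receptor = rep("A", 6), z_um = c(30, 0, 60, 15, 45, 30))
  ba <- basal_apical_index(cells, geom, min_support = 1)
  expect_equal(ba$ba_index, mean(c(0.5, 0, 1, 0.25, 0.75, 0.5)))
  # single cells at the surfaces
  one <- function(z) basal_apical_index(
    data.frame(receptor = "A", z_um = z), geom, min_support = 1)$ba_index
  expect_equal(one(30), 0.5)
  expect_equal(one(0), 0)
  # outside the ribbon: excluded with count
  out <- basal_apical_index(
    data.frame(receptor = rep("A", 3), z_um = c(30, -5, 70)), geom,
    min_support = 1)
  expect_equal(attr(out, "n_excluded"), 2)

  # planted per-receptor depth offsets recovered at 50 cells per receptor
  cfg <- synthetic_config(atlas_cells_per_type = 50L, atlas_n_sections = 1L)
  cells2 <- simulate_moe_cells(cfg, seed = 23)
  truth <- attr(cells2, "receptor_truth")
  ba2 <- basal_apical_index(cells2, slab_geometry(0, cfg$atlas_thickness_um))
  m <- merge(ba2, truth, by = "receptor")
  expect_gt(stats::cor(m$ba_index, m$ba_offset), 0.95)
})

test_that("bulb axis coordinates bin and track as specified", {
  map <- data.frame(receptor = "A", side = "medial", hemisphere = "left",
                    x_um = 0, y_um = 300, z_um = 120)
  co <- ob_axis_coordinates(map, dv_bin_um = 150)$coordinates
  expect_equal(co$dv_um, 225)  # y = 300 falls in the bin centered at 225
  expect_equal(co$ap_um, 120)
  # constant positions give a constant sliding track
  map2 <- do.call(rbind, lapply(sprintf("r%02d", 1:10), function(r)
    data.frame(receptor = r, side = "medial", hemisphere = "left",
               x_um = 5, y_um = 40, z_um = 7)))
  cp <- stats::setNames(seq(0, 1, length.out = 10), sprintf("r%02d", 1:10))
  tr <- ob_axis_coordinates(map2, window = 4, cp = cp)$tracks$medial
  expect_true(all(tr$x_um == 5 & tr$y_um == 40 & tr$z_um == 7))
})

test_that("genomic clustering and the enhancer test behave as planted", {
  md <- data.frame(receptor = c("a", "b", "c"), chrom = "chr1",
                   start = c(0, 50e3, 500e3), end = c(1e3, 51e3, 501e3))
  res <- genomic_cluster_analysis(md)
  expect_equal(res$clusters$cluster, c(1, 1, 2))

  # planted enhancer-boosted abundances: p < 0.01 at 100 receptors
  set.seed(24)
  n <- 100
  md2 <- data.frame(receptor = sprintf("r%03d", 1:n), chrom = "chr1",
                    start = seq(0, by = 2e5, length.out = n))
  md2$end <- md2$start + 1e3
  enh <- data.frame(chrom = "chr1", pos = md2$start[1:30] + 30e3)
  ab <- rlnorm(n, 0, 0.4)
  ab[1:30] <- ab[1:30] * 2
  names(ab) <- md2$receptor
  res2 <- genomic_cluster_analysis(md2, abundance = ab, enhancers = enh)
  expect_lt(res2$enhancer_test$p.value, 0.01)
  expect_equal(res2$n_near_enhancer, 30)

  # shuffled enhancers: null p-values not systematically small
  ps <- replicate(20, {
    ab0 <- rlnorm(n, 0, 0.4); names(ab0) <- md2$receptor
    enh0 <- data.frame(chrom = "chr1",
                       pos = sample(md2$start, 30) + 30e3)
    genomic_cluster_analysis(md2, ab0, enhancers = enh0)$enhancer_test$p.value
  })
  expect_lt(mean(ps < 0.05), 0.3)
  # no enhancers: test skipped with a notice
  expect_message(res3 <- genomic_cluster_analysis(md2, ab))
  expect_null(res3$enhancer_test)
})

test_that("phylogenetic association matches graph-path patristic distances", {
  set.seed(25)
  tree <- ape::rtree(24, tip.label = sprintf("t%02d", 1:24))
  pd <- ape::cophenetic.phylo(tree)
  # independent oracle: shortest paths on the tree's edge graph
  nt <- length(tree$tip.label)
  g <- igraph::graph_from_edgelist(cbind(tree$edge[, 1], tree$edge[, 2]),
                                   directed = FALSE)
  igraph::E(g)$weight <- tree$edge.length
  ref <- igraph::distances(g)[seq_len(nt), seq_len(nt)]
  dimnames(ref) <- list(tree$tip.label, tree$tip.label)
  expect_equal(pd[rownames(ref), colnames(ref)], ref, tolerance = 1e-10)

  # two-clade tree: one clade is phylogenetically compact
  cl_a <- paste0("a", 1:10, ":1", collapse = ",")
  cl_b <- paste0("b", 1:10, ":1", collapse = ",")
  t2 <- ape::read.tree(text = sprintf("((%s):10,(%s):10);", cl_a, cl_b))
  res <- phylo_association(t2, receptor_set = paste0("a", 1:10),
                           n_perm = 1000, seed = 1)
  expect_lt(res$set_test$p_perm, 0.01)
  expect_lt(res$set_test$p_ranksum, 0.01)

  # star tree: all pairwise distances equal, p near 1
  star <- ape::read.tree(text = "(a:1,b:1,c:1,d:1,e:1,f:1);")
  res2 <- suppressWarnings(
    phylo_association(star, receptor_set = c("a", "b", "c"),
                      n_perm = 200, seed = 1))
  expect_gt(res2$set_test$p_perm, 0.5)
  # missing tips are dropped and counted
  res3 <- phylo_association(t2, receptor_set = c("a1", "a2", "zz"),
                            n_perm = 100, seed = 1)
  expect_identical(res3$dropped, "zz")
})
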