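#' Simulate an OSN-type by gene expression matrix
#'
#' Emulates type-averaged single-cell RNA-seq expression: a stated fraction
#' of genes carry a planted spatial gradient, their type mean being a
#' monotone (linear, random sign and slope) function of the type's planted
#' coordinate (central-peripheral or basal-apical); the remaining genes are
#' exchangeable across types. Gaussian noise is added on top of the means,
#' and an optional per-cell mode draws `cells_per_type` Poisson-distributed
#' cells per type around the type mean.
#'
#' @param n_types Number of OSN types (receptors).
#' @param n_genes Number of genes.
#' @param gradient_fraction Fraction of genes with a planted gradient.
#' @param noise_sd Sd of noise added to type means.
#' @param coordinate Optional per-type coordinate in `[0, 1]` (default
#'   uniform draws).
#' @param per_cell If `TRUE`, also return per-cell counts.
#' @param cells_per_type Cells per type in per-cell mode.
#' @param seed Integer seed.
#' @return A list with `type_means` (types x genes matrix), `genes`
#'   (data.frame: gene, is_gradient, slope, intercept), `coordinate`
#'   (named per-type), and in per-cell mode `cells` (cells x genes counts)
#'   with `cell_types`.
#' @export
simulate_scrnaseq <- function(n_types = 50L, n_genes = 100L,
                              gradient_fraction = 0.3, noise_sd = 0.1,
                              coordinate = NULL, per_cell = FALSE,
                              cells_per_type = 20L, seed = 1) {
  if (gradient_fraction < 0 || gradient_fraction > 1)
    stop_orfish("gradient_fraction must be in [0, 1]",
                class = "orfish_config_error")
  with_seed(seed, {
    types <- sprintf("OR%03d", seq_len(n_types))
    genes <- sprintf("gene%03d", seq_len(n_genes))
    coord <- coordinate %||% stats::runif(n_types)
    names(coord) <- types
    n_grad <- round(gradient_fraction * n_genes)
    is_grad <- c(rep(TRUE, n_grad), rep(FALSE, n_genes - n_grad))
    slope <- ifelse(is_grad,
                    sample(c(-1, 1), n_genes, replace = TRUE) *
                      stats::runif(n_genes, 2, 4), 0)
    intercept <- stats::runif(n_genes, 1, 3) + pmax(-slope, 0)
    mu <- outer(coord, slope) + matrix(intercept, n_types, n_genes,
                                       byrow = TRUE)
    expr <- mu + matrix(stats::rnorm(n_types * n_genes, 0, noise_sd),
                        n_types, n_genes)
    expr[expr < 0] <- 0
    dimnames(expr) <- list(types, genes)
    out <- list(type_means = expr,
                genes = data.frame(gene = genes, is_gradient = is_grad,
                                   slope = slope, intercept = intercept,
                                   stringsAsFactors = FALSE),
                coordinate = coord)
    if (per_cell) {
      cell_types <- rep(types, each = cells_per_type)
      lam <- expr[cell_types, , drop = FALSE]
      counts <- matrix(stats::rpois(length(lam), lam), nrow = nrow(lam),
                       dimnames = list(NULL, genes))
      out$cells <- counts
      out$cell_types <- cell_types
    }
    out
  })
}
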