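#' Fit a phylogenetic profile clustering
#'
#' The central analysis: co-clusters a binary gene-by-genome presence/absence
#' matrix with deterministic average linkage on both axes, orders the species
#' dendrogram with ciliated species shifted left, and extracts the
#' seed-anchored gene cluster. Returns a classed object with print, summary
#' and plot methods.
#'
#' @param matrix Binary profile matrix (genes x species).
#' @param annotations Species annotations covering every column.
#' @param seed_gene Gene id anchoring the cluster of interest.
#' @param metric Distance metric, `"euclidean"` (sqrt-Hamming on binary
#'   profiles, the default) or `"mean_squared"` (the Cluster 3.0 dialect).
#' @param mode,param Cluster extraction rule, see [extract_seed_cluster()].
#' @return Object of class `cilia_profile` with components `matrix`,
#'   `annotations`, `gene_dendrogram`, `species_dendrogram`,
#'   `species_order` (ciliated-left), `cluster` (a `seed_cluster`),
#'   `metric`, `call`.
#' @examples
#' sim <- simulate_ciliome(sim_config(
#'   groups = c(opisthokonta = 6, alveolata = 6), n_prokaryotes = 2,
#'   modules = data.frame(name = "cilia_mod", size = 12, lost_with = "cilia"),
#'   n_background_genes = 30, cilium_losses = 2, motility_losses = 0,
#'   n_reduced_complement = 0, false_negative_rate = 0, rng_seed = 7))
#' fit <- cilia_profile(sim$matrix, sim$annotations, sim$truth$seed_gene)
#' fit
#' @export
cilia_profile <- function(matrix, annotations, seed_gene,
                          metric = c("euclidean", "mean_squared"),
                          mode = c("elbow", "fixed_height", "target_size"),
                          param = NULL) {
  metric <- match.arg(metric)
  mode <- match.arg(mode)
  assert_profile_matrix(matrix)
  assert_annotations(annotations)
  miss <- setdiff(colnames(matrix), annotations$species_id)
  if (length(miss))
    stopf("species without annotations: %s", paste(miss, collapse = ", "))
  gene_hc <- average_linkage(profile_distances(matrix, "genes", metric))
  species_hc <- average_linkage(profile_distances(matrix, "species", metric))
  sp_order <- order_leaves_ciliated_left(species_hc, annotations)
  cluster <- extract_seed_cluster(gene_hc, seed_gene, mode, param)
  structure(list(matrix = matrix, annotations = annotations,
                 gene_dendrogram = gene_hc, species_dendrogram = species_hc,
                 species_order = sp_order, cluster = cluster,
                 metric = metric, call = match.call()),
            class = "cilia_profile")
}

#' @export
print.cilia_profile <- function(x, ...) {
  cat("Phylogenetic profile clustering\n")
  cat(sprintf("  matrix     : %d genes x %d genomes (%s distance)\n",
              nrow(x$matrix), ncol(x$matrix), x$metric))
  ann <- x$annotations[match(colnames(x$matrix), x$annotations$species_id), ]
  cat(sprintf("  genomes    : %d ciliated, %d non-ciliated eukaryote, %d prokaryote\n",
              sum(ann$is_ciliated),
              sum(!ann$is_ciliated & ann$major_group != "prokaryote"),
              sum(ann$major_group == "prokaryote")))
  cat(sprintf("  seed gene  : %s\n", x$cluster$seed_gene))
  cat(sprintf("  cluster    : %d genes (%s cut at height %.4g)\n",
              length(x$cluster$members), x$cluster$mode, x$cluster$cut_height))
  invisible(x)
}

#' @export
summary.cilia_profile <- function(object, ...) {
  x <- object
  ann <- x$annotations[match(colnames(x$matrix), x$annotations$species_id), ]
  cil <- ann$is_ciliated
  noncil_euk <- !ann$is_ciliated & ann$major_group != "prokaryote"
  members <- x$cluster$members
  inm <- x$matrix[members, , drop = FALSE]
  out <- list(
    n_genes = nrow(x$matrix),
    n_species = ncol(x$matrix),
    cluster_size = length(members),
    seed_gene = x$cluster$seed_gene,
    cut_height = x$cluster$cut_height,
    mean_conservation_ciliated = mean(inm[, cil, drop = FALSE]),
    mean_conservation_nonciliated = if (any(noncil_euk))
      mean(inm[, noncil_euk, drop = FALSE]) else NA_real_,
    growth_trace = x$cluster$growth_trace,
    species_per_group = table(ann$major_group)
  )
  class(out) <- "summary.cilia_profile"
  out
}

#' @export
print.summary.cilia_profile <- function(x, ...) {
  cat(sprintf("Cluster of %d genes around seed %s (cut height %.4g)\n",
              x$cluster_size, x$seed_gene, x$cut_height))
  cat(sprintf("  conservation in ciliated genomes     : %.3f\n",
              x$mean_conservation_ciliated))
  if (!is.na(x$mean_conservation_nonciliated))
    cat(sprintf("  conservation in non-ciliated eukaryotes: %.3f\n",
                x$mean_conservation_nonciliated))
  cat("  growth trace (last steps):\n")
  print(utils::tail(x$growth_trace, 5L))
  invisible(x)
}

#' Heatmap of a fitted profile clustering
#'
#' Displays the presence/absence matrix with genes in dendrogram order and
#' species in ciliated-left order; cluster members are marked along the
#' left margin.
#'
#' @param x A `cilia_profile` object.
#' @param max_genes Downsample rows for display when the matrix is larger
#'   (cluster members are always kept).
#' @param ... Ignored.
#' @return `x`, invisibly.
#' @export
plot.cilia_profile <- function(x, max_genes = 2000L, ...) {
  g_ord <- x$gene_dendrogram$labels[x$gene_dendrogram$order]
  if (length(g_ord) > max_genes) {
    keep <- unique(c(x$cluster$members,
                     g_ord[seq(1L, length(g_ord),
                               length.out = max_genes)]))
    g_ord <- g_ord[g_ord %in% keep]
  }
  m <- x$matrix[g_ord, x$species_order, drop = FALSE]
  graphics::image(
    x = seq_len(ncol(m)), y = seq_len(nrow(m)), z = t(m),
    col = c("grey95", "grey15"), xlab = "genomes (ciliated left)",
    ylab = "genes (dendrogram order)", axes = FALSE,
    main = sprintf("profile cluster: %d genes around %s",
                   length(x$cluster$members), x$cluster$seed_gene))
  in_cluster <- which(g_ord %in% x$cluster$members)
  if (length(in_cluster))
    graphics::points(rep(0.5, length(in_cluster)), in_cluster,
                     pch = 15, cex = 0.3, col = "firebrick")
  graphics::box()
  invisible(x)
}
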