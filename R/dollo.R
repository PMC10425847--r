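#' Count independent trait losses under Dollo parsimony
#'
#' Assumes the trait (e.g. cilia) was present in the common ancestor and can
#' only be lost, never regained. The minimal explanation of the leaf states
#' is then exactly one loss on the edge above every maximal all-absent
#' clade; those edges are disjoint, so losses are counted once each.
#'
#' @param tree A rooted `phylo` tree (binary or multifurcating) whose tips
#'   carry the species being scored. Outgroups that never possessed the
#'   trait (prokaryotes) should be dropped before calling; see
#'   [drop_species()].
#' @param trait Named logical/0-1 vector over all tips: TRUE/1 = trait
#'   present.
#' @param groups Optional named character vector tip -> major group, used to
#'   attribute each loss to a group (losses spanning several groups are
#'   labelled `"multiple"`).
#' @return List of class `loss_report`: `total_losses`, `per_group_losses`,
#'   `loss_edges` (a list, one entry per loss, with the node number and the
#'   tips below it).
#' @export
count_independent_losses <- function(tree, trait, groups = NULL) {
  if (!inherits(tree, "phylo")) stopf("'tree' must be a phylo object")
  tips <- tree$tip.label
  if (is.null(names(trait))) stopf("'trait' must be named by species id")
  miss <- setdiff(tips, names(trait))
  if (length(miss))
    stopf("trait missing for leaf/leaves: %s", paste(miss, collapse = ", "))
  present <- as.logical(trait[tips])
  if (anyNA(present)) stopf("trait contains NA for tree tips")

  n_tip <- length(tips)
  n_node <- tree$Nnode
  all_absent <- logical(n_tip + n_node)
  all_absent[seq_len(n_tip)] <- !present

  # postorder: every child subtree is finalised before its parent edge
  all_absent[n_tip + seq_len(n_node)] <- TRUE
  po <- ape::reorder.phylo(tree, "postorder")
  for (i in seq_len(nrow(po$edge))) {
    parent <- po$edge[i, 1L]
    child <- po$edge[i, 2L]
    all_absent[parent] <- all_absent[parent] && all_absent[child]
  }

  root <- n_tip + 1L
  parent_of <- integer(n_tip + n_node)
  parent_of[tree$edge[, 2L]] <- tree$edge[, 1L]

  is_loss <- vapply(seq_len(n_tip + n_node), function(v) {
    if (!all_absent[v]) return(FALSE)
    if (v == root) return(TRUE)        # trait lost everywhere: one event
    !all_absent[parent_of[v]]
  }, TRUE)
  loss_nodes <- which(is_loss)

  tips_below <- function(v) {
    if (v <= n_tip) return(tips[v])
    kept <- ape::extract.clade(tree, v)$tip.label
    kept
  }
  loss_edges <- lapply(loss_nodes, function(v)
    list(node = v, tips = tips_below(v)))

  per_group <- NULL
  if (!is.null(groups)) {
    lab <- vapply(loss_edges, function(e) {
      g <- unique(unname(groups[e$tips]))
      if (length(g) == 1L) g else "multiple"
    }, "")
    per_group <- table(lab)
    per_group <- stats::setNames(as.integer(per_group), names(per_group))
  }
  structure(list(total_losses = length(loss_nodes),
                 per_group_losses = per_group,
                 loss_edges = loss_edges),
            class = "loss_report")
}

#' @export
print.loss_report <- function(x, ...) {
  cat(sprintf("Dollo loss report: %d independent loss(es)\n", x$total_losses))
  if (!is.null(x$per_group_losses)) {
    for (g in names(x$per_group_losses))
      cat(sprintf("  %-24s %d\n", g, x$per_group_losses[[g]]))
  }
  invisible(x)
}

#' Drop species from a tree
#'
#' Convenience wrapper to restrict a species tree to, e.g., eukaryotes
#' before Dollo counting.
#'
#' @param tree A `phylo` tree.
#' @param drop Tip labels to remove.
#' @return The pruned `phylo` tree.
#' @export
drop_species <- function(tree, drop) {
  drop <- intersect(drop, tree$tip.label)
  if (!length(drop)) return(tree)
  ape::drop.tip(tree, drop)
}

#' Build a species tree from major-group memberships
#'
#' When no resolved species tree is supplied, groups become polytomous
#' clades hanging off an unresolved eukaryote node, with prokaryotes as a
#' sister outgroup clade. Any Newick tree can be swapped in wherever a
#' `phylo` is accepted.
#'
#' @param annotations Species annotation `data.frame`.
#' @return A rooted `phylo` tree with unit branch lengths.
#' @export
group_polytomy_tree <- function(annotations) {
  assert_annotations(annotations)
  grp_clade <- function(sp) {
    if (length(sp) == 1L) sp else paste0("(", paste(sp, collapse = ","), ")")
  }
  euk <- annotations[annotations$major_group != "prokaryote", ]
  prok <- annotations[annotations$major_group == "prokaryote", ]
  euk_clades <- vapply(split(euk$species_id, euk$major_group), grp_clade, "")
  euk_part <- paste0("(", paste(euk_clades, collapse = ","), ")")
  nwk <- if (nrow(prok)) {
    paste0("(", euk_part, ",", grp_clade(prok$species_id), ");")
  } else paste0(euk_part, ";")
  tr <- ape::read.tree(text = nwk)
  tr$edge.length <- rep(1, nrow(tr$edge))
  tr
}

#' Classify species loss patterns over functional gene categories
#'
#' For every species and gene category, the fraction of that category's
#' genes present is discretised: `high` when the fraction exceeds 2/3,
#' `low` below 1/3, `mid` otherwise (the boundary points fall in `mid`).
#' The number of distinct discretised species patterns is reported, along
#' with a species dendrogram over the category fractions for display.
#'
#' @param matrix Binary profile matrix.
#' @param gene_categories Named character vector gene id -> category, for
#'   (a subset of) the matrix rows.
#' @param species Optional subset of species columns (default all).
#' @return List of class `loss_patterns`: `states` (species x category
#'   character matrix), `fractions`, `n_patterns`, `pattern_id` (per
#'   species), `species_dendrogram`.
#' @export
classify_loss_patterns <- function(matrix, gene_categories, species = NULL) {
  assert_profile_matrix(matrix)
  species <- species %||% colnames(matrix)
  gene_categories <- gene_categories[names(gene_categories) %in% rownames(matrix)]
  if (!length(gene_categories)) stopf("no categorised genes found in matrix")
  cats <- sort(unique(unname(gene_categories)))
  frac <- sapply(cats, function(cc) {
    g <- names(gene_categories)[gene_categories == cc]
    if (!length(g)) stopf("empty gene category: %s", cc)
    colMeans(matrix[g, species, drop = FALSE])
  })
  frac <- base::matrix(frac, nrow = length(species),
                       dimnames = list(species, cats))
  states <- ifelse(frac > 2 / 3, "high", ifelse(frac < 1 / 3, "low", "mid"))
  key <- apply(states, 1L, paste, collapse = "|")
  pattern_id <- match(key, unique(key))
  hc <- if (length(species) >= 2L) {
    d <- stats::dist(frac)
    attr(d, "Labels") <- species
    average_linkage(d)
  } else NULL
  structure(list(states = states, fractions = frac,
                 n_patterns = length(unique(key)),
                 pattern_id = stats::setNames(pattern_id, species),
                 species_dendrogram = hc),
            class = "loss_patterns")
}

#' @export
print.loss_patterns <- function(x, ...) {
  cat(sprintf("%d distinct loss pattern(s) over %d species x %d categories\n",
              x$n_patterns, nrow(x$states), ncol(x$states)))
  invisible(x)
}

#' Predict gene function from its phylogenetic footprint
#'
#' A gene conserved in fewer than half of ciliated species yields no
#' prediction. Otherwise it is called a motility gene when it is absent
#' from every ciliated species whose cilia are nonmotile (the nematode/tick
#' class) while being present in at least half of the motile-ciliated
#' species; all remaining genes are called biogenesis. The 0.5 thresholds
#' are parameters.
#'
#' @param profile_row Named 0/1 vector (one gene across species), or an
#'   unnamed vector aligned to `annotations$species_id`.
#' @param annotations Species annotations (must contain at least one
#'   ciliated species).
#' @param min_ciliated_fraction No-prediction cutoff (default 0.5).
#' @param min_motile_fraction Minimum retention in motile-ciliated species
#'   for a motility call (default 0.5).
#' @return List with `call` (`"biogenesis"`, `"motility"` or
#'   `"no_prediction"`) and `conservation_fraction`.
#' @export
predict_gene_function <- function(profile_row, annotations,
                                  min_ciliated_fraction = 0.5,
                                  min_motile_fraction = 0.5) {
  assert_annotations(annotations)
  if (!is.null(names(profile_row))) {
    idx <- match(annotations$species_id, names(profile_row))
    if (anyNA(idx)) stopf("profile row does not cover all annotated species")
    profile_row <- profile_row[idx]
  } else if (length(profile_row) != nrow(annotations)) {
    stopf("profile row not aligned to annotations")
  }
  cil <- as.logical(annotations$is_ciliated)
  if (!any(cil)) stopf("no ciliated species in annotations")
  p <- as.numeric(profile_row)
  cons <- mean(p[cil])
  if (cons < min_ciliated_fraction)
    return(list(call = "no_prediction", conservation_fraction = cons))
  nonmotile_cil <- cil & !annotations$has_motile_cilia
  motile_cil <- cil & annotations$has_motile_cilia
  motility <- any(nonmotile_cil) &&
    all(p[nonmotile_cil] == 0) &&
    any(motile_cil) && mean(p[motile_cil]) >= min_motile_fraction
  list(call = if (motility) "motility" else "biogenesis",
       conservation_fraction = cons)
}

#' Predict function for every gene in a matrix
#'
#' Vectorised wrapper around [predict_gene_function()].
#'
#' @inheritParams predict_gene_function
#' @param matrix Binary profile matrix.
#' @return `data.frame` with `gene_id`, `call`, `conservation_fraction`.
#' @export
predict_gene_functions <- function(matrix, annotations,
                                   min_ciliated_fraction = 0.5,
                                   min_motile_fraction = 0.5) {
  assert_profile_matrix(matrix)
  assert_annotations(annotations)
  sp <- colnames(matrix)
  ann <- annotations[match(sp, annotations$species_id), ]
  if (anyNA(ann$species_id)) stopf("unannotated species in matrix")
  cil <- as.logical(ann$is_ciliated)
  if (!any(cil)) stopf("no ciliated species in annotations")
  nonmotile_cil <- cil & !ann$has_motile_cilia
  motile_cil <- cil & ann$has_motile_cilia
  cons <- rowMeans(matrix[, cil, drop = FALSE])
  in_nonmotile <- if (any(nonmotile_cil))
    rowSums(matrix[, nonmotile_cil, drop = FALSE]) else rep(NA_real_, nrow(matrix))
  motile_frac <- if (any(motile_cil))
    rowMeans(matrix[, motile_cil, drop = FALSE]) else rep(0, nrow(matrix))
  call <- rep("biogenesis", nrow(matrix))
  call[!is.na(in_nonmotile) & in_nonmotile == 0 &
         motile_frac >= min_motile_fraction] <- "motility"
  call[cons < min_ciliated_fraction] <- "no_prediction"
  data.frame(gene_id = rownames(matrix), call = call,
             conservation_fraction = cons, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Genes universally conserved in ciliated species and lost elsewhere
#'
#' Returns the genes present in every ciliated species and absent from
#' every nonciliated eukaryote. Prokaryote outgroups are excluded from both
#' conditions.
#'
#' @param matrix Binary profile matrix (typically restricted to cluster
#'   genes).
#' @param annotations Species annotations covering the matrix columns.
#' @return Character vector of gene ids.
#' @export
universally_conserved_genes <- function(matrix, annotations) {
  assert_profile_matrix(matrix)
  assert_annotations(annotations)
  ann <- annotations[match(colnames(matrix), annotations$species_id), ]
  if (anyNA(ann$species_id)) stopf("unannotated species in matrix")
  cil <- as.logical(ann$is_ciliated)
  noncil_euk <- !ann$is_ciliated & ann$major_group != "prokaryote"
  keep <- rowSums(matrix[, cil, drop = FALSE]) == sum(cil) &
    rowSums(matrix[, noncil_euk, drop = FALSE]) == 0
  rownames(matrix)[keep]
}
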