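#' Write a TreeView-compatible CDT/GTR/ATR bundle
#'
#' Emits the clustered data table (`.cdt`), gene tree (`.gtr`) and array tree
#' (`.atr`) files understood by Java TreeView and other consumers of the
#' Cluster 3.0 output convention. Leaf ids follow the de-facto convention
#' `GENE{k}X` / `ARRY{k}X` (`k` = 0-based input index) and internal nodes
#' `NODE{k}X`; merge heights are rescaled to similarity scores `1 - h/max(h)`
#' written with 6 significant digits. Data rows appear in dendrogram leaf
#' order (or an explicitly supplied order compatible with the dendrogram).
#'
#' @param matrix Binary profile matrix (genes x species).
#' @param gene_dendrogram `hclust` over genes, or NULL for a single-gene
#'   matrix (a `.gtr` with zero merge lines is then written).
#' @param species_dendrogram `hclust` over species, or NULL for a single
#'   species.
#' @param path_prefix Output path prefix; `.cdt`, `.gtr`, `.atr` are appended.
#' @param gene_order,species_order Optional explicit leaf orders (character
#'   vectors permuting the axis labels), e.g. the ciliated-left species order
#'   from [order_leaves_ciliated_left()].
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_treeview_bundle <- function(matrix, gene_dendrogram, species_dendrogram,
                                  path_prefix,
                                  gene_order = NULL, species_order = NULL) {
  assert_profile_matrix(matrix)
  genes <- rownames(matrix); species <- colnames(matrix)
  check_axis <- function(hc, labels, axis) {
    if (is.null(hc)) {
      if (length(labels) != 1L)
        stopf("%s dendrogram missing for a multi-%s matrix", axis, axis)
      return(labels)
    }
    if (!setequal(hc$labels, labels))
      stopf("%s dendrogram leaves do not match matrix %s axis", axis, axis)
    hc$labels[hc$order]
  }
  g_default <- check_axis(gene_dendrogram, genes, "gene")
  s_default <- check_axis(species_dendrogram, species, "species")
  g_ord <- gene_order %||% g_default
  s_ord <- species_order %||% s_default
  if (!setequal(g_ord, genes) || !setequal(s_ord, species))
    stopf("explicit leaf order does not match matrix axes")

  leaf_id <- function(labels, ordered, prefix) {
    idx <- match(ordered, labels) - 1L
    sprintf("%s%dX", prefix, idx)
  }
  tree_lines <- function(hc, labels, prefix) {
    if (is.null(hc) || length(labels) == 1L) return(character())
    hmax <- max(hc$height)
    denom <- if (hmax > 0) hmax else 1
    score <- signif(1 - hc$height / denom, 6L)
    node_name <- function(v, k) {
      if (v < 0) sprintf("%s%dX", prefix, -v - 1L) else sprintf("NODE%dX", v)
    }
    vapply(seq_len(nrow(hc$merge)), function(k) {
      paste(sprintf("NODE%dX", k),
            node_name(hc$merge[k, 1L]),
            node_name(hc$merge[k, 2L]),
            formatC(score[k], format = "g", digits = 6L),
            sep = "\t")
    }, "")
  }

  paths <- c(cdt = paste0(path_prefix, ".cdt"),
             gtr = paste0(path_prefix, ".gtr"),
             atr = paste0(path_prefix, ".atr"))
  writeLines(tree_lines(gene_dendrogram, genes, "GENE"), paths["gtr"])
  writeLines(tree_lines(species_dendrogram, species, "ARRY"), paths["atr"])

  m <- matrix[g_ord, s_ord, drop = FALSE]
  header <- paste(c("GID", "UNIQID", "NAME", "GWEIGHT", s_ord), collapse = "\t")
  aid <- paste(c("AID", "", "", "", leaf_id(species, s_ord, "ARRY")), collapse = "\t")
  ewt <- paste(c("EWEIGHT", "", "", "", rep("1", length(s_ord))), collapse = "\t")
  gids <- leaf_id(genes, g_ord, "GENE")
  rows <- vapply(seq_along(g_ord), function(i) {
    paste(c(gids[i], g_ord[i], g_ord[i], "1",
            formatC(m[i, ], format = "g", digits = 6L)), collapse = "\t")
  }, "")
  writeLines(c(header, aid, ewt, rows), paths["cdt"])
  invisible(paths)
}

#' Read back the ordered matrix from a CDT file
#'
#' Minimal reader for the CDT dialect written by [write_treeview_bundle()],
#' used to verify leaf-order round trips.
#'
#' @param path `.cdt` file path.
#' @return List with `matrix` (numeric, in file order), `gene_order`,
#'   `species_order`.
#' @export
read_treeview_cdt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 1L) stopf("empty CDT file: %s", path)
  split <- strsplit(lines, "\t", fixed = TRUE)
  header <- split[[1L]]
  species <- header[-(1:4)]
  body <- split[vapply(split, function(x) !x[1L] %in% c("GID", "AID", "EWEIGHT"), TRUE)]
  genes <- vapply(body, `[[`, "", 2L)
  m <- t(vapply(body, function(x) as.numeric(x[-(1:4)]), numeric(length(species))))
  if (length(genes) == 1L) m <- matrix(m, nrow = 1L)
  rownames(m) <- genes; colnames(m) <- species
  list(matrix = m, gene_order = genes, species_order = species)
}
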