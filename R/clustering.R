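#' Pairwise distances between binary profiles
#'
#' For binary vectors the Euclidean distance is `sqrt(hamming)`; the
#' `mean_squared` dialect (the convention of the original Cluster 3.0 tool,
#' whose "Euclidean" is the average squared difference) is `hamming / n`.
#' Computed via cross-products, so it scales to thousands of profiles.
#'
#' @param matrix Binary profile matrix (genes x species).
#' @param axis `"genes"` (rows, the default) or `"species"` (columns).
#' @param metric `"euclidean"` or `"mean_squared"`.
#' @return A `dist` object over the chosen axis, labelled.
#' @export
profile_distances <- function(matrix, axis = c("genes", "species"),
                              metric = c("euclidean", "mean_squared")) {
  axis <- match.arg(axis)
  metric <- match.arg(metric)
  assert_profile_matrix(matrix)
  x <- if (axis == "genes") matrix else t(matrix)
  if (nrow(x) < 2L) stopf("need at least two items on the %s axis", axis)
  storage.mode(x) <- "integer"
  h <- binary_hamming_cpp(x)            # condensed hamming counts
  d <- if (metric == "euclidean") sqrt(h) else h / ncol(x)
  attr(d, "Size") <- nrow(x)
  attr(d, "Labels") <- rownames(x)
  attr(d, "Diag") <- FALSE
  attr(d, "Upper") <- FALSE
  attr(d, "method") <- metric
  class(d) <- "dist"
  d
}

#' Deterministic unweighted average-linkage clustering
#'
#' UPGMA-style agglomeration: the distance between two clusters is the
#' unweighted mean of all pairwise member distances. Ties at equal merge
#' height are broken by the lexicographically smallest member label (then
#' the second-smallest), so the dendrogram is fully determined by the input
#' distances and labels, never by row order.
#'
#' @param distances A `dist` object with labels.
#' @return An object of class `hclust` (merge, height, order, labels).
#' @export
average_linkage <- function(distances) {
  if (!inherits(distances, "dist")) stopf("'distances' must be a dist object")
  n <- attr(distances, "Size")
  labels <- attr(distances, "Labels") %||% as.character(seq_len(n))
  dv <- as.numeric(distances)
  if (anyNA(dv) || any(!is.finite(dv))) stopf("NaN or non-finite distance")
  res <- avg_linkage_cpp(dv, as.integer(n), as.integer(label_ranks(labels)))
  hc <- list(
    merge = res$merge,
    height = as.numeric(res$height),
    order = order_from_merge(res$merge),
    labels = labels,
    method = "average",
    call = match.call(),
    dist.method = attr(distances, "method") %||% "euclidean"
  )
  class(hc) <- "hclust"
  hc
}

# Leaf order for an hclust merge matrix (left child first), iteratively.
order_from_merge <- function(merge) {
  n <- nrow(merge) + 1L
  out <- integer(n)
  pos <- 0L
  stack <- integer(2L * n)
  top <- 1L
  stack[1L] <- nrow(merge)
  while (top > 0L) {
    nd <- stack[top]; top <- top - 1L
    if (nd < 0L) {
      pos <- pos + 1L
      out[pos] <- -nd
    } else {
      stack[top + 1L] <- merge[nd, 2L]
      stack[top + 2L] <- merge[nd, 1L]
      top <- top + 2L
    }
  }
  out
}

#' Order dendrogram leaves with ciliated species shifted left
#'
#' Reorders children at every internal node of a species dendrogram so that
#' the subtree with the higher density of ciliated leaves comes first,
#' without breaking any clade. By the classic exchange argument this
#' minimises the sum of positions of ciliated leaves over all orderings
#' consistent with the dendrogram. Ties keep the input child order.
#'
#' @param dendrogram `hclust` over the species axis.
#' @param annotations Species annotation `data.frame` covering every leaf
#'   (columns `species_id`, `is_ciliated`).
#' @return Character vector: the species ids in ciliated-left order, with
#'   attribute `"objective"` (sum of 1-based positions of ciliated leaves).
#' @export
order_leaves_ciliated_left <- function(dendrogram, annotations) {
  labels <- dendrogram$labels
  idx <- match(labels, annotations$species_id)
  if (anyNA(idx))
    stopf("unannotated leaf/leaves: %s",
          paste(labels[is.na(idx)], collapse = ", "))
  cil <- as.logical(annotations$is_ciliated[idx])
  merge <- dendrogram$merge
  m <- nrow(merge)

  n_leaf <- integer(m); n_cil <- integer(m)
  stats_of <- function(v) {
    if (v < 0L) c(1L, as.integer(cil[-v])) else c(n_leaf[v], n_cil[v])
  }
  ord_cache <- vector("list", m)
  for (k in seq_len(m)) {
    a <- stats_of(merge[k, 1L]); b <- stats_of(merge[k, 2L])
    n_leaf[k] <- a[1L] + b[1L]
    n_cil[k] <- a[2L] + b[2L]
    left_first <- a[2L] * b[1L] >= b[2L] * a[1L]   # density a >= density b
    kids <- if (left_first) merge[k, ] else merge[k, 2:1]
    get_ord <- function(v) if (v < 0L) -v else ord_cache[[v]]
    ord_cache[[k]] <- c(get_ord(kids[1L]), get_ord(kids[2L]))
  }
  ord <- if (m == 0L) 1L else ord_cache[[m]]
  out <- labels[ord]
  attr(out, "objective") <- sum(seq_along(out)[cil[ord]])
  out
}

#' Extract the seed-anchored cluster from a gene dendrogram
#'
#' Walks the merges on the path from the seed gene to the root (heights are
#' nondecreasing under average linkage) and cuts according to `mode`:
#' \describe{
#'   \item{`fixed_height`}{members of the largest seed clade whose merge
#'     height is at most `param`.}
#'   \item{`target_size`}{the smallest seed clade with at least `param`
#'     leaves.}
#'   \item{`elbow`}{the default for de-novo use: the seed cluster grows
#'     gradually along the path and is eventually absorbed into a much
#'     larger super-cluster of unrelated genes. The cut is placed just
#'     below the last merge at which the clade size jumps by more than
#'     `growth_factor` (default 2); when no merge jumps that much, the cut
#'     falls back to just below the largest relative gap in merge heights.}
#' }
#'
#' @param dendrogram `hclust` over the gene axis.
#' @param seed_gene Gene id of the seed (e.g. the core centriolar gene the
#'   ciliary cluster is anchored on).
#' @param mode `"elbow"`, `"fixed_height"` or `"target_size"`.
#' @param param Cut height (`fixed_height`) or minimum size (`target_size`);
#'   ignored for `elbow`.
#' @param growth_factor Size-jump factor defining the absorption point in
#'   `elbow` mode.
#' @return An object of class `seed_cluster`: list with `members`,
#'   `seed_gene`, `cut_height`, `mode`, and `growth_trace`
#'   (`data.frame(height, size)`, one row per seed-path merge).
#' @export
extract_seed_cluster <- function(dendrogram, seed_gene,
                                 mode = c("elbow", "fixed_height", "target_size"),
                                 param = NULL, growth_factor = 2) {
  mode <- match.arg(mode)
  labels <- dendrogram$labels
  seed_idx <- match(seed_gene, labels)
  if (is.na(seed_idx)) stopf("seed gene not found: %s", seed_gene)
  merge <- dendrogram$merge
  m <- nrow(merge)

  sizes <- integer(m)
  contains <- logical(m)
  for (k in seq_len(m)) {
    a <- merge[k, 1L]; b <- merge[k, 2L]
    sz <- function(v) if (v < 0L) 1L else sizes[v]
    has <- function(v) if (v < 0L) -v == seed_idx else contains[v]
    sizes[k] <- sz(a) + sz(b)
    contains[k] <- has(a) || has(b)
  }
  path <- which(contains)                       # ascending = seed-to-root
  trace <- data.frame(height = dendrogram$height[path], size = sizes[path])

  pick <- switch(mode,
    fixed_height = {
      if (is.null(param)) stopf("fixed_height mode needs a cut height in 'param'")
      ok <- which(trace$height <= param)
      if (length(ok)) max(ok) else 0L
    },
    target_size = {
      if (is.null(param)) stopf("target_size mode needs a size in 'param'")
      if (param > m + 1L) stopf("target size %d exceeds number of genes", param)
      ok <- which(trace$size >= param)
      if (length(ok)) min(ok) else 0L
    },
    elbow = {
      if (nrow(trace) <= 1L) nrow(trace)
      else {
        s <- c(1, trace$size)
        jump <- trace$size / s[-length(s)]
        absorb <- which(jump > growth_factor)
        if (length(absorb) && max(absorb) > 1L) {
          max(absorb) - 1L            # cut just below the absorption merge
        } else {
          h <- trace$height
          eps <- max(h[length(h)], 1) * 1e-9
          gaps <- (h[-1L] - h[-length(h)]) / pmax(h[-length(h)], eps)
          which.max(gaps)
        }
      }
    }
  )

  if (pick == 0L) {
    members <- seed_gene
    cut_height <- if (mode == "fixed_height") param else 0
  } else {
    members <- labels[clade_leaves(merge, path[pick])]
    cut_height <- trace$height[pick]
  }
  structure(list(members = members, seed_gene = seed_gene,
                 cut_height = cut_height, mode = mode, param = param,
                 growth_trace = trace),
            class = "seed_cluster")
}

# leaf indices under merge node k (iterative descent)
clade_leaves <- function(merge, k) {
  out <- integer(0)
  stack <- k
  while (length(stack)) {
    nd <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (nd < 0L) out <- c(out, -nd)
    else stack <- c(stack, merge[nd, 1L], merge[nd, 2L])
  }
  out
}

#' @export
print.seed_cluster <- function(x, ...) {
  cat(sprintf("Seed-anchored cluster (%s mode)\n", x$mode))
  cat(sprintf("  seed gene : %s\n", x$seed_gene))
  cat(sprintf("  members   : %d genes\n", length(x$members)))
  cat(sprintf("  cut height: %.4g\n", x$cut_height))
  invisible(x)
}

#' Cluster robustness under stratified species subsampling
#'
#' Removes a fraction of species from every major group (or keeps an
#' explicit species list), re-clusters the reduced matrix, re-extracts the
#' seed cluster and reports the overlap with a reference cluster on the
#' full matrix.
#'
#' @param matrix Full binary profile matrix.
#' @param annotations Species annotations covering all columns.
#' @param seed_gene Seed gene id.
#' @param fraction Fraction of species to remove from each major group
#'   (rounded per group); ignored when `species_keep` is given.
#' @param species_keep Explicit character vector of species to retain.
#' @param mode,param Cluster extraction settings (see
#'   [extract_seed_cluster()]).
#' @param metric Distance metric for re-clustering.
#' @param rng_seed Integer seed for the stratified removal draw (required
#'   when `fraction` is used).
#' @param reference Optional reference `seed_cluster` from the full matrix;
#'   computed if missing.
#' @return List with `retained_count`, `retained_gene_ids`, `cluster` (the
#'   reduced-matrix cluster), `species_used`, `reference_size`.
#' @export
robustness_subsample <- function(matrix, annotations, seed_gene,
                                 fraction = NULL, species_keep = NULL,
                                 mode = "elbow", param = NULL,
                                 metric = "euclidean",
                                 rng_seed = NULL, reference = NULL) {
  assert_profile_matrix(matrix)
  assert_annotations(annotations)
  species <- colnames(matrix)
  if (is.null(species_keep)) {
    if (is.null(fraction)) stopf("supply either 'fraction' or 'species_keep'")
    if (fraction < 0 || fraction >= 1) stopf("fraction must be in [0, 1)")
    if (is.null(rng_seed)) stopf("stratified removal needs an explicit rng_seed")
    grp <- annotations$major_group[match(species, annotations$species_id)]
    if (anyNA(grp)) stopf("unannotated species in matrix")
    rng <- local_rng(rng_seed)
    keep <- unlist(lapply(split(species, grp), function(sp) {
      k <- round(fraction * length(sp))
      if (k >= length(sp) && k > 0L)
        stopf("fraction %.2f would remove an entire major group", fraction)
      if (k == 0L) sp else sp[-rng$sample_int(length(sp), k)]
    }), use.names = FALSE)
    species_keep <- species[species %in% keep]   # preserve column order
  } else {
    miss <- setdiff(species_keep, species)
    if (length(miss))
      stopf("species_keep not in matrix: %s", paste(miss, collapse = ", "))
  }
  if (is.null(reference)) {
    full_hc <- average_linkage(profile_distances(matrix, "genes", metric))
    reference <- extract_seed_cluster(full_hc, seed_gene, mode, param)
  }
  red <- matrix[, species_keep, drop = FALSE]
  hc <- average_linkage(profile_distances(red, "genes", metric))
  cl <- extract_seed_cluster(hc, seed_gene, mode, param)
  retained <- intersect(reference$members, cl$members)
  list(retained_count = length(retained),
       retained_gene_ids = retained,
       cluster = cl,
       species_used = species_keep,
       reference_size = length(reference$members))
}
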