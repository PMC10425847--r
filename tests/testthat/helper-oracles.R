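# Independent oracles and small fixture builders used across the suite.

# --- naive O(n^3) unweighted average linkage with the same deterministic
#     tie-break (smallest member label, then second smallest); independent
#     of the package's compiled implementation.
naive_average_linkage <- function(d, labels) {
  n <- attr(d, "Size")
  dm <- as.matrix(d)
  clusters <- lapply(seq_len(n), function(i) i)   # member leaf indices
  heights <- numeric(0)
  members <- list()                               # member sets per merge
  lab_rank <- rank(labels, ties.method = "first") # labels assumed unique
  avg_dist <- function(a, b) mean(dm[a, b])
  while (length(clusters) > 1L) {
    best <- NULL
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        dij <- avg_dist(clusters[[i]], clusters[[j]])
        ri <- min(lab_rank[clusters[[i]]]); rj <- min(lab_rank[clusters[[j]]])
        key <- c(dij, min(ri, rj), max(ri, rj))
        if (is.null(best) || key_lt(key, best$key))
          best <- list(i = i, j = j, key = key)
      }
    }
    merged <- sort(c(clusters[[best$i]], clusters[[best$j]]))
    heights <- c(heights, best$key[1L])
    members <- c(members, list(merged))
    clusters[[best$i]] <- merged
    clusters[[best$j]] <- NULL
  }
  list(heights = heights, members = members)
}

key_lt <- function(a, b) {
  for (k in seq_along(a)) {
    if (a[k] < b[k]) return(TRUE)
    if (a[k] > b[k]) return(FALSE)
  }
  FALSE
}

# member sets per merge from an hclust object, as sorted leaf indices
hclust_members <- function(hc) {
  m <- hc$merge
  out <- vector("list", nrow(m))
  for (k in seq_len(nrow(m))) {
    get <- function(v) if (v < 0L) -v else out[[v]]
    out[[k]] <- sort(c(get(m[k, 1L]), get(m[k, 2L])))
  }
  out
}

# --- exhaustive Dollo oracle: minimal number of all-absent clades whose
#     union is exactly the absent tip set (branch-and-bound over covers)
dollo_min_oracle <- function(tree, trait) {
  tips <- tree$tip.label
  absent <- tips[!as.logical(trait[tips])]
  if (!length(absent)) return(0L)
  n_tip <- length(tips)
  nodes <- seq_len(n_tip + tree$Nnode)
  clade_of <- lapply(nodes, function(v) {
    if (v <= n_tip) tips[v] else ape::extract.clade(tree, v)$tip.label
  })
  cands <- Filter(function(cl) all(cl %in% absent), clade_of)
  cover <- function(uncovered) {
    if (!length(uncovered)) return(0L)
    t1 <- uncovered[1L]
    best <- Inf
    for (cl in cands) {
      if (t1 %in% cl) {
        sub <- cover(setdiff(uncovered, cl))
        if (1L + sub < best) best <- 1L + sub
      }
    }
    best
  }
  cover(absent)
}

# --- exhaustive ciliated-left oracle: minimum of sum(positions of ciliated
#     leaves) over all 2^(n-1) child orderings of a binary dendrogram
ciliated_left_oracle <- function(hc, ciliated) {
  orders_of <- function(node) {
    if (node < 0L) return(list(-node))
    L <- orders_of(hc$merge[node, 1L])
    R <- orders_of(hc$merge[node, 2L])
    out <- list()
    for (l in L) for (r in R) out <- c(out, list(c(l, r)), list(c(r, l)))
    out
  }
  all_ord <- orders_of(nrow(hc$merge))
  objective <- function(ord) sum(seq_along(ord)[ciliated[ord]])
  min(vapply(all_ord, objective, 0))
}

# --- fixture builders ----------------------------------------------------

random_binary_matrix <- function(n_genes, n_species, p = 0.5) {
  m <- matrix(as.integer(runif(n_genes * n_species) < p),
              nrow = n_genes,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_species))))
  m
}

random_dist <- function(n, labels = sprintf("x%02d", seq_len(n))) {
  d <- dist(matrix(runif(n * 3), nrow = n))
  attr(d, "Labels") <- labels
  d
}

tiny_sim_config <- function(seed, noise = 0, ...) {
  args <- list(
    groups = c(opisthokonta = 8, alveolata = 8, stramenopila = 8),
    n_prokaryotes = 3,
    modules = data.frame(name = "cilia_mod", size = 12L,
                         lost_with = "cilia", stringsAsFactors = FALSE),
    n_background_genes = 40,
    cilium_losses = 3,
    motility_losses = 0,
    n_reduced_complement = 0,
    background_loss_prob = 0,
    false_negative_rate = noise,
    false_positive_rate = 0,
    rng_seed = seed
  )
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(sim_config, args)
}

# annotations for hand-built matrices
make_annotations <- function(species, ciliated, motile = ciliated,
                             group = "opisthokonta") {
  data.frame(species_id = species,
             major_group = rep_len(group, length(species)),
             is_ciliated = ciliated,
             has_motile_cilia = motile & ciliated,
             reduced_complement = FALSE,
             display_name = species,
             stringsAsFactors = FALSE)
}
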