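#' Configuration for the synthetic genome-evolution simulator
#'
#' The defaults emulate the comparative setting the pipeline was designed
#' for: 147 eukaryotic genomes spread over eight major groups plus 12
#' prokaryote outgroups; a ciliary gene complement of 386 genes split into
#' three functionally coherent modules that are lost together with the
#' structure they build (core biogenesis and the BBSome with cilia,
#' the motility module with motile cilia); 13 independent cilium losses
#' distributed over five groups (4 opisthokont, 1 amoebozoan, 3
#' archaeplastid, 2 alveolate, 3 stramenopile); two motility-only losses;
#' a background of broadly conserved genes subject to sporadic lineage
#' loss; and detection noise mimicking false-negative ortholog calls in
#' divergent proteomes plus rare false positives.
#'
#' @param groups Named integer vector: eukaryotic species count per major
#'   group.
#' @param n_prokaryotes Number of prokaryote outgroup genomes.
#' @param modules `data.frame` with columns `name`, `size`, `lost_with`
#'   (`"cilia"` or `"motility"`).
#' @param n_background_genes Number of background conserved genes.
#' @param cilium_losses Either a single count (losses placed uniformly over
#'   eligible within-group edges) or a named vector of per-group counts.
#' @param motility_losses As `cilium_losses`, for motility-only losses
#'   (placed on ciliated subtrees).
#' @param n_reduced_complement Number of ciliated species given a randomly
#'   halved ciliary complement (emulating reduced-complement lineages) and
#'   flagged as such.
#' @param background_loss_prob Per-gene, per-branch probability of a
#'   sporadic Dollo loss.
#' @param false_negative_rate,false_positive_rate Per-cell detection noise
#'   applied to the planted matrix.
#' @param fn_group_multiplier Optional named numeric vector (by major
#'   group) scaling the false-negative rate per group, to mimic
#'   fast-evolving lineages whose divergent sequences drop below the
#'   alignment threshold more often. Default off.
#' @param rng_seed Mandatory integer seed; all randomness flows from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(groups = c(opisthokonta = 40, amoebozoa = 8,
                                  archaeplastida = 25, rhizaria = 4,
                                  alveolata = 20, stramenopila = 20,
                                  discicristata_excavata = 18,
                                  cryptophyta_haptophyta = 12),
                       n_prokaryotes = 12,
                       modules = data.frame(
                         name = c("core_biogenesis", "motility", "bbsome"),
                         size = c(200L, 140L, 46L),
                         lost_with = c("cilia", "motility", "cilia"),
                         stringsAsFactors = FALSE),
                       n_background_genes = 4614,
                       cilium_losses = c(opisthokonta = 4, amoebozoa = 1,
                                         archaeplastida = 3, alveolata = 2,
                                         stramenopila = 3),
                       motility_losses = c(opisthokonta = 2),
                       n_reduced_complement = 1,
                       background_loss_prob = 0.01,
                       false_negative_rate = 0.05,
                       false_positive_rate = 0.002,
                       fn_group_multiplier = NULL,
                       rng_seed) {
  if (missing(rng_seed) || is.null(rng_seed)) stopf("rng_seed is mandatory")
  if (any(groups < 1)) stopf("every major group needs at least one species")
  if (!all(modules$lost_with %in% c("cilia", "motility")))
    stopf("module lost_with must be 'cilia' or 'motility'")
  if (any(modules$size < 1)) stopf("module sizes must be >= 1")
  for (p in c(background_loss_prob, false_negative_rate, false_positive_rate))
    if (p < 0 || p > 1) stopf("probabilities must lie in [0, 1]")
  if (!is.null(fn_group_multiplier)) {
    if (is.null(names(fn_group_multiplier)) ||
        !all(names(fn_group_multiplier) %in% c(names(groups), "prokaryote")))
      stopf("fn_group_multiplier must be named by major group")
    if (any(fn_group_multiplier < 0))
      stopf("fn_group_multiplier must be nonnegative")
  }
  structure(list(groups = groups, n_prokaryotes = n_prokaryotes,
                 modules = modules, n_background_genes = n_background_genes,
                 cilium_losses = cilium_losses,
                 motility_losses = motility_losses,
                 n_reduced_complement = n_reduced_complement,
                 background_loss_prob = background_loss_prob,
                 false_negative_rate = false_negative_rate,
                 false_positive_rate = false_positive_rate,
                 fn_group_multiplier = fn_group_multiplier,
                 rng_seed = as.integer(rng_seed)),
            class = "sim_config")
}

# random binary newick over tip labels, unit branch lengths
random_clade_newick <- function(tips, rng) {
  build <- function(v) {
    if (length(v) == 1L) return(v)
    if (length(v) == 2L) return(paste0("(", v[1L], ",", v[2L], ")"))
    k <- 1L + rng$sample_int(length(v) - 1L, 1L)[1L] - 1L
    k <- max(1L, min(length(v) - 1L, k))
    paste0("(", build(v[seq_len(k)]), ",", build(v[-seq_len(k)]), ")")
  }
  shuffled <- tips[rng$sample_int(length(tips), length(tips))]
  build(shuffled)
}

#' Simulate presence/absence evolution on a species tree
#'
#' Generates a rooted species tree (major groups as clades with random
#' binary structure inside, prokaryotes as outgroup), places the requested
#' independent cilium-loss and motility-loss edges (never nested, never an
#' entire group), deletes module genes on the corresponding loss subtrees,
#' applies sporadic per-gene Dollo background loss, and finally flips
#' observed cells with the configured false-negative/false-positive rates.
#' Fully reproducible from `rng_seed`.
#'
#' @param config A [sim_config()].
#' @return List with `matrix` (observed, noisy), `truth` (list: `tree`,
#'   `trait` data.frame, `planted` noise-free matrix, `modules` named
#'   vector gene -> module, `loss_edges`, `seed_gene`) and `annotations`
#'   (species annotation data.frame).
#' @export
simulate_ciliome <- function(config) {
  if (!inherits(config, "sim_config")) stopf("'config' must be a sim_config")
  rng <- local_rng(config$rng_seed)

  grp_names <- names(config$groups)
  species <- unlist(lapply(grp_names, function(g)
    sprintf("%s_%02d", abbreviate_group(g), seq_len(config$groups[[g]]))),
    use.names = FALSE)
  grp_of <- rep(grp_names, config$groups)
  names(grp_of) <- species
  prok <- if (config$n_prokaryotes > 0)
    sprintf("prok_%02d", seq_len(config$n_prokaryotes)) else character()

  euk_clades <- vapply(grp_names, function(g)
    random_clade_newick(species[grp_of == g], rng), "")
  euk_part <- if (length(euk_clades) == 1L) euk_clades else
    paste0("(", paste(euk_clades, collapse = ","), ")")
  nwk <- if (length(prok)) {
    prok_part <- if (length(prok) == 1L) prok else
      paste0("(", paste(prok, collapse = ","), ")")
    paste0("(", euk_part, ",", prok_part, ");")
  } else paste0(euk_part, ";")
  tree <- ape::read.tree(text = nwk)
  tree$edge.length <- rep(1, nrow(tree$edge))

  n_tip <- length(tree$tip.label)
  # descendant-tip indicator per edge (child node of each edge)
  desc <- edge_tip_indicator(tree)

  # group clade root nodes: the MRCA of each group's species
  group_node <- vapply(grp_names, function(g) {
    sp <- species[grp_of == g]
    if (length(sp) == 1L) match(sp, tree$tip.label)
    else ape::getMRCA(tree, sp)
  }, 0L)

  # eligible edges for a loss in group g: edges whose child lies strictly
  # inside the group clade (child != group root), i.e. all descendant tips
  # belong to g and not all of g's tips are below it
  edge_group <- vapply(seq_len(nrow(tree$edge)), function(e) {
    below <- tree$tip.label[desc[e, ]]
    g <- unique(grp_of[below])
    g <- g[!is.na(g)]
    if (length(g) != 1L || any(is.na(grp_of[below]))) return(NA_character_)
    if (all(species[grp_of == g] %in% below)) return(NA_character_)  # whole group
    g
  }, "")

  node_tips <- node_tip_masks(tree)

  draw_losses <- function(spec, blocked_tips) {
    # spec: count or named per-group counts; returns chosen edge indices
    if (!length(spec) || sum(spec) == 0) return(integer())
    per_group <- if (is.null(names(spec))) NULL else spec
    chosen <- integer()
    covered <- rep(FALSE, n_tip)
    covered[match(blocked_tips, tree$tip.label)] <- TRUE
    pick_one <- function(g) {
      cand <- if (is.null(g)) which(!is.na(edge_group))
        else which(!is.na(edge_group) & edge_group == g)
      parents <- tree$edge[chosen, 1L]
      ok <- vapply(cand, function(e) {
        tips_e <- desc[e, ]
        # never nested in / overlapping an existing loss
        if (any(tips_e & covered)) return(FALSE)
        cov2 <- covered | tips_e
        # losses stay independent events: each chosen subtree must remain a
        # maximal absent clade, i.e. no parent clade becomes fully covered
        for (p in c(tree$edge[e, 1L], parents))
          if (all(cov2[node_tips[[p]]])) return(FALSE)
        # the group keeps at least one unaffected species
        gg <- edge_group[e]
        g_tips <- tree$tip.label %in% species[grp_of == gg]
        sum(g_tips & !cov2) >= 1L
      }, TRUE)
      cand <- cand[ok]
      if (!length(cand)) stopf("more requested losses than eligible edges")
      e <- cand[rng$sample_int(length(cand), 1L)]
      covered[desc[e, ]] <<- TRUE
      e
    }
    if (is.null(per_group)) {
      for (i in seq_len(spec)) chosen <- c(chosen, pick_one(NULL))
    } else {
      for (g in names(per_group))
        for (i in seq_len(per_group[[g]])) chosen <- c(chosen, pick_one(g))
    }
    chosen
  }

  cil_edges <- draw_losses(config$cilium_losses, character())
  cil_lost_tips <- tree$tip.label[colSums(desc[cil_edges, , drop = FALSE] * 1) > 0]
  is_ciliated <- stats::setNames(!(tree$tip.label %in% c(cil_lost_tips, prok)),
                                 tree$tip.label)

  mot_edges <- draw_losses(config$motility_losses, cil_lost_tips)
  mot_lost_tips <- tree$tip.label[colSums(desc[mot_edges, , drop = FALSE] * 1) > 0]
  has_motile <- is_ciliated & !(tree$tip.label %in% mot_lost_tips)

  # gene universe
  mods <- config$modules
  gene_ids <- c(
    unlist(lapply(seq_len(nrow(mods)), function(i)
      sprintf("%s_%04d", mods$name[i], seq_len(mods$size[i]))), use.names = FALSE),
    if (config$n_background_genes > 0)
      sprintf("bg_%05d", seq_len(config$n_background_genes)) else character()
  )
  module_of <- stats::setNames(
    c(rep(mods$name, mods$size), rep(NA_character_, config$n_background_genes)),
    gene_ids)

  tipnames <- tree$tip.label
  is_euk <- !(tipnames %in% prok)
  planted <- base::matrix(0L, nrow = length(gene_ids), ncol = length(tipnames),
                          dimnames = list(gene_ids, tipnames))
  for (i in seq_len(nrow(mods))) {
    base_present <- if (mods$lost_with[i] == "cilia") is_ciliated[tipnames]
      else has_motile[tipnames]
    rows <- which(module_of == mods$name[i])
    planted[rows, ] <- rep(as.integer(base_present), each = length(rows))
  }
  if (config$n_background_genes > 0) {
    planted[which(is.na(module_of)), ] <- 1L   # background present root-wide
  }

  # sporadic per-gene Dollo background loss
  if (config$background_loss_prob > 0) {
    n_edge <- nrow(tree$edge)
    n_lost <- rng$rbinom(length(gene_ids), n_edge, config$background_loss_prob)
    for (gi in which(n_lost > 0L)) {
      edges <- rng$sample_int(n_edge, n_lost[gi])
      gone <- colSums(desc[edges, , drop = FALSE] * 1) > 0
      planted[gi, gone] <- 0L
    }
  }

  # reduced-complement lineages: halve the ciliary complement
  reduced <- character()
  ciliary_rows <- which(!is.na(module_of))
  if (config$n_reduced_complement > 0 && length(ciliary_rows)) {
    cil_sp <- tipnames[is_ciliated[tipnames]]
    pick <- cil_sp[rng$sample_int(length(cil_sp),
                                  min(config$n_reduced_complement, length(cil_sp)))]
    for (sp in pick) {
      drop_rows <- ciliary_rows[rng$runif(length(ciliary_rows)) < 0.5]
      planted[drop_rows, sp] <- 0L
    }
    reduced <- pick
  }

  # detection noise (false-negative rate optionally scaled per group)
  observed <- planted
  grp_all <- ifelse(is_euk, grp_of[tipnames], "prokaryote")
  fn_col <- rep(config$false_negative_rate, length(tipnames))
  if (!is.null(config$fn_group_multiplier)) {
    mult <- config$fn_group_multiplier[grp_all]
    mult[is.na(mult)] <- 1
    fn_col <- pmin(1, fn_col * unname(mult))
  }
  if (any(fn_col > 0)) {
    ones <- which(planted == 1L)
    col_of <- ((ones - 1L) %/% nrow(planted)) + 1L
    flip <- ones[rng$runif(length(ones)) < fn_col[col_of]]
    observed[flip] <- 0L
  }
  if (config$false_positive_rate > 0) {
    zeros <- which(planted == 0L)
    flip <- zeros[rng$runif(length(zeros)) < config$false_positive_rate]
    observed[flip] <- 1L
  }

  annotations <- data.frame(
    species_id = tipnames,
    major_group = ifelse(is_euk, grp_of[tipnames], "prokaryote"),
    is_ciliated = unname(is_ciliated[tipnames]),
    has_motile_cilia = unname(has_motile[tipnames]),
    reduced_complement = tipnames %in% reduced,
    display_name = tipnames,
    stringsAsFactors = FALSE
  )
  assert_annotations(annotations)

  trait <- data.frame(species_id = tipnames,
                      ciliated = unname(is_ciliated[tipnames]),
                      motile = unname(has_motile[tipnames]),
                      stringsAsFactors = FALSE)

  list(
    matrix = observed,
    truth = list(tree = tree, trait = trait, planted = planted,
                 modules = module_of[!is.na(module_of)],
                 loss_edges = list(cilia = cil_edges, motility = mot_edges),
                 seed_gene = gene_ids[ciliary_rows[1L]]),
    annotations = annotations
  )
}

abbreviate_group <- function(g) {
  map <- c(opisthokonta = "opi", amoebozoa = "amo", archaeplastida = "arc",
           rhizaria = "rhi", alveolata = "alv", stramenopila = "str",
           discicristata_excavata = "dis", cryptophyta_haptophyta = "cry")
  if (g %in% names(map)) map[[g]] else substr(g, 1L, 3L)
}

# tip indices below every node (tips included as themselves)
node_tip_masks <- function(tree) {
  n_tip <- length(tree$tip.label)
  below <- vector("list", n_tip + tree$Nnode)
  for (t in seq_len(n_tip)) below[[t]] <- t
  po <- ape::reorder.phylo(tree, "postorder")
  for (i in seq_len(nrow(po$edge))) {
    p <- po$edge[i, 1L]; ch <- po$edge[i, 2L]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  below
}

# logical matrix edges x tips: does tip t descend through edge e?
edge_tip_indicator <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_all <- n_tip + tree$Nnode
  below <- vector("list", n_all)
  po <- ape::reorder.phylo(tree, "postorder")
  for (t in seq_len(n_tip)) below[[t]] <- t
  for (i in seq_len(nrow(po$edge))) {
    p <- po$edge[i, 1L]; ch <- po$edge[i, 2L]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  out <- base::matrix(FALSE, nrow = nrow(tree$edge), ncol = n_tip)
  for (e in seq_len(nrow(tree$edge)))
    out[e, below[[tree$edge[e, 2L]]]] <- TRUE
  out
}

#' Fabricate reciprocal hit tables from a presence/absence matrix
#'
#' Produces forward (human -> species) and reverse (species -> human)
#' 12-column-style hit tables whose bidirectional-best-hit calls reproduce
#' the given matrix exactly: each present cell gets a mutually best
#' reciprocal pair (the reverse hit may land on a non-representative
#' isoform, which still counts at the gene level), and a configurable share
#' of absent cells get decoys — either a forward hit whose E-value exceeds
#' the threshold, or an admissible forward hit whose reverse best maps to a
#' different gene. E-values decrease monotonically with bit score within a
#' query's hit list, as in real alignment output.
#'
#' @param matrix Binary profile matrix (the observed cells to reproduce).
#' @param params A [bbh_params()].
#' @param decoy_prob Probability that an absent cell emits a decoy rather
#'   than no hit at all.
#' @param rng_seed Integer seed for decoy placement.
#' @return List with `forward` and `reverse` (named lists of hit tables,
#'   one per species) and `gmap` (the [gene_map()] used; every gene has a
#'   representative isoform `<gene>.p1` and a secondary isoform
#'   `<gene>.p2`).
#' @export
fabricate_hit_tables <- function(matrix, params = bbh_params(),
                                 decoy_prob = 0.3, rng_seed = 1L) {
  assert_profile_matrix(matrix)
  rng <- local_rng(rng_seed)
  genes <- rownames(matrix); species <- colnames(matrix)
  prot1 <- paste0(genes, ".p1"); prot2 <- paste0(genes, ".p2")
  p2g <- stats::setNames(rep(genes, 2L), c(prot1, prot2))
  gmap <- gene_map(p2g, stats::setNames(prot1, genes))
  thr <- params$e_threshold

  forward <- list(); reverse <- list()
  for (s in seq_along(species)) {
    sp <- species[s]
    pres <- matrix[, s] == 1L
    subj <- paste0(sp, "|", genes)

    fq <- character(); fs <- character(); fe <- numeric(); fb <- numeric()
    rq <- character(); rs <- character(); re <- numeric(); rb <- numeric()

    if (any(pres)) {
      g <- which(pres)
      fq <- c(fq, prot1[g]); fs <- c(fs, subj[g])
      fb <- c(fb, rep(300, length(g))); fe <- c(fe, rep(1e-50, length(g)))
      # a weaker admissible second hit to exercise best-hit selection
      other <- g %% length(genes) + 1L
      fq <- c(fq, prot1[g]); fs <- c(fs, subj[other])
      fb <- c(fb, rep(80, length(g))); fe <- c(fe, rep(1e-4, length(g)))
      # reverse best: random isoform of the same gene
      iso <- ifelse(rng$runif(length(g)) < 0.5, prot1[g], prot2[g])
      rq <- c(rq, subj[g]); rs <- c(rs, iso)
      rb <- c(rb, rep(300, length(g))); re <- c(re, rep(1e-50, length(g)))
      rq <- c(rq, subj[g]); rs <- c(rs, prot1[other])
      rb <- c(rb, rep(70, length(g))); re <- c(re, rep(1e-3, length(g)))
    }
    if (any(!pres) && decoy_prob > 0) {
      g <- which(!pres)
      g <- g[rng$runif(length(g)) < decoy_prob]
      if (length(g)) {
        kind <- rng$runif(length(g)) < 0.5
        # decoy A: inadmissible forward hit
        ga <- g[kind]
        if (length(ga)) {
          fq <- c(fq, prot1[ga]); fs <- c(fs, subj[ga])
          fb <- c(fb, rep(40, length(ga)))
          fe <- c(fe, rep(min(1, thr * 10), length(ga)))
        }
        # decoy B: admissible forward, reverse best is a different gene
        gb <- if (length(genes) > 1L) g[!kind] else integer()
        if (length(gb)) {
          other <- gb %% length(genes) + 1L
          fq <- c(fq, prot1[gb]); fs <- c(fs, subj[gb])
          fb <- c(fb, rep(120, length(gb))); fe <- c(fe, rep(1e-6, length(gb)))
          rq <- c(rq, subj[gb]); rs <- c(rs, prot1[other])
          rb <- c(rb, rep(200, length(gb))); re <- c(re, rep(1e-20, length(gb)))
        }
      }
    }
    mk <- function(q, su, e, b) data.frame(
      query_id = q, subject_id = su, e_value = e, bit_score = b,
      species_id = sp,
      pident = "50", length = "100", mismatch = "50", gapopen = "0",
      qstart = "1", qend = "100", sstart = "1", send = "100",
      stringsAsFactors = FALSE)
    forward[[sp]] <- mk(fq, fs, fe, fb)
    reverse[[sp]] <- mk(rq, rs, re, rb)
  }
  list(forward = forward, reverse = reverse, gmap = gmap)
}
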