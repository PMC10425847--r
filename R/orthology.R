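#' Parameters for bidirectional-best-hit orthology calls
#'
#' @param e_threshold Maximum admissible E-value for a hit. The default 0.1
#'   is a deliberately permissive cutoff so that highly divergent orthologs
#'   (core centriolar components are the canonical example) are not dropped;
#'   hits with `e_value <= e_threshold` are admissible.
#' @return A list of class `bbh_params`.
#' @export
bbh_params <- function(e_threshold = 0.1) {
  if (!is.numeric(e_threshold) || length(e_threshold) != 1L || e_threshold <= 0)
    stopf("e_threshold must be a single positive number")
  structure(list(e_threshold = e_threshold), class = "bbh_params")
}

#' Best admissible hit for one query in one proteome
#'
#' Selects the subject with maximal bit score among hits passing the E-value
#' threshold. Ties on bit score are broken by lower E-value, then by
#' lexicographically smaller subject id, so the call is deterministic and
#' independent of input row order.
#'
#' @param hits Hit table rows sharing one query and one subject species.
#' @param params A [bbh_params()] object.
#' @return The winning `subject_id`, or `NA_character_` if no admissible hit.
#' @export
best_hit <- function(hits, params = bbh_params()) {
  if (nrow(hits) == 0L) return(NA_character_)
  sp <- unique(hits$species_id[!is.na(hits$species_id)])
  if (length(sp) > 1L)
    stopf("best_hit expects hits against a single species, got: %s",
          paste(sp, collapse = ", "))
  if (length(unique(hits$query_id)) > 1L)
    stopf("best_hit expects hits for a single query")
  adm <- hits[hits$e_value <= params$e_threshold, , drop = FALSE]
  if (nrow(adm) == 0L) return(NA_character_)
  ord <- order(-adm$bit_score, adm$e_value, adm$subject_id, method = "radix")
  adm$subject_id[ord[1L]]
}

# Vectorised best hit per query over a whole table: returns a named character
# vector query_id -> best subject (admissible hits only).
best_hits_per_query <- function(hits, params) {
  adm <- hits[hits$e_value <= params$e_threshold, , drop = FALSE]
  if (nrow(adm) == 0L) return(stats::setNames(character(), character()))
  ord <- order(adm$query_id, -adm$bit_score, adm$e_value, adm$subject_id,
               method = "radix")
  adm <- adm[ord, , drop = FALSE]
  keep <- !duplicated(adm$query_id)
  stats::setNames(adm$subject_id[keep], adm$query_id[keep])
}

#' Bidirectional-best-hit presence call for one gene in one species
#'
#' A gene is called present (1) in a species when the forward best hit of its
#' representative protein exists and the reverse best hit of that subject
#' maps, through the gene map, back to the same gene (any isoform counts).
#' Otherwise 0.
#'
#' @param gene_id Human gene identifier.
#' @param species_id Target species identifier.
#' @param forward Hit table, human representative proteins vs the species'
#'   proteome.
#' @param reverse Hit table, species proteins vs the human proteome.
#' @param gmap A [gene_map()].
#' @param params A [bbh_params()].
#' @return Integer 0 or 1.
#' @export
bbh_present <- function(gene_id, species_id, forward, reverse, gmap,
                        params = bbh_params()) {
  rep_prot <- gmap$representative[gene_id]
  if (is.na(rep_prot))
    stopf("gene absent from gene map: %s", gene_id)
  fwd <- forward[forward$query_id == rep_prot, , drop = FALSE]
  if (nrow(fwd) && !all(is.na(fwd$species_id)) &&
      !all(fwd$species_id %in% c(NA, species_id)))
    stopf("forward hits contain species other than %s", species_id)
  subj <- best_hit(fwd, params)
  if (is.na(subj)) return(0L)
  rev <- reverse[reverse$query_id == subj, , drop = FALSE]
  back <- best_hit(rev, params)
  if (is.na(back)) return(0L)
  back_gene <- gmap$protein_to_gene[back]
  if (is.na(back_gene)) return(0L)
  as.integer(back_gene == gene_id)
}

#' Build a binary presence/absence profile matrix from hit tables
#'
#' Applies the bidirectional-best-hit rule gene by gene and species by
#' species. The result is deterministic and independent of hit-file row
#' order.
#'
#' @param genes Character vector of gene ids (rows).
#' @param species Character vector of species ids (columns).
#' @param forward_tables Named list (by species) of forward hit tables.
#' @param reverse_tables Named list (by species) of reverse hit tables.
#' @param gmap A [gene_map()].
#' @param params A [bbh_params()].
#' @return Integer matrix genes x species with 0/1 entries.
#' @export
build_profile_matrix <- function(genes, species, forward_tables, reverse_tables,
                                 gmap, params = bbh_params()) {
  miss_f <- setdiff(species, names(forward_tables))
  miss_r <- setdiff(species, names(reverse_tables))
  if (length(miss_f) || length(miss_r))
    stopf("missing hit table(s) for species: %s",
          paste(union(miss_f, miss_r), collapse = ", "))
  if (anyDuplicated(genes)) stopf("duplicate gene ids")
  if (anyDuplicated(species)) stopf("duplicate species ids")
  rep_prot <- gmap$representative[genes]
  if (anyNA(rep_prot))
    stopf("gene(s) absent from gene map: %s",
          paste(genes[is.na(rep_prot)], collapse = ", "))
  m <- matrix(0L, nrow = length(genes), ncol = length(species),
              dimnames = list(genes, species))
  if (!length(genes)) return(m)
  for (sp in species) {
    fwd_best <- best_hits_per_query(forward_tables[[sp]], params)
    rev_best <- best_hits_per_query(reverse_tables[[sp]], params)
    subj <- unname(fwd_best[rep_prot])                 # per gene
    back <- unname(rev_best[subj])                     # reverse best protein
    back_gene <- unname(gmap$protein_to_gene[back])
    m[, sp] <- as.integer(!is.na(back_gene) & back_gene == genes)
  }
  m
}
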