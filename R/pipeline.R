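#' Run the profiling pipeline end to end
#'
#' Orchestrates the eight analysis stages — build or load the matrix,
#' co-cluster both axes, order species ciliated-left, extract the seed
#' cluster, subsampling robustness, Dollo loss counting, loss-pattern
#' classification and function prediction — writing every report plus a
#' TreeView bundle to `out_dir` and recording a manifest (parameters, rng
#' seeds, input/output MD5 digests, package version). Identical config and
#' inputs yield identical digests.
#'
#' @param config Named list or path to a flat key-value config file (see
#'   [read_config()]). Recognised keys: `matrix` (TSV path) or
#'   `simulate = TRUE` (+ `sim_seed`), `annotations` (CSV path; implied by
#'   simulation), `tree` (Newick path; defaults to the group polytomy
#'   tree), `seed_gene` (required unless simulating), `mode`, `param`,
#'   `metric`, `robustness_fractions`, `robustness_seed`, `out_dir`
#'   (required).
#' @return The manifest, an object of class `run_manifest` (list of stage
#'   records), invisibly written to `out_dir/manifest.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  out_dir <- config$out_dir
  if (is.null(out_dir)) stopf("config must name out_dir")
  simulate <- isTRUE(config$simulate)
  if (!simulate && is.null(config$seed_gene))
    stopf("config must name seed_gene (or set simulate = true)")
  if (!simulate && is.null(config$matrix))
    stopf("config must name a matrix TSV (or set simulate = true)")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  manifest <- list(tool_version = as.character(utils::packageVersion("ciliaprofile")),
                   stages = list())
  t_digest <- function(paths) {
    md <- tools::md5sum(paths)
    stats::setNames(as.character(md), basename(names(md)))
  }
  record <- function(name, params, outputs) {
    manifest$stages[[length(manifest$stages) + 1L]] <<-
      list(stage = name, parameters = params, outputs = t_digest(outputs))
  }

  metric <- config$metric %||% "euclidean"
  mode <- config$mode %||% "elbow"
  param <- config$param

  # stage 1: obtain the matrix
  if (simulate) {
    sim_seed <- as.integer(config$sim_seed %||% 1L)
    sc <- if (!is.null(config$sim_config)) config$sim_config
      else sim_config(rng_seed = sim_seed)
    sim <- simulate_ciliome(sc)
    matrix <- sim$matrix
    annotations <- sim$annotations
    tree <- sim$truth$tree
    seed_gene <- config$seed_gene %||% sim$truth$seed_gene
    gene_categories <- sim$truth$modules
    mpath <- file.path(out_dir, "matrix.tsv")
    write_profile_matrix(matrix, mpath)
    apath <- file.path(out_dir, "annotations.csv")
    write_species_annotations(annotations, apath)
    tpath <- file.path(out_dir, "species_tree.nwk")
    ape::write.tree(tree, tpath)
    record("build_matrix", list(source = "simulate", sim_seed = sim_seed),
           c(mpath, apath, tpath))
  } else {
    matrix <- read_profile_matrix(config$matrix)
    annotations <- read_species_annotations(config$annotations)
    tree <- if (!is.null(config$tree)) ape::read.tree(config$tree)
      else group_polytomy_tree(annotations)
    seed_gene <- config$seed_gene
    gene_categories <- if (!is.null(config$gene_categories)) {
      gc <- utils::read.csv(config$gene_categories, stringsAsFactors = FALSE)
      stats::setNames(gc$category, gc$gene_id)
    } else NULL
    record("build_matrix", list(source = config$matrix), config$matrix)
  }

  # stage 2: co-cluster both axes (+ the fitted object used downstream)
  fit <- cilia_profile(matrix, annotations, seed_gene,
                       metric = metric, mode = mode, param = param)
  bundle <- write_treeview_bundle(matrix, fit$gene_dendrogram,
                                  fit$species_dendrogram,
                                  file.path(out_dir, "profile"),
                                  species_order = as.character(fit$species_order))
  record("cluster", list(metric = metric), unname(bundle))

  # stage 3: ciliated-left species order
  opath <- file.path(out_dir, "species_order.txt")
  writeLines(as.character(fit$species_order), opath)
  record("order_leaves", list(objective = attr(fit$species_order, "objective")),
         opath)

  # stage 4: seed cluster
  cpath <- file.path(out_dir, "cluster_members.csv")
  utils::write.csv(data.frame(gene_id = fit$cluster$members), cpath,
                   row.names = FALSE, quote = FALSE)
  gpath <- file.path(out_dir, "growth_trace.csv")
  utils::write.csv(fit$cluster$growth_trace, gpath, row.names = FALSE)
  record("extract", list(seed_gene = seed_gene, mode = mode,
                         param = param %||% NA,
                         cluster_size = length(fit$cluster$members)),
         c(cpath, gpath))

  # stage 5: robustness
  fracs <- config$robustness_fractions %||% c(0.25, 0.5, 0.75)
  rseed <- as.integer(config$robustness_seed %||% 1L)
  rob <- do.call(rbind, lapply(fracs, function(f) {
    r <- robustness_subsample(matrix, annotations, seed_gene,
                              fraction = f, mode = mode, param = param,
                              metric = metric, rng_seed = rseed + round(100 * f),
                              reference = fit$cluster)
    data.frame(fraction_removed = f, species_used = length(r$species_used),
               retained = r$retained_count, reference = r$reference_size)
  }))
  rpath <- file.path(out_dir, "robustness.csv")
  utils::write.csv(rob, rpath, row.names = FALSE)
  record("robustness", list(fractions = fracs, rng_seed = rseed), rpath)

  # stage 6: Dollo losses on the ciliated trait (eukaryotes only)
  euk <- annotations$species_id[annotations$major_group != "prokaryote"]
  euk_tree <- drop_species(tree, setdiff(tree$tip.label, euk))
  trait <- stats::setNames(annotations$is_ciliated,
                           annotations$species_id)[euk_tree$tip.label]
  groups <- stats::setNames(annotations$major_group, annotations$species_id)
  losses <- count_independent_losses(euk_tree, trait, groups)
  lpath <- file.path(out_dir, "losses.csv")
  utils::write.csv(
    data.frame(group = names(losses$per_group_losses) %||% "all",
               losses = if (is.null(losses$per_group_losses))
                 losses$total_losses else unname(losses$per_group_losses)),
    lpath, row.names = FALSE)
  record("losses", list(total = losses$total_losses), lpath)

  # stage 7: loss patterns over gene categories
  if (!is.null(gene_categories)) {
    pat <- classify_loss_patterns(matrix, gene_categories,
                                  species = euk)
    ppath <- file.path(out_dir, "patterns.csv")
    utils::write.csv(data.frame(species_id = rownames(pat$states),
                                pat$states,
                                pattern_id = unname(pat$pattern_id)),
                     ppath, row.names = FALSE)
    record("patterns", list(n_patterns = pat$n_patterns), ppath)
  } else {
    record("patterns", list(skipped = "no gene categories supplied"), character())
  }

  # stage 8: function prediction for cluster members
  pred <- predict_gene_functions(matrix[fit$cluster$members, , drop = FALSE],
                                 annotations)
  dpath <- file.path(out_dir, "predictions.csv")
  utils::write.csv(pred, dpath, row.names = FALSE)
  record("predict", list(n_motility = sum(pred$call == "motility"),
                         n_biogenesis = sum(pred$call == "biogenesis"),
                         n_no_prediction = sum(pred$call == "no_prediction")),
         dpath)

  class(manifest) <- "run_manifest"
  jsonlite::write_json(unclass(manifest),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("Pipeline manifest (version %s): %d stage(s)\n",
              x$tool_version, length(x$stages)))
  for (s in x$stages)
    cat(sprintf("  %-12s -> %d output file(s)\n", s$stage, length(s$outputs)))
  invisible(x)
}
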