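#' Score the worm dye-fill assay
#'
#' Converts mean counts of dye-filled amphid (head, 0-12) and phasmid
#' (tail, 0-4) neurons into 0-4 phenotype scores and reports the strongest
#' of the two as the overall phenotype. The printed bin edges leave small
#' gaps at one-decimal resolution (e.g. 10.9-11); bins are therefore
#' half-open with the gap attached to the adjacent worse score:
#' amphids `[11.5,12] -> 0`, `[11,11.5) -> 1`, `[10,11) -> 2`,
#' `[6,10) -> 3`, `[0,6) -> 4`; phasmids `[3.85,4] -> 0`, `[3.75,3.85) -> 1`,
#' `[3.5,3.75) -> 2`, `[0.25,3.5) -> 3`, `[0,0.25) -> 4`.
#'
#' @param amphid_mean Mean number of dye-filled amphid neurons, in `[0, 12]`.
#' @param phasmid_mean Mean number of dye-filled phasmid neurons, in `[0, 4]`.
#' @return List with integer `amphid_score`, `phasmid_score`, `overall`.
#' @examples
#' score_dyefill(4.3, 0.3)  # overall dye-fill score 4
#' @export
score_dyefill <- function(amphid_mean, phasmid_mean) {
  if (!is.finite(amphid_mean) || amphid_mean < 0 || amphid_mean > 12)
    stopf("amphid mean out of range [0, 12]: %s", amphid_mean)
  if (!is.finite(phasmid_mean) || phasmid_mean < 0 || phasmid_mean > 4)
    stopf("phasmid mean out of range [0, 4]: %s", phasmid_mean)
  amphid <- bin_score(amphid_mean, c(6, 10, 11, 11.5))
  phasmid <- bin_score(phasmid_mean, c(0.25, 3.5, 3.75, 3.85))
  list(amphid_score = amphid, phasmid_score = phasmid,
       overall = max(amphid, phasmid))
}

# score 4 below cuts[1], ..., 0 at/above cuts[4]; half-open at lower edges
bin_score <- function(x, cuts) {
  4L - sum(x >= cuts)
}

#' Score male fertility from pupae counts
#'
#' Bins the number of pupae produced in the fertility test cross:
#' `>= 90 -> 0`, `60-89 -> 1`, `30-59 -> 2`, `10-29 -> 3`, `< 10 -> 4`
#' (control crosses average around 120 pupae).
#'
#' @param pupae_count Nonnegative pupae count.
#' @return Integer score 0-4.
#' @examples
#' score_fertility(120)
#' @export
score_fertility <- function(pupae_count) {
  if (!is.finite(pupae_count) || pupae_count < 0)
    stopf("pupae count must be nonnegative: %s", pupae_count)
  bin_score(pupae_count, c(10, 30, 60, 90))
}

#' Score a value against a registered phenotype rubric
#'
#' Deterministic bin lookup for the remaining printed rubrics:
#' \describe{
#'   \item{`viability`}{fraction of dead progeny: complete lethality (1)
#'     -> 4, strong lethality with a few survivors (>= 0.9) -> 3, half or
#'     more dead -> 2, dead individuals but less than half -> 1 (requires
#'     `n_affected >= 3` when counts are supplied), else 0.}
#'   \item{`flight`}{fraction of flies unable to fly: more than half -> 2
#'     (strict), otherwise 1 when more than 3 non-fliers
#'     (`n_affected > 3`), else 0. Covers the weak end of the
#'     uncoordination scale; 4 (sticking to the food) and 3 (at the bottom,
#'     unable to climb) are categorical observations passed via
#'     `rubric = "uncoordination"`.}
#'   \item{`uncoordination`}{categorical: `"stuck_to_food"` -> 4,
#'     `"bottom_no_climb"` -> 3, numeric fractions are delegated to the
#'     flight rubric.}
#'   \item{`wing`}{fraction with wing-posture defects: all -> 4, more than
#'     half -> 3, exactly half -> 2, several (`n_affected >= 3`) -> 1,
#'     else 0.}
#'   \item{`spermiogenesis`}{integer stage score passed through after
#'     validation: 0 normal ... 3 all nuclei/cones aberrant, 4 missing
#'     stage.}
#'   \item{`scolopidia`}{fraction of morphologically defective scolopidia:
#'     abnormal (1) iff strictly greater than 0.20, else normal (0).}
#' }
#'
#' @param value Numeric value (fraction, count or stage) or, for
#'   `uncoordination`, a category string.
#' @param rubric_name One of `"viability"`, `"flight"`, `"uncoordination"`,
#'   `"wing"`, `"spermiogenesis"`, `"scolopidia"`.
#' @param n_affected Optional count of affected individuals, used by the
#'   "several/few" clauses.
#' @return Integer score (0-4; `scolopidia` returns 0/1).
#' @examples
#' score_rubric(0.25, "scolopidia")  # abnormal
#' score_rubric(0.20, "scolopidia")  # normal: strict threshold
#' @export
score_rubric <- function(value, rubric_name, n_affected = NULL) {
  switch(rubric_name,
    viability = {
      f <- check_fraction(value, rubric_name)
      if (f >= 1) 4L
      else if (f >= 0.9) 3L
      else if (f >= 0.5) 2L
      else if ((is.null(n_affected) || n_affected >= 3L) && f > 0) 1L
      else 0L
    },
    flight = {
      f <- check_fraction(value, rubric_name)
      if (f > 0.5) 2L
      else if (!is.null(n_affected) && n_affected > 3L && f > 0) 1L
      else if (is.null(n_affected) && f > 0) 1L
      else 0L
    },
    uncoordination = {
      if (is.character(value)) {
        switch(value,
               stuck_to_food = 4L,
               bottom_no_climb = 3L,
               stopf("unknown uncoordination category: %s", value))
      } else score_rubric(value, "flight", n_affected)
    },
    wing = {
      f <- check_fraction(value, rubric_name)
      if (f >= 1) 4L
      else if (f > 0.5) 3L
      else if (abs(f - 0.5) < 1e-9) 2L
      else if ((is.null(n_affected) || n_affected >= 3L) && f > 0) 1L
      else 0L
    },
    spermiogenesis = {
      if (!value %in% 0:4) stopf("spermiogenesis stage score must be 0-4")
      as.integer(value)
    },
    scolopidia = {
      f <- check_fraction(value, rubric_name)
      as.integer(f > 0.20)
    },
    stopf("unknown rubric: %s", rubric_name)
  )
}

check_fraction <- function(x, what) {
  if (!is.numeric(x) || !is.finite(x) || x < 0 || x > 1)
    stopf("%s expects a fraction in [0, 1], got %s", what, x)
  x
}

#' Aggregate screen significance by gene novelty
#'
#' A gene counts as significant when any of its assay scores is strictly
#' greater than 1. Missing assays (NA) are skipped, not treated as zero.
#' Counts and integer percentages are reported separately for known and
#' novel genes.
#'
#' @param records `data.frame` with columns `gene_id`, `novelty`
#'   (`"known"`/`"novel"`) and one or more numeric score columns
#'   (0-4 scales).
#' @param score_columns Which columns to aggregate over (default: all
#'   numeric columns other than `gene_id`/`novelty`).
#' @return `data.frame` with one row per novelty class: `novelty`,
#'   `n_genes`, `n_significant`, `percent_significant` (integer percent).
#' @export
aggregate_significance <- function(records, score_columns = NULL) {
  if (is.null(records$gene_id) || is.null(records$novelty))
    stopf("records need gene_id and novelty columns")
  if (anyNA(records$novelty) || !all(records$novelty %in% c("known", "novel")))
    stopf("every gene needs a novelty annotation of 'known' or 'novel'")
  score_columns <- score_columns %||%
    setdiff(names(records)[vapply(records, is.numeric, TRUE)],
            c("gene_id", "novelty"))
  if (!length(score_columns)) stopf("no score columns to aggregate")
  scores <- as.matrix(records[, score_columns, drop = FALSE])
  bad <- !is.na(scores) & !(scores %in% 0:4)
  if (any(bad)) stopf("scores must be integers 0-4 (or NA for missing assays)")
  sig <- apply(scores, 1L, function(r) {
    r <- r[!is.na(r)]
    length(r) > 0L && any(r > 1)
  })
  out <- do.call(rbind, lapply(c("known", "novel"), function(nv) {
    sel <- records$novelty == nv
    n <- sum(sel)
    k <- sum(sig[sel])
    data.frame(novelty = nv, n_genes = n, n_significant = k,
               percent_significant = if (n) as.integer(round(100 * k / n)) else NA_integer_,
               stringsAsFactors = FALSE)
  }))
  out
}
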