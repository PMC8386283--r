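# The five-criterion definition of a rare, predicted-pathogenic candidate
# variant, applied to the proband call of each normalized trio record.

#' Genotype-call quality criterion
#'
#' A call passes when read depth strictly exceeds the depth threshold and
#' the genotype-score/depth ratio strictly exceeds the ratio threshold
#' (defaults: depth > 10 reads, ratio > 0.5). Missing genotypes never pass.
#'
#' @param gt genotype enum vector.
#' @param depth read depths.
#' @param score genotype quality scores (MPG-style).
#' @param thresholds a [filter_thresholds()].
#' @return logical vector.
#' @examples
#' passes_quality("het", depth = 11, score = 6)   # ratio 0.545 -> TRUE
#' passes_quality("het", depth = 9, score = 8.1)  # depth bound -> FALSE
#' @export
passes_quality <- function(gt, depth, score, thresholds = filter_thresholds()) {
  ok <- !is.na(gt) & gt != "missing" & !is.na(depth) & !is.na(score) &
    depth > thresholds$min_depth_exclusive &
    score / depth > thresholds$min_quality_ratio_exclusive
  ok & depth > 0
}

#' Population-rarity criterion
#'
#' Passes when the population allele frequency is strictly below the cutoff
#' (absent frequency means "not found" and counts as 0), and — only when
#' the proband is homozygous or hemizygous for the variant — the database
#' homozygote count is strictly below its cutoff.
#'
#' @param af population allele frequencies (`NA` = not found).
#' @param nhomalt database homozygote counts (`NA` = not found).
#' @param proband_gt proband genotype enum vector.
#' @param thresholds a [filter_thresholds()].
#' @return logical vector.
#' @export
passes_rarity <- function(af, nhomalt, proband_gt,
                          thresholds = filter_thresholds()) {
  rare <- is.na(af) | af < thresholds$max_af_exclusive
  hom <- proband_gt %in% c("hom_alt", "hemi_alt")
  hom_ok <- !hom | is.na(nhomalt) | nhomalt < thresholds$max_nhomalt_exclusive
  rare & hom_ok
}

#' Protein-altering consequence criterion
#'
#' True for consequence classes that change the predicted amino-acid
#' sequence: missense, nonsense, frameshift, in-frame indel, and canonical
#' splice-site variants.
#'
#' @param consequence consequence enum vector.
#' @return logical vector.
#' @export
is_protein_altering <- function(consequence) {
  consequence %in% c("missense", "nonsense", "frameshift", "inframe_indel",
                     "splice_canonical")
}

#' Predictor-consensus criterion
#'
#' Missense variants pass when at least `min_pathogenic_votes` of the three
#' predictors (SIFT, PolyPhen2, MutationTaster) call them damaging; an
#' absent call is not a damaging vote. Truncating and indel classes
#' (nonsense, frameshift, in-frame indel, canonical splice) pass
#' structurally — the predictors largely cannot score them — and are
#' flagged `truncating_bypass`.
#'
#' @param consequence consequence enum vector.
#' @param sift,polyphen,mutation_taster predictor call vectors
#'   (`"damaging"`, `"tolerated"`/`"benign"`, `"absent"`).
#' @param thresholds a [filter_thresholds()].
#' @return a data.frame with logical columns `pathogenic` and
#'   `truncating_bypass`.
#' @export
is_predicted_pathogenic <- function(consequence, sift, polyphen,
                                    mutation_taster,
                                    thresholds = filter_thresholds()) {
  votes <- (sift == "damaging") + (polyphen == "damaging") +
    (mutation_taster == "damaging")
  truncating <- consequence %in% c("nonsense", "frameshift", "inframe_indel",
                                   "splice_canonical")
  pathogenic <- (consequence == "missense" &
                   votes >= thresholds$min_pathogenic_votes) | truncating
  data.frame(pathogenic = pathogenic, truncating_bypass = truncating)
}

#' Apply the five candidate criteria to trio records
#'
#' Keeps exactly the records where the proband carries the alternate allele
#' and the quality, rarity, protein-altering and predictor-consensus
#' criteria all hold on the proband call. The published criterion of visual
#' alignment inspection is replaced by the quality thresholds; candidates
#' with a quality ratio below `thresholds$review_ratio` are additionally
#' flagged `review_recommended`. Parental quality is not evaluated here —
#' the inheritance stage enforces it where a classification depends on a
#' parental genotype.
#'
#' @param records tibble of trio variant records from [read_trio_vcf()] or
#'   the cohort simulator.
#' @param thresholds a [filter_thresholds()].
#' @return tibble of candidate rows with added per-criterion logical columns
#'   (`crit_quality`, `crit_rarity`, `crit_protein`, `crit_predicted`),
#'   `truncating_bypass` and `review_recommended`; attribute
#'   `criteria_counts` logs how many carried records passed each criterion.
#' @export
filter_candidates <- function(records, thresholds = filter_thresholds()) {
  carrier <- gt_carries(records$pro_gt)
  carrier[is.na(carrier)] <- FALSE

  q <- passes_quality(records$pro_gt, records$pro_dp, records$pro_score,
                      thresholds)
  r <- passes_rarity(records$population_af, records$population_nhomalt,
                     records$pro_gt, thresholds)
  p <- is_protein_altering(records$consequence)
  pred <- is_predicted_pathogenic(records$consequence, records$sift,
                                  records$polyphen, records$mutation_taster,
                                  thresholds)

  keep <- carrier & q & r & p & pred$pathogenic
  out <- records[keep, , drop = FALSE]
  out$crit_quality <- q[keep]
  out$crit_rarity <- r[keep]
  out$crit_protein <- p[keep]
  out$crit_predicted <- pred$pathogenic[keep]
  out$truncating_bypass <- pred$truncating_bypass[keep]
  out$review_recommended <- !is.na(out$pro_ratio) &
    out$pro_ratio < thresholds$review_ratio
  attr(out, "criteria_counts") <- c(
    carrier = sum(carrier), quality = sum(carrier & q),
    rarity = sum(carrier & r), protein_altering = sum(carrier & p),
    predicted_pathogenic = sum(carrier & pred$pathogenic),
    candidates = sum(keep)
  )
  out
}
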