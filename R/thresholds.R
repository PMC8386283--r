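#' Candidate-variant filter thresholds
#'
#' Houses every numeric cutoff of the five-criterion candidate definition.
#' All comparisons downstream are strict, matching the published wording:
#' coverage `> 10` reads, genotype-score/coverage ratio `> 0.5`, population
#' allele frequency `< 1%`, homozygote count in the reference database
#' `< 2`, and at least 2 of 3 predictor algorithms calling the variant
#' damaging.
#'
#' @param min_depth_exclusive read depth must exceed this (default 10).
#' @param min_quality_ratio_exclusive genotype-score / depth must exceed
#'   this (default 0.5). The score is an MPG-style genotype confidence;
#'   with a GQ dialect the same ratio is applied to GQ.
#' @param max_af_exclusive population allele frequency must be below this
#'   (default 0.01). Absent frequency counts as 0 ("not found").
#' @param max_nhomalt_exclusive for homozygous/hemizygous proband genotypes,
#'   the database homozygote count must be below this (default 2).
#' @param min_pathogenic_votes damaging calls required among the three
#'   predictors (SIFT, PolyPhen2, MutationTaster) for missense variants
#'   (default 2).
#' @param review_ratio candidates with quality ratio below this are flagged
#'   `review_recommended` in place of manual alignment inspection
#'   (default 0.6).
#' @return an object of class `filter_thresholds`.
#' @examples
#' filter_thresholds()
#' filter_thresholds(max_af_exclusive = 0.001)
#' @export
filter_thresholds <- function(min_depth_exclusive = 10L,
                              min_quality_ratio_exclusive = 0.5,
                              max_af_exclusive = 0.01,
                              max_nhomalt_exclusive = 2L,
                              min_pathogenic_votes = 2L,
                              review_ratio = 0.6) {
  stopifnot(
    min_depth_exclusive > 0, min_quality_ratio_exclusive > 0,
    max_af_exclusive > 0, max_nhomalt_exclusive > 0,
    min_pathogenic_votes > 0, min_pathogenic_votes <= 3
  )
  structure(
    list(
      min_depth_exclusive = as.integer(min_depth_exclusive),
      min_quality_ratio_exclusive = min_quality_ratio_exclusive,
      max_af_exclusive = max_af_exclusive,
      max_nhomalt_exclusive = as.integer(max_nhomalt_exclusive),
      min_pathogenic_votes = as.integer(min_pathogenic_votes),
      review_ratio = review_ratio
    ),
    class = "filter_thresholds"
  )
}

#' @export
print.filter_thresholds <- function(x, ...) {
  cat("Candidate filter thresholds (all strict):\n")
  cat(sprintf("  depth > %d reads; score/depth > %g\n",
              x$min_depth_exclusive, x$min_quality_ratio_exclusive))
  cat(sprintf("  population AF < %g; homozygote count < %d (hom/hemi proband)\n",
              x$max_af_exclusive, x$max_nhomalt_exclusive))
  cat(sprintf("  damaging predictor votes >= %d of 3 (missense)\n",
              x$min_pathogenic_votes))
  invisible(x)
}
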