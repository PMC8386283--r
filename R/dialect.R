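#' Annotation dialect for trio VCFs
#'
#' Names the INFO and FORMAT keys under which the reader finds annotations.
#' The default dialect uses simple per-allele INFO keys (`GENE`,
#' `CSQ_CLASS`, `GNOMAD_AF`, `GNOMAD_NHOMALT`, `SIFT`, `POLYPHEN`,
#' `MTASTER`) and an MPG-style genotype score with `GQ` fallback; the
#' criterion only needs a score-to-depth ratio, so either key works.
#'
#' @param gene,consequence,af,nhomalt,sift,polyphen,mutation_taster INFO key
#'   names. Multiallelic values may be comma-separated per alternate allele.
#' @param quality_keys FORMAT keys tried in order for the genotype score.
#' @param depth_key FORMAT key for read depth.
#' @param annotation_fun optional hook replacing INFO parsing: a
#'   `function(info, allele_index)` taking the raw INFO strings and 1-based
#'   alternate-allele indices of the already-split biallelic records, and
#'   returning a data.frame with columns `gene`, `consequence`,
#'   `population_af`, `population_nhomalt`, `sift`, `polyphen`,
#'   `mutation_taster`. Use this to consume e.g. VEP-style CSQ strings.
#' @return an object of class `vcf_dialect`.
#' @export
vcf_dialect <- function(gene = "GENE", consequence = "CSQ_CLASS",
                        af = "GNOMAD_AF", nhomalt = "GNOMAD_NHOMALT",
                        sift = "SIFT", polyphen = "POLYPHEN",
                        mutation_taster = "MTASTER",
                        quality_keys = c("MPG", "GQ"),
                        depth_key = "DP",
                        annotation_fun = NULL) {
  structure(
    list(gene = gene, consequence = consequence, af = af, nhomalt = nhomalt,
         sift = sift, polyphen = polyphen, mutation_taster = mutation_taster,
         quality_keys = quality_keys, depth_key = depth_key,
         annotation_fun = annotation_fun),
    class = "vcf_dialect"
  )
}

# Extract `key=value` from raw INFO strings; NA where absent.
#' @keywords internal
info_field <- function(info, key) {
  pat <- paste0("(?:^|;)", key, "=([^;]*)")
  m <- regmatches(info, regexpr(pat, info, perl = TRUE))
  out <- rep(NA_character_, length(info))
  hit <- grepl(pat, info, perl = TRUE)
  out[hit] <- sub(pat, "\\1", m, perl = TRUE)
  out
}

# Pick the allele_index-th comma-separated element (per-allele INFO values);
# scalar values apply to every allele.
#' @keywords internal
pick_allele <- function(value, allele_index) {
  parts <- strsplit(value, ",", fixed = TRUE)
  mapply(function(p, k) {
    if (length(p) == 0 || all(is.na(p))) return(NA_character_)
    if (length(p) == 1) return(p[[1]])
    if (k <= length(p)) p[[k]] else NA_character_
  }, parts, allele_index, USE.NAMES = FALSE)
}

#' @keywords internal
norm_predictor <- function(x) {
  x <- tolower(as.character(x))
  x[is.na(x) | x == "" | x == "."] <- "absent"
  x[!x %in% c("damaging", "tolerated", "benign", "absent")] <- "absent"
  x
}

#' @keywords internal
norm_consequence <- function(x) {
  x <- tolower(as.character(x))
  x[is.na(x) | !x %in% CONSEQUENCE_LEVELS] <- "other"
  x
}
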