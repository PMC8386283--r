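# Transmission classification within a trio and enumeration of gene-level
# monogenic candidates under the fully penetrant models: autosomal
# recessive (homozygous or compound heterozygous), X-linked recessive
# (male probands), and de novo.

INHERITANCE_LEVELS <- c("de_novo", "maternal", "paternal",
                        "biparental_homozygous", "hemizygous_maternal",
                        "inconsistent", "unresolved")

#' Classify the transmission of each variant within a trio
#'
#' Assigns one category per record:
#' * `de_novo` — proband heterozygous (or hemizygous on male non-PAR X)
#'   with both parents confidently non-carriers;
#' * `maternal` / `paternal` — proband heterozygous and exactly that parent
#'   carries the allele;
#' * `biparental_homozygous` — proband homozygous with each parent
#'   contributing at least one alternate allele;
#' * `hemizygous_maternal` — male proband hemizygous on non-PAR X, mother
#'   heterozygous (unaffected carrier), father non-carrier;
#' * `inconsistent` — the triple is impossible under Mendelian transmission
#'   (other than the de novo pattern);
#' * `unresolved` — everything else: missing genotypes, a parental call
#'   failing the quality thresholds, or phase-ambiguous configurations
#'   (e.g. all three members heterozygous).
#'
#' Both parental calls must pass the quality criterion before any definite
#' category is assigned; parental dropout therefore yields `unresolved`,
#' never a false de novo. Male-X hemizygous variants with a carrier mother
#' but mother homozygous or a carrier father are `unresolved`: they are
#' Mendelian-consistent but incompatible with a fully penetrant X-linked
#' recessive model given two unaffected parents.
#'
#' @param records tibble of trio variant records.
#' @param proband_sex `"male"` or `"female"`.
#' @param thresholds a [filter_thresholds()] used for the parental quality
#'   gate.
#' @param par PAR intervals; PAR sites are treated as autosomal.
#' @return character vector of categories, one per record.
#' @export
classify_transmission <- function(records, proband_sex,
                                  thresholds = filter_thresholds(),
                                  par = par_intervals("GRCh37")) {
  pro <- records$pro_gt; mo <- records$mo_gt; fa <- records$fa_gt
  n <- nrow(records)
  out <- rep("unresolved", n)

  known <- pro != "missing" & mo != "missing" & fa != "missing"
  mo_q <- passes_quality(mo, records$mo_dp, records$mo_score, thresholds)
  fa_q <- passes_quality(fa, records$fa_dp, records$fa_score, thresholds)
  gated <- known & mo_q & fa_q

  cons <- mendel_consistent(records, proband_sex, par)
  hemi <- is_male_hemi_site(records$chrom, records$pos, par)
  male_x <- hemi & proband_sex == "male"

  mo_carrier <- gt_carries(mo)
  fa_carrier <- gt_carries(fa)

  de_novo <- gated &
    ((!male_x & pro == "het") | (male_x & pro == "hemi_alt")) &
    !mo_carrier & !fa_carrier
  hemi_mat <- gated & male_x & pro == "hemi_alt" & mo == "het" & !fa_carrier
  bip_hom <- gated & !male_x & pro == "hom_alt" & mo_carrier & fa_carrier
  maternal <- gated & !male_x & pro == "het" & mo_carrier & !fa_carrier
  paternal <- gated & !male_x & pro == "het" & !mo_carrier & fa_carrier
  inconsistent <- gated & !is.na(cons) & !cons & !de_novo

  out[inconsistent] <- "inconsistent"
  out[bip_hom] <- "biparental_homozygous"
  out[maternal] <- "maternal"
  out[paternal] <- "paternal"
  out[hemi_mat] <- "hemizygous_maternal"
  out[de_novo] <- "de_novo"
  out
}

# Collapse a candidate subset into one gene-level row.
#' @keywords internal
gene_candidate_row <- function(trio_id, gene, mode, sub) {
  tibble::tibble(
    trio_id = trio_id, gene = gene, mode = mode,
    n_variants = nrow(sub),
    variants = paste(sub$chrom, sub$pos, sub$ref, sub$alt,
                     sep = ":", collapse = ";")
  )
}

#' Find compound-heterozygous gene candidates in one trio
#'
#' A gene qualifies when the proband carries at least one heterozygous
#' candidate inherited from the mother and at least one from the father
#' (trans configuration by parental transmission; variants heterozygous in
#' both parents are phase-ambiguous and never contribute). One gene-level
#' candidate is emitted per qualifying gene, listing all maternal and
#' paternal variants.
#'
#' @param candidates tibble of candidate variants for one trio with a
#'   `category` column from [classify_transmission()].
#' @return tibble with columns `trio_id`, `gene`, `mode`
#'   (`"AR_compound_het"`), `n_variants`, `variants`.
#' @export
find_compound_het <- function(candidates) {
  empty <- tibble::tibble(trio_id = character(), gene = character(),
                          mode = character(), n_variants = integer(),
                          variants = character())
  ch <- candidates[candidates$category %in% c("maternal", "paternal") &
                     candidates$pro_gt == "het" & !is.na(candidates$gene), ,
                   drop = FALSE]
  if (nrow(ch) == 0) return(empty)
  out <- lapply(split(ch, ch$gene), function(sub) {
    if (any(sub$category == "maternal") && any(sub$category == "paternal")) {
      gene_candidate_row(sub$trio_id[1], sub$gene[1], "AR_compound_het", sub)
    }
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) empty else dplyr::arrange(res, gene)
}

#' Enumerate gene-level monogenic candidates for one trio
#'
#' Unions the four fully penetrant models: de novo singletons, autosomal
#' recessive homozygotes (biparental-homozygous transmission; homozygous X
#' variants in female probands count here too), compound heterozygotes from
#' [find_compound_het()], and X-linked recessive hemizygotes (male probands
#' only). One candidate per (gene, mode), sorted by gene.
#'
#' @param candidates tibble of candidate variants for one trio, already
#'   carrying a `category` column from [classify_transmission()].
#' @param trio_id trio identifier stamped on the output (defaults to the
#'   records' own `trio_id`).
#' @return tibble with columns `trio_id`, `gene`, `mode`, `n_variants`,
#'   `variants`.
#' @export
monogenic_candidates <- function(candidates, trio_id = NULL) {
  if (is.null(trio_id) && nrow(candidates) > 0) {
    trio_id <- candidates$trio_id[1]
  }
  singletons <- function(cat, mode) {
    sub <- candidates[candidates$category == cat & !is.na(candidates$gene), ,
                      drop = FALSE]
    if (nrow(sub) == 0) return(NULL)
    dplyr::bind_rows(lapply(split(sub, sub$gene), function(g) {
      gene_candidate_row(trio_id, g$gene[1], mode, g)
    }))
  }
  out <- dplyr::bind_rows(
    singletons("de_novo", "de_novo"),
    singletons("biparental_homozygous", "AR_homozygous"),
    find_compound_het(candidates),
    singletons("hemizygous_maternal", "XLR")
  )
  if (nrow(out) == 0) {
    return(tibble::tibble(trio_id = character(), gene = character(),
                          mode = character(), n_variants = integer(),
                          variants = character()))
  }
  out <- dplyr::distinct(out, trio_id, gene, mode, .keep_all = TRUE)
  dplyr::arrange(out, gene, mode)
}
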