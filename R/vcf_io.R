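# Reading per-trio annotated VCFs into normalized biallelic trio records.
# Parsing is delegated to vcfR; this file owns multiallelic splitting,
# genotype normalization (including male hemizygosity on non-PAR X) and the
# annotation dialect.

GT_PATTERN <- "^(\\.|[0-9]+)([/|](\\.|[0-9]+))?$"

# Recode a VCF GT string against one alternate allele index: tokens equal to
# `k` become "1", other called alleles "0", "." stays missing. Phase
# separators are preserved.
#' @keywords internal
recode_gt_vs_allele <- function(gt, k) {
  mapply(function(g, kk) {
    if (is.na(g)) return(NA_character_)
    sep <- if (grepl("|", g, fixed = TRUE)) "|" else "/"
    tok <- strsplit(g, "[/|]")[[1]]
    tok <- ifelse(tok == ".", ".", ifelse(tok == as.character(kk), "1", "0"))
    paste(tok, collapse = sep)
  }, gt, k, USE.NAMES = FALSE)
}

#' Split multiallelic VCF rows into biallelic records
#'
#' Expands each raw row into one row per alternate allele. Genotype strings
#' in the columns named by `gt_cols` are recoded against the focal allele
#' (other alternate alleles collapse to non-carrier), and an `allele_index`
#' column records which comma-separated annotation element belongs to each
#' split record. Rows containing a genotype that references an allele index
#' beyond the ALT list (or an unparseable genotype) are counted, reported
#' and dropped.
#'
#' @param raw data.frame with at least `chrom`, `pos`, `ref`, `alt`
#'   (possibly comma-separated) and one or more genotype-string columns.
#' @param gt_cols names of the genotype-string columns.
#' @return the expanded data.frame with single-allele `alt` and an
#'   `allele_index` column; attribute `n_skipped` counts dropped input rows.
#' @examples
#' raw <- data.frame(chrom = "1", pos = 100, ref = "C", alt = "A,G",
#'                   gt = "1/2", stringsAsFactors = FALSE)
#' split_multiallelic(raw, gt_cols = "gt")
#' @export
split_multiallelic <- function(raw, gt_cols) {
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(raw)),
            all(gt_cols %in% names(raw)))
  alts <- strsplit(as.character(raw$alt), ",", fixed = TRUE)
  n_alt <- lengths(alts)

  # record-level validation of every genotype string
  bad <- rep(FALSE, nrow(raw))
  for (col in gt_cols) {
    g <- as.character(raw[[col]])
    ok <- is.na(g) | grepl(GT_PATTERN, g)
    idx <- suppressWarnings(
      vapply(strsplit(ifelse(is.na(g), ".", g), "[/|]"),
             function(tok) max(c(0, as.numeric(tok[tok != "."]))), numeric(1))
    )
    bad <- bad | !ok | (idx > n_alt)
  }
  if (any(bad)) {
    warning(sprintf("skipping %d record(s) with malformed genotypes", sum(bad)))
    raw <- raw[!bad, , drop = FALSE]
    alts <- alts[!bad]
    n_alt <- n_alt[!bad]
  }

  take <- rep(seq_len(nrow(raw)), n_alt)
  out <- raw[take, , drop = FALSE]
  out$allele_index <- sequence(n_alt)
  out$alt <- unlist(alts)
  for (col in gt_cols) {
    out[[col]] <- recode_gt_vs_allele(as.character(out[[col]]), out$allele_index)
  }
  rownames(out) <- NULL
  attr(out, "n_skipped") <- sum(bad)
  out
}

# Map a biallelic GT string to the genotype enum. `male_hemi` marks samples
# on non-PAR X (or Y) in males, where both haploid "1" and diploid "1/1"
# are accepted as hemizygous; a heterozygous call there is uninterpretable
# and becomes missing.
#' @keywords internal
gt_string_to_enum <- function(gt, male_hemi = FALSE) {
  male_hemi <- rep_len(male_hemi, length(gt))
  tok <- strsplit(ifelse(is.na(gt), ".", gt), "[/|]")
  n_miss <- vapply(tok, function(t) sum(t == "."), integer(1))
  n_alt <- vapply(tok, function(t) sum(t == "1"), integer(1))
  n_tok <- lengths(tok)

  out <- rep("missing", length(gt))
  dip <- n_miss == 0 & n_tok == 2
  hap <- n_miss == 0 & n_tok == 1
  out[dip & n_alt == 0] <- "hom_ref"
  out[dip & n_alt == 1] <- "het"
  out[dip & n_alt == 2] <- "hom_alt"
  # haploid calls outside hemizygous context are uninterpretable
  out[hap & !male_hemi] <- "missing"
  out[hap & male_hemi & n_alt == 0] <- "hemi_ref"
  out[hap & male_hemi & n_alt == 1] <- "hemi_alt"
  out[dip & male_hemi & n_alt == 0] <- "hemi_ref"
  out[dip & male_hemi & n_alt == 2] <- "hemi_alt"
  out[dip & male_hemi & n_alt == 1] <- "missing"
  out
}

#' @keywords internal
extract_format_num <- function(vcf, key) {
  fmt <- vcf@gt[, 1]
  if (!any(grepl(paste0("(^|:)", key, "(:|$)"), fmt))) {
    m <- matrix(NA_real_, nrow = nrow(vcf@gt), ncol = ncol(vcf@gt) - 1L)
    colnames(m) <- colnames(vcf@gt)[-1]
    return(m)
  }
  suppressWarnings(vcfR::extract.gt(vcf, element = key, as.numeric = TRUE))
}

#' Read a trio's annotated VCF into normalized biallelic records
#'
#' Parses a VCF (plain or bgzipped) with vcfR, checks that the three trio
#' samples are present, expands multiallelic rows via
#' [split_multiallelic()], normalizes genotypes to the package's genotype
#' vocabulary (male probands and fathers are hemizygous on non-PAR X), and
#' attaches annotations per the dialect. Missing annotation keys map to
#' `NA` / `"absent"`; an absent population frequency means "not found in
#' the reference database" and is treated as frequency 0 by the filters.
#'
#' @param path VCF path.
#' @param trio one-row trio as from [read_pedigree()].
#' @param dialect a [vcf_dialect()].
#' @param par PAR intervals, see [par_intervals()].
#' @return tibble of trio variant records, one per biallelic site, with
#'   per-member genotype (`pro_gt`, `mo_gt`, `fa_gt`), depth (`*_dp`),
#'   genotype score (`*_score`) and quality ratio (`*_ratio`) columns plus
#'   annotation columns; attribute `n_skipped` counts malformed records.
#' @export
read_trio_vcf <- function(path, trio, dialect = vcf_dialect(),
                          par = par_intervals("GRCh37")) {
  stopifnot(file.exists(path), nrow(trio) == 1)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  samples <- colnames(vcf@gt)[-1]
  for (who in c("proband_id", "mother_id", "father_id")) {
    if (!trio[[who]] %in% samples) {
      stop(sprintf("sample '%s' (%s) not found in VCF header of %s",
                   trio[[who]], sub("_id$", "", who), path))
    }
  }

  gt_raw <- suppressWarnings(vcfR::extract.gt(vcf, element = "GT"))
  rownames(gt_raw) <- NULL
  dp <- extract_format_num(vcf, dialect$depth_key)
  rownames(dp) <- NULL
  score <- matrix(NA_real_, nrow = nrow(dp), ncol = ncol(dp),
                  dimnames = dimnames(dp))
  for (key in dialect$quality_keys) {
    s <- extract_format_num(vcf, key)
    rownames(s) <- NULL
    fill <- is.na(score)
    score[fill] <- s[fill]
  }

  raw <- data.frame(
    chrom = normalize_chrom(vcf@fix[, "CHROM"]),
    pos = as.integer(vcf@fix[, "POS"]),
    ref = vcf@fix[, "REF"],
    alt = vcf@fix[, "ALT"],
    info = vcf@fix[, "INFO"],
    row = seq_len(nrow(vcf@fix)),
    gt_pro = gt_raw[, trio$proband_id],
    gt_mo = gt_raw[, trio$mother_id],
    gt_fa = gt_raw[, trio$father_id],
    stringsAsFactors = FALSE
  )
  rec <- split_multiallelic(raw, gt_cols = c("gt_pro", "gt_mo", "gt_fa"))
  n_skipped <- attr(rec, "n_skipped")

  hemi <- is_male_hemi_site(rec$chrom, rec$pos, par)
  pro_hemi <- hemi & trio$proband_sex == "male"

  ann <- if (is.null(dialect$annotation_fun)) {
    data.frame(
      gene = toupper(pick_allele(info_field(rec$info, dialect$gene),
                                 rec$allele_index)),
      consequence = norm_consequence(
        pick_allele(info_field(rec$info, dialect$consequence), rec$allele_index)),
      population_af = suppressWarnings(as.numeric(
        pick_allele(info_field(rec$info, dialect$af), rec$allele_index))),
      population_nhomalt = suppressWarnings(as.integer(
        pick_allele(info_field(rec$info, dialect$nhomalt), rec$allele_index))),
      sift = norm_predictor(
        pick_allele(info_field(rec$info, dialect$sift), rec$allele_index)),
      polyphen = norm_predictor(
        pick_allele(info_field(rec$info, dialect$polyphen), rec$allele_index)),
      mutation_taster = norm_predictor(
        pick_allele(info_field(rec$info, dialect$mutation_taster),
                    rec$allele_index)),
      stringsAsFactors = FALSE
    )
  } else {
    as.data.frame(dialect$annotation_fun(rec$info, rec$allele_index))
  }

  ratio <- function(s, d) ifelse(!is.na(d) & d > 0, s / d, NA_real_)
  i <- rec$row
  out <- tibble::tibble(
    trio_id = trio$family_id,
    chrom = rec$chrom, pos = rec$pos, ref = rec$ref, alt = rec$alt,
    allele_index = rec$allele_index,
    gene = ann$gene, consequence = ann$consequence,
    population_af = ann$population_af,
    population_nhomalt = ann$population_nhomalt,
    sift = ann$sift, polyphen = ann$polyphen,
    mutation_taster = ann$mutation_taster,
    pro_gt = gt_string_to_enum(rec$gt_pro, pro_hemi),
    pro_dp = as.integer(unname(dp[i, trio$proband_id])),
    pro_score = unname(score[i, trio$proband_id]),
    mo_gt = gt_string_to_enum(rec$gt_mo, FALSE),
    mo_dp = as.integer(unname(dp[i, trio$mother_id])),
    mo_score = unname(score[i, trio$mother_id]),
    fa_gt = gt_string_to_enum(rec$gt_fa, hemi),
    fa_dp = as.integer(unname(dp[i, trio$father_id])),
    fa_score = unname(score[i, trio$father_id])
  )
  out$pro_ratio <- ratio(out$pro_score, out$pro_dp)
  out$mo_ratio <- ratio(out$mo_score, out$mo_dp)
  out$fa_ratio <- ratio(out$fa_score, out$fa_dp)
  attr(out, "n_skipped") <- n_skipped
  out
}

# Can a parental genotype transmit a ref (0) / alt (1) allele?
#' @keywords internal
can_transmit <- function(gt, allele) {
  if (allele == 0L) gt %in% c("hom_ref", "het", "hemi_ref")
  else gt %in% c("het", "hom_alt", "hemi_alt")
}

#' Mendelian consistency of trio genotypes
#'
#' Vectorized test of whether each genotype triple is possible under
#' Mendelian transmission. On non-PAR X, male probands receive their single
#' allele from the mother (the father is ignored) and female probands
#' receive the father's hemizygous allele; PAR sites are autosomal.
#'
#' @param records tibble of trio variant records (needs `pro_gt`, `mo_gt`,
#'   `fa_gt`, `chrom`, `pos`).
#' @param proband_sex `"male"` or `"female"`.
#' @param par PAR intervals.
#' @return logical vector, `NA` where any member's genotype is missing.
#' @export
mendel_consistent <- function(records, proband_sex,
                              par = par_intervals("GRCh37")) {
  pro <- records$pro_gt; mo <- records$mo_gt; fa <- records$fa_gt
  m0 <- can_transmit(mo, 0L); m1 <- can_transmit(mo, 1L)
  f0 <- can_transmit(fa, 0L); f1 <- can_transmit(fa, 1L)
  pro_alt <- gt_alt_count(pro)
  hemi <- is_male_hemi_site(records$chrom, records$pos, par)
  male_x <- hemi & proband_sex == "male"

  cons <- rep(NA, nrow(records))
  dip <- !male_x
  cons[dip & pro == "hom_ref"] <- (m0 & f0)[dip & pro == "hom_ref"]
  cons[dip & pro == "het"] <- ((m0 & f1) | (m1 & f0))[dip & pro == "het"]
  cons[dip & pro == "hom_alt"] <- (m1 & f1)[dip & pro == "hom_alt"]
  # hemizygous enums at an autosomal site should not occur; score by dosage
  cons[dip & pro == "hemi_ref"] <- (m0 & f0)[dip & pro == "hemi_ref"]
  cons[dip & pro == "hemi_alt"] <- ((m0 & f1) | (m1 & f0))[dip & pro == "hemi_alt"]

  # male proband, non-PAR X: single allele from the mother
  sel <- male_x & !is.na(pro_alt) & pro_alt >= 1
  cons[sel] <- m1[sel]
  sel <- male_x & !is.na(pro_alt) & pro_alt == 0
  cons[sel] <- m0[sel]
  cons[male_x & pro == "het"] <- FALSE

  cons[pro == "missing" | mo == "missing" | fa == "missing"] <- NA
  cons
}

#' Trio-wide Mendelian error rate
#'
#' Fraction of fully genotyped records whose genotype triple is impossible
#' under Mendelian transmission. Serves as a cohort quality-control
#' surrogate for pedigree confirmation; true de novo events contribute to
#' the numerator, so rates well above the de novo expectation indicate
#' sample mix-ups or genotyping problems.
#'
#' @inheritParams mendel_consistent
#' @return a single number in `[0, 1]`.
#' @export
mendelian_error_rate <- function(records, proband_sex,
                                 par = par_intervals("GRCh37")) {
  cons <- mendel_consistent(records, proband_sex, par)
  usable <- !is.na(cons)
  if (!any(usable)) stop("no records with all three genotypes called")
  mean(!cons[usable])
}

#' Write trio records as a VCF 4.2 file
#'
#' Emits one plain-text VCF per trio with the package's default annotation
#' dialect (`GENE`, `CSQ_CLASS`, `GNOMAD_AF`, `GNOMAD_NHOMALT`, `SIFT`,
#' `POLYPHEN`, `MTASTER`; `GT:DP:MPG`). Hemizygous genotypes are written
#' haploid. Reading the file back with [read_trio_vcf()] reproduces
#' genotypes, depths, scores and annotations.
#'
#' @param records tibble of trio variant records.
#' @param trio one-row trio (sample names for the header).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trio_vcf <- function(records, trio, path) {
  gt_str <- function(gt) {
    c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1",
      hemi_ref = "0", hemi_alt = "1", missing = "./.")[gt]
  }
  fmt_num <- function(x) ifelse(is.na(x), ".", format(x, scientific = FALSE,
                                                      trim = TRUE, digits = 10))
  sample_field <- function(gt, dp, score) {
    paste(gt_str(gt), fmt_num(dp), fmt_num(score), sep = ":")
  }
  opt <- function(key, val) ifelse(is.na(val) | val == "absent", "",
                                   paste0(";", key, "=", val))
  info <- paste0(
    "GENE=", records$gene,
    ";CSQ_CLASS=", records$consequence,
    opt("GNOMAD_AF", fmt_num(records$population_af)),
    opt("GNOMAD_NHOMALT", records$population_nhomalt),
    opt("SIFT", records$sift),
    opt("POLYPHEN", records$polyphen),
    opt("MTASTER", records$mutation_taster)
  )
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=A,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=CSQ_CLASS,Number=A,Type=String,Description=\"Consequence class\">",
    "##INFO=<ID=GNOMAD_AF,Number=A,Type=Float,Description=\"Population allele frequency\">",
    "##INFO=<ID=GNOMAD_NHOMALT,Number=A,Type=Integer,Description=\"Population homozygote count\">",
    "##INFO=<ID=SIFT,Number=A,Type=String,Description=\"SIFT call\">",
    "##INFO=<ID=POLYPHEN,Number=A,Type=String,Description=\"PolyPhen2 call\">",
    "##INFO=<ID=MTASTER,Number=A,Type=String,Description=\"MutationTaster call\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=MPG,Number=1,Type=Float,Description=\"Most probable genotype score\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", trio$proband_id, trio$mother_id, trio$father_id,
          sep = "\t")
  )
  body <- paste(
    records$chrom, records$pos, ".", records$ref, records$alt, ".", "PASS",
    info, "GT:DP:MPG",
    sample_field(records$pro_gt, records$pro_dp, records$pro_score),
    sample_field(records$mo_gt, records$mo_dp, records$mo_score),
    sample_field(records$fa_gt, records$fa_dp, records$fa_score),
    sep = "\t"
  )
  writeLines(c(header, body), path)
  invisible(path)
}
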