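# Canonical genotype vocabulary used throughout the package. Hemizygous
# states are only produced on non-PAR X (and Y) in male samples.
GT_LEVELS <- c("hom_ref", "het", "hom_alt", "hemi_ref", "hemi_alt", "missing")

CONSEQUENCE_LEVELS <- c(
  "missense", "nonsense", "frameshift", "inframe_indel",
  "splice_canonical", "synonymous", "other"
)

PREDICTOR_CALLS <- c("damaging", "tolerated", "benign", "absent")

#' Number of alternate alleles carried by a genotype
#'
#' @param gt character vector of genotype codes (`"hom_ref"`, `"het"`,
#'   `"hom_alt"`, `"hemi_ref"`, `"hemi_alt"`, `"missing"`).
#' @return integer vector; `NA` for `"missing"`.
#' @keywords internal
gt_alt_count <- function(gt) {
  out <- c(hom_ref = 0L, het = 1L, hom_alt = 2L,
           hemi_ref = 0L, hemi_alt = 1L, missing = NA_integer_)[gt]
  unname(out)
}

#' @keywords internal
gt_carries <- function(gt) {
  ac <- gt_alt_count(gt)
  !is.na(ac) & ac > 0L
}

#' Normalize chromosome names
#'
#' Strips a leading `"chr"` prefix (case-insensitive) and maps `"23"` to
#' `"X"`, `"24"` to `"Y"`, so that `"chrX"`, `"X"` and `"23"` compare equal.
#'
#' @param chrom character vector of chromosome names.
#' @return normalized character vector.
#' @export
normalize_chrom <- function(chrom) {
  x <- sub("^[Cc][Hh][Rr]", "", as.character(chrom))
  x[x == "23"] <- "X"
  x[x == "24"] <- "Y"
  x
}

#' @keywords internal
is_x_chrom <- function(chrom) normalize_chrom(chrom) == "X"

#' Pseudoautosomal region intervals
#'
#' PAR intervals on the X chromosome, within which male genotypes are
#' diploid and all inheritance logic is autosomal. `"GRCh37"` gives the
#' standard hg19 coordinates; `"synthetic"` gives the intervals used by the
#' cohort simulator's abstract X contig.
#'
#' @param genome one of `"GRCh37"`, `"synthetic"`.
#' @return a data.frame with columns `chrom`, `start`, `end` (1-based,
#'   inclusive).
#' @export
par_intervals <- function(genome = c("GRCh37", "synthetic")) {
  genome <- match.arg(genome)
  switch(genome,
    GRCh37 = data.frame(
      chrom = c("X", "X"),
      start = c(60001, 154931044),
      end   = c(2699520, 155260560)
    ),
    synthetic = data.frame(
      chrom = c("X", "X"),
      start = c(1, 990001),
      end   = c(10000, 1000000)
    )
  )
}

#' Is a position inside a pseudoautosomal region?
#'
#' @param chrom,pos vectors of chromosome names and 1-based positions.
#' @param par data.frame of PAR intervals as from [par_intervals()].
#' @return logical vector.
#' @export
in_par <- function(chrom, pos, par = par_intervals("GRCh37")) {
  chrom <- normalize_chrom(chrom)
  out <- rep(FALSE, length(chrom))
  for (i in seq_len(nrow(par))) {
    out <- out | (chrom == normalize_chrom(par$chrom[i]) &
                    pos >= par$start[i] & pos <= par$end[i])
  }
  out
}

# TRUE where the site is hemizygous in a male: non-PAR X (or Y).
#' @keywords internal
is_male_hemi_site <- function(chrom, pos, par) {
  ch <- normalize_chrom(chrom)
  (ch == "X" & !in_par(ch, pos, par)) | ch == "Y"
}
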