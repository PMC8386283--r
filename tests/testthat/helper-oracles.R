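# Independent oracles and fixture builders shared across the suite.

# Brute-force two-sided Fisher p: enumerate every table with the observed
# margins, score each with the hypergeometric mass (dhyper, an independent
# code path from the package's lchoose computation), and sum the masses
# not exceeding the observed one.
fisher_oracle <- function(tab) {
  tab <- matrix(as.numeric(tab), nrow = 2)
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- stats::dhyper(tab[1, 1], r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Exact-permutation Mann-Whitney oracle built on the pairwise-comparison
# definition of U (count of (i, j) pairs with a_i > b_j, ties half) rather
# than on midranks: U for a label assignment A is sum(C[A, ]) - choose(|A|, 2)
# where C[i, j] = (x_i > x_j) + (x_i == x_j)/2 off the diagonal.
mw_oracle <- function(a, b) {
  x <- c(a, b)
  n <- length(x); n_a <- length(a)
  C <- outer(x, x, ">") + outer(x, x, "==") / 2
  diag(C) <- 0
  rs <- rowSums(C)
  u_of <- function(idx) sum(rs[idx]) - choose(n_a, 2)
  u_obs <- u_of(seq_len(n_a))
  eu <- n_a * (n - n_a) / 2
  idx <- utils::combn(n, n_a)
  u_all <- colSums(matrix(rs[idx], nrow = n_a)) - choose(n_a, 2)
  list(u = u_obs,
       p = mean(abs(u_all - eu) >= abs(u_obs - eu) - 1e-9))
}

# One fully specified trio variant record; override any field.
make_record <- function(...) {
  rec <- tibble::tibble(
    trio_id = "T1", chrom = "1", pos = 1000L, ref = "A", alt = "G",
    allele_index = 1L, gene = "GENE1", consequence = "missense",
    population_af = NA_real_, population_nhomalt = NA_integer_,
    sift = "damaging", polyphen = "damaging", mutation_taster = "benign",
    pro_gt = "het", pro_dp = 30L, pro_score = 25,
    mo_gt = "hom_ref", mo_dp = 30L, mo_score = 25,
    fa_gt = "hom_ref", fa_dp = 30L, fa_score = 25
  )
  over <- list(...)
  for (nm in names(over)) rec[[nm]] <- over[[nm]]
  rec$pro_ratio <- ifelse(rec$pro_dp > 0, rec$pro_score / rec$pro_dp, NA_real_)
  rec$mo_ratio <- ifelse(rec$mo_dp > 0, rec$mo_score / rec$mo_dp, NA_real_)
  rec$fa_ratio <- ifelse(rec$fa_dp > 0, rec$fa_score / rec$fa_dp, NA_real_)
  rec
}

# Stack make_record rows from a list of override lists.
make_records <- function(rows) {
  dplyr::bind_rows(lapply(rows, function(r) do.call(make_record, r)))
}

# Hand-built autosomal transmission truth table over all 27 genotype
# triples (child x mother x father in hom_ref/het/hom_alt), assuming every
# call passes quality.
autosomal_truth_table <- function() {
  g <- c("hom_ref", "het", "hom_alt")
  grid <- expand.grid(pro = g, mo = g, fa = g, stringsAsFactors = FALSE)
  expected <- character(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    p <- grid$pro[i]; m <- grid$mo[i]; f <- grid$fa[i]
    m_carrier <- m != "hom_ref"; f_carrier <- f != "hom_ref"
    m0 <- m != "hom_alt"; m1 <- m_carrier
    f0 <- f != "hom_alt"; f1 <- f_carrier
    consistent <- switch(p,
      hom_ref = m0 && f0,
      het = (m0 && f1) || (m1 && f0),
      hom_alt = m1 && f1
    )
    expected[i] <-
      if (p == "het" && !m_carrier && !f_carrier) "de_novo"
      else if (!consistent) "inconsistent"
      else if (p == "hom_alt" && m_carrier && f_carrier) "biparental_homozygous"
      else if (p == "het" && m_carrier && !f_carrier) "maternal"
      else if (p == "het" && !m_carrier && f_carrier) "paternal"
      else "unresolved"
  }
  grid$expected <- expected
  grid
}

# Truth table for a male proband on non-PAR X: proband hemizygous, mother
# diploid, father hemizygous.
male_x_truth_table <- function() {
  grid <- expand.grid(pro = c("hemi_ref", "hemi_alt"),
                      mo = c("hom_ref", "het", "hom_alt"),
                      fa = c("hemi_ref", "hemi_alt"),
                      stringsAsFactors = FALSE)
  expected <- character(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    p <- grid$pro[i]; m <- grid$mo[i]; f <- grid$fa[i]
    expected[i] <-
      if (p == "hemi_alt" && m == "hom_ref" && f == "hemi_ref") "de_novo"
      else if (p == "hemi_alt" && m == "hom_ref") "inconsistent"
      else if (p == "hemi_ref" && m == "hom_alt") "inconsistent"
      else if (p == "hemi_alt" && m == "het" && f == "hemi_ref") "hemizygous_maternal"
      else "unresolved"
  }
  grid$expected <- expected
  grid
}

# Truth table for a female proband on X: proband diploid, father hemizygous.
female_x_truth_table <- function() {
  grid <- expand.grid(pro = c("hom_ref", "het", "hom_alt"),
                      mo = c("hom_ref", "het", "hom_alt"),
                      fa = c("hemi_ref", "hemi_alt"),
                      stringsAsFactors = FALSE)
  expected <- character(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    p <- grid$pro[i]; m <- grid$mo[i]; f <- grid$fa[i]
    m_carrier <- m != "hom_ref"
    m0 <- m != "hom_alt"; m1 <- m_carrier
    f_alt <- f == "hemi_alt"
    consistent <- switch(p,
      hom_ref = m0 && !f_alt,
      het = (m0 && f_alt) || (m1 && !f_alt),
      hom_alt = m1 && f_alt
    )
    expected[i] <-
      if (p == "het" && !m_carrier && !f_alt) "de_novo"
      else if (!consistent) "inconsistent"
      else if (p == "hom_alt" && m_carrier && f_alt) "biparental_homozygous"
      else if (p == "het" && m_carrier && !f_alt) "maternal"
      else if (p == "het" && !m_carrier && f_alt) "paternal"
      else "unresolved"
  }
  grid$expected <- expected
  grid
}

# Apply a transmission truth table through classify_transmission.
classify_grid <- function(grid, chrom, pos, sex) {
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    list(chrom = chrom, pos = pos, pro_gt = grid$pro[i],
         mo_gt = grid$mo[i], fa_gt = grid$fa[i])
  })
  rec <- make_records(rows)
  classify_transmission(rec, sex, filter_thresholds(),
                        par_intervals("synthetic"))
}

# A one-trio pedigree row compatible with read_trio_vcf / write_trio_vcf.
make_trio <- function(family_id = "F1", proband_sex = "male") {
  tibble::tibble(
    family_id = family_id, trio_id = family_id,
    proband_id = paste0(family_id, "_P"),
    proband_sex = proband_sex,
    mother_id = paste0(family_id, "_M"),
    father_id = paste0(family_id, "_F"),
    affected = TRUE
  )
}
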