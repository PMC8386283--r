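# Transmission classification (autosomal and X truth tables, quality
# gating) and gene-level monogenic candidate enumeration.

test_that("autosomal classification matches the 27-triple truth table", {
  grid <- autosomal_truth_table()
  got <- classify_grid(grid, chrom = "7", pos = 500000L, sex = "female")
  expect_equal(got, grid$expected)
  # sex does not matter on autosomes
  got_m <- classify_grid(grid, chrom = "7", pos = 500000L, sex = "male")
  expect_equal(got_m, grid$expected)
})

test_that("male-proband non-PAR X classification matches its truth table", {
  grid <- male_x_truth_table()
  got <- classify_grid(grid, chrom = "X", pos = 500000L, sex = "male")
  expect_equal(got, grid$expected)
})

test_that("female-proband X classification matches its truth table", {
  grid <- female_x_truth_table()
  got <- classify_grid(grid, chrom = "X", pos = 500000L, sex = "female")
  expect_equal(got, grid$expected)
})

test_that("PAR sites are classified autosomally even for male probands", {
  rec <- make_record(chrom = "X", pos = 5000L,  # inside synthetic PAR1
                     pro_gt = "het", mo_gt = "hom_ref", fa_gt = "het")
  got <- classify_transmission(rec, "male", par = par_intervals("synthetic"))
  expect_equal(got, "paternal")
})

test_that("parental quality failures yield unresolved, never a definite call", {
  # textbook de novo pattern, but the father is under-covered
  rec <- make_record(pro_gt = "het", mo_gt = "hom_ref", fa_gt = "hom_ref",
                     fa_dp = 5L, fa_score = 4)
  expect_equal(classify_transmission(rec, "female"), "unresolved")
  # low maternal quality ratio blocks a maternal call
  rec2 <- make_record(pro_gt = "het", mo_gt = "het", fa_gt = "hom_ref",
                      mo_dp = 40L, mo_score = 10)
  expect_equal(classify_transmission(rec2, "female"), "unresolved")
  # missing parental genotype
  rec3 <- make_record(pro_gt = "het", mo_gt = "missing", fa_gt = "hom_ref")
  expect_equal(classify_transmission(rec3, "female"), "unresolved")
})

test_that("compound-het detection requires trans configuration", {
  base <- list(
    list(pos = 100L, gene = "G1", pro_gt = "het", mo_gt = "het",
         fa_gt = "hom_ref"),
    list(pos = 200L, gene = "G1", pro_gt = "het", mo_gt = "hom_ref",
         fa_gt = "het")
  )
  cand <- make_records(base)
  cand$category <- classify_transmission(cand, "female")
  expect_equal(cand$category, c("maternal", "paternal"))
  ch <- find_compound_het(cand)
  expect_equal(nrow(ch), 1)
  expect_equal(ch$mode, "AR_compound_het")
  expect_equal(ch$n_variants, 2L)

  # cis: both from the mother -> nothing
  cis <- make_records(list(
    list(pos = 100L, gene = "G1", pro_gt = "het", mo_gt = "het",
         fa_gt = "hom_ref"),
    list(pos = 200L, gene = "G1", pro_gt = "het", mo_gt = "het",
         fa_gt = "hom_ref")
  ))
  cis$category <- classify_transmission(cis, "female")
  expect_equal(nrow(find_compound_het(cis)), 0)

  # 1 maternal + 2 paternal -> one gene-level candidate with 3 variants;
  # cross-checked against a brute-force pairing oracle
  three <- make_records(c(base, list(
    list(pos = 300L, gene = "G1", pro_gt = "het", mo_gt = "hom_ref",
         fa_gt = "het"))))
  three$category <- classify_transmission(three, "female")
  ch3 <- find_compound_het(three)
  expect_equal(nrow(ch3), 1)
  expect_equal(ch3$n_variants, 3L)
  pairs <- utils::combn(nrow(three), 2)
  any_trans_pair <- any(apply(pairs, 2, function(ij) {
    length(unique(three$category[ij])) == 2
  }))
  expect_true(any_trans_pair)

  # a variant het in proband and both parents is phase-ambiguous and
  # contributes nothing
  amb <- make_records(list(
    list(pos = 100L, gene = "G1", pro_gt = "het", mo_gt = "het",
         fa_gt = "het"),
    list(pos = 200L, gene = "G1", pro_gt = "het", mo_gt = "hom_ref",
         fa_gt = "het")
  ))
  amb$category <- classify_transmission(amb, "female")
  expect_equal(nrow(find_compound_het(amb)), 0)
})

test_that("monogenic enumeration unions the four models, one per gene-mode", {
  cand <- make_records(list(
    list(pos = 100L, gene = "TTLL4", pro_gt = "het", mo_gt = "hom_ref",
         fa_gt = "hom_ref"),                                    # de novo
    list(pos = 200L, gene = "TNXB", pro_gt = "het", mo_gt = "het",
         fa_gt = "hom_ref"),                                    # maternal
    list(pos = 300L, gene = "TNXB", pro_gt = "het", mo_gt = "hom_ref",
         fa_gt = "het"),                                        # paternal
    list(pos = 400L, gene = "MET", pro_gt = "hom_alt", mo_gt = "het",
         fa_gt = "het"),                                        # AR hom
    list(chrom = "X", pos = 500000L, gene = "GPC3", pro_gt = "hemi_alt",
         mo_gt = "het", fa_gt = "hemi_ref")                     # XLR
  ))
  cand$category <- classify_transmission(cand, "male",
                                         par = par_intervals("synthetic"))
  mono <- monogenic_candidates(cand)
  expect_equal(nrow(mono), 4)
  expect_setequal(mono$mode,
                  c("de_novo", "AR_compound_het", "AR_homozygous", "XLR"))
  expect_equal(mono$gene[mono$mode == "de_novo"], "TTLL4")
  expect_equal(mono$gene[mono$mode == "AR_compound_het"], "TNXB")
  expect_equal(mono$gene, sort(mono$gene))

  empty <- monogenic_candidates(cand[0, ], trio_id = "T1")
  expect_equal(nrow(empty), 0)
})

test_that("female probands never yield XLR; X homozygotes count as AR", {
  cand <- make_record(chrom = "X", pos = 500000L, gene = "GX",
                      pro_gt = "hom_alt", mo_gt = "het", fa_gt = "hemi_alt")
  cand$category <- classify_transmission(cand, "female",
                                         par = par_intervals("synthetic"))
  expect_equal(cand$category, "biparental_homozygous")
  mono <- monogenic_candidates(cand)
  expect_equal(mono$mode, "AR_homozygous")
})

test_that("classification invariants hold over a synthetic cohort", {
  co <- simulate_cohort(sim_config(n_case_trios = 5, n_control_trios = 5,
                                   n_male_case = 3, n_male_control = 2,
                                   n_background_sites = 800,
                                   genotype_error_rate = 0.001, seed = 77))
  cand <- cohort_candidates(co)
  expect_true(all(cand$category %in%
                    c("de_novo", "maternal", "paternal",
                      "biparental_homozygous", "hemizygous_maternal",
                      "inconsistent", "unresolved")))
  dn <- cand[cand$category == "de_novo", ]
  expect_false(any(dn$mo_gt %in% c("het", "hom_alt", "hemi_alt")))
  expect_false(any(dn$fa_gt %in% c("het", "hom_alt", "hemi_alt")))
  mat <- cand[cand$category == "maternal", ]
  expect_true(all(mat$mo_gt %in% c("het", "hom_alt")))
  expect_false(any(mat$fa_gt %in% c("het", "hom_alt", "hemi_alt")))
})

test_that("parental dropout turns de novo calls unresolved, never false de novo", {
  clean <- sim_config(n_case_trios = 10, n_control_trios = 10,
                      n_male_case = 5, n_male_control = 5,
                      n_background_sites = 600,
                      rate_de_novo = 1.5, rate_comp_het = 0,
                      rate_ar_hom = 0, rate_xlr = 0,
                      panel_variant_rate_case = 0,
                      panel_variant_rate_control = 0,
                      decoy_fraction = 0, seed = 99)
  dropout <- do.call(sim_config, utils::modifyList(
    unclass(clean), list(parental_dropout_rate = 0.25)))
  co <- simulate_cohort(dropout)
  ev <- evaluate_recovery(co)
  # every reported de novo corresponds to a planted one
  expect_equal(nrow(ev$false_de_novo), 0)
  # dropout suppresses part of the planted de novos (they become unresolved)
  dn <- ev$by_mode[ev$by_mode$mode == "de_novo", ]
  expect_lt(dn$n_recovered, dn$n_expected)
  cand <- cohort_candidates(co)
  truth_key <- paste(co$truth$trio_id, co$truth$pos)
  planted <- cand[paste(cand$trio_id, cand$pos) %in% truth_key, ]
  expect_true(all(planted$category %in% c("de_novo", "unresolved")))
})
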