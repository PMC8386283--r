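# The five-criterion candidate definition: strict bounds, absent-value
# semantics, the truncating bypass, and the conjunction over criteria.

test_that("quality criterion applies strict depth and ratio bounds", {
  t <- filter_thresholds()
  expect_false(passes_quality("het", 9, 8.1, t))    # depth 9, ratio 0.9
  expect_false(passes_quality("het", 10, 9, t))     # depth exactly 10
  expect_true(passes_quality("het", 11, 6, t))      # ratio 0.545
  expect_false(passes_quality("het", 20, 8, t))     # ratio 0.4
  expect_false(passes_quality("het", 20, 10, t))    # ratio exactly 0.5
  expect_false(passes_quality("missing", 30, 25, t))
  expect_false(passes_quality("het", NA, 25, t))
})

test_that("rarity criterion treats absent frequency as not-found and gates homozygotes", {
  t <- filter_thresholds()
  expect_false(passes_rarity(0.02, NA, "het", t))
  expect_true(passes_rarity(NA, NA, "het", t))      # "not found" retained
  expect_true(passes_rarity(0.001, NA, "het", t))
  expect_false(passes_rarity(0.01, NA, "het", t))   # exactly 1% fails
  expect_false(passes_rarity(0.001, 2L, "hom_alt", t))  # nhomalt strict
  expect_true(passes_rarity(0.001, 1L, "hom_alt", t))
  expect_true(passes_rarity(0.001, NA, "hom_alt", t))
  expect_true(passes_rarity(0.001, 50L, "het", t))  # nhomalt ignored for hets
  expect_false(passes_rarity(0.001, 2L, "hemi_alt", t))
})

test_that("protein-altering criterion keeps amino-acid-changing classes", {
  expect_true(all(is_protein_altering(
    c("missense", "nonsense", "frameshift", "inframe_indel",
      "splice_canonical"))))
  expect_false(any(is_protein_altering(c("synonymous", "other"))))
})

test_that("predictor consensus needs 2 of 3 for missense, bypasses truncating", {
  t <- filter_thresholds()
  two <- is_predicted_pathogenic("missense", "damaging", "benign",
                                 "damaging", t)
  expect_true(two$pathogenic)
  expect_false(two$truncating_bypass)

  one <- is_predicted_pathogenic("missense", "damaging", "absent", "absent", t)
  expect_false(one$pathogenic)  # absent is not a damaging vote

  fs <- is_predicted_pathogenic("frameshift", "absent", "absent", "absent", t)
  expect_true(fs$pathogenic)
  expect_true(fs$truncating_bypass)

  indel <- is_predicted_pathogenic("inframe_indel", "absent", "absent",
                                   "absent", t)
  expect_true(indel$pathogenic)
})

test_that("filter_candidates equals brute-force application of the predicates", {
  co <- simulate_cohort(sim_config(n_case_trios = 4, n_control_trios = 4,
                                   n_male_case = 2, n_male_control = 2,
                                   n_background_sites = 600,
                                   genotype_error_rate = 0.002, seed = 21))
  t <- filter_thresholds()
  got <- filter_candidates(co$records, t)

  # independent per-record re-derivation with scalar logic
  want <- vapply(seq_len(nrow(co$records)), function(i) {
    r <- co$records[i, ]
    carrier <- r$pro_gt %in% c("het", "hom_alt", "hemi_alt")
    q <- !is.na(r$pro_dp) && r$pro_dp > 10 && r$pro_score / r$pro_dp > 0.5
    rare <- (is.na(r$population_af) || r$population_af < 0.01) &&
      (!r$pro_gt %in% c("hom_alt", "hemi_alt") ||
         is.na(r$population_nhomalt) || r$population_nhomalt < 2)
    prot <- r$consequence %in% c("missense", "nonsense", "frameshift",
                                 "inframe_indel", "splice_canonical")
    votes <- sum(c(r$sift, r$polyphen, r$mutation_taster) == "damaging")
    path <- (r$consequence == "missense" && votes >= 2) ||
      r$consequence %in% c("nonsense", "frameshift", "inframe_indel",
                           "splice_canonical")
    carrier && q && rare && prot && path
  }, logical(1))
  key <- function(d) paste(d$trio_id, d$chrom, d$pos, d$alt)
  expect_setequal(key(got), key(co$records[want, ]))
  expect_gt(nrow(got), 0)
})

test_that("candidate set is order-invariant and excludes non-carriers", {
  co <- simulate_cohort(sim_config(n_case_trios = 2, n_control_trios = 2,
                                   n_male_case = 1, n_male_control = 1,
                                   n_background_sites = 300, seed = 31))
  got <- filter_candidates(co$records)
  set.seed(1)
  shuffled <- co$records[sample.int(nrow(co$records)), ]
  got2 <- filter_candidates(shuffled)
  key <- function(d) paste(d$trio_id, d$chrom, d$pos, d$alt)
  expect_setequal(key(got), key(got2))
  expect_false(any(got$pro_gt %in% c("hom_ref", "hemi_ref", "missing")))

  # a perfectly annotated variant is still excluded if the proband is
  # a non-carrier
  rec <- make_record(pro_gt = "hom_ref")
  expect_equal(nrow(filter_candidates(rec)), 0)
})

test_that("relaxing any threshold never removes a candidate (monotonicity)", {
  co <- simulate_cohort(sim_config(n_case_trios = 3, n_control_trios = 3,
                                   n_male_case = 2, n_male_control = 1,
                                   n_background_sites = 500, seed = 41))
  base <- filter_thresholds()
  key <- function(d) paste(d$trio_id, d$chrom, d$pos, d$alt)
  strict <- key(filter_candidates(co$records, base))
  relaxed <- list(
    filter_thresholds(min_depth_exclusive = 5),
    filter_thresholds(min_quality_ratio_exclusive = 0.3),
    filter_thresholds(max_af_exclusive = 0.05),
    filter_thresholds(max_nhomalt_exclusive = 10),
    filter_thresholds(min_pathogenic_votes = 1)
  )
  for (t in relaxed) {
    expect_true(all(strict %in% key(filter_candidates(co$records, t))))
  }
})

test_that("low-quality-ratio candidates are flagged for review", {
  rec <- make_record(pro_dp = 20L, pro_score = 11)  # ratio 0.55
  got <- filter_candidates(rec)
  expect_equal(nrow(got), 1)
  expect_true(got$review_recommended)
  rec2 <- make_record(pro_dp = 20L, pro_score = 16)  # ratio 0.8
  expect_false(filter_candidates(rec2)$review_recommended)
})
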