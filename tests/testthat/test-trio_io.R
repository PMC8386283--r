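# Pedigree and VCF ingestion: PED parsing, multiallelic splitting,
# genotype normalization (including male X hemizygosity), the annotation
# dialect, and the Mendelian-error QC.

vcf_header <- function(samples = c("P1", "M1", "D1")) {
  c("##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=A,Type=String,Description=\"g\">",
    "##INFO=<ID=CSQ_CLASS,Number=A,Type=String,Description=\"c\">",
    "##INFO=<ID=GNOMAD_AF,Number=A,Type=Float,Description=\"af\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"dp\">",
    "##FORMAT=<ID=MPG,Number=1,Type=Float,Description=\"q\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"gq\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}

write_vcf_fixture <- function(body, samples = c("P1", "M1", "D1")) {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(vcf_header(samples), body), path)
  path
}

fixture_trio <- function(sex = "male") {
  tibble::tibble(family_id = "F1", trio_id = "F1", proband_id = "P1",
                 proband_sex = sex, mother_id = "M1", father_id = "D1",
                 affected = TRUE)
}

test_that("read_pedigree maps PED rows to trios and enforces preconditions", {
  ped <- tempfile(fileext = ".ped")
  writeLines(c("F1 P1 D1 M1 1 2",
               "F1 D1 0 0 1 1",
               "F1 M1 0 0 2 1",
               "F2 P2 0 M2 2 2",
               "F2 M2 0 0 2 1"), ped)
  expect_warning(trios <- read_pedigree(ped), "skipping 1 affected")
  expect_equal(nrow(trios), 1)
  expect_equal(trios$proband_id, "P1")
  expect_equal(trios$proband_sex, "male")
  expect_equal(trios$mother_id, "M1")
  expect_equal(trios$father_id, "D1")
  expect_true(trios$affected)

  bad_sex <- tempfile(fileext = ".ped")
  writeLines(c("F1 P1 D1 M1 0 2", "F1 D1 0 0 1 1", "F1 M1 0 0 2 1"), bad_sex)
  expect_error(read_pedigree(bad_sex), "sex")

  dup <- tempfile(fileext = ".ped")
  writeLines(c("F1 P1 D1 M1 1 2", "F2 P1 D1 M1 1 2",
               "F1 D1 0 0 1 1", "F1 M1 0 0 2 1"), dup)
  expect_error(read_pedigree(dup), "duplicate")
})

test_that("split_multiallelic recodes genotypes per allele and conserves dosage", {
  raw <- data.frame(chrom = "1", pos = c(100, 200, 300),
                    ref = c("C", "C", "T"), alt = c("A,G", "A,G", "A"),
                    gt = c("1/2", "2/2", "0/1"), stringsAsFactors = FALSE)
  out <- split_multiallelic(raw, gt_cols = "gt")
  expect_equal(nrow(out), 5)
  # GT=1/2: het against each allele
  expect_equal(out$gt[out$pos == 100], c("1/0", "0/1"))
  # GT=2/2: non-carrier against allele 1, hom against allele 2
  expect_equal(out$gt[out$pos == 200], c("0/0", "1/1"))
  # single-alt row unchanged
  expect_equal(out$gt[out$pos == 300], "0/1")
  expect_equal(out$allele_index[out$pos == 300], 1L)

  # dosage conservation over random multiallelic rows
  set.seed(42)
  for (i in 1:25) {
    n_alt <- sample(1:3, 1)
    gts <- replicate(4, paste(sample(0:n_alt, 2, replace = TRUE),
                              collapse = "/"))
    raw <- data.frame(chrom = "1", pos = 1, ref = "A",
                      alt = paste(sample(c("C", "G", "T"), n_alt), collapse = ","),
                      t(gts), stringsAsFactors = FALSE)
    names(raw)[5:8] <- paste0("gt_", 1:4)
    out <- split_multiallelic(raw, gt_cols = paste0("gt_", 1:4))
    dosage <- function(g) sum(strsplit(g, "[/|]")[[1]] != "0")
    raw_dosage <- sum(vapply(gts, dosage, numeric(1)))
    split_dosage <- sum(vapply(unlist(out[paste0("gt_", 1:4)]),
                               function(g) sum(strsplit(g, "[/|]")[[1]] == "1"),
                               numeric(1)))
    expect_equal(split_dosage, raw_dosage)
  }
})

test_that("split_multiallelic drops records referencing alleles beyond ALT", {
  raw <- data.frame(chrom = "1", pos = c(1, 2), ref = "A", alt = "C",
                    gt = c("0/2", "0/1"), stringsAsFactors = FALSE)
  expect_warning(out <- split_multiallelic(raw, gt_cols = "gt"), "malformed")
  expect_equal(nrow(out), 1)
  expect_equal(attr(out, "n_skipped"), 1)
})

test_that("read_trio_vcf normalizes fields, dialects and hemizygosity", {
  body <- c(
    paste("chr1", 1000, ".", "A", "G", ".", "PASS",
          "GENE=Lhx4;CSQ_CLASS=missense;GNOMAD_AF=0.004",
          "GT:DP:MPG", "0/1:25:20", "0/0:30:28", "0/0:31:29", sep = "\t"),
    # multiallelic row, no AF key
    paste("1", 2000, ".", "C", "A,G", ".", "PASS",
          "GENE=G2,G3;CSQ_CLASS=missense,nonsense",
          "GT:DP:MPG", "1/2:40:35", "0/1:40:35", "0/2:40:35", sep = "\t"),
    # male X non-PAR: haploid and diploid-homozygous both hemizygous
    paste("chrX", 3000000, ".", "T", "C", ".", "PASS",
          "GENE=GX;CSQ_CLASS=missense",
          "GT:DP:MPG", "1:20:15", "0/1:20:15", "0:20:15", sep = "\t"),
    paste("chrX", 3000100, ".", "T", "C", ".", "PASS",
          "GENE=GX;CSQ_CLASS=missense",
          "GT:DP:MPG", "1/1:20:15", "0/0:20:15", "0/0:20:15", sep = "\t"),
    # X PAR1 site stays diploid for males
    paste("chrX", 61000, ".", "T", "C", ".", "PASS",
          "GENE=GP;CSQ_CLASS=missense",
          "GT:DP:MPG", "0/1:20:15", "0/1:20:15", "0/0:20:15", sep = "\t")
  )
  path <- write_vcf_fixture(body)
  rec <- read_trio_vcf(path, fixture_trio("male"))

  expect_equal(nrow(rec), 6)  # multiallelic row expanded
  r1 <- rec[rec$pos == 1000, ]
  expect_equal(r1$chrom, "1")           # chr prefix stripped
  expect_equal(r1$gene, "LHX4")         # uppercased
  expect_equal(r1$pro_gt, "het")
  expect_equal(r1$pro_dp, 25L)
  expect_equal(r1$pro_score, 20)
  expect_equal(r1$pro_ratio, 0.8)
  expect_equal(r1$population_af, 0.004)

  r2 <- rec[rec$pos == 2000, ]
  expect_equal(r2$gene, c("G2", "G3"))  # per-allele annotation selection
  expect_equal(r2$consequence, c("missense", "nonsense"))
  expect_true(all(is.na(r2$population_af)))  # absent key -> not found
  expect_equal(r2$pro_gt, c("het", "het"))   # 1/2 vs each allele
  expect_equal(r2$fa_gt, c("hom_ref", "het"))

  expect_equal(rec$pro_gt[rec$pos == 3000000], "hemi_alt")
  expect_equal(rec$fa_gt[rec$pos == 3000000], "hemi_ref")
  expect_equal(rec$mo_gt[rec$pos == 3000000], "het")  # mothers stay diploid
  expect_equal(rec$pro_gt[rec$pos == 3000100], "hemi_alt")
  expect_equal(rec$pro_gt[rec$pos == 61000], "het")   # PAR is autosomal
})

test_that("read_trio_vcf falls back to GQ and errors on absent samples", {
  body <- paste("1", 500, ".", "A", "T", ".", "PASS",
                "GENE=G1;CSQ_CLASS=missense",
                "GT:DP:GQ", "0/1:20:18", "0/0:20:18", "0/0:20:18", sep = "\t")
  path <- write_vcf_fixture(body)
  rec <- read_trio_vcf(path, fixture_trio())
  expect_equal(rec$pro_score, 18)

  other <- fixture_trio()
  other$father_id <- "NOT_THERE"
  expect_error(read_trio_vcf(path, other), "NOT_THERE")
})

test_that("VCF round-trip preserves genotypes, quality and annotations", {
  co <- simulate_cohort(sim_config(n_case_trios = 1, n_control_trios = 1,
                                   n_male_case = 1, n_male_control = 0,
                                   n_background_sites = 120, seed = 5))
  trio <- co$pedigree[1, ]
  rec <- co$records[co$records$trio_id == trio$trio_id, ]
  path <- tempfile(fileext = ".vcf")
  write_trio_vcf(rec, trio, path)
  back <- read_trio_vcf(path, trio, par = par_intervals("synthetic"))
  back <- back[order(back$chrom, back$pos), ]
  rec <- rec[order(rec$chrom, rec$pos), ]
  for (col in c("chrom", "pos", "ref", "alt", "gene", "consequence",
                "population_af", "population_nhomalt", "sift", "polyphen",
                "mutation_taster", "pro_gt", "pro_dp", "pro_score",
                "mo_gt", "mo_dp", "mo_score", "fa_gt", "fa_dp", "fa_score")) {
    expect_equal(back[[col]], rec[[col]], ignore_attr = TRUE, label = col)
  }
})

test_that("mendelian_error_rate scores impossible triples and clean cohorts", {
  all_het <- make_records(rep(list(list(pro_gt = "het", mo_gt = "het",
                                        fa_gt = "het")), 5))
  expect_equal(mendelian_error_rate(all_het, "female"), 0)

  impossible <- make_record(pro_gt = "hom_alt", mo_gt = "hom_ref",
                            fa_gt = "hom_ref")
  expect_equal(mendelian_error_rate(impossible, "male"), 1)

  missing <- make_record(pro_gt = "missing")
  expect_error(mendelian_error_rate(missing, "male"), "no records")

  # synthetic cohort without planted errors: background transmission is
  # exactly Mendelian, so only planted de novos can violate it
  co <- simulate_cohort(sim_config(n_case_trios = 3, n_control_trios = 3,
                                   n_male_case = 2, n_male_control = 1,
                                   n_background_sites = 800, seed = 9))
  dn_sites <- co$truth[co$truth$planted_class == "de_novo", ]
  for (i in seq_len(nrow(co$pedigree))) {
    trio <- co$pedigree[i, ]
    rec <- co$records[co$records$trio_id == trio$trio_id, ]
    rec <- rec[!paste(rec$trio_id, rec$pos) %in%
                 paste(dn_sites$trio_id, dn_sites$pos), ]
    expect_lt(mendelian_error_rate(rec, trio$proband_sex,
                                   par_intervals("synthetic")), 0.001)
  }
})
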