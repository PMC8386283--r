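# Synthetic trio-cohort generator. Produces case/control trio cohorts with
# Hardy-Weinberg parental genotypes, Mendelian transmission to the proband,
# and planted de novo / compound-het / AR-homozygous / X-linked-recessive /
# panel-gene events of known truth, so that every pipeline stage and both
# burden analyses are testable without controlled-access human data.
#
# Sites are abstract: synthetic autosomal contigs "1".."22" plus one "X"
# contig of length 1 Mb whose ends are pseudoautosomal (par_intervals
# "synthetic"). Background sites get one unique synthetic gene each;
# monogenic plants draw genes from a synthetic pool disjoint from the
# panel, so the two burden analyses are independently testable.

#' Simulation configuration
#'
#' Defaults encode the study conditions the generator emulates: 13 case
#' trios (5 male) vs 19 control trios (12 male); heterozygous panel-gene
#' candidate rates of 1.1 (case) and 0.21 (control) per proband; gene-level
#' monogenic candidate rates totalling 1.3 (case) and 2.5 (control) per
#' proband, split across de novo / compound-het / AR-homozygous / XLR in
#' the proportions observed for the case cohort (5:6:5:1). The exome is
#' abstracted to `n_background_sites` jointly-called sites.
#'
#' Per-trio planted-event counts are Poisson. Each plant is constructed to
#' satisfy all five candidate criteria with probability
#' `1 - decoy_fraction`; the remainder deliberately violate one criterion
#' (recorded in the truth table). Plants are drawn at rate
#' `rate / (1 - decoy_fraction)` so the expected count of *recoverable*
#' events per trio equals the configured rate.
#'
#' @param n_case_trios,n_control_trios cohort sizes.
#' @param n_male_case,n_male_control male probands per group.
#' @param n_background_sites shared background sites per cohort.
#' @param p_rare fraction of background sites with a rare allele frequency.
#' @param rare_af_range,common_af_range uniform AF ranges for the rare and
#'   common components of the background spectrum.
#' @param x_site_fraction fraction of background sites on the X contig.
#' @param rate_de_novo,rate_comp_het,rate_ar_hom,rate_xlr expected
#'   recoverable gene-level events per trio; either a single number or
#'   `c(case = , control = )`. XLR applies to male-proband trios; in
#'   female-proband trios its rate is reassigned to AR-homozygous so the
#'   expected per-trio total is sex-independent.
#' @param panel_variant_rate_case,panel_variant_rate_control expected
#'   recoverable heterozygous panel-gene candidates per proband.
#' @param depth_mean mean sequencing depth (Poisson).
#' @param quality_ratio_range,plant_quality_ratio_range uniform ranges for
#'   the genotype-score/depth ratio of background and planted calls.
#' @param genotype_error_rate per-member per-site probability of replacing
#'   the true genotype with a random different one.
#' @param parental_dropout_rate per-parent per-site probability of allele
#'   dropout: the observed parental call loses its alternate alleles and
#'   its coverage is capped at 10 reads (dropout is by definition
#'   low-coverage), so affected sites fail the parental quality gate.
#' @param predictor_concordance probability that a plant intended to pass
#'   receives the >= 2 damaging predictor votes it needs (missense plants);
#'   plants that miss become recorded decoys.
#' @param background_candidate_rate target fraction of rare background
#'   missense sites receiving >= 2 damaging votes (incidental burden).
#' @param decoy_fraction fraction of plants built to violate one criterion.
#' @param seed integer; fully determines the cohort.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_case_trios = 13, n_control_trios = 19,
                       n_male_case = 5, n_male_control = 12,
                       n_background_sites = 3000,
                       p_rare = 0.3,
                       rare_af_range = c(1e-5, 0.01),
                       common_af_range = c(0.05, 0.5),
                       x_site_fraction = 0.05,
                       rate_de_novo = c(case = 5 / 17 * 1.3, control = 5 / 17 * 2.5),
                       rate_comp_het = c(case = 6 / 17 * 1.3, control = 6 / 17 * 2.5),
                       rate_ar_hom = c(case = 5 / 17 * 1.3, control = 5 / 17 * 2.5),
                       rate_xlr = c(case = 1 / 17 * 1.3, control = 1 / 17 * 2.5),
                       panel_variant_rate_case = 1.1,
                       panel_variant_rate_control = 0.21,
                       depth_mean = 40,
                       quality_ratio_range = c(0.4, 1),
                       plant_quality_ratio_range = c(0.7, 1),
                       genotype_error_rate = 0,
                       parental_dropout_rate = 0,
                       predictor_concordance = 1,
                       background_candidate_rate = 0.05,
                       decoy_fraction = 0.2,
                       seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(
    cfg$n_case_trios > 0, cfg$n_control_trios > 0,
    cfg$n_background_sites > 0,
    cfg$n_male_case >= 0, cfg$n_male_case <= cfg$n_case_trios,
    cfg$n_male_control >= 0, cfg$n_male_control <= cfg$n_control_trios,
    cfg$p_rare >= 0, cfg$p_rare <= 1,
    cfg$decoy_fraction >= 0, cfg$decoy_fraction < 1,
    cfg$genotype_error_rate >= 0, cfg$genotype_error_rate <= 1,
    cfg$parental_dropout_rate >= 0, cfg$parental_dropout_rate <= 1,
    cfg$predictor_concordance >= 0, cfg$predictor_concordance <= 1,
    all(unlist(cfg[grep("^rate_|_rate", names(cfg))]) >= 0)
  )
  structure(cfg, class = "sim_config")
}

#' Study-scale simulation scenario
#'
#' The [sim_config()] defaults with a fixed seed: 13 vs 19 trios, panel
#' candidate rates 1.1 vs 0.21 per proband, monogenic candidate rates 1.3
#' vs 2.5 per proband.
#'
#' @param seed integer seed.
#' @return a `sim_config`.
#' @export
study_scale_scenario <- function(seed = 1317L) {
  sim_config(seed = as.integer(seed))
}

#' @keywords internal
group_rate <- function(x, group) {
  if (length(x) == 1) unname(x) else unname(x[[group]])
}

#' @keywords internal
dosage_to_gt <- function(d) c("hom_ref", "het", "hom_alt")[d + 1L]

#' @keywords internal
hemi_dosage_to_gt <- function(d) c("hemi_ref", "hemi_alt")[d + 1L]

# Background sites shared by every trio of a cohort.
#' @keywords internal
make_background_sites <- function(config) {
  n <- config$n_background_sites
  n_x <- round(n * config$x_site_fraction)
  n_auto <- n - n_x
  chrom <- c(as.character(rep_len(1:22, n_auto)), rep("X", n_x))
  pos <- c(100000L + seq_len(n_auto) * 10L,          # autosomes
           20000L + seq_len(n_x) * 10L)              # non-PAR X interior
  rare <- runif(n) < config$p_rare
  af <- ifelse(rare,
               runif(n, config$rare_af_range[1], config$rare_af_range[2]),
               runif(n, config$common_af_range[1], config$common_af_range[2]))
  consequence <- sample(c("missense", "synonymous", "other"), n,
                        replace = TRUE, prob = c(0.5, 0.35, 0.15))
  # incidental burden: a small fraction of autosomal background missense
  # sites carry a damaging predictor consensus. X background sites never
  # do, so that rare inherited hemizygous variants cannot mimic planted
  # X-linked-recessive events and planted-event recovery stays identifiable.
  damaging_set <- runif(n) < config$background_candidate_rate & chrom != "X"
  sift <- ifelse(damaging_set, "damaging",
                 sample(c("damaging", "tolerated"), n, replace = TRUE,
                        prob = c(0.15, 0.85)))
  polyphen <- ifelse(damaging_set, "damaging", "benign")
  mtaster <- ifelse(damaging_set,
                    sample(c("damaging", "benign"), n, replace = TRUE,
                           prob = c(0.7, 0.3)), "benign")
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                character(1), USE.NAMES = FALSE)
  tibble::tibble(
    chrom = chrom, pos = pos, ref = ref, alt = alt,
    gene = sprintf("BG%05d", seq_len(n)),
    consequence = consequence,
    population_af = af,
    population_nhomalt = ifelse(rare, 0L, as.integer(round(af^2 * 150000))),
    sift = sift, polyphen = polyphen, mutation_taster = mtaster
  )
}

# Hardy-Weinberg parental genotypes and Mendelian transmission for one
# trio over the shared background sites. Returns genotype enums.
#' @keywords internal
background_genotypes <- function(sites, proband_sex) {
  n <- nrow(sites)
  af <- sites$population_af
  on_x <- sites$chrom == "X"
  mo1 <- rbinom(n, 1, af); mo2 <- rbinom(n, 1, af)
  fa1 <- rbinom(n, 1, af); fa2 <- rbinom(n, 1, af)  # fa2 unused on X
  m_trans <- ifelse(runif(n) < 0.5, mo1, mo2)
  f_trans <- ifelse(on_x, fa1, ifelse(runif(n) < 0.5, fa1, fa2))

  mo_gt <- dosage_to_gt(mo1 + mo2)
  fa_gt <- ifelse(on_x, hemi_dosage_to_gt(fa1), dosage_to_gt(fa1 + fa2))
  pro_gt <- if (proband_sex == "male") {
    ifelse(on_x, hemi_dosage_to_gt(m_trans), dosage_to_gt(m_trans + f_trans))
  } else {
    dosage_to_gt(m_trans + f_trans)
  }
  list(pro_gt = pro_gt, mo_gt = mo_gt, fa_gt = fa_gt)
}

# One planted variant row (member of an event) plus its truth row.
# `violated` is NA for passing plants or one of quality/rarity/protein/
# predictors for decoys.
#' @keywords internal
plant_member <- function(config, trio, chrom, pos, gene, class, event_id,
                         pro_gt, mo_gt, fa_gt, violated) {
  qr <- config$plant_quality_ratio_range
  depth <- pmax(rpois(3, config$depth_mean), 11L)
  ratio <- runif(3, qr[1], qr[2])
  if (!is.na(violated) && violated == "quality") depth[1] <- sample(3:10, 1)

  consequence <- sample(c("missense", "nonsense", "frameshift"), 1,
                        prob = c(0.6, 0.2, 0.2))
  if (!is.na(violated) && violated == "protein") consequence <- "synonymous"
  if (!is.na(violated) && violated == "predictors") consequence <- "missense"

  if (consequence == "missense") {
    if (!is.na(violated) && violated == "predictors") {
      sift <- sample(c("damaging", "tolerated"), 1)  # at most 1 vote
      polyphen <- "benign"; mtaster <- "benign"
    } else {
      sift <- "damaging"; mtaster <- "damaging"
      polyphen <- sample(c("damaging", "benign"), 1)
    }
  } else {
    sift <- "absent"; polyphen <- "absent"; mtaster <- "absent"
  }

  af <- if (!is.na(violated) && violated == "rarity") {
    runif(1, 0.02, 0.2)
  } else if (runif(1) < 0.3) NA_real_ else runif(1, 0, 0.005)

  ref <- sample(c("A", "C", "G", "T"), 1)
  alt <- if (consequence == "frameshift") paste0(ref, "A") else
    sample(setdiff(c("A", "C", "G", "T"), ref), 1)

  rec <- tibble::tibble(
    chrom = chrom, pos = pos, ref = ref, alt = alt, gene = gene,
    consequence = consequence, population_af = af,
    population_nhomalt = if (is.na(af)) NA_integer_ else 0L,
    sift = sift, polyphen = polyphen, mutation_taster = mtaster,
    pro_gt = pro_gt, pro_dp = depth[1], pro_score = round(ratio[1] * depth[1], 2),
    mo_gt = mo_gt, mo_dp = depth[2], mo_score = round(ratio[2] * depth[2], 2),
    fa_gt = fa_gt, fa_dp = depth[3], fa_score = round(ratio[3] * depth[3], 2)
  )
  truth <- tibble::tibble(
    trio_id = trio$trio_id, chrom = chrom, pos = pos, ref = ref, alt = alt,
    gene = gene, event_id = event_id, planted_class = class,
    should_pass_filter = is.na(violated), violated_criterion = violated
  )
  list(rec = rec, truth = truth)
}

#' @keywords internal
draw_violation <- function(config) {
  if (runif(1) < config$decoy_fraction) {
    sample(c("quality", "rarity", "protein", "predictors"), 1)
  } else if (runif(1) > config$predictor_concordance) {
    "predictors"
  } else {
    NA_character_
  }
}

# All planted events for one trio. `counter` is an environment holding a
# global position counter so planted positions are unique cohort-wide.
#' @keywords internal
plant_trio_events <- function(config, trio, panel_genes, counter) {
  thin <- 1 - config$decoy_fraction
  grp <- trio$group
  male <- trio$proband_sex == "male"
  r_dn <- group_rate(config$rate_de_novo, grp)
  r_ch <- group_rate(config$rate_comp_het, grp)
  r_ah <- group_rate(config$rate_ar_hom, grp)
  r_xl <- group_rate(config$rate_xlr, grp)
  if (!male) { r_ah <- r_ah + r_xl; r_xl <- 0 }
  r_panel <- if (grp == "case") config$panel_variant_rate_case else
    config$panel_variant_rate_control

  n_ev <- c(
    de_novo = rpois(1, r_dn / thin),
    ar_hom = rpois(1, r_ah / thin),
    comp_het = rpois(1, r_ch / thin),
    xlr = rpois(1, r_xl / thin),
    panel_het = min(rpois(1, r_panel / thin), length(panel_genes))
  )
  # panel plants model distinct incidental heterozygotes: one gene each,
  # so they never combine into a same-gene compound-het pattern
  trio_panel_genes <- sample(panel_genes, n_ev[["panel_het"]])
  panel_k <- 0L
  next_pos <- function(x = FALSE) {
    counter$i <- counter$i + 1L
    if (x) list(chrom = "X", pos = 400000L + counter$i * 10L)
    else list(chrom = as.character(sample(1:22, 1)),
              pos = 5000000L + counter$i * 10L)
  }
  out <- list()
  k <- 0L
  add <- function(x) { k <<- k + 1L; out[[k]] <<- x }
  ev <- 0L
  for (class in names(n_ev)) {
    for (j in seq_len(n_ev[[class]])) {
      ev <- ev + 1L
      event_id <- sprintf("%s_ev%03d", trio$trio_id, ev)
      gene <- if (class == "panel_het") {
        panel_k <- panel_k + 1L
        trio_panel_genes[panel_k]
      } else sprintf("MG_%s_%03d", trio$trio_id, ev)
      viol <- draw_violation(config)
      if (class == "de_novo") {
        p <- next_pos()
        add(plant_member(config, trio, p$chrom, p$pos, gene, "de_novo",
                         event_id, "het", "hom_ref", "hom_ref", viol))
      } else if (class == "ar_hom") {
        p <- next_pos()
        add(plant_member(config, trio, p$chrom, p$pos, gene, "ar_hom",
                         event_id, "hom_alt", "het", "het", viol))
      } else if (class == "comp_het") {
        p1 <- next_pos(); p2 <- next_pos()
        v2 <- if (is.na(viol)) NA_character_ else draw_violation_forced(config)
        add(plant_member(config, trio, p1$chrom, p1$pos, gene,
                         "comp_het_member", event_id,
                         "het", "het", "hom_ref", viol))
        add(plant_member(config, trio, p2$chrom, p2$pos, gene,
                         "comp_het_member", event_id,
                         "het", "hom_ref", "het", v2))
      } else if (class == "xlr") {
        p <- next_pos(x = TRUE)
        add(plant_member(config, trio, p$chrom, p$pos, gene, "xlr",
                         event_id, "hemi_alt", "het", "hemi_ref", viol))
      } else {
        p <- next_pos()
        from_mother <- runif(1) < 0.5
        add(plant_member(config, trio, p$chrom, p$pos, gene, "panel_het",
                         event_id, "het",
                         if (from_mother) "het" else "hom_ref",
                         if (from_mother) "hom_ref" else "het", viol))
      }
    }
  }
  list(
    rec = dplyr::bind_rows(lapply(out, `[[`, "rec")),
    truth = dplyr::bind_rows(lapply(out, `[[`, "truth"))
  )
}

#' @keywords internal
draw_violation_forced <- function(config) {
  sample(c("quality", "rarity", "protein", "predictors"), 1)
}

# Random genotype errors: replace with a different genotype of the same
# ploidy class.
#' @keywords internal
apply_genotype_errors <- function(gt, rate) {
  if (rate <= 0) return(gt)
  hit <- runif(length(gt)) < rate & gt != "missing"
  if (!any(hit)) return(gt)
  dip <- c("hom_ref", "het", "hom_alt")
  for (i in which(hit)) {
    pool <- if (gt[i] %in% dip) dip else c("hemi_ref", "hemi_alt")
    gt[i] <- sample(setdiff(pool, gt[i]), 1)
  }
  gt
}

#' Simulate a case/control trio cohort with known ground truth
#'
#' Generates per-trio variant records: shared background sites with
#' Hardy-Weinberg parental genotypes and Mendelian transmission (X sites
#' respect proband sex), planted events per the configured Poisson rates,
#' Poisson depths, uniform quality ratios, and optional genotype errors
#' and parental allele dropout. The same seed reproduces the cohort
#' exactly.
#'
#' @param config a [sim_config()].
#' @return an object of class `trio_cohort`: a list with `pedigree`
#'   (includes a `group` column), `records` (all trios, one row per
#'   biallelic site), `truth` (one row per planted event member), `panel`
#'   (the packaged panel), `par` (the synthetic PAR intervals) and
#'   `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  old <- local_seed(config$seed)
  on.exit(restore_seed(old))

  n_case <- config$n_case_trios; n_ctrl <- config$n_control_trios
  pedigree <- tibble::tibble(
    family_id = c(sprintf("CASE%02d", seq_len(n_case)),
                  sprintf("CTRL%02d", seq_len(n_ctrl))),
    group = c(rep("case", n_case), rep("control", n_ctrl)),
    proband_sex = c(
      rep(c("male", "female"), c(config$n_male_case,
                                 n_case - config$n_male_case)),
      rep(c("male", "female"), c(config$n_male_control,
                                 n_ctrl - config$n_male_control))
    )
  )
  pedigree$trio_id <- pedigree$family_id
  pedigree$proband_id <- paste0(pedigree$family_id, "_P")
  pedigree$mother_id <- paste0(pedigree$family_id, "_M")
  pedigree$father_id <- paste0(pedigree$family_id, "_F")
  pedigree$affected <- TRUE

  panel <- read_gene_panel(trioburden_panel(), name = "pituitary_panel")
  sites <- make_background_sites(config)
  counter <- new.env(); counter$i <- 0L

  qr <- config$quality_ratio_range
  per_trio <- lapply(seq_len(nrow(pedigree)), function(i) {
    trio <- pedigree[i, ]
    gts <- background_genotypes(sites, trio$proband_sex)
    n <- nrow(sites)
    depth <- matrix(rpois(3 * n, config$depth_mean), ncol = 3)
    ratio <- matrix(runif(3 * n, qr[1], qr[2]), ncol = 3)
    bg <- tibble::tibble(
      chrom = sites$chrom, pos = sites$pos, ref = sites$ref, alt = sites$alt,
      gene = sites$gene, consequence = sites$consequence,
      population_af = sites$population_af,
      population_nhomalt = sites$population_nhomalt,
      sift = sites$sift, polyphen = sites$polyphen,
      mutation_taster = sites$mutation_taster,
      pro_gt = gts$pro_gt, pro_dp = depth[, 1],
      pro_score = round(ratio[, 1] * depth[, 1], 2),
      mo_gt = gts$mo_gt, mo_dp = depth[, 2],
      mo_score = round(ratio[, 2] * depth[, 2], 2),
      fa_gt = gts$fa_gt, fa_dp = depth[, 3],
      fa_score = round(ratio[, 3] * depth[, 3], 2)
    )
    plants <- plant_trio_events(config, trio, panel$genes, counter)
    rec <- dplyr::bind_rows(bg, plants$rec)
    rec$trio_id <- trio$trio_id
    list(rec = rec, truth = plants$truth)
  })

  records <- dplyr::bind_rows(lapply(per_trio, `[[`, "rec"))
  truth <- dplyr::bind_rows(lapply(per_trio, `[[`, "truth"))

  records$pro_gt <- apply_genotype_errors(records$pro_gt,
                                          config$genotype_error_rate)
  records$mo_gt <- apply_genotype_errors(records$mo_gt,
                                         config$genotype_error_rate)
  records$fa_gt <- apply_genotype_errors(records$fa_gt,
                                         config$genotype_error_rate)

  if (config$parental_dropout_rate > 0) {
    for (par_cols in list(c("mo_gt", "mo_dp", "mo_score"),
                          c("fa_gt", "fa_dp", "fa_score"))) {
      hit <- runif(nrow(records)) < config$parental_dropout_rate
      if (any(hit)) {
        gt <- records[[par_cols[1]]][hit]
        hemi <- grepl("^hemi", gt)
        records[[par_cols[1]]][hit] <- ifelse(hemi, "hemi_ref", "hom_ref")
        dp <- pmin(rpois(sum(hit), 5), 10L)
        records[[par_cols[2]]][hit] <- dp
        records[[par_cols[3]]][hit] <- round(runif(sum(hit), 0.3, 0.9) * dp, 2)
      }
    }
  }

  records$allele_index <- 1L
  records$pro_ratio <- ifelse(records$pro_dp > 0,
                              records$pro_score / records$pro_dp, NA_real_)
  records$mo_ratio <- ifelse(records$mo_dp > 0,
                             records$mo_score / records$mo_dp, NA_real_)
  records$fa_ratio <- ifelse(records$fa_dp > 0,
                             records$fa_score / records$fa_dp, NA_real_)
  records <- dplyr::arrange(records, trio_id, chrom, pos)

  structure(
    list(pedigree = pedigree, records = records, truth = truth,
         panel = panel, par = par_intervals("synthetic"), config = config),
    class = "trio_cohort"
  )
}

#' @export
print.trio_cohort <- function(x, ...) {
  cat(sprintf("Synthetic trio cohort: %d case + %d control trios, %d records, %d planted event members\n",
              sum(x$pedigree$group == "case"),
              sum(x$pedigree$group == "control"),
              nrow(x$records), nrow(x$truth)))
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Emits one VCF 4.2 per trio, a 6-column PED, case/control manifests, the
#' panel file, the truth table (TSV) and a JSON echo of the configuration.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ped <- cohort$pedigree
  vcf_paths <- character(nrow(ped))
  for (i in seq_len(nrow(ped))) {
    trio <- ped[i, ]
    rec <- cohort$records[cohort$records$trio_id == trio$trio_id, ]
    vcf_paths[i] <- file.path(dir, paste0(trio$trio_id, ".vcf"))
    write_trio_vcf(rec, trio, vcf_paths[i])
  }
  ped_lines <- c(
    paste(ped$family_id, ped$proband_id, ped$father_id, ped$mother_id,
          ifelse(ped$proband_sex == "male", 1, 2), 2),
    paste(ped$family_id, ped$father_id, 0, 0, 1, 1),
    paste(ped$family_id, ped$mother_id, 0, 0, 2, 1)
  )
  writeLines(ped_lines, file.path(dir, "cohort.ped"))
  writeLines(basename(vcf_paths[ped$group == "case"]),
             file.path(dir, "cases.txt"))
  writeLines(basename(vcf_paths[ped$group == "control"]),
             file.path(dir, "controls.txt"))
  writeLines(cohort$panel$genes, file.path(dir, "panel.txt"))
  utils::write.table(cohort$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- cohort$config
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
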