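# Comparing pipeline output against the simulator's truth table.

#' Collapse the member-level truth table to gene-level events
#'
#' One row per planted event with the monogenic mode it should be
#' recovered as (`NA` for inherited panel heterozygotes, which are not
#' monogenic candidates) and whether it is expected to survive the filter
#' (for compound heterozygotes: every member must pass).
#'
#' @param truth the `truth` table of a [simulate_cohort()] cohort.
#' @return tibble with `trio_id`, `event_id`, `gene`, `class`,
#'   `expected_mode`, `expected_recovered`.
#' @export
truth_events <- function(truth) {
  mode_map <- c(de_novo = "de_novo", ar_hom = "AR_homozygous",
                comp_het_member = "AR_compound_het", xlr = "XLR",
                panel_het = NA_character_)
  dplyr::bind_rows(lapply(split(truth, truth$event_id), function(ev) {
    cls <- sub("_member$", "", ev$planted_class[1])
    tibble::tibble(
      trio_id = ev$trio_id[1], event_id = ev$event_id[1],
      gene = ev$gene[1], class = cls,
      expected_mode = unname(mode_map[ev$planted_class[1]]),
      expected_recovered = all(ev$should_pass_filter)
    )
  }))
}

#' Recall and precision of planted-event recovery
#'
#' Runs the candidate filter and monogenic enumeration on a simulated
#' cohort and compares the recovered gene-level candidates against the
#' planted truth. Recall is over planted events expected to survive the
#' filter; precision is the fraction of reported candidates of each mode
#' that correspond to a planted event. Variant-level filter agreement is
#' also checked: every planted member marked to pass must be in the
#' candidate set, every decoy member absent.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param thresholds a [filter_thresholds()].
#' @return list with `by_mode` (tibble: mode, n_expected, n_recovered,
#'   n_reported, n_matched, recall, precision), `variant_level` (list:
#'   n_pass_expected, n_pass_found, n_decoy_expected, n_decoy_leaked),
#'   `false_de_novo` (reported de novo candidates with no matching planted
#'   de novo), `candidates` (the recovered gene-level candidate table with
#'   a `group` column), and `group_means` (recovered per-proband panel and
#'   monogenic candidate means for each group, the quantities the burden
#'   analyses compare).
#' @export
evaluate_recovery <- function(cohort, thresholds = filter_thresholds()) {
  cand <- cohort_candidates(cohort, thresholds)
  ped <- cohort$pedigree
  mono <- dplyr::bind_rows(lapply(ped$trio_id, function(id) {
    monogenic_candidates(cand[cand$trio_id == id, ], trio_id = id)
  }))
  ev <- truth_events(cohort$truth)
  ev_mono <- ev[!is.na(ev$expected_mode), , drop = FALSE]

  key <- function(trio, gene, mode) paste(trio, gene, mode, sep = "\r")
  truth_keys <- key(ev_mono$trio_id, ev_mono$gene, ev_mono$expected_mode)
  expected_keys <- truth_keys[ev_mono$expected_recovered]
  reported_keys <- key(mono$trio_id, mono$gene, mono$mode)

  modes <- c("de_novo", "AR_homozygous", "AR_compound_het", "XLR")
  by_mode <- dplyr::bind_rows(lapply(modes, function(m) {
    exp_m <- expected_keys[grepl(paste0("\r", m, "$"), expected_keys)]
    rep_m <- reported_keys[mono$mode == m]
    tibble::tibble(
      mode = m,
      n_expected = length(exp_m),
      n_recovered = sum(exp_m %in% reported_keys),
      n_reported = length(rep_m),
      n_matched = sum(rep_m %in% truth_keys),
      recall = ifelse(length(exp_m) > 0,
                      sum(exp_m %in% reported_keys) / length(exp_m), NA_real_),
      precision = ifelse(length(rep_m) > 0,
                         sum(rep_m %in% truth_keys) / length(rep_m), NA_real_)
    )
  }))

  # variant-level filter agreement
  tkey <- function(d) paste(d$trio_id, d$chrom, d$pos, d$ref, d$alt, sep = "\r")
  truth_pass <- cohort$truth[cohort$truth$should_pass_filter, ]
  truth_fail <- cohort$truth[!cohort$truth$should_pass_filter, ]
  cand_keys <- tkey(cand)
  variant_level <- list(
    n_pass_expected = nrow(truth_pass),
    n_pass_found = sum(tkey(truth_pass) %in% cand_keys),
    n_decoy_expected = nrow(truth_fail),
    n_decoy_leaked = sum(tkey(truth_fail) %in% cand_keys)
  )

  dn <- mono[mono$mode == "de_novo", , drop = FALSE]
  dn_truth <- key(ev_mono$trio_id, ev_mono$gene, ev_mono$expected_mode)
  false_de_novo <- dn[!key(dn$trio_id, dn$gene, dn$mode) %in% dn_truth, ,
                      drop = FALSE]

  mono$group <- ped$group[match(mono$trio_id, ped$trio_id)]

  group_means <- lapply(c(case = "case", control = "control"), function(g) {
    ids <- ped$trio_id[ped$group == g]
    pc <- panel_counts(cand[cand$trio_id %in% ids, ], ids, cohort$panel)
    mc <- table(factor(mono$trio_id[mono$trio_id %in% ids], levels = ids))
    list(panel_mean = mean(pc), monogenic_mean = mean(as.integer(mc)))
  })

  list(by_mode = by_mode, variant_level = variant_level,
       false_de_novo = false_de_novo, candidates = mono,
       group_means = group_means)
}
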