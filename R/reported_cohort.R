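# Published summaries of the motivating case-control trio study (13
# congenital-hypopituitarism trios vs 19 non-familial short-stature
# trios), transcribed from its printed variant tables. These encode the
# study's *results tables*, not its raw data (which are controlled
# access); the counting and statistics operations applied to them
# reproduce the study's printed proportions, means and exact p values.

#' Reported cohort sizes
#' @return tibble with `group`, `n_trios`, `n_male`.
#' @export
reported_cohort_sizes <- function() {
  path <- system.file("extdata", "reported_cohort_sizes.tsv",
                      package = "trioburden", mustWork = TRUE)
  tibble::as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                                      stringsAsFactors = FALSE))
}

#' Reported rare predicted-pathogenic panel-gene variants
#'
#' One row per variant found in the pituitary-development gene panel, with
#' the carrying subject, consequence class, parental origin and population
#' allele frequency (`NA` = not found in the reference database).
#'
#' @return tibble with columns `group`, `subject`, `gene`, `variant`,
#'   `type`, `inherited_from`, `gnomad_af`.
#' @export
reported_panel_variants <- function() {
  path <- system.file("extdata", "reported_panel_variants.tsv",
                      package = "trioburden", mustWork = TRUE)
  tibble::as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                                      na.strings = "NA",
                                      stringsAsFactors = FALSE))
}

#' Reported gene-level monogenic candidates
#'
#' One row per (trio, inheritance mode, gene) candidate compatible with a
#' fully penetrant monogenic etiology; `causative` flags candidates in
#' genes previously established to cause the proband's condition.
#'
#' @return tibble with columns `group`, `trio`, `mode`, `gene`,
#'   `causative`.
#' @export
reported_monogenic_candidates <- function() {
  path <- system.file("extdata", "reported_monogenic_candidates.tsv",
                      package = "trioburden", mustWork = TRUE)
  tibble::as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                                      stringsAsFactors = FALSE))
}

#' Per-proband counts from a reported table
#'
#' Tallies rows per carrier (subject or trio) within one group and pads
#' with zeros up to the group size, giving the count vector that the
#' burden statistics consume.
#'
#' @param tab a reported table with a `group` column and a carrier-ID
#'   column.
#' @param group `"case"` or `"control"`.
#' @param id_col name of the carrier-ID column (`"subject"` or `"trio"`).
#' @param n_probands group size; defaults to the packaged cohort sizes.
#' @return integer vector of length `n_probands`.
#' @export
reported_counts <- function(tab, group, id_col = "subject",
                            n_probands = NULL) {
  if (is.null(n_probands)) {
    sizes <- reported_cohort_sizes()
    n_probands <- sizes$n_trios[sizes$group == group]
  }
  sub <- tab[tab$group == group, , drop = FALSE]
  per_carrier <- as.integer(table(sub[[id_col]]))
  if (length(per_carrier) > n_probands) {
    stop("more carriers than probands in group ", group)
  }
  c(per_carrier, rep(0L, n_probands - length(per_carrier)))
}

#' Reproduce the reported burden comparisons from the printed tables
#'
#' Recomputes, from the transcribed variant tables alone, the quantities
#' the study printed: per-group panel-variant count vectors with their
#' means and percent of probands carrying at least one variant, the Fisher
#' exact p for that proportion comparison, the number of distinct panel
#' genes hit in the case group, the gene-level monogenic candidate mean,
#' and the comparison of trios carrying an established causative candidate.
#'
#' @param mw_seed seed for the Mann-Whitney Monte-Carlo fallback.
#' @return a list with components `panel` (a [compare_groups()]
#'   `burden_result`), `n_case_panel_genes`, `monogenic_case_mean`,
#'   `causative` (list with `n_case`, `n_control`, `p_fisher`).
#' @export
reported_burden_summary <- function(mw_seed = 1L) {
  sizes <- reported_cohort_sizes()
  n_case <- sizes$n_trios[sizes$group == "case"]
  n_control <- sizes$n_trios[sizes$group == "control"]

  pv <- reported_panel_variants()
  case_counts <- reported_counts(pv, "case", "subject", n_case)
  control_counts <- reported_counts(pv, "control", "subject", n_control)
  panel <- compare_groups(case_counts, control_counts, seed = mw_seed)

  mono <- reported_monogenic_candidates()
  mono_case <- reported_counts(mono, "case", "trio", n_case)

  caus <- mono[mono$causative, , drop = FALSE]
  n_caus_case <- length(unique(caus$trio[caus$group == "case"]))
  n_caus_control <- length(unique(caus$trio[caus$group == "control"]))
  caus_tab <- matrix(c(n_caus_case, n_case - n_caus_case,
                       n_caus_control, n_control - n_caus_control),
                     nrow = 2, byrow = TRUE)

  list(
    panel = panel,
    n_case_panel_genes = length(unique(pv$gene[pv$group == "case"])),
    monogenic_case_mean = mean(mono_case),
    causative = list(
      n_case = n_caus_case, n_control = n_caus_control,
      prop_control = n_caus_control / n_control,
      p_fisher = fisher_exact_2x2(caus_tab)
    )
  )
}
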