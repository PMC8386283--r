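# Orchestration: load a cohort from files (or take a simulated one), run
# the panel-burden analysis and the monogenic-candidate analysis, and write
# machine-readable reports.

#' Run configuration for a file-based analysis
#'
#' @param pedigree path to the cohort PED file.
#' @param cases,controls manifest files listing the case / control trio VCF
#'   paths (one per line, relative to the manifest's directory or
#'   absolute). The two manifests must be disjoint.
#' @param panel path to the gene-panel file.
#' @param thresholds a [filter_thresholds()].
#' @param dialect a [vcf_dialect()].
#' @param par PAR intervals.
#' @param out_dir optional report directory.
#' @param seed seed for the Monte-Carlo permutation fallback.
#' @return an object of class `run_config`.
#' @export
run_config <- function(pedigree, cases, controls, panel,
                       thresholds = filter_thresholds(),
                       dialect = vcf_dialect(),
                       par = par_intervals("GRCh37"),
                       out_dir = NULL, seed = 1L) {
  for (f in c(pedigree, cases, controls, panel)) {
    if (!file.exists(f)) stop("file not found: ", f)
  }
  resolve <- function(manifest) {
    x <- trimws(readLines(manifest))
    x <- x[x != "" & !startsWith(x, "#")]
    ifelse(file.exists(x), x, file.path(dirname(manifest), x))
  }
  case_vcfs <- resolve(cases)
  control_vcfs <- resolve(controls)
  if (length(intersect(normalizePath(case_vcfs, mustWork = FALSE),
                       normalizePath(control_vcfs, mustWork = FALSE))) > 0) {
    stop("case and control manifests overlap")
  }
  missing <- c(case_vcfs, control_vcfs)[!file.exists(c(case_vcfs, control_vcfs))]
  if (length(missing) > 0) stop("VCF not found: ", paste(missing, collapse = ", "))
  structure(
    list(pedigree = pedigree, case_vcfs = case_vcfs,
         control_vcfs = control_vcfs, panel = panel,
         thresholds = thresholds, dialect = dialect, par = par,
         out_dir = out_dir, seed = as.integer(seed)),
    class = "run_config"
  )
}

# Sample names from a VCF header without a full parse.
#' @keywords internal
peek_vcf_samples <- function(path) {
  con <- file(path, "r")
  on.exit(close(con))
  repeat {
    lines <- readLines(con, n = 100)
    if (length(lines) == 0) stop("no #CHROM header line in ", path)
    hit <- grep("^#CHROM", lines, value = TRUE)
    if (length(hit) > 0) {
      fields <- strsplit(hit[1], "\t", fixed = TRUE)[[1]]
      return(fields[-(1:9)])
    }
  }
}

#' Load a case/control trio cohort from files
#'
#' Reads the pedigree and every manifest VCF, matching each VCF to the trio
#' whose proband appears in its sample columns. Every pedigree trio must be
#' covered by exactly one manifest VCF containing all three members.
#'
#' @param config a [run_config()].
#' @return a `trio_cohort` list (`pedigree` with `group` column, `records`,
#'   `panel`, `par`), as produced by [simulate_cohort()] minus the truth
#'   table.
#' @export
load_cohort <- function(config) {
  stopifnot(inherits(config, "run_config"))
  ped <- read_pedigree(config$pedigree)
  ped$trio_id <- ped$family_id
  vcfs <- tibble::tibble(
    path = c(config$case_vcfs, config$control_vcfs),
    group = rep(c("case", "control"),
                c(length(config$case_vcfs), length(config$control_vcfs)))
  )
  ped$group <- NA_character_
  ped$vcf <- NA_character_
  for (i in seq_len(nrow(vcfs))) {
    samples <- peek_vcf_samples(vcfs$path[i])
    hit <- which(ped$proband_id %in% samples)
    if (length(hit) != 1) {
      stop("VCF ", vcfs$path[i], " matches ", length(hit), " pedigree trios")
    }
    ped$group[hit] <- vcfs$group[i]
    ped$vcf[hit] <- vcfs$path[i]
  }
  if (any(is.na(ped$vcf))) {
    stop("no VCF provided for trio(s): ",
         paste(ped$family_id[is.na(ped$vcf)], collapse = ", "))
  }
  records <- dplyr::bind_rows(lapply(seq_len(nrow(ped)), function(i) {
    read_trio_vcf(ped$vcf[i], ped[i, ], dialect = config$dialect,
                  par = config$par)
  }))
  structure(
    list(pedigree = ped, records = records,
         panel = read_gene_panel(config$panel), par = config$par),
    class = "trio_cohort"
  )
}

#' Candidate variants of a cohort, with transmission categories
#'
#' Applies [filter_candidates()] to every trio's records and classifies
#' each candidate's transmission with [classify_transmission()]. The
#' returned table is the per-variant substrate of both burden analyses.
#'
#' @param cohort a `trio_cohort` (from [simulate_cohort()] or
#'   [load_cohort()]).
#' @param thresholds a [filter_thresholds()].
#' @return tibble of candidate rows with `category` and `group` columns.
#' @export
cohort_candidates <- function(cohort, thresholds = filter_thresholds()) {
  cand <- filter_candidates(cohort$records, thresholds)
  ped <- cohort$pedigree
  out <- dplyr::bind_rows(lapply(split(cand, cand$trio_id), function(sub) {
    sex <- ped$proband_sex[match(sub$trio_id[1], ped$trio_id)]
    sub$category <- classify_transmission(sub, sex, thresholds, cohort$par)
    sub
  }))
  if (nrow(out) == 0) {
    out <- cand
    out$category <- character(0)
  }
  out$group <- ped$group[match(out$trio_id, ped$trio_id)]
  out
}

#' @keywords internal
inheritance_label <- function(category) {
  c(de_novo = "De novo", maternal = "Mother", paternal = "Father",
    biparental_homozygous = "Both parents",
    hemizygous_maternal = "Mother (hemizygous)",
    inconsistent = "Inconsistent", unresolved = "Unresolved")[category]
}

#' Panel-burden analysis (screen of pituitary-development genes)
#'
#' Counts, per proband, the rare predicted-pathogenic candidate variants
#' falling in the gene panel — regardless of inheritance pattern, so that
#' incompletely penetrant and oligogenic contributions are captured — and
#' compares the case and control distributions with the exact statistics.
#'
#' @param cohort a `trio_cohort`.
#' @param thresholds a [filter_thresholds()].
#' @param panel optional [read_gene_panel()] override (defaults to the
#'   cohort's panel).
#' @param mw_method,seed passed to [compare_groups()].
#' @return a list of class `burden_analysis`: `result` (a
#'   [compare_groups()] `burden_result`), `variants` (per-variant table
#'   with gene, consequence, inheritance and population frequency),
#'   `counts` (per-proband counts with group).
#' @export
run_analysis1 <- function(cohort, thresholds = filter_thresholds(),
                          panel = NULL, mw_method = "exact_permutation",
                          seed = 1L) {
  panel <- panel %||% cohort$panel
  cand <- cohort_candidates(cohort, thresholds)
  ped <- cohort$pedigree
  in_panel <- !is.na(cand$gene) & toupper(cand$gene) %in% panel$genes
  variants <- cand[in_panel, c("trio_id", "group", "gene", "chrom", "pos",
                               "ref", "alt", "consequence", "category",
                               "population_af", "review_recommended")]
  variants$inherited_from <- inheritance_label(variants$category)

  case_ids <- ped$trio_id[ped$group == "case"]
  control_ids <- ped$trio_id[ped$group == "control"]
  case_counts <- panel_counts(cand[cand$group == "case", ], case_ids, panel)
  control_counts <- panel_counts(cand[cand$group == "control", ],
                                 control_ids, panel)
  res <- compare_groups(case_counts, control_counts, mw_method = mw_method,
                        seed = seed)
  counts <- tibble::tibble(
    trio_id = c(case_ids, control_ids),
    group = rep(c("case", "control"),
                c(length(case_ids), length(control_ids))),
    n_panel_variants = c(case_counts, control_counts)
  )
  structure(list(analysis = "panel_burden", result = res,
                 variants = variants, counts = counts),
            class = "burden_analysis")
}

#' Monogenic-candidate analysis (genome-wide, fully penetrant models)
#'
#' Enumerates gene-level monogenic candidates (de novo, AR homozygous, AR
#' compound heterozygous, XLR) per trio via [monogenic_candidates()] and
#' compares the per-proband candidate counts between groups.
#'
#' @inheritParams run_analysis1
#' @return a list of class `burden_analysis`: `result`, `candidates`
#'   (per-trio gene-level table: trio, mode, gene, variants), `counts`.
#' @export
run_analysis2 <- function(cohort, thresholds = filter_thresholds(),
                          mw_method = "exact_permutation", seed = 1L) {
  cand <- cohort_candidates(cohort, thresholds)
  ped <- cohort$pedigree
  mono <- dplyr::bind_rows(lapply(ped$trio_id, function(id) {
    monogenic_candidates(cand[cand$trio_id == id, ], trio_id = id)
  }))
  mono$group <- ped$group[match(mono$trio_id, ped$trio_id)]

  tally <- table(factor(mono$trio_id, levels = ped$trio_id))
  counts <- tibble::tibble(
    trio_id = ped$trio_id, group = ped$group,
    n_monogenic_candidates = as.integer(tally)
  )
  res <- compare_groups(counts$n_monogenic_candidates[counts$group == "case"],
                        counts$n_monogenic_candidates[counts$group == "control"],
                        mw_method = mw_method, seed = seed)
  structure(list(analysis = "monogenic_candidates", result = res,
                 candidates = mono, counts = counts),
            class = "burden_analysis")
}

#' @export
print.burden_analysis <- function(x, ...) {
  cat(sprintf("Analysis: %s\n", x$analysis))
  print(x$result)
  invisible(x)
}

#' Per-trio quality-control report
#'
#' @param cohort a `trio_cohort`.
#' @return tibble with `trio_id`, `n_records`, `mendelian_error_rate`.
#' @export
qc_report <- function(cohort) {
  ped <- cohort$pedigree
  dplyr::bind_rows(lapply(seq_len(nrow(ped)), function(i) {
    rec <- cohort$records[cohort$records$trio_id == ped$trio_id[i], ]
    tibble::tibble(
      trio_id = ped$trio_id[i],
      n_records = nrow(rec),
      mendelian_error_rate = mendelian_error_rate(rec, ped$proband_sex[i],
                                                  cohort$par)
    )
  }))
}

#' Write a burden analysis as TSV + JSON
#'
#' The per-variant (or per-candidate) table goes to
#' `<prefix>_table.tsv`; the summary quantities (means per proband,
#' percent of probands with at least one candidate, both exact p values,
#' count vectors and contingency table) to `<prefix>_summary.json` at full
#' precision with a versioned schema.
#'
#' @param analysis a `burden_analysis`.
#' @param dir output directory.
#' @param prefix file-name prefix (defaults to the analysis name).
#' @return the JSON path, invisibly.
#' @export
write_analysis_report <- function(analysis, dir, prefix = analysis$analysis) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- if (!is.null(analysis$variants)) analysis$variants else
    analysis$candidates
  utils::write.table(tab, file.path(dir, paste0(prefix, "_table.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  r <- analysis$result
  summary <- list(
    schema_version = "1.0",
    analysis = analysis$analysis,
    n_case = length(r$case_counts), n_control = length(r$control_counts),
    case_mean = r$case_mean, control_mean = r$control_mean,
    case_pct_ge1 = 100 * r$case_prop_ge1,
    control_pct_ge1 = 100 * r$control_prop_ge1,
    u_statistic = r$u_statistic, p_mannwhitney = r$p_mannwhitney,
    mw_method_used = r$mw_method_used, p_fisher = r$p_fisher,
    case_counts = r$case_counts, control_counts = r$control_counts,
    contingency = r$contingency
  )
  path <- file.path(dir, paste0(prefix, "_summary.json"))
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Run the full two-stage analysis from a file-based configuration
#'
#' Loads the cohort, runs the panel-burden and monogenic-candidate
#' analyses and the Mendelian-error QC, and (if `out_dir` is set) writes
#' the reports.
#'
#' @param config a [run_config()].
#' @return list with `analysis1`, `analysis2`, `qc`.
#' @export
run_pipeline <- function(config) {
  cohort <- load_cohort(config)
  panel <- read_gene_panel(config$panel)
  a1 <- run_analysis1(cohort, config$thresholds, panel = panel,
                      seed = config$seed)
  a2 <- run_analysis2(cohort, config$thresholds, seed = config$seed)
  qc <- qc_report(cohort)
  if (!is.null(config$out_dir)) {
    write_analysis_report(a1, config$out_dir)
    write_analysis_report(a2, config$out_dir)
    utils::write.table(qc, file.path(config$out_dir, "qc_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(analysis1 = a1, analysis2 = a2, qc = qc)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a
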