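# Gene-panel handling and the case-vs-control burden comparison.

#' Read a gene panel file
#'
#' One symbol per line; `#` starts a comment. Symbols are uppercased and
#' resolved through the alias map (by default only TPIT -> TBX19 ships).
#' The packaged panel (`trioburden_panel()`) lists genes implicated in
#' pituitary gland development but is an incomplete reconstruction of the
#' 42-gene panel used in the motivating study, whose full listing is not
#' redistributable; supply the full panel file for faithful reproduction.
#'
#' @param path panel file path.
#' @param name panel name (defaults to the file name).
#' @param aliases named character vector mapping alias -> canonical symbol.
#' @return an object of class `gene_panel`: list with `name` and sorted
#'   unique `genes`.
#' @export
read_gene_panel <- function(path, name = basename(path),
                            aliases = c(TPIT = "TBX19")) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  genes <- toupper(trimws(lines))
  genes <- genes[genes != ""]
  if (length(genes) == 0) stop("empty gene panel: ", path)
  hit <- genes %in% names(aliases)
  genes[hit] <- unname(aliases[genes[hit]])
  structure(list(name = name, genes = sort(unique(genes))),
            class = "gene_panel")
}

#' Path to the packaged pituitary-development gene panel
#' @return file path of the shipped panel.
#' @export
trioburden_panel <- function() {
  system.file("extdata", "pituitary_panel.txt", package = "trioburden",
              mustWork = TRUE)
}

#' @export
print.gene_panel <- function(x, ...) {
  cat(sprintf("Gene panel '%s': %d genes\n", x$name, length(x$genes)))
  cat(" ", paste(x$genes, collapse = " "), "\n")
  invisible(x)
}

#' Per-proband panel variant counts
#'
#' Counts, for each proband, the candidate *variants* whose gene belongs to
#' the panel (variant-level: a proband with qualifying variants in three
#' panel genes counts 3). Probands without candidates count 0.
#'
#' @param candidates tibble of candidate variants with `trio_id` and `gene`
#'   columns (any gene-level table with those columns works too).
#' @param trio_ids character vector of all proband/trio identifiers in the
#'   group, including those with no candidates.
#' @param panel a [read_gene_panel()] object, or a character vector of
#'   symbols.
#' @return named integer vector of counts, one per element of `trio_ids`.
#' @export
panel_counts <- function(candidates, trio_ids, panel) {
  genes <- if (inherits(panel, "gene_panel")) panel$genes else toupper(panel)
  hit <- candidates[!is.na(candidates$gene) &
                      toupper(candidates$gene) %in% genes, , drop = FALSE]
  counts <- table(factor(hit$trio_id, levels = trio_ids))
  stats::setNames(as.integer(counts), trio_ids)
}

#' Compare candidate burden between case and control groups
#'
#' Populates the full burden comparison: per-group count vectors, means,
#' proportions of probands with at least one candidate, the Mann-Whitney U
#' statistic with its exact-permutation two-sided p value (for the mean
#' comparison), and the two-sided Fisher exact p value on the 2x2 table of
#' probands with/without at least one candidate (for the proportion
#' comparison).
#'
#' @param case_counts,control_counts non-negative integer vectors, one
#'   entry per proband.
#' @param mw_method method for [mann_whitney_u()].
#' @param seed seed for the Monte-Carlo permutation fallback.
#' @return an object of class `burden_result`.
#' @examples
#' compare_groups(c(2, 1, 0, 3), c(0, 0, 1, 0, 0))
#' @export
compare_groups <- function(case_counts, control_counts,
                           mw_method = "exact_permutation", seed = 1L) {
  if (length(case_counts) == 0 || length(control_counts) == 0) {
    stop("both groups must be non-empty")
  }
  stopifnot(all(case_counts >= 0), all(control_counts >= 0))
  contingency <- matrix(
    c(sum(case_counts >= 1), sum(case_counts == 0),
      sum(control_counts >= 1), sum(control_counts == 0)),
    nrow = 2, byrow = TRUE,
    dimnames = list(c("case", "control"), c("ge1", "none"))
  )
  mw <- mann_whitney_u(case_counts, control_counts, method = mw_method,
                       seed = seed)
  structure(
    list(
      case_counts = as.integer(case_counts),
      control_counts = as.integer(control_counts),
      case_mean = mean(case_counts),
      control_mean = mean(control_counts),
      case_prop_ge1 = mean(case_counts >= 1),
      control_prop_ge1 = mean(control_counts >= 1),
      u_statistic = mw$u,
      p_mannwhitney = mw$p,
      mw_method_used = mw$method_used,
      p_fisher = fisher_exact_2x2(contingency),
      contingency = contingency
    ),
    class = "burden_result"
  )
}

#' @export
print.burden_result <- function(x, ...) {
  cat("Burden comparison (case vs control)\n")
  cat(sprintf("  probands:        %d vs %d\n",
              length(x$case_counts), length(x$control_counts)))
  cat(sprintf("  mean/proband:    %.2g vs %.2g  (Mann-Whitney U = %g, P = %.2f, %s)\n",
              x$case_mean, x$control_mean, x$u_statistic, x$p_mannwhitney,
              x$mw_method_used))
  cat(sprintf("  %% with >= 1:     %.0f%% vs %.0f%%  (Fisher exact P = %.2f)\n",
              100 * x$case_prop_ge1, 100 * x$control_prop_ge1, x$p_fisher))
  invisible(x)
}

#' @export
as.list.burden_result <- function(x, ...) unclass(x)
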