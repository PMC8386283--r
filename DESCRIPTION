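Package: trioburden
Title: Rare-Variant Burden and Monogenic-Candidate Analysis for Case-Control Trio Exomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-stage burden analysis of family-trio exome cohorts.
    Reads pedigrees and per-trio annotated VCFs into normalized biallelic trio
    records, applies a five-criterion definition of rare predicted-pathogenic
    candidate variants (depth, genotype-quality ratio, population allele
    frequency, protein-altering consequence, predictor consensus), classifies
    transmission within each trio (de novo, parental, biparental-homozygous,
    X-linked hemizygous), enumerates gene-level monogenic candidates under
    fully penetrant autosomal-recessive, X-linked-recessive and de novo
    models, and compares candidate burden between case and control cohorts
    with exact statistics (two-sided Fisher exact test by the
    point-probability method and an exact-permutation Mann-Whitney U test,
    both implemented from first principles). A synthetic trio-cohort
    generator with Hardy-Weinberg parental genotypes, Mendelian transmission
    and planted events of known truth makes every stage testable without
    access to controlled human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    stats,
    tibble,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
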