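#' Read trios from a 6-column PED file
#'
#' Parses a standard pedigree file (family, individual, father, mother, sex,
#' phenotype; whitespace-separated, `#` comments allowed) and returns one
#' trio per affected child whose two parents are both present. Children with
#' a missing parent (ID `"0"` or a parent ID that has no row of its own) are
#' reported with a warning and skipped. Control probands must be coded
#' affected (phenotype 2) within their own family so that their trio is
#' formed; case/control status is assigned later via cohort manifests.
#'
#' @param path path to the PED file.
#' @return a tibble with columns `family_id`, `proband_id`, `proband_sex`
#'   (`"male"`/`"female"`), `mother_id`, `father_id`, `affected` (logical).
#' @examples
#' ped <- tempfile(fileext = ".ped")
#' writeLines(c("F1 P1 D1 M1 1 2", "F1 D1 0 0 1 1", "F1 M1 0 0 2 1"), ped)
#' read_pedigree(ped)
#' @export
read_pedigree <- function(path) {
  stopifnot(file.exists(path))
  ped <- utils::read.table(path, header = FALSE, comment.char = "#",
                           colClasses = "character")
  if (ncol(ped) < 6) stop("PED file must have 6 columns")
  names(ped)[1:6] <- c("family_id", "id", "father_id", "mother_id",
                       "sex", "phenotype")

  kids <- ped[ped$phenotype == "2", , drop = FALSE]
  have_row <- function(id) id != "0" & id %in% ped$id
  complete <- have_row(kids$father_id) & have_row(kids$mother_id)
  if (any(!complete)) {
    warning(sprintf("skipping %d affected child(ren) without both parents: %s",
                    sum(!complete), paste(kids$id[!complete], collapse = ", ")))
    kids <- kids[complete, , drop = FALSE]
  }
  if (anyDuplicated(kids$id)) {
    stop("duplicate proband IDs in pedigree: ",
         paste(unique(kids$id[duplicated(kids$id)]), collapse = ", "))
  }
  if (any(!kids$sex %in% c("1", "2"))) {
    stop("unknown sex code for proband(s): ",
         paste(kids$id[!kids$sex %in% c("1", "2")], collapse = ", "),
         " (sex is required for X-linked logic)")
  }
  bad <- kids$id == kids$mother_id | kids$id == kids$father_id |
    kids$mother_id == kids$father_id
  if (any(bad)) stop("proband, mother and father IDs must be distinct")

  tibble::tibble(
    family_id = kids$family_id,
    proband_id = kids$id,
    proband_sex = ifelse(kids$sex == "1", "male", "female"),
    mother_id = kids$mother_id,
    father_id = kids$father_id,
    affected = TRUE
  )
}
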