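#' Read a trio pedigree (PED)
#'
#' Parses a whitespace-separated 6-column PED file (family, individual, father,
#' mother, sex, affected) with an optional 7th column carrying the severity of
#' comorbid intellectual developmental disorder (IDD) for probands. Probands
#' are the affected individuals with both parent ids present; both parents must
#' resolve to rows of the same family.
#'
#' @param path path to the PED file.
#' @return a data.frame with one row per individual and columns `family_id`,
#'   `individual_id`, `father_id`, `mother_id` (NA for founders), `sex`
#'   (`"male"`/`"female"`), `affected` (`"yes"`/`"no"`), `idd_severity` (one of
#'   `none`, `borderline`, `mild`, `moderate`, `severe`, `profound`,
#'   `unknown`), and `role` (`proband`/`mother`/`father`/`other`). The number
#'   of complete trios is attached as attribute `n_trios`.
#' @seealso [trio_members()]
#' @export
read_pedigree <- function(path) {
  if (!file.exists(path)) trioppv_stop("pedigree file not found: ", path)
  raw <- tryCatch(
    utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                      colClasses = "character", fill = TRUE),
    error = function(e) NULL)
  if (is.null(raw) || nrow(raw) == 0) {
    ped <- data.frame(family_id = character(), individual_id = character(),
                      father_id = character(), mother_id = character(),
                      sex = character(), affected = character(),
                      idd_severity = character(), role = character(),
                      stringsAsFactors = FALSE)
    attr(ped, "n_trios") <- 0L
    return(ped)
  }
  if (ncol(raw) < 6) trioppv_stop("PED file must have at least 6 columns")
  sev_levels <- c("none", "borderline", "mild", "moderate", "severe",
                  "profound", "unknown")
  sex <- c(`1` = "male", `2` = "female")[raw[[5]]]
  if (anyNA(sex))
    trioppv_stop("unknown sex code in PED: ",
                 paste(unique(raw[[5]][is.na(sex)]), collapse = ", "))
  affected <- ifelse(raw[[6]] == "2", "yes", "no")
  miss <- function(x) ifelse(x %in% c("0", ".", ""), NA_character_, x)
  if (ncol(raw) >= 7) {
    sev <- tolower(miss(raw[[7]]))
    sev[is.na(sev)] <- "unknown"
    bad <- setdiff(unique(sev), sev_levels)
    if (length(bad))
      trioppv_stop("unknown IDD severity value(s): ", paste(bad, collapse = ", "))
  } else {
    sev <- rep("unknown", nrow(raw))
  }
  ped <- data.frame(
    family_id = raw[[1]], individual_id = raw[[2]],
    father_id = miss(raw[[3]]), mother_id = miss(raw[[4]]),
    sex = unname(sex), affected = affected, idd_severity = sev,
    stringsAsFactors = FALSE)

  has_parents <- !is.na(ped$father_id) & !is.na(ped$mother_id)
  ped$role <- "other"
  ped$role[has_parents & ped$affected == "yes"] <- "proband"
  # resolve parents; error when a proband's parent is absent from its family
  for (i in which(ped$role == "proband")) {
    fam <- ped$family_id[i]
    in_fam <- ped$individual_id[ped$family_id == fam]
    if (!(ped$father_id[i] %in% in_fam) || !(ped$mother_id[i] %in% in_fam))
      trioppv_stop("family ", fam, ": proband ", ped$individual_id[i],
                   " has a parent id absent from the pedigree")
    ped$role[ped$family_id == fam & ped$individual_id == ped$father_id[i]] <- "father"
    ped$role[ped$family_id == fam & ped$individual_id == ped$mother_id[i]] <- "mother"
  }
  probands <- ped[ped$role == "proband", ]
  if (any(duplicated(probands$family_id)))
    trioppv_stop("more than one proband in family ",
                 probands$family_id[duplicated(probands$family_id)][1])
  attr(ped, "n_trios") <- nrow(probands)
  ped
}

#' Trio membership table
#'
#' @param ped pedigree data.frame from [read_pedigree()].
#' @return one row per complete trio: `family_id`, `proband`, `mother`,
#'   `father`, `proband_sex`, `idd_severity`, and logical `idd` (severity
#'   mild/moderate/severe/profound; borderline, none and unknown count as
#'   non-IDD, with a warning when unknown severities are present).
#' @export
trio_members <- function(ped) {
  pro <- ped[ped$role == "proband", ]
  if (any(pro$idd_severity == "unknown") && nrow(pro) > 0)
    warning("probands with unknown IDD severity are stratified as non-IDD")
  data.frame(
    family_id = pro$family_id,
    proband = pro$individual_id,
    mother = pro$mother_id,
    father = pro$father_id,
    proband_sex = pro$sex,
    idd_severity = pro$idd_severity,
    idd = pro$idd_severity %in% c("mild", "moderate", "severe", "profound"),
    stringsAsFactors = FALSE)
}
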