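#' Cohort objects
#'
#' A cohort bundles a region atlas with per-subject demographics and a
#' complete subjects-by-regions volume matrix in ml. Diagnosis labels follow
#' the memory-clinic convention: SCD, MCI, AD, VaD, DLB, Other, FTD, with
#' an FTD subtype (bvFTD, svPPA, nfvPPA, rtvFTD, FTD_MND) recorded for FTD
#' subjects only. Every subject must have a volume for every atlas region.
#'
#' @param atlas a [region_atlas()].
#' @param subjects data frame with columns `subject_id`, `diagnosis`,
#'   `ftd_subtype` (NA for non-FTD), `age` (years), `sex`
#'   (`"female"`/`"male"`), `tiv` (ml), optional `field_strength` (tesla).
#' @param volumes numeric matrix, one row per subject (in `subjects` order)
#'   and one column per atlas region, volumes in ml.
#' @param provenance free-text metadata string.
#' @return an object of class `ftd_cohort`.
#' @export
ftd_cohort <- function(atlas, subjects, volumes, provenance = "") {
  atlas <- validate_atlas(atlas)
  obj <- structure(
    list(atlas = atlas, subjects = subjects,
         volumes = as.matrix(volumes), provenance = provenance),
    class = "ftd_cohort"
  )
  validate_cohort(obj)
}

.diagnosis_levels <- c("SCD", "MCI", "AD", "VaD", "DLB", "Other", "FTD")
.ftd_subtypes <- c("bvFTD", "svPPA", "nfvPPA", "rtvFTD", "FTD_MND")

validate_cohort <- function(x) {
  stopifnot(inherits(x, "ftd_cohort"))
  s <- x$subjects
  need <- c("subject_id", "diagnosis", "age", "sex", "tiv")
  missing <- setdiff(need, names(s))
  if (length(missing) > 0L) {
    stop("cohort subjects table missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!"ftd_subtype" %in% names(s)) s$ftd_subtype <- NA_character_
  if (!"field_strength" %in% names(s)) s$field_strength <- NA_real_
  dup <- unique(s$subject_id[duplicated(s$subject_id)])
  if (length(dup) > 0L) {
    stop("duplicate subject_id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(s$diagnosis), .diagnosis_levels)
  if (length(bad) > 0L) {
    stop("unknown diagnosis label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  bad_st <- setdiff(stats::na.omit(unique(s$ftd_subtype)), .ftd_subtypes)
  if (length(bad_st) > 0L) {
    stop("unknown FTD subtype(s): ", paste(bad_st, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.na(s$ftd_subtype) & s$diagnosis != "FTD")) {
    stop("ftd_subtype recorded for a non-FTD subject", call. = FALSE)
  }
  no_st <- s$subject_id[s$diagnosis == "FTD" & is.na(s$ftd_subtype)]
  if (length(no_st) > 0L) {
    warning("FTD subject(s) without subtype: ",
            paste(no_st, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(s$age) | s$age <= 0)) {
    stop("ages must be positive", call. = FALSE)
  }
  if (any(!is.finite(s$tiv) | s$tiv <= 0)) {
    stop("tiv must be positive for all subjects", call. = FALSE)
  }
  v <- x$volumes
  if (nrow(v) != nrow(s)) {
    stop("volume matrix has ", nrow(v), " rows for ", nrow(s), " subjects",
         call. = FALSE)
  }
  missing_r <- setdiff(x$atlas$name, colnames(v))
  if (length(missing_r) > 0L) {
    stop("cohort is missing volume column(s) for region(s): ",
         paste(missing_r, collapse = ", "), call. = FALSE)
  }
  if (anyNA(v[, x$atlas$name]) || any(v[, x$atlas$name] < 0)) {
    stop("volumes must be non-negative and complete (no missing values)",
         call. = FALSE)
  }
  x$subjects <- s
  x$volumes <- v[, x$atlas$name, drop = FALSE]
  rownames(x$volumes) <- s$subject_id
  x
}

#' @export
print.ftd_cohort <- function(x, ...) {
  cat("FTD study cohort:", nrow(x$subjects), "subjects,",
      nrow(x$atlas), "regions\n")
  print(table(diagnosis = x$subjects$diagnosis))
  if (any(x$subjects$diagnosis == "FTD")) {
    st <- x$subjects$ftd_subtype[x$subjects$diagnosis == "FTD"]
    cat("FTD subtypes:\n")
    print(table(subtype = st, useNA = "ifany"))
  }
  if (nzchar(x$provenance)) cat("provenance:", x$provenance, "\n")
  invisible(x)
}

#' Subset a cohort by subject
#'
#' @param cohort an [ftd_cohort()].
#' @param keep logical or integer index, or character vector of subject ids.
#' @return an `ftd_cohort` with the selected subjects, order preserved.
#' @export
subset_cohort <- function(cohort, keep) {
  stopifnot(inherits(cohort, "ftd_cohort"))
  if (is.character(keep)) keep <- match(keep, cohort$subjects$subject_id)
  ftd_cohort(cohort$atlas, cohort$subjects[keep, , drop = FALSE],
             cohort$volumes[keep, , drop = FALSE], cohort$provenance)
}

#' Select subjects by diagnosis label or FTD subtype
#'
#' Labels may mix top-level diagnoses (`"AD"`, `"FTD"`, ...) and FTD
#' subtypes (`"bvFTD"`, `"svPPA"`, ...); `"non-FTD"` expands to all
#' non-FTD diagnoses.
#'
#' @param cohort an [ftd_cohort()].
#' @param labels character vector of labels.
#' @return logical vector over subjects.
#' @export
diagnosis_in <- function(cohort, labels) {
  labels <- unique(unlist(lapply(labels, function(l) {
    if (identical(l, "non-FTD")) setdiff(.diagnosis_levels, "FTD") else l
  })))
  s <- cohort$subjects
  s$diagnosis %in% labels |
    (!is.na(s$ftd_subtype) & s$ftd_subtype %in% labels)
}

#' Read / write a cohort volume table
#'
#' Cohort files are tabular text (comma or tab delimited, auto-detected)
#' with columns `subject_id,diagnosis,ftd_subtype,age,sex,tiv,
#' field_strength` followed by one column per atlas region with the volume
#' in ml. Row order is preserved.
#'
#' @param path path to the cohort file.
#' @param atlas the [region_atlas()] the volume columns must cover.
#' @return `read_cohort` returns an [ftd_cohort()]; `write_cohort`
#'   invisibly returns `path`.
#' @export
read_cohort <- function(path, atlas) {
  atlas <- validate_atlas(atlas)
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  tab <- read_delim_auto(path)
  missing_r <- setdiff(atlas$name, names(tab))
  if (length(missing_r) > 0L) {
    stop("cohort file missing region column(s): ",
         paste(missing_r, collapse = ", "), call. = FALSE)
  }
  for (r in atlas$name) {
    v <- suppressWarnings(as.numeric(tab[[r]]))
    bad <- which(is.na(v) & !is.na(tab[[r]]))
    if (length(bad) > 0L) {
      stop("non-numeric volume at row ", bad[1L], ", column '", r, "'",
           call. = FALSE)
    }
    tab[[r]] <- v
  }
  subj_cols <- c("subject_id", "diagnosis", "ftd_subtype", "age", "sex",
                 "tiv", "field_strength")
  subjects <- data.frame(
    subject_id = as.character(tab$subject_id),
    diagnosis = as.character(tab$diagnosis),
    ftd_subtype = if ("ftd_subtype" %in% names(tab)) {
      st <- as.character(tab$ftd_subtype)
      st[!nzchar(st) | st %in% c("NA", ".")] <- NA_character_
      st
    } else NA_character_,
    age = as.numeric(tab$age),
    sex = as.character(tab$sex),
    tiv = as.numeric(tab$tiv),
    field_strength = if ("field_strength" %in% names(tab)) {
      suppressWarnings(as.numeric(tab$field_strength))
    } else NA_real_,
    stringsAsFactors = FALSE
  )
  volumes <- as.matrix(tab[, atlas$name, drop = FALSE])
  ftd_cohort(atlas, subjects, volumes,
             provenance = paste0("read from ", basename(path)))
}

#' @rdname read_cohort
#' @param cohort an [ftd_cohort()].
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "ftd_cohort"))
  s <- cohort$subjects
  out <- cbind(
    s[, c("subject_id", "diagnosis", "ftd_subtype", "age", "sex", "tiv",
          "field_strength")],
    as.data.frame(cohort$volumes)
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   na = "NA")
  invisible(path)
}
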