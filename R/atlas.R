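#' Region atlas objects
#'
#' A region atlas is the taxonomy of brain regions that drives every
#' anatomical partition used by the indices: anterior vs. posterior cortex
#' (frontal + temporal vs. parietal + occipital) and left vs. right
#' hemisphere. It is an ordered table with one row per region and columns
#' `name`, `hemisphere` (`left`/`right`/`midline`), `lobe` (`frontal`,
#' `temporal`, `parietal`, `occipital`, `subcortical_or_other`) and
#' `cortical` (logical). All package operations are atlas-agnostic: any
#' segmentation tool's region list can be supplied as long as these four
#' columns are present.
#'
#' @param name character vector of unique, non-empty region names.
#' @param hemisphere character vector, one of `"left"`, `"right"`,
#'   `"midline"` per region.
#' @param lobe character vector, one of `"frontal"`, `"temporal"`,
#'   `"parietal"`, `"occipital"`, `"subcortical_or_other"` per region.
#' @param cortical logical vector flagging cortical regions.
#' @return An object of class `region_atlas` (a validated data frame).
#' @examples
#' a <- region_atlas(
#'   name = c("L_sup_frontal", "R_sup_frontal"),
#'   hemisphere = c("left", "right"),
#'   lobe = c("frontal", "frontal"),
#'   cortical = c(TRUE, TRUE)
#' )
#' anterior_regions(a)
#' @export
region_atlas <- function(name, hemisphere, lobe, cortical) {
  atlas <- data.frame(
    name = as.character(name),
    hemisphere = as.character(hemisphere),
    lobe = as.character(lobe),
    cortical = as.logical(cortical),
    stringsAsFactors = FALSE
  )
  class(atlas) <- c("region_atlas", "data.frame")
  validate_atlas(atlas)
}

.hemisphere_levels <- c("left", "right", "midline")
.lobe_levels <- c("frontal", "temporal", "parietal", "occipital",
                  "subcortical_or_other")

validate_atlas <- function(atlas) {
  stopifnot(is.data.frame(atlas))
  required <- c("name", "hemisphere", "lobe", "cortical")
  missing <- setdiff(required, names(atlas))
  if (length(missing) > 0L) {
    stop("atlas is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(!nzchar(atlas$name)) || anyNA(atlas$name)) {
    stop("atlas region names must be non-empty", call. = FALSE)
  }
  dup <- unique(atlas$name[duplicated(atlas$name)])
  if (length(dup) > 0L) {
    stop("duplicate region name(s) in atlas: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  bad_hemi <- which(!atlas$hemisphere %in% .hemisphere_levels)
  if (length(bad_hemi) > 0L) {
    stop("unknown hemisphere token '", atlas$hemisphere[bad_hemi[1L]],
         "' at atlas row ", bad_hemi[1L], call. = FALSE)
  }
  bad_lobe <- which(!atlas$lobe %in% .lobe_levels)
  if (length(bad_lobe) > 0L) {
    stop("unknown lobe token '", atlas$lobe[bad_lobe[1L]],
         "' at atlas row ", bad_lobe[1L], call. = FALSE)
  }
  if (anyNA(atlas$cortical)) {
    stop("atlas 'cortical' flags must be TRUE/FALSE", call. = FALSE)
  }
  atlas
}

#' Read / write a region atlas
#'
#' Atlas files are plain tabular text with header columns
#' `name,hemisphere,lobe,cortical`; comma or tab delimiters are
#' auto-detected from the header line.
#'
#' @param path path to an atlas file.
#' @return `read_atlas` returns a validated [region_atlas()];
#'   `write_atlas` invisibly returns `path`.
#' @seealso [default_atlas()] for the bundled 133-region default.
#' @export
read_atlas <- function(path) {
  if (!file.exists(path)) stop("atlas file not found: ", path, call. = FALSE)
  tab <- read_delim_auto(path)
  required <- c("name", "hemisphere", "lobe", "cortical")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0L) {
    stop("atlas file missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  region_atlas(
    name = tab$name,
    hemisphere = tab$hemisphere,
    lobe = tab$lobe,
    cortical = parse_logical(tab$cortical)
  )
}

#' @rdname read_atlas
#' @param atlas a `region_atlas`.
#' @export
write_atlas <- function(atlas, path) {
  atlas <- validate_atlas(atlas)
  utils::write.csv(as.data.frame(atlas), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

# comma/tab auto-detection from the header line
read_delim_auto <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "", quote = "\"")
}

parse_logical <- function(x) {
  if (is.logical(x)) return(x)
  tolower(as.character(x)) %in% c("true", "t", "1", "yes")
}

#' Anatomical partitions of an atlas
#'
#' The index definitions rest on two partitions of the cortical regions:
#' anterior = cortical regions in the frontal or temporal lobes, posterior =
#' cortical regions in the parietal or occipital lobes. Midline and
#' non-cortical regions belong to neither. Hemisphere subsets select by the
#' atlas `hemisphere` flag, restricted to cortical regions by default.
#'
#' @param atlas a [region_atlas()].
#' @return character vector of region names.
#' @export
anterior_regions <- function(atlas) {
  atlas <- validate_atlas(atlas)
  atlas$name[atlas$cortical & atlas$lobe %in% c("frontal", "temporal") &
               atlas$hemisphere != "midline"]
}

#' @rdname anterior_regions
#' @export
posterior_regions <- function(atlas) {
  atlas <- validate_atlas(atlas)
  atlas$name[atlas$cortical & atlas$lobe %in% c("parietal", "occipital") &
               atlas$hemisphere != "midline"]
}

#' @rdname anterior_regions
#' @param side `"left"` or `"right"`.
#' @param within optional character vector restricting the result to a
#'   region subset (e.g. `anterior_regions(atlas)`).
#' @export
hemisphere_regions <- function(atlas, side = c("left", "right"),
                               within = NULL) {
  side <- match.arg(side)
  atlas <- validate_atlas(atlas)
  out <- atlas$name[atlas$cortical & atlas$hemisphere == side]
  if (!is.null(within)) out <- intersect(out, within)
  out
}

#' @rdname anterior_regions
#' @export
subcortical_regions <- function(atlas) {
  atlas <- validate_atlas(atlas)
  atlas$name[!atlas$cortical]
}

#' Pair left/right homologous regions by name
#'
#' Pairs regions whose names are identical after stripping a leading
#' `L_`/`R_` (or `l_`/`r_`) hemisphere prefix, or a trailing `_left`/
#' `_right` suffix. Used to symmetrize asymmetry-index weights across
#' hemispheres.
#'
#' @param atlas a [region_atlas()].
#' @param within optional region subset to pair within.
#' @return data frame with columns `base`, `left`, `right`.
#' @export
region_pairs <- function(atlas, within = NULL) {
  atlas <- validate_atlas(atlas)
  sel <- atlas[atlas$hemisphere %in% c("left", "right"), , drop = FALSE]
  if (!is.null(within)) sel <- sel[sel$name %in% within, , drop = FALSE]
  base <- sub("_(left|right)$", "", sub("^[LRlr]_", "", sel$name),
              ignore.case = TRUE)
  left <- sel$name[sel$hemisphere == "left"]
  right <- sel$name[sel$hemisphere == "right"]
  base_l <- base[sel$hemisphere == "left"]
  base_r <- base[sel$hemisphere == "right"]
  common <- intersect(base_l, base_r)
  data.frame(
    base = common,
    left = left[match(common, base_l)],
    right = right[match(common, base_r)],
    stringsAsFactors = FALSE
  )
}

#' @export
print.region_atlas <- function(x, ...) {
  cat("Region atlas:", nrow(x), "regions (",
      sum(x$cortical), "cortical /", sum(!x$cortical), "other )\n")
  tab <- table(x$lobe[x$cortical])
  cat("  cortical by lobe:",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  cat("  anterior:", length(anterior_regions(x)),
      " posterior:", length(posterior_regions(x)), "\n")
  invisible(x)
}

#' The bundled default region atlas
#'
#' A synthetic 133-region atlas matching the layout of multi-atlas
#' whole-brain segmentations used in memory-clinic studies: 102 cortical
#' regions (51 per hemisphere; 44 frontal, 24 temporal, 18 parietal, 16
#' occipital) plus 31 subcortical/other structures. Region names are
#' invented but anatomically plausible; any real segmentation's atlas can
#' be substituted via [read_atlas()]. The same table ships as
#' `inst/extdata/atlas_133.csv`.
#'
#' @return a [region_atlas()] with 133 regions.
#' @export
default_atlas <- function() {
  frontal <- c(
    "precentral_gyrus", "superior_frontal_gyrus_medial",
    "superior_frontal_gyrus_lateral", "middle_frontal_gyrus_anterior",
    "middle_frontal_gyrus_posterior", "inferior_frontal_gyrus_opercularis",
    "inferior_frontal_gyrus_triangularis",
    "inferior_frontal_gyrus_orbitalis", "gyrus_rectus",
    "medial_orbital_gyrus", "lateral_orbital_gyrus",
    "anterior_orbital_gyrus", "posterior_orbital_gyrus",
    "frontal_operculum", "frontal_pole", "supplementary_motor_area",
    "anterior_cingulate_gyrus", "middle_cingulate_gyrus",
    "paracentral_lobule_anterior", "precentral_gyrus_medial",
    "olfactory_cortex", "frontomarginal_gyrus"
  )
  temporal <- c(
    "temporal_pole", "superior_temporal_gyrus_anterior",
    "superior_temporal_gyrus_posterior", "middle_temporal_gyrus_anterior",
    "middle_temporal_gyrus_posterior", "inferior_temporal_gyrus",
    "fusiform_gyrus_anterior", "fusiform_gyrus_posterior",
    "parahippocampal_gyrus", "planum_polare", "planum_temporale",
    "heschls_gyrus"
  )
  parietal <- c(
    "postcentral_gyrus", "superior_parietal_lobule", "supramarginal_gyrus",
    "angular_gyrus", "precuneus", "posterior_cingulate_gyrus",
    "paracentral_lobule_posterior", "parietal_operculum",
    "intraparietal_cortex"
  )
  occipital <- c(
    "occipital_pole", "calcarine_cortex", "cuneus", "lingual_gyrus",
    "lateral_occipital_gyrus_superior", "lateral_occipital_gyrus_inferior",
    "occipital_fusiform_gyrus", "occipitotemporal_junction"
  )
  sub_paired <- c(
    "hippocampus", "amygdala", "caudate_nucleus", "putamen", "pallidum",
    "thalamus", "nucleus_accumbens", "insula", "ventral_diencephalon",
    "cerebellum_cortex", "cerebellum_white_matter", "basal_forebrain",
    "substantia_nigra", "subcallosal_area"
  )
  sub_midline <- c("brainstem", "corpus_callosum", "cerebellar_vermis")

  cortical_base <- c(frontal, temporal, parietal, occipital)
  cortical_lobe <- rep(c("frontal", "temporal", "parietal", "occipital"),
                       c(length(frontal), length(temporal),
                         length(parietal), length(occipital)))
  name <- c(paste0("L_", cortical_base), paste0("R_", cortical_base),
            paste0("L_", sub_paired), paste0("R_", sub_paired),
            sub_midline)
  hemisphere <- c(rep("left", length(cortical_base)),
                  rep("right", length(cortical_base)),
                  rep("left", length(sub_paired)),
                  rep("right", length(sub_paired)),
                  rep("midline", length(sub_midline)))
  lobe <- c(cortical_lobe, cortical_lobe,
            rep("subcortical_or_other",
                2L * length(sub_paired) + length(sub_midline)))
  cortical <- c(rep(TRUE, 2L * length(cortical_base)),
                rep(FALSE, 2L * length(sub_paired) + length(sub_midline)))
  region_atlas(name, hemisphere, lobe, cortical)
}
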