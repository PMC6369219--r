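#' Save / load fitted models as self-describing JSON
#'
#' Serializes a fitted normalization ([fit_normalization()]) or index
#' ([fit_index()]) model to a schema-versioned JSON text file, including
#' all region names and parameters at full double precision, so a model
#' fitted on one cohort can score another (external validation) after a
#' lossless round-trip. Index models embed their normalization model.
#'
#' @param model an `ftd_norm` or `ftd_index` object.
#' @param path output file path.
#' @return `write_model` invisibly returns `path`; `read_model` returns
#'   the reconstructed model object.
#' @export
write_model <- function(model, path) {
  if (inherits(model, "ftd_index")) {
    payload <- list(
      schema = "ftdindex/index-model",
      schema_version = 1L,
      index_type = model$index_type,
      numerator_regions = model$numerator_regions,
      denominator_regions = model$denominator_regions,
      weights = as.list(model$weights),
      excluded_regions = model$excluded_regions,
      mu = model$mu, sigma = model$sigma,
      cutoff = model$cutoff, direction = model$direction,
      reference_group = model$reference_group,
      atlas_regions = model$atlas_regions,
      normalization = if (is.null(model$normalization)) NULL else {
        norm_payload(model$normalization)
      }
    )
  } else if (inherits(model, "ftd_norm")) {
    payload <- norm_payload(model)
  } else {
    stop("write_model handles ftd_index and ftd_norm objects",
         call. = FALSE)
  }
  # digits = I(17): doubles round-trip bit-exactly through decimal text
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", pretty = TRUE)
  invisible(path)
}

norm_payload <- function(m) {
  list(
    schema = "ftdindex/normalization-model",
    schema_version = 1L,
    covariates = m$covariates,
    reference_group = m$reference_group,
    regions = m$regions,
    reference_tiv = m$reference_tiv,
    ref_mean_age = m$ref_mean_age,
    age_coef = as.list(m$age_coef),
    sex_coef = as.list(m$sex_coef),
    fs_offsets = if (is.null(m$fs_offsets)) NULL else {
      apply(m$fs_offsets, 2L, as.list, simplify = FALSE)
    },
    fs_reference = m$fs_reference,
    fitted_on = m$fitted_on,
    epsilon = m$epsilon
  )
}

rebuild_norm <- function(p) {
  fs_offsets <- NULL
  if (!is.null(p$fs_offsets)) {
    fs_offsets <- sapply(p$fs_offsets, function(col) {
      unlist(col)[p$regions]
    })
    rownames(fs_offsets) <- p$regions
  }
  structure(list(
    covariates = unlist(p$covariates),
    reference_group = unlist(p$reference_group),
    regions = unlist(p$regions),
    reference_tiv = p$reference_tiv,
    ref_mean_age = p$ref_mean_age,
    age_coef = unlist(p$age_coef),
    sex_coef = unlist(p$sex_coef),
    fs_offsets = fs_offsets,
    fs_reference = if (is.null(p$fs_reference)) NA_real_ else p$fs_reference,
    fitted_on = p$fitted_on,
    epsilon = p$epsilon
  ), class = "ftd_norm")
}

#' @rdname write_model
#' @param atlas optional [region_atlas()]; if supplied, the loaded model
#'   is checked for compatibility and an error names any weighted region
#'   the atlas lacks.
#' @export
read_model <- function(path, atlas = NULL) {
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  schema <- p$schema
  if (is.null(schema)) stop("not a model file (no schema field)",
                            call. = FALSE)
  if (!identical(p$schema_version, 1L) && !identical(p$schema_version, 1)) {
    stop("unsupported model schema version: ", p$schema_version,
         call. = FALSE)
  }
  model <- if (schema == "ftdindex/normalization-model") {
    rebuild_norm(p)
  } else if (schema == "ftdindex/index-model") {
    structure(list(
      index_type = p$index_type,
      numerator_regions = unlist(p$numerator_regions),
      denominator_regions = as.character(unlist(p$denominator_regions)),
      weights = unlist(p$weights),
      excluded_regions = as.character(unlist(p$excluded_regions)),
      mu = p$mu, sigma = p$sigma,
      cutoff = p$cutoff, direction = p$direction,
      reference_group = unlist(p$reference_group),
      atlas_regions = unlist(p$atlas_regions),
      normalization = if (is.null(p$normalization)) NULL else {
        rebuild_norm(p$normalization)
      }
    ), class = "ftd_index")
  } else {
    stop("unknown model schema: ", schema, call. = FALSE)
  }
  if (!is.null(atlas)) {
    atlas <- validate_atlas(atlas)
    needed <- if (inherits(model, "ftd_index")) {
      c(model$numerator_regions, model$denominator_regions)
    } else {
      model$regions
    }
    missing_r <- setdiff(needed, atlas$name)
    if (length(missing_r) > 0L) {
      stop("model is incompatible with atlas; missing region(s): ",
           paste(missing_r, collapse = ", "), call. = FALSE)
    }
  }
  model
}
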