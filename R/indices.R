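#' Learn discriminative region weights from an AD vs. FTD contrast
#'
#' Weights encode how strongly each region's (normalized) volume separates
#' the two most common early-onset dementias. For a numerator (anterior)
#' region r the weight is
#' `w_r = (mean_AD(v_r) - mean_FTD(v_r)) / mean_nonFTD(v_r)`; for a
#' denominator (posterior) region the contrast is reversed,
#' `w_r = (mean_FTD(v_r) - mean_AD(v_r)) / mean_nonFTD(v_r)`. Negative
#' weights are clamped to zero, and regions on the exclusion list are
#' forced to zero regardless of their contrast.
#'
#' @param cohort a normalized [ftd_cohort()].
#' @param numerator_regions,denominator_regions region-name vectors for the
#'   two sides of the ratio (denominator may be empty).
#' @param positive_group labels of the index-positive disease group
#'   (default `"FTD"`).
#' @param contrast_group labels of the contrast group (default `"AD"`).
#' @param reference_group labels of the scaling reference population
#'   (default all non-FTD groups).
#' @param excluded_regions regions whose weight is forced to 0.
#' @return named numeric vector of weights over
#'   `c(numerator_regions, denominator_regions)`.
#' @export
compute_region_weights <- function(cohort, numerator_regions,
                                   denominator_regions = character(0),
                                   positive_group = "FTD",
                                   contrast_group = "AD",
                                   reference_group = "non-FTD",
                                   excluded_regions = character(0)) {
  stopifnot(inherits(cohort, "ftd_cohort"))
  pos <- diagnosis_in(cohort, positive_group)
  con <- diagnosis_in(cohort, contrast_group)
  ref <- diagnosis_in(cohort, reference_group)
  for (g in list(c("positive", sum(pos)), c("contrast", sum(con)),
                 c("reference", sum(ref)))) {
    if (as.integer(g[2L]) < 2L) {
      stop(g[1L], " group has fewer than 2 subjects", call. = FALSE)
    }
  }
  regions <- c(numerator_regions, denominator_regions)
  missing_r <- setdiff(regions, colnames(cohort$volumes))
  if (length(missing_r) > 0L) {
    stop("regions absent from cohort: ", paste(missing_r, collapse = ", "),
         call. = FALSE)
  }
  v <- cohort$volumes[, regions, drop = FALSE]
  m_pos <- colMeans(v[pos, , drop = FALSE])
  m_con <- colMeans(v[con, , drop = FALSE])
  m_ref <- colMeans(v[ref, , drop = FALSE])
  zero_ref <- regions[m_ref == 0]
  if (length(zero_ref) > 0L) {
    stop("zero reference mean volume for region(s): ",
         paste(zero_ref, collapse = ", "), call. = FALSE)
  }
  sign_vec <- ifelse(regions %in% numerator_regions, 1, -1)
  w <- sign_vec * (m_con - m_pos) / m_ref
  w[w < 0] <- 0
  w[regions %in% excluded_regions] <- 0
  stats::setNames(w, regions)
}

#' Raw index value for one or more subjects
#'
#' For ratio indices (API, ASI) the raw value is the natural log of the
#' ratio of weighted volume sums,
#' `log( sum_r w_r v_r (numerator) / sum_r w_r v_r (denominator) )`; it is
#' invariant to global rescaling of a subject's volumes. For the
#' single-region TPL index the raw value is the normalized region volume
#' itself, in ml.
#'
#' @param volumes named numeric vector (one subject) or matrix with region
#'   columns (many subjects) of normalized volumes.
#' @param model an [ftd_index] model (only its regions/weights are used).
#' @return numeric vector of raw index values.
#' @export
compute_raw_index <- function(volumes, model) {
  if (is.null(dim(volumes))) volumes <- t(as.matrix(volumes))
  regions <- c(model$numerator_regions, model$denominator_regions)
  missing_r <- setdiff(regions, colnames(volumes))
  if (length(missing_r) > 0L) {
    stop("volumes missing weighted region(s): ",
         paste(missing_r, collapse = ", "), call. = FALSE)
  }
  w <- model$weights
  if (all(w == 0)) stop("all region weights are zero", call. = FALSE)
  num <- as.vector(volumes[, model$numerator_regions, drop = FALSE] %*%
                     w[model$numerator_regions])
  if (length(model$denominator_regions) == 0L) {
    if (any(num <= 0)) {
      stop("non-positive region volume on the numerator side",
           call. = FALSE)
    }
    return(num)
  }
  den <- as.vector(volumes[, model$denominator_regions, drop = FALSE] %*%
                     w[model$denominator_regions])
  if (any(num <= 0)) {
    stop("non-positive weighted volume sum on the numerator side",
         call. = FALSE)
  }
  if (any(den <= 0)) {
    stop("non-positive weighted volume sum on the denominator side",
         call. = FALSE)
  }
  log(num / den)
}

#' Calibrate the z-score transform on a reference population
#'
#' The z-score of an index is `(raw - mu) / sigma` where `mu` and `sigma`
#' are the sample mean and standard deviation (n-1 denominator) of the raw
#' values over the non-FTD calibration set. By construction the
#' calibration set's own z-scores have mean 0 and SD 1.
#'
#' @param raw_values numeric vector of reference raw index values.
#' @return list with `mu` and `sigma`.
#' @export
calibrate_zscore <- function(raw_values) {
  raw_values <- raw_values[is.finite(raw_values)]
  if (length(raw_values) < 2L) {
    stop("need at least 2 reference values to calibrate", call. = FALSE)
  }
  sigma <- stats::sd(raw_values)
  if (!is.finite(sigma) || sigma == 0) {
    stop("degenerate reference: zero variance in raw index values",
         call. = FALSE)
  }
  list(mu = mean(raw_values), sigma = sigma)
}

#' Classify index z-scores at a fixed cutoff
#'
#' A subject is called index-positive when its z-score falls strictly
#' below the cutoff (default -1.65, the parametric 95%-specificity point
#' for a standard-normal reference). With `two_sided = TRUE` (useful for
#' the asymmetry index, where right-lateralized atrophy sits on the
#' opposite tail) a subject is positive when `|z| > |cutoff|`.
#'
#' @param z numeric vector of z-scores.
#' @param cutoff z threshold (default -1.65).
#' @param two_sided classify on both tails.
#' @return logical vector.
#' @export
classify_index <- function(z, cutoff = -1.65, two_sided = FALSE) {
  if (two_sided) abs(z) > abs(cutoff) else z < cutoff
}

default_api_exclusions <- function(atlas) {
  base <- c("parahippocampal_gyrus", "inferior_temporal_gyrus")
  atlas$name[sub("^[LRlr]_", "", atlas$name) %in% base]
}

#' Fit an MRI atrophy index model
#'
#' The central fitting function of the package. It orchestrates, on a
#' training cohort: (1) volume normalization for head size, age and sex on
#' the reference (non-FTD) subjects; (2) region-weight learning from the
#' AD vs. FTD contrast; (3) z-score calibration of the raw index on the
#' reference subjects. Three index types are supported:
#' \describe{
#'   \item{API}{anterior vs. posterior index: weighted frontotemporal over
#'     weighted parieto-occipital cortical volume, log ratio. Low values
#'     indicate FTD-like anterior atrophy. The parahippocampal gyrus and
#'     inferior temporal gyrus (both hemispheres) are excluded from the
#'     weighting by default as anatomical outliers.}
#'   \item{ASI}{asymmetry index: weighted left over right frontotemporal
#'     volume, log ratio. Deviations indicate lateralized atrophy as in
#'     the primary progressive aphasias. By default the anterior-contrast
#'     weights are symmetrized across hemisphere pairs
#'     (`asi_weight_mode = "anterior_symmetric"`), which makes the raw
#'     value exactly antisymmetric under a left/right mirror swap;
#'     `"left_vs_right"` instead re-estimates weights from the left-minus-
#'     right contrast per pair.}
#'   \item{TPL}{left temporal pole index: the normalized volume of the
#'     left temporal pole, z-scored for consistency with the other two.
#'     Low values indicate svPPA-like atrophy.}
#' }
#'
#' @param cohort an [ftd_cohort()] containing FTD, AD and non-FTD
#'   subjects.
#' @param index_type `"API"`, `"ASI"` or `"TPL"`.
#' @param normalization `"fit"` (default) to fit the normalization chain
#'   on the reference group and embed it in the model, an existing
#'   `ftd_norm` to embed, or `NULL` if `cohort` is already normalized.
#' @param reference_group diagnosis labels of the z-score calibration
#'   population (default all non-FTD groups).
#' @param positive_group,contrast_group label sets for the weight
#'   contrast (defaults `"FTD"` and `"AD"`).
#' @param excluded_regions regions forced to zero weight; defaults to the
#'   parahippocampal and inferior temporal gyri for API, none otherwise.
#' @param tpl_region region name for TPL (default `"L_temporal_pole"`).
#' @param asi_weight_mode see Description.
#' @param cutoff classification z cutoff stored in the model.
#' @param covariates normalization covariates, see [fit_normalization()].
#' @return an object of class `ftd_index` with components
#'   `weights`, `mu`, `sigma`, `cutoff`, the region lists, and the
#'   embedded normalization model (if any). Methods: [predict.ftd_index()],
#'   `print`, `summary`, `coef`.
#' @examples
#' cohort <- generate_cohort(simulation_config(preset = "small"), seed = 1)
#' fit <- fit_index(cohort, "API")
#' scores <- predict(fit, cohort)
#' head(scores)
#' @export
fit_index <- function(cohort,
                      index_type = c("API", "ASI", "TPL"),
                      normalization = "fit",
                      reference_group = c("SCD", "MCI", "AD", "VaD",
                                          "DLB", "Other"),
                      positive_group = "FTD",
                      contrast_group = "AD",
                      excluded_regions = NULL,
                      tpl_region = "L_temporal_pole",
                      asi_weight_mode = c("anterior_symmetric",
                                          "left_vs_right"),
                      cutoff = -1.65,
                      covariates = c("headsize", "age", "sex")) {
  stopifnot(inherits(cohort, "ftd_cohort"))
  index_type <- match.arg(index_type)
  asi_weight_mode <- match.arg(asi_weight_mode)
  atlas <- cohort$atlas

  norm_model <- NULL
  if (identical(normalization, "fit")) {
    norm_model <- fit_normalization(cohort, reference_group, covariates)
  } else if (inherits(normalization, "ftd_norm")) {
    norm_model <- normalization
  } else if (!is.null(normalization)) {
    stop("'normalization' must be \"fit\", an ftd_norm object, or NULL",
         call. = FALSE)
  }
  normed <- if (is.null(norm_model)) cohort else {
    apply_normalization(norm_model, cohort)
  }

  if (index_type == "API") {
    if (is.null(excluded_regions)) {
      excluded_regions <- default_api_exclusions(atlas)
    }
    num <- anterior_regions(atlas)
    den <- posterior_regions(atlas)
    weights <- compute_region_weights(normed, num, den, positive_group,
                                      contrast_group, reference_group,
                                      excluded_regions)
  } else if (index_type == "ASI") {
    if (is.null(excluded_regions)) excluded_regions <- character(0)
    ant <- anterior_regions(atlas)
    num <- hemisphere_regions(atlas, "left", within = ant)
    den <- hemisphere_regions(atlas, "right", within = ant)
    pairs <- region_pairs(atlas, within = ant)
    if (nrow(pairs) == 0L) {
      stop("ASI requires left/right homologous region pairs ",
           "(names matching after the L_/R_ prefix)", call. = FALSE)
    }
    num <- pairs$left
    den <- pairs$right
    if (asi_weight_mode == "anterior_symmetric") {
      # unclamped anterior contrast per region, pair-averaged, then clamped
      v <- normed$volumes
      pos <- diagnosis_in(normed, positive_group)
      con <- diagnosis_in(normed, contrast_group)
      ref <- diagnosis_in(normed, reference_group)
      if (sum(pos) < 2L || sum(con) < 2L || sum(ref) < 2L) {
        stop("each contrast group needs at least 2 subjects", call. = FALSE)
      }
      raw_w <- function(r) {
        (mean(v[con, r]) - mean(v[pos, r])) / mean(v[ref, r])
      }
      w_pair <- (vapply(pairs$left, raw_w, numeric(1)) +
                   vapply(pairs$right, raw_w, numeric(1))) / 2
      w_pair[w_pair < 0] <- 0
      weights <- stats::setNames(c(w_pair, w_pair), c(num, den))
    } else {
      # left-vs-right contrast: weight each pair by its FTD asymmetry
      weights <- compute_region_weights(normed, num, den, positive_group,
                                        contrast_group, reference_group,
                                        excluded_regions)
      w_pair <- (weights[num] + weights[den]) / 2
      weights <- stats::setNames(c(w_pair, w_pair), c(num, den))
    }
    weights[names(weights) %in% excluded_regions] <- 0
  } else { # TPL
    if (!tpl_region %in% atlas$name) {
      stop("TPL region '", tpl_region, "' not in atlas", call. = FALSE)
    }
    if (is.null(excluded_regions)) excluded_regions <- character(0)
    num <- tpl_region
    den <- character(0)
    weights <- stats::setNames(1, tpl_region)
  }

  model <- structure(list(
    index_type = index_type,
    numerator_regions = num,
    denominator_regions = den,
    weights = weights,
    excluded_regions = excluded_regions,
    mu = NA_real_, sigma = NA_real_,
    cutoff = cutoff,
    direction = "lower",
    reference_group = reference_group,
    normalization = norm_model,
    atlas_regions = atlas$name
  ), class = "ftd_index")

  ref <- diagnosis_in(normed, reference_group)
  raw_ref <- compute_raw_index(normed$volumes[ref, , drop = FALSE], model)
  cal <- calibrate_zscore(raw_ref)
  model$mu <- cal$mu
  model$sigma <- cal$sigma
  model
}

#' Score a cohort with a fitted index model
#'
#' Applies the model's embedded normalization (if any), computes raw index
#' values, z-scores them with the stored calibration, and classifies at
#' the stored cutoff.
#'
#' @param object an `ftd_index` from [fit_index()].
#' @param cohort an [ftd_cohort()] covering the model's regions.
#' @param two_sided classify on both tails (see [classify_index()]).
#' @param ... unused.
#' @return data frame with columns `subject_id`, `diagnosis`, `raw`, `z`,
#'   `predicted_positive`.
#' @export
predict.ftd_index <- function(object, cohort, two_sided = FALSE, ...) {
  stopifnot(inherits(cohort, "ftd_cohort"))
  missing_r <- setdiff(c(object$numerator_regions,
                         object$denominator_regions),
                       cohort$atlas$name)
  if (length(missing_r) > 0L) {
    stop("index model incompatible with cohort atlas; missing region(s): ",
         paste(missing_r, collapse = ", "), call. = FALSE)
  }
  normed <- if (is.null(object$normalization)) cohort else {
    apply_normalization(object$normalization, cohort)
  }
  raw <- compute_raw_index(normed$volumes, object)
  z <- (raw - object$mu) / object$sigma
  data.frame(
    subject_id = cohort$subjects$subject_id,
    diagnosis = cohort$subjects$diagnosis,
    raw = raw,
    z = z,
    predicted_positive = classify_index(z, object$cutoff, two_sided),
    stringsAsFactors = FALSE
  )
}

#' @export
print.ftd_index <- function(x, ...) {
  cat("MRI atrophy index model:", x$index_type, "\n")
  cat("  weighted regions:",
      sum(x$weights > 0), "of", length(x$weights),
      "(", length(x$excluded_regions), "excluded )\n")
  cat("  calibration: mu =", signif(x$mu, 4),
      " sigma =", signif(x$sigma, 4),
      " over", paste(x$reference_group, collapse = ","), "\n")
  cat("  cutoff: z <", x$cutoff, "=> index-positive\n")
  if (!is.null(x$normalization)) {
    cat("  normalization:",
        paste(x$normalization$covariates, collapse = "+"),
        "(embedded)\n")
  }
  invisible(x)
}

#' @export
coef.ftd_index <- function(object, ...) object$weights

#' @export
summary.ftd_index <- function(object, ...) {
  w <- object$weights
  out <- list(
    index_type = object$index_type,
    n_regions = length(w),
    n_positive_weight = sum(w > 0),
    top_weights = sort(w[w > 0], decreasing = TRUE)[
      seq_len(min(10L, sum(w > 0)))],
    mu = object$mu, sigma = object$sigma, cutoff = object$cutoff
  )
  class(out) <- "summary.ftd_index"
  out
}

#' @export
print.summary.ftd_index <- function(x, ...) {
  cat(x$index_type, "index:", x$n_positive_weight, "of", x$n_regions,
      "regions with positive weight\n")
  cat("calibration mu =", signif(x$mu, 4), ", sigma =", signif(x$sigma, 4),
      ", cutoff =", x$cutoff, "\n")
  cat("largest weights:\n")
  print(round(x$top_weights, 4))
  invisible(x)
}

#' Screen every region as a stand-alone volumetric biomarker
#'
#' Computes, for each atlas region separately, the AUC for separating a
#' positive from a negative group using low (normalized) volume as the
#' disease signal. This is the screening analysis that singles out the
#' left temporal pole as the best single-region discriminator of svPPA.
#'
#' @param cohort a normalized [ftd_cohort()].
#' @param positive_group,negative_group diagnosis/subtype label sets.
#' @return data frame `region`, `auc`, sorted by decreasing AUC, ties
#'   broken alphabetically by region name.
#' @export
screen_single_regions <- function(cohort, positive_group, negative_group) {
  stopifnot(inherits(cohort, "ftd_cohort"))
  pos <- diagnosis_in(cohort, positive_group)
  neg <- diagnosis_in(cohort, negative_group)
  if (sum(pos) == 0L || sum(neg) == 0L) {
    stop("both screening groups must be non-empty", call. = FALSE)
  }
  keep <- pos | neg
  labels <- pos[keep]
  aucs <- vapply(cohort$atlas$name, function(r) {
    roc_auc(cohort$volumes[keep, r], labels, direction = "lower")$auc
  }, numeric(1))
  out <- data.frame(region = cohort$atlas$name, auc = aucs,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$auc, out$region), ]
  rownames(out) <- NULL
  out
}
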