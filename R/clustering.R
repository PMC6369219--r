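#' Default 18-region set for atrophy-subtype clustering
#'
#' A documented subset of the bundled atlas spanning frontal, temporal,
#' insular and subcortical structures (nine homologous left/right pairs),
#' used as the regions of interest for the behavioural-variant FTD
#' subtype cluster analysis. Fully configurable: any region subset of the
#' working atlas can be passed to [cluster_subjects()] instead.
#'
#' @param atlas a [region_atlas()] (default: the bundled atlas).
#' @return character vector of 18 region names.
#' @export
default_cluster_rois <- function(atlas = default_atlas()) {
  base <- c("superior_frontal_gyrus_lateral", "middle_frontal_gyrus_anterior",
            "temporal_pole", "middle_temporal_gyrus_anterior",
            "insula", "hippocampus", "caudate_nucleus", "putamen",
            "thalamus")
  rois <- c(paste0("L_", base), paste0("R_", base))
  missing_r <- setdiff(rois, atlas$name)
  if (length(missing_r) > 0L) {
    stop("default ROI(s) absent from atlas: ",
         paste(missing_r, collapse = ", "),
         "; supply roi_set explicitly", call. = FALSE)
  }
  rois
}

#' Hierarchical clustering of atrophy patterns
#'
#' Groups subjects (typically the bvFTD subset) by their regional
#' gray-matter atrophy profile: per-region volumes are standardized to
#' z-scores (against a reference group's mean/SD if given, else within
#' the clustered sample), then clustered by deterministic agglomerative
#' hierarchical clustering (Ward linkage on Euclidean distance by
#' default) and the tree is cut at `k` clusters. Cluster labels are
#' renumbered by decreasing mean global atrophy (cluster 1 = lowest mean
#' z = most atrophic) so the labelling is reproducible.
#'
#' @param cohort a normalized [ftd_cohort()] of the subjects to cluster.
#' @param roi_set region names to cluster on (default
#'   [default_cluster_rois()]).
#' @param k number of clusters (default 4).
#' @param linkage `"ward"` (Ward.D2), `"complete"` or `"average"`.
#' @param reference optional [ftd_cohort()] whose per-region mean/SD
#'   standardize the ROI volumes (e.g. the SCD group).
#' @return object of class `ftd_clusters`: `assignments` (named integer
#'   vector subject -> cluster), `tree` (hclust), `heights`, `roi_set`,
#'   `centers` (cluster x region mean z), `k`.
#' @export
cluster_subjects <- function(cohort, roi_set = NULL, k = 4,
                             linkage = c("ward", "complete", "average"),
                             reference = NULL) {
  stopifnot(inherits(cohort, "ftd_cohort"))
  linkage <- match.arg(linkage)
  if (is.null(roi_set)) roi_set <- default_cluster_rois(cohort$atlas)
  missing_r <- setdiff(roi_set, cohort$atlas$name)
  if (length(missing_r) > 0L) {
    stop("roi_set region(s) absent from atlas: ",
         paste(missing_r, collapse = ", "), call. = FALSE)
  }
  n <- nrow(cohort$subjects)
  if (k > n) stop("k = ", k, " exceeds the ", n, " subjects", call. = FALSE)
  v <- cohort$volumes[, roi_set, drop = FALSE]
  if (!is.null(reference)) {
    stopifnot(inherits(reference, "ftd_cohort"))
    rv <- reference$volumes[, roi_set, drop = FALSE]
    ctr <- colMeans(rv)
    scl <- apply(rv, 2L, stats::sd)
  } else {
    ctr <- colMeans(v)
    scl <- apply(v, 2L, stats::sd)
  }
  scl[scl == 0] <- 1
  z <- sweep(sweep(v, 2L, ctr), 2L, scl, "/")
  method <- c(ward = "ward.D2", complete = "complete",
              average = "average")[[linkage]]
  tree <- stats::hclust(stats::dist(z), method = method)
  raw_assign <- stats::cutree(tree, k = k)
  # relabel by increasing mean z over ROIs: cluster 1 = most atrophic
  mean_z <- vapply(seq_len(k), function(cl) {
    mean(z[raw_assign == cl, , drop = FALSE])
  }, numeric(1))
  relabel <- order(order(mean_z))
  assignments <- stats::setNames(relabel[raw_assign],
                                 cohort$subjects$subject_id)
  centers <- t(vapply(seq_len(k), function(cl) {
    colMeans(z[assignments == cl, , drop = FALSE])
  }, numeric(ncol(z))))
  rownames(centers) <- paste0("cluster_", seq_len(k))
  structure(list(
    assignments = assignments,
    tree = tree,
    heights = rev(tree$height),
    roi_set = roi_set,
    centers = centers,
    k = k,
    standardized_to = if (is.null(reference)) "sample" else "reference"
  ), class = "ftd_clusters")
}

#' @export
print.ftd_clusters <- function(x, ...) {
  cat("Atrophy-pattern clustering: k =", x$k, "on", length(x$roi_set),
      "ROIs (standardized to", x$standardized_to, ")\n")
  print(table(cluster = x$assignments))
  cat("top merge heights:",
      paste(sprintf("%.2f", utils::head(x$heights, 6L)), collapse = " "),
      "\n")
  invisible(x)
}

#' Region-wise contrast of a cluster against a reference group
#'
#' For each region, compares normalized volumes between the cluster's
#' subjects and a reference group (e.g. SCD or AD) with Welch's
#' two-sample t-test, adjusting p-values across regions by the
#' Benjamini-Hochberg false discovery rate. This is a region-level
#' analogue of voxel-based atrophy mapping, not a reproduction of it.
#'
#' @param cluster_cohort [ftd_cohort()] of the cluster's subjects.
#' @param reference_cohort [ftd_cohort()] of the reference group.
#' @param regions region names to test (default: all atlas regions).
#' @param fdr_q FDR threshold (default 0.05).
#' @return data frame per region: `region`, `direction` (`"atrophic"` if
#'   the cluster mean is lower), `p`, `q`, `significant`.
#' @export
contrast_cluster_vs_reference <- function(cluster_cohort, reference_cohort,
                                          regions = NULL, fdr_q = 0.05) {
  stopifnot(inherits(cluster_cohort, "ftd_cohort"),
            inherits(reference_cohort, "ftd_cohort"))
  if (is.null(regions)) regions <- cluster_cohort$atlas$name
  if (nrow(cluster_cohort$subjects) < 2L ||
      nrow(reference_cohort$subjects) < 2L) {
    stop("both groups need at least 2 subjects", call. = FALSE)
  }
  res <- lapply(regions, function(r) {
    a <- cluster_cohort$volumes[, r]
    b <- reference_cohort$volumes[, r]
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      list(p = 1, direction = "none",
           note = "zero variance in both groups")
    } else {
      tt <- stats::t.test(a, b)
      list(p = tt$p.value,
           direction = if (mean(a) < mean(b)) "atrophic" else "enlarged",
           note = "")
    }
  })
  p <- vapply(res, `[[`, numeric(1), "p")
  q <- stats::p.adjust(p, method = "BH")
  data.frame(
    region = regions,
    direction = vapply(res, `[[`, character(1), "direction"),
    p = p, q = q,
    significant = q < fdr_q,
    note = vapply(res, `[[`, character(1), "note"),
    stringsAsFactors = FALSE
  )
}

#' Cross-tabulate atrophy clusters against the API cutoff
#'
#' Counts, per cluster, how many subjects fall below versus at/above the
#' API cutoff, and what share of all above-cutoff (API-negative) subjects
#' each cluster holds — the summary showing that bvFTD cases missed by
#' the anterior index concentrate in the subcortical-predominant cluster.
#'
#' @param assignments named integer vector subject -> cluster (from
#'   [cluster_subjects()]).
#' @param api_scores data frame with `subject_id` and `z` (from
#'   [predict.ftd_index()]), or a named numeric vector of z-scores.
#' @param cutoff API cutoff (default -1.65).
#' @return data frame per cluster: `cluster`, `n`, `below_cutoff`,
#'   `at_or_above`, `share_of_above` (fraction of all at/above-cutoff
#'   subjects in this cluster).
#' @export
crosstab_api <- function(assignments, api_scores, cutoff = -1.65) {
  if (is.data.frame(api_scores)) {
    z <- stats::setNames(api_scores$z, api_scores$subject_id)
  } else {
    z <- api_scores
  }
  missing_s <- setdiff(names(assignments), names(z))
  if (length(missing_s) > 0L) {
    stop("missing API score(s) for subject(s): ",
         paste(missing_s, collapse = ", "), call. = FALSE)
  }
  z <- z[names(assignments)]
  ks <- sort(unique(assignments))
  below <- z < cutoff
  total_above <- sum(!below)
  out <- data.frame(
    cluster = ks,
    n = vapply(ks, function(cl) sum(assignments == cl), integer(1)),
    below_cutoff = vapply(ks, function(cl) {
      sum(assignments == cl & below)
    }, integer(1)),
    at_or_above = vapply(ks, function(cl) {
      sum(assignments == cl & !below)
    }, integer(1))
  )
  out$share_of_above <- if (total_above > 0) {
    out$at_or_above / total_above
  } else 0
  out
}
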