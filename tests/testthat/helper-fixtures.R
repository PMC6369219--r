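# Shared fixtures: tiny atlases/cohorts built in code, plus independent
# brute-force oracles used to check the analytic implementations.

# minimal 8-region atlas: 2 anterior + 2 posterior per hemisphere paired,
# no subcortical
tiny_atlas <- function() {
  region_atlas(
    name = c("L_front_a", "R_front_a", "L_temp_a", "R_temp_a",
             "L_par_a", "R_par_a", "L_occ_a", "R_occ_a"),
    hemisphere = rep(c("left", "right"), 4),
    lobe = rep(c("frontal", "temporal", "parietal", "occipital"),
               each = 2),
    cortical = rep(TRUE, 8)
  )
}

# hand-built cohort over tiny_atlas with controllable volumes
tiny_cohort <- function(volumes, diagnosis,
                        ftd_subtype = ifelse(diagnosis == "FTD",
                                             "bvFTD", NA_character_),
                        age = rep(65, nrow(volumes)),
                        sex = rep("female", nrow(volumes)),
                        tiv = rep(1450, nrow(volumes))) {
  atlas <- tiny_atlas()
  colnames(volumes) <- atlas$name
  ftd_cohort(atlas, data.frame(
    subject_id = sprintf("T%03d", seq_len(nrow(volumes))),
    diagnosis = diagnosis, ftd_subtype = ftd_subtype,
    age = age, sex = sex, tiv = tiv,
    field_strength = NA_real_, stringsAsFactors = FALSE
  ), volumes)
}

# independent pairwise AUC oracle (ties count one half); lower = positive
brute_force_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + if (p < q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# synthetic archetype generator: 4 atrophy patterns over the default ROI
# set, expressed directly as z-profiles with within-group noise
archetype_sample <- function(n_per = 10, noise_sd = 0.3, seed = 1) {
  atlas <- default_atlas()
  rois <- default_cluster_rois(atlas)
  frontal <- grep("frontal", rois, value = TRUE)
  temporal <- grep("temporal|insula", rois, value = TRUE)
  subcort <- setdiff(rois, c(frontal, temporal))
  profile <- function(sets, depth) {
    z <- setNames(rep(0, length(rois)), rois)
    for (s in seq_along(sets)) z[sets[[s]]] <- -depth[s]
    z
  }
  profiles <- list(
    ftd_sub = profile(list(frontal, temporal, subcort), c(2, 2, 1.5)),
    frontal_sub = profile(list(frontal, subcort), c(2, 1.5)),
    temporal = profile(list(temporal, subcort), c(2, 0.7)),
    subcortical = profile(list(subcort), 2)
  )
  set.seed(seed)
  z <- do.call(rbind, lapply(profiles, function(p) {
    matrix(rep(p, n_per), nrow = n_per, byrow = TRUE) +
      matrix(rnorm(n_per * length(rois), 0, noise_sd), nrow = n_per)
  }))
  truth <- rep(seq_along(profiles), each = n_per)
  # embed the z-profiles as volumes: mean 5 ml, SD 1 ml per region
  vol <- 5 + z
  full <- matrix(5, nrow = nrow(vol), ncol = nrow(atlas),
                 dimnames = list(NULL, atlas$name))
  full[, rois] <- vol
  cohort <- ftd_cohort(atlas, data.frame(
    subject_id = sprintf("C%03d", seq_len(nrow(full))),
    diagnosis = "FTD", ftd_subtype = "bvFTD",
    age = 63, sex = "female", tiv = 1450, field_strength = NA_real_,
    stringsAsFactors = FALSE
  ), full)
  list(cohort = cohort, truth = truth, rois = rois)
}

# exhaustive cutoff scan oracle for (sens+spec)/2, rule: positive if < c;
# the step function only changes at data values, so scanning one point
# inside every inter-score interval (plus both ends) is exhaustive
brute_force_optimal <- function(scores, labels) {
  xs <- sort(unique(scores))
  candidates <- c(xs[1] - 1, (xs[-length(xs)] + xs[-1]) / 2,
                  xs[length(xs)] + 1)
  max(vapply(candidates, function(cand) {
    (mean(scores[labels] < cand) + mean(scores[!labels] >= cand)) / 2
  }, numeric(1)))
}
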