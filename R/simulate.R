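#' Synthetic 116-ROI atlas with a 6-network partition
#'
#' Builds an atlas table in the shape of the AAL 116-region parcellation,
#' partitioned into the six canonical large-scale networks: attention (ATN),
#' default mode (DMN), sensorimotor (SMN), visual (VN), subcortical (SCN)
#' and cerebellum (CN). ROI-to-network block sizes approximate the usual
#' AAL allocation; labels are synthetic stand-ins, not anatomical names.
#'
#' @param r total number of ROIs; default 116.
#' @return atlas data.frame (roi_index, roi_name, network).
#' @export
synthetic_atlas <- function(r = 116L) {
  nets <- c("ATN", "DMN", "SMN", "VN", "SCN", "CN")
  base <- c(ATN = 20, DMN = 20, SMN = 20, VN = 14, SCN = 16, CN = 26)
  sizes <- round(base / sum(base) * r)
  sizes[length(sizes)] <- r - sum(sizes[-length(sizes)])
  network <- rep(nets, times = sizes)
  data.frame(roi_index = 0:(r - 1L),
             roi_name = sprintf("ROI_%03d_%s", 0:(r - 1L), network),
             network = factor(network, levels = nets))
}

#' Generate network-structured CAP spatial templates
#'
#' Each template concentrates signed weight on one or two networks (as
#' network-dominant co-activation topographies do), plus weak background on
#' the remaining ROIs; templates are centered and scaled to unit norm so
#' pairwise Pearson correlations are inner products. Optionally the last
#' two templates are constructed as an anti-correlated pair with
#' r = \code{anti_r}, emulating states with opposite spatial configurations.
#'
#' @param k number of templates (>= 2 when \code{anti_pair}).
#' @param atlas atlas data.frame defining the networks.
#' @param anti_pair logical; construct templates k-1 and k anti-correlated.
#' @param anti_r target correlation of the anti pair; default -0.6.
#' @param seed integer seed.
#' @return k x R matrix with zero-mean unit-norm rows; pairwise |r| < 0.9.
#' @export
make_templates <- function(k, atlas, anti_pair = TRUE, anti_r = -0.6, seed = 1L) {
  r <- nrow(atlas)
  stopifnot(k <= r)
  if (anti_pair && k < 2L)
    stop("anti-correlated pair requires k >= 2", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  nets <- levels(atlas$network)
  unit <- function(v) { v <- v - mean(v); v / sqrt(sum(v^2)) }
  for (attempt in 1:50) {
    templates <- matrix(0, k, r)
    n_main <- if (anti_pair) k - 1L else k
    for (i in seq_len(n_main)) {
      n_sel <- sample(1:2, 1L)
      sel <- sample(nets, n_sel)
      w <- stats::rnorm(r, 0, 0.15)                 # weak background
      for (s in sel) {
        idx <- atlas$network == s
        w[idx] <- w[idx] + sample(c(-1, 1), 1L) * stats::runif(sum(idx), 0.7, 1.3)
      }
      templates[i, ] <- unit(w)
    }
    if (anti_pair) {
      base <- templates[k - 1L, ]
      u <- unit(stats::rnorm(r))
      u <- unit(u - sum(u * base) * base)           # orthogonal complement
      templates[k, ] <- unit(anti_r * base + sqrt(1 - anti_r^2) * u)
    }
    cc <- tcrossprod(templates)
    diag(cc) <- 0
    if (anti_pair) cc[k - 1L, k] <- cc[k, k - 1L] <- 0
    if (max(abs(cc)) < 0.9) return(templates)
  }
  stop("could not draw templates with pairwise |r| < 0.9", call. = FALSE)
}

#' Build a row-stochastic transition matrix with given self-transitions
#'
#' Off-diagonal mass within each row is spread with mild random variation
#' so transitions are directional (asymmetric), as empirical CAP chains are.
#'
#' @param self length-k (or scalar) self-transition probabilities.
#' @param k number of states.
#' @param jitter relative variation of off-diagonal weights; default 0.3.
#' @param seed integer seed.
#' @return k x k irreducible row-stochastic matrix.
#' @export
make_transition_matrix <- function(self, k, jitter = 0.3, seed = NULL) {
  self <- rep_len(self, k)
  stopifnot(all(self > 0 & self < 1))
  if (!is.null(seed)) set.seed(seed)
  p <- matrix(0, k, k)
  for (i in seq_len(k)) {
    w <- stats::runif(k - 1L, 1 - jitter, 1 + jitter)
    p[i, -i] <- (1 - self[i]) * w / sum(w)
    p[i, i] <- self[i]
  }
  p
}

#' Assemble the ground truth of a synthetic cohort
#'
#' Defines everything the generator needs: spatial templates, per-group
#' Markov transition matrices, the emission noise level, and the symptom
#' model. Defaults emulate the study conditions this package targets:
#' k = 7 states over 116 ROIs in 6 networks, 240 frames at TR = 2 s,
#' a patient-specific increase of one state's self-transition probability
#' (0.80 vs 0.65), and a symptom score (HAMD-like) linear in that state's
#' true dwell time. SNR is the ratio of the per-frame signal amplitude to
#' the emission noise SD (frames are amplitude * sqrt(R) * template + noise,
#' with unit-norm templates, so signal and noise vector norms are directly
#' comparable).
#'
#' @param k number of latent states; default 7.
#' @param atlas atlas data.frame; default [synthetic_atlas()].
#' @param self_control baseline self-transition probability; default 0.65.
#' @param self_patient_effect self-transition of \code{effect_cap} in
#'   patients; default 0.80. Set equal to \code{self_control} for a null
#'   cohort.
#' @param effect_cap 0-based index of the state carrying the group effect;
#'   default 0.
#' @param snr signal-to-noise ratio amplitude / emission_sigma; default 2.
#'   The emitted amplitude is fixed at 1, so snr = 2 means emission noise
#'   SD 0.5.
#' @param emission_sigma per-ROI emission noise SD; overrides \code{snr}
#'   when given (snr is then 1 / emission_sigma; 0 gives noiseless frames).
#' @param anti_pair generate an anti-correlated template pair; default TRUE.
#' @param hamd_slope,hamd_intercept,hamd_sigma linear symptom model:
#'   hamd = intercept + slope * true dwell time (s) of \code{effect_cap} +
#'   N(0, hamd_sigma), truncated at 0. Defaults give severities near the
#'   20-point range typical of moderate depression cohorts.
#' @param seed integer seed.
#' @return An object of class \code{synthetic_truth}.
#' @export
synthetic_truth <- function(k = 7L, atlas = synthetic_atlas(),
                            self_control = 0.65, self_patient_effect = 0.80,
                            effect_cap = 0L, snr = 2, emission_sigma = NULL,
                            anti_pair = TRUE,
                            hamd_slope = 0.8, hamd_intercept = 14,
                            hamd_sigma = 5, seed = 1L) {
  templates <- make_templates(k, atlas, anti_pair = anti_pair, seed = seed)
  p_control <- make_transition_matrix(self_control, k, seed = seed + 1L)
  self_patient <- rep(self_control, k)
  self_patient[effect_cap + 1L] <- self_patient_effect
  p_patient <- make_transition_matrix(self_patient, k, seed = seed + 2L)
  amplitude <- 1
  if (is.null(emission_sigma)) emission_sigma <- amplitude / snr
  snr <- if (emission_sigma > 0) amplitude / emission_sigma else Inf
  structure(
    list(k = as.integer(k), atlas = atlas, templates = templates,
         p_control = p_control, p_patient = p_patient,
         effect_cap = as.integer(effect_cap),
         amplitude = amplitude, emission_sigma = emission_sigma,
         snr = snr,
         hamd = list(slope = hamd_slope, intercept = hamd_intercept,
                     sigma = hamd_sigma),
         seed = seed),
    class = "synthetic_truth")
}

#' Simulate a finite Markov chain
#'
#' @param p k x k row-stochastic matrix.
#' @param t_len chain length.
#' @param init optional initial state (0-based); default drawn from the
#'   stationary distribution.
#' @return integer vector of 0-based states, length \code{t_len}.
#' @export
simulate_markov_chain <- function(p, t_len, init = NULL) {
  k <- nrow(p)
  states <- integer(t_len)
  states[1] <- if (is.null(init))
    sample.int(k, 1L, prob = stationary_distribution(p)) - 1L
  else as.integer(init)
  for (t in 2:t_len)
    states[t] <- sample.int(k, 1L, prob = p[states[t - 1L] + 1L, ]) - 1L
  states
}

#' Simulate one subject's ROI time series
#'
#' Draws a latent state sequence from the group's transition matrix and
#' emits frames as amplitude * sqrt(R) * template[state] + Gaussian noise
#' per ROI. The latent sequence is returned alongside for oracle tests.
#'
#' @param truth \code{synthetic_truth}.
#' @param group \code{"control"} or \code{"patient"}.
#' @param t_len frames per subject; default 240.
#' @param tr_seconds repetition time; default 2.
#' @param subject_id identifier for the returned \code{roi_ts}.
#' @return list with \code{series} (raw \code{roi_ts}) and \code{states}
#'   (0-based latent sequence).
#' @export
simulate_subject <- function(truth, group = c("control", "patient"),
                             t_len = 240L, tr_seconds = 2,
                             subject_id = "sim") {
  group <- match.arg(group)
  p <- if (group == "control") truth$p_control else truth$p_patient
  r <- ncol(truth$templates)
  states <- simulate_markov_chain(p, t_len)
  signal <- truth$amplitude * sqrt(r) * truth$templates[states + 1L, , drop = FALSE]
  noise <- matrix(stats::rnorm(t_len * r, 0, truth$emission_sigma), t_len, r)
  list(series = roi_ts(signal + noise, subject_id, tr_seconds = tr_seconds),
       states = states)
}

#' Simulate a full cohort with manifest, covariates and symptom scores
#'
#' Generates \code{n_control} + \code{n_patient} subjects with latent Markov
#' dynamics from their group's transition matrix, nuisance covariates drawn
#' independently of group (age ~ N(33.5, 12.8^2) truncated at 18, sex with
#' 40% male, education ~ N(12.4, 3.2^2) truncated at 6, six sites, mean FD
#' log-normal around 0.12 mm), and for patients a HAMD-like score linear in
#' the true dwell time of the effect state. Matching the study's cohort
#' shape means n_control = 215, n_patient = 221, T = 240.
#'
#' @param truth \code{synthetic_truth}.
#' @param n_control,n_patient group sizes (>= 2).
#' @param t_len frames per subject; default 240.
#' @param tr_seconds repetition time; default 2.
#' @param seed integer seed.
#' @return list (a cohort as in [load_cohort()], plus ground truth):
#'   \code{manifest}, \code{series} (raw, unstandardized), \code{atlas},
#'   \code{states} (per-subject latent sequences), \code{truth}.
#' @export
simulate_cohort <- function(truth, n_control = 215L, n_patient = 221L,
                            t_len = 240L, tr_seconds = 2, seed = 1L) {
  stopifnot(n_control >= 2L, n_patient >= 2L)
  if (!is.null(seed)) set.seed(seed)
  n <- n_control + n_patient
  grp <- c(rep("control", n_control), rep("patient", n_patient))
  ids <- sprintf("sub-%04d", seq_len(n))
  series <- vector("list", n); states <- vector("list", n)
  for (i in seq_len(n)) {
    sim <- simulate_subject(truth, grp[i], t_len, tr_seconds, subject_id = ids[i])
    series[[i]] <- sim$series
    states[[i]] <- sim$states
  }
  names(series) <- names(states) <- ids
  age <- pmax(18, round(stats::rnorm(n, 33.5, 12.8)))
  sex <- sample(c("male", "female"), n, replace = TRUE, prob = c(0.4, 0.6))
  education <- pmax(6, round(stats::rnorm(n, 12.4, 3.2)))
  site <- sample(sprintf("site%d", 1:6), n, replace = TRUE)
  mean_fd <- stats::rlnorm(n, log(0.12), 0.4)
  hamd <- rep(NA_real_, n)
  pat <- which(grp == "patient")
  true_dwell <- vapply(pat, function(i) {
    d <- dwell_and_occurrence(states[[i]], truth$k, tr_seconds)
    dt <- d$dwell_time[truth$effect_cap + 1L]
    if (is.na(dt)) 0 else dt
  }, numeric(1))
  hamd[pat] <- pmax(0, truth$hamd$intercept + truth$hamd$slope * true_dwell +
                      stats::rnorm(length(pat), 0, truth$hamd$sigma))
  manifest <- data.frame(
    subject_id = ids, group = factor(grp), age = age,
    sex = factor(sex), education = education, site = factor(site),
    mean_fd = mean_fd, hamd = hamd)
  list(manifest = manifest, series = series, atlas = truth$atlas,
       states = states, truth = truth)
}

#' Expected recoverable CAP patterns of a synthetic truth
#'
#' Per-ROI z-scoring of each subject's series centers every ROI at its
#' occupancy-weighted mean across states and scales it by its marginal SD.
#' The spatial pattern a clustering of standardized frames can recover for
#' state c is therefore not the raw template t_c but
#' (A t_c,r - A sum_d pi_d t_d,r) / s_r, with A the emitted amplitude,
#' pi the pooled stationary occupancy and s_r the marginal per-ROI SD
#' (state variance of the signal plus emission noise). This function
#' computes those patterns, the correct reference for centroid-recovery
#' checks.
#'
#' @param truth \code{synthetic_truth}.
#' @param n_control,n_patient group sizes weighting the pooled occupancy.
#' @return k x R matrix of expected standardized state patterns.
#' @export
expected_cap_patterns <- function(truth, n_control = 1L, n_patient = 1L) {
  mu_c <- stationary_distribution(truth$p_control)
  mu_p <- stationary_distribution(truth$p_patient)
  pi_pool <- (n_control * mu_c + n_patient * mu_p) / (n_control + n_patient)
  r <- ncol(truth$templates)
  amp <- truth$amplitude * sqrt(r)
  signal <- amp * truth$templates                 # k x R emitted means
  m <- colSums(pi_pool * signal)                  # per-ROI marginal mean
  v_state <- colSums(pi_pool * sweep(signal, 2L, m)^2)
  s <- sqrt(v_state + truth$emission_sigma^2)
  sweep(sweep(signal, 2L, m), 2L, s, "/")
}

#' Evaluate parameter recovery of a fitted CAP model against ground truth
#'
#' Matches fitted centroids to the expected standardized state patterns of
#' the generating truth (exhaustive assignment maximizing total spatial
#' correlation), then reports the matched correlations and the fraction of
#' frames whose estimated CAP label agrees with the latent state.
#'
#' @param model \code{cap_model} fitted on the simulated cohort.
#' @param cohort output of [simulate_cohort()] (carries states and truth).
#' @return list with \code{perm} (template matched to each CAP),
#'   \code{template_r} (matched spatial correlations),
#'   \code{frame_agreement} (overall fraction of correctly labelled
#'   frames).
#' @export
evaluate_recovery <- function(model, cohort) {
  truth <- cohort$truth
  n_ctl <- sum(cohort$manifest$group == "control")
  n_pat <- sum(cohort$manifest$group == "patient")
  ref <- expected_cap_patterns(truth, n_ctl, n_pat)
  m <- match_caps(model$centroids, ref)
  est <- unlist(model$assignments[cohort$manifest$subject_id])
  lat <- unlist(cohort$states[cohort$manifest$subject_id])
  agree <- mean((m$perm[est + 1L] - 1L) == lat)
  list(perm = m$perm, template_r = m$r, frame_agreement = agree)
}
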