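# Synthetic trial and feature-table generators. These emulate the
# statistical structure the analysis assumes -- a three-arm crossover with
# baseline/post measurements over 52 endpoints, and an aligned LC-MS peak
# table with pooled QCs and blanks -- with known ground truth, so every
# pipeline stage can be exercised and checked for parameter recovery.

.default_response_sd <- c(
  # calibrated so simulated ranges are of the order seen in such trials:
  # plasma nitrite swings by hundreds of percent, blood pressure by tens
  PWV = 20, SBP = 8, DBP = 12, nitrite = 120, glucose = 20, TAG = 60,
  total_cholesterol = 25, HDL_C = 35, LDL_C = 30,
  working_memory = 20, episodic_memory = 10, attention = 12,
  alert = 25, content = 18, calm = 20, mental_fatigue = 50
)

.default_baseline <- list(
  PWV = c(8, 1.2), SBP = c(115, 10), DBP = c(70, 8),
  nitrite = c(0.15, 0.05), glucose = c(5, 0.5), TAG = c(1.0, 0.4),
  total_cholesterol = c(4.5, 0.8), HDL_C = c(1.5, 0.3), LDL_C = c(2.6, 0.7),
  cognitive_score = c(50, 10), cognitive_rt = c(450, 60),
  cognitive_vas = c(55, 12)
)

#' Configuration for the synthetic crossover trial
#'
#' Bundles and validates the parameters of [simulate_trial()]. The
#' defaults describe a 37-participant, three-arm (whole blueberry /
#' blueberry powder / placebo) crossover with baseline and post
#' measurements on the default 52-endpoint registry. Treatment effects
#' default to zero except plasma nitrite, which gets the mean percent
#' shifts such interventions produce (+68.66 / +4.34 / -9.10 for
#' blueberry / powder / placebo); per-endpoint inter-individual response
#' SDs are calibrated so simulated ranges resemble real trial data.
#'
#' @param registry Endpoint registry.
#' @param n_participants Number of participants (>= 4; default 37).
#' @param arm_effects Named list per arm of named numeric vectors
#'   (registry `domain` label -> mean percent shift); missing entries are
#'   zero.
#' @param response_sd Named numeric of inter-individual response SDs in
#'   percent, keyed by registry `domain` label; defaults per
#'   `.default_response_sd`.
#' @param rho Within-person cross-arm correlation of the latent
#'   responsiveness, in \[0, 1\].
#' @param consistency Fraction (on the SD scale, in \[0, 1\]) of each
#'   endpoint's response variance driven by the participant's shared
#'   latent responsiveness rather than endpoint-level noise.
#' @param n_planted_responders Participants given a systematic
#'   direction-of-benefit-aligned boost in `planted_arm` (ground-truth
#'   responders; default 0).
#' @param planted_arm Arm carrying the planted boost.
#' @param planted_effect_sd Size of the planted boost in per-endpoint
#'   response-SD units (default 2.5).
#' @param round_cognitive Round cognitive measurements to integers,
#'   inducing the exact ties discrete scores show (default `TRUE`).
#' @return Validated list of class `trial_sim_config`.
#' @export
trial_sim_config <- function(registry = build_default_registry(),
                             n_participants = 37,
                             arm_effects = list(
                               blueberry = c(nitrite = 68.66),
                               powder = c(nitrite = 4.34),
                               placebo = c(nitrite = -9.10)),
                             response_sd = .default_response_sd,
                             rho = 0.3, consistency = 0.3,
                             n_planted_responders = 0,
                             planted_arm = "powder",
                             planted_effect_sd = 2.5,
                             round_cognitive = TRUE) {
  validate_registry(registry, strict = FALSE)
  if (n_participants < 4) {
    abort("n_participants must be at least 4",
          class = "dietresponder_config_error")
  }
  if (rho < 0 || rho > 1) {
    abort("rho must lie in [0, 1]", class = "dietresponder_config_error")
  }
  if (consistency < 0 || consistency > 1) {
    abort("consistency must lie in [0, 1]",
          class = "dietresponder_config_error")
  }
  if (any(response_sd < 0)) {
    abort("response SDs must be non-negative",
          class = "dietresponder_config_error")
  }
  if (n_planted_responders > n_participants) {
    abort("cannot plant more responders than participants",
          class = "dietresponder_config_error")
  }
  if (!planted_arm %in% .arms) {
    abort("planted_arm must be one of blueberry, powder, placebo",
          class = "dietresponder_config_error")
  }
  sd_full <- .default_response_sd
  sd_full[names(response_sd)] <- response_sd
  structure(list(registry = registry,
                 n_participants = as.integer(n_participants),
                 arm_effects = arm_effects, response_sd = sd_full,
                 rho = rho, consistency = consistency,
                 n_planted_responders = as.integer(n_planted_responders),
                 planted_arm = planted_arm,
                 planted_effect_sd = planted_effect_sd,
                 round_cognitive = round_cognitive),
            class = "trial_sim_config")
}

.baseline_params <- function(registry) {
  get1 <- function(i) {
    dom <- registry$domain[i]
    if (registry$system[i] == "vascular") return(.default_baseline[[dom]])
    if (registry$units[i] == "ms") return(.default_baseline$cognitive_rt)
    if (registry$units[i] == "mm VAS") return(.default_baseline$cognitive_vas)
    .default_baseline$cognitive_score
  }
  t(vapply(seq_len(nrow(registry)), get1, numeric(2)))
}

#' Simulate a three-arm crossover trial
#'
#' Draws baseline values per endpoint from normal distributions, then
#' generates the post value multiplicatively:
#' `post = baseline * (1 + pct / 100)` where the percent response combines
#' the arm's mean treatment effect, a participant latent responsiveness
#' shared across endpoints (aligned with each endpoint's direction of
#' benefit, correlated `rho` across arms), endpoint-level noise, and an
#' optional planted responder boost. Cognitive measurements are rounded
#' to integers so discrete scores can tie exactly between baseline and
#' post.
#'
#' @param config A [trial_sim_config()].
#' @param seed Integer seed; identical seeds give identical output.
#' @return List with `measurements` (long tibble ready for
#'   [build_response_table()]), `covariates` (participant gender, BMI
#'   class and visit order), `truth` (planted responder ids, per-cell
#'   intended percent responses, latent responsiveness draws) and
#'   `config`.
#' @export
simulate_trial <- function(config = trial_sim_config(), seed = 1) {
  stopifnot(inherits(config, "trial_sim_config"))
  set.seed(seed)
  reg <- config$registry
  n <- config$n_participants
  ne <- nrow(reg)
  ids <- sprintf("S%02d", seq_len(n))
  s_e <- config$response_sd[reg$domain]
  base_par <- .baseline_params(reg)
  w <- config$consistency

  planted <- head(ids, config$n_planted_responders)
  z_shared <- rnorm(n)
  rows <- vector("list", length(.arms))
  truth_rows <- vector("list", length(.arms))
  for (a_i in seq_along(.arms)) {
    arm <- .arms[a_i]
    eff <- rep(0, ne)
    ae <- config$arm_effects[[arm]]
    if (!is.null(ae)) {
      hit <- match(names(ae), reg$domain)
      for (k in seq_along(ae)) {
        if (!is.na(hit[k])) eff[reg$domain == names(ae)[k]] <- ae[[k]]
      }
    }
    z_arm <- rnorm(n)
    u <- config$rho * z_shared + sqrt(1 - config$rho^2) * z_arm
    baseline <- matrix(rnorm(n * ne, rep(base_par[, 1], each = n),
                             rep(base_par[, 2], each = n)), n, ne)
    baseline <- pmax(baseline, matrix(rep(0.02 * base_par[, 1], each = n),
                                      n, ne))
    eps <- matrix(rnorm(n * ne), n, ne)
    boost <- ifelse(ids %in% planted & arm == config$planted_arm,
                    config$planted_effect_sd, 0)
    pct <- matrix(rep(eff, each = n), n, ne) +
      outer(u, reg$direction) * matrix(rep(w * s_e, each = n), n, ne) +
      eps * matrix(rep(sqrt(1 - w^2) * s_e, each = n), n, ne) +
      outer(boost, reg$direction) * matrix(rep(s_e, each = n), n, ne)
    post <- baseline * (1 + pct / 100)
    if (config$round_cognitive) {
      cog <- reg$system == "cognitive"
      baseline[, cog] <- round(baseline[, cog])
      post[, cog] <- round(post[, cog])
    }
    long <- tibble::tibble(
      participant_id = rep(ids, times = 2 * ne),
      arm = arm,
      timepoint = rep(c("baseline", "post"), each = n * ne),
      endpoint_id = rep(rep(reg$id, each = n), times = 2),
      value = c(as.vector(baseline), as.vector(post)))
    rows[[a_i]] <- long
    truth_rows[[a_i]] <- tibble::tibble(
      participant_id = rep(ids, times = ne), arm = arm,
      endpoint_id = rep(reg$id, each = n),
      true_pct = as.vector(pct),
      latent = rep(u, times = ne))
  }
  measurements <- dplyr::bind_rows(rows)

  covariates <- tibble::tibble(
    participant_id = ids,
    gender = sample(c("M", "F"), n, replace = TRUE, prob = c(13, 24) / 37),
    bmi_class = sample(c("normal", "overweight"), n, replace = TRUE,
                       prob = c(0.7, 0.3)),
    visit_order = sample(apply(
      gtools_permutations_bpc(), 1, paste, collapse = "-"), n,
      replace = TRUE))

  list(measurements = measurements,
       covariates = covariates,
       truth = list(planted_responders = planted,
                    cells = dplyr::bind_rows(truth_rows)),
       config = config)
}

# the 6 orderings of the three treatments (visit sequences)
gtools_permutations_bpc <- function() {
  arms <- c("B", "P", "C")
  m <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
             c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  matrix(arms[m], nrow = 6)
}

#' Configuration for the synthetic LC-MS feature table
#'
#' Parameters for [simulate_feature_table()]. Defaults emulate a
#' positive-mode urinary peak table for 9 responders and 9 non-responders
#' with pooled QC injections and blanks: log-normal baseline intensities,
#' a configurable number of planted class-discriminating features (higher
#' in RS), a background class drift whose direction is higher-in-NRS for
#' 79% of features, and a subset of QC-unstable features destined to fail
#' the 30% RSD filter.
#'
#' @param n_rs,n_nrs Study samples per class (defaults 9 and 9).
#' @param n_features Total features (default 500).
#' @param n_planted Planted discriminating features, shifted higher in RS
#'   (default 5).
#' @param effect_size Planted between-class shift in units of the
#'   log-scale biological SD (default 1).
#' @param frac_higher_nrs Probability that a non-planted feature's small
#'   background drift points higher-in-NRS (default 0.79).
#' @param background_drift Size of that background drift in log-SD units
#'   (default 0.2).
#' @param n_qc Pooled QC injections (default 6).
#' @param qc_rsd Target QC RSD in percent for stable features (default
#'   10).
#' @param n_qc_unstable Features made QC-unstable (default 0), with
#'   target RSDs drawn uniformly from `unstable_rsd`.
#' @param unstable_rsd Length-2 range of target RSDs for unstable
#'   features (default `c(50, 90)`).
#' @param n_blanks Blank injections (default 2).
#' @param blank_level Blank intensity as a fraction of the feature's
#'   grand mean (default 0.01).
#' @param log_mu,log_mu_sd,log_sigma Mean/SD of the per-feature log-scale
#'   location and the shared biological log-SD.
#' @return Validated list of class `feature_sim_config`.
#' @export
feature_sim_config <- function(n_rs = 9, n_nrs = 9, n_features = 500,
                               n_planted = 5, effect_size = 1,
                               frac_higher_nrs = 0.79,
                               background_drift = 0.2,
                               n_qc = 6, qc_rsd = 10, n_qc_unstable = 0,
                               unstable_rsd = c(50, 90),
                               n_blanks = 2, blank_level = 0.01,
                               log_mu = log(1e6), log_mu_sd = 1,
                               log_sigma = 0.5) {
  if (n_rs < 2 || n_nrs < 2) {
    abort("at least 2 study samples per class are required",
          class = "dietresponder_config_error")
  }
  if (n_planted + n_qc_unstable > n_features) {
    abort("planted plus QC-unstable features exceed the feature count",
          class = "dietresponder_config_error")
  }
  if (frac_higher_nrs < 0 || frac_higher_nrs > 1) {
    abort("frac_higher_nrs must lie in [0, 1]",
          class = "dietresponder_config_error")
  }
  if (n_qc < 2) {
    abort("at least 2 QC samples are required for RSD filtering",
          class = "dietresponder_config_error")
  }
  structure(as.list(environment()), class = "feature_sim_config")
}

#' Simulate an LC-MS feature table with planted structure
#'
#' Generates study, pooled-QC and blank samples over `n_features`
#' log-normal features. Planted discriminators are shifted higher in RS
#' by `effect_size` log-SDs; the remaining features get a small drift
#' whose direction is higher-in-NRS with probability `frac_higher_nrs`.
#' QC injections scatter around each feature's grand mean with the
#' configured target RSD, with a designated subset made unstable; blanks
#' sit at a small fraction of the mean.
#'
#' @param config A [feature_sim_config()].
#' @param seed Integer seed.
#' @return List with `table` (a [feature_table()]) and `truth`
#'   (`planted_features`, `unstable_features`, `higher_in` per feature).
#' @export
simulate_feature_table <- function(config = feature_sim_config(), seed = 1) {
  stopifnot(inherits(config, "feature_sim_config"))
  set.seed(seed)
  nf <- config$n_features
  mz <- round(runif(nf, 80, 800), 3)
  rt <- round(runif(nf, 0.5, 12), 2)
  feat_ids <- make.unique(sprintf("%.3f@%.2f", mz, rt), sep = "_")

  mu <- rnorm(nf, config$log_mu, config$log_mu_sd)
  sigma <- config$log_sigma

  planted <- sample(feat_ids, config$n_planted)
  unstable <- sample(setdiff(feat_ids, planted), config$n_qc_unstable)

  shift <- numeric(nf)               # log-scale RS-minus-NRS difference
  shift[feat_ids %in% planted] <- config$effect_size * sigma
  bg <- !(feat_ids %in% planted)
  drift_sign <- ifelse(runif(sum(bg)) < config$frac_higher_nrs, -1, +1)
  shift[bg] <- drift_sign * config$background_drift * sigma
  higher_in <- ifelse(shift >= 0, "RS", "NRS")

  n_study <- config$n_rs + config$n_nrs
  cls <- c(rep("RS", config$n_rs), rep("NRS", config$n_nrs))
  study <- matrix(0, n_study, nf)
  for (j in seq_len(nf)) {
    centre <- mu[j] + ifelse(cls == "RS", +shift[j] / 2, -shift[j] / 2)
    study[, j] <- exp(rnorm(n_study, centre, sigma))
  }

  grand <- exp(mu + sigma^2 / 2)
  target_rsd <- rep(config$qc_rsd, nf)
  target_rsd[feat_ids %in% unstable] <-
    runif(config$n_qc_unstable, config$unstable_rsd[1],
          config$unstable_rsd[2])
  qc <- matrix(0, config$n_qc, nf)
  for (j in seq_len(nf)) {
    qc[, j] <- pmax(grand[j] * (1 + rnorm(config$n_qc, 0,
                                          target_rsd[j] / 100)),
                    1e-6 * grand[j])
  }
  blanks <- matrix(0, config$n_blanks, nf)
  for (j in seq_len(nf)) {
    blanks[, j] <- pmax(config$blank_level * grand[j] *
                          (1 + rnorm(config$n_blanks, 0, 0.2)), 0)
  }

  mat <- rbind(study, qc, blanks)
  colnames(mat) <- feat_ids
  rownames(mat) <- c(sprintf("RS%02d", seq_len(config$n_rs)),
                     sprintf("NRS%02d", seq_len(config$n_nrs)),
                     sprintf("QC%02d", seq_len(config$n_qc)),
                     sprintf("BLANK%02d", seq_len(config$n_blanks)))
  roles <- c(rep("study", n_study), rep("qc", config$n_qc),
             rep("blank", config$n_blanks))
  labels <- c(cls, rep(NA_character_, config$n_qc + config$n_blanks))

  list(table = feature_table(mat, roles, labels),
       truth = list(planted_features = planted,
                    unstable_features = unstable,
                    higher_in = setNames(higher_in, feat_ids),
                    target_qc_rsd = setNames(target_rsd, feat_ids)))
}
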