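test_that("feature_table validates its inputs", {
  m <- matrix(1:6, 2, 3)
  expect_error(feature_table(m, c("study", "nope")),
               class = "dietresponder_validation_error")
  expect_error(feature_table(matrix(-1, 2, 2), c("study", "study")),
               class = "dietresponder_validation_error")
  expect_error(feature_table(m * 1.0, c("study", "study"),
                             class_labels = c("RS", "XX")),
               class = "dietresponder_validation_error")
  ft <- feature_table(m * 1.0, c("study", "study"),
                      class_labels = c("RS", "NRS"))
  expect_s3_class(ft, "feature_table")
})

test_that("QC-RSD filter keeps stable features and logs removals", {
  study <- matrix(100, 4, 3, dimnames = list(NULL, c("a", "b", "c")))
  qc <- rbind(c(100, 100, 100), c(100, 200, 105))
  colnames(qc) <- c("a", "b", "c")
  ft <- make_ft(study, rep("RS", 4), qc = qc)
  filt <- qc_rsd_filter(ft, threshold_pct = 30)
  # feature b: QC mean 150, SD 70.71 -> RSD 47.1% -> removed
  expect_setequal(colnames(filt$intensities), c("a", "c"))
  log <- attr(filt, "removal_log")
  expect_equal(log$feature, "b")
  expect_match(log$reason, "47.1")
  # identical QC intensities -> RSD 0 -> kept
  expect_true("a" %in% colnames(filt$intensities))
  expect_error(qc_rsd_filter(make_ft(study, rep("RS", 4))),
               class = "dietresponder_validation_error")
})

test_that("QC-RSD filter is monotone in its threshold and idempotent", {
  sim <- simulate_feature_table(
    feature_sim_config(n_features = 120, n_planted = 0,
                       n_qc_unstable = 30), seed = 8)
  ft <- sim$table
  f30 <- qc_rsd_filter(ft, 30)
  f100 <- qc_rsd_filter(ft, 100)
  expect_true(all(colnames(f30$intensities) %in%
                    colnames(f100$intensities)))
  twice <- qc_rsd_filter(f30, 30)
  expect_equal(twice$intensities, f30$intensities)
  # column reordering commutes with filtering
  perm <- sample(ncol(ft$intensities))
  ft_perm <- ft
  ft_perm$intensities <- ft$intensities[, perm]
  f_perm <- qc_rsd_filter(ft_perm, 30)
  expect_setequal(colnames(f_perm$intensities), colnames(f30$intensities))
})

test_that("MAD/median filter scores and drops low-variability features", {
  study <- cbind(flat = rep(5, 5), ramp = c(1, 2, 3, 4, 5),
                 wild = c(1, 10, 3, 20, 2))
  ft <- make_ft(study, c(rep("RS", 3), rep("NRS", 2)))
  # hand computation: ramp has median 3, MAD 1 -> score 1/3
  filt1 <- mad_filter(ft, keep_rule = 1 / 3)  # drop floor(3/3)=1 feature
  expect_false("flat" %in% colnames(filt1$intensities))
  expect_true(all(c("ramp", "wild") %in% colnames(filt1$intensities)))

  none <- mad_filter(ft, keep_rule = "none")
  expect_equal(none$intensities, ft$intensities)

  # scores: flat 0, ramp 1/3, wild 2/3; threshold 0.3 drops only flat
  thr <- mad_filter(ft, keep_rule = list(threshold = 0.3))
  expect_setequal(colnames(thr$intensities), c("ramp", "wild"))
})

test_that("threshold-rule MAD filtering is idempotent", {
  sim <- simulate_feature_table(feature_sim_config(n_features = 80,
                                                   n_planted = 0), seed = 3)
  once <- mad_filter(sim$table, keep_rule = list(threshold = 0.4))
  twice <- mad_filter(once, keep_rule = list(threshold = 0.4))
  expect_equal(twice$intensities, once$intensities)
})

test_that("log transform is exact for positive tables and order preserving", {
  study <- cbind(a = c(1000, 10), b = c(1, 100))
  ft <- make_ft(study, c("RS", "NRS"))
  lt <- log_transform(ft, pseudo = 0)
  expect_equal(lt$intensities[1, "a"], 3)
  expect_equal(lt$intensities[, "b"], log10(study[, "b"]),
               ignore_attr = TRUE)
  # default pseudo-value handles zeros and preserves order
  study0 <- cbind(a = c(0, 5, 50), b = c(2, 1, 3))
  ft0 <- make_ft(study0, c("RS", "RS", "NRS"))
  lt0 <- log_transform(ft0)
  expect_equal(attr(lt0, "pseudo"), 0.5)  # half the smallest positive (1)
  expect_true(all(diff(lt0$intensities[, "a"]) > 0))
  expect_error(log_transform(ft0, pseudo = 0),
               class = "dietresponder_validation_error")
})

test_that("autoscaling standardises study samples and drops constants", {
  sim <- simulate_feature_table(feature_sim_config(n_features = 40,
                                                   n_planted = 0), seed = 5)
  sc <- autoscale(sim$table)
  study <- sc$intensities[sc$sample_roles == "study", ]
  expect_equal(unname(colMeans(study)), rep(0, ncol(study)),
               tolerance = 1e-9)
  expect_equal(unname(apply(study, 2, sd)), rep(1, ncol(study)),
               tolerance = 1e-9)
  # idempotence
  sc2 <- autoscale(sc)
  expect_equal(sc2$intensities, sc$intensities, tolerance = 1e-9)

  # two samples (2, 6): mean 4, sample SD sqrt(8), so scaled -/+ 1/sqrt(2)
  two <- make_ft(cbind(f = c(2, 6)), c("RS", "NRS"))
  sc_two <- autoscale(two)
  expect_equal(unname(sc_two$intensities[, "f"]), c(-1, 1) / sqrt(2))
  const <- make_ft(cbind(f = c(2, 6), g = c(3, 3)), c("RS", "NRS"))
  expect_warning(sc_c <- autoscale(const), "constant")
  expect_false("g" %in% colnames(sc_c$intensities))
})

test_that("univariate ROC equals exhaustive pair counting", {
  # 2v2 toy: RS (5, 7) vs NRS (1, 3) separates perfectly
  ft <- make_ft(cbind(f = c(5, 7, 1, 3)),
                c("RS", "RS", "NRS", "NRS"))
  expect_equal(univariate_roc(ft)$auc, 1.0)

  set.seed(21)
  for (i in 1:40) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    vals <- round(rnorm(n1 + n2), sample(0:1, 1))
    labels <- c(rep("RS", n1), rep("NRS", n2))
    ftab <- make_ft(cbind(f = exp(vals)), labels)
    got <- univariate_roc(ftab)$auc
    want <- oracle_auc(exp(vals)[1:n1], exp(vals)[(n1 + 1):(n1 + n2)])
    expect_equal(got, want)
  }
})

test_that("univariate ROC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(13)
  vals <- rnorm(18)
  labels <- rep(c("RS", "NRS"), each = 9)
  ft <- make_ft(cbind(f = exp(vals)), labels)
  got <- univariate_roc(ft)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = labels, predictor = exp(vals), levels = c("NRS", "RS"),
    direction = "<", quiet = TRUE)))
  expect_equal(got, ref)
})

test_that("permuted labels give chance-level univariate AUC at large n", {
  set.seed(55)
  vals <- rnorm(600)
  labels <- sample(rep(c("RS", "NRS"), each = 300))
  ft <- make_ft(cbind(f = exp(vals)), labels)
  expect_lt(abs(univariate_roc(ft)$auc - 0.5), 0.08)
})

test_that("feature tables round-trip through delimited text", {
  sim <- simulate_feature_table(feature_sim_config(n_features = 25,
                                                   n_planted = 2), seed = 2)
  fp <- withr::local_tempfile(fileext = ".tsv")
  sp <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(sim$table, fp, sp)
  back <- read_feature_table(fp, sp)
  expect_equal(back$intensities, sim$table$intensities)
  expect_equal(back$sample_roles, sim$table$sample_roles)
  expect_equal(back$class_labels, sim$table$class_labels)
})

test_that("multivariate ROC is deterministic and recovers planted signal", {
  sim <- simulate_feature_table(
    feature_sim_config(n_features = 60, n_planted = 3, effect_size = 5),
    seed = 14)
  r1 <- multivariate_roc(sim$table, subset_sizes = c(5, 10),
                         n_repeats = 8, n_boot = 100, ntree = 150,
                         seed = 7)
  r2 <- multivariate_roc(sim$table, subset_sizes = c(5, 10),
                         n_repeats = 8, n_boot = 100, ntree = 150,
                         seed = 7)
  expect_identical(r1$auc, r2$auc)
  expect_identical(r1$class_probabilities, r2$class_probabilities)
  expect_identical(r1$feature_ranking, r2$feature_ranking)
  expect_gte(r1$auc, 0.9)
  expect_lte(r1$ci_low, r1$ci_high)
  expect_true(all(r1$class_probabilities >= 0 &
                    r1$class_probabilities <= 1, na.rm = TRUE))
  top3 <- r1$feature_ranking$feature[1:3]
  expect_setequal(top3, sim$truth$planted_features)
})

test_that("feature report flags RS-high candidates and the NRS fraction", {
  sim <- simulate_feature_table(
    feature_sim_config(n_features = 50, n_planted = 4, effect_size = 4),
    seed = 6)
  res <- multivariate_roc(sim$table, subset_sizes = 10, n_repeats = 6,
                          n_boot = 50, ntree = 100, seed = 1)
  rep <- rank_discriminating_features(res, sim$table)
  # the fraction equals a direct mean comparison
  keep <- sim$table$sample_roles == "study"
  mat <- sim$table$intensities[keep, ]
  lab <- sim$table$class_labels[keep]
  direct <- colMeans(mat[lab == "NRS", ]) > colMeans(mat[lab == "RS", ])
  expect_equal(attr(rep, "fraction_higher_in_nrs"), mean(direct))
  # planted RS-high features are candidate predictors
  expect_true(all(sim$truth$planted_features %in%
                    attr(rep, "candidate_predictors")))
  # degenerate: every feature higher in NRS
  study <- rbind(matrix(1, 4, 3), matrix(10, 4, 3))
  colnames(study) <- c("x", "y", "z")
  ft_deg <- make_ft(study, rep(c("RS", "NRS"), each = 4))
  res_deg <- multivariate_roc(ft_deg, subset_sizes = 3, n_repeats = 4,
                              n_boot = 50, ntree = 50, seed = 2)
  rep_deg <- rank_discriminating_features(res_deg, ft_deg)
  expect_equal(attr(rep_deg, "fraction_higher_in_nrs"), 1)
})
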