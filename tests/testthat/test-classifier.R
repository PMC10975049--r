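test_that("quartile assignment takes floor(n/4) at each extreme", {
  resp <- manual_responses("nitrite", "powder", 8:1)
  qa <- assign_quartiles(resp, default_registry, "powder")
  expect_equal(sort(qa$participant_id[qa$quartile == "Q1"]),
               c("S01", "S02"))
  expect_equal(sort(qa$participant_id[qa$quartile == "Q4"]),
               c("S07", "S08"))
  expect_equal(sort(qa$rank), 1:8)

  resp37 <- manual_responses("nitrite", "powder", rnorm(37))
  qa37 <- assign_quartiles(resp37, default_registry, "powder")
  expect_equal(sum(qa37$quartile == "Q1"), 9L)
  expect_equal(sum(qa37$quartile == "Q4"), 9L)
  expect_equal(sum(qa37$quartile %in% c("Q2", "Q3")), 19L)
})

test_that("quartile membership equals the pair-counting oracle", {
  set.seed(101)
  for (i in 1:60) {
    n <- sample(5:40, 1)
    ids <- sprintf("S%02d", 1:n)
    pct <- round(rnorm(n, 0, 30), sample(0:2, 1))  # rounding induces ties
    resp <- manual_responses("nitrite", "powder", pct, ids = ids)
    qa <- suppressMessages(
      assign_quartiles(resp, default_registry, "powder"))
    orc <- oracle_quartile_membership(pct, ids)  # nitrite direction +1
    expect_setequal(qa$participant_id[qa$quartile == "Q1"], orc$q1)
    expect_setequal(qa$participant_id[qa$quartile == "Q4"], orc$q4)
  }
})

test_that("direction anti-symmetry leaves quartiles unchanged", {
  set.seed(5)
  pct <- rnorm(20, 0, 25)
  reg_flip <- default_registry
  reg_flip$direction <- -reg_flip$direction
  resp <- manual_responses("sbp", "powder", pct)
  resp_neg <- manual_responses("sbp", "powder", -pct)
  qa <- assign_quartiles(resp, default_registry, "powder")
  qa_flip <- assign_quartiles(resp_neg, reg_flip, "powder")
  expect_equal(qa$quartile[order(qa$participant_id)],
               qa_flip$quartile[order(qa_flip$participant_id)])
})

test_that("endpoints with fewer than four participants are skipped", {
  resp <- dplyr::bind_rows(
    manual_responses("nitrite", "powder", c(1, 2, 3)),
    manual_responses("sbp", "powder", c(1, 2, 3, 4, 5)))
  expect_warning(qa <- assign_quartiles(resp, default_registry, "powder"),
                 "nitrite")
  expect_setequal(unique(qa$endpoint_id), "sbp")
})

test_that("responder classification yields floor(n/4) RS and NRS", {
  sim <- simulate_trial(trial_sim_config(), seed = 2)
  rt <- build_response_table(sim$measurements, default_registry)
  qa <- suppressMessages(assign_quartiles(rt, default_registry, "powder"))
  cl <- classify_responders(qa)
  expect_equal(sum(cl$label == "RS"), 9L)
  expect_equal(sum(cl$label == "NRS"), 9L)
  expect_equal(sum(cl$label == "average"), 19L)
  expect_length(intersect(cl$participant_id[cl$label == "RS"],
                          cl$participant_id[cl$label == "NRS"]), 0L)
  expect_true(all(cl$n_responded + cl$n_nonresponded <= 52))
})

test_that("a participant in Q1 everywhere dominates the RS ranking", {
  set.seed(9)
  n <- 12
  ids <- sprintf("S%02d", 1:n)
  resp <- dplyr::bind_rows(lapply(c("nitrite", "hdl_c", "wm_01"), function(e) {
    pct <- c(100, rnorm(n - 1, 0, 5))  # S01 always far ahead
    manual_responses(e, "powder", pct, ids = ids)
  }))
  qa <- assign_quartiles(resp, default_registry, "powder")
  cl <- classify_responders(qa)
  expect_equal(cl$n_responded[cl$participant_id == "S01"], 3L)
  expect_equal(cl$label[cl$participant_id == "S01"], "RS")
})

test_that("classification is invariant to participant input order", {
  sim <- simulate_trial(trial_sim_config(n_participants = 21), seed = 4)
  rt <- build_response_table(sim$measurements, default_registry)
  qa <- suppressMessages(assign_quartiles(rt, default_registry, "blueberry"))
  cl1 <- classify_responders(qa)
  qa_shuf <- qa[sample(nrow(qa)), ]
  cl2 <- classify_responders(qa_shuf)
  expect_equal(as.data.frame(cl1), as.data.frame(cl2))
})

test_that("consistency agreement is 1 for identical arms and excludes missing", {
  eps <- default_registry$id[1:10]
  one <- dplyr::bind_rows(lapply(eps, function(e)
    manual_responses(e, "blueberry", c(10, -5, 0))))
  two <- one
  two$arm <- "powder"
  cm <- consistency_matrix(dplyr::bind_rows(one, two))
  expect_equal(cm$agreement$agreement, rep(1, 3))
  expect_equal(cm$agreement$n_compared, rep(10L, 3))

  # knock out one cell of one arm: that endpoint leaves the denominator
  two_m <- two
  two_m$response_pct[two_m$participant_id == "S01" &
                       two_m$endpoint_id == eps[1]] <- NA
  two_m$category[two_m$participant_id == "S01" &
                   two_m$endpoint_id == eps[1]] <- "missing"
  cm2 <- consistency_matrix(dplyr::bind_rows(one, two_m))
  expect_equal(cm2$agreement$n_compared[cm2$agreement$participant_id == "S01"],
               9L)
  expect_error(consistency_matrix(one),
               class = "dietresponder_validation_error")
})

test_that("independent categories agree about a third of the time", {
  set.seed(31)
  eps <- default_registry$id
  ids <- sprintf("S%02d", 1:60)
  mk <- function(arm) {
    grid <- expand.grid(participant_id = ids, endpoint_id = eps,
                        stringsAsFactors = FALSE)
    tibble::tibble(participant_id = grid$participant_id, arm = arm,
                   endpoint_id = grid$endpoint_id,
                   response_pct = 0,
                   category = sample(c("improved", "no_change", "worsened"),
                                     nrow(grid), replace = TRUE))
  }
  cm <- consistency_matrix(dplyr::bind_rows(mk("blueberry"), mk("powder")))
  expect_equal(mean(cm$agreement$agreement), 1 / 3, tolerance = 0.03)
})

test_that("chi-square matches the direct sum((O-E)^2/E) oracle", {
  # contingency [[5,4],[4,5]]: 18 classified participants
  cl <- tibble::tibble(
    participant_id = sprintf("S%02d", 1:18), arm = "powder",
    n_responded = 0L, n_nonresponded = 0L,
    label = rep(c("RS", "NRS"), each = 9))
  cov <- tibble::tibble(
    participant_id = sprintf("S%02d", 1:18),
    gender = c(rep("M", 5), rep("F", 4), rep("M", 4), rep("F", 5)))
  res <- chi_square_association(cl, cov, "gender")
  tab <- attr(res, "table")
  expect_equal(unname(as.vector(tab)), c(5, 4, 4, 5))
  expect_equal(res$statistic, oracle_chisq(tab))
  expect_equal(res$df, 1L)
  expect_equal(res$n, 18L)

  # perfect separation
  cov_sep <- tibble::tibble(participant_id = sprintf("S%02d", 1:18),
                            gender = rep(c("M", "F"), each = 9))
  res_sep <- chi_square_association(cl, cov_sep, "gender")
  expect_lt(res_sep$p_value, 0.001)

  # identical proportions -> statistic 0, p = 1
  cl2 <- cl
  cl2$label <- rep(c("RS", "NRS"), 9)
  cov2 <- tibble::tibble(participant_id = sprintf("S%02d", 1:18),
                         gender = c(rep("M", 8), rep("F", 10)))
  res0 <- chi_square_association(cl2, cov2, "gender")
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)
})

test_that("chi-square equals the oracle over random small tables", {
  set.seed(77)
  for (i in 1:50) {
    a <- sample(2:9, 1); b <- sample(2:9, 1)
    n_rs <- a + sample(0:3, 1); n_nrs <- b + sample(0:3, 1)
    ids <- sprintf("S%02d", seq_len(n_rs + n_nrs))
    cl <- tibble::tibble(participant_id = ids, arm = "powder",
                         n_responded = 0L, n_nonresponded = 0L,
                         label = c(rep("RS", n_rs), rep("NRS", n_nrs)))
    gender <- c(sample(rep(c("M", "F"), c(a, n_rs - a))),
                sample(rep(c("M", "F"), c(b, n_nrs - b))))
    cov <- tibble::tibble(participant_id = ids, gender = gender)
    res <- suppressWarnings(chi_square_association(cl, cov, "gender"))
    tab <- attr(res, "table")
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0) ||
        nrow(tab) < 2) {
      expect_true(is.na(res$statistic))
    } else {
      expect_equal(res$statistic, oracle_chisq(tab), tolerance = 1e-12)
    }
  }
})

test_that("degenerate contingency tables warn and return NA", {
  cl <- tibble::tibble(participant_id = sprintf("S%02d", 1:18),
                       arm = "powder", n_responded = 0L,
                       n_nonresponded = 0L,
                       label = rep(c("RS", "NRS"), each = 9))
  cov <- tibble::tibble(participant_id = sprintf("S%02d", 1:18),
                        gender = rep("F", 18))
  expect_warning(res <- chi_square_association(cl, cov, "gender"),
                 class = "dietresponder_degenerate_table")
  expect_true(is.na(res$statistic))
})
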