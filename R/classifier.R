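# Direction-aware quartile division: per-endpoint quartile assignment,
# responded/non-responded counting, RS / NRS / average classification,
# cross-arm consistency and covariate association.

#' Assign per-endpoint response quartiles
#'
#' For each endpoint in one arm, folds every participant's percent change
#' by the endpoint's direction of benefit and ranks the folded responses
#' from best to worst. The top `floor(n/4)` participants form Q1 (the
#' endpoint's responders) and the bottom `floor(n/4)` form Q4 (its
#' non-responders); the remainder is split at its median into Q2 and Q3.
#' Ties are broken by participant id ascending so the assignment is
#' deterministic; ties that straddle the Q1 or Q4 boundary are reported
#' via a message. Endpoints with fewer than 4 non-missing participants are
#' skipped with a warning.
#'
#' @param responses Response table from [build_response_table()].
#' @param registry Endpoint registry.
#' @param arm Arm to rank within.
#' @return Tibble `participant_id`, `arm`, `endpoint_id`, `folded_pct`,
#'   `rank` (1 = best), `quartile` (`"Q1"`..`"Q4"`).
#' @export
assign_quartiles <- function(responses, registry, arm) {
  dirs <- setNames(registry$direction, registry$id)
  sub <- dplyr::filter(responses, .data$arm == !!arm,
                       !is.na(.data$response_pct))
  if (nrow(sub) == 0L) {
    abort(sprintf("no non-missing responses in arm '%s'", arm),
          class = "dietresponder_validation_error")
  }
  sub$folded_pct <- sub$response_pct * dirs[sub$endpoint_id]
  pieces <- split(sub, sub$endpoint_id)
  skipped <- character()
  out <- lapply(pieces, function(d) {
    n <- nrow(d)
    if (n < 4L) {
      skipped <<- c(skipped, d$endpoint_id[1])
      return(NULL)
    }
    ord <- order(-d$folded_pct, d$participant_id)
    d <- d[ord, ]
    d$rank <- seq_len(n)
    q <- n %/% 4L
    m <- n - 2L * q
    quart <- c(rep("Q1", q),
               rep("Q2", ceiling(m / 2)), rep("Q3", floor(m / 2)),
               rep("Q4", q))
    # a tie straddling the Q1 or Q4 boundary means the cut is arbitrary
    if (q > 0 && d$folded_pct[q] == d$folded_pct[q + 1L]) {
      message(sprintf("endpoint %s: tie straddles the Q1 boundary",
                      d$endpoint_id[1]))
    }
    if (q > 0 && d$folded_pct[n - q] == d$folded_pct[n - q + 1L]) {
      message(sprintf("endpoint %s: tie straddles the Q4 boundary",
                      d$endpoint_id[1]))
    }
    d$quartile <- quart
    d[, c("participant_id", "arm", "endpoint_id", "folded_pct",
          "rank", "quartile")]
  })
  if (length(skipped)) {
    warn(paste0("skipped endpoints with < 4 non-missing participants: ",
                paste(skipped, collapse = ", ")))
  }
  dplyr::bind_rows(out)
}

#' Classify participants as responders, non-responders or average
#'
#' Counts, per participant, the endpoints on which they sat in Q1
#' (responded) and in Q4 (non-responded). Participants are then ranked by
#' responded count (descending, ties by id) and the top `floor(n/4)`
#' labelled RS; ranked by non-responded count the same way, the top
#' `floor(n/4)` are labelled NRS. A participant qualifying for both lists
#' is kept on the side with the larger count (an exact tie demotes them to
#' average, with a message), and the vacated slot is refilled from that
#' ranking so the two groups keep their quartile size whenever possible.
#' Everyone else is an average responder.
#'
#' @param assignments Quartile assignments from [assign_quartiles()].
#' @param backfill Refill slots vacated by dual-qualified participants
#'   (default `TRUE`); with `FALSE` the groups may fall below
#'   `floor(n/4)`.
#' @return Tibble `participant_id`, `arm`, `n_responded`,
#'   `n_nonresponded`, `label` (`"RS"`, `"NRS"`, `"average"`), sorted by
#'   id.
#' @export
classify_responders <- function(assignments, backfill = TRUE) {
  if (is.null(assignments) || nrow(assignments) == 0L) {
    abort("no quartile assignments to classify",
          class = "dietresponder_validation_error")
  }
  if (length(unique(assignments$arm)) != 1L) {
    abort("classification is per arm: filter assignments to a single arm",
          class = "dietresponder_validation_error")
  }
  counts <- assignments |>
    dplyr::group_by(.data$participant_id, .data$arm) |>
    dplyr::summarise(n_responded = sum(.data$quartile == "Q1"),
                     n_nonresponded = sum(.data$quartile == "Q4"),
                     .groups = "drop") |>
    dplyr::arrange(.data$participant_id)
  n <- nrow(counts)
  q <- n %/% 4L

  rs_rank <- counts$participant_id[
    order(-counts$n_responded, counts$participant_id)]
  nrs_rank <- counts$participant_id[
    order(-counts$n_nonresponded, counts$participant_id)]
  rs <- head(rs_rank, q)
  nrs <- head(nrs_rank, q)
  clash <- intersect(rs, nrs)
  for (id in clash) {
    i <- match(id, counts$participant_id)
    if (counts$n_responded[i] > counts$n_nonresponded[i]) {
      nrs <- setdiff(nrs, id)
    } else if (counts$n_responded[i] < counts$n_nonresponded[i]) {
      rs <- setdiff(rs, id)
    } else {
      message(sprintf(
        "participant %s ties between RS and NRS rankings; labelled average", id))
      rs <- setdiff(rs, id)
      nrs <- setdiff(nrs, id)
    }
  }
  if (backfill) {
    taken <- function() union(rs, nrs)
    for (id in setdiff(rs_rank, taken())) {
      if (length(rs) >= q) break
      rs <- c(rs, id)
    }
    for (id in setdiff(nrs_rank, taken())) {
      if (length(nrs) >= q) break
      nrs <- c(nrs, id)
    }
  }
  counts$label <- "average"
  counts$label[counts$participant_id %in% rs] <- "RS"
  counts$label[counts$participant_id %in% nrs] <- "NRS"
  counts
}

#' Cross-arm consistency of individual responses
#'
#' Builds the dense participant-by-(arm, endpoint) matrix behind a
#' consistency heat map, and summarises, per participant, how often the
#' response category agrees between two arms (by default the two
#' blueberry arms) across endpoints non-missing in both.
#'
#' @param responses Response table covering at least two arms.
#' @param value `"category"` (default) for the improved/no-change/worsened
#'   label, `"folded"` for the direction-folded percent change (requires
#'   `registry`).
#' @param registry Endpoint registry; only needed for `value = "folded"`.
#' @param arms Length-2 character: the pair of arms compared in the
#'   agreement summary.
#' @return List with `matrix` (participants x arm:endpoint, `NA` for
#'   missing cells) and `agreement` (tibble `participant_id`,
#'   `n_compared`, `agreement` in \[0, 1\]).
#' @export
consistency_matrix <- function(responses, value = c("category", "folded"),
                               registry = NULL,
                               arms = c("blueberry", "powder")) {
  value <- match.arg(value)
  present <- unique(responses$arm)
  if (length(present) < 2L) {
    abort("consistency requires responses from at least two arms",
          class = "dietresponder_validation_error")
  }
  if (!all(arms %in% present)) {
    abort(sprintf("arms '%s' and '%s' must both be present in the responses",
                  arms[1], arms[2]),
          class = "dietresponder_validation_error")
  }
  dat <- responses
  if (value == "folded") {
    if (is.null(registry)) {
      abort("value = 'folded' needs the registry for directions",
            class = "dietresponder_config_error")
    }
    dirs <- setNames(registry$direction, registry$id)
    dat$cell <- dat$response_pct * dirs[dat$endpoint_id]
  } else {
    dat$cell <- ifelse(dat$category == "missing", NA_character_,
                       dat$category)
  }
  wide <- dat |>
    dplyr::mutate(col = paste(.data$arm, .data$endpoint_id, sep = ":")) |>
    tidyr::pivot_wider(id_cols = "participant_id", names_from = "col",
                       values_from = "cell")
  mat <- as.matrix(wide[, -1, drop = FALSE])
  rownames(mat) <- wide$participant_id

  a <- dplyr::filter(dat, .data$arm == arms[1])[
    , c("participant_id", "endpoint_id", "cell")]
  b <- dplyr::filter(dat, .data$arm == arms[2])[
    , c("participant_id", "endpoint_id", "cell")]
  merged <- dplyr::inner_join(a, b, by = c("participant_id", "endpoint_id"),
                              suffix = c("_a", "_b")) |>
    dplyr::filter(!is.na(.data$cell_a), !is.na(.data$cell_b))
  agreement <- merged |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(n_compared = dplyr::n(),
                     agreement = mean(.data$cell_a == .data$cell_b),
                     .groups = "drop")
  list(matrix = mat, agreement = agreement)
}

#' Chi-square association between a covariate and response group
#'
#' Pearson chi-square test of independence on the contingency table of a
#' participant covariate (gender, BMI class, visit order) against the
#' RS / NRS label, restricted to classified responders and non-responders
#' (so N = |RS| + |NRS|). No continuity correction is applied by default,
#' matching the plain sum((O - E)^2 / E) statistic; set `correct = TRUE`
#' for Yates' correction on 2x2 tables.
#'
#' @param classification Output of [classify_responders()].
#' @param covariates Tibble with `participant_id` and the covariate
#'   columns.
#' @param factor Name of the covariate column to test.
#' @param correct Apply Yates' continuity correction (default `FALSE`).
#' @return Tibble `factor`, `statistic`, `df`, `p_value`, `n`, plus the
#'   contingency table as attribute `table`. Degenerate tables (a level
#'   with zero margin, or a single level) yield `NA` results with a
#'   warning.
#' @export
chi_square_association <- function(classification, covariates, factor,
                                   correct = FALSE) {
  if (!factor %in% names(covariates)) {
    abort(sprintf("covariate '%s' not found", factor),
          class = "dietresponder_validation_error")
  }
  dat <- classification |>
    dplyr::filter(.data$label %in% c("RS", "NRS")) |>
    dplyr::inner_join(covariates, by = "participant_id")
  tab <- table(factor = as.character(dat[[factor]]), label = dat$label)
  bad <- nrow(tab) < 2L || ncol(tab) < 2L ||
    any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  if (bad) {
    warn(sprintf("degenerate contingency table for '%s'; returning NA",
                 factor),
         class = "dietresponder_degenerate_table")
    res <- tibble::tibble(factor = factor, statistic = NA_real_,
                          df = NA_integer_, p_value = NA_real_,
                          n = nrow(dat))
    attr(res, "table") <- tab
    return(res)
  }
  ht <- suppressWarnings(chisq.test(tab, correct = correct))
  res <- tibble::tibble(factor = factor,
                        statistic = unname(ht$statistic),
                        df = as.integer(ht$parameter),
                        p_value = unname(ht$p.value),
                        n = nrow(dat))
  attr(res, "table") <- tab
  res
}

#' All-covariate association report
#'
#' Convenience wrapper running [chi_square_association()] for each listed
#' covariate, mirroring a factor-by-response summary table.
#'
#' @inheritParams chi_square_association
#' @param factors Covariate columns to test.
#' @return Tibble with one row per factor.
#' @export
association_report <- function(classification, covariates,
                               factors = c("gender", "bmi_class",
                                           "visit_order"),
                               correct = FALSE) {
  dplyr::bind_rows(lapply(factors, function(f) {
    chi_square_association(classification, covariates, f, correct = correct)
  }))
}
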