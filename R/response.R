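# Percentage-change responses from baseline and their categorisation.

.arms <- c("blueberry", "powder", "placebo")

#' Percentage change from baseline
#'
#' The trial's response measure: `100 * (post - baseline) / baseline`.
#' A zero baseline makes the response undefined; such cells return `NA`
#' with a warning so they propagate as missing rather than infinite.
#'
#' @param baseline,post Paired measurements (vectorised).
#' @return Percent change, `NA` where baseline is zero or either value is
#'   missing.
#' @export
#' @examples
#' percent_change(100, 150)  # +50
percent_change <- function(baseline, post) {
  n <- max(length(baseline), length(post))
  baseline <- rep_len(baseline, n)
  post <- rep_len(post, n)
  zero <- !is.na(baseline) & baseline == 0
  if (any(zero)) {
    warn(sprintf("%d zero baseline(s): response undefined, set to missing",
                 sum(zero)))
  }
  out <- 100 * (post - baseline) / baseline
  out[zero] <- NA_real_
  out[!is.finite(out)] <- NA_real_
  out
}

#' Categorise a response as improved / no change / worsened
#'
#' Folds the raw percent change by the endpoint's direction of benefit:
#' a positive folded response is an improvement, a negative one a
#' worsening, and an exact zero (within `tolerance`, default 0) is no
#' change. So a rise in systolic blood pressure (direction -1) is
#' "worsened" even though the raw change is positive.
#'
#' @param response_pct Percent change from baseline.
#' @param direction Direction of benefit, +1 or -1 (recycled).
#' @param tolerance Absolute percent-change band treated as "no change";
#'   the default 0 counts only exact ties, consistent with continuous
#'   assays never showing "no change" while discrete cognitive scores do.
#' @return Character vector in `improved`, `no_change`, `worsened`,
#'   `missing`.
#' @export
categorize_response <- function(response_pct, direction, tolerance = 0) {
  if (!all(direction %in% c(-1, 1))) {
    abort("direction of benefit must be -1 or +1",
          class = "dietresponder_config_error")
  }
  n <- max(length(response_pct), length(direction))
  response_pct <- rep_len(response_pct, n)
  direction <- rep_len(direction, n)
  folded <- response_pct * direction
  dplyr::case_when(
    is.na(response_pct)          ~ "missing",
    abs(response_pct) <= tolerance ~ "no_change",
    folded > 0                   ~ "improved",
    TRUE                         ~ "worsened"
  )
}

.validate_measurements <- function(measurements, registry) {
  needed <- c("participant_id", "arm", "timepoint", "endpoint_id", "value")
  miss <- setdiff(needed, names(measurements))
  if (length(miss)) {
    abort(paste0("measurement table lacks columns: ",
                 paste(miss, collapse = ", ")),
          class = "dietresponder_validation_error")
  }
  if (!all(measurements$timepoint %in% c("baseline", "post"))) {
    abort("timepoint must be 'baseline' or 'post'",
          class = "dietresponder_validation_error")
  }
  unknown <- setdiff(unique(measurements$endpoint_id), registry$id)
  if (length(unknown)) {
    abort(paste0("endpoint ids absent from the registry: ",
                 paste(head(unknown, 10L), collapse = ", "),
                 if (length(unknown) > 10L) ", ..."),
          class = "dietresponder_validation_error")
  }
  key <- paste(measurements$participant_id, measurements$arm,
               measurements$timepoint, measurements$endpoint_id)
  if (anyDuplicated(key)) {
    abort("duplicate (participant, arm, timepoint, endpoint) measurements",
          class = "dietresponder_validation_error")
  }
  invisible(measurements)
}

#' Build the response table from raw measurements
#'
#' Pairs the baseline and post measurement of every
#' (participant, arm, endpoint) cell, computes the percent change and its
#' improved / no-change / worsened category under the registry's direction
#' of benefit. Cells lacking either timepoint, or with a zero baseline,
#' are kept with category `missing` so denominators remain explicit
#' downstream.
#'
#' @param measurements Long-format tibble with columns `participant_id`,
#'   `arm`, `timepoint` (baseline/post), `endpoint_id`, `value`.
#' @param registry Endpoint registry ([build_default_registry()]).
#' @param tolerance No-change band forwarded to [categorize_response()].
#' @return Tibble with one row per (participant, arm, endpoint) observed,
#'   columns `participant_id`, `arm`, `endpoint_id`, `response_pct`,
#'   `category`.
#' @export
build_response_table <- function(measurements, registry, tolerance = 0) {
  .validate_measurements(measurements, registry)
  wide <- measurements |>
    tidyr::pivot_wider(id_cols = c("participant_id", "arm", "endpoint_id"),
                       names_from = "timepoint", values_from = "value")
  if (!"baseline" %in% names(wide)) wide$baseline <- NA_real_
  if (!"post" %in% names(wide)) wide$post <- NA_real_
  wide <- tidyr::complete(
    wide,
    .data$participant_id, .data$arm, .data$endpoint_id)
  dirs <- setNames(registry$direction, registry$id)
  pct <- suppressWarnings(percent_change(wide$baseline, wide$post))
  n_zero <- sum(!is.na(wide$baseline) & wide$baseline == 0 &
                  !is.na(wide$post))
  if (n_zero > 0) {
    warn(sprintf("%d cell(s) with zero baseline set to missing", n_zero))
  }
  tibble::tibble(
    participant_id = wide$participant_id,
    arm = wide$arm,
    endpoint_id = wide$endpoint_id,
    response_pct = pct,
    category = categorize_response(pct, dirs[wide$endpoint_id],
                                   tolerance = tolerance)
  )
}

# Half-up rounding (round() in R rounds half to even).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Proportions of improved / no-change / worsened responses
#'
#' Per-endpoint proportions of participants in each response category for
#' one arm, over non-missing cells. Vascular endpoints are reported
#' individually; for each cognitive domain the per-test-parameter
#' proportions are averaged (unweighted), since multiple task parameters
#' assess each domain.
#'
#' @param responses Response table from [build_response_table()].
#' @param registry Endpoint registry.
#' @param arm Which arm to summarise.
#' @param rounded Round to whole percent (half-up) for display; default
#'   `FALSE` keeps full precision so rows sum to exactly 100.
#' @return Tibble with columns `label` (vascular endpoint or cognitive
#'   domain), `system`, `improved`, `no_change`, `worsened` (percent), and
#'   `n` (participants, or mean per-parameter count for domains).
#' @export
proportion_summary <- function(responses, registry, arm,
                               rounded = FALSE) {
  sub <- dplyr::filter(responses, .data$arm == !!arm,
                       .data$category != "missing")
  if (nrow(sub) == 0L) {
    warn(sprintf("no non-missing responses for arm '%s'", arm),
         class = "dietresponder_empty_summary")
    return(tibble::tibble(label = character(), system = character(),
                          improved = double(), no_change = double(),
                          worsened = double(), n = double()))
  }
  per_endpoint <- sub |>
    dplyr::count(.data$endpoint_id, .data$category) |>
    tidyr::pivot_wider(names_from = "category", values_from = "n",
                       values_fill = 0L)
  for (col in c("improved", "no_change", "worsened")) {
    if (!col %in% names(per_endpoint)) per_endpoint[[col]] <- 0L
  }
  per_endpoint <- per_endpoint |>
    dplyr::mutate(n = .data$improved + .data$no_change + .data$worsened,
                  improved = 100 * .data$improved / .data$n,
                  no_change = 100 * .data$no_change / .data$n,
                  worsened = 100 * .data$worsened / .data$n) |>
    dplyr::left_join(registry[, c("id", "system", "domain")],
                     by = c(endpoint_id = "id"))

  vas <- per_endpoint |>
    dplyr::filter(.data$system == "vascular") |>
    dplyr::transmute(label = .data$domain, system = .data$system,
                     .data$improved, .data$no_change, .data$worsened,
                     .data$n)
  cog <- per_endpoint |>
    dplyr::filter(.data$system == "cognitive") |>
    dplyr::group_by(label = .data$domain) |>
    dplyr::summarise(system = "cognitive",
                     improved = mean(.data$improved),
                     no_change = mean(.data$no_change),
                     worsened = mean(.data$worsened),
                     n = mean(.data$n), .groups = "drop")
  out <- dplyr::bind_rows(vas, cog)
  # fix display order: the 9 vascular endpoints then the 7 domains
  lab_order <- c(.vascular_catalogue()$domain, .cognitive_domains)
  out <- out[order(match(out$label, lab_order)), ]
  if (rounded) {
    out <- dplyr::mutate(out, dplyr::across(
      c("improved", "no_change", "worsened"), ~ round_half_up(.x)))
  }
  out
}

#' Range of responses for an endpoint or cognitive domain
#'
#' Minimum and maximum percent change across participants in one arm. For
#' a cognitive domain the default pools all its task parameters before
#' taking the range; `aggregate = "average"` first averages each
#' participant's parameters so the range is over per-participant domain
#' means.
#'
#' @param responses Response table.
#' @param registry Endpoint registry.
#' @param arm Arm to summarise.
#' @param target An endpoint id, a vascular endpoint label, or a cognitive
#'   domain name.
#' @param aggregate `"pool"` (default) or `"average"`, for domains only.
#' @return Named numeric `c(min, max)` in percent; `NA`s with a warning if
#'   every cell is missing.
#' @export
response_range <- function(responses, registry, arm, target,
                           aggregate = c("pool", "average")) {
  aggregate <- match.arg(aggregate)
  ids <- if (target %in% registry$id) {
    target
  } else if (target %in% registry$domain) {
    registry$id[registry$domain == target]
  } else {
    abort(sprintf("unknown endpoint or domain '%s'", target),
          class = "dietresponder_validation_error")
  }
  sub <- dplyr::filter(responses, .data$arm == !!arm,
                       .data$endpoint_id %in% ids,
                       !is.na(.data$response_pct))
  if (nrow(sub) == 0L) {
    warn(sprintf("no non-missing responses for '%s' in arm '%s'",
                 target, arm),
         class = "dietresponder_empty_range")
    return(c(min = NA_real_, max = NA_real_))
  }
  vals <- if (aggregate == "average" && length(ids) > 1L) {
    sub |>
      dplyr::group_by(.data$participant_id) |>
      dplyr::summarise(v = mean(.data$response_pct), .groups = "drop") |>
      dplyr::pull(.data$v)
  } else {
    sub$response_pct
  }
  c(min = min(vals), max = max(vals))
}

#' Waterfall ordering of individual responses
#'
#' Participants sorted by percent change, largest first (the ordering used
#' in waterfall plots of individual responses), with ties broken by
#' participant id ascending so the ordering is deterministic.
#'
#' @param responses Response table.
#' @param arm Arm.
#' @param endpoint_id Single endpoint id.
#' @return Tibble `rank`, `participant_id`, `response_pct`, `category`,
#'   non-missing cells only.
#' @export
waterfall_order <- function(responses, arm, endpoint_id) {
  sub <- dplyr::filter(responses, .data$arm == !!arm,
                       .data$endpoint_id == !!endpoint_id,
                       !is.na(.data$response_pct))
  if (nrow(sub) == 0L) {
    warn(sprintf("no non-missing responses for '%s' in arm '%s'",
                 endpoint_id, arm),
         class = "dietresponder_empty_range")
  }
  ord <- order(-sub$response_pct, sub$participant_id)
  tibble::tibble(rank = seq_along(ord),
                 participant_id = sub$participant_id[ord],
                 response_pct = sub$response_pct[ord],
                 category = sub$category[ord])
}
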