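#' @keywords internal
"_PACKAGE"

#' @importFrom rlang abort warn .data
#' @importFrom stats sd mad median quantile rnorm runif setNames chisq.test lm coef predict
#' @importFrom utils head
NULL

# The seven cognitive domains assessed by the computerised test battery,
# plus the nine vascular endpoints, form the fixed 52-endpoint catalogue.
.cognitive_domains <- c(
  "working_memory", "episodic_memory", "attention",
  "alert", "content", "calm", "mental_fatigue"
)

.vascular_catalogue <- function() {
  tibble::tibble(
    id        = c("pwv", "sbp", "dbp", "nitrite", "glucose", "tag",
                  "total_chol", "hdl_c", "ldl_c"),
    name      = c("Pulse wave velocity (carotid-radial)",
                  "Systolic blood pressure",
                  "Diastolic blood pressure",
                  "Plasma nitrite",
                  "Plasma glucose",
                  "Plasma triglycerides",
                  "Total cholesterol",
                  "HDL-cholesterol",
                  "LDL-cholesterol"),
    system    = "vascular",
    domain    = c("PWV", "SBP", "DBP", "nitrite", "glucose", "TAG",
                  "total_cholesterol", "HDL_C", "LDL_C"),
    # Direction of benefit: +1 when an increase is an improvement (nitrite,
    # HDL-C), -1 when a decrease is (stiffness, pressure, glucose, lipids).
    direction = c(-1, -1, -1, +1, -1, -1, -1, +1, -1),
    units     = c("m/s", "mmHg", "mmHg", "uM", "mmol/L", "mmol/L",
                  "mmol/L", "mmol/L", "mmol/L")
  )
}

#' Default distribution of the 43 cognitive test parameters over 7 domains
#'
#' The cognitive battery scores 43 test parameters grouped into 7 domains
#' (working memory from serial subtraction tasks; episodic memory from word
#' recall and recognition; attention from digit vigilance; alert, content
#' and calm from visual-analogue mood scales; and self-rated mental
#' fatigue). The exact per-task parameter counts are an editable assumption
#' of this package: the battery's published description fixes only the
#' total (43) and the domain structure. The default follows the usual
#' make-up of such batteries, with the mood scales contributing
#' Bond-Lader-style item groups.
#'
#' @return Named integer vector over the 7 cognitive domains, summing to 43.
#' @export
#' @examples
#' sum(default_cognitive_spec())
default_cognitive_spec <- function() {
  c(working_memory = 10L, episodic_memory = 12L, attention = 4L,
    alert = 9L, content = 5L, calm = 2L, mental_fatigue = 1L)
}

.domain_prefix <- c(
  working_memory = "wm", episodic_memory = "em", attention = "att",
  alert = "alert", content = "content", calm = "calm",
  mental_fatigue = "fatigue"
)

#' Build the default 52-endpoint registry
#'
#' Assembles the endpoint catalogue used throughout the package: 9 fixed
#' vascular endpoints and 43 cognitive test parameters distributed over the
#' 7 cognitive domains, each with a direction of benefit (+1 if a larger
#' value is an improvement, -1 if a smaller value is).
#'
#' Cognitive parameters default to +1 (accuracy-like scores and positive
#' mood ratings), except mental fatigue (-1) and any parameters designated
#' as reaction times, which get -1 and an `_rt` id suffix. Because the
#' original battery's per-parameter directions are not published, both the
#' per-domain counts and the reaction-time designation are configurable,
#' and a registry can be round-tripped through a delimited file
#' ([write_registry()] / [read_registry()]) and edited there.
#'
#' @param cognitive_spec Named integer vector giving the number of test
#'   parameters per cognitive domain; must cover all 7 domains with
#'   positive counts summing to 43. An unnamed length-7 vector is taken in
#'   the canonical domain order.
#' @param reaction_time Named integer vector: how many parameters of a
#'   domain are reaction times (direction -1). Must not exceed the domain's
#'   count.
#' @return A tibble with one row per endpoint and columns `id`, `name`,
#'   `system`, `domain`, `direction`, `units`.
#' @export
#' @examples
#' reg <- build_default_registry()
#' table(reg$system)
build_default_registry <- function(cognitive_spec = default_cognitive_spec(),
                                   reaction_time = c(episodic_memory = 2L,
                                                     attention = 2L)) {
  if (is.null(names(cognitive_spec)) && length(cognitive_spec) == 7L) {
    names(cognitive_spec) <- .cognitive_domains
  }
  missing <- setdiff(.cognitive_domains, names(cognitive_spec))
  extra <- setdiff(names(cognitive_spec), .cognitive_domains)
  if (length(missing) || length(extra)) {
    abort(paste0("cognitive_spec must name exactly the 7 cognitive domains",
                 if (length(missing)) paste0("; missing: ",
                                             paste(missing, collapse = ", ")),
                 if (length(extra)) paste0("; unknown: ",
                                           paste(extra, collapse = ", "))),
          class = "dietresponder_config_error")
  }
  counts <- as.integer(cognitive_spec[.cognitive_domains])
  if (any(counts < 1L)) {
    abort(paste0("every cognitive domain needs at least one test parameter; ",
                 "got 0 for: ",
                 paste(.cognitive_domains[counts < 1L], collapse = ", ")),
          class = "dietresponder_config_error")
  }
  if (sum(counts) != 43L) {
    abort(sprintf(
      "cognitive parameter counts sum to %d, expected 43 (difference %+d)",
      sum(counts), sum(counts) - 43L),
      class = "dietresponder_config_error")
  }
  if (length(reaction_time)) {
    bad <- setdiff(names(reaction_time), .cognitive_domains)
    if (length(bad)) {
      abort(paste0("reaction_time names unknown domains: ",
                   paste(bad, collapse = ", ")),
            class = "dietresponder_config_error")
    }
    over <- reaction_time > cognitive_spec[names(reaction_time)]
    if (any(over)) {
      abort("reaction_time counts exceed the domain's parameter count",
            class = "dietresponder_config_error")
    }
  }

  cog <- lapply(.cognitive_domains, function(dom) {
    k <- counts[match(dom, .cognitive_domains)]
    n_rt <- if (dom %in% names(reaction_time)) as.integer(reaction_time[[dom]]) else 0L
    is_rt <- seq_len(k) > (k - n_rt)  # reaction times fill the tail slots
    pre <- .domain_prefix[[dom]]
    base_dir <- if (dom == "mental_fatigue") -1 else +1
    tibble::tibble(
      id = sprintf("%s_%02d%s", pre, seq_len(k), ifelse(is_rt, "_rt", "")),
      name = sprintf("%s parameter %d%s",
                     gsub("_", " ", dom), seq_len(k),
                     ifelse(is_rt, " (reaction time)", "")),
      system = "cognitive",
      domain = dom,
      direction = ifelse(is_rt, -1, base_dir),
      units = dplyr::case_when(
        is_rt ~ "ms",
        dom %in% c("alert", "content", "calm", "mental_fatigue") ~ "mm VAS",
        TRUE ~ "score"
      )
    )
  })
  reg <- dplyr::bind_rows(.vascular_catalogue(), cog)
  validate_registry(reg)
  reg
}

#' Validate an endpoint registry
#'
#' Checks the structural invariants of a registry table: required columns,
#' unique ids, systems restricted to vascular/cognitive, directions in
#' \{-1, +1\}, cognitive domains among the 7 known ones, and the 9 + 43 = 52
#' cardinality of the default catalogue.
#'
#' @param registry A registry tibble as from [build_default_registry()] or
#'   [read_registry()].
#' @param strict If `TRUE` (default) enforce the 52-endpoint cardinality;
#'   set `FALSE` to validate reduced registries (e.g. vascular-only
#'   analyses).
#' @return The registry, invisibly; errors describe any violation.
#' @export
validate_registry <- function(registry, strict = TRUE) {
  needed <- c("id", "name", "system", "domain", "direction", "units")
  miss <- setdiff(needed, names(registry))
  if (length(miss)) {
    abort(paste0("registry lacks columns: ", paste(miss, collapse = ", ")),
          class = "dietresponder_config_error")
  }
  if (anyDuplicated(registry$id)) {
    abort("registry endpoint ids are not unique",
          class = "dietresponder_config_error")
  }
  if (!all(registry$system %in% c("vascular", "cognitive"))) {
    abort("registry system must be 'vascular' or 'cognitive'",
          class = "dietresponder_config_error")
  }
  if (!all(registry$direction %in% c(-1, 1))) {
    abort("direction of benefit must be -1 or +1, never 0",
          class = "dietresponder_config_error")
  }
  cog <- registry$domain[registry$system == "cognitive"]
  if (!all(cog %in% .cognitive_domains)) {
    abort("cognitive endpoints must map to one of the 7 known domains",
          class = "dietresponder_config_error")
  }
  if (strict) {
    n_vas <- sum(registry$system == "vascular")
    n_cog <- sum(registry$system == "cognitive")
    if (n_vas != 9L || n_cog != 43L) {
      abort(sprintf(
        "expected 9 vascular + 43 cognitive endpoints, found %d + %d",
        n_vas, n_cog), class = "dietresponder_config_error")
    }
  }
  invisible(registry)
}

#' Read / write a registry as delimited text
#'
#' The registry serialises to a tab-separated file with columns
#' `id, name, system, domain, direction, units`; the round-trip is
#' lossless, so a default registry can be exported, edited (e.g. to flip a
#' direction of benefit) and re-imported.
#'
#' @param registry Registry tibble.
#' @param path File path.
#' @param strict Passed to [validate_registry()] on read.
#' @return `write_registry()` returns the path invisibly; `read_registry()`
#'   returns a validated registry tibble.
#' @export
write_registry <- function(registry, path) {
  validate_registry(registry, strict = FALSE)
  readr::write_tsv(registry, path)
  invisible(path)
}

#' @rdname write_registry
#' @export
read_registry <- function(path, strict = TRUE) {
  reg <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           id = "c", name = "c", system = "c",
                           domain = "c", direction = "d", units = "c"))
  validate_registry(reg, strict = strict)
  reg
}
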