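# Small fixtures built in code.

default_registry <- build_default_registry()

# A response table written out by hand: `cats` is a named list
# participant -> category, translated into percent responses under
# direction +1.
manual_responses <- function(endpoint_id, arm, pct, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("S%02d", seq_along(pct))
  tibble::tibble(participant_id = ids, arm = arm,
                 endpoint_id = endpoint_id, response_pct = pct,
                 category = ifelse(is.na(pct), "missing",
                                   ifelse(pct > 0, "improved",
                                          ifelse(pct < 0, "worsened",
                                                 "no_change"))))
}

# feature_table from a study matrix plus optional qc / blank rows
make_ft <- function(study, labels, qc = NULL, blank = NULL) {
  mat <- rbind(study, qc, blank)
  roles <- c(rep("study", nrow(study)),
             rep("qc", if (is.null(qc)) 0 else nrow(qc)),
             rep("blank", if (is.null(blank)) 0 else nrow(blank)))
  cls <- c(labels, rep(NA_character_, nrow(mat) - nrow(study)))
  rownames(mat) <- sprintf("smp%02d", seq_len(nrow(mat)))
  feature_table(mat, roles, cls)
}
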