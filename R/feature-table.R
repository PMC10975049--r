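# LC-MS feature tables: container, QC-RSD and MAD/median filtering, log
# transformation and autoscaling.

#' Construct an LC-MS feature table
#'
#' Container for an aligned peak table: a samples-by-features intensity
#' matrix plus a role per sample (study / pooled QC / blank) and, for
#' study samples, an optional RS/NRS class label. Feature ids follow the
#' `mz@rt` convention (e.g. `170.069@2.1`).
#'
#' @param intensities Numeric matrix, samples in rows (rownames = sample
#'   ids), features in columns (colnames = feature ids); all values >= 0.
#' @param sample_roles Character vector per sample, each `"study"`,
#'   `"qc"` or `"blank"`.
#' @param class_labels Optional character vector per sample, `"RS"` /
#'   `"NRS"` for study samples and `NA` elsewhere.
#' @param polarity Acquisition polarity tag, `"positive"` (default) or
#'   `"negative"`; metadata only.
#' @return Object of class `feature_table`.
#' @export
feature_table <- function(intensities, sample_roles, class_labels = NULL,
                          polarity = "positive") {
  if (!is.matrix(intensities) || !is.numeric(intensities)) {
    abort("intensities must be a numeric matrix (samples x features)",
          class = "dietresponder_validation_error")
  }
  if (is.null(rownames(intensities))) {
    rownames(intensities) <- sprintf("sample_%02d", seq_len(nrow(intensities)))
  }
  if (is.null(colnames(intensities))) {
    colnames(intensities) <- sprintf("F%04d", seq_len(ncol(intensities)))
  }
  if (length(sample_roles) != nrow(intensities)) {
    abort("one sample role per intensity row is required",
          class = "dietresponder_validation_error")
  }
  if (!all(sample_roles %in% c("study", "qc", "blank"))) {
    abort("sample roles must be 'study', 'qc' or 'blank'",
          class = "dietresponder_validation_error")
  }
  if (any(intensities < 0, na.rm = TRUE)) {
    abort("intensities must be non-negative",
          class = "dietresponder_validation_error")
  }
  if (is.null(class_labels)) {
    class_labels <- rep(NA_character_, nrow(intensities))
  }
  if (length(class_labels) != nrow(intensities)) {
    abort("one class label (or NA) per sample is required",
          class = "dietresponder_validation_error")
  }
  if (!all(is.na(class_labels) | class_labels %in% c("RS", "NRS"))) {
    abort("class labels must be 'RS', 'NRS' or NA",
          class = "dietresponder_validation_error")
  }
  all_zero <- colSums(intensities != 0) == 0
  structure(
    list(intensities = intensities,
         sample_roles = sample_roles,
         class_labels = class_labels,
         polarity = polarity,
         all_zero_features = colnames(intensities)[all_zero]),
    class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("LC-MS feature table (%s mode): %d samples x %d features\n",
              x$polarity, nrow(x$intensities), ncol(x$intensities)))
  cat(sprintf("  roles: %s\n",
              paste(sprintf("%s=%d", names(table(x$sample_roles)),
                            table(x$sample_roles)), collapse = ", ")))
  lab <- table(x$class_labels, useNA = "no")
  if (length(lab)) {
    cat(sprintf("  classes: %s\n",
                paste(sprintf("%s=%d", names(lab), lab), collapse = ", ")))
  }
  invisible(x)
}

.study_matrix <- function(ft) {
  ft$intensities[ft$sample_roles == "study", , drop = FALSE]
}

.keep_features <- function(ft, keep, removed, reason) {
  log <- tibble::tibble(feature = colnames(ft$intensities)[!keep],
                       reason = reason)
  prev <- attr(ft, "removal_log")
  ft$intensities <- ft$intensities[, keep, drop = FALSE]
  attr(ft, "removal_log") <- dplyr::bind_rows(prev, log)
  ft
}

#' Filter features by pooled-QC relative standard deviation
#'
#' Screens out unstable or irreproducible features: for each feature the
#' RSD (100 * SD / mean, sample SD with n-1 denominator) across the pooled
#' QC injections is computed and features above the threshold, or with a
#' zero QC mean, are removed. A 30% threshold is the conventional cut for
#' untargeted LC-MS data.
#'
#' @param ft A [feature_table()] with at least 2 QC samples.
#' @param threshold_pct Maximum acceptable QC RSD in percent (default 30).
#' @return Filtered `feature_table`; the cumulative removal log is kept in
#'   attribute `removal_log` and per-feature QC RSDs in attribute
#'   `qc_rsd`.
#' @export
qc_rsd_filter <- function(ft, threshold_pct = 30) {
  stopifnot(inherits(ft, "feature_table"))
  qc <- ft$intensities[ft$sample_roles == "qc", , drop = FALSE]
  if (nrow(qc) < 2L) {
    abort("QC-RSD filtering needs at least 2 pooled QC samples",
          class = "dietresponder_validation_error")
  }
  m <- colMeans(qc)
  s <- apply(qc, 2, sd)
  rsd <- ifelse(m > 0, 100 * s / m, Inf)
  keep <- rsd <= threshold_pct
  out <- .keep_features(ft, keep, !keep,
                        sprintf("QC RSD %.1f%% > %g%%",
                                rsd[!keep], threshold_pct))
  attr(out, "qc_rsd") <- rsd[keep]
  out
}

# MetaboAnalyst-style size-dependent fraction of features dropped by the
# variability filter.
.auto_drop_fraction <- function(n_features) {
  if (n_features < 250) 0.05
  else if (n_features < 500) 0.10
  else if (n_features < 1000) 0.25
  else 0.40
}

#' Nonparametric variability (MAD/median) filter
#'
#' Removes near-constant, baseline-noise features from large untargeted
#' tables. Each feature gets a nonparametric relative-variability score:
#' the median absolute deviation (unscaled, no 1.4826 consistency
#' constant) divided by the median, over study samples. The least variable
#' features are dropped.
#'
#' @param ft A [feature_table()] with at least 2 study samples.
#' @param keep_rule `"auto"` (default) drops a size-dependent fraction of
#'   the lowest-scoring features (5% below 250 features, 10% below 500,
#'   25% below 1000, 40% above); `"none"` keeps everything; a number in
#'   (0, 1) drops that fraction; `list(threshold = x)` drops features with
#'   score <= x (an absolute rule, hence idempotent).
#' @return Filtered `feature_table` with scores of the kept features in
#'   attribute `mad_score`.
#' @export
mad_filter <- function(ft, keep_rule = "auto") {
  stopifnot(inherits(ft, "feature_table"))
  study <- .study_matrix(ft)
  if (nrow(study) < 2L) {
    abort("MAD filtering needs at least 2 study samples",
          class = "dietresponder_validation_error")
  }
  med <- apply(study, 2, median)
  madv <- apply(study, 2, mad, constant = 1)
  score <- ifelse(med != 0, madv / abs(med), NA_real_)
  n_zero_med <- sum(med == 0)
  if (n_zero_med > 0) {
    message(sprintf(
      "%d feature(s) with zero median ranked least variable", n_zero_med))
    score[med == 0] <- -Inf
  }
  nf <- ncol(study)
  if (identical(keep_rule, "none")) {
    keep <- rep(TRUE, nf)
  } else if (is.list(keep_rule) && !is.null(keep_rule$threshold)) {
    keep <- score > keep_rule$threshold
  } else {
    frac <- if (identical(keep_rule, "auto")) {
      .auto_drop_fraction(nf)
    } else if (is.numeric(keep_rule) && keep_rule > 0 && keep_rule < 1) {
      keep_rule
    } else {
      abort("keep_rule must be 'auto', 'none', a fraction or list(threshold=)",
            class = "dietresponder_config_error")
    }
    n_drop <- floor(nf * frac)
    keep <- rep(TRUE, nf)
    if (n_drop > 0) {
      # drop the n_drop lowest scores; ties resolved by column order
      keep[order(score, seq_len(nf))[seq_len(n_drop)]] <- FALSE
    }
  }
  out <- .keep_features(ft, keep, !keep,
                        sprintf("MAD/median score %.4g (low variability)",
                                score[!keep]))
  attr(out, "mad_score") <- score[keep]
  out
}

#' Log-transform intensities
#'
#' Base-10 logarithm after adding a pseudo-value to accommodate zeros,
#' removing heteroscedasticity and correcting the right-skew typical of
#' intensity data. The default pseudo-value is half the smallest positive
#' intensity in the table.
#'
#' @param ft A [feature_table()].
#' @param pseudo Offset added before taking logs; `NULL` (default) uses
#'   half the minimum positive intensity, `0` takes exact logs (only
#'   valid for strictly positive tables).
#' @return `feature_table` on the log10 scale, with the offset recorded in
#'   attribute `pseudo`.
#' @export
log_transform <- function(ft, pseudo = NULL) {
  stopifnot(inherits(ft, "feature_table"))
  x <- ft$intensities
  if (is.null(pseudo)) {
    pos <- x[x > 0]
    if (length(pos) == 0L) {
      abort("all intensities are zero; nothing to transform",
            class = "dietresponder_validation_error")
    }
    pseudo <- min(pos) / 2
  }
  if (pseudo == 0 && any(x == 0)) {
    abort("pseudo = 0 requires strictly positive intensities",
          class = "dietresponder_validation_error")
  }
  ft$intensities <- log10(x + pseudo)
  attr(ft, "pseudo") <- pseudo
  attr(ft, "log_transformed") <- TRUE
  ft
}

#' Autoscale features
#'
#' Per-feature standardisation (subtract the mean, divide by the sample
#' SD, n-1 denominator) computed over the study samples and applied to
#' every sample, so each feature contributes on the same footing
#' regardless of its average intensity. Features with zero SD across the
#' study samples carry no information and are dropped with a warning.
#'
#' @param ft A [feature_table()] with >= 2 study samples.
#' @return Scaled `feature_table`.
#' @export
autoscale <- function(ft) {
  stopifnot(inherits(ft, "feature_table"))
  study <- .study_matrix(ft)
  if (nrow(study) < 2L) {
    abort("autoscaling needs at least 2 study samples",
          class = "dietresponder_validation_error")
  }
  m <- colMeans(study)
  s <- apply(study, 2, sd)
  drop <- s == 0
  if (any(drop)) {
    warn(sprintf("dropping %d constant feature(s) with zero SD", sum(drop)))
  }
  ft <- .keep_features(ft, !drop, drop, "zero SD across study samples")
  m <- m[!drop]
  s <- s[!drop]
  ft$intensities <- sweep(sweep(ft$intensities, 2, m, "-"), 2, s, "/")
  attr(ft, "autoscaled") <- TRUE
  ft
}

#' Read / write a feature table as delimited text
#'
#' The intensity file holds one feature per row: first column
#' `feature_id`, then one column per sample. The companion sample sheet
#' has columns `sample_id`, `role`, `class` (class may be blank for QCs
#' and blanks). The round-trip through these two files is lossless.
#'
#' @param ft A [feature_table()].
#' @param features_path,samples_path Paths for the intensity matrix and
#'   the sample sheet.
#' @param polarity Polarity tag applied on read.
#' @return `write_feature_table()` returns the paths invisibly;
#'   `read_feature_table()` returns a `feature_table`.
#' @export
write_feature_table <- function(ft, features_path, samples_path) {
  stopifnot(inherits(ft, "feature_table"))
  wide <- tibble::as_tibble(t(ft$intensities), rownames = "feature_id")
  readr::write_tsv(wide, features_path)
  sheet <- tibble::tibble(sample_id = rownames(ft$intensities),
                          role = ft$sample_roles,
                          class = ft$class_labels)
  readr::write_tsv(sheet, samples_path)
  invisible(c(features_path, samples_path))
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(features_path, samples_path,
                               polarity = "positive") {
  wide <- readr::read_tsv(features_path, show_col_types = FALSE)
  sheet <- readr::read_tsv(samples_path, show_col_types = FALSE,
                           col_types = readr::cols(.default = "c"))
  ids <- wide$feature_id
  mat <- t(as.matrix(wide[, -1, drop = FALSE]))
  colnames(mat) <- ids
  ord <- match(rownames(mat), sheet$sample_id)
  if (anyNA(ord)) {
    abort("sample sheet does not cover every sample column",
          class = "dietresponder_validation_error")
  }
  cls <- sheet$class[ord]
  cls[cls %in% c("", "NA")] <- NA_character_
  feature_table(mat, sample_roles = sheet$role[ord], class_labels = cls,
                polarity = polarity)
}
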