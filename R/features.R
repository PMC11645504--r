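#' Expand the biomarker catalog into the 183 feature-column names
#'
#' Every biomarker is subdivided by task and target eccentricity while the
#' target side and trial order are averaged out, so a metric applicable to
#' `k` tasks contributes `3 k` columns named `<Task><Ecc>_<Metric>` (e.g.
#' `P7_N_Fix`, `A15_T_Search`, `D20_B_Intrusive_Sac`). Column order is fixed:
#' tasks P, A, D; within task, eccentricities 7, 15, 20; within each
#' task-eccentricity cell, metrics in catalog order. For the full catalog
#' this yields exactly 183 columns.
#'
#' @param catalog a biomarker catalog, see [biomarker_catalog()].
#' @return Character vector of column names, with a `schema` attribute (data
#'   frame mapping column to task, eccentricity, metric).
#' @examples
#' length(expand_variable_names())  # 183
#' @export
expand_variable_names <- function(catalog = biomarker_catalog()) {
  if (!all(c("metric", "tasks") %in% names(catalog))) {
    stop("catalog must have metric and tasks columns")
  }
  if (!all(strsplit(paste(catalog$tasks, collapse = ""), "")[[1]] %in%
           c("P", "A", "D"))) {
    stop("unknown task letter in catalog")
  }
  schema <- do.call(rbind, lapply(c("P", "A", "D"), function(tk) {
    mets <- catalog$metric[grepl(tk, catalog$tasks, fixed = TRUE)]
    do.call(rbind, lapply(c(7, 15, 20), function(ecc) {
      data.frame(column = paste0(tk, ecc, "_", mets),
                 task = tk, eccentricity = ecc, metric = mets,
                 stringsAsFactors = FALSE)
    }))
  }))
  structure(schema$column, schema = schema)
}

#' Aggregate per-trial biomarkers into the participant feature table
#'
#' For each participant and each (task, eccentricity) cell, the up-to-4
#' trials (2 sides x 2 orders) are averaged into one value per metric;
#' Boolean biomarkers, stored as 0/1, thereby become incidence proportions.
#' Missing trial values (e.g. `L_TA_Fix` of uncompleted trials) reduce the
#' denominator; an all-missing cell yields `NA`. Participant attributes and
#' the group label (ADHD = 1, TD = 0) are joined from `participants`.
#'
#' @param trial_biomarkers data frame from [extract_biomarkers()].
#' @param participants optional data frame with `participant_id`, `group`
#'   (`"ADHD"`/`"TD"`), `sex`, `age`, `age_group`.
#' @return A `feature_table` data frame: `participant_id`, label and
#'   attributes, then the 183 feature columns.
#' @export
aggregate_participants <- function(trial_biomarkers, participants = NULL) {
  df <- trial_biomarkers
  if (!nrow(df)) stop("no trials to aggregate")
  cols <- expand_variable_names()
  schema <- attr(cols, "schema")
  pid <- sort(unique(df$participant_id))
  cell <- paste0(vapply(df$task, task_letter, ""), df$eccentricity_deg)
  pid_f <- factor(df$participant_id, levels = pid)
  out <- matrix(NA_real_, nrow = length(pid), ncol = length(cols),
                dimnames = list(pid, cols))
  for (i in seq_len(nrow(schema))) {
    cn <- schema$column[i]
    tgt <- paste0(schema$task[i], schema$eccentricity[i])
    sel <- cell == tgt
    if (!any(sel)) next
    v <- tapply(df[[schema$metric[i]]][sel], pid_f[sel],
                function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE))
    out[names(v), cn] <- unlist(v)
  }
  ft <- data.frame(participant_id = pid, stringsAsFactors = FALSE)
  if (!is.null(participants)) {
    j <- match(pid, participants$participant_id)
    ft$label <- as.integer(participants$group[j] == "ADHD")
    ft$group <- participants$group[j]
    for (a in intersect(c("sex", "age", "age_group"), names(participants))) {
      ft[[a]] <- participants[[a]][j]
    }
  }
  ft <- cbind(ft, as.data.frame(out, stringsAsFactors = FALSE))
  rownames(ft) <- NULL
  class(ft) <- c("feature_table", "data.frame")
  attr(ft, "feature_columns") <- cols
  ft
}

#' Feature matrix of a feature table
#'
#' @param ft a `feature_table`.
#' @return Numeric matrix of the 183 feature columns.
#' @export
feature_matrix <- function(ft) {
  cols <- attr(ft, "feature_columns")
  if (is.null(cols)) cols <- intersect(expand_variable_names(), names(ft))
  as.matrix(ft[, cols, drop = FALSE])
}

#' Median imputation of missing feature values
#'
#' Column medians are learned on the training rows only and applied to both
#' sets, so imputation never leaks information from held-out samples.
#'
#' @param train,test numeric feature matrices.
#' @return List with imputed `train` and `test` matrices.
#' @export
impute_median <- function(train, test = NULL) {
  med <- unname(apply(train, 2, stats::median, na.rm = TRUE))
  med[is.na(med)] <- 0
  fill <- function(m) {
    for (j in seq_len(ncol(m))) {
      na <- is.na(m[, j])
      if (any(na)) m[na, j] <- med[j]
    }
    m
  }
  list(train = fill(train), test = if (!is.null(test)) fill(test))
}

#' Write / read a feature table with its schema sidecar
#'
#' The table is written as CSV; a sidecar `<path>.schema.csv` records each
#' feature column's provenance (metric, task, eccentricity).
#'
#' @param ft a `feature_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(ft, path) {
  utils::write.csv(ft, path, row.names = FALSE, na = "")
  schema <- attr(expand_variable_names(), "schema")
  utils::write.csv(schema, paste0(path, ".schema.csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  ft <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(participant_id = "character"))
  class(ft) <- c("feature_table", "data.frame")
  attr(ft, "feature_columns") <- intersect(expand_variable_names(), names(ft))
  ft
}
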