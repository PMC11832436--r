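#' Per-gene control reference values
#'
#' Computes the per-gene central value of the healthy-control samples, against
#' which every patient's fold change is measured. Genes whose reference is zero
#' (typically all-zero control rows) cannot yield a fold change and are
#' excluded, with their identifiers reported.
#'
#' @param matrix Expression matrix (genes x samples, linear scale) as returned
#'   by [read_expression()] or [generate_cohort()].
#' @param meta Sample metadata with columns `sample_id` and `group`
#'   (`"control"`/`"patient"`).
#' @param method Central value: arithmetic mean on the linear scale (default)
#'   or geometric mean of the positive values.
#' @return An object of class `control_reference`: a list with `values` (named
#'   numeric vector, excluded genes absent), `n_controls`, `excluded`
#'   (character vector of genes with zero reference) and `method`.
#' @export
control_reference <- function(matrix, meta, method = c("mean", "geomean")) {
  method <- match.arg(method)
  validate_expression(matrix)
  controls <- meta$sample_id[meta$group == "control"]
  controls <- intersect(colnames(matrix), controls)
  if (length(controls) == 0L)
    stop("no control samples in metadata/matrix intersection")
  if (length(controls) < 2L)
    stop("need at least 2 control samples, got ", length(controls))
  sub <- matrix[, controls, drop = FALSE]
  ref <- switch(method,
    mean = rowMeans(sub),
    geomean = apply(sub, 1L, function(v) exp(mean(log(v[v > 0]))))
  )
  ref[!is.finite(ref)] <- 0
  excluded <- names(ref)[ref <= 0]
  if (length(excluded) > 0L)
    message("control_reference: excluding ", length(excluded),
            " gene(s) with zero reference: ",
            paste(utils::head(excluded, 5L), collapse = ", "))
  structure(
    list(values = ref[ref > 0], n_controls = length(controls),
         excluded = excluded, method = method),
    class = "control_reference"
  )
}

#' Signed fold change
#'
#' Converts a patient/reference expression ratio r to the signed fold-change
#' convention used throughout the pipeline: +r when r >= 1 and -1/r when
#' r < 1, so every value has magnitude >= 1 and "-1.5" means 1.5-fold down.
#' A patient value of exactly zero has no finite ratio; it is reported as
#' `-cap` (a configurable floor standing in for "below detection") and a
#' message is emitted.
#'
#' @param patient_value Non-negative patient expression value(s).
#' @param reference_value Positive control reference value(s); recycled.
#' @param cap Magnitude assigned to zero patient values (default 64).
#' @return Numeric vector of signed fold changes, |value| >= 1.
#' @export
signed_fc <- function(patient_value, reference_value, cap = 64) {
  if (any(reference_value <= 0)) stop("reference_value must be > 0")
  if (any(patient_value < 0)) stop("patient_value must be >= 0")
  r <- patient_value / reference_value
  out <- ifelse(r >= 1, r, -1 / r)
  zero <- patient_value == 0
  if (any(zero)) {
    message("signed_fc: ", sum(zero), " zero patient value(s) capped at -", cap)
    out[zero] <- -cap
  }
  out
}

#' Classify index-gene status from a signed fold change
#'
#' Patients at or beyond +threshold are labelled `up`, at or beyond -threshold
#' `down`, and everything strictly inside `unchanged`. The boundary is
#' inclusive: a fold change of exactly +1.5 counts as increased, matching the
#' convention that the up-range starts at 1.5-fold.
#'
#' @param fc Signed fold change(s) from [signed_fc()].
#' @param threshold Fold-change threshold > 1 (default 1.5).
#' @return Factor with levels `up`, `down`, `unchanged`.
#' @export
classify_index_status <- function(fc, threshold = 1.5) {
  if (threshold <= 1) stop("threshold must be > 1")
  lab <- ifelse(fc >= threshold, "up", ifelse(fc <= -threshold, "down", "unchanged"))
  factor(lab, levels = c("up", "down", "unchanged"))
}

#' Stratify patients by index-gene expression status
#'
#' Computes each patient's signed fold change for the index gene against the
#' pooled control reference and partitions the patient set into up / down /
#' unchanged strata at the fold-change threshold.
#'
#' @inheritParams control_reference
#' @param index_gene Identifier of the stratifying gene (e.g. `"FGF21"`).
#' @param threshold Fold-change threshold (default 1.5).
#' @param reference Optional precomputed [control_reference()]; computed from
#'   `meta` if `NULL`.
#' @return A list of class `stratification` with `status` (data.frame:
#'   `sample_id`, `fc`, `status`), `counts` (named vector n_up, n_down,
#'   n_unchanged), `index_gene` and `threshold`.
#' @export
stratify <- function(matrix, meta, index_gene, threshold = 1.5,
                     reference = NULL) {
  if (is.null(reference)) reference <- control_reference(matrix, meta)
  if (!index_gene %in% names(reference$values))
    stop("index gene '", index_gene, "' not present (or excluded) in matrix")
  patients <- intersect(colnames(matrix), meta$sample_id[meta$group == "patient"])
  if (length(patients) == 0L) stop("no patient samples")
  fc <- signed_fc(matrix[index_gene, patients], reference$values[[index_gene]])
  status <- classify_index_status(fc, threshold)
  counts <- c(n_up = sum(status == "up"), n_down = sum(status == "down"),
              n_unchanged = sum(status == "unchanged"))
  structure(
    list(status = data.frame(sample_id = patients, fc = as.numeric(fc),
                             status = status, row.names = NULL),
         counts = counts, index_gene = index_gene, threshold = threshold),
    class = "stratification"
  )
}

#' @export
print.stratification <- function(x, ...) {
  cat("Index-gene stratification (", x$index_gene, ", |FC| >= ",
      x$threshold, ")\n", sep = "")
  n <- sum(x$counts)
  for (i in seq_along(x$counts))
    cat(sprintf("  %-12s %4d (%.1f%%)\n", names(x$counts)[i], x$counts[i],
                100 * x$counts[i] / n))
  invisible(x)
}

#' Per-gene, per-patient direction calls
#'
#' For every gene with a valid control reference and every patient, records
#' +1 if the patient's signed fold change reaches +threshold, -1 if it reaches
#' -threshold, and 0 otherwise. This is the per-patient call matrix that the
#' regulator recurrence filter counts over.
#'
#' @inheritParams stratify
#' @param reference A [control_reference()] object.
#' @return Integer matrix (genes x patients) of calls in {-1, 0, +1}; genes
#'   excluded from the reference are absent.
#' @export
direction_calls <- function(matrix, meta, reference, threshold = 1.5) {
  patients <- intersect(colnames(matrix), meta$sample_id[meta$group == "patient"])
  genes <- names(reference$values)
  sub <- matrix[genes, patients, drop = FALSE]
  ratio <- sub / reference$values          # recycles by row
  up <- ratio >= threshold
  down <- ratio <= 1 / threshold
  calls <- matrix(0L, nrow(sub), ncol(sub), dimnames = dimnames(sub))
  calls[up] <- 1L
  calls[down] <- -1L
  calls
}
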