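# Contrasts (case vs reference expression differences), threshold
# calibration by a pooled quantile, and ternary up/down/unchanged labels.

#' Build a contrast-definition table
#'
#' Each contrast compares one group of case samples against one group of
#' reference samples from the same dataset. The `perturbed` flag marks case
#' conditions that are experimental perturbations (stress, knockout, double
#' knockout, overexpression) as opposed to a second baseline.
#'
#' @param contrast character vector of contrast ids (unique).
#' @param dataset dataset id per contrast.
#' @param reference,case lists of character vectors of sample ids (or
#'   `;`-separated strings); disjoint and non-empty per contrast.
#' @param perturbed logical vector.
#' @return data.frame of class `contrast_definitions` with list-columns
#'   `reference` and `case`.
#' @export
contrast_definitions <- function(contrast, dataset, reference, case,
                                 perturbed) {
  split_ids <- function(x) {
    if (is.character(x)) x <- strsplit(x, ";", fixed = TRUE)
    lapply(x, function(v) as.character(v[nzchar(v)]))
  }
  reference <- split_ids(reference)
  case <- split_ids(case)
  n <- length(contrast)
  if (length(dataset) == 1L) dataset <- rep(dataset, n)
  if (length(perturbed) == 1L) perturbed <- rep(perturbed, n)
  if (length(reference) == 1L) reference <- rep(reference, n)
  stopifnot(n == length(dataset), n == length(reference),
            n == length(case), n == length(perturbed))
  if (anyDuplicated(contrast)) stop("duplicate contrast ids")
  for (i in seq_along(contrast)) {
    if (length(reference[[i]]) == 0L || length(case[[i]]) == 0L) {
      stop("contrast ", contrast[i], " has an empty reference or case group")
    }
    if (length(intersect(reference[[i]], case[[i]])) > 0L) {
      stop("contrast ", contrast[i],
           " has overlapping reference and case samples")
    }
  }
  out <- data.frame(contrast = as.character(contrast),
                    dataset = as.character(dataset),
                    perturbed = as.logical(perturbed),
                    stringsAsFactors = FALSE)
  out$reference <- reference
  out$case <- case
  class(out) <- c("contrast_definitions", "data.frame")
  out
}

#' Read contrast definitions from a TSV file
#'
#' Columns: `contrast`, `dataset`, `reference_samples` (`;`-separated),
#' `case_samples` (`;`-separated), `perturbed` (0/1).
#'
#' @param path file path.
#' @return A [contrast_definitions()] table.
#' @export
read_contrasts <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  contrast_definitions(df$contrast, df$dataset, df$reference_samples,
                       df$case_samples, df$perturbed %in% c("1", "TRUE"))
}

#' Write contrast definitions to TSV
#'
#' @param defs a [contrast_definitions()] table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_contrasts <- function(defs, path) {
  df <- data.frame(
    contrast = defs$contrast, dataset = defs$dataset,
    reference_samples = vapply(defs$reference, paste, "", collapse = ";"),
    case_samples = vapply(defs$case, paste, "", collapse = ";"),
    perturbed = as.integer(defs$perturbed))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Compute expression contrasts
#'
#' For every gene and contrast, the contrast value is the difference of group
#' means. The default sign convention is `case - reference`, so a positive
#' value reads "upregulated in the case condition"; all downstream
#' inconsistency counts are invariant to a global sign flip, and the
#' convention can be reversed with `direction`.
#'
#' @param comp a normalized [expression_compendium()].
#' @param defs a [contrast_definitions()] table; all sample ids must exist in
#'   the compendium and reference/case groups must come from the contrast's
#'   dataset.
#' @param direction `"case_minus_ref"` (default) or `"ref_minus_case"`.
#' @return An object of class `contrast_matrix`: list with `deltas` (gene x
#'   contrast numeric matrix) and `definitions`.
#' @export
compute_contrasts <- function(comp, defs,
                              direction = c("case_minus_ref",
                                            "ref_minus_case")) {
  stopifnot(inherits(comp, "expression_compendium"),
            inherits(defs, "contrast_definitions"))
  direction <- match.arg(direction)
  samp_ds <- stats::setNames(comp$sample_meta$dataset,
                             comp$sample_meta$sample)
  deltas <- matrix(NA_real_, nrow(comp$values), nrow(defs),
                   dimnames = list(rownames(comp$values), defs$contrast))
  for (i in seq_len(nrow(defs))) {
    ref <- defs$reference[[i]]
    cas <- defs$case[[i]]
    missing_s <- setdiff(c(ref, cas), colnames(comp$values))
    if (length(missing_s) > 0L) {
      stop("contrast ", defs$contrast[i], " references unknown sample(s): ",
           paste(missing_s, collapse = ", "))
    }
    if (!all(samp_ds[c(ref, cas)] == defs$dataset[i])) {
      stop("contrast ", defs$contrast[i],
           " uses samples outside dataset ", defs$dataset[i])
    }
    d <- rowMeans(comp$values[, cas, drop = FALSE]) -
      rowMeans(comp$values[, ref, drop = FALSE])
    deltas[, i] <- if (direction == "case_minus_ref") d else -d
  }
  if (any(!is.finite(deltas))) stop("non-finite contrast values")
  structure(list(deltas = deltas, definitions = defs),
            class = "contrast_matrix")
}

#' @export
print.contrast_matrix <- function(x, ...) {
  cat(sprintf("contrast_matrix: %d genes x %d contrasts (%d perturbed)\n",
              nrow(x$deltas), ncol(x$deltas), sum(x$definitions$perturbed)))
  invisible(x)
}

#' Calibrate the labelling threshold from a target deregulated fraction
#'
#' Chooses the threshold t so that approximately a fraction `f` of all
#' gene x contrast values satisfy |delta| > t: t is the (1 - f) quantile
#' (linear interpolation) of the pooled |delta| multiset. The realized
#' fraction is reported; for continuous values it matches `f` up to the
#' discreteness of the multiset.
#'
#' @param cm a `contrast_matrix` (or a numeric matrix/vector of deltas).
#' @param f target fraction of up- or downregulated calls, in (0, 1).
#'   Typical choices: 0.5 (default), 1/3, 2/3.
#' @return List of class `threshold_calibration`: `t`, `target_fraction`,
#'   `achieved_fraction`.
#' @export
calibrate_threshold <- function(cm, f = 0.5) {
  if (!is.numeric(f) || length(f) != 1L || f <= 0 || f >= 1) {
    stop("target fraction f must lie strictly between 0 and 1")
  }
  d <- if (inherits(cm, "contrast_matrix")) cm$deltas else cm
  d <- abs(as.numeric(d))
  if (length(d) == 0L) stop("empty contrast matrix")
  t <- stats::quantile(d, probs = 1 - f, type = 7, names = FALSE)
  structure(list(t = t, target_fraction = f,
                 achieved_fraction = mean(d > t)),
            class = "threshold_calibration")
}

#' @export
print.threshold_calibration <- function(x, ...) {
  cat(sprintf(
    "threshold_calibration: t = %.4g (target fraction %.3f, achieved %.3f)\n",
    x$t, x$target_fraction, x$achieved_fraction))
  invisible(x)
}

#' Discretize contrasts into up/down/unchanged labels
#'
#' Entrywise rule: label = sign(delta) if |delta| > t, else 0. The inequality
#' is strict, so a value exactly at the threshold is "unchanged"
#' (conservative boundary convention). Raising t can only turn nonzero labels
#' into zeros.
#'
#' @param cm a `contrast_matrix` (or numeric matrix of deltas).
#' @param t non-negative threshold, typically from [calibrate_threshold()]
#'   (a `threshold_calibration` is accepted directly).
#' @return Integer gene x contrast matrix with entries in \{-1, 0, +1\}.
#' @export
label_genes <- function(cm, t) {
  if (inherits(t, "threshold_calibration")) t <- t$t
  if (!is.numeric(t) || length(t) != 1L || t < 0) {
    stop("threshold t must be a single non-negative number")
  }
  d <- if (inherits(cm, "contrast_matrix")) cm$deltas else cm
  lab <- sign(d) * (abs(d) > t)
  storage.mode(lab) <- "integer"
  lab
}
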