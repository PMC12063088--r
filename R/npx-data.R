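#' NPX dataset container
#'
#' Bundles a samples x proteins matrix of NPX values (Olink's arbitrary unit:
#' relative protein level on the log2 scale) with its per-protein limit of
#' detection (LOD), per-sample batch labels, QC pass flags and a below-LOD
#' mask. All downstream preprocessing and modelling operates on this object.
#'
#' @param values numeric matrix, samples in rows, proteins in columns; both
#'   dimnames required and unique.
#' @param lod per-protein LOD on the NPX scale: either a named numeric vector
#'   (one LOD per protein) or a batches x proteins matrix (per-batch LODs,
#'   as produced by [adjust_batches()]).
#' @param batch per-sample batch/plate label (character or factor).
#' @param qc_pass per-sample logical, `TRUE` when the sample passed QC.
#' @param below_lod optional logical matrix of the same shape as `values`;
#'   computed as `values < lod` (strict) when omitted.
#' @return an object of class `npx_dataset`.
#' @export
npx_dataset <- function(values, lod, batch, qc_pass = NULL, below_lod = NULL) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have sample rownames and protein colnames")
  }
  if (anyDuplicated(rownames(values))) stop("duplicate sample ids")
  if (anyDuplicated(colnames(values))) stop("duplicate protein names")
  n <- nrow(values); p <- ncol(values)
  batch <- as.character(batch)
  if (length(batch) != n) stop("`batch` must have one entry per sample")
  if (is.null(qc_pass)) qc_pass <- rep(TRUE, n)
  stopifnot(is.logical(qc_pass), length(qc_pass) == n)
  lod <- check_lod(lod, colnames(values), batch)
  if (is.null(below_lod)) {
    below_lod <- values < lod_per_sample(lod, batch, colnames(values))
    below_lod[is.na(below_lod)] <- FALSE
  }
  stopifnot(is.logical(below_lod), dim(below_lod) == dim(values))
  dimnames(below_lod) <- dimnames(values)
  structure(
    list(values = values, lod = lod, batch = batch,
         qc_pass = qc_pass, below_lod = below_lod,
         audit = list()),
    class = "npx_dataset")
}

check_lod <- function(lod, proteins, batch) {
  if (is.matrix(lod)) {
    if (!setequal(colnames(lod), proteins)) stop("LOD matrix proteins mismatch")
    lod <- lod[, proteins, drop = FALSE]
    if (!all(unique(batch) %in% rownames(lod))) {
      stop("LOD matrix missing batches: ",
           paste(setdiff(unique(batch), rownames(lod)), collapse = ", "))
    }
    lod
  } else {
    if (is.null(names(lod))) names(lod) <- proteins
    if (!setequal(names(lod), proteins)) stop("LOD names must match proteins")
    lod[proteins]
  }
}

# Expand the LOD representation to a full samples x proteins matrix.
lod_per_sample <- function(lod, batch, proteins) {
  if (is.matrix(lod)) {
    lod[batch, proteins, drop = FALSE]
  } else {
    matrix(lod[proteins], nrow = length(batch), ncol = length(proteins),
           byrow = TRUE, dimnames = list(NULL, proteins))
  }
}

#' @export
print.npx_dataset <- function(x, ...) {
  cat(sprintf("npx_dataset: %d samples x %d proteins, %d batch(es), %d QC fail\n",
              nrow(x$values), ncol(x$values), length(unique(x$batch)),
              sum(!x$qc_pass)))
  cat(sprintf("  below-LOD values: %d (%.2f%%)\n", sum(x$below_lod),
              100 * mean(x$below_lod)))
  invisible(x)
}

#' @export
dim.npx_dataset <- function(x) dim(x$values)

sample_ids <- function(ds) rownames(ds$values)
protein_names <- function(ds) colnames(ds$values)

subset_samples <- function(ds, keep) {
  ds$values <- ds$values[keep, , drop = FALSE]
  ds$batch <- ds$batch[keep]
  ds$qc_pass <- ds$qc_pass[keep]
  ds$below_lod <- ds$below_lod[keep, , drop = FALSE]
  ds
}

subset_proteins <- function(ds, keep) {
  ds$values <- ds$values[, keep, drop = FALSE]
  ds$below_lod <- ds$below_lod[, keep, drop = FALSE]
  if (is.matrix(ds$lod)) ds$lod <- ds$lod[, keep, drop = FALSE]
  else ds$lod <- ds$lod[keep]
  ds
}

audit_add <- function(ds, step, ...) {
  entry <- c(list(step = step, n_samples = nrow(ds$values),
                  n_proteins = ncol(ds$values)), list(...))
  ds$audit <- c(ds$audit, list(entry))
  ds
}

npx_long_cols <- c("SampleID", "Assay", "NPX", "LOD", "PlateID", "QC_Warning")

#' Read a long-format NPX table
#'
#' Parses the long CSV dialect used by Olink exports and by
#' [write_npx_long()]: one row per (sample, assay) with columns SampleID,
#' Assay, NPX, LOD, PlateID, QC_Warning. Missing (sample, assay) pairs become
#' `NA` in the wide matrix; the below-LOD mask is `NPX < LOD` (strict, so a
#' value exactly at the LOD is not flagged).
#'
#' @param path CSV file path.
#' @return an [npx_dataset()].
#' @export
read_npx_long <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(npx_long_cols, names(df))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!is.numeric(df$NPX) || !is.numeric(df$LOD)) stop("NPX and LOD must be numeric")
  if (anyDuplicated(df[, c("SampleID", "Assay")])) {
    stop("duplicate (SampleID, Assay) pairs in ", path)
  }
  samples <- unique(df$SampleID)
  proteins <- unique(df$Assay)
  vals <- matrix(NA_real_, length(samples), length(proteins),
                 dimnames = list(samples, proteins))
  vals[cbind(match(df$SampleID, samples), match(df$Assay, proteins))] <- df$NPX
  # per-(batch, protein) LOD; collapses to a vector when constant over batches
  first <- !duplicated(df[, c("SampleID")])
  batch <- setNames(df$PlateID[first], df$SampleID[first])[samples]
  qc <- setNames(df$QC_Warning[first], df$SampleID[first])[samples]
  lodm <- matrix(NA_real_, length(unique(batch)), length(proteins),
                 dimnames = list(unique(batch), proteins))
  lodm[cbind(match(batch[match(df$SampleID, samples)], rownames(lodm)),
             match(df$Assay, proteins))] <- df$LOD
  if (all(apply(lodm, 2, function(z) length(unique(z[!is.na(z)])) <= 1L))) {
    lod <- apply(lodm, 2, function(z) z[!is.na(z)][1])
    names(lod) <- proteins
  } else {
    lod <- lodm
  }
  npx_dataset(vals, lod = lod, batch = unname(batch),
              qc_pass = unname(qc) %in% c("Pass", "TRUE", "0", "pass"))
}

#' Write an NPX dataset as a long-format CSV
#'
#' @param ds an [npx_dataset()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_npx_long <- function(ds, path) {
  lodm <- lod_per_sample(ds$lod, ds$batch, protein_names(ds))
  df <- data.frame(
    SampleID = rep(sample_ids(ds), times = ncol(ds$values)),
    Assay = rep(protein_names(ds), each = nrow(ds$values)),
    NPX = as.vector(ds$values),
    LOD = as.vector(lodm),
    PlateID = rep(ds$batch, times = ncol(ds$values)),
    QC_Warning = ifelse(rep(ds$qc_pass, times = ncol(ds$values)),
                        "Pass", "Warning"),
    stringsAsFactors = FALSE)
  df <- df[!is.na(df$NPX), , drop = FALSE]
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

meta_cols <- c("SampleID", "Diagnosis", "Location", "Behavior", "Extent",
               "Age", "Sex", "DurationYears", "PriorSurgery",
               "TreatmentNaive", "Cohort")

#' Read / write sample metadata
#'
#' Metadata follow the Montreal classification: diagnosis CD/UC/IBD-U/HC,
#' CD location L1 (ileal) / L2 (colonic) / L3 (ileocolonic) / L4 (upper GI
#' modifier), behavior B1-B3, UC extent E1-E3, plus age, sex, disease
#' duration, prior IBD surgery, treatment-naive flag and cohort label.
#'
#' @param path CSV file path.
#' @return a validated metadata `data.frame`.
#' @export
read_sample_meta <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(PriorSurgery = "logical",
                                TreatmentNaive = "logical"))
  validate_sample_meta(df)
}

#' @rdname read_sample_meta
#' @param meta metadata data.frame.
#' @export
write_sample_meta <- function(meta, path) {
  write.csv(validate_sample_meta(meta), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_sample_meta
#' @export
validate_sample_meta <- function(meta) {
  missing_cols <- setdiff(meta_cols, names(meta))
  if (length(missing_cols)) {
    stop("metadata missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(meta$SampleID)) stop("duplicate SampleID in metadata")
  if (!all(meta$Diagnosis %in% c("CD", "UC", "IBD-U", "HC"))) {
    stop("Diagnosis must be one of CD, UC, IBD-U, HC")
  }
  if (any(meta$Age < 18, na.rm = TRUE)) stop("adult cohort: Age must be >= 18")
  bad_loc <- !is.na(meta$Location) & meta$Diagnosis != "CD"
  if (any(bad_loc)) stop("Montreal location is only defined for CD")
  bad_ext <- !is.na(meta$Extent) & meta$Diagnosis != "UC"
  if (any(bad_ext)) stop("Montreal extent is only defined for UC")
  meta
}
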