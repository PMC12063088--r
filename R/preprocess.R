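#' Remove samples that failed QC
#'
#' Samples not passing the panel's quality criteria are dropped. The removed
#' ids are recorded in the dataset's audit trail and attached as the
#' `"removed"` attribute.
#'
#' @param ds an [npx_dataset()].
#' @return the filtered dataset.
#' @export
apply_qc <- function(ds) {
  removed <- sample_ids(ds)[!ds$qc_pass]
  ds <- subset_samples(ds, ds$qc_pass)
  if (nrow(ds$values) == 0L) warning("all samples removed by QC")
  ds <- audit_add(ds, "apply_qc", removed = removed)
  attr(ds, "removed") <- removed
  ds
}

#' Remove named assays from the panel
#'
#' Used for assays unavailable in all batches or whose chemistry changed over
#' time. Unknown names are reported with a warning, not an error.
#'
#' @param ds an [npx_dataset()].
#' @param names character vector of protein names to drop.
#' @return the filtered dataset.
#' @export
exclude_assays <- function(ds, names) {
  unknown <- setdiff(names, protein_names(ds))
  if (length(unknown)) {
    warning("assay name(s) not in panel: ", paste(unknown, collapse = ", "))
  }
  removed <- intersect(protein_names(ds), names)
  keep <- !(protein_names(ds) %in% names)
  ds <- subset_proteins(ds, keep)
  audit_add(ds, "exclude_assays", removed = removed)
}

#' Remove proteins mostly below the limit of detection
#'
#' A protein is dropped when its fraction of below-LOD values, among
#' non-missing measurements, strictly exceeds `max_fraction` (the ">90%"
#' rule: exactly 90% is retained).
#'
#' @param ds an [npx_dataset()].
#' @param max_fraction retention boundary, default 0.90.
#' @return the filtered dataset.
#' @export
exclude_below_lod <- function(ds, max_fraction = 0.90) {
  n_obs <- colSums(!is.na(ds$values))
  frac <- ifelse(n_obs > 0, colSums(ds$below_lod & !is.na(ds$values)) / n_obs, 0)
  keep <- !(frac > max_fraction)
  removed <- protein_names(ds)[!keep]
  ds <- subset_proteins(ds, keep)
  ds <- audit_add(ds, "exclude_below_lod", removed = removed,
                  max_fraction = max_fraction)
  attr(ds, "removed") <- removed
  ds
}

#' Adjust NPX values for batch effects
#'
#' Location (and optionally scale) alignment of per-batch, per-protein
#' distributions. The supplement describing the original adjustment is not
#' public, so three standard choices are exposed:
#' \describe{
#'   \item{median_center}{per batch and protein, subtract the batch median and
#'     add back the global (pre-adjustment) median — the default.}
#'   \item{reference_align}{shift each batch so its per-protein median matches
#'     the reference batch's median.}
#'   \item{location_scale}{as `reference_align`, additionally matching a
#'     robust scale (MAD) to the reference batch.}
#' }
#' LOD values are transformed with the same per-batch map, so the below-LOD
#' mask is unchanged. Batches with fewer than 3 samples are passed through
#' unchanged with a warning. Within-batch rank order of every protein is
#' preserved (the maps are monotone within batch).
#'
#' @param ds an [npx_dataset()].
#' @param method one of `"median_center"`, `"reference_align"`,
#'   `"location_scale"`.
#' @param reference_batch batch label; required for the two reference methods.
#' @return the adjusted dataset, with per-batch LODs (a matrix).
#' @export
adjust_batches <- function(ds, method = c("median_center", "reference_align",
                                          "location_scale"),
                           reference_batch = NULL) {
  method <- match.arg(method)
  batches <- unique(ds$batch)
  proteins <- protein_names(ds)
  if (method != "median_center") {
    if (is.null(reference_batch)) reference_batch <- batches[1]
    if (!reference_batch %in% batches) {
      stop("reference batch not present: ", reference_batch)
    }
  }
  med <- function(x) median(x, na.rm = TRUE)
  global_med <- apply(ds$values, 2, med)
  batch_med <- t(vapply(batches, function(b) {
    apply(ds$values[ds$batch == b, , drop = FALSE], 2, med)
  }, numeric(length(proteins))))
  rownames(batch_med) <- batches
  lodm <- lod_per_sample(ds$lod, ds$batch, proteins)
  new_lod <- matrix(NA_real_, length(batches), length(proteins),
                    dimnames = list(batches, proteins))
  small <- character(0)
  for (b in batches) {
    idx <- ds$batch == b
    if (sum(idx) < 3L) {
      small <- c(small, b)
      new_lod[b, ] <- lodm[which(idx)[1], ]
      next
    }
    x <- ds$values[idx, , drop = FALSE]
    l <- lodm[which(idx)[1], ]
    if (method == "median_center") {
      shift <- global_med - batch_med[b, ]
      x <- sweep(x, 2, shift, "+"); l <- l + shift
    } else if (method == "reference_align") {
      shift <- batch_med[reference_batch, ] - batch_med[b, ]
      x <- sweep(x, 2, shift, "+"); l <- l + shift
    } else {
      bm <- batch_med[b, ]; rm_ <- batch_med[reference_batch, ]
      bs <- apply(ds$values[idx, , drop = FALSE], 2, mad, na.rm = TRUE)
      rs <- apply(ds$values[ds$batch == reference_batch, , drop = FALSE], 2,
                  mad, na.rm = TRUE)
      ratio <- ifelse(bs > 0 & rs > 0, rs / bs, 1)
      x <- sweep(sweep(x, 2, bm, "-"), 2, ratio, "*")
      x <- sweep(x, 2, rm_, "+")
      l <- (l - bm) * ratio + rm_
    }
    ds$values[idx, ] <- x
    new_lod[b, ] <- l
  }
  if (length(small)) {
    warning("batch(es) with <3 samples passed through unchanged: ",
            paste(small, collapse = ", "))
  }
  ds$lod <- new_lod
  audit_add(ds, "adjust_batches", method = method)
}

#' Map sample metadata to analysis groups
#'
#' Primary groups: HC, UC, IBDU, and CD split by Montreal location into
#' CD_L1 (ileal), CD_L2 (colonic), CD_L3 (ileocolonic). CD with an isolated
#' L4 (upper GI) modifier has no ileal/colonic location and is excluded with a
#' warning (`NA` group); CD with a missing location is an error.
#'
#' @param meta metadata data.frame (see [read_sample_meta()]).
#' @return named character vector sample_id -> group (possibly `NA` for
#'   isolated L4).
#' @export
assign_groups <- function(meta) {
  meta <- validate_sample_meta(meta)
  grp <- rep(NA_character_, nrow(meta))
  grp[meta$Diagnosis == "HC"] <- "HC"
  grp[meta$Diagnosis == "UC"] <- "UC"
  grp[meta$Diagnosis == "IBD-U"] <- "IBDU"
  cd <- meta$Diagnosis == "CD"
  loc <- meta$Location
  if (any(cd & (is.na(loc) | loc == ""))) {
    stop("CD sample(s) missing Montreal location: ",
         paste(meta$SampleID[cd & (is.na(loc) | loc == "")], collapse = ", "))
  }
  base_loc <- sub("\\+?L4.*$", "", loc)  # strip upper-GI modifier
  grp[cd & base_loc == "L1"] <- "CD_L1"
  grp[cd & base_loc == "L2"] <- "CD_L2"
  grp[cd & base_loc == "L3"] <- "CD_L3"
  iso_l4 <- cd & base_loc == "" & grepl("L4", loc)
  if (any(iso_l4)) {
    warning("CD with isolated L4 modifier excluded from location groups: ",
            paste(meta$SampleID[iso_l4], collapse = ", "))
  }
  setNames(grp, meta$SampleID)
}

#' Expand a (possibly composite) group name to primary group members
#'
#' `COLONIC_IBD` is the pooled purely-colonic IBD group (UC plus colonic CD);
#' `CD` pools the three CD location groups.
#'
#' @param name group name.
#' @return character vector of primary group names.
#' @export
expand_group <- function(name) {
  switch(name,
         COLONIC_IBD = c("UC", "CD_L2"),
         CD = c("CD_L1", "CD_L2", "CD_L3"),
         name)
}

group_index <- function(groups, name) {
  which(groups %in% expand_group(name))
}

#' Preprocessing audit report
#'
#' @param ds an [npx_dataset()] after one or more preprocessing steps.
#' @return the audit list (step, sample/protein counts, removals per step).
#' @export
preprocess_report <- function(ds) ds$audit
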