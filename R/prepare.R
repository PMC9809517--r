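# Cohort preparation: accession-level de-duplication and exclusion rules.
#
# Every input row is accounted for exactly once: either it survives into
# the analysis set or it is counted under one removal category of the
# exclusion report. Negative (intensity-inverted) images are not removed;
# their pixels are inverted back in place.

new_exclusion_report <- function() {
  r <- list(duplicates_removed = 0L, documents_removed = 0L,
            read_error_removed = 0L, pediatric_removed = 0L,
            filtered_removed = 0L, negatives_transformed = 0L,
            segmentation_failures_removed = 0L,
            surviving_images = 0L, surviving_patients = 0L)
  class(r) <- "exclusion_report"
  r
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat("Exclusion report\n")
  for (k in setdiff(names(x), c("surviving_images", "surviving_patients")))
    cat(sprintf("  %-32s %d\n", k, x[[k]]))
  cat(sprintf("  surviving: %d images / %d patients\n",
              x$surviving_images, x$surviving_patients))
  invisible(x)
}

#' Keep one image per accession
#'
#' When an accession carries several rows (typically post-processed copies
#' of the original exposure), only the earliest acquisition time is kept;
#' ties keep the first row in input order. In `strict` mode an accession
#' with multiple distinct acquisition times is instead discarded entirely
#' (routed to read errors), the alternative reading of the acquisition
#' rules.
#'
#' @param manifest cohort manifest data frame.
#' @param strict discard multi-time accessions instead of keeping the
#'   earliest row.
#' @return list with the de-duplicated `manifest` and a partial
#'   `report` (counts of duplicates and read errors).
#' @export
deduplicate_by_accession <- function(manifest, strict = FALSE) {
  rep <- new_exclusion_report()
  if (nrow(manifest) == 0)
    return(list(manifest = manifest, report = rep))
  keep <- logical(nrow(manifest))
  for (acc in unique(manifest$accession_id)) {
    ix <- which(manifest$accession_id == acc)
    times <- manifest$acquisition_time[ix]
    if (all(is.na(times))) {
      rep$read_error_removed <- rep$read_error_removed + length(ix)
      next
    }
    if (strict && length(unique(stats::na.omit(times))) > 1) {
      rep$read_error_removed <- rep$read_error_removed + length(ix)
      next
    }
    ok <- ix[!is.na(times)]
    first <- ok[which.min(as.POSIXct(manifest$acquisition_time[ok],
                                     tz = "UTC"))]
    keep[first] <- TRUE
    rep$read_error_removed <- rep$read_error_removed + sum(is.na(times))
    rep$duplicates_removed <- rep$duplicates_removed +
      (length(ix) - sum(is.na(times)) - 1L)
  }
  list(manifest = manifest[keep, , drop = FALSE], report = rep)
}

invert_png_in_place <- function(path) {
  img <- read_gray_png(path)
  write_gray_png(1 - img, path)
}

# heuristic negative detector: a regular radiograph has a dark border and
# a brighter center-of-body; an inverted one flips that relation
looks_negative <- function(img) {
  s <- nrow(img)
  b <- max(2L, round(0.05 * s))
  border <- mean(c(img[seq_len(b), ], img[(s - b + 1):s, ],
                   img[, seq_len(b)], img[, (s - b + 1):s]))
  mid <- round(0.35 * s):round(0.65 * s)
  border > mean(img[mid, mid])
}

#' Apply cohort exclusion rules
#'
#' Removes document-type rows, rows with read errors (missing acquisition
#' time or unreadable image file), pediatric rows (`age < min_age`), and
#' filtered-copy rows. Rows flagged as negatives are kept with their pixel
#' intensities inverted back in place (inversion is an involution).
#' Artifact routing uses the manifest's `artifact` flags; with
#' `detect_negatives = TRUE` an intensity heuristic (border brighter than
#' the central body region) is applied to unflagged images as well.
#'
#' @param manifest de-duplicated manifest.
#' @param min_age minimum age in years retained (18 retains exactly-18).
#' @param report a partial report from [deduplicate_by_accession()] to
#'   accumulate into, or `NULL`.
#' @param detect_negatives also detect unflagged negatives heuristically.
#' @return list of the cleaned `manifest` and the completed
#'   `exclusion_report`.
#' @export
apply_exclusions <- function(manifest, min_age = 18, report = NULL,
                             detect_negatives = FALSE) {
  rep <- report %||% new_exclusion_report()
  if (nrow(manifest) == 0) {
    return(list(manifest = manifest, report = rep))
  }
  art <- manifest$artifact %||% rep("", nrow(manifest))
  art[is.na(art)] <- ""
  drop <- rep_len(NA_character_, nrow(manifest))
  drop[art == "document"] <- "document"
  drop[is.na(drop) & is.na(manifest$acquisition_time)] <- "read_error"
  has_file <- nzchar(manifest$image_path %||% rep("", nrow(manifest)))
  readable <- rep(TRUE, nrow(manifest))
  for (i in which(is.na(drop) & has_file)) {
    ok <- file.exists(manifest$image_path[i]) &&
      !inherits(try(suppressWarnings(read_gray_png(manifest$image_path[i])),
                    silent = TRUE), "try-error")
    if (!ok) readable[i] <- FALSE
  }
  drop[is.na(drop) & !readable] <- "read_error"
  drop[is.na(drop) & manifest$age < min_age] <- "pediatric"
  drop[is.na(drop) & art == "filtered"] <- "filtered"
  rep$documents_removed <- rep$documents_removed + sum(drop == "document",
                                                       na.rm = TRUE)
  rep$read_error_removed <- rep$read_error_removed +
    sum(drop == "read_error", na.rm = TRUE)
  rep$pediatric_removed <- rep$pediatric_removed +
    sum(drop == "pediatric", na.rm = TRUE)
  rep$filtered_removed <- rep$filtered_removed + sum(drop == "filtered",
                                                     na.rm = TRUE)
  out <- manifest[is.na(drop), , drop = FALSE]
  # transform negatives in place rather than excluding them
  neg <- (out$artifact %||% rep("", nrow(out))) == "negative"
  if (detect_negatives && any(!neg & nzchar(out$image_path))) {
    for (i in which(!neg & nzchar(out$image_path)))
      if (looks_negative(read_gray_png(out$image_path[i]))) neg[i] <- TRUE
  }
  for (i in which(neg & nzchar(out$image_path)))
    invert_png_in_place(out$image_path[i])
  if (any(neg)) out$artifact[neg] <- ""
  rep$negatives_transformed <- rep$negatives_transformed + sum(neg)
  rep$surviving_images <- nrow(out)
  rep$surviving_patients <- length(unique(out$patient_id))
  list(manifest = out, report = rep)
}

#' Run the full preparation pipeline
#'
#' De-duplication followed by exclusions; the report reconciles: input rows
#' equal surviving rows plus all removals.
#'
#' @inheritParams apply_exclusions
#' @inheritParams deduplicate_by_accession
#' @export
prepare_cohort <- function(manifest, min_age = 18, strict = FALSE,
                           detect_negatives = FALSE) {
  dd <- deduplicate_by_accession(manifest, strict = strict)
  apply_exclusions(dd$manifest, min_age = min_age, report = dd$report,
                   detect_negatives = detect_negatives)
}

#' Write an exclusion report as JSON
#' @param report an `exclusion_report`.
#' @param path output path.
#' @export
write_exclusion_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE)
  invisible(path)
}
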