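# Synthetic phantom radiographs with known per-lung opacity coverage.
#
# A phantom is a square grayscale raster holding a brighter thorax on a dark
# background, two darker elliptical lung fields, a bright central spine
# band, and per-lung opacity blobs placed strictly inside the target lung
# whose coverage fraction realizes the requested ordinal grade. Laterality
# follows radiographic convention: the patient's LEFT lung appears on the
# viewer-RIGHT half of the image (AP/PA projection).

#' Coverage-fraction bin of an ordinal opacity grade
#'
#' Grade 0 means exactly zero coverage; grades 1-3 are the half-open
#' intervals (0, 0.33], (0.33, 0.66], (0.66, 1].
#'
#' @param grade integer vector of grades in 0..3.
#' @return a 2-column matrix of interval bounds (lower exclusive except for
#'   grade 0, upper inclusive).
#' @export
grade_bin <- function(grade) {
  if (any(!grade %in% 0:3)) stop_input("grades must be in 0..3")
  lo <- c(0, 0, 0.33, 0.66)[grade + 1]
  hi <- c(0, 0.33, 0.66, 1)[grade + 1]
  cbind(lower = lo, upper = hi)
}

fraction_to_grade <- function(f) {
  ifelse(f <= 0, 0L, ifelse(f <= 0.33, 1L, ifelse(f <= 0.66, 2L, 3L)))
}

ellipse_mask <- function(size, cx, cy, a, b) {
  x <- matrix(seq_len(size), size, size, byrow = TRUE)
  y <- matrix(seq_len(size), size, size)
  ((x - cx) / a)^2 + ((y - cy) / b)^2 <= 1
}

# Smooth random potential field thresholded at a per-lung quantile so that
# exactly floor(f * area) lung pixels are covered: blob-shaped opacities
# with a realized fraction guaranteed inside the grade's bin.
place_opacity <- function(lung_mask, grade, size) {
  if (grade == 0L) return(list(sel = lung_mask & FALSE, fraction = 0))
  area <- sum(lung_mask)
  if (area < 20)
    stop(structure(class = c("cxr_generation_failure", "error", "condition"),
                   list(message = "lung mask too small to place opacity",
                        call = NULL)))
  rng <- rbind(c(0.03, 0.30), c(0.36, 0.63), c(0.69, 0.97))[grade, ]
  f <- runif(1, rng[1], rng[2])
  idx <- which(lung_mask, arr.ind = TRUE)
  centers <- idx[sample.int(nrow(idx), 3), , drop = FALSE]
  sig <- runif(3, 0.10, 0.22) * size
  x <- matrix(seq_len(size), size, size, byrow = TRUE)
  y <- matrix(seq_len(size), size, size)
  field <- matrix(0, size, size)
  for (j in 1:3)
    field <- field + exp(-((x - centers[j, 2])^2 + (y - centers[j, 1])^2) /
                           (2 * sig[j]^2))
  field <- field + matrix(runif(size^2, 0, 1e-6), size, size)  # break ties
  vals <- field[lung_mask]
  ncov <- floor(f * area)
  thr <- sort(vals, partial = area - ncov)[area - ncov]
  sel <- lung_mask & (field > thr)
  realized <- sum(sel) / area
  bin <- grade_bin(grade)
  if (!(realized > bin[1] && realized <= bin[2]))
    stop(structure(class = c("cxr_generation_failure", "error", "condition"),
                   list(message = sprintf(
                     "coverage %.3f escaped bin of grade %d", realized, grade),
                     call = NULL)))
  list(sel = sel, fraction = realized)
}

#' Generate one phantom radiograph with ground truth
#'
#' @param left_grade,right_grade ordinal opacity grade (0-3) of the
#'   patient's left and right lung. The patient-left lung is rendered on
#'   the viewer-right half of the image.
#' @param image_size side length in pixels (square image, >= 64).
#' @param noise_sigma standard deviation of additive Gaussian pixel noise
#'   on the 0-1 intensity scale.
#' @param artifact_flags character subset of
#'   `c("negative", "document")`: `"negative"` inverts intensities,
#'   `"document"` replaces the radiograph with a document-type page (no
#'   anatomy; ground-truth masks are empty and fractions `NA`).
#' @param seed integer; generation is bit-reproducible given the seed.
#' @return list with `image` (matrix in \[0,1\], rows = image rows) and
#'   `truth`: logical `left_mask`, `right_mask`, `spine_mask` plus realized
#'   `left_fraction`, `right_fraction`.
#' @export
generate_phantom <- function(left_grade, right_grade, image_size = 256,
                             noise_sigma = 0.02,
                             artifact_flags = character(), seed = NULL) {
  if (image_size < 64) stop_input("image_size must be >= 64")
  if (noise_sigma < 0) stop_input("noise_sigma must be >= 0")
  grade_bin(c(left_grade, right_grade))  # validates
  with_seed(seed, {
    s <- image_size
    if ("document" %in% artifact_flags) {
      img <- matrix(0.95, s, s)
      rows <- seq(round(0.15 * s), round(0.9 * s), by = max(4, round(s / 24)))
      for (r in rows) img[r + seq_len(2) - 1,
                          round(0.1 * s):round(runif(1, 0.5, 0.9) * s)] <- 0.2
      img <- pmin(pmax(img + matrix(rnorm(s^2, 0, noise_sigma), s, s), 0), 1)
      empty <- matrix(FALSE, s, s)
      return(list(image = img,
                  truth = list(left_mask = empty, right_mask = empty,
                               spine_mask = empty, left_fraction = NA_real_,
                               right_fraction = NA_real_)))
    }
    # anatomy: patient-right lung on viewer-left
    right_mask <- ellipse_mask(s, cx = 0.31 * s, cy = 0.50 * s,
                               a = 0.14 * s, b = 0.28 * s)
    left_mask <- ellipse_mask(s, cx = 0.69 * s, cy = 0.50 * s,
                              a = 0.14 * s, b = 0.28 * s)
    x <- matrix(seq_len(s), s, s, byrow = TRUE)
    y <- matrix(seq_len(s), s, s)
    spine_mask <- abs(x - 0.5 * s) <= 0.045 * s & y >= 0.08 * s &
      y <= 0.96 * s
    body <- abs(x - 0.5 * s) <= 0.42 * s & y >= 0.06 * s
    img <- matrix(0.12, s, s)
    img[body] <- 0.50
    img[right_mask | left_mask] <- 0.20
    op_l <- place_opacity(left_mask, as.integer(left_grade), s)
    op_r <- place_opacity(right_mask, as.integer(right_grade), s)
    img[op_l$sel] <- img[op_l$sel] + 0.32
    img[op_r$sel] <- img[op_r$sel] + 0.32
    img[spine_mask] <- 0.75
    img <- img + matrix(rnorm(s^2, 0, noise_sigma), s, s)
    img <- pmin(pmax(img, 0), 1)
    if ("negative" %in% artifact_flags) img <- 1 - img
    list(image = img,
         truth = list(left_mask = left_mask, right_mask = right_mask,
                      spine_mask = spine_mask,
                      left_fraction = op_l$fraction,
                      right_fraction = op_r$fraction))
  })
}

# quantize to 8 bits so written PNGs round-trip exactly
quantize8 <- function(img) round(img * 255) / 255

write_gray_png <- function(img, path) png::writePNG(quantize8(img), path)
write_mask_png <- function(mask, path) png::writePNG(mask * 1.0, path)

#' Read a grayscale image
#' @param path PNG file path.
#' @return matrix in \[0,1\].
#' @export
read_gray_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3) x <- x[, , 1]
  x
}

default_demographic_mix <- function() {
  list(sex = c(Male = 0.52, Female = 0.48),
       race = c(White = 0.46, Black = 0.18, Asian = 0.08, Other = 0.23,
                Unknown = 0.05),
       patient_status = c(IP = 0.59, OP = 0.01, ED = 0.40),
       covid_status = c(positive = 0.38, negative = 0.62),
       view = c(AP = 0.954, PA = 0.012, Unknown = 0.034))
}

sample_cat <- function(n, probs) {
  names(probs)[sample.int(length(probs), n, replace = TRUE, prob = probs)]
}

#' Generate a phantom cohort with manifest and acquisition artifacts
#'
#' Emulates the input of the grading pipeline: one or more accessions per
#' patient, per-lung ordinal grades drawn from class priors, demographics,
#' and optional injected artifacts that the exclusion rules must handle —
#' post-processed duplicate copies sharing an accession id at a later
#' acquisition time, filtered-copy accessions, intensity-inverted
#' negatives, document-type images, pediatric records, and rows with a
#' missing acquisition time.
#'
#' @param n_patients number of patients (>= 1).
#' @param class_priors length-4 probability vector over grades 0..3, used
#'   for both lungs (default mirrors a large clinical opacity cohort).
#' @param artifact_rates named list of per-accession (per-patient for
#'   `pediatric`) probabilities for `duplicate_copy`, `filtered`,
#'   `negative`, `document`, `pediatric`, `missing_time`.
#' @param demographic_mix named list of category probability vectors for
#'   `sex`, `race`, `patient_status`, `covid_status`, `view`; defaults to a
#'   realistic hospital mix.
#' @param dir directory to write images/masks and `manifest.csv`; when
#'   `NULL`, no files are written (metadata-only cohort, `image_path` empty).
#' @param image_size phantom side length in pixels.
#' @param noise_sigma Gaussian pixel-noise sd.
#' @param mean_extra_accessions Poisson mean of additional accessions per
#'   patient beyond the first.
#' @param seed integer seed; the cohort is reproducible given the seed.
#' @return the manifest as a data frame (also written to
#'   `file.path(dir, "manifest.csv")` when `dir` is given). Ground-truth
#'   mask paths and realized coverage fractions ride along as extra
#'   columns.
#' @export
generate_cohort <- function(n_patients,
                            class_priors = c(0.33, 0.32, 0.22, 0.13),
                            artifact_rates = list(),
                            demographic_mix = NULL,
                            dir = NULL, image_size = 128,
                            noise_sigma = 0.02,
                            mean_extra_accessions = 0.3,
                            seed = NULL) {
  if (n_patients < 1) stop_input("n_patients must be >= 1")
  if (length(class_priors) != 4 || abs(sum(class_priors) - 1) > 1e-6)
    stop_input("class_priors must be a 4-vector summing to 1")
  rates <- utils::modifyList(
    list(duplicate_copy = 0, filtered = 0, negative = 0, document = 0,
         pediatric = 0, missing_time = 0), as.list(artifact_rates))
  if (any(unlist(rates) < 0 | unlist(rates) > 1))
    stop_input("artifact rates must lie in [0, 1]")
  mix <- utils::modifyList(default_demographic_mix(),
                           as.list(demographic_mix %||% list()))
  write_files <- !is.null(dir)
  if (write_files) {
    dir.create(file.path(dir, "images"), recursive = TRUE,
               showWarnings = FALSE)
    dir.create(file.path(dir, "masks"), recursive = TRUE,
               showWarnings = FALSE)
  }
  t0 <- as.POSIXct("2020-03-24 00:00:00", tz = "UTC")
  rows <- list()
  with_seed(seed, {
    for (p in seq_len(n_patients)) {
      pid <- sprintf("P%05d", p)
      pediatric <- runif(1) < rates$pediatric
      age <- if (pediatric) sample(1:17, 1)
             else round(min(max(rnorm(1, 61, 17), 18), 99))
      demo <- list(sex = sample_cat(1, mix$sex),
                   race = sample_cat(1, mix$race),
                   patient_status = sample_cat(1, mix$patient_status),
                   covid_status = sample_cat(1, mix$covid_status))
      n_acc <- 1L + stats::rpois(1, mean_extra_accessions)
      for (a in seq_len(n_acc)) {
        acc <- sprintf("%s-A%02d", pid, a)
        acq <- t0 + runif(1, 0, 58 * 86400)
        view <- sample_cat(1, mix$view)
        is_doc <- runif(1) < rates$document
        is_neg <- !is_doc && runif(1) < rates$negative
        is_filt <- !is_doc && runif(1) < rates$filtered
        lg <- sample(0:3, 1, prob = class_priors)
        rg <- sample(0:3, 1, prob = class_priors)
        flags <- c(if (is_neg) "negative", if (is_doc) "document")
        art <- if (is_doc) "document" else if (is_neg) "negative"
               else if (is_filt) "filtered" else ""
        base <- sprintf("%s_%02d", pid, a)
        img_path <- mask_paths <- rep("", 4)
        fr <- c(NA_real_, NA_real_)
        if (write_files) {
          ph <- generate_phantom(lg, rg, image_size, noise_sigma,
                                 artifact_flags = flags,
                                 seed = derive_seed(seed %||% 0, pid, a))
          fr <- c(ph$truth$left_fraction, ph$truth$right_fraction)
          if (write_files) {
            img_path <- file.path(dir, "images", paste0(base, ".png"))
            write_gray_png(ph$image, img_path)
            mask_paths <- file.path(dir, "masks",
                                    paste0(base, c("_left", "_right",
                                                   "_spine"), ".png"))
            write_mask_png(ph$truth$left_mask, mask_paths[1])
            write_mask_png(ph$truth$right_mask, mask_paths[2])
            write_mask_png(ph$truth$spine_mask, mask_paths[3])
          }
        }
        acq_str <- if (runif(1) < rates$missing_time) NA_character_
                   else format(acq, "%Y-%m-%d %H:%M:%S")
        row <- data.frame(patient_id = pid, accession_id = acc,
                          acquisition_time = acq_str, age = age,
                          sex = demo$sex, race = demo$race,
                          patient_status = demo$patient_status,
                          covid_status = demo$covid_status, view = view,
                          left_grade = if (is_doc) NA_integer_ else lg,
                          right_grade = if (is_doc) NA_integer_ else rg,
                          image_path = if (write_files) img_path[1] else "",
                          artifact = art,
                          left_mask_path = mask_paths[1],
                          right_mask_path = mask_paths[2],
                          spine_mask_path = mask_paths[3],
                          left_fraction = fr[1], right_fraction = fr[2],
                          stringsAsFactors = FALSE)
        rows[[length(rows) + 1L]] <- row
        if (!is_doc && runif(1) < rates$duplicate_copy) {
          dup <- row
          dup$acquisition_time <- format(acq + runif(1, 60, 3600),
                                         "%Y-%m-%d %H:%M:%S")
          dup$artifact <- "duplicate_copy"
          if (write_files) {
            dimg <- read_gray_png(row$image_path)^0.7  # post-processed copy
            dup$image_path <- file.path(dir, "images",
                                        paste0(base, "_dup.png"))
            write_gray_png(dimg, dup$image_path)
          }
          rows[[length(rows) + 1L]] <- dup
        }
      }
    }
  })
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  if (write_files)
    write_manifest(manifest, file.path(dir, "manifest.csv"))
  manifest
}

#' Write / read a cohort manifest CSV
#' @param manifest data frame of image records.
#' @param path CSV path.
#' @export
write_manifest <- function(manifest, path) {
  write.csv(manifest, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  m <- read.csv(path, stringsAsFactors = FALSE,
                colClasses = "character", na.strings = character())
  for (col in c("age", "left_fraction", "right_fraction"))
    if (col %in% names(m)) m[[col]] <- suppressWarnings(as.numeric(m[[col]]))
  for (col in c("left_grade", "right_grade"))
    if (col %in% names(m))
      m[[col]] <- suppressWarnings(as.integer(m[[col]]))
  if ("acquisition_time" %in% names(m))
    m$acquisition_time[m$acquisition_time == ""] <- NA_character_
  m
}
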