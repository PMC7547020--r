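# Patient-structured synthetic phantom datasets: the stand-in for private
# clinical images. Two classes differ by texture inside a central "sellar"
# region of interest; each patient contributes correlated images in two
# modalities; an optional extra-ROI confound correlates with class so that
# signal-localization (obfuscation) experiments have something to find
# outside the ROI.

#' Phantom dataset configuration
#'
#' Defaults reproduce the clinical dataset's shape: 23 ACP and 30 NOTACP
#' training patients with 3 images per patient per modality (318 training
#' images), and 16 ACP / 17 NOTACP test patients with 1 image per patient
#' per modality (66 test images), all 299x299.
#'
#' @param train_acp,train_notacp training patients per class.
#' @param test_acp,test_notacp test patients per class.
#' @param images_train images per training patient per modality.
#' @param images_test images per test patient per modality.
#' @param roi a [region_mask()] delimiting the "sellar" region where class
#'   texture lives.
#' @param signal_amplitude intensity scale of the in-ROI class structure
#'   (0 = no class signal; default 40 on the 0..255 scale gives a clearly
#'   separable but noisy problem).
#' @param noise_sd per-pixel Gaussian noise standard deviation (> 0).
#' @param confound_amplitude intensity scale of a class-correlated corner
#'   gradient outside the ROI (0 = none).
#' @param seed integer seed; regeneration with the same config is
#'   byte-identical.
#' @return a `phantom_config` object.
#' @export
phantom_config <- function(train_acp = 23L, train_notacp = 30L,
                           test_acp = 16L, test_notacp = 17L,
                           images_train = 3L, images_test = 1L,
                           roi = region_mask("ellipse", c(149, 149),
                                             c(45, 55)),
                           signal_amplitude = 40, noise_sd = 10,
                           confound_amplitude = 0, seed = 1L) {
  stopifnot(train_acp >= 1, train_notacp >= 1, test_acp >= 1,
            test_notacp >= 1, images_train >= 1, images_test >= 1,
            is.finite(signal_amplitude), signal_amplitude >= 0,
            noise_sd > 0, is.finite(confound_amplitude),
            confound_amplitude >= 0)
  structure(list(train_acp = as.integer(train_acp),
                 train_notacp = as.integer(train_notacp),
                 test_acp = as.integer(test_acp),
                 test_notacp = as.integer(test_notacp),
                 images_train = as.integer(images_train),
                 images_test = as.integer(images_test),
                 roi = roi, signal_amplitude = signal_amplitude,
                 noise_sd = noise_sd,
                 confound_amplitude = confound_amplitude,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# Pixel coordinate grids (0-based), computed once per size.
coord_grids <- function(n = IMG_SIZE) {
  list(r = matrix(0:(n - 1L), n, n),
       c = matrix(0:(n - 1L), n, n, byrow = TRUE))
}

# Modality-specific smooth background: CT darker with a broad vignette, MRI
# brighter with a horizontal shading ramp, so modality statistics differ and
# CT-MRI concatenation is non-trivially informative.
phantom_background <- function(modality, grids, n = IMG_SIZE) {
  ctr <- (n - 1) / 2
  d2 <- ((grids$r - ctr)^2 + (grids$c - ctr)^2) / ctr^2
  if (modality == "CT") 60 + 25 * exp(-d2 * 1.5)
  else 120 + 20 * grids$c / (n - 1) + 15 * exp(-d2 * 0.8)
}

# Class structure inside the ROI for one patient: ACP gets speckled bright
# blobs plus a calcification-rim-like ring; NOTACP gets one smooth disc.
# Returns a unit-amplitude field; the caller scales by signal_amplitude.
# Blob geometry is drawn from the current RNG stream (patient level).
phantom_class_field <- function(class, roi, grids) {
  f <- matrix(0, nrow(grids$r), ncol(grids$c))
  cr <- roi$center[1]; cc <- roi$center[2]
  hr <- roi$half_extents[1]; hc <- roi$half_extents[2]
  if (class == "ACP") {
    n_blob <- 3L + stats::rpois(1L, 5)
    for (b in seq_len(n_blob)) {
      # rejection-free placement inside the ellipse via polar sampling
      th <- stats::runif(1, 0, 2 * pi)
      rad <- sqrt(stats::runif(1)) * 0.8
      br <- cr + rad * hr * sin(th)
      bc <- cc + rad * hc * cos(th)
      sig <- stats::runif(1, 2, 6)
      amp <- stats::runif(1, 0.7, 1.3)
      f <- f + amp * exp(-(((grids$r - br)^2 + (grids$c - bc)^2) /
                            (2 * sig^2)))
    }
    ell <- sqrt(((grids$r - cr) / hr)^2 + ((grids$c - cc) / hc)^2)
    f <- f + 0.8 * exp(-((ell - 0.65)^2) / (2 * 0.05^2))  # rim
  } else {
    sig <- stats::runif(1, 18, 28)
    amp <- stats::runif(1, 0.7, 1.1)
    f <- f + amp * exp(-(((grids$r - cr)^2 + (grids$c - cc)^2) /
                          (2 * sig^2)))
  }
  f * mask_matrix(roi, nrow(grids$r), ncol(grids$c))
}

# Extra-ROI confound: a top-left corner gradient whose sign tracks class.
phantom_confound_field <- function(class, roi, grids, n = IMG_SIZE) {
  bump <- exp(-((grids$r^2 + grids$c^2) / (2 * (0.3 * n)^2)))
  bump <- bump * !mask_matrix(roi, nrow(grids$r), ncol(grids$c))
  if (class == "ACP") bump else -bump
}

#' Generate a patient-structured phantom dataset
#'
#' Builds a full manifest plus in-memory 299x299 images. Class texture
#' (speckled blobs and a rim for ACP, a smooth disc for NOTACP) lives inside
#' the ROI and is scaled by `signal_amplitude`; a patient-level jitter makes
#' a patient's images correlated; `confound_amplitude` adds an extra-ROI
#' corner gradient whose sign tracks class. With zero amplitudes the two
#' classes are statistically identical.
#'
#' @param config a [phantom_config()].
#' @return list with `manifest` (data.frame passing [check_manifest()]) and
#'   `images` (named list of matrices).
#' @export
generate_phantom_dataset <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  grids <- coord_grids()
  records <- list()
  images <- list()
  make_patients <- function(split, class, count) {
    lapply(seq_len(count), function(i)
      list(patient_id = sprintf("%s_%s_%02d", split, class, i),
           split = split, class = class))
  }
  patients <- c(make_patients("train", "ACP", config$train_acp),
                make_patients("train", "NOTACP", config$train_notacp),
                make_patients("test", "ACP", config$test_acp),
                make_patients("test", "NOTACP", config$test_notacp))
  with_seed(config$seed, {
    for (pat in patients) {
      n_img <- if (pat$split == "train") config$images_train
               else config$images_test
      for (mod in c("CT", "MRI")) {
        # patient-level structure shared by this patient's images
        class_field <- phantom_class_field(pat$class, config$roi, grids)
        pat_offset <- stats::rnorm(1, 0, 5)
        conf <- phantom_confound_field(pat$class, config$roi, grids)
        for (k in seq_len(n_img)) {
          img <- phantom_background(mod, grids) + pat_offset +
            config$signal_amplitude * class_field +
            config$confound_amplitude * conf +
            stats::rnorm(length(grids$r), 0, config$noise_sd)
          id <- sprintf("%s_%s_%d", pat$patient_id, mod, k)
          images[[id]] <- clamp(img)
          records[[length(records) + 1L]] <- data.frame(
            image_id = id, patient_id = pat$patient_id, modality = mod,
            class = pat$class, split = pat$split,
            path = paste0(id, ".pgm"), parent_image_id = NA_character_,
            stringsAsFactors = FALSE)
        }
      }
    }
  })
  manifest <- do.call(rbind, records)
  check_manifest(manifest)
  list(manifest = manifest, images = images)
}

#' Per-diagnosis composition emulated for the negative class
#'
#' The negative class ("NOTACP") pools every non-ACP lesion in the
#' radiographic differential of a sellar/suprasellar mass. This registry
#' records the per-diagnosis patient counts of the cohort whose shape the
#' phantom emulates; the counts sum to the 47 negative-class patients
#' (30 training + 17 test).
#'
#' @return data.frame with columns `diagnosis` and `n_patients`.
#' @export
notacp_diagnosis_counts <- function() {
  data.frame(
    diagnosis = c("pilocytic astrocytoma", "germinoma",
                  "pilomixoid astrocytoma", "optic glioma",
                  "pituitary adenoma", "arachnoid cyst", "prolactinoma",
                  "mature teratoma", "low grade glioma",
                  "renal cell carcinoma", "Rathke's cyst", "lipoma",
                  "Langerhans cell histiocytosis"),
    n_patients = c(12L, 7L, 6L, 4L, 3L, 3L, 3L, 2L, 2L, 2L, 1L, 1L, 1L),
    stringsAsFactors = FALSE)
}

#' Hidden-optimum fitness landscape for GA testing
#'
#' Draws a secret target genome from the space under the given seed and
#' returns a deterministic fitness function: the fraction of axes on which a
#' genome matches the target (range [0, 1], 1 only at the target). The
#' target is attached as an attribute for oracle checks.
#'
#' @param space a `search_space`.
#' @param seed integer seed fixing the target.
#' @return function(genome) -> fitness in [0, 1], with attribute `target`.
#' @export
hidden_optimum_fitness <- function(space, seed = 1L) {
  target <- with_seed(derive_seed(seed, "hidden-optimum"),
                      random_genome(space))
  fn <- function(g) {
    mean(unlist(g$choices) == unlist(target$choices))
  }
  attr(fn, "target") <- target
  fn
}
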