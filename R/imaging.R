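# Dataset manifests, grayscale image I/O, the stochastic augmentation
# pipeline, and region-of-interest obfuscation.
#
# Images are plain numeric matrices (rows x cols), intensities in [0, 255],
# fixed 299x299 working size. On disk they are stored as ASCII PGM (P2), a
# plain-text grayscale format readable by any image viewer; the environment
# provides no JPEG codec and recompression drift is unwanted anyway.

IMG_SIZE <- 299L

#' Validate a raster image
#' @param img numeric matrix.
#' @param size required square side length.
#' @return the image, invisibly, after checks.
#' @export
check_image <- function(img, size = IMG_SIZE) {
  if (!is.matrix(img) || !is.numeric(img))
    stop("image must be a numeric matrix")
  if (nrow(img) != size || ncol(img) != size)
    stop("image must be ", size, "x", size, ", got ",
         nrow(img), "x", ncol(img))
  if (any(!is.finite(img))) stop("image contains non-finite values")
  invisible(img)
}

#' Write a grayscale image as ASCII PGM (P2)
#'
#' Values are rounded and clamped to 0..255.
#'
#' @param img numeric matrix in [0, 255].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pgm <- function(img, path) {
  stopifnot(is.matrix(img))
  v <- as.integer(round(clamp(img)))
  m <- matrix(v, nrow = nrow(img))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(m), nrow(m)), "255"), con)
  # one image row per line, row-major as PGM requires
  writeLines(apply(m, 1L, paste, collapse = " "), con)
  invisible(path)
}

#' Read an ASCII PGM (P2) grayscale image
#'
#' @param path file path.
#' @return numeric matrix of intensities.
#' @export
read_pgm <- function(path) {
  if (!file.exists(path)) stop("no such image file: ", path)
  toks <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  if (length(toks) < 4L || toks[1] != "P2")
    stop("not an ASCII PGM (P2) file: ", path)
  w <- as.integer(toks[2]); h <- as.integer(toks[3])
  maxv <- as.integer(toks[4])
  px <- as.numeric(toks[-(1:4)])
  if (length(px) != w * h)
    stop("corrupt PGM (expected ", w * h, " pixels, got ", length(px), "): ",
         path)
  if (maxv != 255) px <- px / maxv * 255
  matrix(px, nrow = h, ncol = w, byrow = TRUE)
}

manifest_columns <- c("image_id", "patient_id", "modality", "class",
                      "split", "path", "parent_image_id")

#' Validate a dataset manifest
#'
#' Checks the structural invariants a manifest must satisfy: required
#' columns, unique image ids, known modality/class/split levels, no patient
#' appearing in both the train and test splits (patient-level leakage), and
#' parent references (augmentation provenance) resolving to existing records
#' of the same patient, class and modality.
#'
#' @param manifest data.frame with columns image_id, patient_id, modality
#'   (CT/MRI), class (ACP/NOTACP), split (train/test), path,
#'   parent_image_id (NA for original images).
#' @return the manifest, invisibly.
#' @export
check_manifest <- function(manifest) {
  missing <- setdiff(manifest_columns, names(manifest))
  if (length(missing))
    stop("manifest missing column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(manifest$image_id))
    stop("duplicate image_id: ",
         manifest$image_id[duplicated(manifest$image_id)][1])
  if (!all(manifest$modality %in% c("CT", "MRI")))
    stop("modality must be CT or MRI")
  if (!all(manifest$class %in% c("ACP", "NOTACP")))
    stop("class must be ACP or NOTACP")
  if (!all(manifest$split %in% c("train", "test")))
    stop("split must be train or test")
  both <- intersect(manifest$patient_id[manifest$split == "train"],
                    manifest$patient_id[manifest$split == "test"])
  if (length(both))
    stop("patient(s) in both train and test splits (leakage): ",
         paste(both, collapse = ", "))
  kids <- which(!is.na(manifest$parent_image_id))
  if (length(kids)) {
    idx <- match(manifest$parent_image_id[kids], manifest$image_id)
    orphan <- kids[is.na(idx)]
    if (length(orphan))
      stop("parent_image_id not found for record: ",
           manifest$image_id[orphan[1]])
    same <- manifest$class[idx] == manifest$class[kids] &
      manifest$modality[idx] == manifest$modality[kids] &
      manifest$patient_id[idx] == manifest$patient_id[kids]
    if (!all(same))
      stop("augmented record disagrees with its parent: ",
           manifest$image_id[kids[!same][1]])
  }
  invisible(manifest)
}

#' Load a dataset from a CSV manifest
#'
#' Reads the manifest, validates its invariants, and decodes every referenced
#' image file (ASCII PGM) into a 299x299 matrix. Relative `path` entries are
#' resolved against the manifest's directory.
#'
#' @param manifest_path path to the manifest CSV.
#' @return list with elements `manifest` (data.frame) and `images` (named
#'   list of matrices keyed by image_id).
#' @export
load_dataset <- function(manifest_path) {
  manifest <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  if (!"parent_image_id" %in% names(manifest))
    manifest$parent_image_id <- NA_character_
  manifest$parent_image_id[manifest$parent_image_id %in% c("", "NA")] <-
    NA_character_
  check_manifest(manifest)
  base <- dirname(manifest_path)
  images <- vector("list", nrow(manifest))
  names(images) <- manifest$image_id
  for (i in seq_len(nrow(manifest))) {
    p <- manifest$path[i]
    if (!file.exists(p)) p <- file.path(base, manifest$path[i])
    if (!file.exists(p))
      stop("image file missing for record '", manifest$image_id[i], "': ",
           manifest$path[i])
    img <- read_pgm(p)
    if (nrow(img) != IMG_SIZE || ncol(img) != IMG_SIZE)
      stop("record '", manifest$image_id[i], "': image is ",
           nrow(img), "x", ncol(img), ", expected ",
           IMG_SIZE, "x", IMG_SIZE)
    images[[i]] <- img
  }
  list(manifest = manifest, images = images)
}

#' Write a dataset to disk as manifest CSV plus PGM images
#'
#' @param dataset list with `manifest` and `images` as from [load_dataset()].
#' @param dir output directory (created if absent).
#' @return path of the written manifest, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- dataset$manifest
  manifest$path <- paste0(manifest$image_id, ".pgm")
  for (i in seq_len(nrow(manifest)))
    write_pgm(dataset$images[[manifest$image_id[i]]],
              file.path(dir, manifest$path[i]))
  out <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, out, row.names = FALSE)
  invisible(out)
}

## ---- augmentation operators -------------------------------------------------

# Bilinear sample of `img` at fractional (row, col) coordinates, clamped to
# the image bounds. r and c are equal-length vectors; returns a vector.
bilinear_sample <- function(img, r, c) {
  nr <- nrow(img); nc <- ncol(img)
  r <- pmin(pmax(r, 1), nr)
  c <- pmin(pmax(c, 1), nc)
  r0 <- floor(r); c0 <- floor(c)
  r1 <- pmin(r0 + 1, nr); c1 <- pmin(c0 + 1, nc)
  fr <- r - r0; fc <- c - c0
  i00 <- img[cbind(r0, c0)]; i01 <- img[cbind(r0, c1)]
  i10 <- img[cbind(r1, c0)]; i11 <- img[cbind(r1, c1)]
  (1 - fr) * ((1 - fc) * i00 + fc * i01) + fr * ((1 - fc) * i10 + fc * i11)
}

#' Random grid distortion
#'
#' Overlays a (grid_w+1) x (grid_h+1) control-point lattice on the image,
#' jitters every interior control point independently and uniformly in
#' [-magnitude, +magnitude] per coordinate (border points stay fixed), and
#' resamples the image through the bilinearly interpolated displacement
#' field. With `magnitude = 0` the output equals the input bit-exactly.
#'
#' @param img 299x299 numeric matrix.
#' @param grid_w,grid_h number of grid cells horizontally / vertically.
#' @param magnitude maximum control-point displacement in pixels.
#' @return distorted image, same size, values clamped to [0, 255].
#' @export
grid_distort <- function(img, grid_w = 4L, grid_h = 4L, magnitude = 8) {
  check_image(img, nrow(img))
  stopifnot(grid_w >= 1L, grid_h >= 1L, magnitude >= 0)
  if (magnitude == 0) return(img)
  nr <- nrow(img); nc <- ncol(img)
  # lattice node positions (rows: grid_h+1, cols: grid_w+1)
  node_r <- seq(1, nr, length.out = grid_h + 1L)
  node_c <- seq(1, nc, length.out = grid_w + 1L)
  dr <- matrix(0, grid_h + 1L, grid_w + 1L)
  dc <- matrix(0, grid_h + 1L, grid_w + 1L)
  if (grid_h > 1L && grid_w > 1L) {
    ir <- 2:grid_h; ic <- 2:grid_w
    n_int <- length(ir) * length(ic)
    dr[ir, ic] <- stats::runif(n_int, -magnitude, magnitude)
    dc[ir, ic] <- stats::runif(n_int, -magnitude, magnitude)
  }
  # bilinear interpolation of the control displacements at every pixel
  px_r <- seq_len(nr); px_c <- seq_len(nc)
  cell_r <- pmin(findInterval(px_r, node_r), grid_h)
  cell_c <- pmin(findInterval(px_c, node_c), grid_w)
  tr <- (px_r - node_r[cell_r]) / (node_r[cell_r + 1L] - node_r[cell_r])
  tc <- (px_c - node_c[cell_c]) / (node_c[cell_c + 1L] - node_c[cell_c])
  interp_field <- function(d) {
    d00 <- d[cbind(rep(cell_r, nc), rep(cell_c, each = nr))]
    d01 <- d[cbind(rep(cell_r, nc), rep(cell_c + 1L, each = nr))]
    d10 <- d[cbind(rep(cell_r + 1L, nc), rep(cell_c, each = nr))]
    d11 <- d[cbind(rep(cell_r + 1L, nc), rep(cell_c + 1L, each = nr))]
    wr <- rep(tr, nc); wc <- rep(tc, each = nr)
    matrix((1 - wr) * ((1 - wc) * d00 + wc * d01) +
             wr * ((1 - wc) * d10 + wc * d11), nr, nc)
  }
  disp_r <- interp_field(dr)
  disp_c <- interp_field(dc)
  src_r <- matrix(px_r, nr, nc) + disp_r
  src_c <- matrix(px_c, nr, nc, byrow = TRUE) + disp_c
  out <- matrix(bilinear_sample(img, as.vector(src_r), as.vector(src_c)),
                nr, nc)
  clamp(out)
}

#' Rotate an image by a multiple of 90 degrees
#' @param img numeric matrix.
#' @param k number of counter-clockwise quarter turns (1, 2 or 3).
#' @return rotated image.
#' @export
rotate90 <- function(img, k = 1L) {
  k <- as.integer(k) %% 4L
  if (k == 0L) return(img)
  for (i in seq_len(k)) img <- t(img)[nrow(t(img)):1, , drop = FALSE]
  img
}

#' Flip an image left-right
#' @param img numeric matrix.
#' @return mirrored image.
#' @export
flip_lr <- function(img) img[, ncol(img):1, drop = FALSE]

#' Random zoom by cropping and rescaling
#'
#' Crops a window whose area is `area` times the image area (side length
#' scaled by sqrt(area)), centered but uniformly jittered in position, then
#' rescales it back to the original size with bilinear interpolation.
#'
#' @param img numeric matrix.
#' @param area crop area fraction in (0, 1].
#' @return zoomed image, original size.
#' @export
zoom_crop <- function(img, area = 0.8) {
  stopifnot(area > 0, area <= 1)
  if (area == 1) return(img)
  nr <- nrow(img); nc <- ncol(img)
  side_r <- max(2L, round(nr * sqrt(area)))
  side_c <- max(2L, round(nc * sqrt(area)))
  off_r <- sample.int(nr - side_r + 1L, 1L)
  off_c <- sample.int(nc - side_c + 1L, 1L)
  src_r <- seq(off_r, off_r + side_r - 1L, length.out = nr)
  src_c <- seq(off_c, off_c + side_c - 1L, length.out = nc)
  out <- matrix(bilinear_sample(img,
                                rep(src_r, times = nc),
                                rep(src_c, each = nr)), nr, nc)
  clamp(out)
}

#' Build the default stochastic augmentation pipeline
#'
#' Four stages applied in order, each firing independently with its
#' probability: grid distortion (p = 0.75, 4x4 grid, magnitude 8 px), random
#' 90/180/270-degree rotation (p = 0.75), random zoom (p = 0.5, crop area
#' 0.8), left-right flip (p = 0.5). The test-time variant keeps the same
#' stages with every probability forced to 1 so each pass produces a
#' distinct, fully transformed sample.
#'
#' @param test_time if TRUE, set all stage probabilities to 1.0.
#' @return an `augmentation_pipeline` object (list of stages).
#' @export
build_default_pipeline <- function(test_time = FALSE) {
  p <- if (test_time) c(1, 1, 1, 1) else c(0.75, 0.75, 0.5, 0.5)
  structure(list(
    list(op = "grid_distortion", probability = p[1],
         grid_w = 4L, grid_h = 4L, magnitude = 8),
    list(op = "rotate90", probability = p[2]),
    list(op = "zoom", probability = p[3], area = 0.8),
    list(op = "flip_lr", probability = p[4])
  ), class = "augmentation_pipeline")
}

#' Apply an augmentation pipeline to one image
#'
#' Stages run in order; each fires independently with its probability using
#' R's current random stream, so a fixed `set.seed()` upstream makes a whole
#' augmentation run byte-reproducible.
#'
#' @param pipeline an `augmentation_pipeline`.
#' @param img numeric matrix in [0, 255].
#' @return augmented image, same size.
#' @export
apply_pipeline <- function(pipeline, img) {
  stopifnot(inherits(pipeline, "augmentation_pipeline") ||
              is.list(pipeline))
  for (stage in pipeline) {
    stopifnot(stage$probability >= 0, stage$probability <= 1)
    fire <- stats::runif(1) < stage$probability
    if (!fire) next
    img <- switch(stage$op,
      grid_distortion = grid_distort(img, stage$grid_w, stage$grid_h,
                                     stage$magnitude),
      rotate90 = rotate90(img, sample(1:3, 1L)),
      zoom = zoom_crop(img, stage$area),
      flip_lr = flip_lr(img),
      stop("unknown pipeline operator: ", stage$op))
  }
  clamp(img)
}

#' Oversample a training split to a fixed per-class image count
#'
#' For every (class, modality) cell of the train split, synthetic images are
#' generated by drawing parent originals uniformly with replacement and
#' passing them through the augmentation pipeline, until the cell holds
#' exactly `per_class_target` images. Originals are always retained.
#' Synthetic records inherit patient_id, class and modality from their
#' parent and carry `parent_image_id` provenance.
#'
#' @param manifest dataset manifest (only its train split is touched).
#' @param images named list of image matrices keyed by image_id.
#' @param per_class_target images per class per modality after oversampling.
#' @param pipeline augmentation pipeline; default [build_default_pipeline()].
#' @return list with expanded `manifest` and `images`.
#' @export
oversample_class_balanced <- function(manifest, images, per_class_target,
                                      pipeline = build_default_pipeline()) {
  check_manifest(manifest)
  stopifnot(per_class_target >= 1)
  train <- manifest[manifest$split == "train", , drop = FALSE]
  new_records <- list()
  new_images <- list()
  aug_count <- new.env(parent = emptyenv())  # per-parent synthetic counter
  for (mod in unique(train$modality)) {
    for (cls in unique(train$class)) {
      cell <- train[train$modality == mod & train$class == cls, ,
                    drop = FALSE]
      if (nrow(cell) == 0L)
        stop("empty class cell: ", cls, " / ", mod)
      n_new <- per_class_target - nrow(cell)
      if (n_new <= 0L) next
      parents <- cell[sample.int(nrow(cell), n_new, replace = TRUE), ,
                      drop = FALSE]
      for (j in seq_len(n_new)) {
        pid <- parents$image_id[j]
        nth <- (aug_count[[pid]] %||% 0L) + 1L
        aug_count[[pid]] <- nth
        new_id <- sprintf("%s_aug%04d", pid, nth)
        new_images[[new_id]] <- apply_pipeline(pipeline, images[[pid]])
        new_records[[length(new_records) + 1L]] <- data.frame(
          image_id = new_id, patient_id = parents$patient_id[j],
          modality = mod, class = cls, split = "train",
          path = paste0(new_id, ".pgm"), parent_image_id = pid,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(new_records)) {
    manifest <- rbind(manifest, do.call(rbind, new_records))
    images <- c(images, new_images)
  }
  check_manifest(manifest)
  list(manifest = manifest, images = images)
}

#' Replicate test images through the deterministic-probability pipeline
#'
#' Builds the augmented test-set variants: every test image is passed
#' `times` times through the pipeline with all stage probabilities at 1.0,
#' each pass yielding a new record with provenance.
#'
#' @param manifest dataset manifest.
#' @param images named list of image matrices.
#' @param times replications per test image (10 or 100 in the search space).
#' @return list with expanded `manifest` and `images` (originals retained).
#' @export
augment_test_set <- function(manifest, images, times) {
  check_manifest(manifest)
  stopifnot(times >= 1)
  pipeline <- build_default_pipeline(test_time = TRUE)
  test <- manifest[manifest$split == "test", , drop = FALSE]
  new_records <- vector("list", nrow(test) * times)
  new_images <- list()
  k <- 0L
  for (i in seq_len(nrow(test))) {
    pid <- test$image_id[i]
    for (j in seq_len(times)) {
      new_id <- sprintf("%s_taug%03d", pid, j)
      new_images[[new_id]] <- apply_pipeline(pipeline, images[[pid]])
      k <- k + 1L
      new_records[[k]] <- data.frame(
        image_id = new_id, patient_id = test$patient_id[i],
        modality = test$modality[i], class = test$class[i], split = "test",
        path = paste0(new_id, ".pgm"), parent_image_id = pid,
        stringsAsFactors = FALSE)
    }
  }
  manifest <- rbind(manifest, do.call(rbind, new_records))
  check_manifest(manifest)
  list(manifest = manifest, images = c(images, new_images))
}

## ---- region masks and obfuscation ------------------------------------------

#' Define a rectangular or elliptical region mask
#'
#' Coordinates are 0-based (row, col) with the origin at the top-left pixel.
#' The mask is intersected with the image bounds at application time.
#'
#' @param shape "rectangle" or "ellipse".
#' @param center numeric length-2, (row, col) center.
#' @param half_extents numeric length-2, half sizes (rows, cols); must be
#'   non-negative.
#' @param fill fill intensity in [0, 255].
#' @return a `region_mask` object.
#' @export
region_mask <- function(shape = c("ellipse", "rectangle"),
                        center = c(149, 149),
                        half_extents = c(45, 55), fill = 0) {
  shape <- match.arg(shape)
  stopifnot(length(center) == 2L, length(half_extents) == 2L,
            all(half_extents >= 0), fill >= 0, fill <= 255)
  structure(list(shape = shape, center = as.numeric(center),
                 half_extents = as.numeric(half_extents),
                 fill = as.numeric(fill)),
            class = "region_mask")
}

# Logical matrix: TRUE where the mask covers the pixel.
mask_matrix <- function(mask, nr, nc) {
  r <- matrix(0:(nr - 1L), nr, nc)
  c <- matrix(0:(nc - 1L), nr, nc, byrow = TRUE)
  if (mask$shape == "rectangle") {
    abs(r - mask$center[1]) <= mask$half_extents[1] &
      abs(c - mask$center[2]) <= mask$half_extents[2]
  } else {
    if (any(mask$half_extents == 0)) return(matrix(FALSE, nr, nc))
    ((r - mask$center[1]) / mask$half_extents[1])^2 +
      ((c - mask$center[2]) / mask$half_extents[2])^2 <= 1
  }
}

#' Obfuscate a region of an image
#'
#' Replaces every pixel inside the mask with the mask's constant fill value;
#' all other pixels are untouched. Used to test whether class signal is
#' localized to an anatomical region: a classifier retrained on obfuscated
#' images can only use information outside the masked region.
#'
#' @param img numeric matrix.
#' @param mask a [region_mask()].
#' @return image with the region filled.
#' @export
obfuscate <- function(img, mask) {
  stopifnot(inherits(mask, "region_mask"))
  m <- mask_matrix(mask, nrow(img), ncol(img))
  img[m] <- mask$fill
  img
}

#' Obfuscate every image of a dataset
#' @param images named list of image matrices.
#' @param mask a [region_mask()].
#' @return named list of obfuscated images.
#' @export
obfuscate_dataset <- function(images, mask) {
  lapply(images, obfuscate, mask = mask)
}
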