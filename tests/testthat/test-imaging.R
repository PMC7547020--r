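# Image I/O, manifest invariants, augmentation operators, oversampling and
# region obfuscation.

test_that("PGM round-trip preserves pixel values", {
  set.seed(1)
  img <- matrix(sample(0:255, 50 * 40, replace = TRUE), 50, 40)
  path <- withr::local_tempfile(fileext = ".pgm")
  write_pgm(img, path)
  expect_equal(read_pgm(path), img)
})

test_that("load_dataset decodes a manifest and enforces invariants", {
  dir <- withr::local_tempdir()
  set.seed(2)
  ds <- small_phantom(train_per_class = 2, test_per_class = 1,
                      images_train = 1)
  # keep a 6-record slice with disjoint train/test patients
  keep <- c(head(which(ds$manifest$split == "train"), 4),
            head(which(ds$manifest$split == "test"), 2))
  ds$manifest <- ds$manifest[keep, ]
  ds$images <- ds$images[ds$manifest$image_id]
  write_dataset(ds, dir)
  loaded <- load_dataset(file.path(dir, "manifest.csv"))
  expect_equal(nrow(loaded$manifest), 6L)
  expect_length(loaded$images, 6L)
  for (img in loaded$images) expect_equal(dim(img), c(299L, 299L))

  # patient in both splits must error
  bad <- loaded$manifest
  bad$patient_id[bad$split == "test"] <- bad$patient_id[1]
  tmp <- file.path(dir, "bad.csv")
  utils::write.csv(bad, tmp, row.names = FALSE)
  expect_error(load_dataset(tmp), "leakage")

  # missing file must name the record
  bad2 <- loaded$manifest
  bad2$path[1] <- "missing.pgm"
  utils::write.csv(bad2, tmp, row.names = FALSE)
  expect_error(load_dataset(tmp), bad2$image_id[1], fixed = TRUE)
})

test_that("default phantom manifest reproduces the reference dataset shape", {
  ds <- generate_phantom_dataset(phantom_config(seed = 5))
  m <- ds$manifest
  expect_equal(sum(m$split == "train"), 318L)
  expect_equal(sum(m$split == "test"), 66L)
  expect_equal(sum(m$split == "test" & m$modality == "CT"), 33L)
  expect_equal(sum(m$split == "test" & m$modality == "MRI"), 33L)
  expect_silent(check_manifest(m))
})

test_that("default pipeline matches the documented stages", {
  pipe <- build_default_pipeline()
  expect_equal(vapply(pipe, `[[`, character(1), "op"),
               c("grid_distortion", "rotate90", "zoom", "flip_lr"))
  expect_equal(vapply(pipe, `[[`, numeric(1), "probability"),
               c(0.75, 0.75, 0.5, 0.5))
  expect_equal(pipe[[1]]$grid_w, 4L)
  expect_equal(pipe[[1]]$grid_h, 4L)
  expect_equal(pipe[[1]]$magnitude, 8)
  expect_equal(pipe[[3]]$area, 0.8)
  test_pipe <- build_default_pipeline(test_time = TRUE)
  expect_equal(vapply(test_pipe, `[[`, numeric(1), "probability"),
               rep(1, 4))
})

test_that("grid distortion: zero magnitude is identity, constant stays constant, seeded runs repeat", {
  set.seed(3)
  img <- matrix(runif(299^2, 0, 255), 299, 299)
  expect_identical(grid_distort(img, 4, 4, 0), img)
  const <- matrix(42.5, 299, 299)
  set.seed(4)
  expect_equal(grid_distort(const, 4, 4, 8), const)
  a <- local({ set.seed(9); grid_distort(img, 4, 4, 8) })
  b <- local({ set.seed(9); grid_distort(img, 4, 4, 8) })
  expect_identical(a, b)
  expect_false(identical(a, img))
})

test_that("pipeline operators obey their algebra", {
  set.seed(6)
  img <- matrix(runif(299^2, 0, 255), 299, 299)
  # zero-probability pipeline is the identity
  pipe0 <- build_default_pipeline()
  for (i in seq_along(pipe0)) pipe0[[i]]$probability <- 0
  expect_identical(apply_pipeline(pipe0, img), img)
  # flip is an involution
  expect_identical(flip_lr(flip_lr(img)), img)
  # rotate90 oracle: independent index formula out[i, j] = img[j, n+1-i]
  n <- nrow(img)
  oracle <- matrix(0, n, n)
  for (i in seq_len(n)) oracle[i, ] <- img[, n + 1 - i]
  expect_identical(rotate90(img, 1), oracle)
  expect_identical(rotate90(img, 4), img)
  # a rotation-only pipeline yields one of the three rotations
  rot_pipe <- structure(list(list(op = "rotate90", probability = 1)),
                        class = "augmentation_pipeline")
  set.seed(7)
  out <- apply_pipeline(rot_pipe, img)
  expect_true(any(vapply(1:3, function(k)
    identical(out, rotate90(img, k)), logical(1))))
  # all outputs stay 299x299 in range
  set.seed(8)
  full <- apply_pipeline(build_default_pipeline(test_time = TRUE), img)
  expect_equal(dim(full), c(299L, 299L))
  expect_true(all(full >= 0 & full <= 255))
})

test_that("oversampling hits exact per-class per-modality targets with valid provenance", {
  set.seed(10)
  ds <- small_phantom(train_per_class = 3, test_per_class = 1,
                      images_train = 2)
  for (target in c(6L, 10L)) {
    set.seed(target)
    out <- oversample_class_balanced(ds$manifest, ds$images, target)
    tr <- out$manifest[out$manifest$split == "train", ]
    counts <- table(tr$class, tr$modality)
    expect_true(all(counts == target))
    # synthetic records resolve to same-class parents
    aug <- tr[!is.na(tr$parent_image_id), ]
    idx <- match(aug$parent_image_id, out$manifest$image_id)
    expect_false(any(is.na(idx)))
    expect_equal(aug$class, out$manifest$class[idx])
    expect_equal(aug$modality, out$manifest$modality[idx])
    expect_equal(aug$patient_id, out$manifest$patient_id[idx])
  }
  # target equal to current count adds nothing
  set.seed(11)
  same <- oversample_class_balanced(ds$manifest, ds$images, 6L)
  set.seed(11)
  expect_equal(nrow(oversample_class_balanced(
    same$manifest, same$images, 6L)$manifest),
    nrow(same$manifest))
})

test_that("obfuscation fills exactly the masked pixels and is idempotent", {
  set.seed(12)
  img <- matrix(runif(299^2, 0, 255), 299, 299)
  # whole-image rectangle -> constant
  whole <- region_mask("rectangle", c(149, 149), c(300, 300), fill = 17)
  expect_true(all(obfuscate(img, whole) == 17))
  # zero-extent mask -> unchanged
  none <- region_mask("ellipse", c(149, 149), c(0, 0))
  expect_identical(obfuscate(img, none), img)
  # ellipse predicate oracle, checked per-pixel
  m <- region_mask("ellipse", c(100, 120), c(30, 50), fill = 0)
  out <- obfuscate(img, m)
  inside <- outer(0:298, 0:298, function(r, c)
    ((r - 100) / 30)^2 + ((c - 120) / 50)^2 <= 1)
  expect_true(all(out[inside] == 0))
  expect_identical(out[!inside], img[!inside])
  # idempotence
  expect_identical(obfuscate(out, m), out)
})
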