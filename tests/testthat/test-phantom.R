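test_that("phantom generation is bit-reproducible under a fixed seed", {
  spec <- tiny_spec(seed = 7L)
  a <- generate_phantom_volume(spec)
  b <- generate_phantom_volume(spec)
  expect_identical(a$intensity$values, b$intensity$values)
  expect_identical(a$label$labels, b$label$labels)
  spec2 <- tiny_spec(seed = 8L)
  c <- generate_phantom_volume(spec2)
  expect_false(identical(a$intensity$values, c$intensity$values))
})

test_that("zero noise gives a piecewise-constant intensity volume", {
  spec <- tiny_spec(noise_sd = 0)
  ph <- generate_phantom_volume(spec)
  for (cls in 0:(tiny_scheme()$num_classes - 1L)) {
    vals <- unique(ph$intensity$values[ph$label$labels == cls])
    expect_length(vals, 1L)
    expect_equal(vals, spec$class_means[cls + 1L])
  }
})

test_that("every class is present and voxel counts follow the size ranks", {
  scheme <- subfield_scheme()  # full 10-class protocol
  spec <- phantom_spec(shape = c(64L, 64L, 16L), seed = 3L, scheme = scheme)
  ph <- generate_phantom_volume(spec)
  counts <- table(factor(ph$label$labels, levels = 0:9))
  expect_true(all(counts > 0))
  cls <- function(nm) which(scheme$class_names == nm) - 1L
  n <- function(nm) counts[[as.character(cls(nm))]]
  expect_gt(n("Head"), n("CA2"))
  expect_gt(n("CA1"), n("CA3"))
  # rank order holds across all foreground classes
  fg_counts <- as.vector(counts[-1L])
  expect_identical(order(spec$size_ranks), order(fg_counts, decreasing = TRUE))
})

test_that("invalid phantom specs are rejected", {
  expect_error(phantom_spec(shape = c(0, 16, 3)), "positive")
  expect_error(phantom_spec(noise_sd = -1), "non-negative")
  expect_error(phantom_spec(class_means = c(1, 2), scheme = tiny_scheme()),
               "exactly 3")
  expect_warning(
    phantom_spec(noise_sd = 0, class_means = c(5, 5, 9),
                 scheme = tiny_scheme()),
    "indistinguishable")
})

test_that("all-zero augmentation parameters reproduce the input exactly", {
  ph <- generate_phantom_volume(tiny_spec())
  s <- extract_slices(ph$intensity, ph$label, "s01")[[2L]]
  params <- augment_params(max_rotation_deg = 0, max_translation_px = 0,
                           noise_sd = 0)
  out <- augment_slice(s, params, seed = 5L)
  expect_equal(out$image, s$image)
  expect_identical(out$label, s$label)
  expect_true(out$is_augmented)
})

test_that("a quarter turn with nearest-neighbour labels is lossless", {
  ph <- generate_phantom_volume(tiny_spec())
  s <- extract_slices(ph$intensity, ph$label, "s01")[[2L]]
  rot <- adverseg:::resample_slice(s$label, theta_deg = 90, shift = c(0, 0),
                                   fill = 0L, interp = "nearest")
  # output pixel (i,j) looks up the source rotated by -90 degrees about the
  # centre: src_i = c + (j - c), src_j = c - (i - c)
  H <- nrow(s$label)
  manual <- matrix(0L, H, H)
  for (i in seq_len(H)) for (j in seq_len(H))
    manual[i, j] <- s$label[j, H + 1L - i]
  expect_identical(rot, manual)
  expect_identical(sort(unique(as.vector(rot))),
                   sort(unique(as.vector(s$label))))
})

test_that("augmentation never invents class labels", {
  ph <- generate_phantom_volume(tiny_spec())
  slices <- extract_slices(ph$intensity, ph$label, "s01")
  params <- augment_params(max_rotation_deg = 25, max_translation_px = 4,
                           noise_sd = 10)
  for (k in seq_along(slices)) {
    for (sd in 1:5) {
      out <- augment_slice(slices[[k]], params, seed = sd * 100L + k)
      expect_true(all(out$label %in% c(0L, unique(as.vector(slices[[k]]$label)))))
      expect_identical(dim(out$image), dim(slices[[k]]$image))
    }
  }
})

test_that("augmentation is seeded and the foreground-retry guard errors out", {
  ph <- generate_phantom_volume(tiny_spec())
  s <- extract_slices(ph$intensity, ph$label, "s01")[[2L]]
  params <- augment_params()
  a <- augment_slice(s, params, seed = 11L)
  b <- augment_slice(s, params, seed = 11L)
  expect_identical(a$image, b$image)
  expect_identical(a$label, b$label)
  # a single-pixel foreground at the corner + forced large translation:
  # every redraw pushes it out of frame, so the retry budget must trip
  lonely <- slice_sample(matrix(0, 16, 16),
                         {m <- matrix(0L, 16, 16); m[1, 1] <- 1L; m},
                         "s", 1L)
  far <- augment_params(max_rotation_deg = 0, max_translation_px = 200,
                        noise_sd = 0)  # draws in [-200, 200]; frame is 16 px
  expect_error(augment_slice(lonely, far, seed = 1L, max_retries = 5L),
               "foreground")
  # an all-background slice passes through without tripping the guard
  empty <- slice_sample(matrix(0, 16, 16), matrix(0L, 16, 16), "s", 1L)
  expect_s3_class(augment_slice(empty, far, seed = 1L), "slice_sample")
})

test_that("corpus counts match the dataset layout", {
  # one subject, depth-24 ROI -> 24 slices
  spec1 <- phantom_spec(shape = c(16L, 16L, 24L), scheme = tiny_scheme())
  corp1 <- build_corpus(1L, spec1, seed = 1L)
  expect_length(corp1$samples, 24L)
  expect_identical(corp1$n_base, 24L)
  # 2 subjects x depth 4, factor 3 -> 8 base, 24 total
  spec2 <- phantom_spec(shape = c(16L, 16L, 4L), scheme = tiny_scheme())
  corp2 <- build_corpus(2L, spec2,
                        augment = augment_params(factor = 3L), seed = 1L)
  expect_identical(corp2$n_base, 8L)
  expect_length(corp2$samples, 24L)
})

test_that("every sample traces to exactly one subject and corpora are seeded", {
  spec <- phantom_spec(shape = c(16L, 16L, 3L), scheme = tiny_scheme())
  corp <- build_corpus(3L, spec, augment = augment_params(factor = 2L),
                       seed = 42L)
  subjects <- names(corp$volumes)
  for (s in corp$samples) {
    expect_length(s$subject_id, 1L)
    expect_true(s$subject_id %in% subjects)
  }
  expect_identical(sum(vapply(corp$samples, function(s) !s$is_augmented, NA)),
                   corp$n_base)
  corp2 <- build_corpus(3L, spec, augment = augment_params(factor = 2L),
                        seed = 42L)
  expect_identical(lapply(corp$samples, `[[`, "image"),
                   lapply(corp2$samples, `[[`, "image"))
})

test_that("target_total truncates augmented samples deterministically", {
  spec <- phantom_spec(shape = c(16L, 16L, 3L), scheme = tiny_scheme())
  corp <- build_corpus(2L, spec, augment = augment_params(factor = 4L),
                       seed = 9L, target_total = 15L)
  expect_length(corp$samples, 15L)
  expect_identical(corp$n_base, 6L)
  expect_error(build_corpus(2L, spec, seed = 9L, target_total = 3L),
               "below")
})
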