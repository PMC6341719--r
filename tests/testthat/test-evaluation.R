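test_that("Dice coefficient matches hand counts and its conventions", {
  # explicit 3x3 pair with |S1| = 4, |S2| = 6, |S1 n S2| = 3 -> 2*3/10 = 0.6
  a <- matrix(FALSE, 3, 3); a[1, ] <- TRUE; a[2, 1] <- TRUE
  b <- matrix(FALSE, 3, 3); b[1, 1:2] <- TRUE; b[2, 1:2] <- TRUE
  b[3, 2:3] <- TRUE
  expect_identical(sum(a), 4L); expect_identical(sum(b), 6L)
  expect_identical(sum(a & b), 3L)
  expect_equal(dsc(a, b), 0.6)
  # identical, disjoint, both-empty, symmetry
  expect_equal(dsc(a, a), 1.0)
  disj <- matrix(FALSE, 3, 3); disj[3, 3] <- TRUE
  expect_equal(dsc(a, disj), 0.0)
  empty <- matrix(FALSE, 3, 3)
  expect_equal(dsc(empty, empty), 1.0)
  expect_equal(dsc(a, b), dsc(b, a))
  expect_error(dsc(a, matrix(FALSE, 2, 2)), "differ")
})

test_that("dsc matches brute-force voxel counting on random 3D masks", {
  set.seed(21)
  for (rep in 1:100) {
    a <- array(runif(8 * 8 * 3) < 0.4, dim = c(8, 8, 3))
    b <- array(runif(8 * 8 * 3) < 0.4, dim = c(8, 8, 3))
    got <- dsc(a, b)
    want <- oracle_dsc(as.vector(a), as.vector(b))
    # both are the same ratio of small exact integers: identical doubles
    expect_identical(got, want)
    expect_identical(got, 2 * sum(a & b) / (sum(a) + sum(b)))
  }
})

test_that("volume-level Dice stacks slices before scoring", {
  scheme <- tiny_scheme()
  ph <- generate_phantom_volume(tiny_spec())
  truth <- ph$label
  pred_perfect <- lapply(seq_len(dim(truth$labels)[3]),
                         function(k) truth$labels[, , k])
  rep <- volume_dsc(pred_perfect, truth, scheme)
  expect_true(all(rep$per_class == 1))
  expect_equal(rep$overall, 1.0)

  # constructed 2-slice toy where volume-level and mean-slice Dice differ:
  # slice 1: truth 3 pixels of class 1, prediction hits 2 of them;
  # slice 2: truth 1 pixel, prediction misses it and adds 1 false pixel
  t1 <- matrix(0L, 4, 4); t1[1, 1:3] <- 1L
  t2 <- matrix(0L, 4, 4); t2[4, 4] <- 1L
  p1 <- matrix(0L, 4, 4); p1[1, 1:2] <- 1L
  p2 <- matrix(0L, 4, 4); p2[2, 2] <- 1L
  truth2 <- label_volume(array(c(t1, t2), dim = c(4, 4, 2)), scheme)
  rep2 <- volume_dsc(list(p1, p2), truth2, scheme)
  # volume level: |S1| = 3, |S2| = 4, |n| = 2 -> 4/7
  expect_equal(rep2$per_class[["large"]], 4 / 7)
  slice_mean <- mean(c(2 * 2 / (2 + 3), 0))
  expect_false(isTRUE(all.equal(rep2$per_class[["large"]], slice_mean)))
  # class absent from both sides is flagged and scored 1
  expect_true(rep2$both_empty[["small"]])
  expect_equal(rep2$per_class[["small"]], 1.0)
  expect_error(volume_dsc(list(p1), truth2, scheme), "slices")
})

test_that("slice-wise prediction applies argmax with a low-index tie break", {
  p <- array(0, dim = c(2, 2, 3))
  p[, , 1] <- c(0.2, 0.5, 0.5, 0.1)
  p[, , 2] <- c(0.3, 0.25, 0.5, 0.8)   # tie with class 0 at pixel (1,2)
  p[, , 3] <- c(0.5, 0.25, 0.0, 0.1)
  lab <- adverseg:::argmax_channels(p)
  expect_identical(lab, matrix(c(2L, 0L, 0L, 1L), 2, 2))
  # through the full generator path: one label slice per depth index
  gp <- build_generator(tiny_gen_arch(), seed = 1L)
  ph <- generate_phantom_volume(tiny_spec())
  preds <- predict_volume(gp, ph$intensity)
  expect_length(preds, dim(ph$intensity$values)[3])
  expect_true(all(vapply(preds, function(m) all(m %in% 0:2), NA)))
})

test_that("fold assignment partitions subjects with near-equal sizes", {
  ids30 <- sprintf("s%02d", 1:30)
  f <- make_folds(ids30, 10L, seed = 1L)
  expect_identical(sort(names(f$assignment)), sort(ids30))
  expect_true(all(table(f$assignment) == 3L))
  ids32 <- sprintf("s%02d", 1:32)
  f32 <- make_folds(ids32, 10L, seed = 2L)
  sizes <- as.vector(table(f32$assignment))
  expect_identical(sort(sizes), sort(c(rep(3L, 8), rep(4L, 2))))
  expect_true(all(table(names(f32$assignment)) == 1L))
  expect_error(make_folds(ids30[1:5], 10L), "exceeds")
  expect_identical(make_folds(ids30, 10L, seed = 1L)$assignment,
                   f$assignment)
})

test_that("cross-validation with an oracle trainer scores perfectly and never leaks", {
  spec <- tiny_spec(shape = c(16L, 16L, 2L))
  corpus <- build_corpus(4L, spec, augment = augment_params(factor = 2L),
                         seed = 6L)
  seen <- list()
  oracle_trainer <- function(corpus, gen_arch, adv_arch, config,
                             train_subjects) {
    seen[[length(seen) + 1L]] <<- train_subjects
    list(generator = train_subjects)
  }
  oracle_predictor <- function(generator, intensity) {
    # reply with the ground truth of whichever subject this volume is
    for (sid in names(corpus$volumes))
      if (identical(corpus$volumes[[sid]]$intensity$values, intensity$values))
        return(lapply(seq_len(dim(intensity$values)[3]),
                      function(k) corpus$volumes[[sid]]$label$labels[, , k]))
    stop("unknown volume")
  }
  rep <- crossvalidate(corpus, k = 2L, gen_arch = tiny_gen_arch(),
                       config = desk_training_config(iterations = 1L),
                       seed = 4L, trainer = oracle_trainer,
                       predictor = oracle_predictor)
  expect_true(all(rep$per_class == 1))
  expect_equal(rep$overall, 1.0)
  expect_equal(rep$overall_sd, 0.0)
  # classes reported in scheme order
  expect_identical(names(rep$per_class),
                   tiny_scheme()$class_names[-1])
  # leakage guard: no training set contains a validation subject
  folds <- make_folds(names(corpus$volumes), 2L, seed = 4L)
  for (f in seq_len(2L)) {
    val <- names(folds$assignment)[folds$assignment == f]
    expect_length(intersect(seen[[f]], val), 0L)
  }
})
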