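# Synthetic scene generator, YOLO label round trips, augmentation box
# geometry and the split/expansion arithmetic.

test_that("scenes are seed-deterministic and respect the fruit count range", {
  s1 <- generate_scene(scene_spec(width = 96, height = 96, seed = 5))
  s2 <- generate_scene(scene_spec(width = 96, height = 96, seed = 5))
  expect_identical(s1, s2)
  expect_true(all(s1$image >= 0 & s1$image <= 1))

  empty <- generate_scene(scene_spec(width = 96, height = 96,
                                     n_fruit = c(0L, 0L), seed = 1))
  expect_equal(nrow(empty$annotations), 0L)
  expect_length(empty$yolo, 0L)
})

test_that("fully occluded fruit are excluded by the visibility rule", {
  spec_clear <- scene_spec(width = 64, height = 64, n_fruit = c(4L, 4L),
                           n_leaves = c(0L, 0L), seed = 21)
  clear <- generate_scene(spec_clear)
  expect_gt(nrow(clear$annotations), 0L)
  expect_true(all(clear$annotations$visibility >= 0.25))
  # blanket of opaque leaves: every fruit under cover, none annotated
  spec_blanket <- scene_spec(width = 64, height = 64, n_fruit = c(4L, 4L),
                             n_leaves = c(80L, 80L), leaf_opacity = 1,
                             seed = 21)
  blanket <- generate_scene(spec_blanket)
  expect_lt(nrow(blanket$annotations), nrow(clear$annotations))
})

test_that("boxes lie inside the frame and YOLO labels round-trip", {
  sc <- generate_scene(scene_spec(width = 120, height = 80, seed = 9))
  ann <- sc$annotations
  expect_true(all(ann$xmin >= 0 & ann$xmax <= 120 &
                    ann$ymin >= 0 & ann$ymax <= 80))
  back <- yolo_to_boxes(sc$yolo, 120, 80)
  expect_equal(nrow(back), nrow(ann))
  for (col in c("xmin", "ymin", "xmax", "ymax"))
    expect_true(all(abs(back[[col]] - ann[[col]]) < 1))
})

test_that("augmentation transforms boxes consistently", {
  img <- array(runif(50 * 100 * 3), c(50, 100, 3))
  ann <- data.frame(xmin = 10, ymin = 20, xmax = 30, ymax = 40)
  # mirror flips x about the image width
  m <- augment(img, ann, "mirror")
  expect_equal(as.numeric(m$ann[1, c("xmin", "ymin", "xmax", "ymax")]),
               c(70, 20, 90, 40))
  expect_equal(m$image[, 1, ], img[, 100, ])
  # brightness leaves annotations untouched
  b <- augment(img, ann, "brightness", list(factor = 1.3))
  expect_identical(b$ann, ann)
  expect_equal(dim(b$image), dim(img))
  # translation shifts boxes
  t1 <- augment(img, ann, "translation", list(dx = 5, dy = 0))
  expect_equal(as.numeric(t1$ann[1, c("xmin", "ymin", "xmax", "ymax")]),
               c(15, 20, 35, 40))
  # a box pushed fully out of frame is dropped
  t2 <- augment(img, ann, "translation", list(dx = 95, dy = 0))
  expect_equal(nrow(t2$ann), 0L)
  # rotation keeps the box centre near the rotated centre and clips
  r <- augment(img, ann, "rotation", list(angle = 15))
  expect_true(all(r$ann$xmin >= 0 & r$ann$xmax <= 100 &
                    r$ann$ymin >= 0 & r$ann$ymax <= 50))
  # mirroring commutes with the box-centre arithmetic
  ctr <- box_center(as.numeric(ann[1, ]))
  ctr_m <- box_center(as.numeric(m$ann[1, c("xmin", "ymin", "xmax", "ymax")]))
  expect_equal(ctr_m, c(100 - ctr[1], ctr[2]))
})

test_that("split and expansion arithmetic reproduces the dataset counts", {
  sp <- split_and_triple(930, seed = 1)
  expect_equal(unname(sp$before), c(744, 93, 93))
  expect_equal(unname(sp$counts), c(2232, 279, 279))
  # small case with largest-remainder rounding
  sp10 <- split_and_triple(10, seed = 2)
  expect_equal(unname(sp10$before), c(8, 1, 1))
  # disjoint cover of all indices
  all_idx <- sort(c(sp10$train, sp10$val, sp10$test))
  expect_equal(all_idx, 1:10)
  # augmented copies inherit their source's split (no leakage)
  for (s in c("train", "val", "test")) {
    rows <- sp$expanded[sp$expanded$split == s, ]
    expect_true(all(rows$source %in% sp[[s]]))
  }
  # train-only augmentation switch leaves val/test at their raw sizes
  sp_safe <- split_and_triple(930, seed = 1, augment_val_test = FALSE)
  expect_equal(unname(sp_safe$counts), c(2232, 93, 93))
  expect_error(split_and_triple(10, ratio = c(0.5, 0.2, 0.2)), "sum to 1")
})
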