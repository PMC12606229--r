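test_that("nearest-reference classification with threshold and tie rule", {
  model <- color_model(transform = diag(3),
                       class_references = rbind(c(200, 200, 200),
                                                c(100, 100, 100)),
                       max_distance = 90)
  mk_rgb <- function(col) {
    a <- array(0L, c(1, 1, 1, 3)); a[1, 1, 1, ] <- as.integer(col)
    rgb_volume(a)
  }
  # exact class-1 colour -> label 1
  expect_equal(segment_collagen(mk_rgb(c(200, 200, 200)), model)$values[1, 1, 1], 1L)
  # nearest reference wins when inside its threshold
  expect_equal(segment_collagen(mk_rgb(c(90, 90, 110)), model)$values[1, 1, 1], 2L)
  # farther than max_distance from every reference -> background
  expect_equal(segment_collagen(mk_rgb(c(0, 0, 0)), model)$values[1, 1, 1], 0L)
  # equidistant between both references and within threshold -> lowest id
  expect_equal(segment_collagen(mk_rgb(c(150, 150, 150)), model)$values[1, 1, 1], 1L)
  # the transform is applied before distances: scaling by 0 collapses all
  # colours onto the references' transform image
  m0 <- color_model(transform = matrix(0, 3, 3),
                    class_references = rbind(c(0, 0, 0)), max_distance = 1)
  expect_equal(segment_collagen(mk_rgb(c(13, 77, 200)), m0)$values[1, 1, 1], 1L)
})

test_that("colour model YAML round-trips", {
  tmp <- withr::local_tempfile(fileext = ".yaml")
  m <- color_model(transform = matrix(c(0.3, 0.6, 0.1, -0.2, 0.5, -0.3,
                                        0.1, 0.1, 0.8), 3, byrow = TRUE),
                   class_references = rbind(c(220, 210, 190), c(240, 220, 170)),
                   max_distance = c(35, 25), class_ids = c(2L, 5L))
  write_color_model(m, tmp)
  m2 <- read_color_model(tmp)
  expect_equal(m2$transform, m$transform)
  expect_equal(m2$class_references, m$class_references)
  expect_equal(m2$max_distance, m$max_distance)
  expect_identical(m2$class_ids, m$class_ids)
})

test_that("artifact cleaning drops small 26-connected components only", {
  v <- array(0L, c(12, 12, 12))
  v[2:3, 2:3, 2:3] <- 1L          # 8-voxel component
  v[8, 8, 8] <- 2L                # isolated voxel, different class
  v[4, 4, 4] <- 2L                # touches the block diagonally (26-conn)
  lv <- label_volume(v, label_names = c(`1` = "a", `2` = "b"))
  out <- clean_artifacts(lv, min_component_voxels = 5)
  expect_equal(out$values[8, 8, 8], 0L)          # small component removed
  expect_equal(out$values[4, 4, 4], 2L)          # survives via class union
  expect_true(all(out$values[2:3, 2:3, 2:3] == 1L))
  # min = 1 is the identity
  expect_identical(clean_artifacts(lv, 1)$values, lv$values)
  # never increases the foreground count
  expect_lte(sum(out$values > 0), sum(lv$values > 0))
  # two 10-voxel components with min = 5 are both kept
  w <- array(0L, c(12, 12, 12))
  w[1:10, 1, 1] <- 1L
  w[1:10, 6, 6] <- 1L
  wl <- label_volume(w)
  expect_identical(clean_artifacts(wl, 5)$values, wl$values)
})

test_that("missing slices are filled by signed-distance interpolation", {
  # identical neighbours reproduce the slice exactly
  sl <- matrix(0, 9, 9); sl[3:7, 3:7] <- 1
  v <- volume3d(array(rep(sl, 3), c(9, 9, 3)))
  filled <- fill_missing_slices(v, 2)
  expect_identical(filled$values[, , 2], sl)
  expect_identical(filled$values[, , c(1, 3)], v$values[, , c(1, 3)])

  # a leading missing slice copies its only valid neighbour
  v2 <- volume3d(array(c(matrix(0, 9, 9), sl, sl), c(9, 9, 3)))
  f2 <- fill_missing_slices(v2, 1)
  expect_identical(f2$values[, , 1], sl)

  # disc radius 10 and radius 6 interpolate to radius 8 within one rim voxel
  mk_disc <- function(r) {
    cc <- (1:41) - 21
    1 * (outer(cc^2, cc^2, "+") <= r^2)
  }
  v3 <- volume3d(array(c(mk_disc(10), matrix(0, 41, 41), mk_disc(6)),
                       c(41, 41, 3)))
  f3 <- fill_missing_slices(v3, 2)
  mid <- f3$values[, , 2]
  rr <- sqrt(outer(((1:41) - 21)^2, ((1:41) - 21)^2, "+"))
  wrong <- which(mid != mk_disc(8))
  expect_true(all(abs(rr[wrong] - 8) <= 1))

  expect_error(fill_missing_slices(v, 1:3), "all slices missing")
  expect_error(fill_missing_slices(v, 9), "out of range")
})

test_that("segmentation is idempotent through a noise-free colourised rendering", {
  ph <- make_phantom(phantom_spec(c(20, 20, 20), c(1, 1, 1), list(
    list(kind = "ball", center = c(7, 7, 7), radius = 5, class = 1),
    list(kind = "cuboid", lo = c(12, 12, 12), hi = c(18, 18, 16), class = 2))))
  model <- color_model()
  cols <- rbind(`1` = model$class_references[1, ], `2` = model$class_references[2, ])
  rgb <- colorize_phantom(ph$truth, cols, color_noise_sd = 0)
  seg <- segment_collagen(rgb, model)
  expect_identical(seg$values, ph$truth$values)
  expect_equal(dice_coef(seg$values > 0, ph$mask$values > 0), 1.0)
})
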