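test_that("isolated voxel gives the isotropic tensor (26/3) I", {
  m <- array(0, c(9, 9, 9)); m[5, 5, 5] <- 1
  A <- orientation_tensor(volume3d(m), c(5, 5, 5),
                          lattice_directions(1, FALSE), cap = 16)
  expect_equal(A, diag(26 / 3, 3), tolerance = 1e-12)
  expect_equal(sum(diag(A)), 26, tolerance = 1e-12)
})

test_that("a 1-voxel fibre yields the hand-derived tensor diag(26/3, 26/3, 26/3 + 576)", {
  m <- array(0, c(5, 5, 41)); m[3, 3, ] <- 1
  A <- orientation_tensor(volume3d(m), c(3, 3, 21),
                          lattice_directions(1, FALSE), cap = 16)
  expect_equal(A, diag(c(26 / 3, 26 / 3, 26 / 3 + 576)), tolerance = 1e-12)
})

test_that("orientation tensor equals the naive dyadic sum on random masks", {
  set.seed(11)
  dirs <- lattice_directions(2, FALSE)
  for (rep in 1:5) {
    m <- random_mask(c(10, 10, 10), 0.5)
    fg <- which(m > 0, arr.ind = TRUE)
    vox <- fg[sample(nrow(fg), 1), ]
    v <- volume3d(m)
    A <- orientation_tensor(v, vox, dirs, cap = 6)
    # naive loop oracle
    B <- matrix(0, 3, 3)
    for (i in seq_len(nrow(dirs$generators))) {
      r <- 1 + ray_run_length(v, vox, dirs$generators[i, ], cap = 6)
      B <- B + r^2 * tcrossprod(dirs$units[i, ])
    }
    expect_equal(A, B, tolerance = 1e-12)
    ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev > -1e-9 * max(ev)))  # PSD
  }
})

test_that("eigensystem sorts, reconstructs, and respects the sign convention", {
  es <- eigensystem(diag(c(2, 1, 0)))
  expect_equal(es$values, c(2, 1, 0))
  expect_equal(abs(es$vectors[, 1]), c(1, 0, 0))
  expect_gt(es$vectors[1, 1], 0)

  es2 <- eigensystem(diag(26 / 3, 3))
  expect_equal(es2$values, rep(26 / 3, 3))

  set.seed(5)
  for (rep in 1:20) {
    A <- random_dyadic_tensor()
    es <- eigensystem(A)
    lam <- es$values
    V <- es$vectors
    expect_true(all(diff(lam) <= 0))
    expect_true(all(lam >= 0))
    expect_equal(crossprod(V), diag(3), tolerance = 1e-9)
    expect_equal(det(V), 1, tolerance = 1e-9)  # right-handed
    recon <- V %*% diag(lam) %*% t(V)
    expect_lt(max(abs(A - recon)), 1e-8 * max(1, lam[1]))
    for (j in 1:2) expect_gt(V[which.max(abs(V[, j])), j], 0)
  }
  expect_error(eigensystem(matrix(c(1, 2, 3, 4, 5, 6, 7, 8, 9), 3)),
               "not symmetric")
})

test_that("Westin measures partition unity and match the closed forms", {
  w <- westin_measures(c(1, 0, 0))
  expect_equal(c(w$c_l, w$c_p, w$c_s), c(1, 0, 0))
  w <- westin_measures(c(1, 1, 1))
  expect_equal(c(w$c_l, w$c_p, w$c_s), c(0, 0, 1))
  w <- westin_measures(c(3, 2, 1))
  expect_equal(c(w$c_l, w$c_p, w$c_s), c(1 / 6, 1 / 3, 1 / 2))

  set.seed(17)
  for (rep in 1:50) {
    lam <- sort(abs(rnorm(3)), decreasing = TRUE)
    w <- westin_measures(lam)
    tri <- c(w$c_l, w$c_p, w$c_s)
    expect_lt(abs(sum(tri) - 1), 1e-9)
    expect_true(all(tri >= 0 & tri <= 1))
  }
  wz <- westin_measures(c(0, 0, 0))
  expect_true(wz$unclassified)
  expect_equal(c(wz$c_l, wz$c_p, wz$c_s), c(0, 0, 0))
})

test_that("structural classification applies argmax, threshold and tie order", {
  mk <- function(l, p, s) structure(list(c_l = l, c_p = p, c_s = s,
                                         unclassified = FALSE),
                                    class = "westin_triple")
  expect_equal(as.character(classify_structure(mk(0.6, 0.3, 0.1))), "fibrous")
  expect_equal(as.character(classify_structure(mk(0, 0, 1))), "spherical")
  expect_equal(as.character(classify_structure(mk(0.4, 0.35, 0.25), 0.5)),
               "unclassified")
  # ties break fibrous > planar > spherical
  expect_equal(attr(classify_structure(mk(0.5, 0.5, 0)), "code"), 1L)
  expect_equal(attr(classify_structure(mk(0, 0.5, 0.5)), "code"), 2L)
  expect_equal(attr(classify_structure(westin_measures(c(0, 0, 0))), "code"), 0L)
  expect_identical(structure_codes(),
                   c(unclassified = 0L, fibrous = 1L, planar = 2L, spherical = 3L))
})

test_that("tensor field block averaging follows the stated rules", {
  ph <- cylinder_phantom(n = 16, radius = 1.5, center = c(8, 8))
  dirs <- lattice_directions(1, FALSE)
  f1 <- tensor_field(ph$mask, dirs, cap = 4, output_bin = 1)
  expect_equal(dim(f1$values)[1:3], c(16, 16, 16))
  # per-voxel mode matches orientation_tensor at a foreground voxel
  A <- orientation_tensor(ph$mask, c(8, 8, 8), dirs, cap = 4)
  expect_equal(tensor_at(f1, 8, 8, 8), A, tolerance = 1e-12)
  # background voxel -> zero tensor
  expect_equal(f1$values[1, 1, 1, ], rep(0, 6))

  f2 <- tensor_field(ph$mask, dirs, cap = 4, output_bin = 2)
  expect_equal(dim(f2$values)[1:3], c(8, 8, 8))
  expect_equal(f2$spacing, ph$mask$spacing * 2)
  # block with no foreground -> zero tensor
  expect_equal(f2$values[1, 1, 1, ], rep(0, 6))
  # block average equals the mean of member foreground tensors
  blk <- c(4, 4, 4)  # covers voxels 7:8 x 7:8 x 7:8
  members <- list()
  for (i in 7:8) for (j in 7:8) for (k in 7:8)
    if (ph$mask$values[i, j, k] > 0)
      members[[length(members) + 1]] <- f1$values[i, j, k, ]
  expect_equal(f2$values[4, 4, 4, ], Reduce(`+`, members) / length(members),
               tolerance = 1e-12)
})

test_that("tensors are covariant under lattice axis permutations and flips", {
  set.seed(23)
  m <- random_mask(c(8, 8, 8), 0.5)
  dirs <- lattice_directions(1, FALSE)
  vox <- c(4, 5, 3)
  m[vox[1], vox[2], vox[3]] <- 1
  A <- orientation_tensor(volume3d(m), vox, dirs, cap = 5)
  # swap x and z axes of the mask: tensor conjugates by the permutation
  mp <- aperm(m, c(3, 2, 1))
  Ap <- orientation_tensor(volume3d(mp), vox[c(3, 2, 1)], dirs, cap = 5)
  P <- matrix(c(0, 0, 1, 0, 1, 0, 1, 0, 0), 3)
  expect_equal(Ap, P %*% A %*% t(P), tolerance = 1e-12)
  expect_equal(eigensystem(Ap)$values, eigensystem(A)$values, tolerance = 1e-12)
  wa <- westin_measures(eigensystem(A))
  wp <- westin_measures(eigensystem(Ap))
  expect_equal(c(wa$c_l, wa$c_p, wa$c_s), c(wp$c_l, wp$c_p, wp$c_s),
               tolerance = 1e-12)
  # flip z: same spectrum
  mf <- m[, , dim(m)[3]:1]
  Af <- orientation_tensor(volume3d(mf), c(vox[1], vox[2], 9 - vox[3]),
                           dirs, cap = 5)
  expect_equal(eigensystem(Af)$values, eigensystem(A)$values, tolerance = 1e-12)
})

test_that("RGB encodings follow the documented colour conventions", {
  # fibre: e1 along z -> e1 mode encodes (0, 0, 255); rank mode red
  m <- array(0, c(3, 3, 33)); m[2, 2, ] <- 1
  f <- tensor_field(volume3d(m), lattice_directions(1, FALSE),
                    cap = 16, output_bin = 1)
  e1 <- encode_tensor_rgb(f, "e1")
  expect_equal(e1$values[2, 2, 17, ], c(0L, 0L, 255L))
  rk <- encode_tensor_rgb(f, "rank")
  expect_equal(rk$values[2, 2, 17, ], c(255L, 0L, 0L))
  # background encodes black in every mode
  for (mode in c("e1", "e2", "westin", "rank"))
    expect_equal(encode_tensor_rgb(f, mode)$values[1, 1, 1, ], c(0L, 0L, 0L))
  # pure linear triple -> westin mode channel red
  lin <- array(0, c(1, 1, 1, 6)); lin[1, 1, 1, ] <- c(1, 0, 0, 0, 0, 0)
  wv <- encode_tensor_rgb(tensor_volume(lin), "westin")
  expect_equal(wv$values[1, 1, 1, ], c(255L, 0L, 0L))
  # structure_rank labels agree with rank colours
  lbl <- structure_rank(f)
  expect_equal(lbl$values[2, 2, 17], 1L)
  expect_equal(lbl$values[1, 1, 1], 0L)
})
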