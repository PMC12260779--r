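test_that("empty phantom rasterizes to an all-zero grid", {
  sp <- phantom_spec(container_diameter_m = 0.01, grid_shape = c(32, 32, 1))
  ph <- make_phantom(sp)
  expect_true(all(ph$beta == 0))
  expect_true(all(ph$labels == 0))
})

test_that("sphere rasterization matches a voxel-by-voxel oracle", {
  vx <- 1e-4
  sp <- phantom_spec(container_diameter_m = 30 * vx, grid_shape = c(33, 33, 5),
                     voxel_size_m = vx,
                     calcifications = list(list(center = c(0, 0, 0),
                                                radius = 2 * vx, beta = 5e-10)))
  ph <- make_phantom(sp)
  # brute-force count over all voxel centers
  cnt <- 0L
  for (i in 1:33) for (j in 1:33) for (k in 1:5) {
    x <- (i - 17) * vx; y <- (j - 17) * vx; z <- (k - 3) * vx
    if (x^2 + y^2 + z^2 <= (2 * vx)^2) cnt <- cnt + 1L
  }
  code <- match("calcification", ph$label_names) - 1L
  expect_equal(sum(ph$labels == code), cnt)
  expect_true(all(ph$beta[ph$labels == code] > 2e-10))
})

test_that("phantom generation is deterministic and validates its inputs", {
  a <- make_phantom(breast_phantom_spec(c(48, 48, 1), seed = 11))
  b <- make_phantom(breast_phantom_spec(c(48, 48, 1), seed = 11))
  expect_identical(a$beta, b$beta)
  expect_identical(a$labels, b$labels)
  # primitive poking out of the container is rejected
  sp <- phantom_spec(container_diameter_m = 0.003, grid_shape = c(32, 32, 1),
                     tissue_components = list(
                       list(label = "adipose", type = "cylinder",
                            center = c(0.002, 0), radius = 0.001, beta = 1.2e-10)))
  expect_error(make_phantom(sp), "container")
  # beta bounds
  expect_error(phantom_spec(0.01, c(8, 8, 1), tissue_components = list(
    list(label = "adipose", type = "cylinder", center = c(0, 0),
         radius = 1e-3, beta = 3e-10))), "soft-tissue")
  expect_error(phantom_spec(0.01, c(8, 8, 1), calcifications = list(
    list(center = c(0, 0, 0), radius = 1e-4, beta = 1e-10))), "calcification")
})

test_that("later primitives override earlier ones inside the container", {
  vx <- 1e-4
  sp <- phantom_spec(container_diameter_m = 30 * vx, grid_shape = c(33, 33, 1),
                     voxel_size_m = vx,
                     tissue_components = list(
                       list(label = "adipose", type = "cylinder",
                            center = c(0, 0), radius = 14 * vx, beta = 1.2e-10),
                       list(label = "glandular", type = "sphere",
                            center = c(0, 0, 0), radius = 4 * vx, beta = 1.6e-10)))
  ph <- make_phantom(sp)
  expect_equal(ph$beta[17, 17, 1], 1.6e-10)  # glandular wins at the center
  expect_equal(ph$beta[17, 3, 1], 1.2e-10)   # adipose elsewhere
  expect_equal(ph$beta[1, 1, 1], 0)          # outside the container
})

test_that("parallel projection is linear and geometrically consistent", {
  vx <- 1e-4
  zero <- array(0, dim = c(32, 32, 1))
  p0 <- project_parallel(zero, c(0, 45, 90), vx)
  expect_true(all(p0 == 0))
  # a voxel on the rotation axis: its projected mass is the same at every
  # angle and always lands on the central detector bin
  one <- array(0, dim = c(33, 33, 1)); one[17, 17, 1] <- 1
  p1 <- project_parallel(one, seq(0, 170, by = 10), vx)
  mass <- rowSums(p1[, , 1])
  expect_lt(max(abs(mass - mass[1])) / mass[1], 0.02)
  expect_true(all(apply(p1[, , 1], 1, which.max) == 17))
  # central ray through a uniform disk ~ 2 rho beta0
  d <- disk_sinogram(n = 129, radius = 40, n_angles = 4)
  expect_equal(d$sino[1, 65], 2 * 40 * d$pixel * d$beta0, tolerance = 0.02)
  expect_error(project_parallel(zero, numeric(0), vx), "empty")
  expect_error(project_parallel(zero, 181, vx))
})
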