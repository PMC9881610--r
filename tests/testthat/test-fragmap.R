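test_that("Boltzmann transform matches the closed form and caps correctly", {
  expect_equal(boltzmann_transform(1, 300), 0)
  expect_equal(boltzmann_transform(0, 300, gfe_cap = 3), 3)
  # direct evaluation of -kB T ln 2
  expect_equal(boltzmann_transform(2, 300), -0.0019872 * 300 * log(2),
               tolerance = 1e-12)
  # tiny probability pushes past the cap
  expect_equal(boltzmann_transform(1e-30, 300, gfe_cap = 3), 3)
  # array in, array out, elementwise
  p <- array(c(1, 2, 0.5, 0), dim = c(2, 2, 1))
  g <- boltzmann_transform(p, 300, gfe_cap = 3)
  expect_equal(dim(g), dim(p))
  expect_equal(g[1, 1, 1], 0)
})

test_that("Boltzmann transform rejects bad input and is monotone in p", {
  expect_error(boltzmann_transform(-0.1, 300), "nonnegative")
  expect_error(boltzmann_transform(c(1, NA), 300), "finite")
  expect_error(boltzmann_transform(1, -5), "positive")
  p <- sort(runif(50, 0.01, 5))
  g <- boltzmann_transform(p, 300, gfe_cap = 100)
  expect_true(all(diff(g) <= 0))
})

test_that("grid construction validates geometry and caps values", {
  expect_error(fragmap_grid(matrix(0, 2, 2)), "3D")
  expect_error(fragmap_grid(array(0, c(2, 2, 2)), spacing = c(1, 0, 1)),
               "positive")
  expect_error(fragmap_grid(array(c(0, Inf), c(2, 1, 1))), "finite")
  g <- fragmap_grid(array(10, c(2, 2, 2)), gfe_cap = 3)
  expect_true(all(g$values == 3))
})

test_that("OpenDX round trip is value- and metadata-preserving", {
  set.seed(42)
  for (rep in 1:3) {
    g <- random_grid(dims = c(3L, 4L, 5L), map_type = "GEND")
    path <- file.path(tempdir(), "rt.GEND.dx")
    write_gfe_map(g, path)
    g2 <- read_gfe_map(path)
    expect_identical(g2$values, g$values)
    expect_identical(g2$dims, g$dims)
    expect_equal(g2$origin, g$origin, tolerance = 1e-15)
    expect_equal(g2$spacing, g$spacing, tolerance = 1e-15)
    expect_identical(g2$map_type, "GEND")
  }
})

test_that("a handcrafted OpenDX fixture parses to its exact values", {
  # 2x2x2, origin 0, unit spacing, values 0..7 in z-fastest order
  path <- file.path(tempdir(), "hand.GENN.dx")
  writeLines(c(
    "object 1 class gridpositions counts 2 2 2",
    "origin 0 0 0",
    "delta 1 0 0", "delta 0 1 0", "delta 0 0 1",
    "object 2 class gridconnections counts 2 2 2",
    "object 3 class array type double rank 0 items 8 data follows",
    "0 1 2", "3 4 5", "6 7",
    'attribute "dep" string "positions"'), path)
  g <- read_gfe_map(path, gfe_cap = 10)
  # value at (x, y, z) voxel index is 4x + 2y + z with z fastest
  for (x in 0:1) for (y in 0:1) for (z in 0:1)
    expect_equal(g$values[x + 1, y + 1, z + 1], 4 * x + 2 * y + z)
  expect_equal(gfe_at(g, c(1, 0, 1)), 5)
})

test_that("malformed OpenDX files are rejected with a parse error", {
  path <- file.path(tempdir(), "bad.GENN.dx")
  writeLines(c(
    "object 1 class gridpositions counts 2 2 2",
    "origin 0 0 0",
    "delta 1 0 0", "delta 0 1 0", "delta 0 0 1",
    "object 2 class gridconnections counts 2 2 2",
    "object 3 class array type double rank 0 items 8 data follows",
    "0 1 2", "3 4 5", "6"), path)
  expect_error(read_gfe_map(path), "7 data values for 8")
  writeLines("not a dx file", path)
  expect_error(read_gfe_map(path), "gridpositions")
})

test_that("gfe_at follows the nearest-voxel convention", {
  set.seed(7)
  g <- random_grid(dims = c(4L, 4L, 4L))
  # at a voxel center
  cen <- g$origin + c(1, 2, 0) * g$spacing
  expect_equal(gfe_at(g, cen), g$values[2, 3, 1])
  # just inside the rounding boundary stays in the same voxel
  expect_equal(gfe_at(g, cen + 0.49 * g$spacing), g$values[2, 3, 1])
  # far outside the grid returns the cap
  expect_equal(gfe_at(g, g$origin - c(10, 10, 10)), g$gfe_cap)
  expect_error(gfe_at(g, c(0, NA, 0)), "finite")
})

test_that("gfe_at agrees with exhaustive voxel-center search on random points", {
  set.seed(11)
  g <- random_grid(dims = c(5L, 5L, 5L))
  lo <- g$origin - 0.4 * g$spacing
  hi <- g$origin + (g$dims - 0.6) * g$spacing
  for (k in 1:200) {
    p <- runif(3, lo, hi)
    expect_identical(gfe_at(g, p), oracle_gfe_at_scan(g, p))
  }
})

test_that("fragmap sets enforce geometric congruence", {
  g1 <- fragmap_grid(array(0, c(3, 3, 3)), map_type = "GENN")
  g2 <- fragmap_grid(array(0, c(3, 3, 3)), map_type = "GEND")
  expect_s3_class(fragmap_set(list(g1, g2)), "fragmap_set")
  g3 <- fragmap_grid(array(0, c(4, 3, 3)), map_type = "GENA")
  expect_error(fragmap_set(list(g1, g3)), "congruent")
  expect_error(fragmap_set(list()), "at least one")
  expect_error(fragmap_set(list(g1, g1)), "duplicate")
})
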