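test_that("a shapeless noise-free spec is a constant canvas with no edges", {
  spec <- phantom_spec(height = 20, width = 24, shapes = list(),
                       background = 77, salt_fraction = 0,
                       pepper_fraction = 0, gaussian_sigma = 0, seed = 1)
  ph <- generate_phantom(spec)
  expect_true(all(ph$clean == 77L))
  expect_identical(unclass(ph$noisy), unclass(ph$clean))
  expect_true(all(ph$edge_truth == 0L))
})

test_that("phantoms are bit-identical across runs and leave the RNG alone", {
  spec <- phantom_spec(height = 40, width = 40, seed = 123)
  set.seed(999)
  before <- stats::runif(1)
  set.seed(999)
  ph1 <- generate_phantom(spec)
  after <- stats::runif(1)
  expect_identical(before, after)  # generator did not consume global stream
  ph2 <- generate_phantom(spec)
  expect_identical(unclass(ph1$noisy), unclass(ph2$noisy))
  expect_identical(ph1$edge_truth, ph2$edge_truth)
  # different seed, different noise
  spec2 <- phantom_spec(height = 40, width = 40, seed = 124)
  expect_false(identical(unclass(generate_phantom(spec2)$noisy),
                         unclass(ph1$noisy)))
})

test_that("disk boundary matches an exhaustive 4-neighbor scan", {
  spec <- phantom_spec(height = 31, width = 31,
                       shapes = list(list(kind = "ellipse",
                                          center = c(16, 16),
                                          radii = c(8, 8), intensity = 200)),
                       background = 20, salt_fraction = 0,
                       pepper_fraction = 0, gaussian_sigma = 0, seed = 1)
  ph <- generate_phantom(spec)
  m <- unclass(ph$clean)
  truth <- matrix(0L, 31, 31)
  for (i in 1:31) for (j in 1:31) {
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      ii <- i + d[1]; jj <- j + d[2]
      if (ii >= 1 && ii <= 31 && jj >= 1 && jj <= 31 &&
          m[ii, jj] != m[i, j]) truth[i, j] <- 1L
    }
  }
  expect_identical(ph$edge_truth, truth)
  expect_gt(sum(truth), 0)
})

test_that("salt corruption count is binomially plausible", {
  spec <- phantom_spec(height = 100, width = 100, shapes = list(),
                       background = 128, salt_fraction = 0.05,
                       pepper_fraction = 0, gaussian_sigma = 0, seed = 7)
  ph <- generate_phantom(spec)
  n_salt <- sum(ph$noisy == 255L)
  sd3 <- 3 * sqrt(10000 * 0.05 * 0.95)
  expect_lt(abs(n_salt - 500), sd3)
})

test_that("spec validation rejects out-of-range noise and shapes", {
  expect_error(phantom_spec(salt_fraction = 0.6), "\\[0, 0.5\\]")
  expect_error(phantom_spec(gaussian_sigma = -1), ">= 0")
  bad <- phantom_spec(height = 20, width = 20,
                      shapes = list(list(kind = "ellipse", center = c(10, 10),
                                         radii = c(30, 30), intensity = 10)))
  expect_error(generate_phantom(bad), "out of bounds")
})

test_that("edge_map_score applies the 1-pixel tolerance ring conventions", {
  truth <- matrix(0L, 12, 12); truth[6, 3:10] <- 1L
  resp <- edge_response(truth * 200)
  sc <- edge_map_score(resp, truth, 100)
  expect_equal(unname(sc), c(1, 1))
  # all-zero prediction: precision 0 by convention
  sc0 <- edge_map_score(edge_response(matrix(0, 12, 12)), truth, 10)
  expect_equal(unname(sc0), c(0, 0))
  # complement of the truth: only pixels inside the ring can count
  comp <- edge_response((1L - truth) * 200)
  scc <- edge_map_score(comp, truth, 100)
  # 136 non-truth pixels, of which the 30-pixel ring around the segment
  # still matches; everything further away is a false positive
  expect_lt(scc[["precision"]], 0.25)
  # one-pixel-shifted prediction is fully forgiven by the ring
  shifted <- matrix(0L, 12, 12); shifted[7, 3:10] <- 1L
  scs <- edge_map_score(edge_response(shifted * 200), truth, 100)
  expect_equal(unname(scs), c(1, 1))
})

test_that("precision_at_recall finds a matched operating point", {
  ph <- generate_phantom(phantom_spec(height = 64, width = 64, seed = 3))
  se <- make_structuring_element(3, "isotropic")
  q <- combined_Q(ph$noisy, se)
  sc <- precision_at_recall(q, ph$edge_truth, target = 0.8)
  expect_gte(sc[["recall"]], 0.8)
  expect_gt(sc[["precision"]], 0)
})
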