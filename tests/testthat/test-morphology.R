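test_that("structuring elements follow the half-line / square definitions", {
  expect_error(make_structuring_element(4, "E"), "odd integer")
  expect_error(make_structuring_element(1, "E"), "odd integer")

  e3 <- make_structuring_element(3, "E")
  expect_identical(e3$offsets, matrix(c(0L, 0L, 0L, 1L), 2, 2, byrow = TRUE,
                                      dimnames = list(NULL, c("row", "col"))))
  n5 <- make_structuring_element(5, "N")
  expect_setequal(apply(n5$offsets, 1, paste, collapse = ","),
                  c("0,0", "-1,0", "-2,0"))
  iso3 <- make_structuring_element(3, "isotropic")
  expect_identical(nrow(iso3$offsets), 9L)

  for (dir in all_directions) {
    for (s in c(3L, 5L, 7L)) {
      se <- make_structuring_element(s, dir)
      # anchor in support, all offsets inside the scale x scale box
      expect_true(any(se$offsets[, 1] == 0 & se$offsets[, 2] == 0))
      expect_true(all(abs(se$offsets) <= (s - 1) / 2))
      expect_identical(nrow(se$offsets),
                       if (dir == "isotropic") s * s else (s + 1L) %/% 2L)
    }
  }
})

test_that("erode and dilate match the exhaustive neighborhood oracle", {
  for (seed in 1:6) {
    img <- random_gray(10, 12, seed)
    m <- matrix(as.numeric(img), 10, 12)
    for (dir in c("isotropic", "E", "NW", "S")) {
      for (s in c(3, 5)) {
        se <- make_structuring_element(s, dir)
        expect_equal(erode(img, se), oracle_erode(m, se), tolerance = 0)
        expect_equal(dilate(img, se), oracle_dilate(m, se), tolerance = 0)
      }
    }
  }
})

test_that("constant and impulse images behave as the definitions force", {
  const <- gray_image(matrix(42L, 6, 6))
  iso <- make_structuring_element(3, "isotropic")
  expect_true(all(erode(const, iso) == 42))
  expect_true(all(dilate(const, iso) == 42))

  imp <- matrix(0L, 7, 7); imp[4, 4] <- 255L
  imp <- gray_image(imp)
  expect_true(all(erode(imp, iso) == 0))          # min absorbs the impulse
  d <- dilate(imp, iso)
  expect_identical(sum(d == 255), 9L)             # 3x3 block of 255
  expect_true(all(d[3:5, 3:5] == 255))
  expect_true(all(open_(imp, iso) == 0))          # opening removes salt
  pep <- gray_image(255L - unclass(imp))
  expect_true(all(close_(pep, iso) == 255))       # closing removes pepper
})

test_that("opening and closing are idempotent", {
  for (seed in 1:4) {
    img <- random_gray(9, 9, seed + 20)
    for (dir in c("isotropic", "E", "S")) {
      se <- make_structuring_element(3, dir)
      o <- open_(img, se)
      expect_equal(open_(o, se), o, tolerance = 0)
      cl <- close_(img, se)
      expect_equal(close_(cl, se), cl, tolerance = 0)
    }
    # diagonal one-sided elements: idempotent away from the border frame,
    # where replicate clamping into corners breaks the adjunction
    se <- make_structuring_element(3, "NE")
    o <- open_(img, se)
    expect_equal(open_(o, se)[2:8, 2:8], o[2:8, 2:8], tolerance = 0)
  }
})

test_that("the morphological ordering chain holds pixelwise", {
  for (seed in 1:25) {
    img <- random_gray(12, 12, seed + 100)
    m <- matrix(as.numeric(img), 12, 12)
    for (s in c(3, 5)) {
      se <- make_structuring_element(s, "isotropic")
      d <- dilate(img, se); cl <- close_(img, se)
      op <- open_(img, se); er <- erode(img, se)
      expect_true(all(d >= cl & cl >= m & m >= op & op >= er))
    }
  }
})

test_that("dilation is the reflected dual of erosion", {
  for (seed in 1:10) {
    img <- random_gray(10, 10, seed + 300)
    for (dir in c("isotropic", "E", "SW", "N")) {
      se <- make_structuring_element(3, dir)
      neg <- gray_image(255L - unclass(img))
      expect_equal(dilate(img, se), 255 - erode(neg, reflect_se(se)),
                   tolerance = 0)
    }
  }
})

test_that("gradient operators p1..p6 match their defining compositions", {
  expect_error(gradient_p(random_gray(5, 5, 1),
                          make_structuring_element(3, "E"), 7), "1\\.\\.6")
  for (seed in 1:5) {
    img <- random_gray(9, 11, seed + 40)
    m <- matrix(as.numeric(img), 9, 11)
    for (dir in c("isotropic", "SE")) {
      se <- make_structuring_element(3, dir)
      d <- oracle_dilate(m, se); er <- oracle_erode(m, se)
      op <- oracle_open(m, se); cl <- oracle_close(m, se)
      expected <- list(d - m, m - er, d - er, pmax(m - op, 0),
                       pmax(cl - m, 0), pmax(cl - op, 0))
      for (k in 1:6) {
        resp <- gradient_p(img, se, k)
        expect_equal(resp$values, expected[[k]], tolerance = 0)
        expect_true(all(resp$values >= 0))
      }
      # algebraic identities
      p <- lapply(1:6, function(k) gradient_p(img, se, k)$values)
      expect_equal(p[[3]], p[[1]] + p[[2]], tolerance = 0)
      expect_true(all(p[[6]] <= p[[3]]))
    }
  }
})

test_that("constant images yield zero response for every operator", {
  const <- gray_image(matrix(99L, 8, 8))
  se <- make_structuring_element(3, "isotropic")
  for (k in 1:6) expect_true(all(gradient_p(const, se, k)$values == 0))
  for (k in 1:2) expect_true(all(gradient_q(const, se, k)$values == 0))
  expect_true(all(combined_Q(const, se)$values == 0))
})

test_that("cascaded q1/q2 match oracle compositions and suppress impulses", {
  expect_error(gradient_q(random_gray(5, 5, 1),
                          make_structuring_element(3, "E"), 3), "1 or 2")
  for (seed in 1:5) {
    img <- random_gray(10, 10, seed + 60)
    m <- matrix(as.numeric(img), 10, 10)
    for (dir in c("isotropic", "W", "NE")) {
      for (s in c(3, 5)) {
        se <- make_structuring_element(s, dir)
        cg <- oracle_close(m, se)
        og <- oracle_open(m, se)
        expect_equal(gradient_q(img, se, 1)$values,
                     oracle_open(cg, se) - oracle_erode(cg, se),
                     tolerance = 0)
        expect_equal(gradient_q(img, se, 2)$values,
                     oracle_dilate(og, se) - oracle_close(og, se),
                     tolerance = 0)
      }
    }
  }
  # single salt pixel: q2 opens it away before differencing
  imp <- matrix(10L, 9, 9); imp[5, 5] <- 255L
  imp <- gray_image(imp)
  iso <- make_structuring_element(3, "isotropic")
  expect_identical(gradient_q(imp, iso, 2)$values[5, 5], 0)
  p3 <- gradient_p(imp, iso, 3)$values
  expect_gt(p3[5, 5], 0)  # the plain gradient fires on the same impulse
})

test_that("step edges localize: q responses live within one SE width", {
  m <- matrix(0L, 12, 12); m[, 7:12] <- 200L
  img <- gray_image(m)
  iso <- make_structuring_element(3, "isotropic")
  p3 <- gradient_p(img, iso, 3)$values
  expect_true(all(p3[, 6:7] == 200))
  expect_true(all(p3[, c(1:4, 9:12)] == 0))
  for (k in 1:2) {
    q <- gradient_q(img, iso, k)$values
    expect_true(all(q[, c(1:3, 10:12)] == 0))
    expect_gt(max(q), 0)
  }
})

test_that("combined Q is the stated convex combination of q1 and q2", {
  expect_error(operator_params(0.7, 0.7), "equal 1")
  expect_error(operator_params(-0.1, 1.1), "\\[0, 1\\]")
  img <- random_gray(9, 9, 77)
  se <- make_structuring_element(3, "isotropic")
  q1 <- gradient_q(img, se, 1)$values
  q2 <- gradient_q(img, se, 2)$values
  expect_equal(combined_Q(img, se, operator_params(1, 0))$values,
               pmax(q1, q2), tolerance = 0)
  expect_equal(combined_Q(img, se, operator_params(0.5, 0.5))$values,
               (q1 + q2) / 2, tolerance = 0)
})
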