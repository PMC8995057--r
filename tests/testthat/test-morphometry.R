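test_that("Otsu separates two-level images and rejects constant ones", {
  img <- gray_image(matrix(c(rep(0, 8), rep(255, 8)), 4, 4), bit_depth = 8)
  expect_identical(plain_mat(binarize_otsu(img)),
                   matrix(as.integer(img == 255), 4, 4))
  img2 <- gray_image(matrix(c(rep(10, 8), rep(200, 8)), 4, 4))
  t2 <- otsu_threshold(img2)
  expect_gte(t2, 10); expect_lt(t2, 200)
  expect_identical(plain_mat(binarize_otsu(img2)),
                   matrix(as.integer(img2 == 200), 4, 4))
  expect_error(otsu_threshold(matrix(100, 5, 5)), "degenerate")
})

test_that("Otsu equals the exhaustive between-class-variance argmax", {
  set.seed(10)
  for (i in 1:30) {
    img <- matrix(sample(0:255, 64 * 64, replace = TRUE,
                         prob = runif(256)^2), 64, 64)
    expect_identical(otsu_threshold(img), oracle_otsu(img))
  }
})

test_that("invert flag swaps the phases", {
  img <- gray_image(matrix(c(rep(10, 8), rep(200, 8)), 4, 4))
  expect_identical(plain_mat(binarize_otsu(img, invert = TRUE)),
                   matrix(as.integer(img == 10), 4, 4))
})

test_that("clean removes isolated pixels; majority follows the 5-of-9 rule", {
  m <- binary_mask(matrix(0L, 9, 9)); m[5, 5] <- 1L
  expect_equal(sum(morphological_clean(m)), 0)
  # solid block: interior is a fixed point; under zero padding the four
  # corners see only 4 of 9 silver pixels and flip
  solid <- binary_mask(matrix(1L, 7, 7))
  expected_solid <- matrix(1L, 7, 7)
  expected_solid[cbind(c(1, 1, 7, 7), c(1, 7, 1, 7))] <- 0L
  expect_equal(plain_mat(morphological_clean(solid)), expected_solid)
  expect_true(all(plain_mat(morphological_clean(solid))[2:6, 2:6] == 1L))
  # direct evaluation of the majority rule on a random mask with the
  # isolated pixels already removed
  set.seed(3)
  r <- matrix(rbinom(15 * 15, 1, 0.5), 15, 15)
  got <- morphological_clean(binary_mask(r))
  ns <- matrix(0L, 15, 15)
  r2 <- r
  for (i in 1:15) for (j in 1:15) {
    nb <- r[max(1, i - 1):min(15, i + 1), max(1, j - 1):min(15, j + 1)]
    if (r[i, j] == 1L && sum(nb) == 1L) r2[i, j] <- 0L  # 'clean'
  }
  expected <- matrix(0L, 15, 15)
  for (i in 1:15) for (j in 1:15) {
    nb <- r2[max(1, i - 1):min(15, i + 1), max(1, j - 1):min(15, j + 1)]
    expected[i, j] <- as.integer(sum(nb) >= 5L)  # zero-padded 'majority'
  }
  expect_identical(plain_mat(got), expected)
})

test_that("distance transform matches the brute-force oracle exactly", {
  all_silver <- binary_mask(matrix(1L, 8, 8))
  expect_true(all(distance_transform(all_silver) == 0))
  m <- binary_mask(matrix(0L, 9, 9)); m[5, 5] <- 1L
  d <- distance_transform(m)
  expect_equal(d[5, 6], 1)  # 4-adjacent gap pixel
  expect_equal(d[1, 1], sqrt(32))
  # 7x7 gap square surrounded by silver: center is 4 px from silver
  sq <- matrix(1L, 9, 9); sq[2:8, 2:8] <- 0L
  expect_equal(distance_transform(binary_mask(sq))[5, 5], 4)
  for (s in 1:6) {
    rm <- random_blob_mask(n = 64, seed = 100 + s)
    expect_equal(unname(distance_transform(rm)[, ]), oracle_distmap(rm))
  }
  expect_error(distance_transform(binary_mask(matrix(0L, 4, 4))),
               "all-gap")
})

test_that("gap skeleton is medial, unit-width, and inside the gap phase", {
  # 5-px-wide vertical gap stripe -> single center column
  m <- stripe_mask(5, height = 40, slab = 10)
  sk <- skeletonize_gaps(m)
  hit <- which(sk, arr.ind = TRUE)
  expect_identical(unique(hit[, 2]), 13L)  # center of columns 11..15
  expect_true(all(unclass(m)[sk] == 0L))
  # a gap phase already 1 px wide is its own skeleton
  line <- matrix(1L, 20, 9); line[, 5] <- 0L
  skl <- skeletonize_gaps(binary_mask(line))
  expect_identical(which(skl, arr.ind = TRUE)[, 2], rep(5L, 20L))
  # all-silver mask -> empty skeleton
  expect_equal(sum(skeletonize_gaps(binary_mask(matrix(1L, 6, 6)))), 0)
})

test_that("skeletonization preserves the Euler number of the gap phase", {
  for (s in 1:12) {
    m <- random_blob_mask(n = 72, seed = 200 + s)
    gap <- unclass(m) == 0L
    sk <- skeletonize_gaps(m)
    expect_identical(euler_number(sk, 4), euler_number(gap, 4))
  }
})

test_that("Euler quad-count formula agrees with flood-fill counting", {
  for (s in 1:8) {
    m <- random_blob_mask(n = 48, seed = 300 + s)
    fg <- unclass(m) == 1L
    expect_identical(euler_number(fg, 4), oracle_euler(fg, 4))
    expect_identical(euler_number(fg, 8), oracle_euler(fg, 8))
  }
})

test_that("gap distances read twice the medial EDT, border excluded", {
  m <- stripe_mask(5, height = 40, slab = 10)
  sk <- skeletonize_gaps(m)
  dm <- distance_transform(m)
  d <- gap_distances(sk, dm)
  expect_true(all(d == 6))           # 2 x 3 px
  expect_length(d, 38L)              # 40 rows minus the 2 border pixels
  dn <- gap_distances(sk, dm, pixel_size = 2, units = "nm")
  expect_true(all(dn == 12))
  empty <- skeletonize_gaps(binary_mask(matrix(1L, 8, 8)))
  expect_warning(d0 <- gap_distances(empty, distance_transform(
    binary_mask(matrix(1L, 8, 8)))), "empty")
  expect_length(d0, 0L)
})

test_that("stripe phantoms give the w + 1 px statistic at every width", {
  for (w in c(3, 5, 7, 9, 15)) {
    m <- stripe_mask(w, height = 50, slab = 12)
    d <- gap_distances(skeletonize_gaps(m), distance_transform(m))
    expect_true(all(d == w + 1), info = paste("width", w))
  }
})

test_that("gamma MLE recovers parameters and rejects degenerate samples", {
  set.seed(99)
  x <- rgamma(1e5, shape = 2, scale = 3)
  f <- fit_gamma(x)
  expect_lt(abs(f$shape - 2) / 2, 0.05)
  expect_lt(abs(f$scale - 3) / 3, 0.05)
  expect_identical(f$n, 100000L)
  # exponential special case: shape 1
  e <- fit_gamma(rexp(5e4, rate = 0.25))
  expect_lt(abs(e$shape - 1), 0.05)
  expect_error(fit_gamma(rep(2, 50)), "variance")
  expect_error(fit_gamma(rgamma(5, 2)), "at least 10")
})

test_that("coverage fractions and component counts are exact", {
  expect_equal(coverage(binary_mask(matrix(1L, 5, 5)))$fraction, 1)
  expect_equal(coverage(binary_mask(matrix(0L, 5, 5)))$fraction, 0)
  chk <- binary_mask(outer(1:8, 1:8, function(i, j) (i + j) %% 2L))
  expect_equal(coverage(chk)$fraction, 0.5)
  # diagonal silver pixels: one 8-connected component
  expect_identical(coverage(chk)$silver_components, 1L)
  # but the gap phase under 4-connectivity is fully fragmented
  expect_identical(coverage(chk)$gap_components, 32L)
})

test_that("regime classification follows the spanning/share rules", {
  expect_identical(classify_regime(mask = binary_mask(matrix(1L, 10, 10)))$
                     label, "continuous")
  disks <- matrix(0L, 40, 40)
  for (c0 in list(c(8, 8), c(8, 30), c(30, 19))) {
    sel <- (row(disks) - c0[1])^2 + (col(disks) - c0[2])^2 <= 9
    disks[sel] <- 1L
  }
  expect_identical(classify_regime(mask = binary_mask(disks))$label,
                   "discrete")
  gp <- growth_params(field_size = c(96, 96), seed_density = 250,
                      target_coverage = 0.6, rng_seed = 21)
  semi <- grow_islands(simulate_seed_field(gp), gp)
  r <- classify_regime(mask = semi)
  expect_identical(r$label, "semi-continuous")
  expect_true(r$spanning || r$largest_component_share >= 0.5)
})

test_that("the full morphometry chain is deterministic", {
  m <- random_blob_mask(n = 72, seed = 17)
  img <- render_sem(m, render_params(noise_sd = 5), rng_seed = 23)
  r1 <- analyze_gaps(img)
  r2 <- analyze_gaps(img)
  expect_identical(as.numeric(r1$distances), as.numeric(r2$distances))
  expect_identical(r1$regime$label, r2$regime$label)
})

test_that("gap profiles pool correctly and order by true gap width", {
  m <- stripe_mask(5, height = 60, slab = 12)
  m2 <- random_blob_mask(n = 64, seed = 31)
  p <- gap_profile(list(m2, m2), c("a", "b"))
  expect_equal(p$fits$a$shape, p$fits$b$shape)
  expect_equal(p$fits$a$scale, p$fits$b$scale)
  # single-mask label fit equals fit_gamma of that mask's sample
  d <- gap_distances(skeletonize_gaps(m2), distance_transform(m2))
  expect_equal(p$fits$a$shape, fit_gamma(d)$shape)
  # upscaling a mask doubles every gap width: fitted means must order
  big <- binary_mask(kronecker(unclass(m2), matrix(1L, 2, 2)))
  wide <- gap_profile(list(big), "wide")
  mean_of <- function(f) f$shape * f$scale
  expect_lt(mean_of(p$fits$a), mean_of(wide$fits$wide))
})
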