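test_that("foreground thresholding uses a strict inequality", {
  m <- matrix(0.8, 4, 4)
  expect_true(all(threshold_foreground(m, "fixed", fixed_threshold = 0.5)))
  expect_false(any(threshold_foreground(m, "fixed", fixed_threshold = 0.8)))
  m2 <- matrix(c(0.1, 0.9, 0.9, 0.1), 2, 2, byrow = TRUE)
  expect_identical(unname(which(threshold_foreground(m2, "fixed",
                                                     fixed_threshold = 0.5))),
                   which(m2 > 0.5))
  expect_error(threshold_foreground(m, "fixed"), "fixed_threshold")
})

test_that("Otsu separates a clearly bimodal OD channel", {
  set.seed(3)
  m <- matrix(abs(rnorm(400, 0.02, 0.01)), 20, 20)
  m[5:10, 5:10] <- rnorm(36, 0.8, 0.02)
  fg <- threshold_foreground(m, "otsu")
  expect_true(all(fg[5:10, 5:10]))
  expect_false(any(fg[15:20, 15:20]))
  thr <- attr(fg, "threshold")
  expect_gt(thr, 0.05); expect_lt(thr, 0.75)
})

test_that("segmentation under a scaled channel matches a scaled fixed threshold", {
  set.seed(4)
  m <- matrix(abs(rnorm(256, 0.02, 0.01)), 16, 16)
  m[4:8, 4:8] <- 0.7
  f1 <- threshold_foreground(m, "fixed", fixed_threshold = 0.3)
  f2 <- threshold_foreground(3 * m, "fixed", fixed_threshold = 0.9)
  expect_equal(unclass(f1), unclass(f2), ignore_attr = TRUE)
})

test_that("distance map matches the spec'd degenerate conventions", {
  z <- compute_distance_map(matrix(FALSE, 3, 3))
  expect_equal(unclass(z), matrix(0, 3, 3), ignore_attr = TRUE)
  one <- matrix(FALSE, 5, 5); one[3, 3] <- TRUE
  d <- compute_distance_map(one)
  expect_equal(d[3, 3], 1)
  expect_equal(sum(d), 1)
  expect_equal(attr(d, "raw_max"), 1)
  allfg <- compute_distance_map(matrix(TRUE, 4, 4))
  expect_true(all(allfg == 1))
})

test_that("distance map normalises the hand-derived 1x5 strip", {
  m <- matrix(c(FALSE, TRUE, TRUE, TRUE, FALSE), 1, 5)
  d <- compute_distance_map(m)
  expect_equal(as.numeric(d), c(0, 0.5, 1, 0.5, 0))
  expect_equal(attr(d, "raw_max"), 2)
})

test_that("raw distances agree exactly with brute-force nearest-zero search", {
  set.seed(5)
  for (k in 1:15) {
    H <- sample(2:20, 1); W <- sample(2:20, 1)
    m <- matrix(runif(H * W) < 0.6, H, W)
    if (!any(m) || all(m)) next
    d <- compute_distance_map(m)
    raw <- d * attr(d, "raw_max")
    expect_equal(unclass(raw), brute_force_edt(m), ignore_attr = TRUE)
  }
})

test_that("seed detection finds isolated peaks and suppresses close ones", {
  # two discs 20 px apart: two seeds at the disc centres
  m <- disc_mask(30, 44, rbind(c(15, 12), c(15, 32)), 6)
  d <- compute_distance_map(m)
  s <- detect_seeds(d, min_distance = 10, min_height = 0.2)
  expect_equal(nrow(s), 2)
  expect_true(all(abs(s[, 1] - 15) <= 1))
  expect_true(all(abs(sort(s[, 2]) - c(12, 32)) <= 1))
  # with min_distance spanning both discs, only the first peak survives
  s1 <- detect_seeds(d, min_distance = 30, min_height = 0.2)
  expect_equal(nrow(s1), 1)
  expect_error(detect_seeds(d, min_distance = 0), ">= 1")
})

test_that("an equal-valued plateau yields one topmost-leftmost seed", {
  d <- matrix(0, 5, 5)
  d[2:4, 2:4] <- 1
  s <- detect_seeds(d, min_distance = 1, min_height = 0.5)
  expect_equal(nrow(s), 1)
  expect_equal(as.numeric(s[1, ]), c(2, 2))
})

test_that("seed detection agrees with exhaustive local-maxima search", {
  # smooth two-bump surface without plateaus
  H <- 21; W <- 35
  g <- function(r0, c0) outer(1:H, 1:W, function(r, c)
    exp(-((r - r0)^2 + (c - c0)^2) / 18))
  d <- g(10, 9) + 0.8 * g(12, 27)
  d <- d / max(d)
  ref <- brute_force_peaks(d, min_height = 0.1)
  s <- detect_seeds(d, min_distance = 5, min_height = 0.1)
  expect_equal(nrow(s), nrow(ref))
  expect_setequal(paste(s[, 1], s[, 2]), paste(ref[, 1], ref[, 2]))
})

test_that("watershed labels a single blob from a single seed", {
  m <- disc_mask(15, 15, rbind(c(8, 8)), 5)
  d <- compute_distance_map(m)
  lab <- watershed_segment(d, cbind(8L, 8L), m)
  expect_equal(sort(unique(as.vector(lab))), c(0L, 1L))
  expect_true(all((lab > 0) == m))
})

test_that("disjoint blobs keep their own seed's label", {
  m <- disc_mask(20, 40, rbind(c(10, 10), c(10, 30)), 5)
  d <- compute_distance_map(m)
  lab <- watershed_segment(d, rbind(c(10L, 10L), c(10L, 30L)), m)
  expect_equal(max(lab), 2L)
  expect_true(all(lab[m & col(m) < 20] == 1L))
  expect_true(all(lab[m & col(m) >= 20] == 2L))
  expect_true(all((lab > 0) == m))
})

test_that("a dumbbell splits into two labels partitioning the foreground", {
  m <- disc_mask(21, 41, rbind(c(11, 10), c(11, 31)), 6)
  m[11, 10:31] <- TRUE # 1-px bridge
  d <- compute_distance_map(m)
  s <- detect_seeds(d, min_distance = 10, min_height = 0.3)
  expect_equal(nrow(s), 2)
  lab <- watershed_segment(d, s, m)
  expect_equal(max(lab), 2L)
  expect_true(all((lab > 0) == m))            # partition: label>0 <=> mask
  expect_equal(lab[11, 10], lab[cbind(s[1, 1], s[1, 2])])
  # each disc centre belongs to the seed sitting in it
  expect_false(lab[11, 10] == lab[11, 31])
})

test_that("watershed tie-breaks contested equal-height pixels by seed order", {
  # 1 x 7 strip, two height-3 seeds; the middle valley pixel goes to seed 1
  d <- matrix(c(1, 2, 3, 1, 3, 2, 1) / 3, 1, 7)
  m <- matrix(TRUE, 1, 7)
  lab <- watershed_segment(d, rbind(c(1L, 3L), c(1L, 5L)), m)
  expect_equal(as.integer(lab), c(1L, 1L, 1L, 1L, 2L, 2L, 2L))
})

test_that("watershed with no seeds warns and returns an empty label map", {
  m <- matrix(TRUE, 3, 3)
  d <- compute_distance_map(m)
  expect_warning(lab <- watershed_segment(d, matrix(integer(0), 0, 2), m),
                 "no seeds")
  expect_true(all(lab == 0L))
})

test_that("nucleus size filtering drops out-of-range objects and renumbers", {
  lab <- matrix(0L, 80, 80)
  lab[1:3, 1] <- 1L                # area 3
  lab[10:14, 10:19] <- 2L          # area 50
  lab[21:70, 21:70] <- 3L          # area 2500
  out <- filter_nuclei(lab, min_area = 10, max_area = 2000)
  expect_equal(max(out), 1L)
  expect_true(all(out[10:14, 10:19] == 1L))
  expect_true(all(out[1:3, 1] == 0L))
  expect_identical(filter_nuclei(lab, 0, Inf), lab)
  expect_error(filter_nuclei(lab, 10, 5), "min_area")
})

test_that("debris specks are removed while true nuclei survive", {
  sim <- simulate_roi_image(simulation_config(n_nuclei = 20, n_debris = 30,
                                              width = 320, height = 320,
                                              seed = 99))
  ch <- separate_stains(rgb_to_od(sim$image), mpp = sim$image$mpp)
  lab <- segment_nuclei(ch)
  expect_equal(max(lab), 20L)
})

test_that("watershed output always partitions the thresholded foreground", {
  sim <- simulate_roi_image(clean_sim_config(seed = 17, n_nuclei = 30))
  ch <- separate_stains(rgb_to_od(sim$image), mpp = sim$image$mpp)
  mask <- threshold_foreground(ch$hematoxylin)
  d <- compute_distance_map(mask)
  s <- detect_seeds(d)
  lab <- watershed_segment(d, s, mask)
  expect_true(all(lab[!mask] == 0L))
  expect_equal(max(lab), nrow(s))
  # every seed kept its own label
  expect_identical(lab[s], seq_len(nrow(s)))
})
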