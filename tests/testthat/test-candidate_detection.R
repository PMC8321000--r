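test_that("inner structures are the bright spots inside the lung mask", {
  img <- matrix(0L, 40, 40)
  lung <- draw_disc(40, 40, 20, 20, 15)
  img[lung] <- 40L
  disc <- draw_disc(40, 40, 20, 20, 5)
  img[disc] <- 220L
  st <- extract_inner_structures(img, lung)
  expect_identical(st, disc & lung)

  expect_warning(st0 <- extract_inner_structures(img, matrix(FALSE, 40, 40)),
                 "empty")
  expect_false(any(st0))
  flat <- matrix(0L, 40, 40); flat[lung] <- 40L
  expect_warning(stc <- extract_inner_structures(flat, lung), "constant")
  expect_false(any(stc))
})

test_that("structure masks are always subsets of the lung mask", {
  for (seed in 1:3) {
    ph <- generate_stack(phantom_config(seed = seed, n_slices = 1))
    seg <- segment_lungs(ph$stack$slices[[1]])
    st <- extract_inner_structures(seg$lung_image, seg$mask)
    expect_true(all(seg$mask$mask[st]))
  }
})

test_that("filled discs pass the circularity gate with accurate centers", {
  m <- draw_disc(64, 64, 31, 33, 10)
  cands <- detect_round_centers(m)
  expect_equal(nrow(cands), 1L)
  expect_gte(cands$circularity, 0.85)
  expect_lte(abs(cands$center_r - 31), 1)
  expect_lte(abs(cands$center_c - 33), 1)

  # per-component independence: two disjoint discs give two candidates
  m2 <- draw_disc(64, 64, 16, 16, 6) | draw_disc(64, 64, 45, 45, 8)
  c2 <- detect_round_centers(m2)
  expect_equal(nrow(c2), 2L)
  expect_gt(sum(abs(c2$center_r[1] - c2$center_r[2]),
                abs(c2$center_c[1] - c2$center_c[2])), 10)
})

test_that("elongated bars fall far below the circularity gate", {
  bar <- matrix(FALSE, 50, 50)
  bar[10:12, 5:44] <- TRUE # 3 x 40
  expect_equal(nrow(detect_round_centers(bar)), 0L)
  lab <- lungcad:::.label_components_cpp(bar)
  st <- lungcad:::.component_stats_cpp(lab, 1L)
  circ <- 4 * pi * st$area / st$perimeter^2
  # analytic circularity of a 3 x 40 rectangle is ~0.2
  expect_lte(circ, 0.4)
  expect_gte(circ, 0.1)
})

test_that("digital discs score >= 0.85 and long bars <= 0.4 across sizes", {
  for (r in c(5, 10, 20, 50)) {
    side <- 2 * r + 9
    m <- draw_disc(side, side, (side + 1) / 2, (side + 1) / 2, r)
    cands <- detect_round_centers(m)
    expect_equal(nrow(cands), 1L)
    expect_gte(cands$circularity, 0.85)
    expect_lte(cands$circularity, 1)
  }
  # a w x l rectangle has circularity 4*pi*wl/(2(w+l))^2: ~0.44 at aspect 5,
  # falling to ~0.26 at aspect 10; the digital chain-code perimeter measures
  # slightly rounder for thin bars, but stays below the 0.6 candidate gate at
  # aspect >= 5 (width >= 3 px) and below 0.4 at aspect >= 10
  for (w in c(3, 4, 8)) {
    for (aspect in c(5, 10)) {
      len <- aspect * w
      bar <- matrix(FALSE, len + 10, len + 10)
      bar[5:(4 + w), 5:(4 + len)] <- TRUE
      lab <- lungcad:::.label_components_cpp(bar)
      st <- lungcad:::.component_stats_cpp(lab, 1L)
      circ <- 4 * pi * st$area / st$perimeter^2
      expect_lt(circ, 0.6)
      if (aspect >= 10) expect_lte(circ, 0.4)
      expect_equal(nrow(detect_round_centers(bar)), 0L)
    }
  }
})

test_that("region growing absorbs a uniform blob and nothing else", {
  img <- matrix(40L, 30, 30)
  blob <- draw_disc(30, 30, 15, 15, 6)
  img[blob] <- 200L # background gap 160/255 = 0.63 > 0.18
  mask <- matrix(TRUE, 30, 30)
  reg <- grow_region(img, c(15, 15), mask, 0.18)
  expect_identical(reg$region, blob)
  expect_equal(reg$area, sum(blob))
})

test_that("max_distance 0 keeps only a unique-valued seed", {
  img <- matrix(40L, 20, 20)
  img[10, 10] <- 200L
  reg <- grow_region(img, c(10, 10), matrix(TRUE, 20, 20), 0)
  expect_equal(reg$pixels, which(img == 200L))
  expect_error(grow_region(img, c(5, 5), matrix(FALSE, 20, 20), 0.18),
               "seed")
})

test_that("two-level blobs match the reference breadth-first grower", {
  img <- matrix(40L, 40, 40)
  rim <- draw_disc(40, 40, 20, 20, 9)
  core <- draw_disc(40, 40, 20, 20, 5)
  img[rim] <- 180L
  img[core] <- 200L # normalized core-rim gap 20/255 = 0.078 <= 0.18
  mask <- matrix(TRUE, 40, 40)
  reg <- grow_region(img, c(20, 20), mask, 0.18)
  expect_identical(reg$region, rim) # core union rim
  ref <- oracle_grow(img, mask, c(20, 20), 0.18)
  expect_identical(reg$region, ref)

  # determinism and the reference agreement on irregular images
  set.seed(44)
  for (i in 1:5) {
    img2 <- matrix(sample(c(40:60, 190:210), 400, replace = TRUE), 20, 20)
    r1 <- grow_region(img2, c(10, 10), mask[1:20, 1:20], 0.12)
    r2 <- grow_region(img2, c(10, 10), mask[1:20, 1:20], 0.12)
    expect_identical(r1$region, r2$region)
    expect_identical(r1$region, oracle_grow(img2, mask[1:20, 1:20],
                                            c(10, 10), 0.12))
  }
})

test_that("growing with a larger distance yields a superset on the fixtures", {
  # nestedness is checked empirically on layered-blob fixtures; it is not a
  # theorem under a running-mean rule, so pure-noise images are not asserted
  set.seed(55)
  mask <- matrix(TRUE, 41, 41)
  for (i in 1:8) {
    img <- matrix(40L, 41, 41)
    levels <- sort(sample(150:230, 4), decreasing = TRUE)
    for (k in seq_along(levels)) {
      ring <- draw_disc(41, 41, 21, 21, 3 + 3 * k)
      img[ring & img == 40L] <- levels[k]
    }
    prev <- NULL
    for (d in c(0.02, 0.05, 0.1, 0.18, 0.4)) {
      reg <- grow_region(img, c(21, 21), mask, d)
      if (!is.null(prev)) expect_true(all(reg$region[prev]))
      prev <- reg$region
    }
  }
})

test_that("candidate regions stay inside the lung mask on phantom slices", {
  ph <- generate_stack(phantom_config(seed = 8))
  sl <- ph$stack$slices[[5]]
  seg <- segment_lungs(sl)
  cands <- detect_candidates(sl, seg)
  expect_gt(length(cands), 0L)
  for (x in cands) {
    expect_true(all(seg$mask$mask[x$region$pixels]))
    expect_gte(x$region$area, 1)
  }
  # the planted nodules present on this slice are among the candidates
  nod <- ph$truth$nodules[ph$truth$nodules$slice_index == 5, ]
  centers <- do.call(rbind, lapply(cands, function(x)
    c(x$candidate$center_r, x$candidate$center_c)))
  for (i in seq_len(nrow(nod))) {
    d <- sqrt((centers[, 1] - nod$center_r[i])^2 +
              (centers[, 2] - nod$center_c[i])^2)
    expect_lte(min(d), nod$radius_px[i])
  }
})

test_that("seeds growing to the same region are deduplicated", {
  # two bright discs bridged by a slightly dimmer neck: the structure mask
  # splits them, but growth crosses the neck from either seed
  img <- matrix(0L, 40, 60)
  a <- draw_disc(40, 60, 20, 18, 6)
  b <- draw_disc(40, 60, 20, 42, 6)
  neck <- matrix(FALSE, 40, 60)
  neck[19:21, 20:40] <- TRUE
  img[neck] <- 165L # |165 - 200| / 255 = 0.137 <= 0.18
  img[a] <- 200L
  img[b] <- 200L
  mask <- a | b | neck
  lung_mask <- structure(list(mask = mask, empty = FALSE), class = "lung_mask")
  seg <- list(mask = lung_mask, lung_image = img,
              thresholds = list(lambda = 0, tau = 0, lambda_source = "x"))
  st <- extract_inner_structures(img, lung_mask)
  expect_equal(attr(lungcad:::.label_components_cpp(st), "n_components"), 2L)
  cands <- detect_candidates(grayscale_slice(img), seg)
  expect_equal(length(cands), 1L)
  expect_true(all(cands[[1]]$region$region[a | b]))

  empty_img <- matrix(0L, 40, 60); empty_img[mask] <- 40L
  empty_seg <- list(mask = lung_mask, lung_image = empty_img,
                    thresholds = list(lambda = 0, tau = 0, lambda_source = "x"))
  expect_equal(length(suppressWarnings(
    detect_candidates(grayscale_slice(empty_img), empty_seg))), 0L)
})
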