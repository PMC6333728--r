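make_hot_sphere <- function(dm = c(24, 24, 24), ctr = c(12, 12, 12),
                            r_vox = 6, bg = 1, hot = 10, spacing = c(4, 4, 4)) {
  m <- sphere_mask(dm, ctr, r_vox)
  v <- array(bg, dm); v[m] <- hot
  list(vol = pet_volume(v, spacing), truth = m, ctr = ctr)
}

test_that("40% threshold on a hard-edged sphere recovers the truth volume", {
  ph <- make_hot_sphere()
  seg <- threshold_segment(ph$vol, seed = ph$ctr)
  ## brute force: voxels >= 0.4 * max, component of the seed
  expect_equal(sum(seg$mask), sum(ph$vol$voxels >= 0.4 * 10 &
                                  ph$vol$voxels == 10))
  expect_identical(seg$mask, ph$truth)
  expect_equal(seg$threshold_fraction_used, 0.40)
})

test_that("near-1 threshold isolates the unique maximum voxel", {
  ph <- make_hot_sphere()
  v <- ph$vol$voxels
  v[12, 12, 12] <- 12      # unique max
  vol <- pet_volume(v, ph$vol$spacing)
  seg <- threshold_segment(vol, seed = c(12, 12, 12),
                           fraction = 0.999)
  expect_equal(sum(seg$mask), 1)
  expect_true(seg$mask[12, 12, 12])
})

test_that("uniform volume segments to the whole grid at any fraction", {
  vol <- pet_volume(array(5, c(6, 6, 6)), c(4, 4, 4))
  seg <- threshold_segment(vol, seed = c(3, 3, 3), fraction = 0.9)
  expect_equal(sum(seg$mask), 216)
})

test_that("lowering the threshold never shrinks the mask", {
  set.seed(7)
  for (i in 1:12) {
    ph <- make_phantom(phantom_spec(grid_shape = c(20, 20, 20),
                                    tumor_radius_mm = 16,
                                    texture_amplitude = 2,
                                    noise_sd = 0.2, seed = i))
    seed <- arrayInd(which.max(ph$volume$voxels), dim(ph$volume$voxels))[1, ]
    prev <- NULL
    for (f in c(0.6, 0.5, 0.4, 0.3)) {
      seg <- threshold_segment(ph$volume, seed = seed, fraction = f)
      if (!is.null(prev)) expect_true(all(seg$mask[prev]))
      prev <- seg$mask
    }
  }
})

test_that("segmentation is deterministic", {
  ph <- make_phantom(phantom_spec(seed = 3))
  s1 <- threshold_segment(ph$volume, ph$spec$tumor_center)
  s2 <- threshold_segment(ph$volume, ph$spec$tumor_center)
  expect_identical(s1, s2)
})

test_that("seed outside the grid or below threshold errors", {
  ph <- make_hot_sphere()
  expect_error(threshold_segment(ph$vol, seed = c(0, 5, 5)), "outside")
  expect_error(threshold_segment(ph$vol, seed = c(1, 1, 1)),
               "below the threshold")
})

test_that("threshold adapts downward until the reference extent is covered", {
  ## cold-centred shell: at 40% the rim is captured but the centre is not
  dm <- c(24, 24, 24); ctr <- c(12, 12, 12)
  m <- sphere_mask(dm, ctr, 6)
  inner <- sphere_mask(dm, ctr, 3.5)
  v <- array(1, dm)
  v[m] <- 10
  v[inner] <- 3.5          # below 0.4 * 10 but above 0.3 * 10
  vol <- pet_volume(v, c(4, 4, 4))
  seed <- c(12, 12, 6)     # rim voxel (hot)
  seg40 <- threshold_segment(vol, seed)
  expect_lt(sum(seg40$mask & m) / sum(m), 0.90)
  seg <- adapt_threshold(vol, seed, reference_extent = m)
  expect_lt(seg$threshold_fraction_used, 0.40)
  expect_gte(sum(seg$mask & m) / sum(m), 0.90)
  expect_true(seg$coverage_ok)

  ## fully covered at 40%: no adaptation
  ph <- make_hot_sphere()
  seg2 <- adapt_threshold(ph$vol, ph$ctr, reference_extent = ph$truth)
  expect_equal(seg2$threshold_fraction_used, 0.40)

  ## reference disjoint from the lesion: floor reached, warning flag
  far <- array(FALSE, dm); far[2:4, 2:4, 2:4] <- TRUE
  expect_warning(seg3 <- adapt_threshold(ph$vol, ph$ctr,
                                         reference_extent = far),
                 "coverage")
  expect_false(seg3$coverage_ok)
})

test_that("manual edits apply set union/difference and flag the mask", {
  ph <- make_hot_sphere()
  seg <- threshold_segment(ph$vol, ph$ctr)
  rm_ix <- which(seg$mask, arr.ind = TRUE)[1:5, ]
  add_ix <- matrix(c(1, 1, 1), 1)
  out <- apply_manual_edits(seg, add = add_ix, remove = rm_ix)
  expect_true(out$manually_edited)
  expect_true(out$mask[1, 1, 1])
  expect_false(any(out$mask[rm_ix]))
  expect_gte(attr(out, "n_components"), 2)  # far-corner voxel disconnects

  same <- apply_manual_edits(seg)
  expect_identical(same$mask, seg$mask)
  expect_true(same$manually_edited)
  expect_error(apply_manual_edits(seg, add = matrix(c(99, 1, 1), 1)),
               "outside")
})

test_that("the 5 ml inclusion gate is inclusive at the boundary", {
  sp <- c(10, 10, 10)  # 1 ml voxels
  vol <- pet_volume(array(1, c(10, 10, 10)), sp)
  mk <- function(n) { m <- array(FALSE, c(10, 10, 10)); m[seq_len(n)] <- TRUE; m }
  expect_false(gate_min_volume(voi_mask(mk(4)), vol, 5))   # 4 ml
  expect_true(gate_min_volume(voi_mask(mk(5)), vol, 5))    # exactly 5 ml
  expect_false(gate_min_volume(voi_mask(mk(0)), vol, 5))   # empty
  ## fractional case: 4.9 ml lesion at 0.7 ml voxels
  vol2 <- pet_volume(array(1, c(10, 10, 10)), c(7, 10, 10))
  expect_false(gate_min_volume(voi_mask(mk(7)), vol2, 5))  # 4.9 ml
})
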