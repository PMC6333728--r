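toy_q <- function() {
  ## 2x2x1 labels [[1,1],[2,2]]: like-pairs along x, cross-pairs along
  ## y and the in-plane diagonals
  lab <- array(0L, c(2, 2, 1))
  lab[, , 1] <- matrix(c(1L, 1L, 2L, 2L), 2, 2)
  structure(list(labels = lab, G = 2L, source_stats = c(min = 0, max = 1)),
            class = "quantised_voi")
}

test_that("GLCM on the toy volume matches manual pair enumeration", {
  M <- compute_glcm(toy_q())
  expect_equal(M, matrix(c(2, 4, 4, 2), 2, 2))
  expect_equal(M, t(M))
})

test_that("GLRLM on the toy volume contains the two x-direction runs", {
  R <- compute_glrlm(toy_q())
  expect_equal(R[, 2], c(1, 1))        # one length-2 run per level (x)
  expect_equal(R[, 1], c(24, 24))      # 12 other directions x 2 voxels
})

test_that("GLSZM on the toy volume finds one size-2 zone per level", {
  Z <- compute_glszm(toy_q())
  expect_equal(Z, matrix(c(0, 0, 1, 1), 2, 2))
  expect_equal(glszm_size_zone_variance(Z), 0)   # sizes {2, 2}
})

test_that("size-zone variance matches hand computation", {
  ## zones of sizes {3, 1}: mu = 2, variance 1
  Z <- matrix(0, 2, 3); Z[1, 3] <- 1; Z[2, 1] <- 1
  expect_equal(glszm_size_zone_variance(Z), 1)
  ## single zone
  Z1 <- matrix(0, 1, 4); Z1[1, 4] <- 1
  expect_equal(glszm_size_zone_variance(Z1), 0)
  expect_error(glszm_size_zone_variance(matrix(0, 2, 2)), "zero zones")
})

test_that("NGTDM on a 1x1x3 line matches manual enumeration", {
  lab <- array(c(1L, 2L, 1L), c(1, 1, 3))
  q <- structure(list(labels = lab, G = 2L, source_stats = c(0, 1)),
                 class = "quantised_voi")
  ng <- compute_ngtdm(q)
  ## ends see only the middle voxel: |1 - 2| = 1 each, so s_1 = 2;
  ## the middle voxel sees the two ends: |2 - 1| = 1, so s_2 = 1
  expect_equal(ng$s, c(2.0, 1.0))
  expect_equal(ng$p, c(2 / 3, 1 / 3))
  expect_equal(ng$n, 3)
  ## complexity by hand over the ordered level pairs (1,2) and (2,1):
  ## each contributes |1-2| / (3 * (2/3 + 1/3)) * (2/3 * 2 + 1/3 * 1)
  expect_equal(ngtdm_complexity(ng),
               2 * (1 / 3) * (2 / 3 * 2 + 1 / 3 * 1))
})

test_that("constant VOIs are degenerate limits: diagonal GLCM, single zone,
           zero NGTDM", {
  lab <- array(1L, c(3, 3, 3))
  q <- structure(list(labels = lab, G = 4L, source_stats = c(5, 5)),
                 class = "quantised_voi")
  M <- compute_glcm(q)
  expect_true(all(M[row(M) != col(M)] == 0))
  Z <- compute_glszm(q)
  expect_equal(sum(Z), 1)
  expect_equal(which(Z > 0, arr.ind = TRUE)[1, 2], c(col = 27))
  ng <- compute_ngtdm(q)
  expect_equal(sum(ng$s), 0)
  expect_equal(ngtdm_complexity(ng), 0)
})

test_that("builders agree with brute-force oracles on random 6^3 VOIs", {
  set.seed(101)
  for (i in 1:30) {
    q <- random_qvoi(c(6, 6, 6), G = sample(2:5, 1))
    expect_identical(compute_glcm(q), oracle_glcm(q$labels, q$G))
    expect_identical(unname(compute_glrlm(q)),
                     unname(oracle_glrlm(q$labels, q$G)))
    expect_identical(unname(compute_glszm(q)),
                     unname(oracle_glszm(q$labels, q$G)))
    ng <- compute_ngtdm(q); or <- oracle_ngtdm(q$labels, q$G)
    expect_equal(ng$s, or$s)
    expect_equal(ng$p, or$p)
    expect_equal(ng$n, or$n)
  }
})

test_that("mass-conservation identities hold on random VOIs", {
  set.seed(202)
  for (i in 1:20) {
    q <- random_qvoi(c(7, 6, 5), G = 4)
    nvox <- sum(q$labels > 0)
    ## GLCM total = 2 x valid ordered pairs over 13 directions
    M <- compute_glcm(q)
    npairs <- 0
    for (r in seq_len(nrow(oracle_dirs13))) {
      d <- oracle_dirs13[r, ]
      sh <- petrad:::shift_array(q$labels, d, 0L)
      npairs <- npairs + sum(q$labels > 0 & sh > 0)
    }
    expect_equal(sum(M), 2 * npairs)
    ## each voxel sits in exactly one run per direction
    R <- compute_glrlm(q)
    expect_equal(sum(R %*% seq_len(ncol(R))), 13 * nvox)
    ## zones partition the VOI
    Z <- compute_glszm(q)
    expect_equal(sum(Z %*% seq_len(ncol(Z))), nvox)
    ## occupancies sum to 1
    ng <- compute_ngtdm(q)
    expect_equal(sum(ng$p), 1)
  }
})

test_that("quantisation follows the ceiling rule, is monotone, and is
           scale-invariant", {
  v <- array(c(0, 5, 10, 0, 0, 0, 0, 0), c(2, 2, 2))
  m <- array(c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
             c(2, 2, 2))
  q <- quantise(v, m, 2)
  expect_equal(q$labels[m], c(1L, 1L, 2L))
  ## G larger than the number of distinct values keeps them distinct
  q256 <- quantise(v, m, 256)
  expect_equal(length(unique(q256$labels[m])), 3)
  ## constant VOI -> all labels 1
  qc <- quantise(array(4, c(2, 2, 2)), array(TRUE, c(2, 2, 2)), 16)
  expect_true(all(qc$labels == 1))
  ## monotone in value; invariant to global scaling
  set.seed(5)
  vals <- array(runif(64, 1, 9), c(4, 4, 4))
  mm <- array(TRUE, c(4, 4, 4))
  qa <- quantise(vals, mm, 8)
  qb <- quantise(vals * 3.7, mm, 8)
  expect_identical(qa$labels, qb$labels)
  ord <- order(vals[mm])
  expect_true(all(diff(qa$labels[mm][ord]) >= 0))
  expect_error(quantise(vals, array(FALSE, c(4, 4, 4)), 8), "empty")
})
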