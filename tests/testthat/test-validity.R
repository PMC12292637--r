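twoClusterLine <- list(points = matrix(c(0, 1, 10, 11), ncol = 1),
                       labels = c(0L, 0L, 1L, 1L))

test_that("the five indices reproduce the hand-computed two-cluster values", {
  p <- twoClusterLine$points; l <- twoClusterLine$labels
  expect_equal(calinskiHarabasz(p, l), 200)
  expect_equal(cIndex(p, l), 0)
  expect_equal(dunnIndex(p, l), 9)
  expect_equal(hartiganIndex(p, l), log(100))
  expect_equal(mcclainRao(p, l), 0.1)
})

test_that("indices agree with loop-based brute force on random instances", {
  for (case in 1:50) {
    ps <- randomPointSet(n = sample(8:30, 1), p = sample(1:4, 1),
                         k = sample(2:5, 1), seed = case)
    if (length(unique(ps$labels)) < 2) next
    expect_equal(calinskiHarabasz(ps$points, ps$labels),
                 bfCalinskiHarabasz(ps$points, ps$labels), tolerance = 1e-9)
    ci <- cIndex(ps$points, ps$labels)
    expect_equal(ci, bfCIndex(ps$points, ps$labels), tolerance = 1e-9)
    expect_gte(ci, 0); expect_lte(ci, 1)
    expect_equal(dunnIndex(ps$points, ps$labels),
                 bfDunn(ps$points, ps$labels), tolerance = 1e-9)
    expect_equal(hartiganIndex(ps$points, ps$labels),
                 bfHartigan(ps$points, ps$labels), tolerance = 1e-9)
    expect_equal(mcclainRao(ps$points, ps$labels),
                 bfMcclainRao(ps$points, ps$labels), tolerance = 1e-9)
  }
})

test_that("indices are invariant to relabeling, point order, and scaling where expected", {
  ps <- randomPointSet(20, 3, 3, seed = 77)
  perm <- withr::with_seed(1, sample(nrow(ps$points)))
  relab <- c(2L, 0L, 1L)[ps$labels + 1L]
  for (fn in list(calinskiHarabasz, cIndex, dunnIndex, hartiganIndex,
                  mcclainRao)) {
    base <- fn(ps$points, ps$labels)
    expect_equal(fn(ps$points, relab), base)
    expect_equal(fn(ps$points[perm, ], ps$labels[perm]), base)
  }
  # CH and Hartigan are scale-invariant (traces scale together)
  expect_equal(calinskiHarabasz(2 * ps$points, ps$labels),
               calinskiHarabasz(ps$points, ps$labels))
  expect_equal(hartiganIndex(ps$points, ps$labels),
               hartiganIndex(3 * ps$points, ps$labels))
  # duplicating every point doubles SSB and SSW, leaving Hartigan unchanged
  expect_equal(hartiganIndex(rbind(ps$points, ps$points),
                             c(ps$labels, ps$labels)),
               hartiganIndex(ps$points, ps$labels))
})

test_that("moving a cluster away improves separation-sensitive indices", {
  base <- randomPointSet(18, 2, 3, seed = 5)
  shifted <- base$points
  shifted[base$labels == 2L, ] <- shifted[base$labels == 2L, ] + 50
  far <- shifted
  far[base$labels == 2L, ] <- far[base$labels == 2L, ] + 100
  expect_gte(calinskiHarabasz(far, base$labels),
             calinskiHarabasz(shifted, base$labels))
  expect_gte(dunnIndex(far, base$labels), dunnIndex(shifted, base$labels))
  expect_gte(hartiganIndex(far, base$labels),
             hartiganIndex(shifted, base$labels))
  expect_lte(cIndex(far, base$labels), cIndex(shifted, base$labels))
  expect_lte(mcclainRao(far, base$labels), mcclainRao(shifted, base$labels))
})

test_that("degenerate inputs raise degenerate-input errors", {
  coincident <- matrix(c(0, 0, 1, 1), ncol = 1)
  expect_error(calinskiHarabasz(coincident, c(0, 0, 1, 1)), "degenerate")
  expect_error(hartiganIndex(coincident, c(0, 0, 1, 1)), "degenerate")
  expect_error(dunnIndex(matrix(c(0, 0, 5, 5), ncol = 1), c(0, 0, 1, 1)),
               "degenerate")
  # equilateral triangle: every pairwise distance equal -> C is undefined
  tri <- matrix(c(0, 0, 1, 0, 0.5, sqrt(3) / 2), 3, 2, byrow = TRUE)
  expect_error(cIndex(tri, c(0, 0, 1)), "degenerate")
})

test_that("consensus selection is direction-aware with majority and tie rules", {
  mk <- function(k, ch, ci, du, ha, mr)
    data.frame(k = k, ch = ch, c_index = ci, dunn = du, hartigan = ha,
               mcclain_rao = mr)
  # k = 10 wins 3 indices (ch, dunn, hartigan), k = 12 wins 2 -> 10
  r <- rbind(mk(10, 5, 0.5, 2, 1, 0.9), mk(12, 4, 0.1, 1, 0.5, 0.2))
  expect_equal(consensusSelectK(r)$k, 10)
  # 2-2-1 vote split -> smaller of the two leaders
  r2 <- rbind(mk(8, 9, 0.9, 9, 1, 0.9),   # wins ch, dunn
              mk(6, 1, 0.1, 1, 0.5, 0.95),  # wins c_index, mcclain? no:
              mk(12, 2, 0.2, 2, 9, 0.1))  # wins hartigan, mcclain_rao
  sel <- consensusSelectK(r2)
  expect_equal(unname(sort(table(sel$winners), decreasing = TRUE))[1], 2L)
  expect_equal(sel$k, min(as.numeric(names(which(
    table(sel$winners) == max(table(sel$winners)))))))
  # permutation invariance of report order
  expect_equal(consensusSelectK(r2[c(3, 1, 2), ])$k, sel$k)
  expect_error(consensusSelectK(rbind(mk(5, 1, 1, 1, 1, 1),
                                      mk(5, 2, 2, 2, 2, 2))), "duplicate")
  expect_error(consensusSelectK(mk(5, 1, 1, 1, 1, 1)), "at least 2")
})

test_that("validityIndexReport collects all five indices for one labeling", {
  ps <- randomPointSet(15, 2, 3, seed = 21)
  rep <- validityIndexReport(ps$points, ps$labels)
  expect_named(rep, c("k", "ch", "c_index", "dunn", "hartigan",
                      "mcclain_rao"))
  expect_equal(rep$k, 3L)
  expect_equal(rep$ch, calinskiHarabasz(ps$points, ps$labels))
})
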