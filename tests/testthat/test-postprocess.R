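test_that("opening: identity at Lw=1, removes isolated voxels, idempotent, matches brute force", {
  d <- c(16, 16, 16)
  a <- random_labels(d, 0.35, seed = 7)
  expect_identical(morphological_opening(a, 1L), a)
  iso <- array(0L, d); iso[8, 8, 8] <- 1L
  expect_true(all(morphological_opening(iso, 3L) == 0))
  solid <- array(0L, d); solid[4:9, 4:9, 4:9] <- 1L
  expect_identical(morphological_opening(solid, 3L), solid)
  op <- morphological_opening(a, 3L)
  expect_identical(morphological_opening(op, 3L), op)    # idempotence
  expect_true(all(op <= a))                              # anti-extensive
  expect_equal(op, bf_opening(a, 3L), ignore_attr = TRUE)
})

test_that("connectivity semantics: corner-touching voxels join only under 26", {
  d <- c(5, 5, 5)
  a <- array(0L, d)
  a[2, 2, 2] <- 1L; a[3, 3, 3] <- 1L
  expect_identical(nrow(connected_regions(a, 26L, c(1, 1, 1))$regions), 1L)
  expect_identical(nrow(connected_regions(a, 6L, c(1, 1, 1))$regions), 2L)
  # edge-touching joins under 18 but not 6
  b <- array(0L, d); b[2, 2, 2] <- 1L; b[3, 3, 2] <- 1L
  expect_identical(nrow(connected_regions(b, 18L, c(1, 1, 1))$regions), 1L)
  expect_identical(nrow(connected_regions(b, 6L, c(1, 1, 1))$regions), 2L)
  empty <- connected_regions(array(0L, d), 26L, c(1, 1, 1))
  expect_identical(nrow(empty$regions), 0L)
})

test_that("component labelling matches a flood-fill oracle on random volumes", {
  for (seed in 1:3) {
    a <- random_labels(c(10, 10, 10), 0.18, seed = seed)
    for (conn in c(6L, 26L)) {
      got <- connected_regions(a, conn, c(1, 1, 1))
      want <- bf_components(a, conn)
      expect_identical(nrow(got$regions), want$n)
      # identical partitions: component ids must be a relabelling
      pos <- which(a == 1)
      tab <- table(got$label_map[pos], want$labels[pos])
      expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
      expect_identical(sort(as.integer(got$regions$voxel_count)),
                       sort(as.integer(table(want$labels[pos]))))
    }
  }
})

test_that("region volumes and the Ts conversion are consistent", {
  a <- array(0L, c(8, 8, 8)); a[2:4, 2:4, 2:4] <- 1L
  sp <- c(0.5, 0.5, 0.5)
  rs <- connected_regions(a, 26L, sp)
  expect_equal(rs$regions$volume_mm3, 27 * prod(sp))
  expect_equal(ts_voxel_count(112.5, c(0.5, 0.5, 0.5)), 900)
  expect_equal(ts_voxel_count(112.5, c(0.8594, 0.8594, 0.9)),
               112.5 / (0.8594 * 0.8594 * 0.9))
})

test_that("size filtering removes small regions and guarantees the survivor bound", {
  d <- c(20, 20, 10)
  a <- array(0L, d)
  a[2:6, 2:6, 2:6] <- 1L          # 125 voxels
  a[10:12, 10:12, 2:4] <- 1L      # 27 voxels
  a[15, 15, 8] <- 1L              # 1 voxel
  rs <- connected_regions(a, 26L, c(1, 1, 1))
  filt <- filter_small_regions(rs, Ts_mm3 = 112.5)
  surv <- connected_regions(filt$labels, 26L, c(1, 1, 1))
  expect_identical(nrow(surv$regions), 1L)
  expect_true(all(surv$regions$volume_mm3 >= 112.5))
  expect_identical(sum(filt$labels), 125)
  # the 100-voxel case at 1 mm^3/voxel falls below 112.5 and is removed
  b <- array(0L, d); b[1:4, 1:5, 1:5] <- 1L
  rsb <- connected_regions(b, 26L, c(1, 1, 1))
  expect_identical(sum(filter_small_regions(rsb, 112.5)$labels), 0)
  # Ts = 0 is the identity
  expect_identical(filter_small_regions(rs, 0)$labels,
                   array(as.numeric(a), d))
  # brute-force check of survivors on a random volume
  r <- random_labels(c(12, 12, 12), 0.25, seed = 5)
  rr <- connected_regions(r, 26L, c(1, 1, 1))
  fr <- filter_small_regions(rr, 10)
  want <- bf_components(r, 26L)
  keep <- as.integer(names(which(table(want$labels[want$labels > 0]) >= 10)))
  oracle <- array(0, dim(r))
  oracle[want$labels %in% keep] <- 1
  expect_equal(fr$labels, oracle, ignore_attr = TRUE)
})

test_that("subject calls and the full refinement chain preserve monotonicity", {
  expect_false(subject_call(array(0, c(4, 4, 4)), "s")$is_patient_pred)
  one <- array(0, c(6, 6, 6)); one[2:4, 2:4, 2:4] <- 1
  expect_true(subject_call(one, "s")$is_patient_pred)
  a <- random_labels(c(16, 16, 16), 0.3, seed = 11)
  ref <- refine_labels(a, c(1, 1, 1), "s", Lw = 3L, Ts_mm3 = 20)
  expect_true(all(ref$opened <= a))
  expect_true(all(ref$filtered <= ref$opened))
  if (nrow(ref$surviving))
    expect_true(all(ref$surviving$volume_mm3 >= 20))
  expect_identical(ref$call$is_patient_pred, sum(ref$filtered) > 0)
})
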