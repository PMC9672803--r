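test_that("connected-component labeling respects connectivity", {
  m <- array(0, c(8, 8, 8))
  expect_equal(nrow(label_lesions(volume3d(m))$table), 0L)

  # two voxels touching only at a corner
  m[2, 2, 2] <- 1; m[3, 3, 3] <- 1
  v <- volume3d(m)
  expect_equal(nrow(label_lesions(v, eval_config(connectivity = 26L))$table), 1L)
  expect_equal(nrow(label_lesions(v, eval_config(connectivity = 6L))$table), 2L)
  # an edge-touching pair merges at 18 but not 6
  m2 <- array(0, c(8, 8, 8)); m2[2, 2, 2] <- 1; m2[3, 3, 2] <- 1
  expect_equal(nrow(label_lesions(volume3d(m2),
                                  eval_config(connectivity = 18L))$table), 1L)
  expect_equal(nrow(label_lesions(volume3d(m2),
                                  eval_config(connectivity = 6L))$table), 2L)

  # conservation: labeled voxels = positive voxels
  set.seed(31)
  m3 <- array(rbinom(12^3, 1, 0.1), c(12, 12, 12))
  lab <- label_lesions(volume3d(m3))
  expect_equal(sum(lab$labels > 0), sum(m3))
  expect_equal(sum(lab$table$voxels), sum(m3))
  expect_equal(lab$table$label, seq_len(nrow(lab$table)))

  expect_error(label_lesions(volume3d(array(0.5, c(4, 4, 4)))), "binary")
})

test_that("the 3 mm3 filter removes strictly smaller lesions only", {
  mk <- function(nvox) {
    # a straight line of nvox voxels is one 26-connected component
    m <- array(0, c(8, 8, 40))
    m[3, 3, 2 + seq_len(nvox)] <- 1
    volume3d(m, voxel_size_mm = 0.5)
  }
  cfg <- eval_config()
  l23 <- filter_small(label_lesions(mk(23L), cfg), cfg)  # 2.875 mm3
  expect_equal(nrow(l23$table), 0L)
  l24 <- filter_small(label_lesions(mk(24L), cfg), cfg)  # exactly 3 mm3
  expect_equal(nrow(l24$table), 1L)
  expect_equal(l24$table$volume_mm3, 3)

  # min volume 0 is the identity
  cfg0 <- eval_config(min_lesion_mm3 = 0)
  lab <- label_lesions(mk(5L), cfg0)
  expect_identical(filter_small(lab, cfg0)$labels, lab$labels)

  # filtering relabels consecutively and never increases K
  m <- array(0, c(8, 8, 40))
  m[2, 2, 2] <- 1                 # 0.125 mm3, removed
  m[6, 6, 2 + 1:30] <- 1          # 3.75 mm3, kept
  lab2 <- filter_small(label_lesions(volume3d(m, 0.5), cfg), cfg)
  expect_equal(lab2$table$label, 1L)
  expect_equal(max(lab2$labels), 1L)
})

test_that("lesion matching handles the perfect, disjoint and alpha-fail cases", {
  cfg <- eval_config()
  m <- array(0, c(24, 24, 24))
  m[3:6, 3:6, 3:6] <- 1
  m[15:18, 15:18, 15:18] <- 1
  v <- volume3d(m)
  lab <- label_lesions(v, cfg)
  self <- match_lesions(lab, lab, cfg)
  expect_equal(self$TP_gt, 2L)
  expect_equal(self$TP_pred, 2L)

  disj <- array(0, c(24, 24, 24)); disj[20:22, 3:5, 3:5] <- 1
  md <- match_lesions(label_lesions(volume3d(disj), cfg), lab, cfg)
  expect_equal(md$TP_gt, 0L)
  expect_equal(md$TP_pred, 0L)

  # 100-voxel gt lesion covered on 5 voxels only (5% < alpha = 10%)
  gt <- array(0, c(24, 24, 24)); gt[3:7, 3:7, 3:6] <- 1  # 100 voxels
  pr <- array(0, c(24, 24, 24)); pr[3, 3:7, 3] <- 1      # 5 overlapping
  mm <- match_lesions(label_lesions(volume3d(pr), cfg),
                      label_lesions(volume3d(gt), cfg), cfg)
  expect_equal(mm$TP_gt, 0L)
})

test_that("matching is symmetric under swapping prediction and ground truth", {
  set.seed(33)
  cfg <- eval_config()
  for (i in 1:5) {
    a <- array(rbinom(16^3, 1, 0.08), c(16, 16, 16))
    b <- a
    flip <- sample(length(b), 200)
    b[flip] <- 1 - b[flip]
    la <- label_lesions(volume3d(a), cfg)
    lb <- label_lesions(volume3d(b), cfg)
    ab <- match_lesions(la, lb, cfg)
    ba <- match_lesions(lb, la, cfg)
    expect_equal(ab$TP_gt, ba$TP_pred)
    expect_equal(ab$TP_pred, ba$TP_gt)
    expect_equal(ab$n_gt, ba$n_pred)
  }
  expect_error(match_lesions(label_lesions(volume3d(array(0, c(4, 4, 4)))),
                             label_lesions(volume3d(array(0, c(5, 5, 5))))),
               "mismatch")
})

test_that("dice follows its formula and empty-mask conventions", {
  a <- array(0, c(10, 10, 10)); a[1:5, 1:5, 1:4] <- 1   # 100 voxels
  b <- array(0, c(10, 10, 10)); b[1:5, 1:5, 3:6] <- 1   # 100 voxels, 50 shared
  expect_equal(dice(a, b), 0.5)
  expect_equal(dice(a, a), 1)
  e <- array(0, c(10, 10, 10))
  expect_equal(dice(e, e), 1)
  expect_equal(dice(a, e), 0)
  expect_equal(dice(e, a), 0)
})

test_that("patient metrics implement Sens, PPV and F1 with their conventions", {
  mk_matching <- function(TP_gt, TP_pred, n_gt, n_pred) {
    structure(list(TP_gt = TP_gt, TP_pred = TP_pred, n_gt = n_gt,
                   n_pred = n_pred, gt_detected = logical(n_gt),
                   pred_detected = logical(n_pred)),
              class = "lesion_matching")
  }
  lab0 <- label_lesions(volume3d(array(0, c(4, 4, 4))))
  msk <- array(0, c(4, 4, 4))

  pm <- patient_metrics(mk_matching(2L, 2L, 4L, 4L), msk, msk, lab0)
  expect_equal(pm$sens, 0.5)
  expect_equal(pm$ppv, 0.5)
  expect_equal(pm$f1, 0.5)  # harmonic mean of equals

  pm2 <- patient_metrics(mk_matching(4L, 0L, 4L, 4L), msk, msk, lab0)
  expect_equal(pm2$sens, 1)
  expect_equal(pm2$f1, 0)   # Sens = 1, PPV = 0

  # no ground-truth lesions: routed to the without-lesions subset
  pm3 <- patient_metrics(mk_matching(0L, 0L, 0L, 2L), msk, msk, lab0)
  expect_false(pm3$has_new_lesions)
  expect_true(is.na(pm3$sens))
})

test_that("cohort summaries compute mean and SEM by subset", {
  rows <- rbind(
    patient_metrics(structure(list(TP_gt = 0L, TP_pred = 0L, n_gt = 1L,
                                   n_pred = 0L, gt_detected = FALSE,
                                   pred_detected = logical(0)),
                    class = "lesion_matching"),
                    array(0, c(4, 4, 4)), array(0, c(4, 4, 4)),
                    label_lesions(volume3d(array(0, c(4, 4, 4)))), "a"),
    patient_metrics(structure(list(TP_gt = 1L, TP_pred = 1L, n_gt = 1L,
                                   n_pred = 1L, gt_detected = TRUE,
                                   pred_detected = TRUE),
                    class = "lesion_matching"),
                    array(0, c(4, 4, 4)), array(0, c(4, 4, 4)),
                    label_lesions(volume3d(array(0, c(4, 4, 4)))), "b"))
  s <- cohort_summary(rows)
  sens_row <- s$with_lesions[s$with_lesions$metric == "sens", ]
  expect_equal(sens_row$mean, 0.5)
  expect_equal(sens_row$sem, 0.5)  # sd(c(0,1))/sqrt(2) = 0.7071/1.414
  expect_equal(sens_row$n, 2L)

  # constant values give SEM 0; single values give SEM NA
  one <- cohort_summary(rows[2, , drop = FALSE])
  expect_true(is.na(one$with_lesions$sem[1]))
  both_same <- cohort_summary(rbind(rows[2, ], rows[2, ]))
  expect_equal(both_same$with_lesions$sem[1], 0)
})

test_that("a perfect prediction scores 1 everywhere on generated cases", {
  cfg <- eval_config()
  for (cs in tiny_cases(4, seed = 44L, n_new = 2L)) {
    r <- evaluate_case(cs$gt_mask, cs$gt_mask, cfg, cs$patient_id)
    if (r$has_new_lesions) {
      expect_equal(r$dice, 1)
      expect_equal(r$sens, 1)
      expect_equal(r$ppv, 1)
      expect_equal(r$f1, 1)
    }
    # volume bookkeeping: surviving lesion volume = positive voxels x voxel volume
    pl <- filter_small(label_lesions(cs$gt_mask, cfg), cfg)
    expect_equal(sum(pl$table$volume_mm3),
                 sum(pl$labels > 0) * prod(cs$gt_mask$voxel_size_mm))
    expect_equal(r$pred_volume_mm3, sum(pl$table$volume_mm3))
  }
})
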