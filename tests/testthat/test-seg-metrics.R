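test_that("Dice matches counting and handles degenerate masks", {
  m <- array(0, c(4, 4, 4)); m[1:2, 1, 1] <- 1
  expect_equal(dice(m, m), 1)
  n <- array(0, c(4, 4, 4)); n[3:4, 4, 4] <- 1
  expect_equal(dice(m, n), 0)
  # |A| = 4, |B| = 4, |A n B| = 2 -> 0.5
  a <- array(0, c(4, 4, 4)); a[1:4, 1, 1] <- 1
  b <- array(0, c(4, 4, 4)); b[3:4, 1, 1] <- 1; b[1:2, 2, 1] <- 1
  expect_equal(dice(a, b), 2 * 2 / 8)
  expect_true(is.na(dice(array(0, c(2, 2, 2)), array(0, c(2, 2, 2)))))
  # symmetry on random masks
  ra <- with_test_seed(1, array(stats::runif(216) > 0.5, c(6, 6, 6)))
  rb <- with_test_seed(2, array(stats::runif(216) > 0.5, c(6, 6, 6)))
  expect_equal(dice(ra, rb), dice(rb, ra))
})

test_that("Hausdorff distances match an exhaustive pairwise oracle", {
  # single-pair case with unit spacing
  A <- matrix(c(0, 0, 0), 1); B <- matrix(c(3, 0, 0), 1)
  h <- hausdorff(A, B)
  expect_equal(h$h_ab, 3); expect_equal(h$h_ba, 3); expect_equal(h$H, 3)
  # physical spacing scales distances
  h2 <- hausdorff(A, B, spacing = c(0.5, 1, 1))
  expect_equal(h2$H, 1.5)
  # random voxel sets vs brute-force oracle
  with_test_seed(3, {
    pa <- matrix(sample(0:19, 3 * 60, TRUE), ncol = 3)
    pb <- matrix(sample(0:19, 3 * 80, TRUE), ncol = 3)
  })
  sp <- c(0.7, 0.8, 1.1)
  h3 <- hausdorff(pa, pb, spacing = sp)
  sa <- sweep(pa, 2, sp, `*`); sb <- sweep(pb, 2, sp, `*`)
  dmat <- sqrt(outer(rowSums(sa^2), rowSums(sb^2), `+`) - 2 * sa %*% t(sb))
  dab <- apply(dmat, 1, min); dba <- apply(dmat, 2, min)
  expect_equal(h3$h_ab, max(dab), tolerance = 1e-9)
  expect_equal(h3$h_ba, max(dba), tolerance = 1e-9)
  expect_equal(h3$H, max(max(dab), max(dba)), tolerance = 1e-9)
  expect_equal(h3$hd95, max(stats::quantile(dab, 0.95, names = FALSE),
                            stats::quantile(dba, 0.95, names = FALSE)),
               tolerance = 1e-9)
  expect_lte(h3$hd95, h3$H)
  # symmetry of H
  h4 <- hausdorff(pb, pa, spacing = sp)
  expect_equal(h4$H, h3$H, tolerance = 1e-12)
  expect_error(hausdorff(matrix(numeric(0), 0, 3), pb), "empty")
})

test_that("identical masks give zero distances everywhere", {
  m <- array(0, c(8, 8, 8)); m[3:6, 3:6, 3:6] <- 1
  h <- hausdorff(m, m)
  expect_equal(h$H, 0); expect_equal(h$hd95, 0)
})

test_that("per-label family report scores overlap, boundaries and flags", {
  lab <- array(0L, c(10, 10, 10))
  lab[2:5, 2:5, 2:5] <- 1L; lab[7:9, 7:9, 7:9] <- 2L
  gt <- label_volume(lab)
  expect_equal(unname(attr(per_mask_family_report(gt, gt), "family_mean")),
               c(1, 0))
  rep0 <- per_mask_family_report(gt, gt)
  expect_true(all(rep0$dice == 1) && all(rep0$hd95 == 0) && !any(rep0$flag))
  # erosion by one voxel: Dice from a counting oracle
  lab2 <- lab
  lab2[lab == 1L] <- 0L; lab2[3:4, 3:4, 3:4] <- 1L
  syn <- label_volume(lab2)
  rep <- per_mask_family_report(gt, syn)
  n1 <- 4^3; n2 <- 2^3
  expect_equal(rep$dice[rep$label == 1], 2 * n2 / (n1 + n2))
  # label present only in gt
  lab3 <- lab; lab3[lab == 2L] <- 0L
  rep2 <- per_mask_family_report(gt, label_volume(lab3))
  expect_equal(rep2$dice[rep2$label == 2], 0)
  expect_true(rep2$flag[rep2$label == 2])
  expect_error(per_mask_family_report(gt, label_volume(lab[1:5, , ])), "differ")
})

test_that("regional volumetry converts voxel counts to cm3 and percent ICV", {
  lab <- array(0L, c(20, 20, 20))
  lab[1:10, 1:10, 1:10] <- 1L           # 1000 voxels
  lab[11:20, 1:10, 1:10] <- 2L          # 1000 voxels
  lv <- label_volume(lab, spacing = c(1, 1, 1))
  # constructor guards duplicates across regions
  expect_error(region_table(data.frame(region = c("A", "B"),
                                       label_ids = c("1", "1"))), "more than one")
  # composite ICV region reuses ids, so build the table directly
  rt <- structure(list(region = c("A", "B", "ICV"),
                       label_ids = list(1L, 2L, 1:2),
                       side = rep(NA_character_, 3),
                       pair_region = rep(NA_character_, 3)),
                  class = "region_table")
  rep <- region_volume(lv, rt, icv_region = "ICV")
  expect_equal(rep$cm3, c(1, 1, 2))                 # 1000 mm3 = 1 cm3
  expect_equal(rep$pct_icv, c(50, 50, 100))
  # partition property: tiles of the ICV sum to exactly 100%
  expect_equal(sum(rep$pct_icv[1:2]), 100)
  # anisotropic spacing scales the voxel volume
  lv2 <- label_volume(lab, spacing = c(0.5, 0.5, 2))
  rep2 <- region_volume(lv2, rt, "ICV")
  expect_equal(rep2$cm3[1], 1000 * 0.5 * 0.5 * 2 / 1000)
})

test_that("percent error/difference reproduce published volumetry arithmetic", {
  # white matter and cerebellum rows of a GT-vs-synthetic comparison
  expect_equal(round(percent_error(409.262, 415.564), 3), 1.540)
  expect_equal(round(percent_error(102.823, 112.559), 3), 9.469)
  expect_equal(percent_error(5, 5), 0)
  expect_error(percent_error(0, 1), "zero")
  # CSF and amygdala rows of a 3T-vs-7T comparison
  expect_equal(round(percent_difference(239.683, 162.003), 3), 47.950)
  expect_equal(round(percent_difference(1.570, 2.223), 3), -29.375)
  expect_equal(percent_difference(4, 4), 0)
  # the two denominator conventions disagree off the diagonal
  expect_equal(percent_difference(2, 1, form = "relative_to_7t"), -50)
  # algebraic identity linking the two error directions
  gt <- 123.4; syn <- 150.1
  expect_equal(percent_error(gt, syn),
               -percent_error(syn, gt) * syn / gt, tolerance = 1e-12)
})

test_that("asymmetry index and its error behave as documented", {
  expect_equal(as.numeric(asymmetry_index(2, 2)), 0)
  expect_equal(as.numeric(asymmetry_index(1, 3)), 100)   # 100 * 2 / 2
  expect_equal(as.numeric(asymmetry_index(3, 1)),
               -as.numeric(asymmetry_index(1, 3)))       # antisymmetry
  expect_error(asymmetry_index(0, 0), "zero")
  # hippocampal asymmetry-error row arithmetic
  expect_equal(round(asymmetry_error(-4.7443, -1.8469), 4), -61.0712)
  expect_equal(asymmetry_error(2, 2), 0)
  expect_equal(asymmetry_error(2, 3), 50)
})
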