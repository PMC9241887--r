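test_that("trans profiles match brute force and count each pair at both ends", {
  set.seed(61)
  for (rep in 1:50) {
    lay <- genome_layout(c(a = 40000, b = 30000, c = 30000), telomere_extent = 2000)
    bins <- make_bins(lay, 1000)
    n <- nrow(bins)
    ct <- tibble::tibble(bin1 = sample.int(n, 60, TRUE),
                         bin2 = sample.int(n, 60, TRUE),
                         count = sample.int(5, 60, TRUE))
    ct <- ct[ct$bin1 != ct$bin2, ]
    cm <- contact_matrix(bins, ct)
    prof <- trans_profile(cm, end_exclusion_bp = 2000)
    expect_equal(prof$count, bf_trans_profile(cm))
    s <- cis_trans_summary(cm)
    expect_equal(sum(prof$count), 2 * s$total_trans)
  }
})

test_that("single-chromosome matrices give an all-zero trans profile", {
  lay <- genome_layout(c(solo = 20000))
  cm <- contact_matrix(make_bins(lay, 1000),
                       tibble::tibble(bin1 = 1:5, bin2 = 6:10, count = 1))
  prof <- trans_profile(cm, end_exclusion_bp = 1000)
  expect_true(all(prof$count == 0))
  expect_warning(call_centromeres(prof), "all-zero")

  expect_error(trans_profile(cm, end_exclusion_bp = 15000), "swallows")
})

test_that("centromere calls anchor at the leftmost argmax on ties", {
  lay <- genome_layout(c(chrA = 40000), telomere_extent = 1000)
  bins <- make_bins(lay, 1000)
  counts <- rep(1, 40)
  counts[c(12, 28)] <- 50            # two equal peaks, far apart
  prof <- structure(
    dplyr::bind_cols(bins[c("bin", "chrom", "start", "end")],
                     tibble::tibble(count = counts, smoothed = counts,
                                    excluded = c(TRUE, rep(FALSE, 38), TRUE))),
    resolution = 1000, smooth_bins = 1,
    class = c("hic_trans_profile", "tbl_df", "tbl", "data.frame"))
  cen <- call_centromeres(prof)
  expect_equal(nrow(cen), 1)
  expect_true(cen$start < 12000 & cen$end > 11000)   # the left peak
  expect_false(cen$flat)
})

test_that("flat-profile chromosomes carry the flatness flag", {
  p0 <- small_sim_params(k_c = 0, k_t = 0)
  tr0 <- simulate_genome(p0, 63, with_sequence = FALSE)
  m0 <- sample_contacts(expected_intensity(tr0, 20000), 64)
  cen0 <- suppressWarnings(call_centromeres(trans_profile(m0)))
  expect_true(all(cen0$flat))
})

test_that("a uniform trans matrix gives corner scores of 1", {
  lay <- genome_layout(c(a = 40000, b = 40000),
                       centromeres = tibble::tibble(chrom = c("a", "b"),
                                                    start = 18000, end = 22000))
  bins <- make_bins(lay, 1000)
  pr <- expand.grid(bin1 = 1:40, bin2 = 41:80)
  cm <- contact_matrix(bins, tibble::tibble(bin1 = pr$bin1, bin2 = pr$bin2,
                                            count = 3))
  am <- aca(cm, lay$centromeres, F = 10, k = 3)
  expect_equal(am$cen_score, 1, tolerance = 1e-9)
  expect_equal(am$tel_score, 1, tolerance = 1e-9)
  expect_true(isSymmetric(am$map))
  expect_equal(classify_rabl(am), "non_rabl")
})

test_that("the ACA map is invariant to chromosome order and reflection", {
  set.seed(65)
  lay <- genome_layout(c(a = 30000, b = 24000),
                       centromeres = tibble::tibble(chrom = c("a", "b"),
                                                    start = c(12000, 10000),
                                                    end = c(16000, 14000)))
  bins <- make_bins(lay, 1000)
  n <- nrow(bins)
  ct <- tibble::tibble(bin1 = sample.int(n, 300, TRUE),
                       bin2 = sample.int(n, 300, TRUE),
                       count = sample.int(6, 300, TRUE))
  ct <- ct[ct$bin1 != ct$bin2, ]
  cm <- contact_matrix(bins, ct)
  am <- aca(cm, lay$centromeres, F = 8)

  # swap chromosome order (relabel bins: b first)
  lay2 <- genome_layout(c(b = 24000, a = 30000),
                        centromeres = lay$centromeres[2:1, ])
  bins2 <- make_bins(lay2, 1000)
  remap <- c(25:54, 1:24)   # old bin -> new bin (a: 1..30 -> 25..54, b: 31..54 -> 1..24)
  cm2 <- contact_matrix(bins2, tibble::tibble(bin1 = remap[ct$bin1],
                                              bin2 = remap[ct$bin2],
                                              count = ct$count))
  am2 <- aca(cm2, lay2$centromeres, F = 8)
  expect_equal(am2$map, am$map, tolerance = 1e-9)

  # reflect chromosome a (reverse its bins and mirror its centromere)
  refl <- c(30:1, 31:54)
  cen3 <- lay$centromeres
  cen3$start[1] <- 30000 - 16000; cen3$end[1] <- 30000 - 12000
  cm3 <- contact_matrix(bins, tibble::tibble(bin1 = refl[ct$bin1],
                                             bin2 = refl[ct$bin2],
                                             count = ct$count))
  am3 <- aca(cm3, cen3, F = 8)
  expect_equal(am3$map, am$map, tolerance = 1e-9)
})

test_that("single-pair aggregation equals the directly rescaled pair map", {
  set.seed(66)
  lay <- genome_layout(c(a = 20000, b = 16000),
                       centromeres = tibble::tibble(chrom = c("a", "b"),
                                                    start = c(8000, 6000),
                                                    end = c(10000, 8000)))
  bins <- make_bins(lay, 1000)
  A <- matrix(stats::rpois(20 * 16, 3), 20, 16)
  idx <- which(A > 0, arr.ind = TRUE)
  cm <- contact_matrix(bins, tibble::tibble(bin1 = idx[, 1], bin2 = idx[, 2] + 20,
                                            count = A[idx]))
  F <- 6
  am <- aca(cm, lay$centromeres, F = F)

  # brute-force oracle: average the four orientation combinations of the
  # rescaled cross matrix over both chromosome orders, then symmetrise
  P <- function(n, cen_mid, rev) microhic:::.iso_map(n, cen_mid, F, rev)
  Pa <- list(fwd = P(20, 9, FALSE), rev = P(20, 9, TRUE))
  Pb <- list(fwd = P(16, 7, FALSE), rev = P(16, 7, TRUE))
  acc <- matrix(0, 2 * F, 2 * F); nacc <- 0
  for (o1 in 1:2) for (o2 in 1:2) {
    acc <- acc + t(Pa[[o1]]) %*% A %*% Pb[[o2]]; nacc <- nacc + 1
    acc <- acc + t(Pb[[o2]]) %*% t(A) %*% Pa[[o1]]; nacc <- nacc + 1
  }
  oracle <- acc / nacc
  oracle <- (oracle + t(oracle)) / 2
  expect_equal(am$trans_map, oracle, tolerance = 1e-9)
})

test_that("Rabl classification is inclusive at the threshold and monotone in k_c", {
  fake <- structure(list(cen_score = 1.5, tel_score = 1, F = 20, k = 3),
                    class = "hic_aca")
  expect_equal(classify_rabl(fake), "type_I_rabl")
  fake$cen_score <- 1.4999
  expect_equal(classify_rabl(fake), "non_rabl")

  scores <- vapply(c(0, 2, 4, 8), function(kc) {
    p <- small_sim_params(k_c = kc)
    tr <- simulate_genome(p, 67, with_sequence = FALSE)
    m <- sample_contacts(expected_intensity(tr, 20000), 68)
    cen <- suppressWarnings(call_centromeres(trans_profile(m)))
    aca(m, cen)$cen_score
  }, 0)
  expect_true(all(diff(scores) > 0))    # cen corner grows with bundling
  lab <- ifelse(scores >= 1.5, "type_I_rabl", "non_rabl")
  expect_false(any(lab[-length(lab)] == "type_I_rabl" & lab[-1] == "non_rabl"))
})

test_that("bundled simulations order the corner scores as cen > tel > 1", {
  p <- small_sim_params(n_pairs = 5e5)
  tr <- simulate_genome(p, 69, with_sequence = FALSE)
  m <- sample_contacts(expected_intensity(tr, 20000), 70)
  cen <- call_centromeres(trans_profile(m))
  am <- aca(m, cen)
  expect_gt(am$cen_score, am$tel_score)
  expect_gt(am$tel_score, 1)
  expect_equal(classify_rabl(am), "type_I_rabl")
})
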