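test_that("the generator is deterministic under a fixed seed", {
  p <- small_sim_params(chrom_len_range = c(2e5, 3e5))
  t1 <- simulate_genome(p, 9)
  t2 <- simulate_genome(p, 9)
  expect_identical(as.character(t1$seqs), as.character(t2$seqs))
  expect_identical(t1$domains, t2$domains)
  expect_identical(t1$genes, t2$genes)
  t3 <- simulate_genome(p, 10)
  expect_false(identical(as.character(t1$seqs), as.character(t3$seqs)))

  # byte-identical FASTA under the same seed
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_fasta(t1$seqs, f1); write_fasta(t2$seqs, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("simulated sequence respects GC content and telomeric repeats", {
  p <- sim_params(n_chrom = 2, chrom_len_range = c(9e5, 1.1e6), gc = 0.5,
                  cen_width = 60000, telomere_copies = 5,
                  omit_last_3prime_telomere = TRUE)
  tr <- simulate_genome(p, 3)
  s1 <- as.character(tr$seqs[[1]])
  # observed GC within 3 binomial sd of the target
  gc_obs <- mean(strsplit(s1, "")[[1]] %in% c("G", "C"))
  sd3 <- 3 * sqrt(0.5 * 0.5 / nchar(s1))
  expect_lt(abs(gc_obs - 0.5), sd3 + 1e-9)

  tel5 <- strrep("TTAGGGG", 5)
  tel3 <- strrep("CCCCTAA", 5)
  expect_true(startsWith(s1, tel5))
  expect_true(endsWith(s1, tel3))
  s2 <- as.character(tr$seqs[[2]])
  expect_true(startsWith(s2, tel5))
  expect_false(endsWith(s2, tel3))     # deliberately omitted 3' end
})

test_that("planted domains tile arms and boundaries sit at junctions", {
  tr <- simulate_genome(small_sim_params(), 5, with_sequence = FALSE)
  dm <- tr$domains
  expect_true(all(dm$end > dm$start))
  by_arm <- split(dm, paste(dm$chrom, dm$arm))
  for (arm in by_arm) {
    arm <- arm[order(arm$start), ]
    if (nrow(arm) > 1) {
      expect_equal(arm$start[-1], arm$end[-nrow(arm)])   # no gaps, no overlap
    }
  }
  # every boundary start coincides with a domain junction
  expect_true(all(tr$boundaries$start %in% dm$start))
  # centromeres inside chromosomes, domains clear of the centromere
  cen <- tr$layout$centromeres
  for (r in seq_len(nrow(cen))) {
    dch <- dm[dm$chrom == cen$chrom[r], ]
    expect_false(any(bf_overlaps(dch$start, dch$end, cen$start[r], cen$end[r])))
  }
})

test_that("expected intensity follows the stated decay, boost and trans structure", {
  p <- small_sim_params()
  tr <- simulate_genome(p, 7, with_sequence = FALSE)
  lam <- expected_intensity(tr)

  # pick an interior run of one domain >= 5 bins wide
  res <- p$resolution
  wide <- tr$domains[tr$domains$end - tr$domains$start >= 10 * res, ][1, ]
  b0 <- lam$bins$bin[lam$bins$chrom == wide$chrom &
                       lam$bins$start == wide$start][1] + 1
  # same-domain pairs at distances 1 and 3 bins: ratio (3+1)/(1+1) = 2
  expect_equal(intensity_at(lam, b0, b0 + 1) / intensity_at(lam, b0, b0 + 3), 2)

  # uniform-trans limit: k_c = k_t = 0 makes every trans intensity equal
  p0 <- small_sim_params(k_c = 0, k_t = 0)
  tr0 <- simulate_genome(p0, 7, with_sequence = FALSE)
  lam0 <- expected_intensity(tr0)
  cid <- match(lam0$bins$chrom, unique(lam0$bins$chrom))
  set.seed(8)
  i <- sample(which(cid == 1), 20); j <- sample(which(cid == 3), 20)
  expect_equal(stats::sd(intensity_at(lam0, i, j)), 0)

  # brute-force normalisation check on a tiny genome: sum lambda = N
  pt <- sim_params(n_chrom = 2, chrom_len_range = c(4e4, 6e4), resolution = 2000,
                   n_pairs = 5000, cen_width = 8000, telomere_extent = 4000)
  trt <- simulate_genome(pt, 2, with_sequence = FALSE)
  lamt <- expected_intensity(trt)
  nb <- nrow(lamt$bins)
  pairs <- t(utils::combn(nb, 2))
  tot <- sum(intensity_at(lamt, pairs[, 1], pairs[, 2]))
  expect_equal(tot, pt$n_pairs, tolerance = 1e-6)
  expect_equal(intensity_total(lamt), pt$n_pairs)

  # cis share matches the trans_frac split
  expect_equal(lamt$cis_total / pt$n_pairs, 1 - pt$trans_frac, tolerance = 1e-9)
})

test_that("sampling is Poisson around lambda and replicates correlate", {
  pt <- sim_params(n_chrom = 2, chrom_len_range = c(3e4, 4e4), resolution = 2000,
                   n_pairs = 2000, cen_width = 8000, telomere_extent = 4000)
  trt <- simulate_genome(pt, 4, with_sequence = FALSE)
  lamt <- expected_intensity(trt)
  probe <- rbind(c(1, 2), c(1, 5), c(3, 9))
  mu <- intensity_at(lamt, probe[, 1], probe[, 2])
  draws <- sapply(1:200, function(s) {
    m <- sample_contacts(lamt, s)
    contact_count(m, probe[, 1], probe[, 2])
  })
  emp <- rowMeans(draws)
  # empirical mean within 3 sd of lambda
  expect_true(all(abs(emp - mu) <= 3 * sqrt(mu / 200) + 1e-9))

  # replicates from one lambda are positively correlated on nonzero pairs
  p <- small_sim_params()
  tr <- simulate_genome(p, 6, with_sequence = FALSE)
  lam <- expected_intensity(tr)
  reps <- sample_replicates(lam, 11, 12)
  ct1 <- reps[[1]]$contacts
  common <- dplyr::inner_join(ct1, reps[[2]]$contacts, by = c("bin1", "bin2"))
  expect_gt(stats::cor(common$count.x, common$count.y), 0)
  expect_false(identical(reps[[1]]$contacts, reps[[2]]$contacts))
})

test_that("decay exponent is recoverable from a boost-free simulation", {
  p <- small_sim_params(n_pairs = 5e5, domain_boost = 1)
  tr <- simulate_genome(p, 13, with_sequence = FALSE)
  m <- sample_contacts(expected_intensity(tr), 14)
  slope <- decay_slope(decay_curve(m))
  expect_gt(slope, -1.1)
  expect_lt(slope, -0.9)
})

test_that("centromere bundling enrichment is recoverable at its planted strength", {
  p <- small_sim_params(n_pairs = 1e6)
  tr <- simulate_genome(p, 15, with_sequence = FALSE)
  lam <- expected_intensity(tr, 20000)
  m <- sample_contacts(lam, 16)
  cid <- match(m$bins$chrom, unique(m$bins$chrom))
  cw <- lam$cen_w
  core <- cw >= 1
  bg <- cw == 0 & lam$tel_w == 0
  ct <- m$contacts
  tk <- cid[ct$bin1] != cid[ct$bin2]
  cc <- tk & core[ct$bin1] & core[ct$bin2]
  bb <- tk & bg[ct$bin1] & bg[ct$bin2]
  n_cc_pairs <- sum(outer(tapply(core, cid, sum), tapply(core, cid, sum))[
    upper.tri(diag(length(unique(cid))))])
  n_bb_pairs <- sum(outer(tapply(bg, cid, sum), tapply(bg, cid, sum))[
    upper.tri(diag(length(unique(cid))))])
  ratio <- (sum(ct$count[cc]) / n_cc_pairs) / (sum(ct$count[bb]) / n_bb_pairs)
  expect_lt(abs(ratio - (1 + p$k_c)), 0.2 * (1 + p$k_c))
})

test_that("motif planting hits the requested fraction of boundaries", {
  p <- small_sim_params(chrom_len_range = c(4e5, 6e5))
  tr <- simulate_genome(p, 17)
  cons <- "TGACGTCA"
  nb <- nrow(tr$boundaries)

  pl0 <- plant_boundary_motifs(tr$seqs, tr, cons, 0, seed = 1)
  expect_identical(as.character(pl0$seqs), as.character(tr$seqs))
  expect_equal(nrow(pl0$planted), 0)

  pl1 <- plant_boundary_motifs(tr$seqs, tr, cons, 1, seed = 1)
  expect_equal(nrow(pl1$planted), nb)
  for (r in seq_len(nb)) {
    bnd <- pl1$planted[r, ]
    seg <- substr(as.character(pl1$seqs[[bnd$chrom]]), bnd$start + 1, bnd$end)
    expect_true(grepl(cons, seg, fixed = TRUE))
  }

  pl6 <- plant_boundary_motifs(tr$seqs, tr, cons, 0.6, seed = 2)
  expect_equal(nrow(pl6$planted), round(0.6 * nb))

  expect_error(plant_boundary_motifs(tr$seqs, tr, strrep("ACGT", 600), 0.5),
               "longer than")
})
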