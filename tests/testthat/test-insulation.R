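test_that("insulation raw scores equal the brute-force square mean", {
  set.seed(41)
  for (rep in 1:50) {
    cm <- random_cis_matrix(30, density = stats::runif(1, 0.1, 0.5))
    w <- sample(2:5, 1)
    track <- insulation_score(cm, w_bp = w * 1000)
    expect_equal(track$raw[track$valid], bf_insulation_raw(cm, w)[track$valid])
    expect_true(all(is.na(track$score[!track$valid])))
  }
})

test_that("a constant matrix has normalised score zero everywhere valid", {
  lay <- genome_layout(c(chrA = 20000))
  bins <- make_bins(lay, 1000)
  pairs <- t(utils::combn(20, 2))
  cm <- contact_matrix(bins, tibble::tibble(bin1 = pairs[, 1], bin2 = pairs[, 2],
                                            count = 4))
  track <- insulation_score(cm, w_bp = 3000)
  expect_equal(track$score[track$valid], rep(0, sum(track$valid)))
  # chromosome mean of raw ratios is 1
  expect_equal(mean(track$raw[track$valid]) / mean(track$raw[track$valid]), 1)
})

test_that("a two-block matrix yields its junction as the unique boundary", {
  lay <- genome_layout(c(chrA = 20000))
  bins <- make_bins(lay, 1000)
  blocks <- rbind(t(utils::combn(1:10, 2)), t(utils::combn(11:20, 2)))
  cm <- contact_matrix(bins, tibble::tibble(bin1 = blocks[, 1], bin2 = blocks[, 2],
                                            count = 5))
  track <- insulation_score(cm, w_bp = 3000)
  v <- track$score[track$valid]
  # the minimum sits on the two junction bins (the last bin of block 1 and
  # the first of block 2, whose squares are both fully cross-block)
  expect_true(track$bin[track$valid][which.min(v)] %in% c(10, 11))
  expect_true(all(v[!track$bin[track$valid] %in% c(10, 11)] > min(v)))

  bnd_p <- call_boundaries(track, min_strength = 0.1, method = "prominence")
  expect_equal(bnd_p$bin, 10)      # leftmost of the junction plateau
  bnd_f <- call_boundaries(track, min_strength = 0.1, method = "flank",
                           flank = c(1, 3))
  expect_equal(nrow(bnd_f), 1)
  expect_true(bnd_f$bin %in% c(10, 11))
})

test_that("boundary calling on synthetic tracks follows the stated strength rules", {
  mk_track <- function(score) {
    n <- length(score)
    structure(tibble::tibble(bin = 1:n, chrom = "chrA",
                             start = (0:(n - 1)) * 1000, end = (1:n) * 1000,
                             raw = 2^score, score = score, valid = TRUE),
              class = c("hic_insulation", "tbl_df", "tbl", "data.frame"))
  }
  # monotone track: no interior minimum, no boundary under either method
  mono <- mk_track(seq(0, 1.9, by = 0.1))
  expect_equal(nrow(call_boundaries(mono, method = "prominence")), 0)
  expect_equal(nrow(call_boundaries(mono, 0.1, method = "flank")), 0)

  # V-shaped track of depth 0.5: one boundary with that strength (prominence)
  v <- mk_track(c(seq(0.5, 0, by = -0.1), seq(0.1, 0.5, by = 0.1)))
  bp <- call_boundaries(v, min_strength = 0.1, method = "prominence")
  expect_equal(nrow(bp), 1)
  expect_equal(bp$strength, 0.5)
  expect_equal(bp$bin, 6)

  # plateau minimum resolves to the leftmost bin
  plat <- mk_track(c(1, 0.8, 0.2, 0.2, 0.2, 0.8, 1))
  bpl <- call_boundaries(plat, min_strength = 0.1, method = "prominence")
  expect_equal(bpl$bin, 3)
})

test_that("boundary count is non-increasing in min_strength", {
  sim <- simulate_hic(small_sim_params(), seed = 43)
  track <- insulation_multiscale(sim$matrix)
  for (method in c("flank", "prominence")) {
    counts <- vapply(c(0.05, 0.1, 0.2, 0.3, 0.5),
                     function(ms) nrow(call_boundaries(track, ms, method = method)), 0)
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("segmentation closes globules at chromosome ends and conserves bins", {
  lay <- genome_layout(c(chrA = 40000))
  bins <- make_bins(lay, 2000)      # 20 bins of 2 kb
  bnd <- tibble::tibble(chrom = "chrA", bin = 11, start = 20000, end = 22000,
                        score = -1, strength = 1)
  gl <- segment_globules(bnd, bins)
  expect_equal(nrow(gl$globules), 2)
  expect_equal(gl$globules$size_kb, c(20, 18))

  # zero boundaries: one globule spanning each chromosome
  lay2 <- genome_layout(c(chrA = 40000, chrB = 30000))
  bins2 <- make_bins(lay2, 2000)
  gl2 <- segment_globules(bnd[0, ], bins2)
  expect_equal(nrow(gl2$globules), 2)
  expect_equal(gl2$globules$size_kb, c(40, 30))

  # label partition: boundary + interior + edge = all bins
  sim <- simulate_hic(small_sim_params(), seed = 44)
  track <- insulation_multiscale(sim$matrix)
  bnd3 <- call_boundaries(track)
  gl3 <- segment_globules(bnd3, sim$matrix$bins, valid = track$valid)
  tab <- table(gl3$labels$label)
  expect_equal(sum(tab), nrow(sim$matrix$bins))
  expect_equal(unname(tab["boundary"]), nrow(bnd3))
  # globules ordered and non-overlapping per chromosome
  for (ch in unique(gl3$globules$chrom)) {
    g <- gl3$globules[gl3$globules$chrom == ch, ]
    expect_true(all(g$start[-1] >= g$end[-nrow(g)]))
  }
})

test_that("globule bin statistics detect planted differences and admit nulls", {
  lay <- genome_layout(c(chrA = 2e6))
  bins <- make_bins(lay, 2000)     # 1000 bins
  labels <- rep(c("boundary", "interior"), length.out = nrow(bins))
  gl <- structure(list(
    globules = tibble::tibble(chrom = "chrA", start = 0, end = 2e6,
                              n_bins = nrow(bins), size_kb = 2000),
    boundaries = tibble::tibble(),
    labels = tibble::tibble(bin = bins$bin, chrom = bins$chrom, label = labels),
    bins = bins), class = "hic_globules")

  # null: genes scattered uniformly; p should rarely clear 0.05
  set.seed(45)
  hits <- 0
  for (s in 1:100) {
    starts <- sort(sample.int(2e6 - 1000, 300))
    genes <- tibble::tibble(chrom = "chrA", start = starts, end = starts + 800,
                            strand = "+", id = paste0("g", seq_along(starts)),
                            expression = stats::rlnorm(300))
    st <- globule_bin_stats(gl, genes)
    p <- st$tests$p_value[st$tests$metric == "genes"]
    if (!is.na(p) && p <= 0.05) hits <- hits + 1
  }
  expect_lte(hits, 10)      # close to nominal: > 0.05 in >= 90% of shuffles

  # power: doubled gene density on boundary bins is detected
  set.seed(46)
  bsel <- bins[labels == "boundary", ]
  isel <- bins[labels == "interior", ]
  genes2 <- dplyr::bind_rows(
    tibble::tibble(chrom = "chrA",
                   start = bsel$start[sample.int(nrow(bsel), 400, TRUE)] + 100),
    tibble::tibble(chrom = "chrA",
                   start = isel$start[sample.int(nrow(isel), 200, TRUE)] + 100))
  genes2$end <- genes2$start + 500
  genes2$strand <- "+"
  genes2$id <- paste0("h", seq_len(nrow(genes2)))
  st2 <- globule_bin_stats(gl, genes2)
  expect_lt(st2$tests$p_value[st2$tests$metric == "genes"], 0.05)

  # degenerate: empty gene set gives zero counts and undefined p
  st0 <- globule_bin_stats(gl, genes2[0, ])
  expect_true(all(st0$per_bin$genes == 0))
  expect_true(is.na(st0$tests$p_value[st0$tests$metric == "genes"]))
})
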