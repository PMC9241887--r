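# Brute-force oracles and small fixture builders shared across test files.
# Oracles are deliberately naive (double loops, full enumeration) and
# independent of the package's vectorised implementations.

toy_layout <- function(lens = c(chrA = 60000, chrB = 40000), telomere_extent = 4000) {
  genome_layout(lens, telomere_extent = telomere_extent)
}

# random sparse symmetric single-chromosome matrix
random_cis_matrix <- function(n_bins = 30, res = 1000, density = 0.3, max_count = 9) {
  lay <- genome_layout(stats::setNames(n_bins * res, "chrT"))
  bins <- make_bins(lay, res)
  pairs <- which(upper.tri(matrix(0, n_bins, n_bins)) |
                   diag(n_bins) == 1, arr.ind = TRUE)
  keep <- stats::runif(nrow(pairs)) < density
  contact_matrix(bins, tibble::tibble(bin1 = pairs[keep, 1], bin2 = pairs[keep, 2],
                                      count = sample.int(max_count, sum(keep), TRUE)))
}

# brute-force insulation raw score: mean count over the w x w square
bf_insulation_raw <- function(cm, w) {
  n <- nrow(cm$bins)
  raw <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i - w < 1 || i + w > n) next
    total <- 0
    for (a in (i - w):(i - 1)) for (b in (i + 1):(i + w)) {
      total <- total + contact_count(cm, a, b)
    }
    raw[i] <- total / w^2
  }
  raw
}

# brute-force BH step-up q-values
bf_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  for (i in (n - 1):1) q[i] <- min(q[i], q[i + 1])
  out <- numeric(n)
  out[o] <- pmin(q, 1)
  out
}

# brute-force per-bin trans sums
bf_trans_profile <- function(cm) {
  ch <- cm$bins$chrom
  out <- numeric(nrow(cm$bins))
  for (r in seq_len(nrow(cm$contacts))) {
    i <- cm$contacts$bin1[r]; j <- cm$contacts$bin2[r]
    if (ch[i] != ch[j]) {
      out[i] <- out[i] + cm$contacts$count[r]
      out[j] <- out[j] + cm$contacts$count[r]
    }
  }
  out
}

# brute-force exact binomial upper tail by summation
bf_binom_tail <- function(k, n, p) {
  sum(vapply(k:n, function(x) stats::dbinom(x, n, p), 0))
}

# brute-force interval overlap (>= 1 bp, half-open)
bf_overlaps <- function(s1, e1, s2, e2) s1 < e2 & e1 > s2

# brute-force PWM null distribution by enumerating all 4^w words
bf_pwm_null <- function(pw, background, granularity = 1e-3) {
  S <- round(log2(pw$mat / background) / granularity)
  w <- pw$width
  words <- as.matrix(expand.grid(rep(list(1:4), w)))
  score <- integer(nrow(words))
  prob <- numeric(nrow(words))
  for (r in seq_len(nrow(words))) {
    score[r] <- sum(S[cbind(words[r, ], seq_len(w))])
    prob[r] <- prod(background[words[r, ]])
  }
  agg <- rowsum(prob, score)
  tibble::tibble(score_int = as.integer(rownames(agg)), prob = unname(agg[, 1]))
}

# a small default simulation shared by several files (4 chromosomes ~1 Mb)
small_sim_params <- function(...) {
  args <- utils::modifyList(
    list(n_chrom = 4, chrom_len_range = c(6e5, 1.2e6), n_pairs = 2e5,
         cen_width = 60000),
    list(...))
  do.call(sim_params, args)
}

# globule-set fixture with chosen boundary bins on one chromosome
make_globules_fixture <- function(n_bins = 30, res = 1000, boundary_bins = c(10, 20)) {
  lay <- genome_layout(stats::setNames(n_bins * res, "chrA"))
  bins <- make_bins(lay, res)
  labels <- rep("interior", n_bins)
  labels[boundary_bins] <- "boundary"
  structure(list(
    globules = tibble::tibble(chrom = "chrA", start = 0, end = n_bins * res,
                              n_bins = n_bins, size_kb = n_bins * res / 1000),
    boundaries = tibble::tibble(chrom = "chrA", bin = boundary_bins,
                                start = (boundary_bins - 1) * res,
                                end = boundary_bins * res),
    labels = tibble::tibble(bin = bins$bin, chrom = bins$chrom, label = labels),
    bins = bins), class = "hic_globules")
}

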