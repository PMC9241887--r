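#' Fit a distance-decay contact prior from a cis matrix
#'
#' Distance-stratified estimate of the per-pair contact probability, in the
#' spirit of spline-based Hi-C significance callers: cis bin-pair distances
#' are grouped into (approximately) equal-occupancy strata -- each stratum
#' holding a similar share of the cis reads -- and the per-pair probability of
#' a stratum is its read share divided by its number of possible pairs.
#' Stratum probabilities are made monotone non-increasing in distance by
#' isotonic correction, connected by piecewise-linear interpolation in log
#' distance, and renormalised so the expected probabilities over all possible
#' cis pairs sum to one. The matrix diagonal (distance 0) is excluded
#' throughout.
#'
#' @param cm A `contact_matrix` with cis reads.
#' @param n_strata Target number of strata (reduced if fewer distinct
#'   distances are present).
#' @return A `hic_prior` object with a `$prob(d_bins)` evaluator,
#'   `$strata` tibble, and bookkeeping totals.
#' @export
fit_distance_prior <- function(cm, n_strata = 100) {
  idx <- .bin_index(cm$bins)
  kind <- .contact_kind(cm)
  ct <- cm$contacts[kind == "cis" & cm$contacts$bin2 > cm$contacts$bin1, ]
  if (!nrow(ct)) rlang::abort("no off-diagonal cis reads to fit a prior on")
  d <- ct$bin2 - ct$bin1
  dmax <- max(idx$n) - 1
  counts_d <- numeric(dmax)
  agg <- tapply(ct$count, d, sum)
  counts_d[as.integer(names(agg))] <- agg
  npairs_d <- vapply(seq_len(dmax), function(dd) sum(pmax(idx$n - dd, 0)), 0)
  live <- npairs_d > 0
  total_cis <- sum(counts_d)

  # equal-occupancy strata: split distances so each stratum carries roughly
  # total/n_strata reads (empty-tail distances fold into the last stratum)
  n_strata <- min(n_strata, sum(live & counts_d > 0))
  target <- total_cis / n_strata
  stratum <- pmin(n_strata, floor(cumsum(counts_d) / target - 1e-9) + 1)
  stratum[!live] <- NA
  strata <- tibble::tibble(d = seq_len(dmax), stratum = stratum,
                           count = counts_d, n_pairs = npairs_d) |>
    dplyr::filter(!is.na(.data$stratum)) |>
    dplyr::group_by(.data$stratum) |>
    dplyr::summarise(
      mid = sum(.data$d * .data$n_pairs) / sum(.data$n_pairs),
      count = sum(.data$count), n_pairs = sum(.data$n_pairs), .groups = "drop") |>
    dplyr::mutate(p_raw = .data$count / total_cis / .data$n_pairs)

  # isotonic non-increasing correction (pool-adjacent-violators on -p)
  iso <- stats::isoreg(strata$mid, -strata$p_raw)
  strata$p_iso <- pmax(-iso$yf, .Machine$double.xmin)

  # piecewise-linear in log distance, constant beyond the end strata
  fx <- log(strata$mid)
  fy <- strata$p_iso
  raw_prob <- if (length(fx) < 2) {
    function(d_bins) rep(fy[1], length(d_bins))
  } else {
    function(d_bins) {
      x <- log(pmax(d_bins, 0.5))
      stats::approx(fx, fy, xout = x, rule = 2, ties = "ordered")$y
    }
  }
  # renormalise so the expected total probability over all cis pairs is 1
  denom <- sum(npairs_d[live] * raw_prob(which(live)))
  prob <- function(d_bins) raw_prob(d_bins) / denom

  structure(list(strata = strata, prob = prob, total_cis = total_cis,
                 npairs_d = npairs_d, dmax = dmax, n_strata = n_strata),
            class = "hic_prior")
}

#' @export
print.hic_prior <- function(x, ...) {
  cat("<hic_prior> ", x$n_strata, " equal-occupancy strata over ",
      x$total_cis, " cis reads\n", sep = "")
  invisible(x)
}

# shared binomial upper-tail machinery: P(X >= k), X ~ Bin(n, p)
.binom_upper <- function(k, n, p) {
  stats::pbinom(k - 1, n, p, lower.tail = FALSE)
}

#' Significance of cis contacts under a distance-decay prior
#'
#' Every cis bin pair with at least one read is tested: the p-value is the
#' binomial upper tail of observing at least the recorded count in
#' `total cis reads` trials with the prior's per-pair probability at that
#' pair's distance. Benjamini-Hochberg q-values are computed over all tested
#' cis pairs. Pairs with zero counts and diagonal pairs are outside the
#' tested universe (stated in the result's metadata).
#'
#' @param cm A `contact_matrix`.
#' @param prior A `hic_prior` fitted on `cm` (or on a stated training
#'   matrix sharing the bin table).
#' @return A `hic_contacts` object; `$records` holds `bin1`, `bin2`, anchor
#'   coordinates, `count`, `prior_p`, `p_value`, `q_value`, `kind = "cis"`.
#' @export
cis_significance <- function(cm, prior) {
  if (prior$dmax > max(.bin_index(cm$bins)$n) - 1) {
    rlang::abort("prior and matrix bin tables disagree")
  }
  kind <- .contact_kind(cm)
  ct <- cm$contacts[kind == "cis" & cm$contacts$bin2 > cm$contacts$bin1 &
                      cm$contacts$count >= 1, ]
  d <- ct$bin2 - ct$bin1
  p0 <- prior$prob(d)
  n <- prior$total_cis
  pv <- .binom_upper(ct$count, n, p0)
  rec <- .contact_records(cm$bins, ct, prior_p = p0, p_value = pv, kind = "cis")
  rec$q_value <- stats::p.adjust(rec$p_value, method = "BH")
  .new_hic_contacts(rec, meta = list(kind = "cis", n_trials = n,
                                     tested = nrow(rec),
                                     universe = "cis pairs with count >= 1"))
}

#' Significance of trans contacts under a uniform-expectation model
#'
#' Trans pairs are tested against the uniform null: per-pair probability
#' `1 / number of possible trans pairs`, `n = total trans reads`. BH
#' correction runs over tested trans pairs, separately from cis.
#'
#' @param cm A `contact_matrix` with at least two chromosomes.
#' @return A `hic_contacts` object with `kind = "trans"` records.
#' @export
trans_significance <- function(cm) {
  idx <- .bin_index(cm$bins)
  m_trans <- (nrow(cm$bins)^2 - sum(idx$n^2)) / 2
  if (m_trans <= 0) rlang::abort("no trans pairs possible: single chromosome")
  kind <- .contact_kind(cm)
  ct <- cm$contacts[kind == "trans" & cm$contacts$count >= 1, ]
  n <- sum(ct$count)
  p0 <- 1 / m_trans
  pv <- .binom_upper(ct$count, n, p0)
  rec <- .contact_records(cm$bins, ct, prior_p = p0, p_value = pv, kind = "trans")
  rec$q_value <- stats::p.adjust(rec$p_value, method = "BH")
  .new_hic_contacts(rec, meta = list(kind = "trans", n_trials = n,
                                     tested = nrow(rec),
                                     universe = "trans pairs with count >= 1"))
}

.contact_records <- function(bins, ct, prior_p, p_value, kind) {
  tibble::tibble(
    chrom1 = bins$chrom[ct$bin1], start1 = bins$start[ct$bin1], end1 = bins$end[ct$bin1],
    chrom2 = bins$chrom[ct$bin2], start2 = bins$start[ct$bin2], end2 = bins$end[ct$bin2],
    bin1 = ct$bin1, bin2 = ct$bin2, count = ct$count,
    prior_p = prior_p, p_value = p_value, kind = kind)
}

.new_hic_contacts <- function(records, meta) {
  structure(list(records = records, meta = meta), class = "hic_contacts")
}

#' @export
print.hic_contacts <- function(x, ...) {
  cat("<hic_contacts> ", x$meta$kind %||% "mixed", ": ", nrow(x$records),
      " tested pairs", sep = "")
  if (!is.null(x$meta$thresholds)) {
    cat(" (filtered: q <= ", x$meta$thresholds$q_max, ", count >= ",
        x$meta$thresholds$min_count, ")", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Filter significance records to the reported contact set
#'
#' Keeps records with `q_value <= q_max` and `count >= min_count` (a
#' `min_count` of 3 implements a "more than 2 reads" rule). Cis and trans
#' record sets can be filtered together or separately.
#'
#' @param ... One or more `hic_contacts` objects (typically the cis and trans
#'   results).
#' @param q_max FDR threshold (default 0.01).
#' @param min_count Minimum read count (default 3).
#' @return A `hic_contacts` with the retained records, thresholds and
#'   kept/tested totals in `$meta`.
#' @export
filter_significant <- function(..., q_max = 0.01, min_count = 3) {
  objs <- list(...)
  rec <- dplyr::bind_rows(lapply(objs, function(o) o$records))
  tested <- nrow(rec)
  keep <- rec[!is.na(rec$q_value) & rec$q_value <= q_max & rec$count >= min_count, ]
  .new_hic_contacts(keep, meta = list(
    kind = paste(unique(keep$kind), collapse = "+"),
    tested = tested, kept = nrow(keep),
    thresholds = list(q_max = q_max, min_count = min_count)))
}

#' Draw a null contact matrix from a fitted distance prior
#'
#' Scatters `n_reads` cis reads over all possible cis bin pairs
#' multinomially, with per-pair probabilities given by the prior at each
#' pair's distance -- the null model of the cis significance test.
#'
#' @param prior A `hic_prior`.
#' @param bins The `bin_table` the prior was fitted on.
#' @param n_reads Total reads to scatter.
#' @param seed Integer seed.
#' @return A `contact_matrix` of null cis counts.
#' @export
simulate_null_from_prior <- function(prior, bins, n_reads, seed = 1) {
  set.seed(seed)
  idx <- .bin_index(bins)
  dmax <- max(idx$n) - 1
  npairs_d <- vapply(seq_len(dmax), function(dd) sum(pmax(idx$n - dd, 0)), 0)
  live <- which(npairs_d > 0)
  p_d <- prior$prob(live)
  # reads per distance, then uniform scatter over that distance's pairs
  per_d <- stats::rmultinom(1, n_reads, p_d * npairs_d[live])[, 1]
  pieces <- vector("list", length(live))
  for (ii in seq_along(live)) {
    k <- per_d[ii]
    if (k == 0) next
    dd <- live[ii]
    # scatter reads uniformly over the (chrom, offset) pairs at distance dd
    avail <- pmax(idx$n - dd, 0)
    ch <- sample.int(nrow(idx), k, replace = TRUE, prob = avail)
    off <- floor(stats::runif(k) * avail[ch])
    pieces[[ii]] <- cbind(idx$first[ch] + off, dd)
  }
  acc <- do.call(rbind, pieces)
  contact_matrix(bins, tibble::tibble(bin1 = acc[, 1], bin2 = acc[, 1] + acc[, 2],
                                      count = 1L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
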