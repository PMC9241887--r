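#' Genome-wide contact decay curve
#'
#' Summarises how cis contact frequency falls with genomic separation. For
#' each distance stratum the observed counts are divided by the number of
#' possible bin pairs at that separation and by the total cis read count,
#' giving a per-pair contact probability; `mass` is the plain fraction of cis
#' reads in the stratum (summing to 1 over strata).
#'
#' @param cm A `contact_matrix` with cis entries.
#' @param log_binning Group distances into geometric strata (factor 1.25);
#'   otherwise one stratum per bin distance.
#' @return A `hic_decay` tibble: `distance` (bp, stratum mean separation),
#'   `n_pairs` (possible pairs), `count`, `prob`, `mass`.
#' @export
decay_curve <- function(cm, log_binning = TRUE) {
  res <- bin_resolution(cm$bins)
  idx <- .bin_index(cm$bins)
  kind <- .contact_kind(cm)
  ct <- cm$contacts[kind == "cis", ]
  ct <- ct[ct$bin2 > ct$bin1, ]
  if (!nrow(ct)) rlang::abort("matrix has no off-diagonal cis pairs")
  d <- ct$bin2 - ct$bin1
  dmax <- max(idx$n) - 1
  counts_d <- numeric(dmax)
  agg <- tapply(ct$count, d, sum)
  counts_d[as.integer(names(agg))] <- agg
  npairs_d <- vapply(seq_len(dmax), function(dd) sum(pmax(idx$n - dd, 0)), 0)
  total_cis <- sum(ct$count)

  dist_bins <- seq_len(dmax)
  if (log_binning) {
    edges <- unique(c(1, ceiling(1.25^(1:ceiling(log(dmax + 1) / log(1.25))))))
    stratum <- findInterval(dist_bins, edges)
  } else {
    stratum <- dist_bins
  }
  out <- tibble::tibble(stratum = stratum, d = dist_bins,
                        count = counts_d, n_pairs = npairs_d) |>
    dplyr::filter(.data$n_pairs > 0) |>
    dplyr::group_by(.data$stratum) |>
    dplyr::summarise(distance = sum(.data$d * .data$n_pairs) / sum(.data$n_pairs) * res,
                     count = sum(.data$count), n_pairs = sum(.data$n_pairs),
                     .groups = "drop") |>
    dplyr::arrange(.data$distance) |>
    dplyr::mutate(prob = .data$count / .data$n_pairs / total_cis,
                  mass = .data$count / total_cis) |>
    dplyr::select("distance", "n_pairs", "count", "prob", "mass")
  structure(out, resolution = res, total_cis = total_cis,
            class = c("hic_decay", class(out)))
}

#' Fit the log-log slope of a decay curve
#'
#' Weighted least squares of `log(prob)` on `log(distance + offset)`, weights
#' proportional to observed counts; strata with zero counts are dropped.
#'
#' @param curve A `hic_decay`.
#' @param offset_bp Decay offset added to distance before the log (defaults
#'   to one bin).
#' @return The fitted slope (a negative number for decaying contact maps).
#' @export
decay_slope <- function(curve, offset_bp = attr(curve, "resolution")) {
  cv <- curve[curve$count > 0, ]
  fit <- stats::lm(log(prob) ~ log(distance + offset_bp), data = cv,
                   weights = cv$count)
  unname(stats::coef(fit)[2])
}

#' Cis/trans partition of a contact matrix
#'
#' @param cm A `contact_matrix`.
#' @return List with `total_cis`, `total_trans`, `cis_share` and `per_chrom`
#'   (tibble of per-chromosome cis/trans read totals; trans pairs count once
#'   per involved chromosome).
#' @export
cis_trans_summary <- function(cm) {
  kind <- .contact_kind(cm)
  total_cis <- sum(cm$contacts$count[kind == "cis"])
  total_trans <- sum(cm$contacts$count[kind == "trans"])
  ch <- cm$bins$chrom
  per <- dplyr::bind_rows(
    tibble::tibble(chrom = ch[cm$contacts$bin1], kind = kind, count = cm$contacts$count),
    tibble::tibble(chrom = ch[cm$contacts$bin2], kind = kind,
                   count = cm$contacts$count)[kind == "trans", ]) |>
    dplyr::group_by(.data$chrom, .data$kind) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "kind", values_from = "count", values_fill = 0)
  for (k in c("cis", "trans")) if (!k %in% names(per)) per[[k]] <- 0
  tot <- total_cis + total_trans
  list(total_cis = total_cis, total_trans = total_trans,
       cis_share = if (tot > 0) total_cis / tot else NA_real_,
       per_chrom = per)
}

# dense symmetric cis matrix for one chromosome (local indices)
.dense_cis <- function(cm, chrom) {
  idx <- .bin_index(cm$bins)
  k <- match(chrom, idx$chrom)
  f <- idx$first[k]; n <- idx$n[k]
  A <- matrix(0, n, n)
  ct <- cm$contacts
  sel <- ct$bin1 >= f & ct$bin1 < f + n & ct$bin2 >= f & ct$bin2 < f + n
  ct <- ct[sel, ]
  if (nrow(ct)) {
    A[cbind(ct$bin1 - f + 1, ct$bin2 - f + 1)] <- ct$count
    A[cbind(ct$bin2 - f + 1, ct$bin1 - f + 1)] <- ct$count
  }
  A
}

#' Random-walk reproducibility score between two replicate matrices
#'
#' A re-implementation of the random-walk concordance idea behind
#' GenomeDISCO: per chromosome, each cis matrix is converted to a
#' row-stochastic transition matrix, raised to the `t_steps`-th power, and the
#' two smoothed matrices are compared by their elementwise L1 difference
#' divided by the number of retained (nonzero-degree in either replicate)
#' bins. The score is the mean over chromosomes of `1 - d/2`, clipped to
#' `[0, 1]`; identical matrices score exactly 1 and the score is invariant to
#' global count scaling.
#'
#' @param m1,m2 Two `contact_matrix` objects on the same bin table.
#' @param t_steps Random-walk steps (default 3).
#' @return A score in `[0, 1]`.
#' @export
reproducibility_score <- function(m1, m2, t_steps = 3) {
  if (!identical(m1$bins$chrom, m2$bins$chrom) ||
      !identical(m1$bins$start, m2$bins$start)) {
    rlang::abort("replicate matrices must share a bin table")
  }
  chroms <- unique(m1$bins$chrom)
  per <- vapply(chroms, function(ch) {
    A1 <- .dense_cis(m1, ch); A2 <- .dense_cis(m2, ch)
    keep <- rowSums(A1) > 0 | rowSums(A2) > 0
    if (!any(keep)) return(NA_real_)
    A1 <- A1[keep, keep, drop = FALSE]; A2 <- A2[keep, keep, drop = FALSE]
    walk <- function(A) {
      rs <- rowSums(A)
      P <- A / ifelse(rs > 0, rs, 1)   # all-zero rows stay zero
      Pt <- P
      for (s in seq_len(t_steps - 1)) Pt <- Pt %*% P
      Pt
    }
    d <- sum(abs(walk(A1) - walk(A2))) / sum(keep)
    min(1, max(0, 1 - d / 2))
  }, 0)
  mean(per, na.rm = TRUE)
}
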