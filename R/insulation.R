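#' Insulation score along the matrix diagonal
#'
#' For each bin `i`, the raw score is the mean contact count in the `w x w`
#' square upstream-by-downstream of the bin (`a` in `i-w..i-1`, `b` in
#' `i+1..i+w`, same chromosome). Bins without a full square (within `w` bins
#' of a chromosome end) are masked invalid rather than computed on a
#' truncated square, so scores are comparable along the chromosome. The
#' normalised score is `log2(raw / mean(raw))` with the mean taken per
#' chromosome over valid bins only; insulating boundaries appear as local
#' minima.
#'
#' @param cm A `contact_matrix`.
#' @param w_bp Square side in bp (at least twice the resolution); default 5
#'   bins at the matrix resolution.
#' @return A `hic_insulation` tibble: `bin`, `chrom`, `start`, `end`, `raw`,
#'   `score`, `valid`; attribute `w` holds the window in bins.
#' @export
insulation_score <- function(cm, w_bp = 5 * bin_resolution(cm$bins)) {
  res <- bin_resolution(cm$bins)
  if (w_bp < 2 * res) rlang::abort("insulation window must be at least 2 bins")
  w <- as.integer(round(w_bp / res))
  idx <- .bin_index(cm$bins)
  kind <- .contact_kind(cm)
  ct <- cm$contacts[kind == "cis", ]

  out <- vector("list", nrow(idx))
  for (k in seq_len(nrow(idx))) {
    f <- idx$first[k]; n <- idx$n[k]
    raw <- rep(NA_real_, n)
    valid <- seq_len(n) > w & seq_len(n) <= n - w
    if (any(valid)) {
      sel <- ct$bin1 >= f & ct$bin1 < f + n
      a <- ct$bin1[sel] - f + 1; b <- ct$bin2[sel] - f + 1; cnt <- ct$count[sel]
      # each contact (a, b) feeds the squares of bins i with a < i < b,
      # i - a <= w and b - i <= w: a contiguous range, so accumulate
      # range-additions and take a cumulative sum
      lo <- pmax(a + 1, b - w); hi <- pmin(b - 1, a + w)
      ok <- lo <= hi
      sums <- numeric(n)
      if (any(ok)) {
        delta <- numeric(n + 1)
        ag <- rowsum(c(cnt[ok], -cnt[ok]), c(lo[ok], hi[ok] + 1))
        delta[as.integer(rownames(ag))] <- ag[, 1]
        sums <- cumsum(delta)[seq_len(n)]
      }
      raw[valid] <- sums[valid] / w^2
    }
    mu <- mean(raw[valid])
    # bins with an empty square score -Inf: a maximal dip, still valid
    score <- if (any(valid) && is.finite(mu) && mu > 0) log2(raw / mu) else rep(NA_real_, n)
    score[!valid] <- NA_real_
    out[[k]] <- tibble::tibble(bin = f:(f + n - 1), raw = raw, score = score,
                               valid = valid & !is.na(score))
  }
  track <- dplyr::bind_cols(cm$bins[c("chrom", "start", "end")], dplyr::bind_rows(out))
  track <- track[, c("bin", "chrom", "start", "end", "raw", "score", "valid")]
  structure(track, w = w, resolution = res,
            class = c("hic_insulation", class(track)))
}

# run-compressed local extrema of a numeric vector; returns leftmost index
# and value of interior minimum/maximum runs
.local_extrema <- function(v) {
  r <- rle(v)
  nr <- length(r$values)
  if (nr < 3) return(list(min = integer(0), max = integer(0)))
  starts <- c(1, cumsum(r$lengths)[-nr] + 1)
  inner <- 2:(nr - 1)
  is_min <- r$values[inner] < r$values[inner - 1] & r$values[inner] < r$values[inner + 1]
  is_max <- r$values[inner] > r$values[inner - 1] & r$values[inner] > r$values[inner + 1]
  list(min = starts[inner][is_min], max = starts[inner][is_max])
}

#' Multi-scale insulation track
#'
#' Averages the normalised insulation score over several window sizes and
#' lightly smooths the result (centred moving average), which suppresses the
#' window-scale correlated noise of a single-window track while preserving
#' domain-junction dips across the range of domain sizes. A bin is valid if
#' it is valid at any contributing window.
#'
#' @param cm A `contact_matrix`.
#' @param windows_bp Window sizes to average over (default 6, 8, 10 and 12
#'   bins at the matrix resolution).
#' @param smooth_bins Width of the final moving average (default 3; 0
#'   disables).
#' @return A `hic_insulation` track.
#' @export
insulation_multiscale <- function(cm,
                                  windows_bp = c(6, 8, 10, 12) * bin_resolution(cm$bins),
                                  smooth_bins = 3) {
  tracks <- lapply(windows_bp, function(w) insulation_score(cm, w_bp = w))
  avg <- tracks[[1]]
  sc <- vapply(tracks, function(t) t$score, numeric(nrow(avg)))
  avg$score <- rowMeans(sc, na.rm = TRUE)
  avg$raw <- rowMeans(vapply(tracks, function(t) t$raw, numeric(nrow(avg))), na.rm = TRUE)
  avg$valid <- rowSums(vapply(tracks, function(t) t$valid, logical(nrow(avg)))) > 0 &
    is.finite(avg$score)
  half <- floor(smooth_bins / 2)
  if (half > 0) {
    for (ch in unique(avg$chrom)) {
      sel <- which(avg$chrom == ch)
      v <- avg$score[sel]; v[!avg$valid[sel]] <- NA
      n <- length(v)
      sm <- vapply(seq_len(n), function(i) {
        mean(v[max(1, i - half):min(n, i + half)], na.rm = TRUE)
      }, 0)
      avg$score[sel] <- ifelse(avg$valid[sel], sm, avg$score[sel])
    }
  }
  attr(avg, "windows_bp") <- windows_bp
  avg
}

#' Call insulating boundaries from an insulation track
#'
#' Boundaries are dips of the normalised insulation score. Two strength
#' definitions are available:
#'
#' * `"flank"` (default): the strength of bin `i` is the mean score over the
#'   two flanking windows (`flank[1]`..`flank[2]` bins away on each side)
#'   minus the score at `i`; boundaries are local maxima of this
#'   matched-filter statistic reaching `min_strength`. Robust to the
#'   window-scale correlated noise of insulation tracks.
#' * `"prominence"`: boundaries are local minima of the score whose
#'   strength -- the smaller of the drops from the nearest flanking local
#'   maxima -- reaches `min_strength`.
#'
#' In both cases candidates at the valid-mask edges (no usable flank) are
#' discarded and plateau ties resolve to the leftmost bin.
#'
#' @param track A `hic_insulation`.
#' @param min_strength Minimum boundary strength in log2 units (default
#'   0.25).
#' @param method Strength definition, see above.
#' @param flank Inner and outer flank offsets in bins for `method = "flank"`.
#' @return Tibble of boundaries: `chrom`, `bin`, `start`, `end`, `score`,
#'   `strength`, sorted by position.
#' @export
call_boundaries <- function(track, min_strength = 0.25,
                            method = c("flank", "prominence"),
                            flank = c(2, 7)) {
  method <- match.arg(method)
  out <- list()
  for (ch in unique(track$chrom)) {
    tr <- track[track$chrom == ch & track$valid, ]
    if (nrow(tr) < 3) next
    if (method == "prominence") {
      ext <- .local_extrema(tr$score)
      if (!length(ext$min)) next
      # segment endpoints serve as flanking maxima where no interior local
      # maximum exists between a dip and the mask edge
      cand_max <- sort(unique(c(1, ext$max, nrow(tr))))
      for (m in ext$min) {
        lmax <- cand_max[cand_max < m]
        rmax <- cand_max[cand_max > m]
        if (!length(lmax) || !length(rmax)) next
        strength <- min(tr$score[max(lmax)], tr$score[min(rmax)]) - tr$score[m]
        if (strength >= min_strength) {
          out[[length(out) + 1]] <- dplyr::mutate(
            tr[m, c("chrom", "bin", "start", "end", "score")], strength = strength)
        }
      }
    } else {
      v <- tr$score
      # floor -Inf (empty-square) scores well below the finite range so the
      # flank statistic stays finite at and around maximal dips
      if (any(is.infinite(v))) {
        v[is.infinite(v)] <- min(v[is.finite(v)], 0) - 10
      }
      n <- length(v)
      st <- rep(NA_real_, n)
      for (i in seq_len(n)) {
        if (i - flank[2] < 1 || i + flank[2] > n) next  # full flanks only
        lf <- v[(i - flank[2]):(i - flank[1])]
        rf <- v[(i + flank[1]):(i + flank[2])]
        st[i] <- (mean(lf, na.rm = TRUE) + mean(rf, na.rm = TRUE)) / 2 - v[i]
      }
      ns <- -st
      ns[is.na(ns)] <- Inf         # masked bins act as barriers, never minima
      ext <- .local_extrema(ns)    # maxima of st, leftmost on plateaus
      for (m in ext$min) {
        if (is.na(st[m]) || st[m] < min_strength) next
        out[[length(out) + 1]] <- dplyr::mutate(
          tr[m, c("chrom", "bin", "start", "end", "score")], strength = st[m])
      }
    }
  }
  if (!length(out)) {
    return(tibble::tibble(chrom = character(), bin = integer(), start = numeric(),
                          end = numeric(), score = numeric(), strength = numeric()))
  }
  dplyr::arrange(dplyr::bind_rows(out), match(.data$chrom, unique(track$chrom)), .data$bin)
}

#' Segment chromosomes into globules between called boundaries
#'
#' Globules are the intervals between consecutive boundary bins on a
#' chromosome (boundary bins belong to neither flanking globule); chromosome
#' ends close the first and last globule. Each bin is labelled `boundary`,
#' `interior`, or `edge` (bins in the insulation mask's invalid end zones,
#' when a validity mask is supplied).
#'
#' @param boundaries Boundary tibble from [call_boundaries()].
#' @param bins The `bin_table` the boundaries refer to.
#' @param valid Optional logical vector over bins (the insulation validity
#'   mask); invalid non-boundary bins are labelled `edge`.
#' @return A `hic_globules` object: list with `$globules` (tibble: `chrom`,
#'   `start`, `end`, `size_kb`, `n_bins`), `$boundaries`, `$labels` (per-bin
#'   tibble) and `$bins`.
#' @export
segment_globules <- function(boundaries, bins, valid = NULL) {
  idx <- .bin_index(bins)
  labels <- rep("interior", nrow(bins))
  if (!is.null(valid)) labels[!valid] <- "edge"
  labels[match(boundaries$bin, bins$bin)] <- "boundary"
  glob <- list()
  for (k in seq_len(nrow(idx))) {
    f <- idx$first[k]; n <- idx$n[k]
    bnd <- sort(boundaries$bin[boundaries$chrom == idx$chrom[k]])
    seg_start <- c(f, bnd + 1)
    seg_end <- c(bnd - 1, f + n - 1)
    keep <- seg_start <= seg_end
    if (!any(keep)) next
    glob[[k]] <- tibble::tibble(
      chrom = idx$chrom[k],
      start = bins$start[seg_start[keep]],
      end = bins$end[seg_end[keep]],
      n_bins = seg_end[keep] - seg_start[keep] + 1)
  }
  globules <- dplyr::bind_rows(glob)
  globules$size_kb <- (globules$end - globules$start) / 1000
  structure(list(globules = globules, boundaries = boundaries,
                 labels = tibble::tibble(bin = bins$bin, chrom = bins$chrom,
                                         label = labels),
                 bins = bins),
            class = "hic_globules")
}

#' @export
print.hic_globules <- function(x, ...) {
  cat("<hic_globules> ", nrow(x$globules), " globules (",
      sprintf("%.1f-%.1f kb", min(x$globules$size_kb), max(x$globules$size_kb)),
      "), ", nrow(x$boundaries), " boundaries\n", sep = "")
  invisible(x)
}

# per-bin count of overlapping genes plus mean expression of those genes
.gene_bin_cover <- function(bins, genes) {
  counts <- numeric(nrow(bins))
  expr_sum <- numeric(nrow(bins))
  expr_n <- numeric(nrow(bins))
  if (nrow(genes)) {
    b0 <- .pos_to_bin(bins, genes$chrom, genes$start + 1)
    b1 <- .pos_to_bin(bins, genes$chrom, genes$end)
    ok <- !is.na(b0) & !is.na(b1)
    lens <- b1[ok] - b0[ok] + 1
    target <- sequence(lens, from = b0[ok])
    counts <- counts + tabulate(target, nbins = nrow(bins))
    if ("expression" %in% names(genes)) {
      ex <- rep(genes$expression[ok], lens)
      ag <- rowsum(cbind(ex, 1), target)
      at <- as.integer(rownames(ag))
      expr_sum[at] <- ag[, 1]; expr_n[at] <- ag[, 2]
    }
  }
  tibble::tibble(genes = counts,
                 expression = ifelse(expr_n > 0, expr_sum / expr_n, NA_real_))
}

#' Compare boundary and interior bins on gene density, expression and GC
#'
#' Computes per-bin gene counts (overlap of at least 1 bp), mean expression
#' of overlapping genes, and GC fraction, then tests boundary vs interior
#' bins with a two-sided Wilcoxon rank-sum test for each available metric.
#'
#' @param globules A `hic_globules`.
#' @param genes Gene tibble (`chrom`, `start`, `end`, optionally
#'   `expression`).
#' @param seqs Optional `DNAStringSet` for per-bin GC content.
#' @return List with `$per_bin` (tibble) and `$tests` (tibble: `metric`,
#'   `median_boundary`, `median_interior`, `p_value`; `p_value` is `NA` when
#'   a class has fewer than two informative bins or a metric is degenerate).
#' @export
globule_bin_stats <- function(globules, genes, seqs = NULL) {
  bins <- globules$bins
  per_bin <- dplyr::bind_cols(globules$labels, .gene_bin_cover(bins, genes))
  if (!is.null(seqs)) {
    per_bin$gc <- .bin_gc(bins, seqs)
  }
  metrics <- intersect(c("genes", "expression", "gc"), names(per_bin))
  tests <- purrr::map_dfr(metrics, function(mt) {
    b <- per_bin[[mt]][per_bin$label == "boundary"]
    i <- per_bin[[mt]][per_bin$label == "interior"]
    b <- b[is.finite(b)]; i <- i[is.finite(i)]
    p <- NA_real_
    if (length(b) >= 2 && length(i) >= 2 && length(unique(c(b, i))) > 1) {
      p <- suppressWarnings(stats::wilcox.test(b, i)$p.value)
    }
    tibble::tibble(metric = mt,
                   median_boundary = if (length(b)) stats::median(b) else NA_real_,
                   median_interior = if (length(i)) stats::median(i) else NA_real_,
                   p_value = p)
  })
  list(per_bin = per_bin, tests = tests)
}

# GC fraction per bin from chromosome sequences
.bin_gc <- function(bins, seqs) {
  gc <- rep(NA_real_, nrow(bins))
  for (ch in unique(bins$chrom)) {
    if (!ch %in% names(seqs)) next
    sel <- which(bins$chrom == ch)
    v <- Biostrings::Views(seqs[[ch]],
                           start = bins$start[sel] + 1, end = bins$end[sel])
    fr <- Biostrings::letterFrequency(v, c("G", "C"))
    gc[sel] <- rowSums(fr) / (bins$end[sel] - bins$start[sel])
  }
  gc
}
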