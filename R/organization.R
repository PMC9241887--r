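#' Per-bin trans-contact profile
#'
#' Sums, for every bin, the contacts it makes with bins on other
#' chromosomes; each trans pair is counted at both of its ends. Bins within
#' `end_exclusion_bp` of a chromosome end are flagged (telomere bundling
#' otherwise masquerades as a centromere signal) but kept in the table. A
#' centred moving average over `smooth_bins` bins (shrunk near chromosome
#' ends) gives the smoothed profile.
#'
#' @param cm A `contact_matrix`.
#' @param end_exclusion_bp Width of the excluded chromosome-end zones;
#'   default `max(2 bins, 40 kb)`.
#' @param smooth_bins Moving-average window (default 5).
#' @return A `hic_trans_profile` tibble: `bin`, `chrom`, `start`, `end`,
#'   `count`, `smoothed`, `excluded`.
#' @export
trans_profile <- function(cm, end_exclusion_bp = NULL, smooth_bins = 5) {
  res <- bin_resolution(cm$bins)
  if (is.null(end_exclusion_bp)) end_exclusion_bp <- max(2 * res, 40000)
  idx <- .bin_index(cm$bins)
  kind <- .contact_kind(cm)
  ct <- cm$contacts[kind == "trans", ]
  counts <- numeric(nrow(cm$bins))
  if (nrow(ct)) {
    ag <- rowsum(c(ct$count, ct$count), c(ct$bin1, ct$bin2))
    counts[as.integer(rownames(ag))] <- ag[, 1]
  }
  chrom_len <- idx$length[match(cm$bins$chrom, idx$chrom)]
  excluded <- cm$bins$start < end_exclusion_bp |
    cm$bins$end > chrom_len - end_exclusion_bp
  gone <- tapply(!excluded, cm$bins$chrom, sum)[unique(cm$bins$chrom)] == 0
  if (any(gone)) {
    rlang::abort(sprintf("end exclusion swallows chromosome %s",
                         names(gone)[gone][1]))
  }
  smoothed <- numeric(nrow(cm$bins))
  half <- floor(smooth_bins / 2)
  for (k in seq_len(nrow(idx))) {
    sel <- idx$first[k]:(idx$first[k] + idx$n[k] - 1)
    v <- counts[sel]
    n <- length(v)
    cs <- cumsum(c(0, v))
    lo <- pmax(seq_len(n) - half, 1); hi <- pmin(seq_len(n) + half, n)
    smoothed[sel] <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  }
  out <- dplyr::bind_cols(cm$bins[c("bin", "chrom", "start", "end")],
                          tibble::tibble(count = counts, smoothed = smoothed,
                                         excluded = excluded))
  structure(out, end_exclusion_bp = end_exclusion_bp, smooth_bins = smooth_bins,
            resolution = res, class = c("hic_trans_profile", class(out)))
}

#' Call one centromere interval per chromosome from a trans profile
#'
#' Within the non-excluded part of each chromosome, the centromere region is
#' the maximal contiguous run of bins whose smoothed trans frequency rises at
#' least halfway from the chromosome's median to its maximum, anchored at the
#' (leftmost) argmax. The reported midpoint `mid` is then refined by a
#' Poisson template fit: a flat-background-plus-boxcar model is slid over the
#' raw per-bin counts on a sub-bin grid around the run (width profiled over a
#' small range) and the maximum-likelihood centre is kept. Chromosomes whose
#' profile is flat (max/median of the smoothed signal below 2, as when
#' centromere bundling is absent) are flagged `flat`; all-zero chromosomes
#' yield no call with a warning.
#'
#' @param profile A `hic_trans_profile`.
#' @return Tibble: `chrom`, `start`, `end`, `mid` (template-fit midpoint,
#'   bp), `peak`, `flat`.
#' @export
call_centromeres <- function(profile) {
  res <- attr(profile, "resolution") %||%
    max(profile$end - profile$start)
  out <- list()
  for (ch in unique(profile$chrom)) {
    tr <- profile[profile$chrom == ch & !profile$excluded, ]
    if (!nrow(tr) || all(tr$count == 0)) {
      rlang::warn(sprintf("all-zero trans profile on %s: no centromere call", ch))
      next
    }
    v <- tr$smoothed
    peak <- max(v)
    med <- stats::median(v)
    thr <- med + 0.5 * (peak - med)
    amax <- which(v == peak)[1]            # leftmost argmax on ties
    above <- v >= thr
    lo <- amax; while (lo > 1 && above[lo - 1]) lo <- lo - 1
    hi <- amax; while (hi < length(v) && above[hi + 1]) hi <- hi + 1
    mid <- .refine_peak_ml(tr$count, (lo + hi) / 2, hi - lo + 1)
    out[[ch]] <- tibble::tibble(
      chrom = ch, start = tr$start[lo], end = tr$end[hi],
      mid = tr$start[1] + (mid - 0.5) * res, peak = peak,
      flat = med > 0 && peak / med < 2)
  }
  dplyr::bind_rows(out)
}

# maximum-likelihood centre of a boxcar-on-flat-background Poisson signal:
# slide a width-profiled boxcar template over the counts on a 0.1-bin grid
# around the detected run and keep the best centre (local bin units)
.refine_peak_ml <- function(counts, centre0, width0) {
  n <- length(counts)
  B <- stats::median(counts)
  if (B <= 0) return(centre0)
  pos <- seq_len(n)
  best <- -Inf; best_c <- centre0
  for (W in unique(pmax(2, round(width0 + (-3:3))))) {
    for (cg in seq(centre0 - 5, centre0 + 5, by = 0.1)) {
      wt <- pmax(pmin(cg + W / 2, pos + 0.5) - pmax(cg - W / 2, pos - 0.5), 0)
      sel <- wt > 0
      if (!any(sel)) next
      E <- sum(wt[sel] * (counts[sel] - B)) / sum(wt[sel]^2)
      if (!is.finite(E) || E <= 0) next
      mu <- B + E * wt[sel]
      ll <- sum(counts[sel] * log(mu) - mu) - sum(counts[sel] * log(B) - B)
      if (ll > best) { best <- ll; best_c <- cg }
    }
  }
  best_c
}

# overlap-weighted mapping of an ordered bin run onto F slots, columns
# normalised so a slot is the weighted mean of the bins it covers
.arm_map <- function(ord, F) {
  La <- length(ord)
  P <- matrix(0, La, F)
  edges <- seq(0, F, length.out = La + 1)
  for (r in seq_len(La)) {
    s0 <- edges[r]; s1 <- edges[r + 1]
    for (s in (floor(s0) + 1):min(F, ceiling(s1))) {
      ov <- min(s1, s) - max(s0, s - 1)
      if (ov > 0) P[r, s] <- ov
    }
  }
  sweep(P, 2, pmax(colSums(P), .Machine$double.eps), "/")
}

# bin -> isochromosome mapping for one chromosome and orientation:
# slots 1..F = one arm telomere-to-centromere, F+1..2F = other arm
# centromere-to-telomere
.iso_map <- function(n, cen_local, F, reverse = FALSE) {
  m <- cen_local
  if (m < 1 || m >= n) rlang::abort("chromosome arm shorter than one bin")
  if (!reverse) { armA <- 1:m; armB <- (m + 1):n }
  else { armA <- n:(m + 1); armB <- m:1 }
  P <- matrix(0, n, 2 * F)
  # rows of each arm map land at the arm's bin indices, in tel->cen /
  # cen->tel order
  P[armA, 1:F] <- .arm_map(armA, F)
  P[armB, (F + 1):(2 * F)] <- .arm_map(armB, F)
  P
}

#' Aggregate chromosome analysis (ACA)
#'
#' Rescales every chromosome arm to `F` slots and aggregates all
#' chromosome-pair contact sub-matrices -- over every ordered pair and both
#' orientations of each chromosome -- into one `2F x 2F` isochromosome map
#' with the centromere slots adjacent at the centre and telomeres at the
#' corners. The aggregate map includes cis and trans signal; corner scores
#' (centromere centre block, telomere corner blocks, each `k x k` and
#' normalised by the map mean) are computed on the trans-only aggregation,
#' where Rabl-type bundling is not swamped by the cis diagonal.
#'
#' @param cm A `contact_matrix`.
#' @param centromeres Tibble with `chrom`, `start`, `end` covering every
#'   chromosome (called or known centromeres).
#' @param F Slots per arm (default 20).
#' @param k Corner block size (default 3).
#' @return A `hic_aca` object: `$map`, `$trans_map` (2F x 2F matrices),
#'   `$cen_score`, `$tel_score`.
#' @export
aca <- function(cm, centromeres, F = 20, k = 3) {
  stopifnot(F >= 4)
  idx <- .bin_index(cm$bins)
  if (!all(idx$chrom %in% centromeres$chrom)) {
    rlang::abort("a centromere is required for every chromosome")
  }
  maps <- lapply(seq_len(nrow(idx)), function(kk) {
    cen <- centromeres[centromeres$chrom == idx$chrom[kk], ][1, ]
    mid <- (cen$start + cen$end) / 2
    sel <- cm$bins$chrom == idx$chrom[kk]
    local <- which.min(abs((cm$bins$start[sel] + cm$bins$end[sel]) / 2 - mid))
    list(fwd = .iso_map(idx$n[kk], local, F, reverse = FALSE),
         rev = .iso_map(idx$n[kk], local, F, reverse = TRUE))
  })
  dense_pair <- function(k1, k2) {
    f1 <- idx$first[k1]; n1 <- idx$n[k1]
    f2 <- idx$first[k2]; n2 <- idx$n[k2]
    A <- matrix(0, n1, n2)
    ct <- cm$contacts
    sel <- ct$bin1 >= f1 & ct$bin1 < f1 + n1 & ct$bin2 >= f2 & ct$bin2 < f2 + n2
    if (any(sel)) A[cbind(ct$bin1[sel] - f1 + 1, ct$bin2[sel] - f2 + 1)] <- ct$count[sel]
    if (k1 == k2) A <- A + t(A) - diag(diag(A))
    else {
      sel2 <- ct$bin1 >= f2 & ct$bin1 < f2 + n2 & ct$bin2 >= f1 & ct$bin2 < f1 + n1
      if (any(sel2)) A[cbind(ct$bin2[sel2] - f1 + 1, ct$bin1[sel2] - f2 + 1)] <-
          A[cbind(ct$bin2[sel2] - f1 + 1, ct$bin1[sel2] - f2 + 1)] + ct$count[sel2]
    }
    A
  }
  acc_all <- matrix(0, 2 * F, 2 * F); n_all <- 0
  acc_trans <- matrix(0, 2 * F, 2 * F); n_trans <- 0
  for (k1 in seq_len(nrow(idx))) for (k2 in seq_len(nrow(idx))) {
    A <- dense_pair(k1, k2)
    for (o1 in c("fwd", "rev")) for (o2 in c("fwd", "rev")) {
      M <- t(maps[[k1]][[o1]]) %*% A %*% maps[[k2]][[o2]]
      acc_all <- acc_all + M; n_all <- n_all + 1
      if (k1 != k2) { acc_trans <- acc_trans + M; n_trans <- n_trans + 1 }
    }
  }
  sym <- function(M) (M + t(M)) / 2
  map <- sym(acc_all / n_all)
  trans_map <- if (n_trans > 0) sym(acc_trans / n_trans) else NULL
  scores <- c(cen = NA_real_, tel = NA_real_)
  if (!is.null(trans_map) && mean(trans_map) > 0) {
    c_idx <- seq(F - (k - 1) %/% 2, length.out = k)
    cen_block <- trans_map[c_idx, c_idx]
    n2 <- 2 * F
    corners <- list(trans_map[1:k, 1:k], trans_map[1:k, (n2 - k + 1):n2],
                    trans_map[(n2 - k + 1):n2, 1:k],
                    trans_map[(n2 - k + 1):n2, (n2 - k + 1):n2])
    scores["cen"] <- mean(cen_block) / mean(trans_map)
    scores["tel"] <- mean(unlist(corners)) / mean(trans_map)
  }
  structure(list(map = map, trans_map = trans_map, F = F, k = k,
                 cen_score = unname(scores["cen"]),
                 tel_score = unname(scores["tel"])),
            class = "hic_aca")
}

#' @export
print.hic_aca <- function(x, ...) {
  cat(sprintf("<hic_aca> %dx%d map; cen score %.2f, tel score %.2f\n",
              2 * x$F, 2 * x$F, x$cen_score, x$tel_score))
  invisible(x)
}

#' Classify the nuclear architecture as Rabl type I or non-Rabl
#'
#' Type I (Rabl-like centromere clustering) is called when the ACA
#' centromere-centre score reaches `cen_threshold` (inclusive).
#'
#' @param aca_map A `hic_aca`.
#' @param cen_threshold Centromere corner-score threshold (default 1.5).
#' @return `"type_I_rabl"` or `"non_rabl"`.
#' @export
classify_rabl <- function(aca_map, cen_threshold = 1.5) {
  if (!is.na(aca_map$cen_score) && aca_map$cen_score >= cen_threshold) {
    "type_I_rabl"
  } else {
    "non_rabl"
  }
}
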