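#' Convert contact counts to wish distances
#'
#' The target ("wish") spatial distance of an observed bin pair is
#' `count^(-1/exponent)` -- high-contact pairs are wished close -- rescaled so
#' that the median wish distance between adjacent bins on a chromosome equals
#' 1. Only pairs with a positive count receive a wish distance; absence of a
#' contact is treated as missing, not as far.
#'
#' @param cm A `contact_matrix`.
#' @param exponent Count-to-distance exponent (default 3, the
#'   `contact ~ distance^-3` convention).
#' @return A `hic_wish` tibble: `bin1`, `bin2`, `delta`; attributes carry the
#'   bin table.
#' @export
counts_to_wish_distances <- function(cm, exponent = 3) {
  stopifnot(exponent > 0)
  ct <- cm$contacts[cm$contacts$count > 0 & cm$contacts$bin2 > cm$contacts$bin1, ]
  if (!nrow(ct)) rlang::abort("empty contact matrix")
  delta <- ct$count^(-1 / exponent)
  cid <- .bin_chrom_id(cm$bins)
  nn <- cid[ct$bin1] == cid[ct$bin2] & ct$bin2 - ct$bin1 == 1
  scale <- if (any(nn)) stats::median(delta[nn]) else stats::median(delta)
  out <- tibble::tibble(bin1 = ct$bin1, bin2 = ct$bin2, delta = delta / scale)
  structure(out, bins = cm$bins, class = c("hic_wish", class(out)))
}

# dense pairwise Euclidean distances of the rows of X
.pair_dist <- function(X) {
  G <- tcrossprod(X)
  sq <- diag(G)
  D2 <- outer(sq, sq, "+") - 2 * G
  sqrt(pmax(D2, 0))
}

#' Metric MDS embedding of wish distances by majorisation (SMACOF)
#'
#' Minimises the weighted squared stress
#' `sum w_ij (|x_i - x_j| - delta_ij)^2` over observed pairs, with
#' `w_ij = delta_ij^-2`, by iterative majorisation (the Guttman transform).
#' The start is deterministic: classical scaling of the wish-distance matrix
#' completed by graph shortest paths, so repeated runs give identical
#' coordinates without a seed. If the wish-distance graph is disconnected,
#' the largest connected component is embedded and the remaining bins are
#' returned with `NA` coordinates and flagged.
#'
#' @param wish A `hic_wish` from [counts_to_wish_distances()].
#' @param max_iter Iteration cap (non-convergence is reported, the result
#'   still returned).
#' @param tol Relative stress-change stopping threshold.
#' @param init Optional n x 3 start coordinates (rows aligned with embedded
#'   bins); overrides the classical-scaling start.
#' @return A `hic_structure`: `$coords` tibble (`bin`, `chrom`, `start`,
#'   `end`, `x`, `y`, `z`), `$stress`, `$trace` (stress per iteration),
#'   `$converged`, `$embedded` (logical per bin).
#' @export
mds_embed <- function(wish, max_iter = 1000, tol = 1e-6, init = NULL) {
  bins <- attr(wish, "bins")
  n_all <- nrow(bins)
  g <- igraph::graph_from_data_frame(
    data.frame(from = wish$bin1, to = wish$bin2, weight = wish$delta),
    directed = FALSE, vertices = data.frame(name = seq_len(n_all)))
  comp <- igraph::components(g)
  keep <- which(comp$membership == which.max(comp$csize))
  if (length(keep) < n_all) {
    rlang::warn(sprintf("wish-distance graph disconnected: embedding %d of %d bins",
                        length(keep), n_all))
  }
  pos <- match(seq_len(n_all), keep)  # global bin -> embedded row
  n <- length(keep)

  sel <- !is.na(pos[wish$bin1]) & !is.na(pos[wish$bin2])
  i <- pos[wish$bin1[sel]]; j <- pos[wish$bin2[sel]]; del <- wish$delta[sel]

  Delta <- matrix(0, n, n)
  Delta[cbind(i, j)] <- del; Delta[cbind(j, i)] <- del
  W <- matrix(0, n, n)
  W[cbind(i, j)] <- del^-2; W[cbind(j, i)] <- del^-2

  if (is.null(init)) {
    sub <- igraph::induced_subgraph(g, keep)
    D0 <- igraph::distances(sub)
    ord <- match(as.integer(igraph::V(sub)$name), keep)  # vertex -> row
    D0 <- D0[order(ord), order(ord)]
    X <- stats::cmdscale(D0, k = min(3, n - 1))
    if (ncol(X) < 3) X <- cbind(X, matrix(0, n, 3 - ncol(X)))
  } else {
    X <- as.matrix(init)
    stopifnot(nrow(X) == n, ncol(X) == 3)
  }

  # Guttman transform: X <- V^+ B(X) X with V from the weights
  V <- -W; diag(V) <- rowSums(W)
  Vinv <- solve(V + 1 / n) - 1 / n

  WD <- W * Delta                       # fixed numerator of the B matrix
  stress_of <- function(D) sum(W * (D - Delta)^2) / 2
  D <- .pair_dist(X)
  trace <- numeric(max_iter + 1)
  trace[1] <- stress_of(D)
  converged <- FALSE
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    Dsafe <- D
    Dsafe[Dsafe < 1e-12] <- 1           # where W > 0 and D ~ 0 is measure-zero
    B <- -WD / Dsafe
    diag(B) <- 0
    diag(B) <- -rowSums(B)
    X <- Vinv %*% (B %*% X)
    D <- .pair_dist(X)
    s <- stress_of(D)
    trace[it + 1] <- s
    prev <- trace[it]
    if (prev - s < tol * max(prev, .Machine$double.eps)) { converged <- TRUE; break }
  }
  trace <- trace[seq_len(it + 1)]
  if (!converged) {
    rlang::warn(sprintf("majorisation not converged after %d iterations", max_iter))
  }
  coords <- bins[c("bin", "chrom", "start", "end")]
  coords$x <- NA_real_; coords$y <- NA_real_; coords$z <- NA_real_
  coords[keep, c("x", "y", "z")] <- as.data.frame(X)
  structure(list(coords = tibble::as_tibble(coords), stress = trace[length(trace)],
                 trace = trace, converged = converged,
                 embedded = !is.na(pos), wish = wish),
            class = "hic_structure")
}

#' @export
print.hic_structure <- function(x, ...) {
  cat(sprintf("<hic_structure> %d/%d bins embedded; stress %.4g after %d iterations%s\n",
              sum(x$embedded), nrow(x$coords), x$stress, length(x$trace) - 1,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Correlation between embedded and wish distances
#'
#' Pearson correlation over observed pairs between the wish distances and the
#' distances realised by the embedding; a fit-quality summary.
#' @param structure A `hic_structure`.
#' @export
embedding_correlation <- function(structure) {
  w <- structure$wish
  co <- structure$coords
  ok <- structure$embedded[w$bin1] & structure$embedded[w$bin2]
  dx <- as.matrix(co[w$bin1[ok], c("x", "y", "z")]) -
    as.matrix(co[w$bin2[ok], c("x", "y", "z")])
  stats::cor(sqrt(rowSums(dx^2)), w$delta[ok])
}

#' Structural summary metrics: clustering ratios and clothes-pin geometry
#'
#' Centromere (telomere) clustering ratio: mean pairwise 3D distance among
#' centromeric (telomeric) bins divided by the average of the same quantity
#' over `n_draws` random bin sets of equal size -- below 1 means clustered.
#' The per-chromosome clothes-pin score is the distance between the
#' centromere centroid and the telomere centroid divided by the chromosome's
#' radius of gyration; a folded (clothes-pin) chromosome keeps this of order
#' 1 with centromere and telomeres at opposite ends of the fold.
#'
#' @param structure A `hic_structure`.
#' @param layout A `genome_layout` with centromeres annotated.
#' @param n_draws Random draws for the null (default 100).
#' @param seed Seed for the random draws.
#' @return List: `cen_ratio`, `tel_ratio`, `clothespin` tibble, and the null
#'   means used.
#' @export
structure_metrics <- function(structure, layout, n_draws = 100, seed = 1) {
  if (!nrow(layout$centromeres)) rlang::abort("layout carries no centromere annotation")
  co <- structure$coords[structure$embedded, ]
  X <- as.matrix(co[, c("x", "y", "z")])
  mids <- (co$start + co$end) / 2
  in_any <- function(ivs) {
    hit <- rep(FALSE, nrow(co))
    for (r in seq_len(nrow(ivs))) {
      hit <- hit | (co$chrom == ivs$chrom[r] & mids >= ivs$start[r] & mids < ivs$end[r])
    }
    hit
  }
  cen_set <- which(in_any(layout$centromeres))
  tel_set <- which(in_any(.telomere_intervals(layout)))
  mean_pd <- function(rows) {
    if (length(rows) < 2) return(NA_real_)
    mean(stats::dist(X[rows, , drop = FALSE]))
  }
  set.seed(seed)
  null_mean <- function(sz) {
    mean(vapply(seq_len(n_draws), function(...) {
      mean_pd(sample.int(nrow(X), sz))
    }, 0))
  }
  cen_null <- null_mean(length(cen_set))
  tel_null <- null_mean(length(tel_set))
  clothespin <- purrr::map_dfr(unique(co$chrom), function(ch) {
    rows <- which(co$chrom == ch)
    cenr <- intersect(rows, cen_set); telr <- intersect(rows, tel_set)
    rg <- sqrt(mean(rowSums(sweep(X[rows, , drop = FALSE], 2,
                                  colMeans(X[rows, , drop = FALSE]))^2)))
    d <- if (length(cenr) && length(telr)) {
      sqrt(sum((colMeans(X[cenr, , drop = FALSE]) -
                  colMeans(X[telr, , drop = FALSE]))^2))
    } else NA_real_
    tibble::tibble(chrom = ch, cen_tel_distance = d, radius_gyration = rg,
                   clothespin = d / rg)
  })
  list(cen_ratio = mean_pd(cen_set) / cen_null,
       tel_ratio = mean_pd(tel_set) / tel_null,
       cen_null = cen_null, tel_null = tel_null,
       clothespin = clothespin)
}

#' Write embedded coordinates as TSV
#' @param structure A `hic_structure`.
#' @param path Output path.
#' @export
write_structure <- function(structure, path) {
  readr::write_tsv(structure$coords, path)
  invisible(path)
}
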