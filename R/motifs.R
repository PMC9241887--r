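# integer score matrix on the discretisation grid (log2-odds / granularity)
.pwm_int_scores <- function(pwm, background, granularity = 1e-3) {
  round(log2(pwm$mat / background) / granularity)
}

#' Exact null score distribution of a PWM
#'
#' Distribution of the log2-odds score of a random word drawn from the
#' 0-order background, computed by dynamic programming over motif positions
#' with scores discretised to a fixed grid (default granularity 1e-3 log2
#' units). The upper-tail mass of this distribution is the exact p-value
#' used by [scan_pwm()].
#'
#' @param pwm A `pwm`.
#' @param background Length-4 background frequencies (default the PWM's).
#' @param granularity Score grid in log2 units.
#' @return Tibble: `score` (log2 odds, grid-rounded), `prob`, `p_tail`
#'   (probability of a score at least this large).
#' @export
pwm_score_distribution <- function(pwm, background = pwm$background,
                                   granularity = 1e-3) {
  S <- .pwm_int_scores(pwm, background, granularity)
  lo <- sum(apply(S, 2, min)); hi <- sum(apply(S, 2, max))
  probs <- numeric(hi - lo + 1)  # index = score - lo + 1
  # position 1
  p_lo <- min(S[, 1])
  cur_lo <- p_lo
  cur <- numeric(max(S[, 1]) - p_lo + 1)
  for (b in 1:4) cur[S[b, 1] - p_lo + 1] <- cur[S[b, 1] - p_lo + 1] + background[b]
  for (pos in seq_len(pwm$width)[-1]) {
    s <- S[, pos]
    new_lo <- cur_lo + min(s)
    new <- numeric(length(cur) + max(s) - min(s))
    for (b in 1:4) {
      off <- s[b] - min(s)
      idx <- seq_along(cur) + off
      new[idx] <- new[idx] + cur * background[b]
    }
    cur <- new; cur_lo <- new_lo
  }
  nz <- which(cur > 0)
  tb <- tibble::tibble(score_int = nz + cur_lo - 1, prob = cur[nz])
  tb$p_tail <- rev(cumsum(rev(tb$prob)))
  tb$score <- tb$score_int * granularity
  tb[, c("score", "score_int", "prob", "p_tail")]
}

# strand-symmetrised 0-order base frequencies of a sequence set
.seq_background <- function(seqs) {
  fr <- colSums(Biostrings::letterFrequency(seqs, c("A", "C", "G", "T")))
  fr <- fr + 1  # avoid zero background on skewed sequence
  bg <- (fr + rev(fr)) / 2
  unname(bg / sum(bg))
}

.encode_seq <- function(s) {
  code <- match(strsplit(toupper(s), "")[[1]], c("A", "C", "G", "T"))
  code
}

#' Scan sequences with a PWM, reporting hits with exact p-values
#'
#' Every window on both strands is scored as the sum of per-position
#' log2-odds (motif probability over background); the p-value of a score is
#' the upper-tail mass of the exact null distribution from
#' [pwm_score_distribution()]. Windows containing non-ACGT symbols are
#' skipped. The background is estimated from the scanned sequence
#' (strand-symmetrised 0-order frequencies) unless `background = "uniform"`.
#'
#' @param pwm A `pwm` (or list of them; results are row-bound).
#' @param seqs A `DNAStringSet` or named character vector.
#' @param p_max Report hits with `p_value <= p_max` (default 1e-4).
#' @param background `"seq"` (default) or `"uniform"`.
#' @return Tibble of hits: `motif`, `chrom`, `start`, `end` (0-based
#'   half-open), `strand`, `score` (log2 odds), `p_value`.
#' @export
scan_pwm <- function(pwm, seqs, p_max = 1e-4, background = c("seq", "uniform")) {
  background <- match.arg(background)
  if (!methods::is(seqs, "DNAStringSet")) seqs <- Biostrings::DNAStringSet(seqs)
  if (inherits(pwm, "pwm")) pwm <- list(pwm)
  bg <- if (background == "uniform") rep(0.25, 4) else .seq_background(seqs)
  chars <- as.character(seqs)
  if (is.null(names(chars))) names(chars) <- paste0("seq", seq_along(chars))
  codes <- lapply(chars, .encode_seq)

  out <- purrr::map_dfr(pwm, function(pw) {
    w <- pw$width
    S_fwd <- .pwm_int_scores(pw, bg)
    S_rev <- S_fwd[4:1, w:1, drop = FALSE]  # reverse complement scan
    null <- pwm_score_distribution(pw, bg)
    # minimal integer score whose tail mass is within p_max
    ok_tail <- null$score_int[null$p_tail <= p_max]
    if (!length(ok_tail)) return(NULL)
    t_min <- min(ok_tail)
    pval_of <- function(si) {
      pos <- findInterval(si, null$score_int)
      null$p_tail[pmax(pos, 1)]
    }
    purrr::map_dfr(names(codes), function(ch) {
      code <- codes[[ch]]
      L <- length(code)
      if (L < w) return(NULL)
      nwin <- L - w + 1
      score_one <- function(S) {
        sc <- numeric(nwin)
        for (pos in seq_len(w)) {
          sc <- sc + S[cbind(code[pos:(pos + nwin - 1)], pos)]
        }
        sc
      }
      res <- list()
      for (str in c("+", "-")) {
        sc <- score_one(if (str == "+") S_fwd else S_rev)
        hit <- which(!is.na(sc) & sc >= t_min)
        if (length(hit)) {
          res[[str]] <- tibble::tibble(
            motif = pw$id, chrom = ch, start = hit - 1, end = hit - 1 + w,
            strand = str, score = sc[hit] * 1e-3, p_value = pval_of(sc[hit]))
        }
      }
      dplyr::bind_rows(res)
    })
  })
  if (!nrow(out)) {
    out <- tibble::tibble(motif = character(), chrom = character(),
                          start = numeric(), end = numeric(), strand = character(),
                          score = numeric(), p_value = numeric())
  }
  dplyr::arrange(out, .data$motif, .data$chrom, .data$start, .data$strand)
}

#' Rank motifs by the proportion of boundaries containing a hit
#'
#' A boundary "contains" a motif when at least one hit overlaps the boundary
#' interval by at least 1 bp. Motifs are ranked by descending proportion of
#' motif-containing boundaries; ties break by motif id.
#'
#' @param hits Hit tibble from [scan_pwm()].
#' @param boundaries Boundary intervals (`chrom`, `start`, `end`).
#' @return Tibble: `motif`, `n_boundaries_with_hit`, `total_boundaries`,
#'   `proportion`, `rank`.
#' @export
boundary_enrichment <- function(hits, boundaries) {
  if (!nrow(boundaries)) rlang::abort("zero boundaries")
  nb <- nrow(boundaries)
  out <- purrr::map_dfr(unique(hits$motif), function(mo) {
    h <- hits[hits$motif == mo, ]
    with_hit <- vapply(seq_len(nb), function(r) {
      any(h$chrom == boundaries$chrom[r] & h$start < boundaries$end[r] &
            h$end > boundaries$start[r])
    }, FALSE)
    tibble::tibble(motif = mo, n_boundaries_with_hit = sum(with_hit),
                   total_boundaries = nb, proportion = sum(with_hit) / nb)
  })
  out <- dplyr::arrange(out, dplyr::desc(.data$proportion), .data$motif)
  out$rank <- seq_len(nrow(out))
  out
}

#' Promoter intervals upstream of genes
#'
#' The promoter is the `upstream_bp` window 5' of the gene start on its
#' strand, truncated at chromosome edges. Genes without strand are skipped
#' with a warning.
#'
#' @param genes Gene tibble (`chrom`, `start`, `end`, `strand`, `id`).
#' @param layout A `genome_layout` (for chromosome-edge truncation).
#' @param upstream_bp Promoter width (default 1500).
#' @return Tibble: `id`, `chrom`, `start`, `end`, `strand`.
#' @export
promoters <- function(genes, layout, upstream_bp = 1500) {
  stranded <- genes$strand %in% c("+", "-")
  if (any(!stranded)) {
    rlang::warn(sprintf("%d genes without strand skipped", sum(!stranded)))
  }
  g <- genes[stranded, ]
  len <- layout$chroms$length[match(g$chrom, layout$chroms$chrom)]
  start <- ifelse(g$strand == "+", pmax(0, g$start - upstream_bp), g$end)
  end <- ifelse(g$strand == "+", g$start, pmin(len, g$end + upstream_bp))
  out <- tibble::tibble(id = g$id, chrom = g$chrom, start = start, end = end,
                        strand = g$strand)
  out[out$end > out$start, ]
}

#' Motif presence in gene promoters
#'
#' @param hits Hit tibble from [scan_pwm()].
#' @param genes Gene tibble with strand.
#' @param layout A `genome_layout`.
#' @param upstream_bp Promoter width (default 1500).
#' @return Long tibble: one row per gene x motif with `n_hits` and `present`.
#' @export
promoter_scan <- function(hits, genes, layout, upstream_bp = 1500) {
  pr <- promoters(genes, layout, upstream_bp)
  motifs <- unique(hits$motif)
  purrr::map_dfr(motifs, function(mo) {
    h <- hits[hits$motif == mo, ]
    n <- vapply(seq_len(nrow(pr)), function(r) {
      sum(h$chrom == pr$chrom[r] & h$start < pr$end[r] & h$end > pr$start[r])
    }, 0L)
    tibble::tibble(id = pr$id, motif = mo, promoter_start = pr$start,
                   promoter_end = pr$end, strand = pr$strand,
                   n_hits = n, present = n > 0)
  })
}
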