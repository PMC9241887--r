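#' Parameters for the synthetic Hi-C generator
#'
#' The generator emulates the contact structure of a small multi-chromosome
#' fungal genome in a Rabl configuration: power-law intra-chromosomal distance
#' decay, planted self-interacting domains, centromere-centromere and
#' telomere-telomere trans-contact bundling, and Poisson count sampling.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_len_range Chromosome length range in bp.
#' @param resolution Working bin width in bp; domain and boundary ground truth
#'   are laid out on this grid.
#' @param alpha Power-law distance-decay exponent (contact intensity
#'   proportional to `(d + d0)^-alpha` with `d` in bins).
#' @param d0_bins Decay offset in bins.
#' @param domain_size_range Planted domain size range in bp.
#' @param domain_boost Multiplicative intensity boost for bin pairs inside the
#'   same domain (beta).
#' @param k_c,k_t Centromere / telomere trans-bundling strengths: a
#'   centromere-centromere trans pair has `1 + k_c` times the background trans
#'   intensity (and analogously for telomeres).
#' @param trans_frac Expected fraction of total read pairs that are trans.
#'   (Resolution-independent; the cis/trans split is fixed before bundling.)
#' @param n_pairs Total expected read pairs N; the expected intensity is
#'   normalised so its genome-wide sum equals N.
#' @param loops Optional planted loops: data frame with `chrom1`, `pos1`,
#'   `chrom2`, `pos2`, `fold` (bp positions; fold multiplies the local cis
#'   intensity).
#' @param gc GC fraction of the simulated sequence.
#' @param cen_width Centromere width in bp.
#' @param telomere_extent Width of chromosome-end regions treated as
#'   telomeric.
#' @param telomere_copies Tandem copies of the telomeric repeat unit planted
#'   at chromosome ends.
#' @param telomere_unit Telomeric repeat unit, planted as written at 5' ends
#'   and as its reverse complement at 3' ends.
#' @param omit_last_3prime_telomere If `TRUE` (default) the 3' end of the last
#'   chromosome carries no telomeric repeat, mirroring an incompletely
#'   assembled chromosome end.
#' @param gene_density Mean bp of genome per gene; genes are placed uniformly
#'   and non-overlapping.
#' @param gene_len_range Gene length range in bp.
#' @param promoter_bp Promoter width reserved upstream of each gene.
#' @param dispersion Negative-binomial overdispersion; 0 (default) gives pure
#'   Poisson sampling.
#' @return A `sim_params` list.
#' @export
sim_params <- function(n_chrom = 8,
                       chrom_len_range = c(1.8e6, 5.9e6),
                       resolution = 2000,
                       alpha = 1.0,
                       d0_bins = 1,
                       domain_size_range = c(2000, 80000),
                       domain_boost = 2.0,
                       k_c = 4.0,
                       k_t = 2.0,
                       trans_frac = 0.25,
                       n_pairs = 1e6,
                       loops = NULL,
                       gc = 0.5,
                       cen_width = 160000,
                       telomere_extent = 40000,
                       telomere_copies = 5,
                       telomere_unit = "TTAGGGG",
                       omit_last_3prime_telomere = TRUE,
                       gene_density = 3150,
                       gene_len_range = c(500, 3000),
                       promoter_bp = 1500,
                       dispersion = 0) {
  p <- as.list(environment())
  stopifnot(p$n_chrom >= 1, p$resolution > 0, p$alpha > 0,
            p$k_c >= 0, p$k_t >= 0, p$trans_frac >= 0, p$trans_frac < 1,
            p$n_pairs > 0, p$domain_boost >= 1, p$dispersion >= 0)
  structure(p, class = "sim_params")
}

.ROMAN <- function(i) paste0("chr", as.character(utils::as.roman(i)))

# uniform non-overlapping placement of n intervals of given widths on [0, len)
.place_intervals <- function(len, widths) {
  free <- len - sum(widths)
  if (free < 0) return(NULL)
  gaps <- stats::runif(length(widths) + 1)
  gaps <- gaps / sum(gaps) * free
  starts <- cumsum(gaps)[seq_along(widths)] + c(0, cumsum(widths))[seq_along(widths)]
  floor(starts)
}

#' Simulate a genome: layout, sequence, genes and domain/centromere truth
#'
#' Chromosome lengths are drawn uniformly from `chrom_len_range`; one
#' centromere per chromosome is placed away from the ends (midpoint uniform in
#' the central half); self-interacting domains tile both chromosome arms with
#' sizes uniform on `domain_size_range` (snapped to the working bin grid);
#' the single bin at each junction between consecutive domains is recorded as
#' a boundary. Sequence is i.i.d. at the requested GC with tandem telomeric
#' repeats planted at chromosome ends (reverse complement at 3' ends). Genes
#' are placed uniformly without overlap, leaving room for their promoters
#' where possible.
#'
#' @param params A [sim_params()] list.
#' @param seed Integer seed; the same seed reproduces the genome exactly.
#' @param with_sequence Generate the DNA sequence (set `FALSE` to skip the
#'   most expensive step when only coordinates are needed).
#' @return A `hic_truth` object: list with `$layout`, `$domains`,
#'   `$boundaries`, `$genes`, `$seqs` (DNAStringSet or NULL), `$loops`,
#'   `$params`.
#' @export
simulate_genome <- function(params = sim_params(), seed = 1, with_sequence = TRUE) {
  set.seed(seed)
  res <- params$resolution
  lens <- stats::runif(params$n_chrom, params$chrom_len_range[1], params$chrom_len_range[2])
  lens <- floor(lens)
  chroms <- tibble::tibble(chrom = .ROMAN(seq_len(params$n_chrom)), length = lens)

  # centromeres: fixed width, midpoint uniform in the central half, snapped to grid
  cen_half <- params$cen_width / 2
  mid <- stats::runif(params$n_chrom, 0.3, 0.7) * lens
  cen_start <- pmax(res, round((mid - cen_half) / res) * res)
  cen_end <- pmin(cen_start + params$cen_width, floor((lens - 1) / res) * res)
  cens <- tibble::tibble(chrom = chroms$chrom, start = cen_start, end = cen_end)
  layout <- genome_layout(chroms, cens, telomere_extent = params$telomere_extent)

  # domains tile each arm independently; sizes snapped to the bin grid
  min_dom <- max(res, params$domain_size_range[1])
  max_dom <- max(min_dom, params$domain_size_range[2])
  tile_arm <- function(ch, a0, a1) {
    a0 <- ceiling(a0 / res) * res
    a1 <- floor(a1 / res) * res
    if (a1 - a0 < min_dom) return(NULL)
    out_start <- numeric(0); out_end <- numeric(0); pos <- a0
    while (a1 - pos >= min_dom) {
      size <- round(stats::runif(1, min_dom, max_dom) / res) * res
      size <- max(res, min(size, a1 - pos))
      if (a1 - (pos + size) < min_dom) size <- a1 - pos  # absorb the stub
      out_start <- c(out_start, pos); out_end <- c(out_end, pos + size)
      pos <- pos + size
    }
    tibble::tibble(chrom = ch, start = out_start, end = out_end)
  }
  domains <- dplyr::bind_rows(purrr::pmap(
    list(chroms$chrom, chroms$length, cens$start, cens$end),
    function(ch, len, cs, ce) {
      dplyr::bind_rows(
        dplyr::mutate(tile_arm(ch, 0, cs), arm = "left"),
        dplyr::mutate(tile_arm(ch, ce, len), arm = "right"))
    }))

  # boundary = the bin starting at each junction between consecutive domains
  boundaries <- domains |>
    dplyr::group_by(.data$chrom, .data$arm) |>
    dplyr::filter(dplyr::row_number() > 1) |>
    dplyr::ungroup() |>
    dplyr::transmute(.data$chrom, start = .data$start, end = .data$start + res) |>
    dplyr::arrange(match(.data$chrom, chroms$chrom), .data$start)
  boundaries$boundary_id <- seq_len(nrow(boundaries))

  # genes: uniform non-overlapping, promoter gap reserved upstream
  genes <- dplyr::bind_rows(purrr::map2(chroms$chrom, chroms$length, function(ch, len) {
    n <- max(1, round(len / params$gene_density))
    glen <- round(stats::runif(n, params$gene_len_range[1], params$gene_len_range[2]))
    starts <- .place_intervals(len - params$promoter_bp, glen + params$promoter_bp)
    if (is.null(starts)) {
      n <- floor(len / (max(params$gene_len_range) + 2 * params$promoter_bp))
      glen <- glen[seq_len(n)]
      starts <- .place_intervals(len - params$promoter_bp, glen + params$promoter_bp)
    }
    starts <- starts + params$promoter_bp  # room for the upstream promoter
    tibble::tibble(chrom = ch, start = starts, end = starts + glen,
                   strand = sample(c("+", "-"), n, replace = TRUE))
  }))
  genes$id <- sprintf("g%05d", seq_len(nrow(genes)))
  genes$expression <- round(stats::rlnorm(nrow(genes), meanlog = 2, sdlog = 1), 3)

  seqs <- NULL
  if (with_sequence) {
    seqs <- .simulate_sequence(layout, params)
  }

  structure(list(layout = layout, domains = domains, boundaries = boundaries,
                 genes = genes, seqs = seqs, loops = params$loops,
                 params = params),
            class = "hic_truth")
}

# i.i.d. sequence at given GC with telomeric repeats planted at the ends
.simulate_sequence <- function(layout, params) {
  gc <- params$gc
  probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  bases <- as.raw(c(65L, 67L, 71L, 84L))  # A C G T
  unit5 <- toupper(params$telomere_unit)
  unit3 <- .revcomp_chr(unit5)
  tel5 <- strrep(unit5, params$telomere_copies)
  tel3 <- strrep(unit3, params$telomere_copies)
  n_chrom <- nrow(layout$chroms)
  seqs <- purrr::map_chr(seq_len(n_chrom), function(k) {
    len <- layout$chroms$length[k]
    s <- rawToChar(bases[sample.int(4L, len, replace = TRUE, prob = probs)])
    substr(s, 1, nchar(tel5)) <- tel5
    omit3 <- params$omit_last_3prime_telomere && k == n_chrom
    if (!omit3) substr(s, len - nchar(tel3) + 1, len) <- tel3
    s
  })
  Biostrings::DNAStringSet(stats::setNames(seqs, layout$chroms$chrom))
}

.revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' @export
print.hic_truth <- function(x, ...) {
  cat("<hic_truth> ", nrow(x$layout$chroms), " chromosomes, ",
      nrow(x$domains), " planted domains, ", nrow(x$boundaries),
      " boundaries, ", nrow(x$genes), " genes",
      if (is.null(x$seqs)) " (no sequence)" else "", "\n", sep = "")
  invisible(x)
}

# centromere / telomere bin weights: trapezoidal profile -- 1 inside the
# interval, decaying linearly to 0 over one bin width beyond each edge --
# averaged over each bin, so the weight field is centred exactly on the
# interval regardless of how it sits on the bin grid
.interval_weights <- function(bins, intervals) {
  w <- numeric(nrow(bins))
  if (!nrow(intervals)) return(w)
  res <- bin_resolution(bins)
  trap <- function(p, s, e) {
    ifelse(p >= s & p < e, 1,
           ifelse(p >= s - res & p < s, (p - (s - res)) / res,
                  ifelse(p >= e & p < e + res, (e + res - p) / res, 0)))
  }
  for (r in seq_len(nrow(intervals))) {
    s <- intervals$start[r]; e <- intervals$end[r]
    near <- which(bins$chrom == intervals$chrom[r] &
                    bins$end > s - res & bins$start < e + res)
    for (b in near) {
      # midpoint quadrature of the trapezoid over the bin
      p <- seq(bins$start[b], bins$end[b], length.out = 21)
      p <- (p[-1] + p[-21]) / 2
      w[b] <- max(w[b], mean(trap(p, s, e)))
    }
  }
  w
}

.telomere_intervals <- function(layout) {
  te <- layout$telomere_extent
  dplyr::bind_rows(
    tibble::tibble(chrom = layout$chroms$chrom, start = 0,
                   end = pmin(te, layout$chroms$length)),
    tibble::tibble(chrom = layout$chroms$chrom,
                   start = pmax(0, layout$chroms$length - te),
                   end = layout$chroms$length))
}

#' Expected contact intensity for a simulated genome
#'
#' Builds the per-bin-pair expected intensity lambda implied by the ground
#' truth: cis pairs follow `(d + d0)^-alpha` (d in bins) times the
#' `domain_boost` for same-domain pairs and any planted loop fold; trans pairs
#' have a flat baseline times `1 + k_c c_i c_j + k_t t_i t_j` with c/t the
#' centromeric/telomeric bin weights. The whole field is scaled so it sums to
#' `n_pairs`, with an expected trans share of `trans_frac`.
#'
#' The object stores the field in factored form (scales plus per-bin weights),
#' so it stays cheap at fine resolutions; use [intensity_at()] to evaluate
#' individual pairs and [intensity_total()] for the genome-wide sum.
#'
#' @param truth A `hic_truth` from [simulate_genome()].
#' @param resolution Bin width at which to lay out the field (defaults to the
#'   generator's working resolution).
#' @return A `hic_intensity` object.
#' @export
expected_intensity <- function(truth, resolution = truth$params$resolution) {
  params <- truth$params
  bins <- make_bins(truth$layout, resolution)
  idx <- .bin_index(bins)
  n_chrom <- nrow(idx)
  d0 <- params$d0_bins * params$resolution / resolution  # offset kept in bp terms
  beta <- params$domain_boost

  # domain id per bin by midpoint containment
  dom_id <- rep(NA_integer_, nrow(bins))
  mids <- (bins$start + bins$end) / 2
  for (r in seq_len(nrow(truth$domains))) {
    hit <- which(bins$chrom == truth$domains$chrom[r] &
                   mids >= truth$domains$start[r] & mids < truth$domains$end[r])
    dom_id[hit] <- r
  }

  loops <- NULL
  if (!is.null(truth$loops) && nrow(truth$loops)) {
    b1 <- .pos_to_bin(bins, truth$loops$chrom1, truth$loops$pos1 + 1)
    b2 <- .pos_to_bin(bins, truth$loops$chrom2, truth$loops$pos2 + 1)
    loops <- tibble::tibble(bin1 = pmin(b1, b2), bin2 = pmax(b1, b2),
                            fold = truth$loops$fold)
    loops <- loops[loops$bin1 != loops$bin2 &
                     !duplicated(paste(loops$bin1, loops$bin2)), ]
  }

  # unnormalised cis mass: sum over diagonals of u(d) * domain boost (+ loops)
  u <- function(d) (d + d0)^(-params$alpha)
  s_cis <- 0
  for (k in seq_len(n_chrom)) {
    n <- idx$n[k]
    if (n < 2) next
    dom <- dom_id[idx$first[k]:(idx$first[k] + n - 1)]
    for (d in seq_len(n - 1)) {
      a <- dom[1:(n - d)]; b <- dom[(1 + d):n]
      same <- !is.na(a) & !is.na(b) & a == b
      s_cis <- s_cis + u(d) * (n - d + (beta - 1) * sum(same))
    }
  }
  if (!is.null(loops)) {
    cid <- .bin_chrom_id(bins)
    cis_loop <- loops[cid[loops$bin1] == cid[loops$bin2], ]
    if (nrow(cis_loop)) {
      d <- cis_loop$bin2 - cis_loop$bin1
      same <- !is.na(dom_id[cis_loop$bin1]) & !is.na(dom_id[cis_loop$bin2]) &
        dom_id[cis_loop$bin1] == dom_id[cis_loop$bin2]
      s_cis <- s_cis + sum((cis_loop$fold - 1) * u(d) * ifelse(same, beta, 1))
    }
  }

  # trans: flat baseline with centromere/telomere bundling
  cw <- .interval_weights(bins, truth$layout$centromeres)
  tw <- .interval_weights(bins, .telomere_intervals(truth$layout))
  csum <- tapply(cw, .bin_chrom_id(bins), sum)
  tsum <- tapply(tw, .bin_chrom_id(bins), sum)
  m_trans <- (nrow(bins)^2 - sum(idx$n^2)) / 2
  s_cc <- (sum(csum)^2 - sum(csum^2)) / 2
  s_tt <- (sum(tsum)^2 - sum(tsum^2)) / 2
  w_trans <- m_trans + params$k_c * s_cc + params$k_t * s_tt
  if (!is.null(loops)) {
    cid0 <- .bin_chrom_id(bins)
    tl <- loops[cid0[loops$bin1] != cid0[loops$bin2], ]
    if (nrow(tl)) {
      wij <- 1 + params$k_c * cw[tl$bin1] * cw[tl$bin2] +
        params$k_t * tw[tl$bin1] * tw[tl$bin2]
      w_trans <- w_trans + sum((tl$fold - 1) * wij)
    }
  }

  tf <- if (m_trans > 0) params$trans_frac else 0
  cis_total <- (1 - tf) * params$n_pairs
  trans_total <- tf * params$n_pairs
  structure(list(
    bins = bins, params = params, dom_id = dom_id, loops = loops,
    d0 = d0, alpha = params$alpha, beta = beta,
    cis_scale = if (s_cis > 0) cis_total / s_cis else 0,
    trans_base = if (w_trans > 0) trans_total / w_trans else 0,
    cen_w = cw, tel_w = tw,
    cis_total = if (s_cis > 0) cis_total else 0,
    trans_total = if (w_trans > 0) trans_total else 0,
    truth = truth), class = "hic_intensity")
}

#' Evaluate the expected intensity at bin pairs
#' @param lambda A `hic_intensity`.
#' @param i,j Global bin indices (vectorised); self-pairs have intensity 0.
#' @export
intensity_at <- function(lambda, i, j) {
  b1 <- pmin(i, j); b2 <- pmax(i, j)
  cid <- .bin_chrom_id(lambda$bins)
  out <- numeric(length(b1))
  cis <- cid[b1] == cid[b2] & b1 != b2
  if (any(cis)) {
    d <- b2[cis] - b1[cis]
    same <- !is.na(lambda$dom_id[b1[cis]]) & !is.na(lambda$dom_id[b2[cis]]) &
      lambda$dom_id[b1[cis]] == lambda$dom_id[b2[cis]]
    v <- lambda$cis_scale * (d + lambda$d0)^(-lambda$alpha) *
      ifelse(same, lambda$beta, 1)
    out[cis] <- v
  }
  tr <- cid[b1] != cid[b2]
  if (any(tr)) {
    out[tr] <- lambda$trans_base *
      (1 + lambda$params$k_c * lambda$cen_w[b1[tr]] * lambda$cen_w[b2[tr]] +
         lambda$params$k_t * lambda$tel_w[b1[tr]] * lambda$tel_w[b2[tr]])
  }
  if (!is.null(lambda$loops) && nrow(lambda$loops)) {
    m <- match(paste(b1, b2), paste(lambda$loops$bin1, lambda$loops$bin2))
    hit <- !is.na(m)
    out[hit] <- out[hit] * lambda$loops$fold[m[hit]]
  }
  out
}

#' Genome-wide sum of the expected intensity
#' @param lambda A `hic_intensity`.
#' @export
intensity_total <- function(lambda) lambda$cis_total + lambda$trans_total

#' Sample a contact matrix from an expected intensity field
#'
#' Counts are independent Poisson draws with the per-pair means of `lambda`
#' (negative binomial if the generator's `dispersion` is positive). Trans
#' background counts are drawn in aggregate and scattered uniformly, which is
#' distributionally identical to per-pair draws and much faster at fine bins.
#'
#' @param lambda A `hic_intensity`.
#' @param seed Integer seed.
#' @return A `contact_matrix`.
#' @export
sample_contacts <- function(lambda, seed = 1) {
  set.seed(seed)
  bins <- lambda$bins
  idx <- .bin_index(bins)
  params <- lambda$params
  disp <- params$dispersion
  draw <- function(mu) {
    if (disp > 0) stats::rnbinom(length(mu), size = 1 / disp, mu = mu)
    else stats::rpois(length(mu), mu)
  }
  u <- function(d) (d + lambda$d0)^(-lambda$alpha)

  pieces <- vector("list", nrow(idx) + 2)
  # cis: diagonal by diagonal per chromosome
  for (k in seq_len(nrow(idx))) {
    n <- idx$n[k]
    if (n < 2) next
    f <- idx$first[k]
    dom <- lambda$dom_id[f:(f + n - 1)]
    acc <- vector("list", n - 1)
    for (d in seq_len(n - 1)) {
      a <- 1:(n - d); b <- a + d
      same <- !is.na(dom[a]) & !is.na(dom[b]) & dom[a] == dom[b]
      mu <- lambda$cis_scale * u(d) * ifelse(same, lambda$beta, 1)
      if (!is.null(lambda$loops)) {
        lp <- lambda$loops[lambda$loops$bin2 - lambda$loops$bin1 == d &
                             lambda$loops$bin1 >= f & lambda$loops$bin2 < f + n, ]
        if (nrow(lp)) mu[lp$bin1 - f + 1] <- mu[lp$bin1 - f + 1] * lp$fold
      }
      cnt <- draw(mu)
      nz <- which(cnt > 0)
      if (length(nz)) {
        acc[[d]] <- cbind(a[nz] + f - 1, b[nz] + f - 1, cnt[nz])
      }
    }
    acc <- do.call(rbind, acc)
    if (!is.null(acc)) {
      pieces[[k]] <- tibble::tibble(bin1 = acc[, 1], bin2 = acc[, 2], count = acc[, 3])
    }
  }

  # trans background: aggregate Poisson mass scattered uniformly over pairs
  if (lambda$trans_total > 0) {
    m_trans_pairs <- (nrow(bins)^2 - sum(idx$n^2)) / 2
    k_total <- draw(lambda$trans_base * m_trans_pairs)
    if (k_total > 0) {
      cp <- utils::combn(nrow(idx), 2)
      wts <- idx$n[cp[1, ]] * idx$n[cp[2, ]]
      pick <- sample.int(ncol(cp), k_total, replace = TRUE, prob = wts)
      i <- idx$first[cp[1, pick]] + floor(stats::runif(k_total) * idx$n[cp[1, pick]])
      j <- idx$first[cp[2, pick]] + floor(stats::runif(k_total) * idx$n[cp[2, pick]])
      pieces[[nrow(idx) + 1]] <- tibble::tibble(bin1 = i, bin2 = j, count = 1L)
    }
    # bundling excess on centromeric/telomeric cross-chromosome pairs
    cid <- .bin_chrom_id(bins)
    enr <- function(w, strength) {
      nz <- which(w > 0)
      if (length(nz) < 2 || strength <= 0) return(NULL)
      pr <- t(utils::combn(nz, 2))
      pr <- pr[cid[pr[, 1]] != cid[pr[, 2]], , drop = FALSE]
      if (!nrow(pr)) return(NULL)
      mu <- lambda$trans_base * strength * w[pr[, 1]] * w[pr[, 2]]
      cnt <- draw(mu)
      keep <- cnt > 0
      tibble::tibble(bin1 = pr[keep, 1], bin2 = pr[keep, 2], count = cnt[keep])
    }
    loop_extra <- NULL
    if (!is.null(lambda$loops)) {
      tl <- lambda$loops[cid[lambda$loops$bin1] != cid[lambda$loops$bin2], ]
      if (nrow(tl)) {
        wij <- 1 + params$k_c * lambda$cen_w[tl$bin1] * lambda$cen_w[tl$bin2] +
          params$k_t * lambda$tel_w[tl$bin1] * lambda$tel_w[tl$bin2]
        cnt <- draw(lambda$trans_base * wij * (tl$fold - 1))
        keep <- cnt > 0
        loop_extra <- tibble::tibble(bin1 = tl$bin1[keep], bin2 = tl$bin2[keep],
                                     count = cnt[keep])
      }
    }
    pieces[[nrow(idx) + 2]] <- dplyr::bind_rows(
      enr(lambda$cen_w, params$k_c), enr(lambda$tel_w, params$k_t), loop_extra)
  }
  contact_matrix(bins, dplyr::bind_rows(pieces))
}

#' Sample two independent replicate matrices from one intensity field
#' @param lambda A `hic_intensity`.
#' @param seed1,seed2 Seeds for the two replicates.
#' @return List of two `contact_matrix` objects.
#' @export
sample_replicates <- function(lambda, seed1 = 1, seed2 = 2) {
  list(sample_contacts(lambda, seed1), sample_contacts(lambda, seed2))
}

#' Plant a motif consensus into a fraction of boundary bins
#'
#' Exactly `round(f_m * n_boundaries)` boundaries (chosen uniformly) receive
#' one copy of the consensus at a uniform offset inside the boundary bin.
#'
#' @param seqs A `DNAStringSet` of chromosome sequences.
#' @param truth A `hic_truth` (supplies the boundary bins).
#' @param consensus Motif string to plant.
#' @param f_m Fraction of boundaries to receive the motif, in `[0, 1]`.
#' @param seed Integer seed.
#' @return List with `$seqs` (modified sequences) and `$planted` (tibble of
#'   boundary ids and planted positions).
#' @export
plant_boundary_motifs <- function(seqs, truth, consensus, f_m, seed = 1) {
  stopifnot(f_m >= 0, f_m <= 1)
  set.seed(seed)
  bnd <- truth$boundaries
  w <- nchar(consensus)
  if (any(bnd$end - bnd$start < w)) {
    rlang::abort("consensus longer than boundary bin")
  }
  n_plant <- round(f_m * nrow(bnd))
  chosen <- sort(sample.int(nrow(bnd), n_plant))
  out <- as.character(seqs)
  planted <- bnd[chosen, ]
  if (n_plant > 0) {
    off <- floor(stats::runif(n_plant) * (planted$end - planted$start - w + 1))
    planted$pos <- planted$start + off
    for (r in seq_len(n_plant)) {
      ch <- planted$chrom[r]
      substr(out[ch], planted$pos[r] + 1, planted$pos[r] + w) <- consensus
    }
  } else {
    planted$pos <- numeric(0)
  }
  list(seqs = Biostrings::DNAStringSet(out),
       planted = tibble::as_tibble(planted))
}

#' One-call synthetic Hi-C dataset
#'
#' Convenience wrapper: simulate a genome, build the expected intensity at the
#' working resolution, and sample one contact matrix.
#'
#' @inheritParams simulate_genome
#' @param resolution Resolution for the sampled matrix (defaults to the
#'   generator's working resolution).
#' @return List with `$truth`, `$lambda`, `$matrix`.
#' @export
simulate_hic <- function(params = sim_params(), seed = 1,
                         resolution = params$resolution, with_sequence = FALSE) {
  truth <- simulate_genome(params, seed, with_sequence = with_sequence)
  lambda <- expected_intensity(truth, resolution)
  list(truth = truth, lambda = lambda, matrix = sample_contacts(lambda, seed + 1000L))
}
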