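#' Run the full demonstration pipeline on a simulated dataset
#'
#' One call that exercises every stage of the package on a synthetic
#' Rabl-structured genome: simulate genome and contacts, decay curve and
#' replicate reproducibility, insulation-score globule calling,
#' cis/trans contact significance, centromere calling, aggregate chromosome
#' analysis and Rabl classification, 3D embedding, motif scanning at globule
#' boundaries, and gene-level annotation. All outputs are written as plain
#' text under `outdir`; given the same `seed` and parameters the run is
#' fully reproducible (all stage seeds derive from `seed`).
#'
#' Three working resolutions are used: the generator's fine grid for
#' insulation/globules, a middle grid for significance and reproducibility,
#' and a coarse grid for centromeres, ACA and the 3D model.
#'
#' @param outdir Output directory (created if needed).
#' @param seed Master seed.
#' @param params Generator parameters ([sim_params()]).
#' @param res_mid,res_coarse Middle / coarse resolutions (bp).
#' @param q_max,min_count Significance filter thresholds.
#' @param motif_consensus Consensus planted at boundaries and scanned back.
#' @param f_m Fraction of boundaries receiving the planted motif.
#' @param n_promoter_genes Number of genes included in the promoter scan.
#' @param mds_max_iter,mds_tol Embedding controls.
#' @return Invisibly, the report: a named list of the run's headline numbers
#'   (also written to `report.txt`).
#' @export
run_pipeline <- function(outdir, seed = 1,
                         params = sim_params(n_pairs = 5e5),
                         res_mid = 10000, res_coarse = 20000,
                         q_max = 0.01, min_count = 3,
                         motif_consensus = "TGACTCA", f_m = 0.6,
                         n_promoter_genes = 200,
                         mds_max_iter = 200, mds_tol = 1e-5) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  stage <- function(name, expr) {
    say("[stage] %s", name)
    tryCatch(expr, error = function(e) {
      writeLines(log_lines, file.path(outdir, "run.log"))
      rlang::abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  report <- list(seed = seed)
  outputs <- character(0)
  emit <- function(fname) outputs <<- c(outputs, fname)

  truth <- stage("simulate", {
    tr <- simulate_genome(params, seed, with_sequence = TRUE)
    if (is.null(tr$loops)) {
      # give the demo genuine point interactions for the significance and
      # hub-gene stages to find
      tr$loops <- demo_loops(tr$layout, seed = seed + 7L)
    }
    if (f_m > 0) {
      pl <- plant_boundary_motifs(tr$seqs, tr, motif_consensus, f_m, seed + 1L)
      tr$seqs <- pl$seqs
      tr$planted <- pl$planted
    }
    write_chromsizes(tr$layout, file.path(outdir, "genome.chrom.sizes")); emit("genome.chrom.sizes")
    write_fasta(tr$seqs, file.path(outdir, "genome.fa")); emit("genome.fa")
    write_gff_genes(tr$genes, file.path(outdir, "genes.gff")); emit("genes.gff")
    write_bed(tr$domains, file.path(outdir, "truth_domains.bed")); emit("truth_domains.bed")
    write_bed(tr$boundaries, file.path(outdir, "truth_boundaries.bed")); emit("truth_boundaries.bed")
    write_bed(tr$layout$centromeres, file.path(outdir, "truth_centromeres.bed")); emit("truth_centromeres.bed")
    tr
  })
  report$n_chrom <- nrow(truth$layout$chroms)
  report$genome_mb <- round(sum(truth$layout$chroms$length) / 1e6, 2)

  glob <- stage("insulation/globules", {
    lam <- expected_intensity(truth, params$resolution)
    m <- sample_contacts(lam, seed + 2L)
    write_matrix(m, file.path(outdir, "matrix_fine.tsv")); emit("matrix_fine.tsv")
    track <- insulation_multiscale(m)
    bnd <- call_boundaries(track)
    gl <- segment_globules(bnd, m$bins, valid = track$valid)
    readr::write_tsv(track, file.path(outdir, "insulation.tsv")); emit("insulation.tsv")
    write_bed(dplyr::transmute(bnd, .data$chrom, .data$start, .data$end,
                               name = paste0("b", dplyr::row_number()),
                               score = round(.data$strength, 4), strand = "."),
              file.path(outdir, "boundaries.bed")); emit("boundaries.bed")
    write_bed(dplyr::transmute(gl$globules, .data$chrom, .data$start, .data$end,
                               name = sprintf("globule_%d|%skb", dplyr::row_number(),
                                              format(.data$size_kb, trim = TRUE))),
              file.path(outdir, "globules.bed")); emit("globules.bed")
    list(globules = gl, track = track, matrix = m)
  })
  gsum <- glance(glob$globules)
  report$n_globules <- gsum$n_globules
  report$globule_min_kb <- gsum$min_kb
  report$globule_max_kb <- gsum$max_kb
  report$boundary_f1 <- round(boundary_f1(glob$globules$boundaries,
                                          truth, glob$matrix$bins), 4)

  sig <- stage("significance/reproducibility", {
    lam <- expected_intensity(truth, res_mid)
    reps <- sample_replicates(lam, seed + 3L, seed + 4L)
    m1 <- reps[[1]]
    dc <- decay_curve(m1)
    readr::write_tsv(dc, file.path(outdir, "decay.tsv")); emit("decay.tsv")
    prior <- fit_distance_prior(m1)
    cis <- cis_significance(m1, prior)
    trans <- trans_significance(m1)
    filt <- filter_significant(cis, trans, q_max = q_max, min_count = min_count)
    readr::write_tsv(filt$records, file.path(outdir, "significant_contacts.tsv"))
    emit("significant_contacts.tsv")
    list(matrix = m1, decay = dc, filtered = filt,
         repro = reproducibility_score(m1, reps[[2]]),
         cts = cis_trans_summary(m1))
  })
  report$decay_slope <- round(decay_slope(sig$decay), 3)
  report$cis_share <- round(sig$cts$cis_share, 4)
  report$reproducibility <- round(sig$repro, 4)
  report$n_cis_significant <- sum(sig$filtered$records$kind == "cis")
  report$n_trans_significant <- sum(sig$filtered$records$kind == "trans")

  org <- stage("centromeres/aca/embedding", {
    lam <- expected_intensity(truth, res_coarse)
    m <- sample_contacts(lam, seed + 5L)
    prof <- trans_profile(m)
    cens <- call_centromeres(prof)
    write_bed(cens[c("chrom", "start", "end")],
              file.path(outdir, "centromeres.bed")); emit("centromeres.bed")
    readr::write_tsv(prof, file.path(outdir, "trans_profile.tsv")); emit("trans_profile.tsv")
    am <- aca(m, cens)
    utils::write.table(round(am$map, 6), file.path(outdir, "aca_map.tsv"),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
    emit("aca_map.tsv")
    wish <- counts_to_wish_distances(m)
    st <- suppressWarnings(mds_embed(wish, max_iter = mds_max_iter, tol = mds_tol))
    write_structure(st, file.path(outdir, "structure_3d.tsv")); emit("structure_3d.tsv")
    met <- structure_metrics(st, truth$layout, seed = seed + 6L)
    list(cens = cens, aca = am, structure = st, metrics = met)
  })
  report$centromere_max_offset_bins <- centromere_offset_bins(
    org$cens, truth$layout$centromeres, res_coarse)
  report$cen_corner_score <- round(org$aca$cen_score, 3)
  report$tel_corner_score <- round(org$aca$tel_score, 3)
  report$rabl_class <- classify_rabl(org$aca)
  report$embedding_correlation <- round(embedding_correlation(org$structure), 4)
  report$cen_clustering_ratio <- round(org$metrics$cen_ratio, 4)

  mot <- stage("motifs", {
    bnd_seqs <- .extract_windows(truth$seqs, glob$globules$boundaries)
    pwms <- c(list(pwm_from_consensus(motif_consensus, id = paste0("planted_", motif_consensus))),
              lapply(.decoy_motifs(motif_consensus), pwm_from_consensus))
    hits <- scan_pwm(pwms, bnd_seqs)
    local_bnd <- tibble::tibble(chrom = names(bnd_seqs), start = 0,
                                end = Biostrings::width(bnd_seqs))
    enr <- boundary_enrichment(hits, local_bnd)
    readr::write_tsv(enr, file.path(outdir, "boundary_motif_enrichment.tsv"))
    emit("boundary_motif_enrichment.tsv")
    gsub_genes <- utils::head(truth$genes, n_promoter_genes)
    pr <- promoters(gsub_genes, truth$layout)
    pr_seqs <- .extract_windows(truth$seqs, pr, names = pr$id)
    pr_hits <- scan_pwm(pwms[[1]], pr_seqs)
    presence <- tibble::tibble(id = names(pr_seqs),
                               present = names(pr_seqs) %in% pr_hits$chrom)
    readr::write_tsv(presence, file.path(outdir, "promoter_motif_presence.tsv"))
    emit("promoter_motif_presence.tsv")
    list(enrichment = enr, presence = presence)
  })
  report$top_motif <- mot$enrichment$motif[1]
  report$top_motif_proportion <- round(mot$enrichment$proportion[1], 4)

  ann <- stage("annotation", {
    ga <- assign_genes_to_globules(truth$genes, glob$globules)
    mc <- map_contacts_to_genes(sig$filtered, truth$genes, sig$matrix$bins)
    hubs <- hub_ranking(mc$per_gene)
    readr::write_tsv(ga, file.path(outdir, "genes_globule_labels.tsv"))
    emit("genes_globule_labels.tsv")
    readr::write_tsv(mc$per_gene, file.path(outdir, "genes_contact_counts.tsv"))
    emit("genes_contact_counts.tsv")
    tel <- telomere_repeat_scan(truth$seqs, unit = params$telomere_unit)
    readr::write_tsv(tel, file.path(outdir, "telomere_repeats.tsv"))
    emit("telomere_repeats.tsv")
    list(assign = ga, contacts = mc, hubs = hubs, telomeres = tel)
  })
  asum <- attr(ann$assign, "summary")
  report$genes_boundary <- asum$boundary %||% 0
  report$genes_interior <- asum$interior %||% 0
  report$genes_spanning <- asum$spanning %||% 0
  report$genes_with_cis <- ann$contacts$summary$genes_cis
  report$genes_with_trans <- ann$contacts$summary$genes_trans
  report$genes_with_both <- ann$contacts$summary$genes_both
  report$telomere_ends_present <- sum(ann$telomeres$present)

  writeLines(sprintf("%s: %s", names(report),
                     vapply(report, function(v) paste(format(v, scientific = FALSE), collapse = ","), "")),
             file.path(outdir, "report.txt"))
  emit("report.txt")
  writeLines(sort(outputs), file.path(outdir, "manifest.txt"))
  writeLines(log_lines, file.path(outdir, "run.log"))
  invisible(report)
}

#' Seeded point-interaction (loop) set for demonstration runs
#'
#' Plants cis loops at 30-300 kb separations and trans loops between random
#' chromosome pairs, with fold enrichments strong enough to be detectable at
#' the demo sequencing depth.
#'
#' @param layout A `genome_layout`.
#' @param n_cis,n_trans Number of cis / trans loops.
#' @param cis_fold,trans_fold Fold enrichment over the local expected
#'   intensity.
#' @param seed Integer seed.
#' @return Loop tibble (`chrom1`, `pos1`, `chrom2`, `pos2`, `fold`).
#' @export
demo_loops <- function(layout, n_cis = 150, n_trans = 60,
                       cis_fold = 8, trans_fold = 100, seed = 1) {
  set.seed(seed)
  lens <- layout$chroms$length
  ch <- sample.int(length(lens), n_cis, replace = TRUE, prob = lens)
  sep <- stats::runif(n_cis, 3e4, 3e5)
  pos1 <- floor(stats::runif(n_cis) * pmax(lens[ch] - sep - 1e5, 1)) + 5e4
  cis <- tibble::tibble(chrom1 = layout$chroms$chrom[ch], pos1 = floor(pos1),
                        chrom2 = layout$chroms$chrom[ch],
                        pos2 = floor(pos1 + sep), fold = cis_fold)
  c1 <- sample.int(length(lens), n_trans, replace = TRUE, prob = lens)
  c2 <- vapply(c1, function(k) sample(setdiff(seq_along(lens), k), 1), 0L)
  trans <- tibble::tibble(
    chrom1 = layout$chroms$chrom[c1],
    pos1 = floor(stats::runif(n_trans, 5e4, lens[c1] - 5e4)),
    chrom2 = layout$chroms$chrom[c2],
    pos2 = floor(stats::runif(n_trans, 5e4, lens[c2] - 5e4)),
    fold = trans_fold)
  dplyr::bind_rows(cis, trans)
}

# extract [start, end) windows from chromosome sequences as a DNAStringSet
.extract_windows <- function(seqs, intervals, names = NULL) {
  out <- vapply(seq_len(nrow(intervals)), function(r) {
    substr(as.character(seqs[[intervals$chrom[r]]]),
           intervals$start[r] + 1, intervals$end[r])
  }, "")
  if (is.null(names)) {
    names <- sprintf("%s:%d-%d", intervals$chrom,
                     as.integer(intervals$start), as.integer(intervals$end))
  }
  Biostrings::DNAStringSet(stats::setNames(out, names))
}

# simple decoys: shuffled variants of a consensus (deterministic)
.decoy_motifs <- function(consensus) {
  b <- strsplit(consensus, "")[[1]]
  d1 <- paste(rev(b), collapse = "")
  d2 <- paste(b[c(seq(2, length(b)), 1)], collapse = "")
  unique(setdiff(c(d1, d2), consensus))
}

#' F1 score of called boundaries against planted truth
#'
#' Matches called boundary bins to ground-truth boundary bins within
#' `tol_bins` (greedy one-to-one matching, closest first) and returns the
#' F1 score.
#'
#' @param called Boundary tibble (needs `chrom` and `start`).
#' @param truth A `hic_truth` (or a boundary tibble with `chrom`/`start`).
#' @param bins `bin_table` at the calling resolution.
#' @param tol_bins Matching tolerance in bins (default 1).
#' @export
boundary_f1 <- function(called, truth, bins, tol_bins = 1) {
  tb <- if (inherits(truth, "hic_truth")) truth$boundaries else truth
  res <- bin_resolution(bins)
  n_true <- nrow(tb); n_call <- nrow(called)
  if (n_true == 0 || n_call == 0) return(0)
  matched_t <- rep(FALSE, n_true); matched_c <- rep(FALSE, n_call)
  cand <- list()
  for (ci in seq_len(n_call)) {
    dd <- abs(tb$start - called$start[ci]) / res
    ok <- which(tb$chrom == called$chrom[ci] & dd <= tol_bins)
    if (length(ok)) cand[[length(cand) + 1]] <-
        tibble::tibble(ci = ci, ti = ok, d = dd[ok])
  }
  if (length(cand)) {
    cand <- dplyr::arrange(dplyr::bind_rows(cand), .data$d)
    for (r in seq_len(nrow(cand))) {
      if (!matched_c[cand$ci[r]] && !matched_t[cand$ti[r]]) {
        matched_c[cand$ci[r]] <- TRUE; matched_t[cand$ti[r]] <- TRUE
      }
    }
  }
  tp <- sum(matched_c)
  prec <- tp / n_call; rec <- sum(matched_t) / n_true
  if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
}

#' Largest centromere-call offset, in bins, across chromosomes
#' @param called,truth Centromere tibbles (`chrom`, `start`, `end`).
#' @param resolution Bin width used for the calls.
#' @export
centromere_offset_bins <- function(called, truth, resolution) {
  m <- match(called$chrom, truth$chrom)
  mid <- if ("mid" %in% names(called)) called$mid else (called$start + called$end) / 2
  off <- abs(mid - (truth$start[m] + truth$end[m]) / 2) / resolution
  if (!nrow(called) || anyNA(off)) return(NA_real_)
  round(max(off), 2)
}
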