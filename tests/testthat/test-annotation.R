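test_that("gene labels follow the bins they overlap", {
  gl <- make_globules_fixture()
  genes <- tibble::tibble(
    chrom = "chrA",
    start = c(3000, 9100, 8000, 9500),
    end = c(4000, 9900, 8500, 11000),
    strand = "+",
    id = c("interior_gene", "boundary_gene", "small_interior", "spanning_gene"))
  out <- assign_genes_to_globules(genes, gl)
  expect_equal(out$label, c("interior", "boundary", "interior", "spanning"))
  expect_equal(attr(out, "summary")$interior, 2)

  expect_error(assign_genes_to_globules(
    tibble::tibble(chrom = "chrZ", start = 1, end = 10, id = "x"), gl),
    "outside")
})

test_that("gene labels equal a brute-force interval-overlap oracle", {
  set.seed(81)
  gl <- make_globules_fixture(50, 1000, boundary_bins = c(8, 17, 33, 41))
  starts <- sample.int(48000, 50)
  genes <- tibble::tibble(chrom = "chrA", start = starts,
                          end = starts + sample(200:4000, 50, TRUE),
                          strand = "+", id = sprintf("g%02d", 1:50))
  genes$end <- pmin(genes$end, 50000)
  out <- assign_genes_to_globules(genes, gl)
  bnd <- gl$boundaries
  for (r in 1:50) {
    hit_b <- any(bf_overlaps(genes$start[r], genes$end[r], bnd$start, bnd$end))
    other <- gl$bins[gl$labels$label != "boundary", ]
    hit_i <- any(bf_overlaps(genes$start[r], genes$end[r], other$start, other$end))
    want <- if (hit_b && hit_i) "spanning" else if (hit_b) "boundary" else "interior"
    expect_equal(out$label[r], want)
  }
  # every gene gets exactly one label and the summary adds up
  expect_equal(sum(unlist(attr(out, "summary"))), 50)
})

test_that("contacts map to genes through their anchor bins", {
  lay <- genome_layout(c(chrA = 10000, chrB = 10000))
  bins <- make_bins(lay, 1000)
  genes <- tibble::tibble(chrom = c("chrA", "chrA", "chrB"),
                          start = c(100, 1200, 500), end = c(900, 1800, 2500),
                          strand = "+", id = c("A", "B", "C"))
  rec <- tibble::tibble(
    chrom1 = c("chrA", "chrA"), start1 = c(0, 4000), end1 = c(1000, 5000),
    chrom2 = c("chrA", "chrB"), start2 = c(1000, 1000), end2 = c(2000, 2000),
    bin1 = c(1, 5), bin2 = c(2, 12), count = c(5, 4),
    prior_p = 1e-4, p_value = 1e-6, q_value = 1e-4,
    kind = c("cis", "trans"))
  contacts <- microhic:::.new_hic_contacts(rec, meta = list(kind = "cis+trans"))
  mapped <- map_contacts_to_genes(contacts, genes, bins)
  pg <- mapped$per_gene
  expect_equal(pg$cis[pg$id == "A"], 1)     # cis contact anchors overlap A and B
  expect_equal(pg$cis[pg$id == "B"], 1)
  expect_equal(pg$trans[pg$id == "C"], 1)   # trans contact overlaps C only
  expect_equal(mapped$summary$genes_both, 0)
  expect_equal(mapped$summary$intergenic_cis, 0)

  # a contact overlapping no gene lands in the intergenic tally
  rec2 <- rec[2, ]; rec2$bin1 <- 9; rec2$chrom1 <- "chrA"; rec2$bin2 <- 20
  contacts2 <- microhic:::.new_hic_contacts(rec2, meta = list())
  mapped2 <- map_contacts_to_genes(contacts2, genes, bins)
  expect_equal(mapped2$summary$intergenic_trans, 1)
})

test_that("contact-to-gene assignment matches a brute-force double loop", {
  set.seed(82)
  lay <- genome_layout(c(chrA = 30000, chrB = 30000))
  bins <- make_bins(lay, 1000)
  starts <- sort(sample.int(28000, 15))
  genes <- dplyr::bind_rows(
    tibble::tibble(chrom = "chrA", start = starts, end = starts + 1500),
    tibble::tibble(chrom = "chrB", start = starts, end = starts + 1500))
  genes$strand <- "+"
  genes$id <- sprintf("g%02d", seq_len(nrow(genes)))
  b <- sample.int(60, 40, TRUE); b2 <- sample.int(60, 40, TRUE)
  keep <- b != b2
  rec <- tibble::tibble(bin1 = pmin(b, b2)[keep], bin2 = pmax(b, b2)[keep])
  rec <- dplyr::distinct(rec)
  cid <- microhic:::.bin_chrom_id(bins)
  rec <- dplyr::mutate(rec,
    chrom1 = bins$chrom[bin1], start1 = bins$start[bin1], end1 = bins$end[bin1],
    chrom2 = bins$chrom[bin2], start2 = bins$start[bin2], end2 = bins$end[bin2],
    count = 3, prior_p = 1e-5, p_value = 1e-8, q_value = 1e-6,
    kind = ifelse(cid[bin1] == cid[bin2], "cis", "trans"))
  contacts <- microhic:::.new_hic_contacts(rec, meta = list())
  mapped <- map_contacts_to_genes(contacts, genes, bins)

  for (g in seq_len(nrow(genes))) {
    for (kd in c("cis", "trans")) {
      n_bf <- 0
      for (r in seq_len(nrow(rec))) {
        if (rec$kind[r] != kd) next
        o1 <- rec$chrom1[r] == genes$chrom[g] &
          bf_overlaps(genes$start[g], genes$end[g], rec$start1[r], rec$end1[r])
        o2 <- rec$chrom2[r] == genes$chrom[g] &
          bf_overlaps(genes$start[g], genes$end[g], rec$start2[r], rec$end2[r])
        if (o1 || o2) n_bf <- n_bf + 1
      }
      got <- mapped$per_gene[[kd]][mapped$per_gene$id == genes$id[g]]
      if (length(got) == 0) got <- 0
      expect_equal(got, n_bf)
    }
  }
})

test_that("hub ranking orders by count with id tie-breaks", {
  pg <- tibble::tibble(id = c("A", "B", "C"), cis = c(3, 5, 0), trans = c(2, 2, 9))
  h <- hub_ranking(pg, top_n = 2)
  expect_equal(h$cis$id, c("B", "A"))
  expect_equal(h$trans$id, c("C", "A"))      # tie A/B at 2 -> A first
  expect_equal(h$cis$rank, 1:2)

  sim_pg <- tibble::tibble(id = sprintf("g%02d", 1:20),
                           cis = c(rep(1, 19), 40), trans = 0)
  expect_equal(hub_ranking(sim_pg)$cis$id[1], "g20")   # planted hub ranks first
})

test_that("telomeric repeats are detected where planted and absent otherwise", {
  p <- small_sim_params(chrom_len_range = c(2e5, 3e5))
  tr <- simulate_genome(p, 83)
  tel <- telomere_repeat_scan(tr$seqs)
  expect_equal(nrow(tel), 2 * p$n_chrom)
  missing <- tel[!tel$present, ]
  expect_equal(nrow(missing), 1)
  expect_equal(missing$chrom, tr$layout$chroms$chrom[p$n_chrom])
  expect_equal(missing$end, "3p")

  # random sequence without planting: no tandem runs
  set.seed(84)
  rnd <- Biostrings::DNAStringSet(c(r1 = paste(
    sample(c("A", "C", "G", "T"), 20000, TRUE), collapse = "")))
  tel0 <- telomere_repeat_scan(rnd)
  expect_false(any(tel0$present))

  # a single unit counts when min_copies = 1
  one <- Biostrings::DNAStringSet(c(
    s = paste0("TTAGGGG", paste(rep("A", 100), collapse = ""))))
  expect_true(telomere_repeat_scan(one, min_copies = 1)$present[1])
  expect_false(telomere_repeat_scan(one, min_copies = 3)$present[1])
})

test_that("category shares tabulate a user-supplied annotation table", {
  cats <- tibble::tibble(id = c("g1", "g1", "g2", "g3", "g4"),
                         category = c("metabolism", "transport", "metabolism",
                                      "metabolism", "signalling"))
  sh <- category_shares(c("g1", "g2", "g3"), cats)
  expect_equal(sh$category[1], "metabolism")
  expect_equal(sh$n[sh$category == "metabolism"], 3)
  expect_equal(sh$share[sh$category == "metabolism"], 1)     # 3 of 3 genes
  expect_equal(sh$share[sh$category == "transport"], 1 / 3)
  expect_equal(nrow(category_shares("gX", cats)), 0)
})
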