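#' Assign genes to globule boundaries and interiors
#'
#' A gene overlapping only boundary bins is `boundary`, only non-boundary
#' bins `interior`, both `spanning`. Bins inside the insulation edge mask
#' count as interior (the interior of the first/last globule); labels ignore
#' the mask.
#'
#' @param genes Gene tibble (`chrom`, `start`, `end`, `id`).
#' @param globules A `hic_globules`.
#' @return The gene tibble with a `label` column; attribute `summary` holds
#'   the per-label counts.
#' @export
assign_genes_to_globules <- function(genes, globules) {
  bins <- globules$bins
  lab <- globules$labels$label
  b0 <- .pos_to_bin(bins, genes$chrom, genes$start + 1)
  b1 <- .pos_to_bin(bins, genes$chrom, genes$end)
  if (anyNA(b0) || anyNA(b1)) {
    rlang::abort("gene outside any chromosome of the bin table")
  }
  label <- vapply(seq_len(nrow(genes)), function(r) {
    ll <- lab[b0[r]:b1[r]]
    has_b <- any(ll == "boundary"); has_i <- any(ll != "boundary")
    if (has_b && has_i) "spanning" else if (has_b) "boundary" else "interior"
  }, "")
  out <- dplyr::mutate(genes, label = label)
  attr(out, "summary") <- as.list(table(label))
  out
}

# gene x bin incidence (>= 1 bp overlap), as a tibble of (bin, id)
.gene_bin_pairs <- function(bins, genes) {
  b0 <- .pos_to_bin(bins, genes$chrom, genes$start + 1)
  b1 <- .pos_to_bin(bins, genes$chrom, genes$end)
  ok <- which(!is.na(b0) & !is.na(b1))
  lens <- b1[ok] - b0[ok] + 1
  tibble::tibble(bin = sequence(lens, from = b0[ok]),
                 id = rep(genes$id[ok], lens))
}

#' Map significant contacts onto genes
#'
#' A contact is assigned to every gene overlapping either of its two anchor
#' bins by at least 1 bp; each contact counts once per overlapped gene,
#' split by cis/trans kind. Contacts overlapping no gene are tallied as
#' intergenic.
#'
#' @param contacts A `hic_contacts` (typically the filtered significant set).
#' @param genes Gene tibble.
#' @param bins The `bin_table` of the contact records.
#' @return List: `per_gene` (tibble `id`, `cis`, `trans`),
#'   `summary` (genes with cis / trans / both, intergenic tallies).
#' @export
map_contacts_to_genes <- function(contacts, genes, bins) {
  rec <- contacts$records
  rec$contact_id <- seq_len(nrow(rec))
  gb <- .gene_bin_pairs(bins, genes)
  hit <- dplyr::bind_rows(
    dplyr::inner_join(rec[c("contact_id", "bin1", "kind")], gb,
                      by = c(bin1 = "bin"), relationship = "many-to-many"),
    dplyr::inner_join(rec[c("contact_id", "bin2", "kind")], gb,
                      by = c(bin2 = "bin"), relationship = "many-to-many")) |>
    dplyr::distinct(.data$contact_id, .data$id, .data$kind)
  per_gene <- hit |>
    dplyr::count(.data$id, .data$kind) |>
    tidyr::pivot_wider(names_from = "kind", values_from = "n", values_fill = 0)
  for (k in c("cis", "trans")) if (!k %in% names(per_gene)) per_gene[[k]] <- 0
  genic <- unique(hit$contact_id)
  intergenic <- rec[!rec$contact_id %in% genic, ]
  list(per_gene = per_gene[c("id", "cis", "trans")],
       summary = list(
         genes_cis = sum(per_gene$cis > 0),
         genes_trans = sum(per_gene$trans > 0),
         genes_both = sum(per_gene$cis > 0 & per_gene$trans > 0),
         intergenic_cis = sum(intergenic$kind == "cis"),
         intergenic_trans = sum(intergenic$kind == "trans")))
}

#' Rank hub genes by interaction count
#'
#' @param per_gene Tibble from [map_contacts_to_genes()].
#' @param top_n Rows to keep per table (default 10).
#' @return List of two tibbles (`cis`, `trans`), descending by count, ties
#'   broken by gene id.
#' @export
hub_ranking <- function(per_gene, top_n = 10) {
  one <- function(col) {
    out <- per_gene[order(-per_gene[[col]], per_gene$id), c("id", col)]
    names(out)[2] <- "count"
    out <- utils::head(out, top_n)
    out$rank <- seq_len(nrow(out))
    out
  }
  list(cis = one("cis"), trans = one("trans"))
}

#' Detect tandem telomeric repeats at chromosome ends
#'
#' Scans the first and last `window_bp` of each chromosome for at least
#' `min_copies` tandem copies of the repeat unit: the unit as written at 5'
#' ends, its reverse complement at 3' ends.
#'
#' @param seqs A `DNAStringSet` of chromosomes.
#' @param unit Repeat unit (default `TTAGGGG`).
#' @param min_copies Minimum tandem copies (default 3).
#' @param window_bp End window scanned (default 5000; clipped to the
#'   chromosome).
#' @return Tibble: `chrom`, `end` (`"5p"`/`"3p"`), `present`.
#' @export
telomere_repeat_scan <- function(seqs, unit = "TTAGGGG", min_copies = 3,
                                 window_bp = 5000) {
  unit5 <- toupper(unit)
  unit3 <- .revcomp_chr(unit5)
  pat <- function(u) paste0("(?:", u, "){", min_copies, ",}")
  purrr::map_dfr(names(seqs), function(ch) {
    s <- as.character(seqs[[ch]])
    L <- nchar(s)
    wnd <- min(window_bp, L)
    head5 <- substr(s, 1, wnd)
    tail3 <- substr(s, L - wnd + 1, L)
    tibble::tibble(
      chrom = ch, end = c("5p", "3p"),
      present = c(grepl(pat(unit5), head5, perl = TRUE),
                  grepl(pat(unit3), tail3, perl = TRUE)))
  })
}

#' Tabulate functional-category shares for a gene set
#'
#' Functional annotation itself is out of scope here; when a user-supplied
#' gene-to-category table is available (e.g. from an external annotation
#' pipeline), this tabulates the share of each category within a gene set --
#' typically the genes carrying cis or trans interactions, or the genes at
#' globule boundaries.
#'
#' @param ids Character vector of gene ids (the set of interest).
#' @param categories Data frame with columns `id` and `category`; genes may
#'   carry several categories (one row each).
#' @return Tibble: `category`, `n`, `share` (of categorised genes in the
#'   set), descending by share.
#' @export
category_shares <- function(ids, categories) {
  hit <- categories[categories$id %in% ids, c("id", "category")]
  if (!nrow(hit)) {
    return(tibble::tibble(category = character(), n = integer(), share = numeric()))
  }
  out <- dplyr::count(hit, .data$category, name = "n")
  out$share <- out$n / length(unique(hit$id))
  dplyr::arrange(out, dplyr::desc(.data$share), .data$category)
}
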