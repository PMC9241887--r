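#' Genome layout: chromosome set with optional centromere and telomere annotation
#'
#' The layout is the lightweight coordinate backbone every other object refers
#' to: an ordered chromosome table plus (optionally) one centromere interval
#' per chromosome and a width of chromosome-end sequence treated as telomeric.
#' All genomic coordinates in this package are 0-based half-open.
#'
#' @param chroms A data frame with columns `chrom` and `length` (bp), or a
#'   named numeric vector of chromosome lengths.
#' @param centromeres Optional data frame with columns `chrom`, `start`, `end`
#'   (bp, 0-based half-open), at most one row per chromosome, each interval
#'   strictly inside its chromosome.
#' @param telomere_extent Width in bp of the chromosome-end regions treated as
#'   telomeric by downstream analyses (default 40 kb).
#' @return A `genome_layout` object: list with `$chroms` (tibble),
#'   `$centromeres` (tibble) and `$telomere_extent`.
#' @export
genome_layout <- function(chroms, centromeres = NULL, telomere_extent = 40000) {
  if (is.numeric(chroms) && !is.null(names(chroms))) {
    chroms <- tibble::tibble(chrom = names(chroms), length = unname(chroms))
  }
  chroms <- tibble::as_tibble(chroms)[, c("chrom", "length")]
  chroms$chrom <- as.character(chroms$chrom)
  chroms$length <- as.numeric(chroms$length)
  if (anyDuplicated(chroms$chrom)) {
    rlang::abort("duplicate chromosome names in layout", class = "microhic_format_error")
  }
  if (any(!is.finite(chroms$length) | chroms$length <= 0)) {
    rlang::abort("chromosome lengths must be positive", class = "microhic_format_error")
  }
  if (is.null(centromeres)) {
    centromeres <- tibble::tibble(chrom = character(), start = numeric(), end = numeric())
  } else {
    centromeres <- tibble::as_tibble(centromeres)[, c("chrom", "start", "end")]
    len <- chroms$length[match(centromeres$chrom, chroms$chrom)]
    if (anyNA(len)) {
      rlang::abort("centromere on unknown chromosome", class = "microhic_format_error")
    }
    bad <- centromeres$start < 0 | centromeres$end > len |
      centromeres$start >= centromeres$end |
      centromeres$start == 0 | centromeres$end == len
    if (any(bad)) {
      rlang::abort("centromere intervals must lie strictly inside their chromosome",
                   class = "microhic_format_error")
    }
  }
  structure(list(chroms = chroms, centromeres = centromeres,
                 telomere_extent = telomere_extent),
            class = "genome_layout")
}

#' @export
print.genome_layout <- function(x, ...) {
  cat("<genome_layout> ", nrow(x$chroms), " chromosomes, ",
      sprintf("%.2f Mb", sum(x$chroms$length) / 1e6),
      "; ", nrow(x$centromeres), " centromeres annotated\n", sep = "")
  invisible(x)
}

#' Read a two-column chrom.sizes table
#'
#' @param path Path to a tab/space separated file with columns
#'   `name<TAB>length`.
#' @param telomere_extent Passed to [genome_layout()].
#' @return A `genome_layout` (centromeres empty), chromosomes in file order.
#' @export
read_chromsizes <- function(path, telomere_extent = 40000) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- stringr::str_split_fixed(trimws(lines), "\\s+", 3)
  lens <- suppressWarnings(as.numeric(parts[, 2]))
  bad <- which(!nzchar(parts[, 1]) | is.na(lens) | lens <= 0)
  if (length(bad)) {
    rlang::abort(sprintf("chrom.sizes format error at line %d: '%s'", bad[1], lines[bad[1]]),
                 class = "microhic_format_error")
  }
  dup <- which(duplicated(parts[, 1]))
  if (length(dup)) {
    rlang::abort(sprintf("duplicate chromosome name at line %d: '%s'", dup[1], parts[dup[1], 1]),
                 class = "microhic_format_error")
  }
  genome_layout(tibble::tibble(chrom = parts[, 1], length = lens),
                telomere_extent = telomere_extent)
}

#' Write a chrom.sizes table
#' @param layout A `genome_layout`.
#' @param path Output path.
#' @export
write_chromsizes <- function(layout, path) {
  readr::write_tsv(layout$chroms, path, col_names = FALSE)
  invisible(path)
}

#' Tile a genome into fixed-width bins
#'
#' Each chromosome is tiled left to right with bins of width `resolution`;
#' the final bin of a chromosome is truncated at the chromosome end and kept.
#' Bins carry a global 1-based integer index running in chromosome order.
#'
#' @param layout A `genome_layout`.
#' @param resolution Bin width in bp (> 0).
#' @return A `bin_table`: tibble with columns `bin`, `chrom`, `start`, `end`
#'   and attributes `resolution` and `layout`.
#' @export
make_bins <- function(layout, resolution) {
  stopifnot(inherits(layout, "genome_layout"))
  if (!is.numeric(resolution) || length(resolution) != 1 || resolution <= 0) {
    rlang::abort("resolution must be a single positive number")
  }
  per <- purrr::map2(layout$chroms$chrom, layout$chroms$length, function(ch, len) {
    n <- ceiling(len / resolution)
    start <- (seq_len(n) - 1) * resolution
    tibble::tibble(chrom = ch, start = start, end = pmin(start + resolution, len))
  })
  bins <- dplyr::bind_rows(per)
  bins <- tibble::add_column(bins, bin = seq_len(nrow(bins)), .before = 1)
  structure(bins, resolution = resolution, layout = layout,
            class = c("bin_table", class(bins)))
}

#' Bin width of a bin table
#' @param bins A `bin_table`.
#' @export
bin_resolution <- function(bins) {
  res <- attr(bins, "resolution")
  if (is.null(res)) res <- max(bins$end - bins$start)
  res
}

#' Genome layout underlying a bin table
#' @param bins A `bin_table`.
#' @export
bin_layout <- function(bins) {
  lay <- attr(bins, "layout")
  if (is.null(lay)) {
    chroms <- dplyr::summarise(dplyr::group_by(bins, .data$chrom),
                               length = max(.data$end), .groups = "drop")
    lay <- genome_layout(chroms[match(unique(bins$chrom), chroms$chrom), ])
  }
  lay
}

# per-chromosome index ranges: first global bin, bin count, chrom length
.bin_index <- function(bins) {
  grp <- dplyr::summarise(dplyr::group_by(bins, .data$chrom),
                          first = min(.data$bin), n = dplyr::n(),
                          length = max(.data$end), .groups = "drop")
  grp[match(unique(bins$chrom), grp$chrom), ]
}

# map 1-based bp positions to global bin indices; NA for unknown chrom,
# error for out-of-range positions on known chromosomes
.pos_to_bin <- function(bins, chrom, pos1) {
  idx <- .bin_index(bins)
  res <- bin_resolution(bins)
  m <- match(chrom, idx$chrom)
  known <- !is.na(m)
  out <- rep(NA_integer_, length(chrom))
  if (any(known)) {
    p <- pos1[known]
    len <- idx$length[m[known]]
    if (any(p < 1 | p > len)) {
      rlang::abort("pair position outside chromosome", class = "microhic_format_error")
    }
    out[known] <- idx$first[m[known]] + as.integer((p - 1) %/% res)
  }
  out
}

#' Construct a sparse symmetric contact matrix
#'
#' Only the upper triangle (`bin1 <= bin2`) is stored; duplicate and swapped
#' entries are merged by summation. Counts must be non-negative.
#'
#' @param bins A `bin_table`.
#' @param contacts Data frame with columns `bin1`, `bin2`, `count`.
#' @return A `contact_matrix` object.
#' @export
contact_matrix <- function(bins, contacts) {
  contacts <- tibble::as_tibble(contacts)[, c("bin1", "bin2", "count")]
  if (nrow(contacts)) {
    if (any(contacts$count < 0)) rlang::abort("negative contact count")
    nb <- nrow(bins)
    if (any(contacts$bin1 < 1 | contacts$bin1 > nb | contacts$bin2 < 1 | contacts$bin2 > nb)) {
      rlang::abort("bin index outside bin table", class = "microhic_format_error")
    }
    i <- pmin(contacts$bin1, contacts$bin2)
    j <- pmax(contacts$bin1, contacts$bin2)
    # aggregate duplicates on a numeric pair key (exact below 2^53)
    key <- i * (nb + 1) + j
    ag <- rowsum(contacts$count, key)
    k <- as.numeric(rownames(ag))
    contacts <- tibble::tibble(bin1 = as.integer(k %/% (nb + 1)),
                               bin2 = as.integer(k %% (nb + 1)),
                               count = unname(ag[, 1]))
    contacts <- contacts[contacts$count > 0, ]
    contacts <- contacts[order(contacts$bin1, contacts$bin2), ]
  }
  structure(list(bins = bins, contacts = contacts), class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  s <- cis_trans_summary(x)
  cat("<contact_matrix> ", nrow(x$bins), " bins @ ", bin_resolution(x$bins), " bp; ",
      nrow(x$contacts), " nonzero pairs; cis ", s$total_cis, ", trans ", s$total_trans,
      "\n", sep = "")
  invisible(x)
}

# chromosome id (integer) of every bin, aligned with bins$bin
.bin_chrom_id <- function(bins) {
  match(bins$chrom, unique(bins$chrom))
}

# annotate a contact tibble with cis/trans kind
.contact_kind <- function(cm) {
  cid <- .bin_chrom_id(cm$bins)
  ifelse(cid[cm$contacts$bin1] == cid[cm$contacts$bin2], "cis", "trans")
}

#' Look up a contact count; symmetric in its arguments
#' @param cm A `contact_matrix`.
#' @param i,j Global bin indices (vectorised).
#' @export
contact_count <- function(cm, i, j) {
  a <- pmin(i, j); b <- pmax(i, j)
  key <- paste(a, b)
  m <- match(key, paste(cm$contacts$bin1, cm$contacts$bin2))
  out <- cm$contacts$count[m]
  out[is.na(out)] <- 0
  out
}

#' Read a valid-pairs text file into a contact matrix
#'
#' Lines are `chrom1 pos1 chrom2 pos2` (whitespace separated, 1-based
#' positions). Pairs on chromosomes absent from the bin table are rejected and
#' their number reported via the `rejected` attribute.
#'
#' @param path Pairs file path.
#' @param bins A `bin_table`.
#' @return A `contact_matrix`; attribute `rejected` holds the number of pairs
#'   skipped for unknown chromosomes.
#' @export
read_pairs <- function(path, bins) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !startsWith(lines, "#")
  lines_kept <- lines[keep]
  line_no <- which(keep)
  parts <- stringr::str_split_fixed(trimws(lines_kept), "\\s+", 5)
  p1 <- suppressWarnings(as.numeric(parts[, 2]))
  p2 <- suppressWarnings(as.numeric(parts[, 4]))
  bad <- which(!nzchar(parts[, 1]) | !nzchar(parts[, 3]) | is.na(p1) | is.na(p2))
  if (length(bad)) {
    rlang::abort(sprintf("malformed pairs line %d: '%s'", line_no[bad[1]], lines_kept[bad[1]]),
                 class = "microhic_format_error")
  }
  b1 <- .pos_to_bin(bins, parts[, 1], p1)
  b2 <- .pos_to_bin(bins, parts[, 3], p2)
  ok <- !is.na(b1) & !is.na(b2)
  cm <- contact_matrix(bins, tibble::tibble(bin1 = b1[ok], bin2 = b2[ok], count = 1))
  attr(cm, "rejected") <- sum(!ok)
  cm
}

#' Write a contact matrix as pair lines (one line per read pair)
#'
#' Counts are expanded into individual pairs placed at bin midpoints (1-based
#' positions), the inverse convention of [read_pairs()].
#' @param cm A `contact_matrix`.
#' @param path Output path.
#' @export
write_pairs <- function(cm, path) {
  ct <- cm$contacts
  rep_idx <- rep.int(seq_len(nrow(ct)), ct$count)
  b <- cm$bins
  mid <- function(k) as.integer((b$start[k] + b$end[k]) %/% 2 + 1)
  df <- tibble::tibble(chrom1 = b$chrom[ct$bin1[rep_idx]], pos1 = mid(ct$bin1[rep_idx]),
                       chrom2 = b$chrom[ct$bin2[rep_idx]], pos2 = mid(ct$bin2[rep_idx]))
  readr::write_tsv(df, path, col_names = FALSE)
  invisible(path)
}

#' Write / read a contact matrix in triplet text form
#'
#' Format: a `# resolution: <bp>` comment line, a header, then
#' `bin1<TAB>bin2<TAB>count` rows (upper triangle, global 1-based indices).
#' `read_matrix` checks the stored resolution against the supplied bin table.
#'
#' @param cm A `contact_matrix`.
#' @param path File path.
#' @export
write_matrix <- function(cm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# resolution: %d", as.integer(bin_resolution(cm$bins))), con)
  writeLines("bin1\tbin2\tcount", con)
  if (nrow(cm$contacts)) {
    writeLines(sprintf("%d\t%d\t%s", cm$contacts$bin1, cm$contacts$bin2,
                       format(cm$contacts$count, trim = TRUE, scientific = FALSE)), con)
  }
  invisible(path)
}

#' @rdname write_matrix
#' @param bins A `bin_table` the triplets refer to.
#' @export
read_matrix <- function(path, bins) {
  first <- readLines(path, n = 1)
  res <- suppressWarnings(as.numeric(sub(".*resolution:\\s*", "", first)))
  if (!is.na(res) && res != bin_resolution(bins)) {
    rlang::abort(sprintf("matrix file resolution %d does not match bin table %d",
                         as.integer(res), as.integer(bin_resolution(bins))),
                 class = "microhic_format_error")
  }
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
  contact_matrix(bins, df)
}

#' Read / write BED intervals (BED3 or BED6)
#'
#' Coordinates are written and read 0-based half-open, as BED defines them.
#' @param path File path.
#' @return Tibble with `chrom`, `start`, `end` and, if present, `name`,
#'   `score`, `strand`.
#' @export
read_bed <- function(path) {
  df <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                        show_col_types = FALSE, progress = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 6) names(df)[4:6] <- c("name", "score", "strand")
  else if (ncol(df) >= 4) names(df)[4] <- "name"
  if (any(df$start >= df$end)) {
    rlang::abort("BED interval with start >= end", class = "microhic_format_error")
  }
  tibble::as_tibble(df)
}

#' @rdname read_bed
#' @param x Data frame with columns `chrom`, `start`, `end` and optionally
#'   `name`, `score`, `strand`.
#' @export
write_bed <- function(x, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"), names(x))
  # BED6 requires all of name/score/strand; fall back to BED3 + name otherwise
  if (!all(c("name", "score", "strand") %in% cols)) {
    cols <- intersect(cols, c("chrom", "start", "end", "name"))
  }
  df <- as.data.frame(x)[, cols, drop = FALSE]
  df$start <- format(df$start, trim = TRUE, scientific = FALSE)
  df$end <- format(df$end, trim = TRUE, scientific = FALSE)
  readr::write_tsv(df, path, col_names = FALSE)
  invisible(path)
}

#' Read gene records from a GFF-lite file
#'
#' Consumes only `gene` features of a 9-column GFF; converts 1-based inclusive
#' GFF coordinates to 0-based half-open. The gene id is taken from the `ID=`
#' (or `gene_id=`) attribute, falling back to the whole attribute string.
#'
#' @param path GFF path.
#' @return Tibble with `chrom`, `start`, `end`, `strand`, `id`.
#' @export
read_gff_genes <- function(path) {
  df <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                        show_col_types = FALSE, progress = FALSE)
  if (ncol(df) < 9) rlang::abort("GFF requires 9 columns", class = "microhic_format_error")
  df <- df[df[[3]] == "gene", ]
  attrs <- as.character(df[[9]])
  id <- stringr::str_match(attrs, "(?:^|;)\\s*(?:ID|gene_id)=([^;]+)")[, 2]
  id[is.na(id)] <- attrs[is.na(id)]
  tibble::tibble(chrom = as.character(df[[1]]), start = as.numeric(df[[4]]) - 1,
                 end = as.numeric(df[[5]]), strand = as.character(df[[7]]), id = id)
}

#' Write gene records as GFF-lite
#' @param genes Tibble with `chrom`, `start`, `end`, `strand`, `id`
#'   (0-based half-open).
#' @param path Output path.
#' @export
write_gff_genes <- function(genes, path) {
  lines <- sprintf("%s\tmicrohic\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                   genes$chrom, as.integer(genes$start + 1), as.integer(genes$end),
                   genes$strand, genes$id)
  writeLines(lines, path)
  invisible(path)
}

#' Read / write FASTA sequences
#' @importFrom methods is
#' @param path FASTA path.
#' @return A [Biostrings::DNAStringSet].
#' @export
read_fasta <- function(path) Biostrings::readDNAStringSet(path)

#' @rdname read_fasta
#' @param seqs A `DNAStringSet` (or named character vector).
#' @export
write_fasta <- function(seqs, path) {
  if (!methods::is(seqs, "DNAStringSet")) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Position-weight matrix
#'
#' Builds a PWM from a 4 x w count (or probability) matrix with rows A, C, G,
#' T. Counts get `pseudocount` added to every cell before column
#' normalisation, the smoothing convention of standard motif scanners.
#'
#' @param mat 4 x w numeric matrix, rows in A,C,G,T order.
#' @param id Motif identifier.
#' @param pseudocount Added to each cell of a count matrix (default 0.25).
#' @param background Length-4 base frequencies (default uniform); must sum
#'   to 1.
#' @return A `pwm` object: list with `$id`, `$mat` (probabilities), `$width`,
#'   `$background`, `$pseudocount`.
#' @export
pwm <- function(mat, id = "motif", pseudocount = 0.25, background = rep(0.25, 4)) {
  mat <- as.matrix(mat)
  if (nrow(mat) != 4 || ncol(mat) < 1) rlang::abort("PWM must be 4 x w with w >= 1")
  if (any(mat < 0)) rlang::abort("PWM entries must be non-negative")
  colsums <- colSums(mat)
  if (max(abs(colsums - 1)) > 1e-6) {          # counts: smooth and normalise
    mat <- sweep(mat + pseudocount, 2, colsums + 4 * pseudocount, "/")
  }
  background <- background / sum(background)
  rownames(mat) <- c("A", "C", "G", "T")
  structure(list(id = id, mat = mat, width = ncol(mat),
                 background = background, pseudocount = pseudocount),
            class = "pwm")
}

#' Build a PWM from a consensus string
#' @param consensus A/C/G/T string.
#' @param p Probability of the consensus base at each position (rest split
#'   evenly).
#' @inheritParams pwm
#' @export
pwm_from_consensus <- function(consensus, p = 0.97, id = consensus,
                               background = rep(0.25, 4)) {
  bases <- strsplit(toupper(consensus), "")[[1]]
  stopifnot(all(bases %in% c("A", "C", "G", "T")))
  mat <- matrix((1 - p) / 3, nrow = 4, ncol = length(bases),
                dimnames = list(c("A", "C", "G", "T"), NULL))
  for (k in seq_along(bases)) mat[bases[k], k] <- p
  pwm(mat, id = id, background = background)
}

#' Read JASPAR-style PFM files
#'
#' Accepts the JASPAR text format: a `>id name` header followed by four rows
#' of counts, with or without the `A [ ... ]` decoration. Multiple motifs per
#' file are supported.
#'
#' @param path PFM path.
#' @inheritParams pwm
#' @return A named list of `pwm` objects.
#' @export
read_jaspar_pfm <- function(path, pseudocount = 0.25, background = rep(0.25, 4)) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- which(startsWith(lines, ">"))
  if (!length(hdr)) hdr <- 0  # headerless single motif
  starts <- if (identical(hdr, 0)) 1 else hdr + 1
  ids <- if (identical(hdr, 0)) "motif1" else {
    sub("^>\\s*", "", vapply(strsplit(lines[hdr], "\\s+"), `[`, "", 1))
  }
  out <- purrr::map2(starts, ids, function(s, id) {
    rows <- lines[s:(s + 3)]
    vals <- lapply(rows, function(r) {
      r <- gsub("^[ACGTacgt]\\s*", "", r)
      r <- gsub("\\[|\\]", "", r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1]])
    })
    w <- unique(lengths(vals))
    if (length(w) != 1) {
      rlang::abort(sprintf("PFM '%s': rows of unequal width", id),
                   class = "microhic_format_error")
    }
    pwm(do.call(rbind, vals), id = id, pseudocount = pseudocount,
        background = background)
  })
  stats::setNames(out, ids)
}
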