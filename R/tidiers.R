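#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.hic_contacts <- function(x, ...) x$records

#' @export
glance.hic_contacts <- function(x, ...) {
  tibble::tibble(kind = x$meta$kind %||% NA_character_,
                 tested = x$meta$tested %||% nrow(x$records),
                 kept = x$meta$kept %||% NA_integer_,
                 n_cis = sum(x$records$kind == "cis"),
                 n_trans = sum(x$records$kind == "trans"))
}

#' @export
tidy.hic_globules <- function(x, ...) x$globules

#' @export
glance.hic_globules <- function(x, ...) {
  tibble::tibble(n_globules = nrow(x$globules),
                 n_boundaries = nrow(x$boundaries),
                 min_kb = min(x$globules$size_kb),
                 max_kb = max(x$globules$size_kb),
                 median_kb = stats::median(x$globules$size_kb))
}

#' @export
tidy.hic_structure <- function(x, ...) x$coords

#' @export
glance.hic_structure <- function(x, ...) {
  tibble::tibble(stress = x$stress, iterations = length(x$trace) - 1,
                 converged = x$converged, n_embedded = sum(x$embedded),
                 n_bins = nrow(x$coords))
}

#' @export
tidy.hic_prior <- function(x, ...) x$strata

#' @export
tidy.hic_aca <- function(x, ...) {
  F2 <- 2 * x$F
  tibble::tibble(slot1 = rep(seq_len(F2), F2),
                 slot2 = rep(seq_len(F2), each = F2),
                 value = as.vector(x$map))
}

#' @export
glance.hic_aca <- function(x, ...) {
  tibble::tibble(cen_score = x$cen_score, tel_score = x$tel_score, F = x$F)
}
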