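# Shipped reference tables: the published category-(iii) marker sites with
# their principal-component loadings, and the published per-type counts of
# the curated human tRNA modification catalog. Both are reproduced from the
# printed results of the human neuronal cell-line tRNA/tsRNA study the
# package's workflow implements, and serve as worked-example inputs.

#' Published category-(iii) marker sites with PC loadings
#'
#' The 20 variable ("category iii") human tRNA modification sites, with
#' their Pearson correlations to the first four principal components of
#' the published stoichiometry analysis. Site ids are
#' `isoacceptor_Sprinzl-position`.
#'
#' @return tibble with columns `site`, `modification`, `pc1`..`pc4` and a
#'   derived `amino_acid` column (first token of the site id).
#' @export
#' @examples
#' v <- variable_site_table()
#' nrow(v)  # 20
variable_site_table <- function() {
  p <- system.file("extdata", "variable_site_loadings.tsv",
                   package = "trnamod", mustWork = TRUE)
  x <- readr::read_tsv(p, show_col_types = FALSE, progress = FALSE)
  x$amino_acid <- sub("_.*$", "", x$site)
  x
}

#' Fraction of marker sites from given isoacceptor groups
#'
#' @param tbl a [variable_site_table()]-shaped tibble.
#' @param amino_acids amino-acid three-letter codes (default Ser and Lys).
#' @return fraction of rows whose site belongs to those isoacceptors.
#' @export
marker_fraction <- function(tbl, amino_acids = c("Ser", "Lys")) {
  if (!"amino_acid" %in% names(tbl)) tbl$amino_acid <- sub("_.*$", "", tbl$site)
  mean(tbl$amino_acid %in% amino_acids)
}

#' Published per-type counts of the curated site catalog
#'
#' Per-modification counts of the published 149-site human tRNA
#' modification catalog, with the counts of fully modified sites
#' (estimated stoichiometry above 80%).
#'
#' @return tibble with columns `modification`, `n_sites`,
#'   `n_fully_modified`.
#' @export
site_count_reference <- function() {
  p <- system.file("extdata", "site_count_reference.tsv",
                   package = "trnamod", mustWork = TRUE)
  readr::read_tsv(p, show_col_types = FALSE, progress = FALSE)
}

#' Totals of a per-type site-count table
#'
#' @param tbl tibble with `n_sites` and `n_fully_modified` columns.
#' @return list with `total` and `total_fully_modified`.
#' @export
tally_site_counts <- function(tbl) {
  stopifnot(all(c("n_sites", "n_fully_modified") %in% names(tbl)))
  list(total = sum(tbl$n_sites),
       total_fully_modified = sum(tbl$n_fully_modified))
}
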