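# Comparative analyses on the curated catalog: sites x conditions
# stoichiometry matrix (median over replicates of the quantification
# score), Mann-Whitney-Wilcoxon group tests, variability categories,
# hierarchical clustering, correlation-PCA and signature extraction.

# fixed quantification score per modification type
.QUANT_SCORE <- c(m5C = "NonConv", Nm = "C", m7G = "StopRatio",
                  m3C = "StopRatio", D = "StopRatio")

#' Read or validate a condition map
#'
#' @param x TSV path or tibble with columns `sample`, `cell_line`,
#'   `species` (`tRNA`/`tsRNA`), `treatment`, `replicate`.
#' @return tibble with an added `condition` column
#'   (`cell_line.species.treatment`).
#' @export
condition_map <- function(x) {
  if (is.character(x)) x <- readr::read_tsv(x, show_col_types = FALSE,
                                            progress = FALSE)
  x <- as_tibble(x)
  need <- c("sample", "cell_line", "species", "treatment", "replicate")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("condition map is missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(x$sample)) stop("duplicated sample ids", call. = FALSE)
  x$condition <- paste(x$cell_line, x$species, x$treatment, sep = ".")
  x
}

#' Build the sites x conditions stoichiometry matrix
#'
#' For every non-discarded catalog site, the quantification score fixed by
#' its modification type (NonConv for m5C, MethScore/Score C for Nm, stop
#' ratio for m7G/m3C/D) is taken per sample, the median over the replicates
#' of each condition forms the matrix entry, and replicate values are
#' retained alongside so medians stay recomputable.
#'
#' @param tracks score-track tibble covering all samples (all chemistries
#'   row-bound).
#' @param catalog catalog tibble from [curate()].
#' @param conditions a [condition_map()].
#' @param min_coverage replicate values with coverage below this are
#'   treated as missing (default 30).
#' @return object of class `stoich_matrix`: list with `matrix` (sites x
#'   conditions, values in \[0,1\] or `NA`), `sites` (site annotation
#'   tibble with `site`, `family`, `label`, `modification`), `replicates`
#'   (long tibble of retained per-sample values) and `conditions`.
#' @export
build_matrix <- function(tracks, catalog, conditions, min_coverage = 30) {
  conditions <- condition_map(conditions)
  kept <- catalog %>%
    filter(.data$status != "discarded") %>%
    mutate(site = paste(.data$family, .data$label, sep = "_"),
           score_type = unname(.QUANT_SCORE[.data$modification]))
  # same family+label can carry two modification calls (e.g. m3C32 and
  # Nm32); disambiguate the site id with the type where needed
  dup <- kept$site %in% kept$site[duplicated(kept$site)]
  kept$site[dup] <- paste(kept$site[dup], kept$modification[dup], sep = "_")
  if (nrow(kept) == 0) stop("catalog holds no non-discarded sites",
                            call. = FALSE)
  long <- kept %>%
    select("site", "family", "position", "label", "modification",
           "score_type") %>%
    left_join(tracks, by = c("family", "position", "label", "score_type")) %>%
    filter(.data$valid, .data$coverage >= min_coverage) %>%
    left_join(conditions, by = "sample")
  med <- long %>%
    group_by(.data$site, .data$condition) %>%
    summarise(value = median(.data$value), .groups = "drop")
  m <- med %>%
    tidyr::pivot_wider(names_from = "condition", values_from = "value") %>%
    arrange(match(.data$site, kept$site))
  mat <- as.matrix(m[, -1, drop = FALSE])
  rownames(mat) <- m$site
  cond_order <- unique(conditions$condition)
  mat <- mat[, intersect(cond_order, colnames(mat)), drop = FALSE]
  sites <- kept %>%
    select("site", "family", "label", "modification") %>%
    distinct() %>%
    filter(.data$site %in% rownames(mat))
  structure(list(matrix = mat, sites = sites,
                 replicates = long %>%
                   select("site", "modification", "sample", "condition",
                          "value"),
                 conditions = conditions),
            class = "stoich_matrix")
}

#' @export
print.stoich_matrix <- function(x, ...) {
  cat("<stoich_matrix> ", nrow(x$matrix), " sites x ", ncol(x$matrix),
      " conditions\n", sep = "")
  invisible(x)
}

# exact two-sided rank-sum p-value by enumeration of all group assignments
# (mid-ranks under ties); doubling rule, capped at 1
.ranksum_exact <- function(x, y) {
  v <- c(x, y)
  r <- rank(v)
  nx <- length(x)
  obs <- sum(r[seq_len(nx)])
  combs <- utils::combn(length(v), nx)
  ws <- colSums(matrix(r[combs], nrow = nx))
  p_ge <- mean(ws >= obs)
  p_le <- mean(ws <= obs)
  min(1, 2 * min(p_ge, p_le))
}

#' Mann-Whitney-Wilcoxon comparison between two condition groups
#'
#' Per modification type, the site-level matrix values of the two groups'
#' conditions are compared with a two-sided rank-sum test: an exact
#' enumeration null (mid-ranks under ties) when both groups have at most
#' `exact_max` values, otherwise the normal approximation with tie and
#' continuity correction of [stats::wilcox.test()]. No multiplicity
#' correction is applied by default (raw 0.05 / 0.01 flags are reported);
#' Benjamini-Hochberg adjusted p-values are added with `adjust = TRUE`.
#'
#' @param sm a [build_matrix()] result.
#' @param group_by condition-map column defining the two groups
#'   (default `"species"`).
#' @param exact_max largest per-group size for the exact null (default 8).
#' @param adjust add Benjamini-Hochberg adjusted p-values.
#' @return tibble: `modification`, `group1`, `group2`, `n1`, `n2`,
#'   `p_value`, `sig_05`, `sig_01` (and `p_adj` when `adjust`).
#' @export
compare_groups <- function(sm, group_by = "species", exact_max = 8,
                           adjust = FALSE) {
  stopifnot(inherits(sm, "stoich_matrix"))
  cond <- sm$conditions %>% distinct(.data$condition, .data[[group_by]])
  lv <- unique(cond[[group_by]])
  if (length(lv) != 2) stop("grouping '", group_by, "' must have exactly ",
                            "two levels", call. = FALSE)
  g1 <- cond$condition[cond[[group_by]] == lv[1]]
  g2 <- cond$condition[cond[[group_by]] == lv[2]]
  out <- lapply(unique(sm$sites$modification), function(mod) {
    rows <- sm$sites$site[sm$sites$modification == mod]
    m <- sm$matrix[rownames(sm$matrix) %in% rows, , drop = FALSE]
    x <- as.vector(m[, colnames(m) %in% g1, drop = FALSE])
    y <- as.vector(m[, colnames(m) %in% g2, drop = FALSE])
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (!length(x) || !length(y)) {
      stop("empty group for modification ", mod, call. = FALSE)
    }
    p <- if (length(x) <= exact_max && length(y) <= exact_max) {
      .ranksum_exact(x, y)
    } else {
      suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                          correct = TRUE)$p.value)
    }
    tibble(modification = mod, group1 = lv[1], group2 = lv[2],
           n1 = length(x), n2 = length(y), p_value = p,
           sig_05 = p < 0.05, sig_01 = p < 0.01)
  })
  out <- bind_rows(out)
  if (adjust) out$p_adj <- stats::p.adjust(out$p_value, "BH")
  out
}

#' Classify sites into variability categories
#'
#' Default numeric rule over the condition values of each site:
#' category (i) "high-stable" when the grand median is >= `high` and the
#' cross-condition SD <= `sd_max`; (ii) "low-stable" when the grand median
#' is <= `low` with SD <= `sd_max`; (iii) "variable" when the
#' cross-condition range is >= `range_min`; anything else is unclassified.
#' Categories are assigned in that order, so they are mutually exclusive.
#'
#' @param sm a [build_matrix()] result.
#' @param high,low,sd_max,range_min rule boundaries (defaults 0.8, 0.3,
#'   0.1, 0.25).
#' @return tibble: `site`, `modification`, `category` (`i`, `ii`, `iii`,
#'   `unclassified`), `grand_median`, `sd`, `range`.
#' @export
classify_categories <- function(sm, high = 0.8, low = 0.3, sd_max = 0.1,
                                range_min = 0.25) {
  stopifnot(inherits(sm, "stoich_matrix"))
  m <- sm$matrix
  stats_tbl <- tibble(
    site = rownames(m),
    grand_median = apply(m, 1, median, na.rm = TRUE),
    sd = apply(m, 1, sd, na.rm = TRUE),
    range = apply(m, 1, function(v) diff(range(v, na.rm = TRUE))))
  cat_of <- function(med, s, rg) {
    if (is.na(med) || is.na(s) || is.na(rg)) return("unclassified")
    if (med >= high && s <= sd_max) return("i")
    if (med <= low && s <= sd_max) return("ii")
    if (rg >= range_min) return("iii")
    "unclassified"
  }
  stats_tbl$category <- mapply(cat_of, stats_tbl$grand_median, stats_tbl$sd,
                               stats_tbl$range)
  stats_tbl %>%
    left_join(sm$sites %>% select("site", "modification"), by = "site") %>%
    select("site", "modification", "category", "grand_median", "sd", "range")
}

#' Hierarchically cluster the stoichiometry matrix
#'
#' Agglomerative clustering on Euclidean distances (complete linkage by
#' default), for sites (rows) and conditions (columns); rows with missing
#' values are dropped from the row clustering. Ordering is deterministic.
#'
#' @param sm a [build_matrix()] result or a plain numeric matrix.
#' @param linkage linkage method for [stats::hclust()] (default
#'   `"complete"`).
#' @return list: `row_hc`, `col_hc` (hclust objects; `NULL` when fewer
#'   than 2 rows/columns), `matrix` (ordered by the dendrograms),
#'   `dropped` (row names removed for missingness).
#' @export
cluster_heatmap <- function(sm, linkage = "complete") {
  m <- if (inherits(sm, "stoich_matrix")) sm$matrix else as.matrix(sm)
  ok <- stats::complete.cases(m)
  dropped <- rownames(m)[!ok]
  m <- m[ok, , drop = FALSE]
  row_hc <- if (nrow(m) >= 2) hclust(dist(m), method = linkage) else NULL
  col_hc <- if (ncol(m) >= 2) hclust(dist(t(m)), method = linkage) else NULL
  ord <- m[if (is.null(row_hc)) seq_len(nrow(m)) else row_hc$order,
           if (is.null(col_hc)) seq_len(ncol(m)) else col_hc$order,
           drop = FALSE]
  list(row_hc = row_hc, col_hc = col_hc, matrix = ord, dropped = dropped)
}

#' Principal component analysis of the stoichiometry matrix
#'
#' Conditions are the observations and sites the variables; variables are
#' centered and standardized (correlation-PCA). m7G sites are excluded by
#' default for noise reduction - their stoichiometry is constantly high and
#' contributes no variance of interest. Sites with missing values or zero
#' variance across conditions are dropped (listed in `dropped`); a
#' constant site carries no directional information and its loading is
#' reported as 0. Loadings are the Pearson correlations between a site's
#' condition values and the component scores, so they live in \[-1, 1\].
#'
#' @param sm a [build_matrix()] result.
#' @param exclude modification types excluded before the PCA
#'   (default `"m7G"`).
#' @param impute median-impute missing values instead of dropping the site.
#' @return object of class `mod_pca`: list with `var_explained` (fraction
#'   per component, non-increasing), `coords` (conditions x components),
#'   `loadings` (sites x components, correlation scale), `dropped`,
#'   `sites` (annotation of the sites used), `prcomp` (the underlying fit).
#' @export
run_pca <- function(sm, exclude = "m7G", impute = FALSE) {
  stopifnot(inherits(sm, "stoich_matrix"))
  keep_sites <- sm$sites$site[!sm$sites$modification %in% exclude]
  m <- sm$matrix[rownames(sm$matrix) %in% keep_sites, , drop = FALSE]
  x <- t(m)  # conditions as observations
  dropped <- character()
  if (impute) {
    for (j in seq_len(ncol(x))) {
      miss <- is.na(x[, j])
      if (any(miss)) x[miss, j] <- median(x[, j], na.rm = TRUE)
    }
  }
  complete <- colSums(is.na(x)) == 0
  constant <- apply(x, 2, function(v) isTRUE(sd(v, na.rm = TRUE) == 0))
  use <- complete & !constant
  dropped <- colnames(x)[!use]
  x <- x[, use, drop = FALSE]
  if (ncol(x) < 2 || nrow(x) < 2) {
    stop("PCA needs at least 2 sites and 2 conditions after exclusion",
         call. = FALSE)
  }
  fit <- prcomp(x, center = TRUE, scale. = TRUE)
  ve <- fit$sdev^2 / sum(fit$sdev^2)
  k <- ncol(fit$x)
  loads <- cor(x, fit$x)            # sites x PCs, Pearson correlations
  if (length(dropped)) {
    zero <- matrix(0, length(dropped), k,
                   dimnames = list(dropped, colnames(fit$x)))
    loads <- rbind(loads, zero)
  }
  structure(
    list(var_explained = ve, coords = fit$x, loadings = loads,
         dropped = dropped,
         sites = sm$sites %>% filter(.data$site %in% rownames(loads)),
         prcomp = fit),
    class = "mod_pca")
}

#' @export
print.mod_pca <- function(x, ...) {
  cat("<mod_pca> ", nrow(x$coords), " conditions, ",
      nrow(x$loadings) - length(x$dropped), " sites; variance: ",
      paste(sprintf("PC%d %.1f%%", seq_len(min(4, length(x$var_explained))),
                    100 * x$var_explained[seq_len(min(4, length(x$var_explained)))]),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Extract per-component signature sets
#'
#' Sites whose absolute correlation with a component exceeds `cutoff`
#' (strict inequality). Sets may in principle overlap on degenerate input;
#' the pairwise overlap matrix is reported so disjointness can be checked.
#'
#' @param pca a [run_pca()] result.
#' @param cutoff absolute-correlation cutoff (default 0.70).
#' @param components which components to report (default up to the first
#'   four).
#' @return list with `signatures` (named list of site-id vectors per
#'   component) and `overlap` (matrix of pairwise intersection sizes).
#' @export
extract_signatures <- function(pca, cutoff = 0.70, components = NULL) {
  stopifnot(inherits(pca, "mod_pca"))
  k <- ncol(pca$loadings)
  if (is.null(components)) components <- seq_len(min(4, k))
  stopifnot(all(components >= 1), all(components <= k))
  sig <- lapply(components, function(j) {
    rownames(pca$loadings)[abs(pca$loadings[, j]) > cutoff]
  })
  names(sig) <- paste0("PC", components)
  ov <- outer(seq_along(sig), seq_along(sig),
              Vectorize(function(a, b) length(intersect(sig[[a]], sig[[b]]))))
  dimnames(ov) <- list(names(sig), names(sig))
  list(signatures = sig, overlap = ov)
}
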