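# End-to-end orchestration: scores -> noise calibration -> detection ->
# curation -> stoichiometry matrix -> categories, group tests, PCA and
# signatures; plus evaluation helpers against a known synthetic truth.

#' Derive plausibility rules from a synthetic truth table
#'
#' Planted sites flagged `documented` become the documented-site list, so a
#' synthetic study exercises the documented / retained-candidate /
#' added-back curation paths.
#'
#' @param truth truth tibble from [simulate_truth()].
#' @param ... passed to [plausibility_rules()] (e.g. a replacement
#'   whitelist).
#' @return a [plausibility_rules()] object.
#' @export
rules_from_truth <- function(truth, ...) {
  doc <- truth %>%
    filter(.data$documented) %>%
    distinct(.data$family, .data$label, .data$modification)
  plausibility_rules(documented = doc, ...)
}

#' Calibrate all noise models for a study
#'
#' Bisulfite NonConv and AlkAnilineSeq stop-ratio backgrounds come from a
#' designated unmodified background family (Gaussian fit, k = 3; stop
#' ratios per parent nucleotide, the A channel acting as the negative
#' control); without one, a robust (median/MAD) fit to all families is
#' used. RiboMethSeq Score A and Score Angle thresholds come from robust
#' Gaussian fits to the genome-wide unclipped score distributions (k = 2),
#' resisting contamination by true sites.
#'
#' @param tracks score-track tibble (all chemistries row-bound).
#' @param samples sample universe for calibration (the detection samples).
#' @param background_family id of an unmodified family, or `NULL`.
#' @param min_coverage minimum coverage for a value to enter calibration.
#' @return named list of [noise_model()] objects (`NonConv`,
#'   `StopRatio_A/C/G/U` or `StopRatio`, `A`, `Angle`, as available).
#' @export
calibrate_noise <- function(tracks, samples = unique(tracks$sample),
                            background_family = NULL, min_coverage = 30) {
  tr <- tracks %>%
    filter(.data$sample %in% samples, .data$valid,
           .data$coverage >= min_coverage)
  noise <- list()
  bs <- tr %>% filter(.data$score_type == "NonConv")
  if (nrow(bs)) {
    if (!is.null(background_family)) {
      vals <- bs$value[bs$family == background_family]
      noise$NonConv <- estimate_noise(vals, k = 3, method = "gaussian",
                                      source = paste("unmodified family",
                                                     background_family))
    } else {
      noise$NonConv <- estimate_noise(bs$value, k = 3, method = "robust",
                                      source = "all C positions (robust)")
    }
  }
  aas <- tr %>% filter(.data$score_type == "StopRatio")
  if (nrow(aas)) {
    pool <- if (!is.null(background_family)) {
      aas %>% filter(.data$family == background_family)
    } else {
      aas
    }
    method <- if (!is.null(background_family)) "gaussian" else "robust"
    for (nt in c("A", "C", "G", "U")) {
      vals <- pool$value[pool$base == nt]
      if (length(vals) >= 10) {
        noise[[paste0("StopRatio_", nt)]] <- estimate_noise(
          vals, k = 3, method = method,
          source = paste0("stop background at ", nt, " residues"))
      }
    }
    if (!any(grepl("^StopRatio_", names(noise)))) {
      noise$StopRatio <- estimate_noise(pool$value, k = 3, method = method,
                                        source = "pooled stop background")
    }
  }
  rms <- tr %>% filter(.data$chemistry == "rms")
  for (ty in c("A", "Angle")) {
    vals <- rms$value_raw[rms$score_type == ty]
    if (length(vals) >= 10) {
      noise[[ty]] <- estimate_noise(
        vals, k = 2, method = "robust",
        source = paste0("genome-wide Score ", ty, " distribution (robust)"))
    }
  }
  noise
}

#' Run the full quantification workflow on a study
#'
#' Computes score tracks for the three chemistries, calibrates noise on the
#' detection samples (the tRNA-species samples by default, mirroring the
#' "signal in at least half of the tRNA samples" rule), filters and curates
#' candidate sites, builds the sites x conditions stoichiometry matrix over
#' all samples, and runs the comparative analyses.
#'
#' @param study list with `counts` (list `rms`, `aas`, `bs` count tibbles;
#'   any subset), `families`, `conditions` and optionally `decoy_family`,
#'   as produced by [simulate_study()] or assembled from
#'   [read_count_tables()] output.
#' @param rules a [plausibility_rules()] object.
#' @param cfg a [score_config()].
#' @param angle_plugin Score Angle plugin (default [angle_scaled_c()]).
#' @param min_coverage,min_fraction detection filters (defaults 30, 0.5).
#' @param detection_species condition-map species whose samples form the
#'   detection universe (default `"tRNA"`; `NULL` uses all samples).
#' @param pca_exclude modification types excluded from the PCA
#'   (default `"m7G"`).
#' @return object of class `study_result`: list with `tracks`, `noise`,
#'   `all_sites`, `catalog`, `summary`, `matrix` (the `stoich_matrix`),
#'   `categories`, `tests`, `pca`, `signatures`, `conditions`.
#' @export
run_study <- function(study, rules = plausibility_rules(),
                      cfg = score_config(), angle_plugin = angle_scaled_c,
                      min_coverage = 30, min_fraction = 0.5,
                      detection_species = "tRNA", pca_exclude = "m7G") {
  conditions <- condition_map(study$conditions)
  tracks <- bind_rows(lapply(names(study$counts), function(chem) {
    compute_score_tracks(study$counts[[chem]], chem, study$families,
                         cfg = cfg, angle_plugin = angle_plugin)
  }))
  det_samples <- if (is.null(detection_species)) {
    conditions$sample
  } else {
    conditions$sample[conditions$species == detection_species]
  }
  noise <- calibrate_noise(tracks, det_samples,
                           background_family = study$decoy_family,
                           min_coverage = min_coverage)
  all_sites <- filter_candidates(tracks, noise, min_coverage = min_coverage,
                                 min_fraction = min_fraction,
                                 samples = det_samples, keep_all = TRUE)
  catalog <- curate(all_sites, rules, all_sites = all_sites)
  summary <- summarize_catalog(catalog)
  kept <- catalog %>% filter(.data$status != "discarded")
  sm <- NULL; categories <- NULL; tests <- NULL; pca <- NULL; sig <- NULL
  if (nrow(kept) > 0) {
    sm <- build_matrix(tracks, catalog, conditions,
                       min_coverage = min_coverage)
    categories <- classify_categories(sm)
    tests <- tryCatch(compare_groups(sm, group_by = "species"),
                      error = function(e) NULL)
    pca <- tryCatch(run_pca(sm, exclude = pca_exclude),
                    error = function(e) NULL)
    if (!is.null(pca)) sig <- extract_signatures(pca)
  }
  structure(
    list(tracks = tracks, noise = noise, all_sites = all_sites,
         catalog = catalog, summary = summary, matrix = sm,
         categories = categories, tests = tests, pca = pca,
         signatures = sig, conditions = conditions),
    class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat("<study_result> catalog: ", x$summary$total, " site(s) (",
      x$summary$total_fully_modified, " fully modified)\n", sep = "")
  if (!is.null(x$pca)) print(x$pca)
  invisible(x)
}

#' Stoichiometry recovery error against a known truth
#'
#' Joins the estimated stoichiometry matrix with the planted truth (per
#' site and condition, matching modification type) and reports the mean
#' absolute error per quantification score.
#'
#' @param result a [run_study()] result.
#' @param truth truth tibble from [simulate_truth()].
#' @return list with `per_site` (tibble `site`, `modification`,
#'   `condition`, `estimate`, `theta`, `abs_error`) and `mae` (tibble
#'   `score`, `mae`, `n`).
#' @export
evaluate_recovery <- function(result, truth) {
  stopifnot(inherits(result, "study_result"), !is.null(result$matrix))
  sm <- result$matrix
  est <- as_tibble(sm$matrix, rownames = "site") %>%
    tidyr::pivot_longer(-"site", names_to = "condition",
                        values_to = "estimate") %>%
    left_join(sm$sites, by = "site")
  per_site <- est %>%
    dplyr::inner_join(truth,
                      by = c("family", "label", "modification", "condition")) %>%
    mutate(abs_error = abs(.data$estimate - .data$theta)) %>%
    select("site", "modification", "condition", "estimate", "theta",
           "abs_error") %>%
    filter(!is.na(.data$abs_error))
  score_of <- c(m5C = "NonConv", Nm = "MethScore", m7G = "StopRatio",
                m3C = "StopRatio", D = "StopRatio")
  mae <- per_site %>%
    mutate(score = unname(score_of[.data$modification])) %>%
    group_by(.data$score) %>%
    summarise(mae = mean(.data$abs_error), n = dplyr::n(), .groups = "drop")
  list(per_site = per_site, mae = mae)
}

#' Silhouette separation of two groups along one principal component
#'
#' Mean silhouette width of the grouping on the 1-D component coordinates;
#' positive values mean the groups separate along that component.
#'
#' @param result a [run_study()] result with a PCA.
#' @param group_by condition-map column (default `"species"`).
#' @param component which component (default 1).
#' @return mean silhouette width in \[-1, 1\].
#' @export
pc_separation <- function(result, group_by = "species", component = 1) {
  stopifnot(inherits(result, "study_result"), !is.null(result$pca))
  coords <- result$pca$coords[, component]
  cond <- result$conditions %>% distinct(.data$condition, .data[[group_by]])
  grp <- cond[[group_by]][match(names(coords), cond$condition)]
  sil <- cluster::silhouette(as.integer(factor(grp)), dist(coords))
  mean(sil[, "sil_width"])
}

#' Recall of planted sites in the curated catalog
#'
#' @param result a [run_study()] result.
#' @param truth truth tibble from [simulate_truth()].
#' @return list with `recall` (fraction of planted sites present
#'   non-discarded in the catalog), `n_planted`, `missed` (tibble).
#' @export
catalog_recall <- function(result, truth) {
  planted <- truth %>%
    distinct(.data$family, .data$label, .data$modification)
  kept <- result$catalog %>%
    filter(.data$status != "discarded") %>%
    distinct(.data$family, .data$label, .data$modification)
  hit <- dplyr::inner_join(planted, kept,
                           by = c("family", "label", "modification"))
  missed <- anti_join(planted, kept,
                      by = c("family", "label", "modification"))
  list(recall = if (nrow(planted)) nrow(hit) / nrow(planted) else NA_real_,
       n_planted = nrow(planted), missed = missed)
}
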