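# Site detection and curation: apply noise-calibrated thresholds with the
# coverage and >= 50%-of-samples filters, then curate candidates against
# modification-type plausibility rules (whitelisted Sprinzl positions,
# known-unmodified discard lists, documented-site add-back).

# AlkAnilineSeq parent nucleotide -> modification call; the A channel has no
# known responsive modification and acts as the negative-control channel.
.AAS_MODS <- c(G = "m7G", C = "m3C", U = "D", A = "A_control")

.mod_for <- function(chemistry, base) {
  switch(chemistry,
         bs = ifelse(base == "C", "m5C", NA_character_),
         rms = "Nm",
         aas = unname(.AAS_MODS[base]))
}

#' Default plausibility rules
#'
#' Whitelisted Sprinzl positions per modification type, from the positions
#' with literature-documented enzymatic activity in cytoplasmic tRNA:
#' m5C at 38 (DNMT2), 48/49/50 (NSUN2) and 72 (NSUN6); Nm at 18, 32, 34,
#' 39, 44 and 54 (position 4 deliberately absent: too close to the 5'
#' terminus for reliable RiboMethSeq quantification); m7G at 46; m3C at 20,
#' 32 and e2; D at 16, 17, 20, 20a and 47. The documented-site and
#' known-unmodified lists default to empty and are study inputs.
#'
#' @param whitelist,documented,known_unmodified optional replacement
#'   tibbles; `whitelist` has columns `modification`, `label`, the other
#'   two `family`, `label`, `modification`.
#' @return list of class `plausibility_rules`.
#' @export
plausibility_rules <- function(whitelist = NULL, documented = NULL,
                               known_unmodified = NULL) {
  if (is.null(whitelist)) {
    whitelist <- tibble(
      modification = rep(c("m5C", "Nm", "m7G", "m3C", "D"),
                         times = c(5L, 6L, 1L, 3L, 5L)),
      label = c("38", "48", "49", "50", "72",
                "18", "32", "34", "39", "44", "54",
                "46",
                "20", "32", "e2",
                "16", "17", "20", "20a", "47"))
  }
  empty <- tibble(family = character(), label = character(),
                  modification = character())
  if (is.null(documented)) documented <- empty
  if (is.null(known_unmodified)) known_unmodified <- empty
  overlap <- dplyr::inner_join(documented, known_unmodified,
                               by = c("family", "label", "modification"))
  if (nrow(overlap)) {
    stop("documented and known-unmodified lists overlap", call. = FALSE)
  }
  structure(list(whitelist = as_tibble(whitelist),
                 documented = as_tibble(documented),
                 known_unmodified = as_tibble(known_unmodified)),
            class = "plausibility_rules")
}

#' Read plausibility rules from TSV files
#'
#' Expects `whitelist.tsv` (columns `modification`, `label`) and optionally
#' `documented.tsv` / `known_unmodified.tsv` (columns `family`, `label`,
#' `modification`) in `dir`. Missing optional files yield empty lists.
#'
#' @param dir directory holding the rule files.
#' @return a [plausibility_rules()] object.
#' @export
read_rules <- function(dir) {
  rd <- function(f) {
    p <- file.path(dir, f)
    if (file.exists(p)) {
      x <- readr::read_tsv(p, show_col_types = FALSE, progress = FALSE)
      x$label <- as.character(x$label)
      x
    } else NULL
  }
  plausibility_rules(whitelist = rd("whitelist.tsv"),
                     documented = rd("documented.tsv"),
                     known_unmodified = rd("known_unmodified.tsv"))
}

.threshold_for <- function(noise, score_type, base) {
  if (length(score_type) == 0 || is.na(score_type)) return(NA_real_)
  key <- if (score_type == "StopRatio") paste0("StopRatio_", base) else score_type
  nm <- noise[[key]]
  if (is.null(nm) && score_type == "StopRatio") nm <- noise[["StopRatio"]]
  if (is.null(nm)) {
    stop("no noise model for score type '", key, "'", call. = FALSE)
  }
  nm$threshold
}

#' Filter scored positions into candidate sites
#'
#' A site is evaluable in a sample when its score is valid there and the
#' coverage is at least `min_coverage`; sites evaluable in fewer than
#' `min_fraction` of the sample universe are dropped as unquantifiable. A
#' quantifiable site becomes a candidate when its detection score exceeds
#' the noise threshold in at least `min_fraction` of its evaluable samples
#' - for RiboMethSeq, Score A and Score Angle must BOTH pass their own
#' thresholds (dual-score rule); thresholds for the stop ratio are looked
#' up per parent nucleotide (`StopRatio_A/C/G/U`, falling back to
#' `StopRatio`).
#'
#' @param tracks score-track tibble from [compute_score_tracks()] (several
#'   chemistries may be row-bound).
#' @param noise named list of [noise_model()] objects: `NonConv`,
#'   `StopRatio_*` (or `StopRatio`), `A`, `Angle` as needed by the
#'   chemistries present.
#' @param min_coverage minimum per-sample coverage (default 30 reads).
#' @param min_fraction minimum fraction of samples with signal
#'   (default 0.5).
#' @param samples sample universe over which the fraction is evaluated;
#'   default all samples present in `tracks`. In the full study design this
#'   is the 12 tRNA-species samples.
#' @param keep_all also return quantifiable sites that failed the
#'   threshold rule (`candidate = FALSE` rows); needed downstream for
#'   documented-site add-back.
#' @return tibble of candidate sites: `family`, `position`, `label`,
#'   `base`, `chemistry`, `modification`, `median_score` (median of the
#'   quantification score over evaluable samples), `frac_above` (binding
#'   fraction across the required detection scores), `n_evaluable`,
#'   `candidate`.
#' @export
filter_candidates <- function(tracks, noise, min_coverage = 30,
                              min_fraction = 0.5, samples = NULL,
                              keep_all = FALSE) {
  detection_types <- list(bs = "NonConv", aas = "StopRatio",
                          rms = c("A", "Angle"))
  quant_types <- c(bs = "NonConv", aas = "StopRatio", rms = "C")
  if (is.null(samples)) samples <- unique(tracks$sample)
  tracks <- tracks %>% filter(.data$sample %in% samples)
  n_universe <- length(samples)

  out <- list()
  for (chem in intersect(names(detection_types), unique(tracks$chemistry))) {
    sub <- tracks %>% filter(.data$chemistry == chem)
    need <- c(detection_types[[chem]], quant_types[[chem]])
    missing_types <- setdiff(need, unique(sub$score_type))
    if (length(missing_types)) {
      stop("chemistry '", chem, "' is missing score type(s): ",
           paste(missing_types, collapse = ", "), call. = FALSE)
    }
    ev <- sub %>%
      filter(.data$score_type %in% need) %>%
      mutate(evaluable = .data$valid & .data$coverage >= min_coverage)

    per_type <- ev %>%
      filter(.data$score_type %in% detection_types[[chem]],
             .data$evaluable) %>%
      group_by(.data$family, .data$position, .data$label, .data$base,
               .data$score_type) %>%
      summarise(
        n_eval = dplyr::n_distinct(.data$sample),
        frac_above = mean(.data$value_raw >
                            .threshold_for(noise, .data$score_type[1],
                                           .data$base[1])),
        .groups = "drop")

    if (nrow(per_type) == 0) next
    site <- per_type %>%
      group_by(.data$family, .data$position, .data$label, .data$base) %>%
      summarise(
        n_types = dplyr::n(),
        n_evaluable = min(.data$n_eval),
        frac_above = min(.data$frac_above),
        .groups = "drop") %>%
      filter(.data$n_types == length(detection_types[[chem]]),
             .data$n_evaluable >= min_fraction * n_universe)

    med <- ev %>%
      filter(.data$score_type == quant_types[[chem]], .data$evaluable) %>%
      group_by(.data$family, .data$position) %>%
      summarise(median_score = median(.data$value), .groups = "drop")

    res <- site %>%
      left_join(med, by = c("family", "position")) %>%
      mutate(chemistry = chem,
             modification = .mod_for(chem, .data$base),
             candidate = .data$frac_above >= min_fraction) %>%
      filter(!is.na(.data$modification))
    out[[chem]] <- res
  }
  res <- bind_rows(out)
  if (nrow(res) == 0) {
    res <- tibble(family = character(), position = integer(),
                  label = character(), base = character(),
                  chemistry = character(), modification = character(),
                  median_score = numeric(), frac_above = numeric(),
                  n_evaluable = integer(), candidate = logical())
  } else {
    res <- res %>%
      select("family", "position", "label", "base", "chemistry",
             "modification", "median_score", "frac_above", "n_evaluable",
             "candidate") %>%
      arrange(.data$family, .data$position, .data$chemistry)
  }
  if (keep_all) res else res %>% filter(.data$candidate)
}

#' Curate candidate sites into the final catalog
#'
#' Applies the plausibility rules: candidates on the known-unmodified list
#' or at positions not whitelisted for their modification type are
#' discarded (with a machine-readable reason); surviving candidates are
#' labelled `documented` when literature-documented and
#' `retained_candidate` otherwise. Documented sites that failed the
#' threshold rule but are quantifiable are `added_back` when `all_sites`
#' (the `keep_all = TRUE` output of [filter_candidates()]) is supplied -
#' except at positions not whitelisted for quantification (e.g. Nm4).
#'
#' @param candidates candidate tibble from [filter_candidates()].
#' @param rules a [plausibility_rules()] object.
#' @param all_sites optional `keep_all = TRUE` candidate table used as the
#'   source for add-backs.
#' @return catalog tibble: candidate columns plus `status` (one of
#'   `documented`, `retained_candidate`, `discarded`, `added_back`) and
#'   `reason`.
#' @export
curate <- function(candidates, rules = plausibility_rules(),
                   all_sites = NULL) {
  stopifnot(inherits(rules, "plausibility_rules"))
  cand <- candidates %>% filter(.data$candidate)
  keyed <- function(x) paste(x$family, x$label, x$modification, sep = "\r")
  wl <- split(rules$whitelist$label, rules$whitelist$modification)
  status <- character(nrow(cand))
  reason <- character(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    mod <- cand$modification[i]
    if (keyed(cand[i, ]) %in% keyed(rules$known_unmodified)) {
      status[i] <- "discarded"
      reason[i] <- "known unmodified position"
    } else if (!(cand$label[i] %in% wl[[mod]])) {
      status[i] <- "discarded"
      reason[i] <- paste0("implausible position for ", mod)
    } else if (keyed(cand[i, ]) %in% keyed(rules$documented)) {
      status[i] <- "documented"
      reason[i] <- "documented site above threshold"
    } else {
      status[i] <- "retained_candidate"
      reason[i] <- "above threshold at plausible position"
    }
  }
  catalog <- cand %>% mutate(status = status, reason = reason)

  if (!is.null(all_sites) && nrow(rules$documented)) {
    pool <- all_sites %>% filter(!.data$candidate)
    back <- pool[keyed(pool) %in% keyed(rules$documented) &
                   !(keyed(pool) %in% keyed(catalog)), , drop = FALSE]
    # add-back only at positions quantifiable/whitelisted for the type
    ok <- vapply(seq_len(nrow(back)), function(i)
      back$label[i] %in% wl[[back$modification[i]]], logical(1))
    back <- back[ok, , drop = FALSE]
    if (nrow(back)) {
      back <- back %>%
        mutate(status = "added_back",
               reason = "documented site below threshold; added back")
      catalog <- bind_rows(catalog, back)
    }
  }
  stopifnot(all(nzchar(catalog$reason)))
  catalog %>% arrange(.data$family, .data$position, .data$chemistry)
}

#' Summarize a site catalog
#'
#' Per-modification counts of the non-discarded catalog entries, their
#' total, and the counts of "fully modified" sites (median quantification
#' score above `fully_cutoff`, default 0.8).
#'
#' @param catalog catalog tibble from [curate()].
#' @param fully_cutoff stoichiometry above which a site counts as fully
#'   modified (default 0.8).
#' @return list with `by_type` (tibble `modification`, `n_sites`,
#'   `n_fully_modified`), `total` and `total_fully_modified`.
#' @export
summarize_catalog <- function(catalog, fully_cutoff = 0.8) {
  kept <- catalog %>% filter(.data$status != "discarded")
  if (nrow(kept) == 0) {
    return(list(by_type = tibble(modification = character(),
                                 n_sites = integer(),
                                 n_fully_modified = integer()),
                total = 0L, total_fully_modified = 0L))
  }
  by_type <- kept %>%
    group_by(.data$modification) %>%
    summarise(
      n_sites = dplyr::n(),
      n_fully_modified = sum(!is.na(.data$median_score) &
                               .data$median_score > fully_cutoff),
      .groups = "drop")
  list(by_type = by_type,
       total = sum(by_type$n_sites),
       total_fully_modified = sum(by_type$n_fully_modified))
}
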