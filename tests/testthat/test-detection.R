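# Noise calibration, threshold filtering, curation, catalog bookkeeping.

test_that("noise estimation: moments, constant background, robustness", {
  set.seed(31)
  v <- rbeta(200, 1, 30)
  nm <- estimate_noise(v, k = 3)
  expect_equal(nm$mean, sum(v) / length(v))
  expect_equal(nm$sd, sqrt(sum((v - mean(v))^2) / (length(v) - 1)))
  expect_equal(nm$threshold, nm$mean + 3 * nm$sd)

  expect_equal(estimate_noise(rep(0.02, 50), k = 3)$threshold, 0.02)
  expect_error(estimate_noise(rnorm(5), k = 2), "insufficient")

  # robust fit resists contamination by true sites
  clean <- rnorm(500, 0.01, 0.05)
  contaminated <- c(clean, rep(0.9, 50))
  g <- estimate_noise(contaminated, k = 2, method = "gaussian")
  r <- estimate_noise(contaminated, k = 2, method = "robust")
  truth <- estimate_noise(clean, k = 2, method = "gaussian")
  expect_lt(abs(r$threshold - truth$threshold),
            abs(g$threshold - truth$threshold))
})

test_that("Gaussian exclusion percentages", {
  expect_equal(gaussian_exclusion(0), 50)
  expect_equal(round(gaussian_exclusion(3), 2), 99.87)
})

make_tracks <- function(values, coverage = 100, score_type = "NonConv",
                        chemistry = "bs", base = "C", label = "48",
                        family = "Fam", position = 48L) {
  tibble::tibble(
    family = family, position = position, label = label, base = base,
    sample = paste0("s", seq_along(values)), chemistry = chemistry,
    score_type = score_type, value = values, value_raw = values,
    valid = !is.na(values),
    coverage = rep_len(coverage, length(values)))
}

test_that("50%-of-samples rule and coverage filter", {
  noise <- list(NonConv = noise_model(0.02, 0.05, 3))  # threshold 0.17
  # above threshold in 3 of 6 samples -> kept
  tr <- make_tracks(c(0.5, 0.5, 0.5, 0.01, 0.01, 0.01))
  kept <- filter_candidates(tr, noise)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$modification, "m5C")
  expect_equal(kept$frac_above, 0.5)
  # in 2 of 6 -> dropped
  tr2 <- make_tracks(c(0.5, 0.5, 0.01, 0.01, 0.01, 0.01))
  expect_equal(nrow(filter_candidates(tr2, noise)), 0)
  # coverage below 30 makes the sample unevaluable; a site evaluable in
  # fewer than half the universe is unquantifiable
  tr3 <- make_tracks(0.5, coverage = 29)
  expect_equal(nrow(filter_candidates(tr3, noise, keep_all = TRUE)), 0)
})

test_that("RiboMethSeq dual-score rule requires Score A AND Angle", {
  noise <- list(A = noise_model(0, 0.1, 2),       # threshold 0.2
                Angle = noise_model(0, 100, 2))   # threshold 200
  mk <- function(a_vals, angle_vals, c_vals) {
    dplyr::bind_rows(
      make_tracks(a_vals, score_type = "A", chemistry = "rms", base = "G",
                  label = "18", position = 18L),
      make_tracks(angle_vals, score_type = "Angle", chemistry = "rms",
                  base = "G", label = "18", position = 18L),
      make_tracks(c_vals, score_type = "C", chemistry = "rms", base = "G",
                  label = "18", position = 18L))
  }
  both <- mk(rep(0.5, 4), rep(500, 4), rep(0.6, 4))
  expect_equal(nrow(filter_candidates(both, noise)), 1)
  # above Score A threshold but below Angle threshold -> dropped
  a_only <- mk(rep(0.5, 4), rep(150, 4), rep(0.6, 4))
  expect_equal(nrow(filter_candidates(a_only, noise)), 0)
  # missing score type errors, listing what is absent
  expect_error(
    filter_candidates(both[both$score_type != "Angle", ], noise), "Angle")
})

test_that("stop-ratio thresholds resolve per parent nucleotide", {
  noise <- list(StopRatio_G = noise_model(0.02, 0.1, 3),   # 0.32
                StopRatio_U = noise_model(0.03, 0.1, 3))   # 0.33
  g <- make_tracks(rep(0.5, 4), score_type = "StopRatio", chemistry = "aas",
                   base = "G", label = "46", position = 46L)
  u <- make_tracks(rep(0.2, 4), score_type = "StopRatio", chemistry = "aas",
                   base = "U", label = "47", position = 47L,
                   family = "Fam2")
  out <- filter_candidates(dplyr::bind_rows(g, u), noise)
  expect_equal(out$modification, "m7G")  # U site at 0.2 stays below 0.33
})

cand_row <- function(family, label, mod, median_score = 0.6,
                     candidate = TRUE) {
  tibble::tibble(family = family, position = 1L, label = label,
                 base = "C", chemistry = "bs", modification = mod,
                 median_score = median_score, frac_above = 1,
                 n_evaluable = 6L, candidate = candidate)
}

test_that("curation: implausible positions, known-unmodified, add-back", {
  rules <- plausibility_rules(
    documented = tibble::tibble(family = c("Gly_GCC", "Ala_AGC"),
                                label = c("18", "48"),
                                modification = c("Nm", "m5C")),
    known_unmodified = tibble::tibble(family = "Sec_TCA", label = "32",
                                      modification = "m3C"))
  cands <- dplyr::bind_rows(
    cand_row("Ser_GCT", "11", "m5C"),           # never an m5C position
    cand_row("Thr_CGT", "48", "m5C"),           # plausible, new
    cand_row("Ala_AGC", "48", "m5C"),           # plausible, documented
    dplyr::mutate(cand_row("Sec_TCA", "32", "m3C"), chemistry = "aas"))
  all_sites <- dplyr::bind_rows(
    cands,
    dplyr::mutate(cand_row("Gly_GCC", "18", "Nm", median_score = 0.2,
                           candidate = FALSE), chemistry = "rms"))
  cat <- curate(all_sites, rules, all_sites = all_sites)
  get <- function(f, l) cat[cat$family == f & cat$label == l, ]
  expect_equal(get("Ser_GCT", "11")$status, "discarded")
  expect_match(get("Ser_GCT", "11")$reason, "implausible")
  expect_equal(get("Thr_CGT", "48")$status, "retained_candidate")
  expect_equal(get("Ala_AGC", "48")$status, "documented")
  expect_equal(get("Sec_TCA", "32")$status, "discarded")
  expect_match(get("Sec_TCA", "32")$reason, "unmodified")
  # documented Gm18 below threshold comes back in
  expect_equal(get("Gly_GCC", "18")$status, "added_back")
  expect_true(all(nzchar(cat$reason)))
})

test_that("Nm4 is never added back: too close to the 5' end to quantify", {
  rules <- plausibility_rules(
    documented = tibble::tibble(family = "Ala_AGC", label = "4",
                                modification = "Nm"))
  all_sites <- dplyr::mutate(cand_row("Ala_AGC", "4", "Nm",
                                      candidate = FALSE), chemistry = "rms")
  cat <- curate(all_sites[0, ], rules, all_sites = all_sites)
  expect_equal(nrow(cat), 0)
})

test_that("catalog summary counts types, totals and full modification", {
  cat <- dplyr::bind_rows(
    dplyr::mutate(cand_row("F1", "48", "m5C", 0.95), status = "documented",
                  reason = "r"),
    dplyr::mutate(cand_row("F2", "49", "m5C", 0.4),
                  status = "retained_candidate", reason = "r"),
    dplyr::mutate(cand_row("F3", "46", "m7G", 0.99), status = "documented",
                  reason = "r"),
    dplyr::mutate(cand_row("F4", "11", "m5C", 0.9), status = "discarded",
                  reason = "r"))
  s <- summarize_catalog(cat)
  expect_equal(s$total, 3L)
  expect_equal(s$total_fully_modified, 2L)
  expect_equal(s$by_type$n_sites[s$by_type$modification == "m5C"], 2L)
  empty <- summarize_catalog(cat[cat$status == "nope", ])
  expect_equal(empty$total, 0L)
  expect_equal(empty$total_fully_modified, 0L)
})

test_that("curated catalog on the synthetic study partitions exhaustively", {
  res <- small_result()
  expect_true(all(res$catalog$status %in%
                    c("documented", "retained_candidate", "discarded",
                      "added_back")))
  expect_true(all(nzchar(res$catalog$reason)))
  expect_false(any(duplicated(
    res$catalog[, c("family", "label", "modification")])))
})
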