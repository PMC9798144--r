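# Synthetic-data generator: determinism, effect arithmetic, count models,
# fixture emission.

test_that("truth is deterministic given the seed and responds to effects", {
  cfg <- sim_config(seed = 77, n_families = 4)
  t1 <- simulate_truth(cfg)
  t2 <- simulate_truth(cfg)
  expect_identical(t1$truth, t2$truth)
  expect_identical(vapply(t1$families, `[[`, "", "consensus"),
                   vapply(t2$families, `[[`, "", "consensus"))

  # species delta 0.4 on a theta0 = 0.9 site -> tsRNA theta 0.5
  sp <- t1$truth[t1$truth$effect == "species_effect" &
                   t1$truth$theta0 == 0.9, ]
  expect_true(all(sp$theta[grepl("tsRNA", sp$condition)] == 0.5))
  expect_true(all(sp$theta[grepl("\\.tRNA\\.", sp$condition)] == 0.9))

  # zero effect sizes -> all conditions share theta0
  cfg0 <- sim_config(seed = 77, n_families = 4, species_delta = 0,
                     cellline_delta = 0, treatment_delta = 0)
  t0 <- simulate_truth(cfg0)
  by_site <- split(t0$truth$theta,
                   paste(t0$truth$family, t0$truth$label,
                         t0$truth$modification))
  expect_true(all(vapply(by_site, function(v) length(unique(v)) == 1,
                         logical(1))))
  expect_true(all(t1$truth$theta >= 0 & t1$truth$theta <= 1))
})

test_that("null configuration plants nothing", {
  t0 <- simulate_truth(sim_config(seed = 5, planted = FALSE))
  expect_equal(nrow(t0$truth), 0)
})

test_that("planted positions carry the base their modification requires", {
  tr <- simulate_truth(sim_config(seed = 9))
  req <- c(m5C = "C", m3C = "C", m7G = "G", D = "U")
  sites <- unique(tr$truth[, c("family", "position", "modification")])
  for (i in seq_len(nrow(sites))) {
    mod <- sites$modification[i]
    if (mod %in% names(req)) {
      b <- substr(tr$families[[sites$family[i]]]$consensus,
                  sites$position[i], sites$position[i])
      expect_equal(b, unname(req[mod]))
    }
  }
})

test_that("D47 site responds divergently to treatment", {
  tr <- simulate_truth(sim_config(seed = 13))
  d47 <- tr$truth[tr$truth$modification == "D" & tr$truth$label == "47", ]
  expect_gt(nrow(d47), 0)
  pick <- function(sp, t) d47$theta[grepl(paste0("\\.", sp, "\\.", t, "$"),
                                          d47$condition) &
                                      grepl("^MZ", d47$condition)]
  expect_lt(pick("tRNA", "ANG"), pick("tRNA", "untreated"))
  expect_gt(pick("tsRNA", "ANG"), pick("tsRNA", "untreated"))
})

test_that("RiboMethSeq counts: full protection zeroes the site's ends", {
  cfg <- sim_config(seed = 21, n_families = 1, depth = 5000,
                    rms_dispersion = 0)
  tr <- simulate_truth(cfg)
  # force a fully modified Nm site
  tr$truth$theta[tr$truth$modification == "Nm"] <- 1
  nm <- tr$truth[tr$truth$modification == "Nm", ]
  counts <- simulate_rms_counts(tr, cfg)
  at_site <- counts[counts$family == nm$family[1] &
                      counts$position == nm$position[1], ]
  expect_true(all(at_site$end3 == 0))  # Poisson(0) is exactly 0
  # theta = 0 positions look like their neighbors in expectation
  off <- counts[counts$family == nm$family[1] &
                  counts$position %in% (nm$position[1] + 3:5), ]
  expect_gt(mean(off$end3), 0.5 * cfg$depth / 76)
})

test_that("bisulfite counts converge to theta + (1-theta) * background", {
  cfg <- sim_config(seed = 23, n_families = 2, depth = 50000)
  tr <- simulate_truth(cfg)
  counts <- simulate_bs_counts(tr, cfg)
  tracks <- compute_score_tracks(counts, "bs", tr$families)
  planted <- unique(tr$truth[tr$truth$modification == "m5C",
                             c("family", "position")])
  bg <- tracks[!paste(tracks$family, tracks$position) %in%
                 paste(planted$family, planted$position), ]
  expect_lt(abs(mean(bg$value, na.rm = TRUE) - 0.0252), 0.01)
  # a theta = 0.5 site averages 0.5 + 0.5 * 0.0252
  sel <- tr$truth[tr$truth$theta == 0.5 & tr$truth$modification == "m5C", ]
  if (nrow(sel)) {
    v <- tracks$value[tracks$family == sel$family[1] &
                        tracks$position == sel$position[1] &
                        tracks$sample %in%
                        tr$conditions$sample[tr$conditions$condition ==
                                               sel$condition[1]]]
    expect_lt(abs(mean(v) - 0.5126), 0.05)
  }
})

test_that("AlkAnilineSeq: saturated stops at theta 1, background at theta 0", {
  cfg <- sim_config(seed = 27, n_families = 1, depth = 5000)
  tr <- simulate_truth(cfg)
  tr$truth$theta[tr$truth$modification == "m7G"] <- 1
  counts <- simulate_aas_counts(tr, cfg)
  g46 <- tr$truth[tr$truth$modification == "m7G", ][1, ]
  at <- counts[counts$family == g46$family & counts$position == g46$position, ]
  expect_true(all(at$starts == cfg$depth))  # p = 1 exactly
  # unplanted U positions: stop ratio near the U background mean
  base <- strsplit(tr$families[[g46$family]]$consensus, "")[[1]]
  planted <- tr$truth$position[tr$truth$family == g46$family]
  upos <- setdiff(which(base == "U"), planted)
  uu <- counts[counts$family == g46$family & counts$position %in% upos, ]
  expect_lt(abs(mean(uu$starts / cfg$depth) - 0.0329), 0.02)
})

test_that("planted m7G is detected above a recomputed threshold", {
  # small Monte-Carlo: theta 0.95, depth 5000, threshold recomputed from the
  # decoy family each replicate
  hits <- vapply(1:10, function(s) {
    cfg <- sim_config(seed = 1000 + s, n_families = 1, depth = 5000,
                      replicates = 1)
    st <- simulate_study(cfg)
    tracks <- compute_score_tracks(st$counts$aas, "aas", st$families)
    noise <- calibrate_noise(tracks, background_family = st$decoy_family)
    g46 <- st$truth[st$truth$modification == "m7G", ][1, ]
    v <- tracks$value[tracks$family == g46$family &
                        tracks$position == g46$position]
    all(v > noise$StopRatio_G$threshold)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("fixture emission is complete and byte-stable under the seed", {
  cfg <- sim_config(seed = 33, n_families = 2, depth = 500, replicates = 1)
  d1 <- tempfile(); d2 <- tempfile()
  st <- emit_fixture(cfg, d1)
  emit_fixture(cfg, d2)
  n_samples <- nrow(st$conditions)
  for (chem in c("rms", "aas", "bs")) {
    expect_length(list.files(d1, pattern = paste0("^", chem, "_")),
                  n_samples)
  }
  expect_true(file.exists(file.path(d1, "conditions.tsv")))
  f1 <- list.files(d1, full.names = TRUE)
  f2 <- list.files(d2, full.names = TRUE)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  # truth rows = planted sites x conditions
  tru <- readr::read_tsv(file.path(d1, "truth.tsv"), show_col_types = FALSE)
  expect_equal(nrow(tru), nrow(unique(tru[, c("family", "label",
                                              "modification")])) * 8)
  # a different seed changes counts but not the schema
  st2 <- emit_fixture(sim_config(seed = 34, n_families = 2, depth = 500,
                                 replicates = 1), tempfile())
  expect_false(identical(st$counts$rms$end5, st2$counts$rms$end5))
  expect_identical(names(st$counts$rms), names(st2$counts$rms))
})
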