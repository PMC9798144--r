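# Synthetic study generator: ground-truth stoichiometries plus
# chemistry-specific count tables with the statistical structure the
# analysis assumes, so every stage is testable without external data.
#
# The default design emulates the study layout: 2 cell lines x
# {tRNA, tsRNA} x {untreated, ANG} = 8 conditions, 3 replicates each,
# with planted tsRNA hypomodification (species effect), cell-line-specific
# and treatment-responsive sites, an unmodified decoy family for noise
# calibration, and a D47 site whose tRNA level decreases under ANG while
# the tsRNA level increases.

.subseed <- function(seed, stream) {
  (as.integer(seed) %% 100000L) * 20011L + as.integer(stream)
}

#' Simulation configuration
#'
#' Defaults state the emulated study conditions: 8 conditions x 3
#' replicates, sequencing depth 1e4 per family and sample, bisulfite
#' non-conversion background mean 0.0252 / SD 0.0677, AlkAnilineSeq
#' per-nucleotide stop backgrounds with means/SDs matching the reported
#' channel calibrations (A 0.0473/0.117, U 0.0329/0.0964; C and G chosen so
#' mean + 3 SD lands near the published 0.263 / 0.418 channel thresholds),
#' a mild log-normal RiboMethSeq positional baseline (sdlog 0.1), full
#' protection efficiency, and effect sizes: species (tRNA vs tsRNA) delta
#' 0.4, cell line 0.15, treatment 0.1.
#'
#' @param n_families number of modified tRNA families (default 8).
#' @param decoy include an unmodified decoy family for noise calibration.
#' @param length consensus length in nt (default 76, canonical).
#' @param depth per-sample per-family sequencing depth (default 10000).
#' @param replicates replicates per condition (default 3).
#' @param bs_background_mean,bs_background_sd bisulfite non-conversion
#'   background (Beta-distributed per position and sample).
#' @param aas_background tibble `nucleotide`, `mean`, `sd`: per-nucleotide
#'   stop-ratio background (Gamma-distributed per position and sample).
#' @param rms_dispersion log-normal sdlog of the RiboMethSeq positional
#'   cleavage baseline.
#' @param protection_efficiency fraction of the cleavage suppressed at a
#'   fully 2'-O-methylated position (eta, default 1).
#' @param cleavage_efficiency AlkAnilineSeq cleavage efficiency at a fully
#'   modified site (s, default 1).
#' @param species_delta,cellline_delta,treatment_delta effect sizes on the
#'   stoichiometry scale.
#' @param planted plant modification sites (`FALSE` gives a null study).
#' @param artifact_mode plant spurious A-channel stop background next to
#'   the anticodon, emulating ligation-bias artifacts of bulky anticodon
#'   modifications.
#' @param seed mandatory random seed; all randomness flows from it through
#'   fixed per-module streams.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_families = 8L, decoy = TRUE, length = 76L,
                       depth = 10000L, replicates = 3L,
                       bs_background_mean = 0.0252,
                       bs_background_sd = 0.0677,
                       aas_background = NULL,
                       rms_dispersion = 0.1,
                       protection_efficiency = 1,
                       cleavage_efficiency = 1,
                       species_delta = 0.4, cellline_delta = 0.15,
                       treatment_delta = 0.1,
                       planted = TRUE, artifact_mode = FALSE, seed) {
  if (missing(seed) || is.null(seed)) {
    stop("a seed is mandatory for reproducibility", call. = FALSE)
  }
  if (is.null(aas_background)) {
    aas_background <- tibble(
      nucleotide = c("A", "C", "G", "U"),
      mean = c(0.0473, 0.020, 0.025, 0.0329),
      sd = c(0.117, 0.081, 0.131, 0.0964))
  }
  stopifnot(n_families >= 1, length == 76L, depth >= 100, replicates >= 1,
            bs_background_mean >= 0, bs_background_mean <= 1,
            protection_efficiency >= 0, protection_efficiency <= 1,
            cleavage_efficiency >= 0, cleavage_efficiency <= 1,
            species_delta >= 0, species_delta <= 1)
  structure(
    list(n_families = as.integer(n_families), decoy = decoy,
         length = as.integer(length), depth = as.integer(depth),
         replicates = as.integer(replicates),
         bs_background_mean = bs_background_mean,
         bs_background_sd = bs_background_sd,
         aas_background = aas_background,
         rms_dispersion = rms_dispersion,
         protection_efficiency = protection_efficiency,
         cleavage_efficiency = cleavage_efficiency,
         species_delta = species_delta, cellline_delta = cellline_delta,
         treatment_delta = treatment_delta,
         planted = planted, artifact_mode = artifact_mode,
         seed = as.integer(seed)),
    class = "sim_config")
}

.FAMILY_POOL <- c("Ala_AGC", "Gly_GCC", "Lys_CTT", "Ser_GCT", "Thr_CGT",
                  "Arg_ACG", "Phe_GAA", "Trp_CCA", "Val_AAC", "Leu_TAA",
                  "Ile_AAT", "Tyr_GTA")

# Planted-site design per family index (recycled past 8). Base stoichiometry
# theta0 and an effect annotation; `documented` routes sites through the
# documented/add-back curation paths.
.plant_design <- function(k) {
  rows <- list()
  add <- function(label, mod, effect, theta0, documented) {
    rows[[length(rows) + 1]] <<- tibble(
      label = label, modification = mod, effect = effect,
      theta0 = theta0, documented = documented)
  }
  j <- ((k - 1L) %% 8L) + 1L
  # m5C
  if (j <= 5) add(if (j %% 2 == 1) "48" else "49", "m5C", "species_effect",
                  0.9, j <= 2)
  if (j %in% 6:7) add("38", "m5C", "stable_high", 0.9, TRUE)
  if (j == 8) add("72", "m5C", "stable_low", 0.15, TRUE)
  # Nm
  if (j <= 4) add(if (j %% 2 == 1) "44" else "54", "Nm", "species_effect",
                  0.9, j <= 2)
  if (j == 5) add("34", "Nm", "stable_high", 0.85, TRUE)
  if (j == 6) add("18", "Nm", "stable_low", 0.2, TRUE)
  if (j == 7) add("39", "Nm", "cellline_effect", 0.75, FALSE)
  if (j == 8) add("54", "Nm", "stable_high", 0.9, TRUE)
  # m7G: constant high stoichiometry everywhere
  add("46", "m7G", "stable_high", 0.95, TRUE)
  # D
  if (j <= 3) add(c("16", "20", "17")[j], "D", "species_effect", 0.85,
                  j == 1)
  if (j == 4) add("47", "D", "treatment_effect", 0.7, FALSE)
  if (j == 5) add("17", "D", "stable_high", 0.9, TRUE)
  if (j == 6) add("20", "D", "stable_low", 0.15, TRUE)
  # m3C
  if (j == 2) add("32", "m3C", "cellline_effect", 0.7, FALSE)
  if (j == 5) add("20", "m3C", "treatment_effect", 0.65, FALSE)
  bind_rows(rows)
}

.REQUIRED_BASE <- c(m5C = "C", m3C = "C", m7G = "G", D = "U", Nm = "")

.condition_grid <- function(replicates) {
  grid <- expand.grid(replicate = seq_len(replicates),
                      treatment = c("untreated", "ANG"),
                      species = c("tRNA", "tsRNA"),
                      cell_line = c("MZ", "SH"),
                      stringsAsFactors = FALSE)
  grid <- grid[, c("cell_line", "species", "treatment", "replicate")]
  grid$sample <- paste(grid$cell_line, grid$species, grid$treatment,
                       paste0("r", grid$replicate), sep = "_")
  condition_map(as_tibble(grid))
}

# theta for one site under one condition
.theta_for <- function(theta0, effect, species, cell_line, treatment, cfg) {
  th <- theta0
  if (effect == "species_effect" && species == "tsRNA") {
    th <- th - cfg$species_delta
  }
  if (effect == "cellline_effect" && cell_line == "SH") {
    th <- th - cfg$cellline_delta
  }
  if (effect == "treatment_effect" && treatment == "ANG") {
    # processing-coupled response: ANG lowers the tRNA level and raises the
    # tsRNA level at responsive sites
    th <- th + if (species == "tRNA") -cfg$treatment_delta else
      cfg$treatment_delta
  }
  min(max(th, 0), 1)
}

#' Simulate ground truth: families, conditions and stoichiometries
#'
#' Deterministic given the seed. Builds the family references (planted
#' positions carry the base their modification type requires), the
#' condition map, and the per-site per-condition truth table. With
#' `planted = FALSE` (null study) the truth table is empty. A decoy family
#' with no modifications is included by default for noise calibration.
#'
#' @param cfg a [sim_config()].
#' @return list with `families` (named list of numbered
#'   [family_reference()]), `conditions` (a [condition_map()]), `truth`
#'   (long tibble: `family`, `label`, `position`, `modification`, `effect`,
#'   `documented`, `theta0`, `condition`, `theta`) and `decoy_family`
#'   (id or `NULL`).
#' @export
simulate_truth <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(.subseed(cfg$seed, 1L))
  fam_ids <- .FAMILY_POOL[((seq_len(cfg$n_families) - 1L) %%
                             length(.FAMILY_POOL)) + 1L]
  fam_ids <- make.unique(fam_ids, sep = "_")
  conditions <- .condition_grid(cfg$replicates)

  design <- if (cfg$planted) {
    bind_rows(lapply(seq_len(cfg$n_families), function(k) {
      .plant_design(k) %>% mutate(family = fam_ids[k], .before = 1)
    }))
  } else {
    tibble(family = character(), label = character(),
           modification = character(), effect = character(),
           theta0 = numeric(), documented = logical())
  }

  families <- list()
  for (k in seq_len(cfg$n_families)) {
    seqv <- sample(c("A", "C", "G", "U"), cfg$length, replace = TRUE)
    fam <- family_reference(fam_ids[k], paste(seqv, collapse = ""),
                            members = paste0(fam_ids[k], "-1"))
    fam <- assign_sprinzl(fam)
    des <- design[design$family == fam_ids[k], , drop = FALSE]
    if (nrow(des)) {
      idx <- sprinzl_index(fam, des$label) + 1L
      req <- .REQUIRED_BASE[des$modification]
      seqv[idx[req != ""]] <- req[req != ""]
      fam$consensus <- paste(seqv, collapse = "")
    }
    families[[fam_ids[k]]] <- fam
  }
  decoy_id <- NULL
  if (cfg$decoy) {
    decoy_id <- "Ctl_unmod"
    seqv <- sample(c("A", "C", "G", "U"), cfg$length, replace = TRUE)
    families[[decoy_id]] <- assign_sprinzl(
      family_reference(decoy_id, paste(seqv, collapse = ""),
                       members = "Ctl_unmod-1"))
  }

  truth <- tibble(family = character(), label = character(),
                  position = integer(), modification = character(),
                  effect = character(), documented = logical(),
                  theta0 = numeric(), condition = character(),
                  theta = numeric())
  if (nrow(design)) {
    conds <- conditions %>%
      distinct(.data$condition, .data$cell_line, .data$species,
               .data$treatment)
    truth <- tidyr::crossing(design, conds) %>%
      mutate(position = as.integer(mapply(
               function(f, l) sprinzl_index(families[[f]], l) + 1L,
               .data$family, .data$label)),
             theta = mapply(.theta_for, .data$theta0, .data$effect,
                            .data$species, .data$cell_line, .data$treatment,
                            MoreArgs = list(cfg = cfg))) %>%
      select("family", "label", "position", "modification", "effect",
             "documented", "theta0", "condition", "theta") %>%
      arrange(.data$family, .data$position, .data$modification,
              .data$condition)
  }
  list(families = families, conditions = conditions, truth = truth,
       decoy_family = decoy_id)
}

# theta vector (length L) for one family, one condition, one set of
# modification types
.theta_vector <- function(truth, family, condition, mods, L) {
  th <- numeric(L)
  sel <- truth[truth$family == family & truth$condition == condition &
                 truth$modification %in% mods, , drop = FALSE]
  th[sel$position] <- sel$theta
  th
}

#' Simulate RiboMethSeq end counts
#'
#' Per family and sample, a log-normal positional cleavage baseline is
#' drawn (independently per sample), and the two observable ends of each
#' internucleotide bond are Poisson counts of that bond's intensity,
#' attenuated by `1 - theta * eta` at 2'-O-methylated positions (the
#' protection model under which MethScore is linear in theta).
#'
#' @param truth a [simulate_truth()] result.
#' @param cfg the same [sim_config()].
#' @return `rms` count tibble (`family`, `sample`, `position`, `end5`,
#'   `end3`, `coverage`) over all samples.
#' @export
simulate_rms_counts <- function(truth, cfg) {
  conds <- truth$conditions
  out <- vector("list", nrow(conds))
  for (i in seq_len(nrow(conds))) {
    set.seed(.subseed(cfg$seed, 100L + i))
    smp <- conds$sample[i]
    per_fam <- lapply(names(truth$families), function(fid) {
      L <- nchar(truth$families[[fid]]$consensus)
      th <- .theta_vector(truth$truth, fid, conds$condition[i], "Nm", L)
      lamb <- rlnorm(L + 1, meanlog = log(cfg$depth / L),
                     sdlog = cfg$rms_dispersion)
      prot <- c(1, 1 - th * cfg$protection_efficiency)  # bonds 0..L
      intens <- lamb * prot
      end3 <- rpois(L, intens[-1])
      end5 <- rpois(L, intens[-(L + 1)])
      tibble(family = fid, sample = smp, position = seq_len(L),
             end5 = end5, end3 = end3,
             coverage = rpois(L, cfg$depth / 10))
    })
    out[[i]] <- bind_rows(per_fam)
  }
  bind_rows(out)
}

#' Simulate AlkAnilineSeq stop counts
#'
#' Per position and sample, a per-nucleotide Gamma background stop
#' probability `b` is drawn; the read-start probability is
#' `theta * s + (1 - theta * s) * b` (background cleavage acts on the
#' molecules not already cleaved at the modified site), and starts are
#' Binomial at the configured depth.
#'
#' @inheritParams simulate_rms_counts
#' @return `aas` count tibble (`family`, `sample`, `position`, `starts`,
#'   `through`).
#' @export
simulate_aas_counts <- function(truth, cfg) {
  conds <- truth$conditions
  bg <- cfg$aas_background
  shape <- (bg$mean / bg$sd)^2
  scale <- bg$sd^2 / bg$mean
  names(shape) <- names(scale) <- bg$nucleotide
  out <- vector("list", nrow(conds))
  for (i in seq_len(nrow(conds))) {
    set.seed(.subseed(cfg$seed, 300L + i))
    smp <- conds$sample[i]
    per_fam <- lapply(names(truth$families), function(fid) {
      fam <- truth$families[[fid]]
      base <- strsplit(fam$consensus, "")[[1]]
      L <- length(base)
      th <- .theta_vector(truth$truth, fid, conds$condition[i],
                          c("m7G", "m3C", "D"), L)
      b <- pmin(rgamma(L, shape = shape[base], scale = scale[base]), 0.95)
      if (cfg$artifact_mode) {
        # ligation-bias artifact: spurious stops at A residues flanking the
        # anticodon (positions 36-38)
        hit <- seq_len(L) %in% 36:38 & base == "A"
        b[hit] <- pmin(b[hit] + 0.5, 0.95)
      }
      ts <- th * cfg$cleavage_efficiency
      p <- ts + (1 - ts) * b
      starts <- rbinom(L, cfg$depth, p)
      tibble(family = fid, sample = smp, position = seq_len(L),
             starts = starts, through = cfg$depth - starts)
    })
    out[[i]] <- bind_rows(per_fam)
  }
  bind_rows(out)
}

#' Simulate bisulfite pileup counts
#'
#' At consensus C positions the unconverted-read probability is
#' `theta + (1 - theta) * bg` with a Beta-distributed per-position,
#' per-sample non-conversion background; C counts are Binomial at the
#' configured depth. U positions read as fully converted (T), purines
#' contribute neither C nor T.
#'
#' @inheritParams simulate_rms_counts
#' @return `bs` count tibble (`family`, `sample`, `position`, `count_c`,
#'   `count_t`, `depth`).
#' @export
simulate_bs_counts <- function(truth, cfg) {
  m <- cfg$bs_background_mean
  v <- cfg$bs_background_sd^2
  stopifnot(v < m * (1 - m))
  kappa <- m * (1 - m) / v - 1
  alpha <- m * kappa; beta <- (1 - m) * kappa
  conds <- truth$conditions
  out <- vector("list", nrow(conds))
  for (i in seq_len(nrow(conds))) {
    set.seed(.subseed(cfg$seed, 500L + i))
    smp <- conds$sample[i]
    per_fam <- lapply(names(truth$families), function(fid) {
      fam <- truth$families[[fid]]
      base <- strsplit(fam$consensus, "")[[1]]
      L <- length(base)
      th <- .theta_vector(truth$truth, fid, conds$condition[i], "m5C", L)
      is_c <- base == "C"
      bgp <- rbeta(L, alpha, beta)
      p <- th + (1 - th) * bgp
      cc <- integer(L); ct <- integer(L)
      cc[is_c] <- rbinom(sum(is_c), cfg$depth, p[is_c])
      ct[is_c] <- cfg$depth - cc[is_c]
      ct[base == "U"] <- cfg$depth
      tibble(family = fid, sample = smp, position = seq_len(L),
             count_c = cc, count_t = ct, depth = cfg$depth)
    })
    out[[i]] <- bind_rows(per_fam)
  }
  bind_rows(out)
}

#' Simulate a complete study in memory
#'
#' @param cfg a [sim_config()].
#' @return list with `truth`, `families`, `conditions`, `decoy_family` and
#'   `counts` (list `rms`, `aas`, `bs`), ready for [run_study()].
#' @export
simulate_study <- function(cfg) {
  tr <- simulate_truth(cfg)
  list(truth = tr$truth, families = tr$families,
       conditions = tr$conditions, decoy_family = tr$decoy_family,
       counts = list(rms = simulate_rms_counts(tr, cfg),
                     aas = simulate_aas_counts(tr, cfg),
                     bs = simulate_bs_counts(tr, cfg)))
}

#' Write a full synthetic study to disk
#'
#' Emits one TSV count file per chemistry and sample (the canonical
#' interchange dialect), plus `conditions.tsv`, `truth.tsv`, the family
#' consensus FASTA and the Sprinzl numbering table. Byte-identical across
#' runs with the same seed.
#'
#' @param cfg a [sim_config()].
#' @param dir output directory (created if needed).
#' @return invisibly, the in-memory study list.
#' @export
emit_fixture <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  st <- simulate_study(cfg)
  for (chem in names(st$counts)) {
    tab <- st$counts[[chem]]
    for (smp in unique(tab$sample)) {
      write_count_tables(tab[tab$sample == smp, , drop = FALSE],
                         file.path(dir, paste0(chem, "_", smp, ".tsv")),
                         chemistry = chem)
    }
  }
  readr::write_tsv(st$conditions, file.path(dir, "conditions.tsv"),
                   progress = FALSE)
  readr::write_tsv(st$truth, file.path(dir, "truth.tsv"), progress = FALSE)
  write_reference(st$families, fasta = file.path(dir, "families.fa"),
                  table = file.path(dir, "numbering.tsv"))
  invisible(st)
}
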