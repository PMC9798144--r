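# Per-position scores of the three chemistries.
#
# RiboMethSeq works on the merged 5'/3' cleavage profile n_i; Scores A, B,
# C (MethScore) and Mean compare n_i with its delta-neighborhood.
# AlkAnilineSeq uses the stop ratio, bisulfite the non-conversion rate.
#
# The published formula block for the RiboMethSeq scores is typographically
# garbled in the source text; the forms implemented here follow the stated
# symbol definitions and the established published score definitions, with
# the absolute-value and +1 guards written out explicitly next to each
# function.

#' Scoring configuration
#'
#' @param delta half-width of the neighborhood window (positions i-delta ..
#'   i-1 and i+1 .. i+delta); default 2, must be in 1..6.
#' @param clip clip Scores A, C and Mean to \[0, 1\] (default `TRUE`).
#'   Stoichiometry interpretation requires \[0,1\]; raw values are kept
#'   alongside in score tracks.
#' @return object of class `score_config`.
#' @details Neighbor weights decrease linearly with distance d from the
#'   position of interest: `w(d) = 1 - 0.1 * (d - 1)`, i.e. 1 at d = 1 down
#'   to 0.5 at d = 6. Only distances up to `delta` are used.
#' @export
score_config <- function(delta = 2L, clip = TRUE) {
  delta <- as.integer(delta)
  stopifnot(delta >= 1, delta <= 6, is.logical(clip))
  w <- 1 - 0.1 * (seq_len(delta) - 1)
  stopifnot(all(w > 0), all(diff(w) <= 0))
  structure(list(delta = delta, clip = clip, weights = w),
            class = "score_config")
}

.clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Merge read-end counts into a cleavage profile
#'
#' The RiboMethSeq signal for position i is the cleavage of the
#' phosphodiester bond 3' of i: the 3'-end count at i and the 5'-end count
#' at i + 1 record the two sides of that same cleavage and are summed by
#' default (`mode = "sum"`). With `mode = "five_prime"` only 5'-end evidence
#' is used and the last position is undefined.
#'
#' @param end5,end3 integer vectors of per-position end counts (equal
#'   length, position-ordered).
#' @param mode `"sum"` or `"five_prime"`.
#' @return numeric cleavage-count vector, same length.
#' @export
cleavage_profile <- function(end5, end3, mode = c("sum", "five_prime")) {
  mode <- match.arg(mode)
  stopifnot(length(end5) == length(end3))
  L <- length(end5)
  shifted5 <- c(end5[-1], 0)
  if (mode == "sum") {
    shifted5 + end3
  } else {
    out <- shifted5
    out[L] <- NA_real_
    out
  }
}

# window accessors; return NULL when the window would leave the profile
.win_left  <- function(n, i, d) if (i - d >= 1) n[(i - d):(i - 1)] else NULL
.win_right <- function(n, i, d) if (i + d <= length(n)) n[(i + 1):(i + d)] else NULL

.wavg <- function(w, x) {
  # x ordered from the window edge towards i for the left window and from i
  # outward for the right window; weights indexed by distance from i
  d <- seq_along(x)
  sum(w[d] * x) / sum(w[d])
}

#' RiboMethSeq Score A
#'
#' `ScoreA(i) = 1 - (2 n_i + 1) / ( |mu_l - sd_l|/2 + n_i + |mu_r - sd_r|/2 + 1 )`
#' where `mu`/`sd` are the mean and (sample) standard deviation of the end
#' counts over the left and right `delta`-windows. High values indicate a
#' local drop in cleavage, i.e. protection by 2'-O-methylation. Positions
#' with fewer than `delta` neighbors on either side are `NA`.
#'
#' @param n cleavage-count vector (see [cleavage_profile()]).
#' @param cfg a [score_config()].
#' @return numeric score vector (clipped to \[0,1\] when `cfg$clip`).
#' @export
#' @examples
#' score_a(c(100, 100, 0, 100, 100))  # ~0.99 at the protected center
score_a <- function(n, cfg = score_config()) {
  d <- cfg$delta
  out <- rep(NA_real_, length(n))
  for (i in seq_along(n)) {
    lw <- .win_left(n, i, d); rw <- .win_right(n, i, d)
    if (is.null(lw) || is.null(rw) || anyNA(lw) || anyNA(rw) || is.na(n[i]))
      next
    den <- 0.5 * abs(mean(lw) - sd(lw)) + n[i] + 0.5 * abs(mean(rw) - sd(rw)) + 1
    out[i] <- 1 - (2 * n[i] + 1) / den
  }
  if (cfg$clip) .clip01(out) else out
}

#' RiboMethSeq Score B
#'
#' `ScoreB(i) = | n_i - (wavg_l + wavg_r)/2 | / (n_i + 1)` with `wavg`
#' the distance-weighted window averages. Reported for completeness; not
#' used for detection, and not clipped (its natural range is unbounded).
#' Whether the published form carries the absolute value is not legible in
#' the source; it is implemented with it.
#'
#' @inheritParams score_a
#' @return numeric score vector.
#' @export
score_b <- function(n, cfg = score_config()) {
  d <- cfg$delta; w <- cfg$weights
  out <- rep(NA_real_, length(n))
  for (i in seq_along(n)) {
    lw <- .win_left(n, i, d); rw <- .win_right(n, i, d)
    if (is.null(lw) || is.null(rw) || anyNA(lw) || anyNA(rw) || is.na(n[i]))
      next
    wl <- .wavg(w, rev(lw))  # rev: order by distance from i
    wr <- .wavg(w, rw)
    out[i] <- abs(n[i] - 0.5 * (wl + wr)) / (n[i] + 1)
  }
  out
}

#' RiboMethSeq Score C (MethScore)
#'
#' `ScoreC(i) = 1 - n_i / ( (wavg_l + wavg_r)/2 )`, clipped to \[0,1\] by
#' default. Linear in modification stoichiometry under the protection
#' model; this is the quantification score for Nm. `NA` when both weighted
#' window averages are zero.
#'
#' @inheritParams score_a
#' @return numeric score vector.
#' @export
#' @examples
#' score_c(c(100, 100, 50, 100, 100))  # 0.5 at the center
score_c <- function(n, cfg = score_config()) {
  d <- cfg$delta; w <- cfg$weights
  out <- rep(NA_real_, length(n))
  for (i in seq_along(n)) {
    lw <- .win_left(n, i, d); rw <- .win_right(n, i, d)
    if (is.null(lw) || is.null(rw) || anyNA(lw) || anyNA(rw) || is.na(n[i]))
      next
    den <- 0.5 * (.wavg(w, rev(lw)) + .wavg(w, rw))
    if (den == 0) next
    out[i] <- 1 - n[i] / den
  }
  if (cfg$clip) .clip01(out) else out
}

#' RiboMethSeq Score Mean
#'
#' Built from the end-count ratios `r_i = n_i / n_(i-1)` and
#' `f_i = n_i / n_(i+1)`:
#' `ScoreMean(i) = ( (1 - r_i / mean(r_j)) + (1 - f_i / mean(f_j)) ) / 2`
#' with the means taken over both `delta`-windows around i. Ratios with a
#' zero denominator are undefined and dropped from the window means; when
#' `r_i` (or `f_i`) itself is undefined its whole term is dropped and the
#' score is the remaining term.
#'
#' @inheritParams score_a
#' @return numeric score vector (clipped when `cfg$clip`).
#' @export
score_mean <- function(n, cfg = score_config()) {
  d <- cfg$delta
  L <- length(n)
  rat <- function(num, den) {
    out <- num / den
    out[!is.finite(out)] <- NA_real_
    out
  }
  r <- rat(n, c(NA_real_, n[-L]))      # r_i = n_i / n_{i-1}
  f <- rat(n, c(n[-1], NA_real_))      # f_i = n_i / n_{i+1}
  out <- rep(NA_real_, L)
  for (i in seq_along(n)) {
    if (i - d < 1 || i + d > L) next
    idx <- c((i - d):(i - 1), (i + 1):(i + d))
    idx <- idx[idx >= 1 & idx <= L]
    terms <- c()
    for (v in list(r, f)) {
      win <- v[idx]
      m <- mean(win, na.rm = TRUE)
      if (!is.na(v[i]) && is.finite(m) && m != 0) {
        terms <- c(terms, 1 - v[i] / m)
      }
    }
    if (length(terms)) out[i] <- mean(terms)
  }
  if (cfg$clip) .clip01(out) else out
}

#' RiboMethSeq Score Angle (pluggable)
#'
#' No public formula exists for the Score Angle used alongside Score A for
#' Nm detection; it is therefore a plugin slot. [angle_scaled_c()] is the
#' package-defined surrogate (1000 x MethScore, matching the published
#' score's order of magnitude and its default threshold of 300); it is NOT
#' the original score.
#'
#' @inheritParams score_a
#' @param plugin function `(n, cfg) -> numeric vector`; supplying `NULL` is
#'   a configuration error.
#' @return numeric score vector from the plugin.
#' @export
score_angle <- function(n, cfg = score_config(), plugin = angle_scaled_c) {
  if (is.null(plugin)) {
    stop("no Score Angle plugin configured; supply a function (n, cfg) -> numeric",
         call. = FALSE)
  }
  stopifnot(is.function(plugin))
  v <- plugin(n, cfg)
  stopifnot(length(v) == length(n))
  v
}

#' @rdname score_angle
#' @export
angle_scaled_c <- function(n, cfg = score_config()) {
  1000 * score_c(n, cfg)
}

#' AlkAnilineSeq stop ratio
#'
#' Fraction of the reads passing through a position whose 5' extremity
#' starts there: `starts / (starts + through)`, in \[0,1\] by construction.
#' `NA` where no read passes.
#'
#' @param starts,through integer vectors of read-start and read-through
#'   counts.
#' @return numeric ratio vector.
#' @export
stop_ratio <- function(starts, through) {
  stopifnot(length(starts) == length(through))
  tot <- starts + through
  out <- ifelse(tot > 0, starts / tot, NA_real_)
  as.numeric(out)
}

#' Bisulfite non-conversion rate
#'
#' `NonConv = C / (C + T)` at a cytidine position: the fraction of reads
#' still carrying a C after bisulfite conversion, directly proportional to
#' m5C stoichiometry. `NA` where C + T = 0.
#'
#' @param count_c,count_t integer vectors of unconverted (C) and converted
#'   (T) read counts.
#' @return numeric rate vector in \[0,1\].
#' @export
nonconv_rate <- function(count_c, count_t) {
  stopifnot(length(count_c) == length(count_t))
  tot <- count_c + count_t
  out <- ifelse(tot > 0, count_c / tot, NA_real_)
  as.numeric(out)
}

#' Compute score tracks for one chemistry
#'
#' Turns a count table into the long score-track table used by detection
#' and quantification: one row per family x position x sample x score type,
#' with the clipped `value`, the unclipped `value_raw` (used for noise
#' calibration), a validity flag and the per-sample coverage.
#'
#' Score types by chemistry: `rms` produces `A`, `B`, `C`, `Mean`, `Angle`;
#' `aas` produces `StopRatio`; `bs` produces `NonConv` at consensus C
#' positions only.
#'
#' @param counts count tibble (see [read_count_tables()] for the dialects).
#' @param chemistry `"rms"`, `"aas"` or `"bs"`.
#' @param families list of numbered [family_reference()] objects; provides
#'   Sprinzl labels and consensus bases.
#' @param cfg a [score_config()].
#' @param angle_plugin Score Angle plugin for `rms` (default
#'   [angle_scaled_c()]).
#' @param end_mode end-merge rule for `rms`, see [cleavage_profile()].
#' @return tibble with columns `family`, `position`, `label`, `base`,
#'   `sample`, `chemistry`, `score_type`, `value`, `value_raw`, `valid`,
#'   `coverage`.
#' @export
compute_score_tracks <- function(counts, chemistry = c("rms", "aas", "bs"),
                                 families, cfg = score_config(),
                                 angle_plugin = angle_scaled_c,
                                 end_mode = "sum") {
  chemistry <- match.arg(chemistry)
  bases <- .family_bases(families)
  counts <- as_tibble(counts) %>%
    arrange(.data$family, .data$sample, .data$position)
  cfg_raw <- cfg; cfg_raw$clip <- FALSE

  one_group <- function(df) {
    fam <- df$family[1]
    L <- nrow(df)
    if (!all(df$position == seq_len(L))) {
      stop("count table for family '", fam, "' does not cover positions 1..",
           L, " contiguously", call. = FALSE)
    }
    if (chemistry == "rms") {
      n <- cleavage_profile(df$end5, df$end3, mode = end_mode)
      raw <- list(A = score_a(n, cfg_raw), B = score_b(n, cfg_raw),
                  C = score_c(n, cfg_raw), Mean = score_mean(n, cfg_raw),
                  Angle = score_angle(n, cfg_raw, angle_plugin))
      clip_types <- c("A", "C", "Mean")
      bind_rows(lapply(names(raw), function(ty) {
        v <- raw[[ty]]
        tibble(family = fam, position = df$position, sample = df$sample,
               chemistry = chemistry, score_type = ty,
               value = if (cfg$clip && ty %in% clip_types) .clip01(v) else v,
               value_raw = v, valid = !is.na(v), coverage = df$coverage)
      }))
    } else if (chemistry == "aas") {
      v <- stop_ratio(df$starts, df$through)
      tibble(family = fam, position = df$position, sample = df$sample,
             chemistry = chemistry, score_type = "StopRatio",
             value = v, value_raw = v, valid = !is.na(v),
             coverage = df$starts + df$through)
    } else {
      v <- nonconv_rate(df$count_c, df$count_t)
      tibble(family = fam, position = df$position, sample = df$sample,
             chemistry = chemistry, score_type = "NonConv",
             value = v, value_raw = v, valid = !is.na(v),
             coverage = df$count_c + df$count_t)
    }
  }

  groups <- split(counts, paste(counts$family, counts$sample, sep = "\r"))
  out <- bind_rows(lapply(groups, one_group))
  out <- left_join(out, bases, by = c("family", "position"))
  if (chemistry == "bs") {
    out <- out %>% filter(.data$base == "C")
  }
  out %>%
    select("family", "position", "label", "base", "sample", "chemistry",
           "score_type", "value", "value_raw", "valid", "coverage")
}
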