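# Independent brute-force re-implementations of every score, written as
# direct transcriptions of the formulas with explicit loops and no shared
# code with the package. Used for two-implementation equivalence tests.

oracle_weight <- function(d) 1 - 0.1 * (d - 1)

oracle_mean <- function(x) sum(x) / length(x)

oracle_sd <- function(x) {
  m <- oracle_mean(x)
  sqrt(sum((x - m)^2) / (length(x) - 1))
}

oracle_wavg <- function(x, dists) {
  w <- oracle_weight(dists)
  sum(w * x) / sum(w)
}

oracle_clip <- function(x) min(max(x, 0), 1)

oracle_score_a <- function(n, delta = 2, clip = TRUE) {
  L <- length(n)
  out <- rep(NA_real_, L)
  for (i in seq_len(L)) {
    if (i - delta < 1 || i + delta > L) next
    left <- n[(i - delta):(i - 1)]
    right <- n[(i + 1):(i + delta)]
    mu_l <- oracle_mean(left); sd_l <- oracle_sd(left)
    mu_r <- oracle_mean(right); sd_r <- oracle_sd(right)
    v <- 1 - (2 * n[i] + 1) /
      (0.5 * abs(mu_l - sd_l) + n[i] + 0.5 * abs(mu_r - sd_r) + 1)
    out[i] <- if (clip) oracle_clip(v) else v
  }
  out
}

oracle_score_b <- function(n, delta = 2) {
  L <- length(n)
  out <- rep(NA_real_, L)
  for (i in seq_len(L)) {
    if (i - delta < 1 || i + delta > L) next
    # left window positions i-delta..i-1 have distances delta..1 from i
    wl <- oracle_wavg(n[(i - delta):(i - 1)], delta:1)
    wr <- oracle_wavg(n[(i + 1):(i + delta)], 1:delta)
    out[i] <- abs(n[i] - 0.5 * (wl + wr)) / (n[i] + 1)
  }
  out
}

oracle_score_c <- function(n, delta = 2, clip = TRUE) {
  L <- length(n)
  out <- rep(NA_real_, L)
  for (i in seq_len(L)) {
    if (i - delta < 1 || i + delta > L) next
    wl <- oracle_wavg(n[(i - delta):(i - 1)], delta:1)
    wr <- oracle_wavg(n[(i + 1):(i + delta)], 1:delta)
    den <- 0.5 * (wl + wr)
    if (den == 0) next
    v <- 1 - n[i] / den
    out[i] <- if (clip) oracle_clip(v) else v
  }
  out
}

oracle_score_mean <- function(n, delta = 2, clip = TRUE) {
  L <- length(n)
  r <- rep(NA_real_, L); f <- rep(NA_real_, L)
  for (i in seq_len(L)) {
    if (i > 1 && n[i - 1] != 0) r[i] <- n[i] / n[i - 1]
    if (i < L && n[i + 1] != 0) f[i] <- n[i] / n[i + 1]
  }
  out <- rep(NA_real_, L)
  for (i in seq_len(L)) {
    if (i - delta < 1 || i + delta > L) next
    win <- c((i - delta):(i - 1), (i + 1):(i + delta))
    terms <- numeric(0)
    rwin <- r[win]; rwin <- rwin[!is.na(rwin)]
    if (!is.na(r[i]) && length(rwin) > 0 && oracle_mean(rwin) != 0) {
      terms <- c(terms, 1 - r[i] / oracle_mean(rwin))
    }
    fwin <- f[win]; fwin <- fwin[!is.na(fwin)]
    if (!is.na(f[i]) && length(fwin) > 0 && oracle_mean(fwin) != 0) {
      terms <- c(terms, 1 - f[i] / oracle_mean(fwin))
    }
    if (length(terms)) {
      v <- oracle_mean(terms)
      out[i] <- if (clip) oracle_clip(v) else v
    }
  }
  out
}

oracle_stop_ratio <- function(starts, through) {
  out <- rep(NA_real_, length(starts))
  for (i in seq_along(starts)) {
    tot <- starts[i] + through[i]
    if (tot > 0) out[i] <- starts[i] / tot
  }
  out
}

oracle_nonconv <- function(cc, ct) {
  out <- rep(NA_real_, length(cc))
  for (i in seq_along(cc)) {
    tot <- cc[i] + ct[i]
    if (tot > 0) out[i] <- cc[i] / tot
  }
  out
}

# brute-force single-linkage closure on a distance matrix: repeatedly merge
# any two clusters holding a pair at distance <= cutoff
oracle_single_linkage <- function(d, cutoff) {
  n <- nrow(d)
  grp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (d[i, j] <= cutoff && grp[i] != grp[j]) {
          grp[grp == grp[j]] <- grp[i]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  grp
}

random_profile <- function(L, values = c(0, 10, 100)) {
  sample(values, L, replace = TRUE)
}
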