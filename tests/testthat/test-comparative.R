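# Stoichiometry matrix, rank tests, categories, clustering, PCA,
# signatures.

make_sm <- function(m, mods = NULL) {
  # wrap a plain matrix as a stoich_matrix for the classification/PCA units
  sites <- tibble::tibble(
    site = rownames(m),
    family = sub("_[^_]+$", "", rownames(m)),
    label = sub("^.*_", "", rownames(m)),
    modification = if (is.null(mods)) "m5C" else mods)
  conds <- tibble::tibble(
    sample = colnames(m), cell_line = "MZ",
    species = rep(c("tRNA", "tsRNA"), length.out = ncol(m)),
    treatment = "untreated", replicate = 1)
  conds$sample <- colnames(m)
  cm <- condition_map(conds)
  cm$condition <- colnames(m)
  structure(list(matrix = m, sites = sites,
                 replicates = tibble::tibble(), conditions = cm),
            class = "stoich_matrix")
}

test_that("matrix entries are replicate medians; permutation-invariant", {
  res <- small_result()
  st <- small_study()
  sm <- res$matrix
  # recompute a handful of medians from the retained replicate values
  reps <- sm$replicates
  for (i in sample(nrow(sm$matrix), 5)) {
    site <- rownames(sm$matrix)[i]
    for (cond in colnames(sm$matrix)[c(1, 4)]) {
      v <- reps$value[reps$site == site & reps$condition == cond]
      if (length(v)) {
        expect_equal(sm$matrix[site, cond], median(v))
        expect_equal(median(sample(v)), median(v))
      }
    }
  }
  expect_true(all(sm$matrix >= 0 & sm$matrix <= 1, na.rm = TRUE))
})

test_that("explicit median examples", {
  expect_equal(median(c(0.2, 0.4, 0.9)), 0.4)
  tracks <- tibble::tibble(
    family = "F", position = 48L, label = "48", base = "C",
    sample = c("s1", "s2", "s3"), chemistry = "bs", score_type = "NonConv",
    value = c(0.2, 0.4, NA), value_raw = c(0.2, 0.4, NA),
    valid = c(TRUE, TRUE, FALSE), coverage = 100)
  catalog <- tibble::tibble(family = "F", position = 48L, label = "48",
                            base = "C", chemistry = "bs",
                            modification = "m5C", median_score = 0.3,
                            frac_above = 1, n_evaluable = 2L,
                            candidate = TRUE, status = "retained_candidate",
                            reason = "r")
  conds <- tibble::tibble(sample = c("s1", "s2", "s3"), cell_line = "MZ",
                          species = "tRNA", treatment = "untreated",
                          replicate = 1:3)
  sm <- build_matrix(tracks, catalog, conds)
  # replicate s3 is missing; the median of the remaining two is used
  expect_equal(unname(sm$matrix["F_48", 1]), median(c(0.2, 0.4)))
  expect_equal(nrow(sm$replicates), 2)
})

test_that("rank-sum test: identity, exact separation tail, empty group", {
  m <- matrix(c(0.9, 0.9, 0.8, 0.85, 0.1, 0.2, 0.15, 0.1), nrow = 1,
              dimnames = list("F_48", paste0("c", 1:8)))
  sm <- make_sm(m)
  sm$conditions$species <- rep(c("tRNA", "tsRNA"), each = 4)
  out <- compare_groups(sm)
  # complete separation at 4 vs 4: two-sided exact p = 2/choose(8,4)
  expect_equal(out$p_value, 2 / choose(8, 4))
  expect_true(out$sig_05); expect_false(out$sig_01)

  m2 <- matrix(rep(c(0.3, 0.5, 0.4, 0.5), 2), nrow = 1,
               dimnames = list("F_48", paste0("c", 1:8)))
  sm2 <- make_sm(m2)
  sm2$conditions$species <- rep(c("tRNA", "tsRNA"), each = 4)
  expect_equal(compare_groups(sm2)$p_value, 1)

  sm3 <- make_sm(m)
  sm3$matrix[1, 5:8] <- NA
  sm3$conditions$species <- rep(c("tRNA", "tsRNA"), each = 4)
  expect_error(compare_groups(sm3), "empty group")
})

test_that("exact rank-sum agrees with wilcox.test when ties are absent", {
  set.seed(41)
  for (i in 1:10) {
    x <- runif(5); y <- runif(6)
    sm <- make_sm(matrix(c(x, y), nrow = 1,
                         dimnames = list("F_48", paste0("c", 1:11))))
    sm$conditions$species <- rep(c("tRNA", "tsRNA"), times = c(5, 6))
    expect_equal(compare_groups(sm)$p_value,
                 wilcox.test(x, y, exact = TRUE)$p.value)
  }
})

test_that("category rule: examples and exact boundaries", {
  m <- rbind(
    high   = rep(0.95, 8),
    low    = rep(0.05, 8),
    var    = rep(c(0.85, 0.35), each = 4),
    bd_i   = c(rep(0.8, 8)),                  # median exactly at 0.8
    bd_iii = c(rep(0.5, 7), 0.75),            # range exactly 0.25
    none   = c(rep(0.5, 7), 0.6))
  colnames(m) <- paste0("c", 1:8)
  cats <- classify_categories(make_sm(m))
  got <- setNames(cats$category, cats$site)
  expect_equal(unname(got["high"]), "i")
  expect_equal(unname(got["low"]), "ii")
  expect_equal(unname(got["var"]), "iii")
  expect_equal(unname(got["bd_i"]), "i")      # >= boundary inclusive
  expect_equal(unname(got["bd_iii"]), "iii")  # >= boundary inclusive
  expect_equal(unname(got["none"]), "unclassified")
  expect_true(all(table(cats$site) == 1))     # mutually exclusive
})

test_that("hierarchical clustering: identical rows, brute-force merges", {
  m <- rbind(a = c(0, 0, 0, 0), b = c(0, 0, 0, 0), c = c(1, 1, 1, 1))
  colnames(m) <- paste0("c", 1:4)
  ch <- cluster_heatmap(m)
  expect_equal(ch$row_hc$height[1], 0)  # identical rows merge at height 0
  # 3 rows: first merge must be the closest pair, last height the complete-
  # linkage maximum
  m2 <- rbind(a = c(0, 0), b = c(3, 0), c = c(10, 0))
  ch2 <- cluster_heatmap(m2)
  d <- as.matrix(dist(m2))
  expect_equal(ch2$row_hc$height[1], min(d[upper.tri(d)]))
  expect_equal(ch2$row_hc$height[2], max(d[upper.tri(d)]))
  # single row: no dendrogram, matrix passes through
  ch1 <- cluster_heatmap(m2[1, , drop = FALSE])
  expect_null(ch1$row_hc)
  expect_equal(nrow(ch1$matrix), 1)
})

test_that("PCA: rank-1 dominance, constant sites, orientation", {
  set.seed(51)
  ind <- rep(c(0, 1), each = 4)  # condition indicator
  m <- t(sapply(1:12, function(i) 0.3 + 0.4 * ind + rnorm(8, sd = 1e-3)))
  rownames(m) <- paste0("F", 1:12, "_48")
  colnames(m) <- paste0("c", 1:8)
  m <- rbind(m, Const_48 = rep(0.5, 8))
  pca <- run_pca(make_sm(m))
  expect_gt(pca$var_explained[1], 0.99)
  expect_true(all(diff(pca$var_explained) <= 1e-12))
  expect_lte(sum(pca$var_explained), 1 + 1e-12)
  # constant site: dropped from the fit, zero loading magnitude
  expect_true("Const_48" %in% pca$dropped)
  expect_equal(unname(abs(pca$loadings["Const_48", ])),
               rep(0, ncol(pca$loadings)))
  # loadings are correlations
  expect_true(all(abs(pca$loadings) <= 1 + 1e-12))
})

test_that("planted species and cell-line effects land on separate PCs", {
  set.seed(57)
  species <- rep(c(0, 1), each = 4)
  cell <- rep(c(0, 1, 0, 1), each = 2)
  n_sites <- 20
  m <- t(sapply(seq_len(n_sites), function(i) {
    base <- 0.5 + rnorm(8, sd = 0.01)
    if (i <= 12) base <- base - 0.35 * species       # 60%: species effect
    else if (i <= 14) base <- base - 0.2 * cell      # 10%: cell-line effect
    base
  }))
  rownames(m) <- paste0("F", seq_len(n_sites), "_48")
  colnames(m) <- paste0("c", 1:8)
  sm <- make_sm(m)
  sm$conditions$species <- ifelse(species == 0, "tRNA", "tsRNA")
  pca <- run_pca(sm)
  # sign-invariant: PC1 separates the species axis
  expect_gt(abs(cor(pca$coords[, 1], species)), 0.95)
  cors <- abs(apply(pca$coords[, 2:4], 2, cor, y = cell))
  expect_gt(max(cors), 0.9)  # a later component carries the cell-line axis
})

test_that("signature extraction respects the strict 0.70 cutoff", {
  loads <- matrix(c(-0.99, 0.69, 0.71, 0.1,
                    0.05, 0.2, 0.71, 0.3),
                  ncol = 2,
                  dimnames = list(c("s1", "s2", "s3", "s4"),
                                  c("PC1", "PC2")))
  fake <- structure(list(loadings = loads,
                         var_explained = c(0.7, 0.3)),
                    class = "mod_pca")
  sig <- extract_signatures(fake, components = 1:2)
  expect_setequal(sig$signatures$PC1, c("s1", "s3"))  # 0.69 excluded
  expect_setequal(sig$signatures$PC2, "s3")           # shared contributor
  expect_equal(sig$overlap["PC1", "PC2"], 1)
})
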