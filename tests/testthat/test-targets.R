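gm_df <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(transcript_id = r[[1]], genotype = r[[2]],
               mean_tsi = as.numeric(r[[3]]),
               n_replicates_defined = 3L, stringsAsFactors = FALSE)))
}

test_that("reference targets use a strict TSI threshold", {
  tab <- fake_tsi_table(gm_df(list("A", "Col0", 5.0),
                              list("B", "Col0", 2.9),
                              list("C", "Col0", 3.0)))
  pars <- target_params("Col0")
  expect_equal(call_reference_targets(tab, pars), "A")

  # all undefined -> empty set with a warning
  und <- fake_tsi_table(gm_df(list("A", "Col0", NA)))
  expect_warning(res <- call_reference_targets(und, pars), "no transcript")
  expect_length(res, 0)

  # degenerate threshold keeps everything positive
  pars0 <- target_params("Col0", tsi_min_reference = 1e-9)
  expect_setequal(call_reference_targets(tab, pars0), c("A", "B", "C"))
})

test_that("mutant targets require a two-fold TSI decrease", {
  tab <- fake_tsi_table(gm_df(
    list("A", "Col0", 6.0), list("A", "xrn4", 2.9),
    list("B", "Col0", 6.0), list("B", "xrn4", 3.1),
    list("C", "Col0", 2.8), list("C", "xrn4", 0.5),
    list("D", "Col0", 6.0), list("D", "xrn4", 0.0),
    list("E", "Col0", 6.0), list("E", "xrn4", NA)))
  pars <- target_params("Col0")
  res <- call_mutant_targets(tab, "xrn4", pars)
  # C fails the reference threshold and is absent entirely
  expect_setequal(res$transcript_id, c("A", "B", "D", "E"))
  expect_true(res$is_target[res$transcript_id == "A"])
  expect_equal(res$fold_change[res$transcript_id == "A"], 6 / 2.9,
               tolerance = 1e-12)
  expect_false(res$is_target[res$transcript_id == "B"])
  expect_equal(res$fold_change[res$transcript_id == "D"], Inf)
  expect_true(res$is_target[res$transcript_id == "D"])
  expect_true(is.na(res$is_target[res$transcript_id == "E"]))
  expect_error(call_mutant_targets(tab, "nope", pars), "unknown genotype")
})

test_that("venn partition is a disjoint cover with consistent counts", {
  v <- venn_partition(c(1, 2, 3), c(2, 3, 4))
  expect_equal(unname(v$counts), c(1L, 1L, 2L))
  expect_equal(venn_partition(letters[1:3], letters[1:3])$counts,
               c(only_a = 0L, only_b = 0L, common = 3L))
  expect_equal(venn_partition(1:3, 4:6)$counts,
               c(only_a = 3L, only_b = 3L, common = 0L))
  # partition identities on random sets
  set.seed(3)
  for (i in 1:20) {
    a <- sample(100, sample(40, 1)); b <- sample(100, sample(40, 1))
    v <- venn_partition(a, b)
    expect_equal(v$counts[["only_a"]] + v$counts[["common"]],
                 length(unique(a)))
    expect_equal(v$counts[["only_b"]] + v$counts[["common"]],
                 length(unique(b)))
  }
})

test_that("paired Wilcoxon handles degenerate and one-sided cases exactly", {
  x <- c(1, 2, 3, 4, 5, 6)
  expect_warning(res <- wilcoxon_shift(x, x), "p undefined")
  expect_true(is.na(res$p_value))

  # 10 pairs, all differences negative: exact two-sided p = 2 / 2^10
  set.seed(1)
  a <- rnorm(10); b <- a + abs(rnorm(10)) + 0.1
  res <- wilcoxon_shift(a, b)
  expect_equal(res$p_value, 2 / 1024)
  expect_equal(res$direction, "lower")
})

test_that("exact signed-rank p matches full sign-permutation enumeration", {
  set.seed(77)
  for (n in c(6, 8, 10)) {
    for (i in 1:5) {
      a <- round(rnorm(n), 2)
      b <- round(rnorm(n), 2)
      d <- a - b
      if (any(d == 0) || any(duplicated(abs(d[d != 0])))) next
      res <- wilcoxon_shift(a, b, paired = TRUE)
      expect_equal(res$p_value, oracle_signed_rank_p(d))
    }
  }
})

test_that("wilcoxon p-values are uniform under the null", {
  set.seed(123)
  p <- replicate(1000, {
    wilcoxon_shift(rnorm(1000), rnorm(1000), paired = FALSE)$p_value
  })
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("hypergeometric overlap matches closed-form and edge cases", {
  # N=10, |A|=5, |B|=4, overlap 4: C(5,4)C(5,0)/C(10,4) = 5/210
  res <- overlap_test(10, 5, 4, 4)
  expect_equal(res$p_value, 5 / 210)
  expect_equal(overlap_test(10, 0, 4, 0)$p_value, 1)
  expect_error(overlap_test(10, 3, 4, 4), "overlap larger")
  expect_error(overlap_test(10, 12, 4, 2), "exceeds universe")

  sets <- hypergeometric_overlap(10, c("a", "b", "c", "d", "e"),
                                 c("a", "b", "c", "d"))
  expect_equal(sets$n_overlap, 4)
  expect_equal(sets$p_value, 5 / 210)
})

test_that("hypergeometric p equals exhaustive enumeration for N <= 12", {
  for (N in c(4, 7, 9, 12)) {
    for (K in 0:N) {
      for (n in c(0, 1, N %/% 2, N)) {
        for (k in 0:min(K, n)) {
          expect_equal(overlap_test(N, K, n, k)$p_value,
                       oracle_hyper_p(N, K, n, k),
                       tolerance = 1e-12,
                       info = sprintf("N=%d K=%d n=%d k=%d", N, K, n, k))
        }
      }
    }
  }
})

test_that("external gene lists intersect with id normalisation", {
  tab <- fake_tsi_table(gm_df(list("AT1G66900.1", "Col0", 5),
                              list("AT2G21350.1", "Col0", 4),
                              list("AT3G01000.2", "Col0", 2)))
  res <- intersect_external_list(tab, c("at1g66900", "AT2G21350.2"),
                                 level = "gene")
  expect_setequal(res$genotype_means$transcript_id,
                  c("AT1G66900.1", "AT2G21350.1"))
  # transcript-level matching keeps the version suffix
  res_t <- intersect_external_list(tab, "AT1G66900.1", level = "transcript")
  expect_equal(res_t$genotype_means$transcript_id, "AT1G66900.1")
  expect_warning(intersect_external_list(tab, "AT9G99999"), "empty")
})

test_that("percentage of called transcripts is unrounded", {
  expect_equal(percent_called(1, 4), 25)
  expect_equal(percent_called(2511, 3011), 100 * 2511 / 3011)
  expect_error(percent_called(5, 4))
})

test_that("sample concordance separates simulated genotype groups", {
  set.seed(21)
  base <- matrix(rpois(300 * 9, 20), nrow = 300)
  base[, 4:6] <- base[, 4:6] + rpois(300 * 3, 15)
  base[1:80, 7:9] <- base[1:80, 7:9] + rpois(80 * 3, 40)
  colnames(base) <- paste0("s", 1:9)
  sc <- sample_concordance(base)
  expect_lte(sum(sc$var_explained), 1)
  xy <- as.matrix(sc$coordinates[, c("pc1", "pc2")])
  dists <- as.matrix(dist(xy))
  grp <- rep(1:3, each = 3)
  within <- dists[outer(grp, grp, "==") & upper.tri(dists)]
  between <- dists[outer(grp, grp, "!=") & upper.tri(dists)]
  expect_lt(mean(within), mean(between))

  # identical samples coincide in the projection
  m2 <- cbind(a = base[, 1], b = base[, 1], c = base[, 2])
  sc2 <- sample_concordance(m2)
  expect_equal(sc2$coordinates$pc1[1], sc2$coordinates$pc1[2])
  expect_equal(sc2$coordinates$pc2[1], sc2$coordinates$pc2[2])
  expect_error(sample_concordance(base[, 1:2]), "at least 3")
})
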