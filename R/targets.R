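#' Parameters for CTRD target calling
#'
#' Transcripts with a replicate-mean TSI strictly above `tsi_min_reference`
#' in the reference genotype are considered under active co-translational
#' decay; among those, a transcript is called a target of a mutated factor
#' when its mean TSI in the mutant is at least `fold_decrease` times lower
#' than in the reference.
#'
#' @param reference_genotype Name of the reference genotype (e.g. `"Col0"`).
#' @param tsi_min_reference Strict lower TSI threshold in the reference.
#' @param fold_decrease Required reference/mutant TSI ratio.
#' @return Object of class `target_params`.
#' @export
target_params <- function(reference_genotype, tsi_min_reference = 3,
                          fold_decrease = 2) {
  stopifnot(tsi_min_reference > 0, fold_decrease >= 1)
  structure(list(reference_genotype = reference_genotype,
                 tsi_min_reference = tsi_min_reference,
                 fold_decrease = fold_decrease),
            class = "target_params")
}

.genotype_means <- function(tsi_tab, genotype) {
  gm <- tsi_tab$genotype_means
  gm <- gm[gm$genotype == genotype, , drop = FALSE]
  setNames(gm$mean_tsi, gm$transcript_id)
}

#' Transcripts under active co-translational decay in the reference
#'
#' @param tsi_tab A [tsi_table()].
#' @param params A [target_params()].
#' @return Character vector of transcript ids whose reference-genotype mean
#'   TSI is strictly greater than `params$tsi_min_reference`. Transcripts
#'   with an undefined reference mean are excluded; an empty result gives a
#'   warning, not an error.
#' @export
call_reference_targets <- function(tsi_tab, params) {
  if (!params$reference_genotype %in% tsi_tab$genotype_means$genotype)
    stop("reference genotype ", params$reference_genotype,
         " absent from TSI table")
  m <- .genotype_means(tsi_tab, params$reference_genotype)
  out <- names(m)[!is.na(m) & m > params$tsi_min_reference]
  if (length(out) == 0)
    warning("no transcript exceeds the reference TSI threshold")
  out
}

#' Call targets of a mutated decay factor
#'
#' Restricted to [call_reference_targets()] output. A transcript is a
#' target when reference_mean / mutant_mean >= `fold_decrease`; a mutant
#' mean of exactly 0 under a positive reference mean is a target with an
#' infinite fold; an undefined mutant mean leaves the call `NA` (flagged).
#'
#' @inheritParams call_reference_targets
#' @param mutant_genotype Genotype to compare against the reference.
#' @return Data.frame with one row per reference-target transcript:
#'   `transcript_id`, `reference_mean_tsi`, `mutant_genotype`,
#'   `mutant_mean_tsi`, `fold_change`, `is_target`.
#' @export
call_mutant_targets <- function(tsi_tab, mutant_genotype, params) {
  if (!mutant_genotype %in% tsi_tab$genotype_means$genotype)
    stop("unknown genotype: ", mutant_genotype)
  ref_ids <- suppressWarnings(call_reference_targets(tsi_tab, params))
  ref <- .genotype_means(tsi_tab, params$reference_genotype)[ref_ids]
  mut <- .genotype_means(tsi_tab, mutant_genotype)[ref_ids]
  fold <- ifelse(is.na(mut), NA_real_,
                 ifelse(mut == 0, Inf, ref / mut))
  data.frame(transcript_id = ref_ids,
             reference_mean_tsi = unname(ref),
             mutant_genotype = mutant_genotype,
             mutant_mean_tsi = unname(mut),
             fold_change = unname(fold),
             is_target = unname(fold >= params$fold_decrease),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Two-set Venn partition
#'
#' @param set_a,set_b Vectors of identifiers.
#' @return List with `counts` (named integer vector `only_a`, `only_b`,
#'   `common`) and the three membership vectors.
#' @export
venn_partition <- function(set_a, set_b) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  common <- intersect(set_a, set_b)
  only_a <- setdiff(set_a, set_b)
  only_b <- setdiff(set_b, set_a)
  list(counts = c(only_a = length(only_a), only_b = length(only_b),
                  common = length(common)),
       only_a = only_a, only_b = only_b, common = common)
}

#' Wilcoxon test for a shift between TSI distributions
#'
#' Paired mode (default) applies the signed-rank test to per-transcript
#' differences, dropping zero differences; unpaired mode applies the
#' rank-sum test. The exact null distribution is used for n <= `exact_max_n`
#' (and no ties); the normal approximation otherwise. Two-sided.
#'
#' @param tsi_ref,tsi_other Numeric vectors; in paired mode, same length
#'   and transcript order. `NA` pairs/values are dropped.
#' @param paired Logical.
#' @param exact_max_n Largest n for the exact null.
#' @return List with `p_value` (`NA` with a warning when fewer than 5
#'   observations remain), `statistic`, `n_used`, `direction` (`"higher"`,
#'   `"lower"` or `"none"`, the position of `tsi_ref` relative to
#'   `tsi_other`) and `method`.
#' @export
wilcoxon_shift <- function(tsi_ref, tsi_other, paired = TRUE,
                           exact_max_n = 25L) {
  if (paired) {
    if (length(tsi_ref) != length(tsi_other))
      stop("paired mode requires equal-length vectors")
    ok <- !is.na(tsi_ref) & !is.na(tsi_other)
    d <- tsi_ref[ok] - tsi_other[ok]
    d <- d[d != 0]
    n <- length(d)
    dir <- if (n == 0) "none"
           else if (median(d) > 0) "higher"
           else if (median(d) < 0) "lower" else "none"
    if (n < 5) {
      warning("fewer than 5 non-zero paired differences; p undefined")
      return(list(p_value = NA_real_, statistic = NA_real_, n_used = n,
                  direction = dir, method = "wilcoxon signed-rank"))
    }
    ht <- suppressWarnings(
      wilcox.test(d, exact = n <= exact_max_n, correct = TRUE))
    list(p_value = ht$p.value, statistic = unname(ht$statistic), n_used = n,
         direction = dir, method = "wilcoxon signed-rank")
  } else {
    x <- tsi_ref[!is.na(tsi_ref)]; y <- tsi_other[!is.na(tsi_other)]
    n <- min(length(x), length(y))
    dir <- if (median(x) > median(y)) "higher"
           else if (median(x) < median(y)) "lower" else "none"
    if (n < 5) {
      warning("fewer than 5 observations in a group; p undefined")
      return(list(p_value = NA_real_, statistic = NA_real_, n_used = n,
                  direction = dir, method = "wilcoxon rank-sum"))
    }
    ht <- suppressWarnings(
      wilcox.test(x, y, exact = max(length(x), length(y)) <= exact_max_n,
                  correct = TRUE))
    list(p_value = ht$p.value, statistic = unname(ht$statistic),
         n_used = length(x) + length(y),
         direction = dir, method = "wilcoxon rank-sum")
  }
}

#' Upper-tail hypergeometric overlap test
#'
#' Probability of observing at least the given overlap between two gene
#' sets drawn from a common universe:
#' p = P(X >= k), X ~ Hypergeometric(N, |A|, |B|).
#'
#' @param n_universe Universe size N.
#' @param set_a,set_b Identifier vectors (subsets of the universe).
#' @return List of class `overlap_result` with `n_universe`, `n_set_a`,
#'   `n_set_b`, `n_overlap`, `p_value`.
#' @export
hypergeometric_overlap <- function(n_universe, set_a, set_b) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  k <- length(intersect(set_a, set_b))
  overlap_test(n_universe, length(set_a), length(set_b), k)
}

#' @rdname hypergeometric_overlap
#' @param n_set_a,n_set_b,n_overlap Set and overlap sizes, when only the
#'   counts are known (e.g. published Venn counts).
#' @export
overlap_test <- function(n_universe, n_set_a, n_set_b, n_overlap) {
  if (n_set_a > n_universe || n_set_b > n_universe)
    stop("set size exceeds universe size")
  if (n_overlap > min(n_set_a, n_set_b))
    stop("overlap larger than the smaller set")
  p <- phyper(n_overlap - 1, n_set_a, n_universe - n_set_a, n_set_b,
              lower.tail = FALSE)
  structure(list(n_universe = n_universe, n_set_a = n_set_a,
                 n_set_b = n_set_b, n_overlap = n_overlap, p_value = p),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(
    "<overlap_result> %d/%d vs %d in universe %d: overlap %d, p = %.3g\n",
    x$n_overlap, x$n_set_a, x$n_set_b, x$n_universe, x$n_overlap,
    x$p_value))
  invisible(x)
}

#' Percentage of analysed transcripts that are called
#'
#' @param n_called,n_analyzed Counts.
#' @return `100 * n_called / n_analyzed` (unrounded).
#' @export
percent_called <- function(n_called, n_analyzed) {
  stopifnot(n_analyzed > 0, n_called >= 0, n_called <= n_analyzed)
  100 * n_called / n_analyzed
}

#' Normalise transcript/gene identifiers
#'
#' Uppercases and, at gene level, strips an isoform version suffix
#' (`AT1G66900.1` -> `AT1G66900`).
#'
#' @param ids Character vector.
#' @param level `"gene"` or `"transcript"`.
#' @return Character vector of normalised identifiers.
#' @export
normalize_ids <- function(ids, level = c("gene", "transcript")) {
  level <- match.arg(level)
  ids <- toupper(trimws(ids))
  if (level == "gene") ids <- sub("\\.\\d+$", "", ids)
  ids
}

#' Restrict a TSI table to an external gene list
#'
#' Keeps only transcripts whose (normalised) identifier appears in an
#' externally supplied list, e.g. an independently determined set of
#' NAD+-capped transcripts.
#'
#' @param tsi_tab A [tsi_table()].
#' @param gene_list Character vector of identifiers, or path to a one-column
#'   text file.
#' @param level Passed to [normalize_ids()].
#' @return The restricted `tsi_table`; empty intersection gives a warning.
#' @export
intersect_external_list <- function(tsi_tab, gene_list,
                                    level = c("gene", "transcript")) {
  level <- match.arg(level)
  if (is.character(gene_list) && length(gene_list) == 1 &&
      file.exists(gene_list))
    gene_list <- readLines(gene_list, warn = FALSE)
  wanted <- normalize_ids(gene_list, level)
  keep_rec <- normalize_ids(tsi_tab$records$transcript_id, level) %in% wanted
  keep_gm <- normalize_ids(tsi_tab$genotype_means$transcript_id,
                           level) %in% wanted
  if (!any(keep_gm)) warning("empty intersection with the external list")
  structure(list(records = tsi_tab$records[keep_rec, , drop = FALSE],
                 genotype_means =
                   tsi_tab$genotype_means[keep_gm, , drop = FALSE],
                 params = tsi_tab$params),
            class = "tsi_table")
}

#' Sample concordance by principal components
#'
#' Projects libraries onto the top two principal axes of the centred,
#' log-scaled count (or TSI) matrix, as a quick replicate-concordance
#' check.
#'
#' @param mat Numeric matrix, features in rows, samples (>= 3) in columns.
#' @param log_transform Apply `log1p` before centring.
#' @return List with `coordinates` (data.frame `sample`, `pc1`, `pc2`) and
#'   `var_explained` (proportion per component, sums to <= 1). A constant
#'   matrix gives degenerate axes with a warning.
#' @export
sample_concordance <- function(mat, log_transform = TRUE) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 3) stop("at least 3 samples required")
  if (log_transform) mat <- log1p(mat)
  mat <- mat[stats::complete.cases(mat), , drop = FALSE]
  if (all(apply(mat, 1, stats::var) == 0))
    warning("constant matrix: principal axes are degenerate")
  pc <- prcomp(t(mat), center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  k <- min(2L, ncol(pc$x))
  coords <- data.frame(sample = colnames(mat),
                       pc1 = pc$x[, 1],
                       pc2 = if (k >= 2) pc$x[, 2] else 0,
                       stringsAsFactors = FALSE, row.names = NULL)
  list(coordinates = coords, var_explained = ve[seq_len(k)])
}
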