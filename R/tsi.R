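#' Parameters for the Terminational Stalling Index
#'
#' The TSI of a transcript in one library is the ratio of the number of
#' 5'P read ends at the ribosome boundary (16-17 nt upstream of the first
#' stop-codon nucleotide, i.e. relative positions -17 and -16) to the mean
#' per-position number of 5'P read ends in the flanking 100 nt. The flank
#' is laid out as `flank_half_width` positions on each side of the
#' boundary, excluding the boundary itself: under the defaults, relative
#' positions -67..-18 and -15..+34. Note the asymmetry of the definition:
#' the boundary is a SUM over its (two) positions while the flank is a
#' per-position MEAN, so positionally uniform data has an expected TSI of
#' 2, not 1; `boundary_stat = "mean"` switches to a mean/mean ratio.
#'
#' @param boundary_offsets Integer offsets of the ribosome boundary
#'   relative to the first stop-codon nucleotide (r = 0).
#' @param flank_half_width Flank positions on each side of the boundary.
#' @param min_flank_positions Minimum number of flank positions that must
#'   lie inside the transcript for a defined record (only reachable below
#'   the full flank when `truncate_flank = TRUE`).
#' @param min_total_reads Minimum total reads on the transcript for a
#'   defined record.
#' @param boundary_stat `"sum"` (default) or `"mean"` over the boundary
#'   positions.
#' @param truncate_flank If `TRUE`, transcripts whose window runs past the
#'   transcript ends are kept and the flank mean is taken over the
#'   available positions; by default such transcripts are excluded so that
#'   every TSI is computed over an identical window.
#' @return Object of class `tsi_params`.
#' @export
tsi_params <- function(boundary_offsets = c(-17L, -16L),
                       flank_half_width = 50L,
                       min_flank_positions = 2L * flank_half_width,
                       min_total_reads = 10L,
                       boundary_stat = c("sum", "mean"),
                       truncate_flank = FALSE) {
  boundary_stat <- match.arg(boundary_stat)
  boundary_offsets <- sort(as.integer(boundary_offsets))
  stopifnot(length(boundary_offsets) >= 1, flank_half_width >= 1)
  p <- structure(list(boundary_offsets = boundary_offsets,
                      flank_half_width = as.integer(flank_half_width),
                      min_flank_positions = as.integer(min_flank_positions),
                      min_total_reads = min_total_reads,
                      boundary_stat = boundary_stat,
                      truncate_flank = truncate_flank),
                 class = "tsi_params")
  if (any(p$boundary_offsets %in% flank_offsets(p)))
    stop("boundary offsets overlap flank positions")
  p
}

#' Flank offsets implied by a `tsi_params`
#'
#' @param params A [tsi_params()].
#' @return Integer vector of relative positions making up the flank.
#' @export
flank_offsets <- function(params) {
  lo <- min(params$boundary_offsets)
  hi <- max(params$boundary_offsets)
  c(seq.int(lo - params$flank_half_width, lo - 1L),
    seq.int(hi + 1L, hi + params$flank_half_width))
}

#' Terminational Stalling Index of one transcript in one library
#'
#' @param counts Integer vector of 5'P end counts along the transcript
#'   (length `model$length_t`).
#' @param model A [transcript_model()].
#' @param params A [tsi_params()].
#' @param library_id Optional library identifier recorded in the result.
#' @return One-row data.frame with columns `transcript_id`, `library_id`,
#'   `n_reads`, `boundary_count`, `flank_mean`, `tsi`, `complete_window`.
#'   `tsi` is `NA` (undefined, not an error) when the flank mean is zero,
#'   when the transcript has fewer than `min_total_reads` reads, when the
#'   window does not fit the transcript (unless truncating), or when the
#'   CDS is out of frame.
#' @export
compute_tsi <- function(counts, model, params = tsi_params(),
                        library_id = NA_character_) {
  stopifnot(length(counts) == model$length_t)
  ss <- model$stop_codon_start_t
  b_idx <- ss + params$boundary_offsets
  f_idx <- ss + flank_offsets(params)
  complete <- all(c(b_idx, f_idx) >= 1L & c(b_idx, f_idx) <= model$length_t)
  n_reads <- sum(counts)
  rec <- data.frame(transcript_id = model$transcript_id,
                    library_id = library_id, n_reads = n_reads,
                    boundary_count = NA_real_, flank_mean = NA_real_,
                    tsi = NA_real_, complete_window = complete,
                    stringsAsFactors = FALSE)
  if (!model$in_frame) {
    warning("transcript ", model$transcript_id,
            " has an out-of-frame CDS; TSI undefined")
    return(rec)
  }
  if (!complete && !params$truncate_flank) return(rec)
  b_use <- b_idx[b_idx >= 1L & b_idx <= model$length_t]
  f_use <- f_idx[f_idx >= 1L & f_idx <= model$length_t]
  if (length(b_use) < length(params$boundary_offsets) ||
      length(f_use) < params$min_flank_positions)
    return(rec)
  bc <- sum(counts[b_use])
  if (params$boundary_stat == "mean") bc <- bc / length(b_use)
  fm <- mean(counts[f_use])
  rec$boundary_count <- bc
  rec$flank_mean <- fm
  if (n_reads >= params$min_total_reads && fm > 0) rec$tsi <- bc / fm
  rec
}

#' TSI table across libraries with per-genotype means
#'
#' Computes one TSI record per (transcript, library) and aggregates the
#' defined values into per-(transcript, genotype) replicate means. A
#' genotype mean is reported only when at least two replicates have a
#' defined TSI.
#'
#' @param libraries Named list (by library id) of `end_counts` objects or
#'   named lists of per-transcript count vectors.
#' @param models Named list of [transcript_model()] objects.
#' @param sample_sheet Data.frame with columns `library_id`, `genotype`,
#'   `organ`, `replicate` covering `names(libraries)`.
#' @param params A [tsi_params()].
#' @return Object of class `tsi_table`: list with `records` (long
#'   data.frame of per-library TSI records with genotype attached),
#'   `genotype_means` (data.frame with `transcript_id`, `genotype`,
#'   `mean_tsi`, `n_replicates_defined`) and `params`.
#' @export
tsi_table <- function(libraries, models, sample_sheet,
                      params = tsi_params()) {
  sample_sheet <- read_sample_sheet(sample_sheet)
  if (!all(names(libraries) %in% sample_sheet$library_id))
    stop("libraries missing from sample sheet: ",
         paste(setdiff(names(libraries), sample_sheet$library_id),
               collapse = ", "))
  geno_of <- setNames(sample_sheet$genotype, sample_sheet$library_id)
  usable <- table(geno_of[names(libraries)])
  empty <- setdiff(unique(sample_sheet$genotype), names(usable))
  if (length(empty) > 0)
    stop("genotype(s) with no usable library: ",
         paste(empty, collapse = ", "))
  recs <- list()
  for (lib in names(libraries)) {
    prof <- libraries[[lib]]
    if (inherits(prof, "end_counts")) prof <- prof$profiles
    ids <- intersect(names(prof), names(models))
    rl <- lapply(ids, function(id)
      suppressWarnings(
        compute_tsi(prof[[id]], models[[id]], params, library_id = lib)))
    recs[[lib]] <- do.call(rbind, rl)
  }
  records <- do.call(rbind, recs)
  rownames(records) <- NULL
  records$genotype <- unname(geno_of[records$library_id])
  agg <- stats::aggregate(
    records$tsi,
    by = list(transcript_id = records$transcript_id,
              genotype = records$genotype),
    FUN = function(v) c(n = sum(!is.na(v)),
                        m = if (sum(!is.na(v)) >= 2) mean(v, na.rm = TRUE)
                            else NA_real_))
  genotype_means <- data.frame(
    transcript_id = agg$transcript_id, genotype = agg$genotype,
    mean_tsi = agg$x[, "m"],
    n_replicates_defined = as.integer(agg$x[, "n"]),
    stringsAsFactors = FALSE)
  structure(list(records = records, genotype_means = genotype_means,
                 params = params),
            class = "tsi_table")
}

#' @export
print.tsi_table <- function(x, ...) {
  cat(sprintf(
    "<tsi_table> %d records (%d transcripts x %d libraries), genotypes: %s\n",
    nrow(x$records), length(unique(x$records$transcript_id)),
    length(unique(x$records$library_id)),
    paste(unique(x$records$genotype), collapse = ", ")))
  invisible(x)
}
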