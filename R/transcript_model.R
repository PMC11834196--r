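#' Transcript model
#'
#' A light container describing one mRNA: its exon structure on the genome
#' and the location of the CDS and stop codon in transcript coordinates.
#' All coordinates are 1-based and closed (the R/Bioconductor convention);
#' transcript position 1 is the 5'-most nucleotide of the mature transcript
#' on its own strand.
#'
#' @param transcript_id,gene_id Identifiers.
#' @param chrom Chromosome / sequence name.
#' @param strand `"+"` or `"-"`.
#' @param exons `data.frame` with columns `start`, `end` (1-based, closed),
#'   sorted by genomic position, non-overlapping.
#' @param cds_start_t Transcript coordinate of the first CDS nucleotide.
#' @param stop_codon_start_t Transcript coordinate of the first nucleotide
#'   of the stop codon.
#'
#' @return An object of class `transcript_model` with fields
#'   `transcript_id`, `gene_id`, `chrom`, `strand`, `exons`, `cds_start_t`,
#'   `stop_codon_start_t`, `length_t` and `in_frame` (`FALSE` when the
#'   distance from CDS start to stop codon is not a multiple of 3; such
#'   transcripts are excluded from TSI computation with a warning).
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand, exons,
                             cds_start_t, stop_codon_start_t) {
  stopifnot(strand %in% c("+", "-"), is.data.frame(exons),
            all(c("start", "end") %in% names(exons)))
  exons <- exons[order(exons$start), c("start", "end"), drop = FALSE]
  rownames(exons) <- NULL
  if (any(exons$end < exons$start))
    stop("exon with end < start in ", transcript_id)
  if (nrow(exons) > 1 &&
      any(exons$start[-1] <= exons$end[-nrow(exons)]))
    stop("overlapping exons in ", transcript_id)
  length_t <- sum(exons$end - exons$start + 1L)
  if (!(cds_start_t >= 1 && cds_start_t < stop_codon_start_t &&
        stop_codon_start_t <= length_t - 2L))
    stop("CDS/stop codon coordinates outside transcript in ", transcript_id)
  in_frame <- (stop_codon_start_t - cds_start_t) %% 3L == 0L
  structure(
    list(transcript_id = transcript_id, gene_id = gene_id, chrom = chrom,
         strand = strand, exons = exons,
         cds_start_t = as.integer(cds_start_t),
         stop_codon_start_t = as.integer(stop_codon_start_t),
         length_t = as.integer(length_t), in_frame = in_frame),
    class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf(
    "<transcript_model> %s (%s) %s:%s strand %s | %d nt, %d exon(s), CDS %d..%d (stop at %d)\n",
    x$transcript_id, x$gene_id, x$chrom,
    paste0(min(x$exons$start), "-", max(x$exons$end)), x$strand,
    x$length_t, nrow(x$exons), x$cds_start_t, x$stop_codon_start_t + 2L,
    x$stop_codon_start_t))
  invisible(x)
}

# exon indices in transcript (5'->3') order
.exon_order <- function(model) {
  n <- nrow(model$exons)
  if (model$strand == "+") seq_len(n) else rev(seq_len(n))
}

# cumulative transcript length preceding each exon, in transcript order
.exon_offsets <- function(model) {
  ex <- model$exons[.exon_order(model), , drop = FALSE]
  w <- ex$end - ex$start + 1L
  list(exons = ex, offsets = cumsum(c(0L, w))[seq_len(nrow(ex))])
}

#' Map genomic positions to transcript coordinates
#'
#' @param model A [transcript_model()].
#' @param pos Integer vector of genomic positions (1-based).
#' @return Integer vector of transcript coordinates; `NA` for positions not
#'   covered by an exon.
#' @export
genomic_to_tx <- function(model, pos) {
  eo <- .exon_offsets(model)
  out <- rep(NA_integer_, length(pos))
  for (i in seq_len(nrow(eo$exons))) {
    s <- eo$exons$start[i]; e <- eo$exons$end[i]
    hit <- !is.na(pos) & pos >= s & pos <= e
    out[hit] <- eo$offsets[i] +
      (if (model$strand == "+") pos[hit] - s else e - pos[hit]) + 1L
  }
  out
}

#' Map transcript coordinates to genomic positions
#'
#' @inheritParams genomic_to_tx
#' @param tpos Integer vector of transcript coordinates (1-based).
#' @return Integer vector of genomic positions; `NA` when out of range.
#' @export
tx_to_genomic <- function(model, tpos) {
  eo <- .exon_offsets(model)
  w <- eo$exons$end - eo$exons$start + 1L
  out <- rep(NA_integer_, length(tpos))
  for (i in seq_len(nrow(eo$exons))) {
    rel <- tpos - eo$offsets[i]
    hit <- !is.na(tpos) & rel >= 1L & rel <= w[i]
    out[hit] <- if (model$strand == "+") eo$exons$start[i] + rel[hit] - 1L
                else eo$exons$end[i] - rel[hit] + 1L
  }
  out
}

# genomic intervals (1-based closed, genomic order) covering transcript
# positions t1..t2
.tx_range_to_genomic <- function(model, t1, t2) {
  stopifnot(t1 <= t2, t1 >= 1, t2 <= model$length_t)
  eo <- .exon_offsets(model)
  w <- eo$exons$end - eo$exons$start + 1L
  out <- list()
  for (i in seq_len(nrow(eo$exons))) {
    a <- max(t1, eo$offsets[i] + 1L)
    b <- min(t2, eo$offsets[i] + w[i])
    if (a > b) next
    g <- sort(tx_to_genomic(model, c(a, b)))
    out[[length(out) + 1L]] <- data.frame(start = g[1], end = g[2])
  }
  res <- do.call(rbind, out)
  res[order(res$start), , drop = FALSE]
}
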