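#' Parse a GFF3 annotation into transcript models
#'
#' Reads mRNA/exon/CDS features (linked through `Parent` attributes) and
#' builds one [transcript_model()] per mRNA that carries at least one CDS
#' feature. Transcript coordinates are obtained by concatenating exons
#' 5'->3' on the transcript strand. Two annotation dialects are handled:
#' when an explicit `stop_codon` feature is present it defines the stop
#' codon; otherwise the last three nucleotides of the concatenated CDS are
#' taken as the stop codon (Araport/TAIR-style CDS-includes-stop).
#'
#' @param path Path to a GFF3 file.
#' @return Named list of [transcript_model()] objects (names are
#'   transcript ids). mRNAs without CDS are skipped with a warning, as are
#'   CDS features whose `Parent` mRNA is missing.
#' @export
parse_gff <- function(path) {
  raw <- readLines(path, warn = FALSE)
  body <- which(!grepl("^#", raw) & nzchar(raw))
  nf <- lengths(strsplit(raw[body], "\t", fixed = TRUE))
  if (any(nf < 9))
    stop("malformed GFF3 at line ", body[which(nf < 9)[1]], " of ", path,
         ": fewer than 9 tab-separated fields")
  gr <- rtracklayer::import(path, format = "gff3")
  typ <- as.character(gr$type)
  mrna <- gr[typ %in% c("mRNA", "transcript")]
  if (length(mrna) == 0) stop("no mRNA/transcript features in ", path)
  mrna_id <- as.character(mrna$ID)

  parent1 <- function(x) {
    p <- x$Parent
    if (is.null(p)) return(rep(NA_character_, length(x)))
    vapply(as.list(p), function(v) if (length(v)) v[[1]] else NA_character_,
           character(1))
  }
  kids <- gr[typ %in% c("exon", "CDS", "stop_codon")]
  kid_parent <- parent1(kids)
  kid_type <- as.character(kids$type)
  orphan_cds <- kid_type == "CDS" & !(kid_parent %in% mrna_id)
  if (any(orphan_cds))
    warning(sum(orphan_cds), " CDS feature(s) without a parent mRNA skipped")

  models <- list()
  for (k in seq_along(mrna)) {
    id <- mrna_id[k]
    mine <- kids[!is.na(kid_parent) & kid_parent == id]
    mtyp <- as.character(mine$type)
    cds <- mine[mtyp == "CDS"]
    if (length(cds) == 0) {
      warning("mRNA ", id, " has no CDS feature; skipped")
      next
    }
    ex <- mine[mtyp == "exon"]
    exdf <- if (length(ex) > 0)
      data.frame(start = GenomicRanges::start(ex),
                 end = GenomicRanges::end(ex))
    else
      data.frame(start = GenomicRanges::start(mrna[k]),
                 end = GenomicRanges::end(mrna[k]))
    strand <- as.character(GenomicRanges::strand(mrna[k]))
    gene <- parent1(mrna[k])
    if (is.na(gene)) gene <- id
    # provisional model to reuse the coordinate map; stop location fixed below
    m <- transcript_model(
      transcript_id = id, gene_id = gene,
      chrom = as.character(GenomicRanges::seqnames(mrna[k])),
      strand = strand, exons = exdf,
      cds_start_t = 1L, stop_codon_start_t = 4L)
    cds_first_g <- if (strand == "+") min(GenomicRanges::start(cds))
                   else max(GenomicRanges::end(cds))
    cds_last_g <- if (strand == "+") max(GenomicRanges::end(cds))
                  else min(GenomicRanges::start(cds))
    cds_start_t <- genomic_to_tx(m, cds_first_g)
    cds_end_t <- genomic_to_tx(m, cds_last_g)
    if (is.na(cds_start_t) || is.na(cds_end_t)) {
      warning("CDS of ", id, " falls outside its exons; skipped")
      next
    }
    stopf <- mine[mtyp == "stop_codon"]
    stop_start_t <- if (length(stopf) > 0) {
      g <- if (strand == "+") min(GenomicRanges::start(stopf))
           else max(GenomicRanges::end(stopf))
      genomic_to_tx(m, g)
    } else cds_end_t - 2L
    models[[id]] <- transcript_model(
      transcript_id = id, gene_id = gene, chrom = m$chrom, strand = strand,
      exons = exdf, cds_start_t = cds_start_t,
      stop_codon_start_t = stop_start_t)
    if (!models[[id]]$in_frame)
      warning("CDS of ", id, " is not a multiple of 3; ",
              "transcript flagged and excluded from TSI")
  }
  models
}

#' Count read 5' ends along transcripts
#'
#' Assigns the biological 5' end of each aligned read to transcript
#' coordinates. For a `+` strand alignment the 5' end is the leftmost
#' aligned base; for a `-` strand alignment the rightmost. An end is
#' assigned to every transcript whose strand matches the read strand and
#' whose exons contain the base (overlapping isoforms are each
#' incremented); reads matching no transcript are tallied as discarded.
#'
#' @param path Path to a BED6 file (one record per read) or a
#'   coordinate-sorted, indexed BAM file.
#' @param models Named list of [transcript_model()] objects.
#' @param library_id Library identifier attached to the result.
#' @param format `"auto"` (by file extension), `"bed"` or `"bam"`.
#' @return An object of class `end_counts`: a list with `profiles` (named
#'   list of integer count vectors, one per transcript, length equal to the
#'   transcript length), `library_id`, `n_assigned` and `n_discarded`
#'   (reads; `n_assigned + n_discarded` equals the number of input reads).
#' @export
load_5p_ends <- function(path, models, library_id,
                         format = c("auto", "bed", "bam")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.bam$", path, ignore.case = TRUE)) "bam" else "bed"
  reads <- if (format == "bed") {
    rtracklayer::import(path, format = "BED")
  } else {
    if (!file.exists(paste0(path, ".bai")) &&
        !file.exists(sub("\\.bam$", ".bai", path)))
      stop("BAM file ", path, " is not indexed; run samtools index first")
    GenomicRanges::granges(GenomicAlignments::readGAlignments(path))
  }
  five_p <- GenomicRanges::resize(reads, width = 1L, fix = "start")
  count_5p_ends(five_p, models, library_id)
}

#' @rdname load_5p_ends
#' @param ends A `GRanges` of 1-nt read 5' ends (stranded).
#' @export
count_5p_ends <- function(ends, models, library_id) {
  exgr <- .exon_granges(models)
  ov <- GenomicRanges::findOverlaps(ends, exgr, ignore.strand = FALSE)
  q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
  pos <- GenomicRanges::start(ends)[q]
  tx <- exgr$tx[s]
  tpos <- exgr$offset[s] + ifelse(exgr$fwd[s],
                                  pos - GenomicRanges::start(exgr)[s],
                                  GenomicRanges::end(exgr)[s] - pos) + 1L
  profiles <- lapply(models, function(m) integer(m$length_t))
  if (length(tpos) > 0) {
    key <- split(tpos, tx)
    for (id in names(key)) {
      tab <- tabulate(key[[id]], nbins = models[[id]]$length_t)
      profiles[[id]] <- profiles[[id]] + as.integer(tab)
    }
  }
  n_assigned <- length(unique(q))
  structure(list(profiles = profiles, library_id = library_id,
                 n_assigned = n_assigned,
                 n_discarded = length(ends) - n_assigned),
            class = "end_counts")
}

# one GRanges row per exon, annotated with transcript id, strand direction
# and the transcript length preceding the exon
.exon_granges <- function(models) {
  rows <- lapply(models, function(m) {
    eo <- .exon_offsets(m)
    data.frame(chrom = m$chrom, start = eo$exons$start, end = eo$exons$end,
               strand = m$strand, tx = m$transcript_id,
               offset = eo$offsets, fwd = m$strand == "+")
  })
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = df$strand)
  gr$tx <- df$tx; gr$offset <- df$offset; gr$fwd <- df$fwd
  gr
}

#' Export per-read 5' ends as BED6
#'
#' Writes one 1-nt BED record per counted read at the genomic position of
#' its 5' end, on the transcript strand. `load_5p_ends()` on the result
#' reproduces the profiles (up to reads shared by overlapping isoforms).
#'
#' @param counts An `end_counts` object or named list of count vectors.
#' @param models Named list of [transcript_model()] objects.
#' @param path Output BED path.
#' @export
export_bed <- function(counts, models, path) {
  profiles <- if (inherits(counts, "end_counts")) counts$profiles else counts
  lib <- if (inherits(counts, "end_counts")) counts$library_id else "lib"
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(profiles)) {
    m <- models[[id]]
    cnt <- profiles[[id]]
    nz <- which(cnt > 0)
    if (length(nz) == 0) next
    g <- tx_to_genomic(m, nz)
    g <- rep(g, cnt[nz])
    writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s",
                       m$chrom, g - 1L, g, lib, m$strand), con)
  }
  invisible(path)
}

#' Export count profiles as bedGraph
#'
#' @inheritParams export_bed
#' @export
export_bedgraph <- function(counts, models, path) {
  profiles <- if (inherits(counts, "end_counts")) counts$profiles else counts
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(profiles)) {
    m <- models[[id]]
    cnt <- profiles[[id]]
    nz <- which(cnt > 0)
    if (length(nz) == 0) next
    g <- tx_to_genomic(m, nz)
    writeLines(sprintf("%s\t%d\t%d\t%d", m$chrom, g - 1L, g, cnt[nz]), con)
  }
  invisible(path)
}

#' Read and write the pipeline's tab-separated tables
#'
#' Plain TSV with a header row; `read_pipeline_table(write_pipeline_table(x))`
#' returns `x`.
#'
#' @param x A data.frame.
#' @param path File path.
#' @param required_cols Columns that must be present on read; a missing one
#'   raises a schema error. Extra columns are preserved with a warning.
#' @return `read_pipeline_table` returns a data.frame.
#' @export
write_pipeline_table <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pipeline_table
#' @export
read_pipeline_table <- function(path, required_cols = NULL) {
  x <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                  check.names = FALSE)
  if (!is.null(required_cols)) {
    miss <- setdiff(required_cols, names(x))
    if (length(miss) > 0)
      stop("table ", path, " is missing required column(s): ",
           paste(miss, collapse = ", "))
    extra <- setdiff(names(x), required_cols)
    if (length(extra) > 0)
      warning("table ", path, " has extra column(s) preserved: ",
              paste(extra, collapse = ", "))
  }
  x
}

#' Validate a sample sheet
#'
#' @param x Data.frame (or TSV path) with columns `library_id`, `genotype`,
#'   `organ`, `replicate` and optionally `path`.
#' @param reference_genotype If given, at least one library of this
#'   genotype must be present.
#' @return The validated data.frame.
#' @export
read_sample_sheet <- function(x, reference_genotype = NULL) {
  if (is.character(x) && length(x) == 1)
    x <- read_pipeline_table(x)
  need <- c("library_id", "genotype", "organ", "replicate")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0)
    stop("sample sheet missing column(s): ", paste(miss, collapse = ", "))
  key <- paste(x$genotype, x$organ, x$replicate)
  if (anyDuplicated(key))
    stop("duplicate (genotype, organ, replicate) combination in sample sheet")
  if (anyDuplicated(x$library_id))
    stop("duplicate library_id in sample sheet")
  if (!is.null(reference_genotype) &&
      !reference_genotype %in% x$genotype)
    stop("no library of reference genotype ", reference_genotype,
         " in sample sheet")
  x
}
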