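write_gff <- function(lines, path = tempfile(fileext = ".gff3")) {
  writeLines(c("##gff-version 3", lines), path)
  path
}

test_that("parse_gff locates the stop codon in both annotation dialects", {
  # plus strand with an explicit stop_codon feature (CDS excludes the stop)
  # and minus strand with CDS-includes-stop
  path <- write_gff(c(
    "chr1\tsrc\tgene\t101\t400\t.\t+\t.\tID=G1",
    "chr1\tsrc\tmRNA\t101\t400\t.\t+\t.\tID=T1;Parent=G1",
    "chr1\tsrc\texon\t101\t400\t.\t+\t.\tParent=T1",
    "chr1\tsrc\tCDS\t131\t367\t.\t+\t0\tParent=T1",
    "chr1\tsrc\tstop_codon\t368\t370\t.\t+\t0\tParent=T1",
    "chr1\tsrc\tgene\t1101\t1400\t.\t-\t.\tID=G2",
    "chr1\tsrc\tmRNA\t1101\t1400\t.\t-\t.\tID=T2;Parent=G2",
    "chr1\tsrc\texon\t1101\t1400\t.\t-\t.\tParent=T2",
    "chr1\tsrc\tCDS\t1131\t1370\t.\t-\t0\tParent=T2"))
  models <- parse_gff(path)
  expect_named(models, c("T1", "T2"))
  t1 <- models$T1
  expect_equal(t1$length_t, 300L)
  expect_equal(t1$cds_start_t, 31L)
  expect_equal(t1$stop_codon_start_t, 268L)
  expect_equal(t1$gene_id, "G1")
  expect_true(t1$in_frame)
  # minus strand: transcript position 1 is genomic 1400; the CDS 5' end is
  # genomic 1370 and the stop codon starts 2 nt before the CDS 3' end
  t2 <- models$T2
  expect_equal(t2$strand, "-")
  expect_equal(t2$cds_start_t, 31L)
  expect_equal(t2$stop_codon_start_t, 268L)
})

test_that("parse_gff skips mRNAs without CDS and reports malformed lines", {
  path <- write_gff(c(
    "chr1\tsrc\tmRNA\t101\t400\t.\t+\t.\tID=T1",
    "chr1\tsrc\texon\t101\t400\t.\t+\t.\tParent=T1"))
  expect_warning(models <- parse_gff(path), "no CDS")
  expect_length(models, 0)

  bad <- write_gff(c(
    "chr1\tsrc\tmRNA\t101\t400\t.\t+\t.\tID=T1",
    "chr1\tsrc\texon\t101\t400"))
  expect_error(parse_gff(bad), "line 3")
})

test_that("out-of-frame CDS is flagged and excluded from TSI", {
  path <- write_gff(c(
    "chr1\tsrc\tmRNA\t101\t400\t.\t+\t.\tID=T1",
    "chr1\tsrc\texon\t101\t400\t.\t+\t.\tParent=T1",
    "chr1\tsrc\tCDS\t131\t369\t.\t+\t0\tParent=T1"))
  expect_warning(models <- parse_gff(path), "multiple of 3")
  expect_false(models$T1$in_frame)
  expect_warning(compute_tsi(uniform_profile(models$T1), models$T1),
                 "out-of-frame")
  rec <- suppressWarnings(compute_tsi(uniform_profile(models$T1),
                                      models$T1))
  expect_true(is.na(rec$tsi))
})

test_that("coordinate maps agree with a brute-force per-base lookup", {
  for (m in spliced_models()) {
    tab <- oracle_coord_table(m)
    expect_equal(genomic_to_tx(m, tab$gpos), tab$tpos)
    expect_equal(tx_to_genomic(m, tab$tpos), tab$gpos)
    # intronic and flanking bases do not map
    inside <- unlist(Map(`:`, m$exons$start, m$exons$end))
    outside <- setdiff(min(inside):max(inside), inside)
    if (length(outside) > 0)
      expect_true(all(is.na(genomic_to_tx(m, outside))))
  }
})

test_that("read 5' ends follow the strand convention and discard tally", {
  models <- list(TXP = make_plus_model(), TXM = make_minus_model())
  bed <- tempfile(fileext = ".bed")
  writeLines(c(
    "chr1\t250\t300\tr1\t0\t+",   # + read: 5' end = leftmost base
    "chr1\t250\t300\tr2\t0\t-",   # - read: 5' end = rightmost base
    "chr1\t50\t60\tr3\t0\t+"),    # outside both transcripts
    bed)
  ec <- load_5p_ends(bed, models, "lib1")
  # + read 5' end at genomic 251 -> transcript position 151 on TXP
  expect_equal(which(ec$profiles$TXP > 0), 151L)
  expect_equal(ec$profiles$TXP[151], 1L)
  # - read 5' end at genomic 300 -> transcript position 500-300+1 = 201
  expect_equal(which(ec$profiles$TXM > 0), 201L)
  expect_equal(ec$n_assigned, 2L)
  expect_equal(ec$n_discarded, 1L)
})

test_that("counts are conserved and BED export round-trips", {
  set.seed(42)
  models <- list(TXP = make_plus_model(), TXM = make_minus_model(),
                 B = spliced_models()$B)
  profiles <- lapply(models, random_profile, lambda = 0.5)
  bed <- tempfile(fileext = ".bed")
  export_bed(profiles, models, bed)
  ec <- load_5p_ends(bed, models, "rt")
  expect_equal(ec$profiles, profiles)
  total_reads <- length(readLines(bed))
  expect_equal(ec$n_assigned + ec$n_discarded, total_reads)
})

test_that("reverse-complementing the genome leaves profiles unchanged", {
  set.seed(7)
  G <- 2000L  # reflect positions around a genome of length G
  models <- list(TXP = make_plus_model(), B = spliced_models()$B)
  profiles <- lapply(models, random_profile, lambda = 0.3)
  bed <- tempfile(fileext = ".bed")
  export_bed(profiles, models, bed)
  # mirror every model and every read
  flip_strand <- function(s) if (s == "+") "-" else "+"
  mirrored <- lapply(models, function(m) transcript_model(
    m$transcript_id, m$gene_id, m$chrom, flip_strand(m$strand),
    data.frame(start = G - m$exons$end + 1L, end = G - m$exons$start + 1L),
    m$cds_start_t, m$stop_codon_start_t))
  bed_df <- read.delim(bed, header = FALSE)
  mirrored_bed <- tempfile(fileext = ".bed")
  writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s",
                     bed_df$V1, G - bed_df$V3, G - bed_df$V2, bed_df$V4,
                     ifelse(bed_df$V6 == "+", "-", "+")),
             mirrored_bed)
  ec1 <- load_5p_ends(bed, models, "fwd")
  ec2 <- load_5p_ends(mirrored_bed, mirrored, "rev")
  expect_equal(ec2$profiles, ec1$profiles)
})

test_that("pipeline tables round-trip through TSV", {
  x <- data.frame(transcript_id = c("AT1G01010.1", "AT1G01020.1"),
                  library_id = "L1", boundary_count = c(12, 0),
                  flank_mean = c(1.5, 0.25), tsi = c(8, 0),
                  stringsAsFactors = FALSE)
  p <- tempfile(fileext = ".tsv")
  write_pipeline_table(x, p)
  expect_equal(read_pipeline_table(p), x)

  empty <- x[0, ]
  write_pipeline_table(empty, p)
  expect_equal(length(readLines(p)), 1L)  # header only
  expect_equal(names(read_pipeline_table(p)), names(x))

  expect_error(read_pipeline_table(p, required_cols = "nope"),
               "missing required")
  x$extra <- 1:2
  write_pipeline_table(x, p)
  expect_warning(y <- read_pipeline_table(p, required_cols = names(x)[1:5]),
                 "extra column")
  expect_true("extra" %in% names(y))
})

test_that("sample sheets are validated", {
  sheet <- data.frame(library_id = c("a", "b"), genotype = "Col0",
                      organ = "shoot", replicate = 1:2)
  expect_silent(read_sample_sheet(sheet, reference_genotype = "Col0"))
  expect_error(read_sample_sheet(sheet, reference_genotype = "xrn4"),
               "reference genotype")
  sheet$replicate <- c(1, 1)
  expect_error(read_sample_sheet(sheet), "duplicate")
})
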