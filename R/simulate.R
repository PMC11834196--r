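#' Configuration for the synthetic degradome generator
#'
#' The generator draws a transcriptome and, per genotype and replicate,
#' 5'P end-count libraries whose positional structure mimics
#' co-translational decay: a fraction `ctrd_fraction` of a transcript's 5'P
#' ends comes from the ribosome-tracked component, which is concentrated on
#' the codon-frame lattice of the CDS (weight `frame_bias`) and carries an
#' extra termination-stall mass at the ribosome-boundary positions -17/-16
#' relative to the stop codon; the remaining ends are positionally uniform.
#' `stall_weight` is the dwell of the terminating ribosome expressed in
#' units of one average elongation step: each boundary position receives
#' `stall_weight` times the weight of a single codon-lattice position.
#' Replicate noise is negative-binomial on transcript read totals with
#' multinomial positions.
#'
#' @param n_transcripts Number of transcripts.
#' @param cds_length_range Range (nt) of CDS lengths (stop codon included);
#'   drawn uniformly and rounded to a multiple of 3.
#' @param utr5_length,utr3_length UTR lengths (nt); `utr3_length` must be
#'   at least 40 so the downstream TSI flank fits inside the transcript.
#' @param expression_mean Mean read count per transcript per library;
#'   per-transcript means are log-normal across transcripts with
#'   log-scale SD `expression_sdlog` (mean preserved).
#' @param expression_sdlog Between-transcript log-scale SD of expression.
#' @param ctrd_fraction Fraction of 5'P ends from ribosome-tracked decay.
#' @param stall_weight Termination dwell in elongation-step units (see
#'   above).
#' @param frame_bias Concentration of the tracked component on the codon
#'   frame lattice (0 = uniform over the CDS, 1 = lattice only).
#' @param boundary_split Share of the stall mass at -17 (the rest at -16).
#' @param dispersion Negative-binomial size parameter for replicate noise
#'   on transcript totals.
#' @param genotypes Named list mapping genotype to multipliers
#'   `c(phi = , stall = )` applied to `ctrd_fraction` and `stall_weight`;
#'   the first entry is the reference genotype.
#' @param n_replicates Biological replicates per genotype.
#' @param two_exon_fraction Fraction of transcripts receiving an intron.
#' @param organ Organ label written to the sample sheet.
#' @param seed Integer seed; together with genotype and replicate it fully
#'   determines every library.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_transcripts = 500L,
                       cds_length_range = c(300L, 1500L),
                       utr5_length = 50L,
                       utr3_length = 60L,
                       expression_mean = 500,
                       expression_sdlog = 0.5,
                       ctrd_fraction = 0.4,
                       stall_weight = 10,
                       frame_bias = 0.8,
                       boundary_split = 0.5,
                       dispersion = 20,
                       genotypes = list(Col0 = c(phi = 1, stall = 1)),
                       n_replicates = 3L,
                       two_exon_fraction = 0.3,
                       organ = "shoot",
                       seed = 20260101L) {
  if (utr3_length < 40)
    stop("utr3_length must be >= 40 nt so the downstream TSI flank ",
         "(34 nt past the stop codon) fits inside every transcript")
  stopifnot(n_transcripts >= 1, length(cds_length_range) == 2,
            cds_length_range[1] >= 60, diff(cds_length_range) >= 0,
            utr5_length >= 20,
            expression_mean > 0, expression_sdlog >= 0,
            ctrd_fraction >= 0, ctrd_fraction <= 1,
            stall_weight >= 0, frame_bias >= 0, frame_bias <= 1,
            boundary_split >= 0, boundary_split <= 1,
            dispersion > 0, n_replicates >= 1,
            two_exon_fraction >= 0, two_exon_fraction <= 1,
            length(genotypes) >= 1, !is.null(names(genotypes)))
  for (g in genotypes)
    if (!all(c("phi", "stall") %in% names(g)) || any(g < 0))
      stop("each genotype needs non-negative multipliers c(phi=, stall=)")
  structure(as.list(environment()), class = "sim_config")
}

# per-transcript positional probabilities for one genotype
.position_probs <- function(model, config, genotype) {
  mult <- config$genotypes[[genotype]]
  phi <- min(1, config$ctrd_fraction * mult[["phi"]])
  s <- config$stall_weight * mult[["stall"]]
  fb <- config$frame_bias
  L <- model$length_t
  cs <- model$cds_start_t
  ss <- model$stop_codon_start_t
  cds_idx <- cs:(ss + 2L)
  lattice <- seq.int(cs, ss, by = 3L)
  w <- numeric(L)
  w[cds_idx] <- (1 - fb) / length(cds_idx)
  w[lattice] <- w[lattice] + fb / length(lattice)
  w_lat <- fb / length(lattice) + (1 - fb) / length(cds_idx)
  stall_mass <- 2 * s * w_lat
  w[ss - 17L] <- w[ss - 17L] + stall_mass * config$boundary_split
  w[ss - 16L] <- w[ss - 16L] + stall_mass * (1 - config$boundary_split)
  w <- w / sum(w)
  (1 - phi) / L + phi * w
}

# expected TSI of the positional distribution (depth-free)
.expected_tsi <- function(p, model, params = tsi_params()) {
  ss <- model$stop_codon_start_t
  b <- sum(p[ss + params$boundary_offsets])
  if (params$boundary_stat == "mean") b <- b / length(params$boundary_offsets)
  f <- mean(p[ss + flank_offsets(params)])
  b / f
}

.lib_seed <- function(config, genotype, replicate) {
  gi <- match(genotype, names(config$genotypes))
  if (is.na(gi)) stop("unknown genotype: ", genotype)
  as.integer((config$seed + gi * 1000003 + replicate * 10007) %%
               .Machine$integer.max)
}

#' Simulate a transcriptome
#'
#' Draws single- and two-exon transcripts on both strands, placed head to
#' tail along one synthetic chromosome, with CDS lengths that are
#' multiples of 3. Optionally writes a GFF3 annotation (CDS includes the
#' stop codon, the Araport dialect) and a FASTA genome with the stop codon
#' planted at its annotated position; `parse_gff()` on the written file
#' reproduces the returned models.
#'
#' @param config A [sim_config()].
#' @param dir Output directory for `annotation.gff3` (and
#'   `genome.fa` when `write_fasta`); `NULL` writes nothing.
#' @param write_fasta Write the genome FASTA (only when `dir` is given).
#' @return List with `models` (named list of [transcript_model()]),
#'   `expression` (named per-transcript mean read counts), and the file
#'   paths (`gff`, `fasta`) when written.
#' @export
simulate_transcriptome <- function(config, dir = NULL, write_fasta = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_transcripts
  cds_len <- 3L * as.integer(round(runif(
    n, config$cds_length_range[1] / 3, config$cds_length_range[2] / 3)))
  strand <- sample(c("+", "-"), n, replace = TRUE)
  two_exon <- runif(n) < config$two_exon_fraction
  intron_len <- ifelse(two_exon, as.integer(round(runif(n, 50, 500))), 0L)
  expression <- rlnorm(n,
                       meanlog = log(config$expression_mean) -
                         config$expression_sdlog^2 / 2,
                       sdlog = config$expression_sdlog)
  models <- vector("list", n)
  cursor <- 1000L
  for (i in seq_len(n)) {
    len_t <- config$utr5_length + cds_len[i] + config$utr3_length
    tid <- sprintf("SYNT%04d.1", i)
    gid <- sprintf("SYNG%04d", i)
    if (two_exon[i]) {
      # intron inserted at a position interior to the transcript
      brk <- as.integer(round(runif(1, 30, len_t - 30)))
      w1 <- brk; w2 <- len_t - brk
      # exon genomic order depends on strand (transcript runs 5'->3')
      if (strand[i] == "+") {
        e1 <- c(cursor, cursor + w1 - 1L)
        e2 <- c(e1[2] + intron_len[i] + 1L, e1[2] + intron_len[i] + w2)
      } else {
        e2 <- c(cursor, cursor + w2 - 1L)
        e1 <- c(e2[2] + intron_len[i] + 1L, e2[2] + intron_len[i] + w1)
      }
      exons <- data.frame(start = c(e1[1], e2[1]), end = c(e1[2], e2[2]))
      gspan <- len_t + intron_len[i]
    } else {
      exons <- data.frame(start = cursor, end = cursor + len_t - 1L)
      gspan <- len_t
    }
    models[[i]] <- transcript_model(
      transcript_id = tid, gene_id = gid, chrom = "chrS1",
      strand = strand[i], exons = exons,
      cds_start_t = config$utr5_length + 1L,
      stop_codon_start_t = config$utr5_length + cds_len[i] - 2L)
    cursor <- cursor + gspan + 200L
  }
  names(models) <- vapply(models, `[[`, character(1), "transcript_id")
  names(expression) <- names(models)
  out <- list(models = models, expression = expression)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    out$gff <- file.path(dir, "annotation.gff3")
    .write_gff3(models, out$gff)
    if (write_fasta) {
      out$fasta <- file.path(dir, "genome.fa")
      .write_genome_fasta(models, cursor + 1000L, out$fasta,
                          seed = config$seed)
    }
  }
  out
}

.write_gff3 <- function(models, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  fmt <- "chrS1\tctrdseq_sim\t%s\t%d\t%d\t.\t%s\t%s\t%s"
  for (m in models) {
    g1 <- min(m$exons$start); g2 <- max(m$exons$end)
    writeLines(sprintf(fmt, "gene", g1, g2, m$strand, ".",
                       paste0("ID=", m$gene_id)), con)
    writeLines(sprintf(fmt, "mRNA", g1, g2, m$strand, ".",
                       paste0("ID=", m$transcript_id,
                              ";Parent=", m$gene_id)), con)
    for (j in seq_len(nrow(m$exons)))
      writeLines(sprintf(fmt, "exon", m$exons$start[j], m$exons$end[j],
                         m$strand, ".",
                         paste0("Parent=", m$transcript_id)), con)
    cds <- .tx_range_to_genomic(m, m$cds_start_t, m$stop_codon_start_t + 2L)
    for (j in seq_len(nrow(cds)))
      writeLines(sprintf(fmt, "CDS", cds$start[j], cds$end[j], m$strand,
                         "0", paste0("Parent=", m$transcript_id)), con)
  }
  invisible(path)
}

.write_genome_fasta <- function(models, chrom_len, path, seed) {
  set.seed(seed + 1L)
  seq <- sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE)
  for (m in models) {
    g <- tx_to_genomic(m, m$stop_codon_start_t + 0:2)
    codon <- if (m$strand == "+") c("T", "A", "A") else c("T", "T", "A")
    seq[sort(g)] <- codon
  }
  dna <- Biostrings::DNAStringSet(paste(seq, collapse = ""))
  names(dna) <- "chrS1"
  Biostrings::writeXStringSet(dna, path)
  invisible(path)
}

#' Simulate one 5'P degradome library
#'
#' Per transcript, the read total is negative-binomial
#' (mean = per-transcript expression, size = `dispersion`) and positions
#' are multinomial with the genotype-specific positional distribution of
#' [sim_config()]. Fully determined by `(seed, genotype, replicate)`.
#'
#' @param transcriptome Result of [simulate_transcriptome()].
#' @param config The same [sim_config()].
#' @param genotype Genotype name (must be in `config$genotypes`).
#' @param replicate Replicate index.
#' @return An `end_counts` object (see [load_5p_ends()]), with
#'   `library_id` `"<genotype>_rep<replicate>"`.
#' @export
simulate_degradome_library <- function(transcriptome, config, genotype,
                                       replicate = 1L) {
  stopifnot(inherits(config, "sim_config"))
  models <- transcriptome$models
  set.seed(.lib_seed(config, genotype, replicate))
  totals <- rnbinom(length(models), mu = transcriptome$expression,
                    size = config$dispersion)
  profiles <- vector("list", length(models))
  for (i in seq_along(models)) {
    p <- .position_probs(models[[i]], config, genotype)
    profiles[[i]] <- as.integer(rmultinom(1, totals[i], p)[, 1])
  }
  names(profiles) <- names(models)
  structure(list(profiles = profiles,
                 library_id = sprintf("%s_rep%d", genotype, replicate),
                 n_assigned = sum(totals), n_discarded = 0L),
            class = "end_counts")
}

#' Analytic ground truth of a simulation
#'
#' Expected TSI per transcript and genotype, computed from the exact
#' positional distributions (read depth cancels from the ratio), together
#' with the target flags the thresholds imply.
#'
#' @inheritParams simulate_degradome_library
#' @param tsi_pars [tsi_params()] under which the expectation is taken.
#' @param tsi_min,fold_decrease Thresholds for the truth flags.
#' @return Data.frame with one row per transcript: `transcript_id`,
#'   `expected_tsi_<genotype>` per genotype, `is_ctrd` (reference expected
#'   TSI above `tsi_min`) and, per non-reference genotype,
#'   `true_target_<genotype>` (`is_ctrd` and expected fold >=
#'   `fold_decrease`).
#' @export
simulation_ground_truth <- function(transcriptome, config,
                                    tsi_pars = tsi_params(),
                                    tsi_min = 3, fold_decrease = 2) {
  models <- transcriptome$models
  out <- data.frame(transcript_id = names(models),
                    stringsAsFactors = FALSE)
  for (g in names(config$genotypes)) {
    out[[paste0("expected_tsi_", g)]] <- vapply(models, function(m)
      .expected_tsi(.position_probs(m, config, g), m, tsi_pars),
      numeric(1))
  }
  ref <- names(config$genotypes)[1]
  ref_tsi <- out[[paste0("expected_tsi_", ref)]]
  out$is_ctrd <- ref_tsi > tsi_min
  for (g in setdiff(names(config$genotypes), ref)) {
    fold <- ref_tsi / out[[paste0("expected_tsi_", g)]]
    out[[paste0("true_target_", g)]] <- out$is_ctrd & fold >= fold_decrease
  }
  out
}

#' Simulate a complete 5'Pseq experiment
#'
#' Transcriptome plus one library per genotype and replicate, with sample
#' sheet and analytic ground truth — the synthetic counterpart of a
#' multi-genotype 5'Pseq batch (three biological replicates per genotype
#' per organ).
#'
#' @param config A [sim_config()].
#' @param dir Optional output directory: writes the GFF3 annotation, one
#'   BED file of read 5' ends per library, `samples.tsv` and
#'   `ground_truth.tsv`.
#' @return List with `models`, `expression`, `libraries` (named list of
#'   `end_counts` by library id), `sample_sheet`, `truth` and `config`.
#' @export
simulate_experiment <- function(config = sim_config(), dir = NULL) {
  tr <- simulate_transcriptome(config, dir = dir)
  libs <- list()
  sheet <- list()
  for (g in names(config$genotypes)) {
    for (r in seq_len(config$n_replicates)) {
      ec <- simulate_degradome_library(tr, config, g, r)
      libs[[ec$library_id]] <- ec
      sheet[[ec$library_id]] <- data.frame(
        library_id = ec$library_id, genotype = g, organ = config$organ,
        replicate = r, stringsAsFactors = FALSE)
    }
  }
  sample_sheet <- do.call(rbind, unname(sheet))
  truth <- simulation_ground_truth(tr, config)
  if (!is.null(dir)) {
    for (id in names(libs))
      export_bed(libs[[id]], tr$models,
                 file.path(dir, paste0(id, ".bed")))
    write_pipeline_table(sample_sheet, file.path(dir, "samples.tsv"))
    write_pipeline_table(truth, file.path(dir, "ground_truth.tsv"))
  }
  list(models = tr$models, expression = tr$expression, libraries = libs,
       sample_sheet = sample_sheet, truth = truth, config = config)
}

#' Simulate a transcription-arrest decay time course
#'
#' Abundance follows N0 * 2^(-t / half-life) with multiplicative
#' log-normal noise, per replicate.
#'
#' @param true_halflife True half-life (minutes).
#' @param times Sampling times (minutes), first must be 0.
#' @param n_replicates Biological replicates.
#' @param noise_sd Log-scale SD of the multiplicative noise (>= 0).
#' @param seed Integer seed.
#' @param transcript_id,condition Labels for the output table.
#' @param n0 Abundance at t = 0 before noise.
#' @return Long-format time-course data.frame (see [read_timecourse()]).
#' @export
simulate_timecourse <- function(true_halflife, times = c(0, 30, 60, 120),
                                n_replicates = 3L, noise_sd = 0.1,
                                seed = 1L, transcript_id = "TX1",
                                condition = "cordycepin", n0 = 100) {
  stopifnot(true_halflife > 0, times[1] == 0, all(diff(times) > 0))
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  set.seed(seed)
  rows <- expand.grid(replicate = seq_len(n_replicates), time_min = times,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- rows[order(rows$replicate, rows$time_min), ]
  ab <- n0 * 2^(-rows$time_min / true_halflife) *
    exp(rnorm(nrow(rows), 0, noise_sd))
  data.frame(transcript_id = transcript_id, condition = condition,
             replicate = rows$replicate, time_min = rows$time_min,
             abundance = ab, stringsAsFactors = FALSE, row.names = NULL)
}
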