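#' Metagene profile of 5'P read ends around a common anchor
#'
#' Sums 5'P end counts across transcripts in a window anchored at the first
#' nucleotide of the stop codon (or of the CDS). Relative position r = 0 is
#' the anchor nucleotide itself, so the ribosome-boundary accumulation of
#' co-translational decay appears at r in {-17, -16}. Transcripts whose
#' window runs past the transcript ends contribute only their in-bounds
#' positions.
#'
#' @param profiles Named list of per-transcript count vectors, or an
#'   `end_counts` object from [load_5p_ends()].
#' @param models Named list of [transcript_model()] objects.
#' @param anchor `"stop"` (first stop-codon nucleotide) or `"start"`
#'   (first CDS nucleotide).
#' @param w_up,w_down Window half-widths in nt (positions -w_up .. +w_down).
#' @param normalize `"off"` sums raw counts; `"per_transcript"` divides
#'   each transcript's window by its own window sum before averaging, so
#'   abundant transcripts do not dominate (zero-sum windows are skipped).
#' @return Object of class `metagene_profile`: list with `anchor`,
#'   `rel_pos` (integer vector -w_up..w_down), `values`, `n_transcripts`
#'   (number of transcripts contributing at least one in-bounds position)
#'   and `normalize`.
#' @export
aggregate_metagene <- function(profiles, models, anchor = c("stop", "start"),
                               w_up = 100L, w_down = 100L,
                               normalize = c("off", "per_transcript")) {
  anchor <- match.arg(anchor)
  normalize <- match.arg(normalize)
  stopifnot(w_up >= 1, w_down >= 1)
  if (inherits(profiles, "end_counts")) profiles <- profiles$profiles
  ids <- intersect(names(profiles), names(models))
  rel <- seq.int(-w_up, w_down)
  acc <- numeric(length(rel))
  nper <- integer(length(rel))
  n_tx <- 0L
  for (id in ids) {
    m <- models[[id]]
    a <- if (anchor == "stop") m$stop_codon_start_t else m$cds_start_t
    idx <- a + rel
    ok <- idx >= 1L & idx <= m$length_t
    if (!any(ok)) next
    w <- profiles[[id]][idx[ok]]
    if (normalize == "per_transcript") {
      s <- sum(w)
      if (s == 0) next
      w <- w / s
    }
    acc[ok] <- acc[ok] + w
    nper[ok] <- nper[ok] + 1L
    n_tx <- n_tx + 1L
  }
  if (n_tx == 0L)
    stop("no transcript overlaps the requested metagene window")
  values <- if (normalize == "per_transcript")
    ifelse(nper > 0, acc / pmax(nper, 1L), 0) else acc
  structure(list(anchor = anchor, rel_pos = rel, values = values,
                 n_transcripts = n_tx, normalize = normalize),
            class = "metagene_profile")
}

#' @export
print.metagene_profile <- function(x, ...) {
  pk <- x$rel_pos[which.max(x$values)]
  cat(sprintf(
    "<metagene_profile> anchor=%s, %d transcripts, window %d..%d, peak at r=%d\n",
    x$anchor, x$n_transcripts, min(x$rel_pos), max(x$rel_pos), pk))
  invisible(x)
}

#' Position of the metagene maximum relative to the anchor
#'
#' @param x A `metagene_profile`.
#' @return Integer relative position of the global maximum (ties broken
#'   towards the most upstream position). For a stop-codon anchor,
#'   `-metagene_peak(x)` is the distance of the peak upstream of the stop
#'   codon in nt.
#' @export
metagene_peak <- function(x) {
  stopifnot(inherits(x, "metagene_profile"))
  x$rel_pos[which.max(x$values)]
}

#' Plot a metagene profile
#'
#' @param x A `metagene_profile`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot_metagene <- function(x, ...) {
  graphics::plot(x$rel_pos, x$values, type = "l",
                 xlab = sprintf("position relative to %s codon (nt)", x$anchor),
                 ylab = if (x$normalize == "off") "5'P end count"
                        else "mean normalized 5'P signal", ...)
  graphics::abline(v = 0, lty = 2, col = "grey50")
}

#' Reading-frame preference and periodicity of the degradome signal
#'
#' Pools 5'P end counts over CDS positions (relative to the CDS start,
#' stop codon excluded) across transcripts and summarises (i) the fraction
#' of counts in each codon frame and (ii) the dominant spacing of the
#' pooled profile, taken as the lag in 2..10 nt maximising the
#' mean-subtracted autocorrelation. Ribosome-tracked decay gives a strong
#' frame preference and a dominant period of 3 nt.
#'
#' @inheritParams aggregate_metagene
#' @param min_cds Minimum CDS length (nt, stop codon excluded) for a
#'   transcript to be included.
#' @return Object of class `frame_periodicity`: list with
#'   `frame_fractions` (length 3, sums to 1), `dominant_period`,
#'   `n_transcripts` and `pooled` (the pooled per-position vector over the
#'   shared CDS length). All-zero pooled counts give `NA` fractions and
#'   period with a warning.
#' @export
periodicity_score <- function(profiles, models, min_cds = 30L) {
  if (inherits(profiles, "end_counts")) profiles <- profiles$profiles
  ids <- intersect(names(profiles), names(models))
  cds_len <- vapply(models[ids],
                    function(m) m$stop_codon_start_t - m$cds_start_t,
                    integer(1))
  ids <- ids[cds_len >= min_cds]
  if (length(ids) == 0) stop("no transcript with CDS >= ", min_cds, " nt")
  shared <- min(cds_len[cds_len >= min_cds])
  pooled <- numeric(shared)
  frame_counts <- numeric(3)
  for (id in ids) {
    m <- models[[id]]
    body <- profiles[[id]][m$cds_start_t:(m$stop_codon_start_t - 1L)]
    fr <- (seq_along(body) - 1L) %% 3L
    frame_counts <- frame_counts + vapply(0:2, function(f) sum(body[fr == f]),
                                          numeric(1))
    pooled <- pooled + body[seq_len(shared)]
  }
  if (sum(frame_counts) == 0) {
    warning("all-zero CDS profile; frame fractions and period undefined")
    return(structure(list(frame_fractions = rep(NA_real_, 3),
                          dominant_period = NA_integer_,
                          n_transcripts = length(ids), pooled = pooled),
                     class = "frame_periodicity"))
  }
  lags <- 2:10
  dominant <- if (stats::sd(pooled) == 0) NA_integer_ else {
    ac <- acf(pooled, lag.max = 10L, plot = FALSE, demean = TRUE)$acf[-1]
    # harmonics of the true period (6, 9 nt for a 3-nt lattice) run within
    # a whisker of the fundamental; report the smallest near-maximal lag
    acl <- ac[lags]
    near_max <- acl >= 0.9 * max(acl) & acl > 0
    if (any(near_max)) lags[which(near_max)[1]] else lags[which.max(acl)]
  }
  structure(list(frame_fractions = frame_counts / sum(frame_counts),
                 dominant_period = dominant,
                 n_transcripts = length(ids), pooled = pooled),
            class = "frame_periodicity")
}

#' @export
print.frame_periodicity <- function(x, ...) {
  cat(sprintf(
    "<frame_periodicity> %d transcripts | frame fractions %.3f/%.3f/%.3f | dominant period %s nt\n",
    x$n_transcripts, x$frame_fractions[1], x$frame_fractions[2],
    x$frame_fractions[3], x$dominant_period))
  invisible(x)
}
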