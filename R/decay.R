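#' Read a decay time-course table
#'
#' @param path TSV with columns `transcript_id`, `condition`, `replicate`,
#'   `time_min`, `abundance`.
#' @return Data.frame (a decay time course in long format).
#' @export
read_timecourse <- function(path) {
  read_pipeline_table(path, required_cols = c("transcript_id", "condition",
                                              "replicate", "time_min",
                                              "abundance"))
}

.tc_check <- function(tc) {
  need <- c("transcript_id", "condition", "replicate", "time_min",
            "abundance")
  miss <- setdiff(need, names(tc))
  if (length(miss) > 0)
    stop("time course missing column(s): ", paste(miss, collapse = ", "))
  tc
}

#' Normalise a decay time course to its t = 0 abundance
#'
#' Each (transcript, condition, replicate) trajectory is divided by its own
#' abundance at time 0. When `reference_id` names a stable reference
#' transcript present in the table, every trajectory is first divided by
#' the reference trajectory of the same condition and replicate (matched
#' by time point).
#'
#' @param tc Long-format time course (see [read_timecourse()]).
#' @param reference_id Optional reference transcript id.
#' @return The normalised time course; idempotent on already-normalised
#'   input. A zero abundance at t = 0 is an error.
#' @export
normalize_timecourse <- function(tc, reference_id = NULL) {
  tc <- .tc_check(tc)
  if (!is.null(reference_id)) {
    ref <- tc[tc$transcript_id == reference_id, , drop = FALSE]
    if (nrow(ref) == 0) stop("reference transcript ", reference_id,
                             " absent from time course")
    key <- function(d) paste(d$condition, d$replicate, d$time_min)
    ref_ab <- setNames(ref$abundance, key(ref))
    tc <- tc[tc$transcript_id != reference_id, , drop = FALSE]
    denom <- ref_ab[key(tc)]
    if (anyNA(denom)) stop("reference trajectory does not cover all ",
                           "(condition, replicate, time) combinations")
    tc$abundance <- tc$abundance / denom
  }
  grp <- paste(tc$transcript_id, tc$condition, tc$replicate)
  for (g in unique(grp)) {
    i <- grp == g
    t0 <- tc$abundance[i & tc$time_min == 0]
    if (length(t0) != 1 || t0 <= 0)
      stop("trajectory ", g, " lacks a positive t = 0 abundance")
    tc$abundance[i] <- tc$abundance[i] / t0
  }
  tc
}

#' Fit first-order decay and report the mRNA half-life
#'
#' Per replicate, ordinary least squares on the log scale:
#' ln(abundance) = ln(N0) - lambda * t, giving half-life ln(2) / lambda.
#' Replicate half-lives are summarised as mean +/- SD. Non-positive
#' abundances are dropped with a warning; a replicate with fewer than 3
#' usable points, or a non-positive fitted lambda ("non-decaying"), has an
#' undefined half-life.
#'
#' @param tc Long-format time course for a single transcript and condition.
#' @return Object of class `decay_fit`: list with `transcript_id`,
#'   `condition`, `per_replicate` (data.frame `replicate`, `lambda`,
#'   `half_life`, `r_squared`, `n_points`, `non_decaying`),
#'   `mean_half_life`, `sd_half_life`, `n_replicates`.
#' @export
fit_halflife <- function(tc) {
  tc <- .tc_check(tc)
  if (length(unique(tc$transcript_id)) != 1 ||
      length(unique(tc$condition)) != 1)
    stop("fit_halflife expects a single transcript and condition; ",
         "see fit_halflife_all for tables")
  reps <- sort(unique(tc$replicate))
  rows <- lapply(reps, function(r) {
    d <- tc[tc$replicate == r, , drop = FALSE]
    bad <- d$abundance <= 0
    if (any(bad)) {
      warning("replicate ", r, ": ", sum(bad),
              " non-positive abundance value(s) dropped")
      d <- d[!bad, , drop = FALSE]
    }
    if (nrow(d) < 3)
      return(data.frame(replicate = r, lambda = NA_real_,
                        half_life = NA_real_, r_squared = NA_real_,
                        n_points = nrow(d), non_decaying = NA))
    fit <- lm(log(abundance) ~ time_min, data = d)
    lambda <- -unname(coef(fit)[2])
    # computed directly: summary.lm() warns on noiseless (perfect) fits
    y <- log(d$abundance)
    sst <- sum((y - mean(y))^2)
    r2 <- if (sst == 0) NA_real_ else 1 - sum(fit$residuals^2) / sst
    data.frame(replicate = r, lambda = lambda,
               half_life = if (lambda > 0) log(2) / lambda else NA_real_,
               r_squared = r2, n_points = nrow(d),
               non_decaying = lambda <= 0)
  })
  per_rep <- do.call(rbind, rows)
  hl <- per_rep$half_life[!is.na(per_rep$half_life)]
  structure(list(transcript_id = unique(tc$transcript_id),
                 condition = unique(tc$condition),
                 per_replicate = per_rep,
                 mean_half_life = if (length(hl)) mean(hl) else NA_real_,
                 sd_half_life = if (length(hl) >= 2) sd(hl) else NA_real_,
                 n_replicates = length(hl)),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf(
    "<decay_fit> %s [%s]: t1/2 = %.1f +/- %s min (n = %d replicate(s))\n",
    x$transcript_id, x$condition, x$mean_half_life,
    if (is.na(x$sd_half_life)) "NA" else sprintf("%.1f", x$sd_half_life),
    x$n_replicates))
  invisible(x)
}

#' Fit half-lives for every (transcript, condition) in a table
#'
#' @param tc Long-format time course.
#' @return Named list of [fit_halflife()] results, names
#'   `"<transcript>|<condition>"`.
#' @export
fit_halflife_all <- function(tc) {
  tc <- .tc_check(tc)
  grp <- unique(tc[, c("transcript_id", "condition")])
  out <- list()
  for (i in seq_len(nrow(grp))) {
    d <- tc[tc$transcript_id == grp$transcript_id[i] &
            tc$condition == grp$condition[i], , drop = FALSE]
    out[[paste(grp$transcript_id[i], grp$condition[i], sep = "|")]] <-
      fit_halflife(d)
  }
  out
}

#' Compare half-lives between two conditions
#'
#' Two-sided Welch t-test on per-replicate half-lives; replicates with an
#' undefined fit are excluded.
#'
#' @param fit_a,fit_b [fit_halflife()] results.
#' @param var_equal Use the pooled-variance t-test instead of Welch.
#' @return List with `p_value` (`NA` when fewer than 2 usable replicates
#'   remain on either side), `statistic`, `df`, and the two half-life
#'   vectors used.
#' @export
compare_halflives <- function(fit_a, fit_b, var_equal = FALSE) {
  ha <- fit_a$per_replicate$half_life
  hb <- fit_b$per_replicate$half_life
  ha <- ha[!is.na(ha)]; hb <- hb[!is.na(hb)]
  if (length(ha) < 2 || length(hb) < 2) {
    warning("fewer than 2 defined replicate half-lives; p undefined")
    return(list(p_value = NA_real_, statistic = NA_real_, df = NA_real_,
                half_lives_a = ha, half_lives_b = hb))
  }
  if (sd(ha) == 0 && sd(hb) == 0 && mean(ha) == mean(hb))
    return(list(p_value = 1, statistic = 0, df = NA_real_,
                half_lives_a = ha, half_lives_b = hb))
  ht <- t.test(ha, hb, var.equal = var_equal)
  list(p_value = ht$p.value, statistic = unname(ht$statistic),
       df = unname(ht$parameter), half_lives_a = ha, half_lives_b = hb)
}
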