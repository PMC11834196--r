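# Independent brute-force oracles. These deliberately re-derive each
# quantity from first principles with plain loops so they share no code
# with the package implementation.

# per-base genomic<->transcript lookup table built by walking the exons
oracle_coord_table <- function(model) {
  ex <- model$exons
  ord <- if (model$strand == "+") seq_len(nrow(ex)) else rev(seq_len(nrow(ex)))
  gpos <- integer(0)
  for (i in ord) {
    run <- ex$start[i]:ex$end[i]
    if (model$strand == "-") run <- rev(run)
    gpos <- c(gpos, run)
  }
  data.frame(tpos = seq_along(gpos), gpos = gpos)
}

# TSI recomputed from raw counts with explicit loops
oracle_tsi <- function(counts, model, boundary = c(-17L, -16L), half = 50L,
                       min_reads = 10L) {
  ss <- model$stop_codon_start_t
  b_sum <- 0
  for (r in boundary) b_sum <- b_sum + counts[ss + r]
  flank <- c((min(boundary) - half):(min(boundary) - 1L),
             (max(boundary) + 1L):(max(boundary) + half))
  f_sum <- 0
  for (r in flank) f_sum <- f_sum + counts[ss + r]
  f_mean <- f_sum / length(flank)
  if (sum(counts) < min_reads || f_mean == 0) return(NA_real_)
  b_sum / f_mean
}

# metagene by a double loop over transcripts and relative positions
oracle_metagene <- function(profiles, models, w_up, w_down) {
  rel <- (-w_up):w_down
  vals <- numeric(length(rel))
  for (id in names(profiles)) {
    m <- models[[id]]
    for (j in seq_along(rel)) {
      i <- m$stop_codon_start_t + rel[j]
      if (i >= 1 && i <= m$length_t) vals[j] <- vals[j] + profiles[[id]][i]
    }
  }
  vals
}

# exact two-sided signed-rank p by enumerating all 2^n sign assignments
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  mu <- n * (n + 1) / 4
  p <- mean(abs(v_all - mu) >= abs(v_obs - mu) - 1e-9)
  min(1, p)
}

# upper-tail hypergeometric p by exhaustive subset enumeration
oracle_hyper_p <- function(N, K, n, k) {
  a_set <- seq_len(K)
  if (n == 0) return(as.numeric(k <= 0))
  subs <- utils::combn(N, n)
  ov <- apply(subs, 2, function(s) sum(s %in% a_set))
  mean(ov >= k)
}

# Welch two-sample t-test computed by hand
oracle_welch <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# log-linear least squares decay fit written out longhand
oracle_loglinear_halflife <- function(times, abundance) {
  y <- log(abundance)
  tb <- mean(times); yb <- mean(y)
  slope <- sum((times - tb) * (y - yb)) / sum((times - tb)^2)
  log(2) / (-slope)
}
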