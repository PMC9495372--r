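# Independent brute-force oracles.  These deliberately share no code with
# the package implementations: explicit loops, explicit run scans, lm() per
# box.  They are slow and only meant for small n.

# Sample entropy by explicit template-pair counting (Chebyshev, <= r,
# self-matches excluded, N - m*delay templates for both lengths).
sampen_oracle <- function(x, m = 2, r_fraction = 0.2, delay = 1) {
  n <- length(x)
  r <- r_fraction * sd(x)
  nt <- n - m * delay
  a_count <- 0
  b_count <- 0
  for (i in seq_len(nt - 1)) {
    js <- (i + 1):nt
    dist_m <- rep(0, length(js))
    for (k in 0:(m - 1)) {
      dist_m <- pmax(dist_m, abs(x[i + k * delay] - x[js + k * delay]))
    }
    dist_m1 <- pmax(dist_m, abs(x[i + m * delay] - x[js + m * delay]))
    b_count <- b_count + sum(dist_m <= r)
    a_count <- a_count + sum(dist_m1 <= r)
  }
  if (a_count == 0L || b_count == 0L) Inf else -log(a_count / b_count)
}

# %Rec and %Det by explicit distance loops and an explicit diagonal
# run-length scan over the full matrix.
rqa_oracle <- function(x, dim = 10, delay = 5, radius_fraction = 0.25,
                       l_min = 3) {
  n <- length(x)
  nv <- n - (dim - 1) * delay
  vecs <- t(sapply(seq_len(nv), function(i) x[i + (0:(dim - 1)) * delay]))
  if (dim == 1) vecs <- matrix(x[seq_len(nv)], ncol = 1)
  d <- matrix(0, nv, nv)
  for (i in seq_len(nv)) {
    for (j in seq_len(nv)) {
      d[i, j] <- sqrt(sum((vecs[i, ] - vecs[j, ])^2))
    }
  }
  dmax <- max(d)
  rec <- if (dmax == 0) matrix(TRUE, nv, nv) else (d / dmax) < radius_fraction
  counted <- 0L
  recurrent <- 0L
  det_points <- 0L
  for (k in 1:(nv - 1)) {          # upper-triangle diagonals
    run <- 0L
    for (i in 1:(nv - k)) {
      counted <- counted + 1L
      if (rec[i, i + k]) {
        recurrent <- recurrent + 1L
        run <- run + 1L
      } else {
        if (run >= l_min) det_points <- det_points + run
        run <- 0L
      }
    }
    if (run >= l_min) det_points <- det_points + run
  }
  list(pct_rec = if (counted > 0) 100 * recurrent / counted else 0,
       pct_det = if (recurrent > 0) 100 * det_points / recurrent else 0)
}

# DFA re-implemented naively: per-box lm() fits, same definition.
dfa_naive <- function(x, sizes) {
  z <- cumsum(x - mean(x))
  n <- length(x)
  fl <- sapply(sizes, function(bs) {
    nb <- n %/% bs
    res <- numeric(0)
    for (b in seq_len(nb)) {
      idx <- ((b - 1) * bs + 1):(b * bs)
      fit <- lm(z[idx] ~ idx)
      res <- c(res, residuals(fit))
    }
    sqrt(mean(res^2))
  })
  unname(coef(lm(log10(fl) ~ log10(sizes)))[2])
}

# Manual sums-of-squares decomposition of the fully within-subject
# two-way design; returns F per effect.
rm_anova_ss_oracle <- function(df) {
  gm <- mean(df$value)
  s_means <- tapply(df$value, df$subject, mean)
  a_means <- tapply(df$value, df$condition, mean)
  b_means <- tapply(df$value, df$time, mean)
  as_means <- tapply(df$value, list(df$condition, df$subject), mean)
  bs_means <- tapply(df$value, list(df$time, df$subject), mean)
  ab_means <- tapply(df$value, list(df$condition, df$time), mean)
  nS <- length(s_means); nA <- length(a_means); nB <- length(b_means)

  ss_a <- nS * nB * sum((a_means - gm)^2)
  ss_b <- nS * nA * sum((b_means - gm)^2)
  ss_as <- nB * sum(sweep(sweep(as_means, 2, s_means), 1, a_means - gm)^2)
  ss_bs <- nA * sum(sweep(sweep(bs_means, 2, s_means), 1, b_means - gm)^2)
  ss_ab <- nS * sum(sweep(sweep(ab_means, 2, b_means), 1, a_means - gm)^2)
  resid_abs <- 0
  for (i in seq_len(nrow(df))) {
    y <- df$value[i]
    a <- as.character(df$condition[i]); b <- as.character(df$time[i])
    s <- as.character(df$subject[i])
    resid_abs <- resid_abs +
      (y - ab_means[a, b] - as_means[a, s] - bs_means[b, s] +
         a_means[a] + b_means[b] + s_means[s] - gm)^2
  }
  f_a <- (ss_a / (nA - 1)) / (ss_as / ((nA - 1) * (nS - 1)))
  f_b <- (ss_b / (nB - 1)) / (ss_bs / ((nB - 1) * (nS - 1)))
  f_ab <- (ss_ab / ((nA - 1) * (nB - 1))) /
    (resid_abs / ((nA - 1) * (nB - 1) * (nS - 1)))
  list(condition = unname(f_a), time = unname(f_b),
       interaction = unname(f_ab),
       ss = lapply(list(condition = ss_a, time = ss_b, interaction = ss_ab,
                        err_condition = ss_as, err_time = ss_bs,
                        err_interaction = resid_abs), unname))
}
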