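# independent brute-force oracle for the zero-or-one-occurrence motif
# mixture: enumerate every (none | motif, start, strand) placement and
# compute exact posteriors from first principles (no shared code with the
# package's E-step)
oracle_posterior <- function(seqs, pwms, pi, bg) {
  K <- length(pwms)
  rcp <- function(m) m[rev(seq_len(nrow(m))), c(4, 3, 2, 1), drop = FALSE]
  out <- matrix(0, length(seqs), K + 1)
  for (si in seq_along(seqs)) {
    e <- match(strsplit(seqs[si], "")[[1]], BASES4)
    n <- length(e)
    bg_lik <- function(idx_in_window, pwm, p) {
      # full sequence log-likelihood with window [p, p+L-1] (1-based)
      # emitted by the PWM and everything else by the order-1 background
      lik <- 0
      for (i in seq_len(n)) {
        lik <- lik + if (i %in% idx_in_window)
          log(pwm[i - p + 1, e[i]])
        else if (i == 1) log(bg$p0[e[1]]) else log(bg$T[e[i - 1], e[i]])
      }
      lik
    }
    w <- log(1 - sum(pi)) + bg_lik(integer(0), NULL, 0)
    labs <- 0
    for (k in seq_len(K)) {
      for (strand in 1:2) {
        pwm <- if (strand == 1) pwms[[k]] else rcp(pwms[[k]])
        L <- nrow(pwm)
        npos <- n - L + 1
        if (npos <= 0) next
        for (p in seq_len(npos)) {
          w <- c(w, log(pi[k]) - log(2 * npos) +
                   bg_lik(p:(p + L - 1), pwm, p))
          labs <- c(labs, k)
        }
      }
    }
    g <- exp(w - max(w)); g <- g / sum(g)
    for (k in 0:K) out[si, k + 1] <- sum(g[labs == k])
  }
  out
}
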