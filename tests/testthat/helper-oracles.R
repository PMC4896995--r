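# Independent oracles used across the suite.

# Full complex-valued EPG reference: excitation 90 degrees about y
# (F0 = 1 real), refocusing pulses of angle alpha about x, T1 recovery of
# Z0. Kept deliberately naive (per-order loop, complex arithmetic).
epg_complex_oracle <- function(n_echoes, esp, alpha, t2, t1 = 1000) {
  K <- n_echoes + 1
  Fst <- rep(0 + 0i, 2 * K + 1)   # orders -K..K at index k + K + 1
  Zst <- rep(0 + 0i, K + 1)       # orders 0..K
  Fst[K + 1] <- 1 + 0i
  e2h <- exp(-esp / 2 / t2)
  e1h <- exp(-esp / 2 / t1)
  c2 <- cos(alpha / 2)^2; s2 <- sin(alpha / 2)^2
  sa <- sin(alpha); ca <- cos(alpha)
  evolve <- function() {
    Fst <<- Fst * e2h
    Zst <<- Zst * e1h
    Zst[1] <<- Zst[1] + (1 - e1h)
    Fst <<- c(0 + 0i, Fst[-(2 * K + 1)])   # F(k) -> F(k+1)
  }
  echoes <- numeric(n_echoes)
  for (e in seq_len(n_echoes)) {
    evolve()
    Fn <- Fst; Zn <- Zst
    for (k in 0:K) {
      Fk <- Fst[K + 1 + k]; Fbk <- Conj(Fst[K + 1 - k]); Zk <- Zst[k + 1]
      Fn[K + 1 + k] <- c2 * Fk + s2 * Fbk - 1i * sa * Zk
      if (k > 0) Fn[K + 1 - k] <- Conj(s2 * Fk + c2 * Fbk + 1i * sa * Zk)
      Zn[k + 1] <- -0.5i * sa * Fk + 0.5i * sa * Fbk + ca * Zk
    }
    Fst <- Fn; Zst <- Zn
    evolve()
    echoes[e] <- Mod(Fst[K + 1])
  }
  echoes
}

# Exhaustive active-set NNLS oracle: tries every support subset, keeps the
# feasible candidate (unconstrained LS on the subset is elementwise >= 0)
# with the smallest SSE.
nnls_bruteforce <- function(a, y) {
  n <- ncol(a)
  best <- rep(0, n)
  best_sse <- sum(y^2)
  for (code in seq_len(2^n) - 1L) {
    sel <- which(bitwAnd(code, 2^(seq_len(n) - 1)) > 0)
    if (!length(sel)) next
    sub <- a[, sel, drop = FALSE]
    if (qr(sub)$rank < length(sel)) next
    z <- qr.solve(sub, y)
    if (any(z < 0)) next
    sse <- sum((y - sub %*% z)^2)
    if (sse < best_sse - 1e-12) {
      best_sse <- sse
      best <- rep(0, n); best[sel] <- z
    }
  }
  best
}

# Single-region truth helper for small targeted phantoms.
uniform_truth <- function(shape, values) {
  out <- list(region = array(1L, shape))
  for (nm in names(values)) {
    v <- values[[nm]]
    out[[nm]] <- if (length(v) == 1 && is.numeric(v)) array(v, shape) else v
  }
  out
}
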