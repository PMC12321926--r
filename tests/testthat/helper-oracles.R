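# Independent brute-force oracles used to validate the fast implementations.

# naive triple-loop version of the adaptive expansion: static per-voxel
# eligibility (band HU, strictly below in-plane 3x3 non-air mean), then
# layer-by-layer growth from the initial mask until no voxel is added
bf_adaptive_expand <- function(vol, initial, allowed, air_thr = -400,
                               soft_thr = -125) {
  d <- dim(vol)
  eligible <- array(FALSE, d)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    v <- vol[i, j, k]
    if (initial[i, j, k] || !allowed[i, j, k]) next
    if (v < air_thr || v >= soft_thr) next
    acc <- 0; cnt <- 0
    for (dj in -1:1) for (dk in -1:1) {
      if (dj == 0 && dk == 0) next
      jj <- j + dj; kk <- k + dk
      if (jj < 1 || jj > d[2] || kk < 1 || kk > d[3]) next
      w <- vol[i, jj, kk]
      if (w >= air_thr) { acc <- acc + w; cnt <- cnt + 1 }
    }
    if (cnt > 0 && v < acc / cnt) eligible[i, j, k] <- TRUE
  }
  mask <- initial
  repeat {
    added_any <- FALSE
    for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
      if (!eligible[i, j, k] || mask[i, j, k]) next
      nb <- mask[max(1, i - 1):min(d[1], i + 1),
                 max(1, j - 1):min(d[2], j + 1),
                 max(1, k - 1):min(d[3], k + 1)]
      if (any(nb)) { mask[i, j, k] <- TRUE; added_any <- TRUE }
    }
    if (!added_any) break
  }
  mask & !initial
}

# exact two-sided Mann-Whitney p by enumerating every group assignment
bf_mann_whitney_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x); n <- length(pooled)
  u_of <- function(idx) {
    a <- pooled[idx]; b <- pooled[-idx]
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  u_obs <- u_of(seq_len(n1))
  us <- combn(n, n1, u_of)
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  min(p, 1)
}
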