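# Independent brute-force oracles, deliberately written without reusing the
# package's computational paths.

conn_offsets <- function(conn) {
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nz <- rowSums(abs(off))
  if (conn == 6) off[nz == 1, , drop = FALSE]
  else if (conn == 18) off[nz >= 1 & nz <= 2, , drop = FALSE]
  else off[nz >= 1, , drop = FALSE]
}

# flood-fill connected-component labelling of a logical 3D array
label_components_bfs <- function(mask, conn = 26) {
  d <- dim(mask)
  off <- conn_offsets(conn)
  lab <- array(0L, d)
  cur <- 0L
  idx_all <- which(mask, arr.ind = TRUE)
  for (r in seq_len(nrow(idx_all))) {
    start <- idx_all[r, ]
    if (lab[start[1], start[2], start[3]] > 0L) next
    cur <- cur + 1L
    queue <- matrix(start, 1, 3)
    lab[start[1], start[2], start[3]] <- cur
    while (nrow(queue) > 0) {
      v <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
      for (k in seq_len(nrow(off))) {
        w <- v + off[k, ]
        if (any(w < 1) || any(w > d)) next
        if (mask[w[1], w[2], w[3]] && lab[w[1], w[2], w[3]] == 0L) {
          lab[w[1], w[2], w[3]] <- cur
          queue <- rbind(queue, w)
        }
      }
    }
  }
  lab
}

# direct sum-over-thresholds TFCE of the positive part of a 3D array
tfce_oracle <- function(arr, E = 0.5, H = 2, n_steps = 100, conn = 26) {
  out <- array(0, dim(arr))
  hmax <- max(arr)
  if (hmax <= 0) return(out)
  dh <- hmax / n_steps
  for (k in seq_len(n_steps)) {
    h <- k * dh
    mask <- arr >= h
    if (!any(mask)) next
    lab <- label_components_bfs(mask, conn)
    sizes <- tabulate(lab[mask])
    out[mask] <- out[mask] + sizes[lab[mask]]^E * h^H * dh
  }
  out
}

# exact sign-flip max-TFCE permutation p-values (no variance smoothing),
# enumerating all 2^N sign patterns
perm_fwe_oracle <- function(mat, dims, E = 0.5, H = 2, n_steps = 100,
                            conn = 26) {
  N <- ncol(mat)
  domain <- rowSums(mat != 0) > 0
  tmap <- function(signs) {
    sm <- sweep(mat, 2, signs, `*`)
    mu <- rowMeans(sm)
    va <- apply(sm, 1, stats::var)
    t <- ifelse(domain & va > 1e-12, mu / sqrt(va / N), 0)
    array(pmax(t, 0), dims)
  }
  obs <- tfce_oracle(tmap(rep(1, N)), E, H, n_steps, conn)
  signs_all <- as.matrix(expand.grid(rep(list(c(-1, 1)), N)))
  max_null <- apply(signs_all, 1, function(s)
    max(tfce_oracle(tmap(s), E, H, n_steps, conn)))
  P <- nrow(signs_all)
  p <- (1 + vapply(as.numeric(obs), function(o) sum(max_null >= o), 0)) /
    (P + 1)
  p[!domain] <- 1
  array(p, dims)
}

# OLS by explicit normal equations
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  c(intercept = beta[1], slope = beta[2])
}

# Spearman rho from manually computed average ranks + explicit moment sums
spearman_oracle <- function(x, y) {
  avg_rank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v))
      r[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    r
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  n <- length(x)
  num <- sum(rx * ry) - n * mean(rx) * mean(ry)
  den <- sqrt((sum(rx^2) - n * mean(rx)^2) * (sum(ry^2) - n * mean(ry)^2))
  num / den
}
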