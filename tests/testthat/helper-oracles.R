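# Independent brute-force oracles, deliberately written without reusing any
# package internals.

oracle_fd <- function(motion, head_radius_mm = 50) {
  n <- nrow(motion)
  out <- numeric(n - 1)
  for (t in 2:n) {
    s <- 0
    for (j in 1:3) s <- s + abs(motion[t, j] - motion[t - 1, j])
    for (j in 4:6) {
      s <- s + head_radius_mm * abs(motion[t, j] - motion[t - 1, j]) * pi / 180
    }
    out[t - 1] <- s
  }
  out
}

# least-squares residuals via explicit normal equations
oracle_residuals <- function(y, confounds) {
  x <- cbind(1, as.matrix(confounds))
  beta <- solve(t(x) %*% x, t(x) %*% y)
  y - as.vector(x %*% beta)
}

# Benjamini-Hochberg step-up from scratch
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    val <- min(prev, p[o[i]] * m / i)
    adj[o[i]] <- val
    prev <- val
  }
  adj
}

oracle_pairwise_dist <- function(mat) {
  n <- ncol(mat)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      d[i, j] <- sqrt(sum((mat[, i] - mat[, j])^2))
    }
  }
  d
}

oracle_rmssd <- function(z) {
  n <- length(z)
  s <- 0
  for (t in 1:(n - 1)) s <- s + (z[t + 1] - z[t])^2
  sqrt(s / (n - 1))
}

oracle_sd <- function(z) {
  m <- sum(z) / length(z)
  sqrt(sum((z - m)^2) / (length(z) - 1))
}

restate_test <- function(values, template) {
  state_matrix(values, tr_seconds = attr(template, "tr_seconds"),
               normalized = isTRUE(attr(template, "normalized")))
}

# a small ready-made item table hitting specific totals
items_row <- function(cdrisc, brs, rsa) {
  as.data.frame(c(setNames(as.list(cdrisc), sprintf("cdrisc_%02d", 1:25)),
                  setNames(as.list(brs), sprintf("brs_%02d", 1:6)),
                  setNames(as.list(rsa), sprintf("rsa_%02d", 1:29))))
}
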