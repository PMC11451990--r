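# Independent reference implementations ("oracles") used to check the
# package's algorithms. These deliberately avoid calling any package
# internals so that agreement is meaningful.

# Brute-force flood fill on a logical kymograph mask. 8-connectivity in
# (row, frame); rows r and r+1 are adjacent only when adjacent_next[r]
# is TRUE (the last element encodes the wrap across the seam).
flood_fill_oracle <- function(mask, adjacent_next = rep(TRUE, nrow(mask))) {
  s_count <- nrow(mask); n_t <- ncol(mask)
  lab <- matrix(0L, s_count, n_t)
  up_of <- function(r) {
    prev <- if (r == 1L) s_count else r - 1L
    if (s_count > 1L && adjacent_next[prev]) prev else NA_integer_
  }
  dn_of <- function(r) {
    nxt <- if (r == s_count) 1L else r + 1L
    if (s_count > 1L && adjacent_next[r]) nxt else NA_integer_
  }
  n_lab <- 0L
  for (r0 in seq_len(s_count)) for (c0 in seq_len(n_t)) {
    if (!mask[r0, c0] || lab[r0, c0] > 0L) next
    n_lab <- n_lab + 1L
    queue <- list(c(r0, c0))
    lab[r0, c0] <- n_lab
    while (length(queue) > 0) {
      p <- queue[[length(queue)]]
      queue[[length(queue)]] <- NULL
      r <- p[1]; cc <- p[2]
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        rr <- if (dr == -1) up_of(r) else if (dr == 1) dn_of(r) else r
        c2 <- cc + dc
        if (is.na(rr) || c2 < 1 || c2 > n_t) next
        if (mask[rr, c2] && lab[rr, c2] == 0L) {
          lab[rr, c2] <- n_lab
          queue[[length(queue) + 1L]] <- c(rr, c2)
        }
      }
    }
  }
  lab
}

# canonical description of a labeled component map: one sorted string
# per component listing its pixels, order-independent
component_signature <- function(lab) {
  ids <- setdiff(sort(unique(as.vector(lab))), 0L)
  sort(vapply(ids, function(k) {
    paste(sort(which(lab == k)), collapse = ",")
  }, character(1)))
}

# Exact two-sided Mann-Whitney p-value by exhaustive enumeration of all
# choose(n, n1) group assignments (untied samples only).
mw_enumeration_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(n, n1)
  us <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Direct-formula Pearson correlation.
pcc_direct_oracle <- function(a, b) {
  am <- a - mean(a); bm <- b - mean(b)
  sum(am * bm) / sqrt(sum(am^2) * sum(bm^2))
}

# Exhaustive two-segment piecewise-constant RSS minimizer.
split_bruteforce_oracle <- function(prof) {
  n <- length(prof)
  best <- Inf; best_c <- NA_integer_
  for (cf in 1:(n - 1)) {
    lo <- prof[1:cf]; hi <- prof[(cf + 1):n]
    rss <- sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
    if (rss < best) { best <- rss; best_c <- cf }
  }
  best_c
}
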