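# Independent brute-force oracles used to check the package's statistics.
# These deliberately avoid the code paths they verify.

# Spearman rho via the explicit rank-covariance formula with average ranks
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  dx <- rx - mean(rx); dy <- ry - mean(ry)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# upper-tail hypergeometric probability by direct enumeration of the
# binomial-ratio terms (exact in double arithmetic for small totals)
oracle_fisher_greater <- function(a, b, c, d) {
  N <- a + b + c + d
  K <- a + c
  m <- a + b
  if (a == 0) return(1)
  ks <- seq.int(a, min(K, m))
  sum(choose(K, ks) * choose(N - K, m - ks)) / choose(N, m)
}

# step-up BH by literal definition: q_(i) = min_{j>=i} (m/j) p_(j)
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min((m / seq.int(i, m)) * ps[seq.int(i, m)]))
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# best-hit assignment by exhaustive scan over rows
oracle_best_hits <- function(hits, identity_threshold = 65) {
  out <- list()
  for (q in unique(hits$query_id)) {
    rows <- hits[hits$query_id == q, ]
    best <- NULL
    for (i in seq_len(nrow(rows))) {
      r <- rows[i, ]
      if (is.null(best) ||
          r$bitscore > best$bitscore ||
          (r$bitscore == best$bitscore &&
             r$percent_identity > best$percent_identity) ||
          (r$bitscore == best$bitscore &&
             r$percent_identity == best$percent_identity &&
             r$subject_id < best$subject_id)) {
        best <- r
      }
    }
    if (best$percent_identity >= identity_threshold) {
      out[[q]] <- best$subject_id
    }
  }
  out
}

# HGT candidates by double scan over both hit tables
oracle_hgt <- function(ncldv, self, max_e = 1e-10, min_cov = 50, min_id = 50) {
  cand <- character(0)
  for (q in unique(ncldv$query_id)) {
    rows <- ncldv[ncldv$query_id == q &
                    ncldv$e_value <= max_e &
                    ncldv$percent_query_coverage >= min_cov &
                    ncldv$percent_identity >= min_id, ]
    if (nrow(rows) == 0) next
    best_n <- min(rows$e_value)
    srows <- self[self$query_id == q & self$subject_id != q, ]
    if (nrow(srows) == 0 || best_n < min(srows$e_value)) cand <- c(cand, q)
  }
  cand
}

# random hit-table generator shared by hostval / virophage oracle tests
random_hit_table <- function(n, queries, subjects) {
  tibble::tibble(
    query_id = sample(queries, n, replace = TRUE),
    subject_id = sample(subjects, n, replace = TRUE),
    percent_identity = round(stats::runif(n, 20, 100), 1),
    percent_query_coverage = round(stats::runif(n, 10, 100), 1),
    e_value = 10^stats::runif(n, -80, 0),
    bitscore = round(stats::runif(n, 30, 400), 1))
}
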