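# Internal numerical helpers.

# Row-wise log-sum-exp of a finite matrix, vectorised (no apply).
.row_lse <- function(m) {
  mx <- m[cbind(seq_len(nrow(m)), max.col(m, ties.method = "first"))]
  mx + log(rowSums(exp(m - mx)))
}

.col_lse <- function(m) .row_lse(t(m))

# Standard Gumbel(0,1) draws.
.rgumbel <- function(n) -log(-log(stats::runif(n)))

# Maximum-weight assignment on a finite score matrix: returns p with p[i] the
# column assigned to row i, maximising sum(score[i, p[i]]).
.max_assignment <- function(score) {
  n <- nrow(score)
  if (n == 1L) return(1L)
  # igraph's weighted bipartite matching requires positive weights; shifting
  # all entries changes every perfect matching's total by the same constant.
  w <- score - min(score) + 1
  g <- igraph::graph_from_biadjacency_matrix(w, weighted = TRUE)
  m <- igraph::max_bipartite_match(g, weights = igraph::E(g)$weight)
  as.integer(m$matching[seq_len(n)]) - n
}

# FNV-1a hash of a character string, hex-encoded; used for config fingerprints.
# 32-bit arithmetic carried in doubles (split multiply keeps everything < 2^53).
.fnv1a <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
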