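# Brute-force centrality oracle: enumerates every simple path between each
# node pair, takes geodesics within relative tolerance, and derives strength,
# betweenness and closeness directly from the definitions.  Independent of
# the package's Floyd-Warshall implementation; only usable for small p.

oracle_centrality <- function(W, reltol = 1e-9) {
  p <- nrow(W)
  A <- abs(W)
  L <- 1 / A
  all_paths <- function(j, k) {
    res <- list()
    rec <- function(cur, visited, len) {
      for (nxt in seq_len(p)) {
        if (A[cur, nxt] > 0 && !(nxt %in% visited)) {
          nl <- len + L[cur, nxt]
          if (nxt == k) {
            res[[length(res) + 1L]] <<- list(len = nl, mid = visited[-1])
          } else {
            rec(nxt, c(visited, nxt), nl)
          }
        }
      }
    }
    rec(j, j, 0)
    res
  }
  D <- matrix(Inf, p, p); diag(D) <- 0
  sigma <- matrix(0, p, p)
  through <- array(0, c(p, p, p))
  for (j in seq_len(p - 1)) {
    for (k in seq(j + 1, p)) {
      ps <- all_paths(j, k)
      if (!length(ps)) next
      lens <- vapply(ps, `[[`, numeric(1), "len")
      dmin <- min(lens)
      geo <- ps[lens <= dmin * (1 + reltol)]
      D[j, k] <- D[k, j] <- dmin
      sigma[j, k] <- sigma[k, j] <- length(geo)
      for (g in geo) {
        for (i in g$mid) {
          through[i, j, k] <- through[i, j, k] + 1
          through[i, k, j] <- through[i, k, j] + 1
        }
      }
    }
  }
  bet <- vapply(seq_len(p), function(i) {
    s <- 0
    for (j in seq_len(p - 1)) for (k in seq(j + 1, p)) {
      if (i != j && i != k && sigma[j, k] > 0)
        s <- s + through[i, j, k] / sigma[j, k]
    }
    s
  }, numeric(1))
  tot <- rowSums(D)
  clo <- ifelse(is.finite(tot) & tot > 0, (p - 1) / tot, 0)
  list(strength = rowSums(A), betweenness = bet, closeness = clo,
       D = D, sigma = sigma, through = through)
}

# random signed weighted network on p nodes
random_network <- function(p, seed, density = 0.55) {
  set.seed(seed)
  W <- matrix(0, p, p)
  ut <- which(upper.tri(W))
  on <- stats::runif(length(ut)) < density
  w <- stats::runif(length(ut), 0.1, 0.9) * sample(c(-1, 1), length(ut), TRUE)
  W[ut[on]] <- w[on]
  W <- W + t(W)
  weighted_network(W, paste0("N", seq_len(p)))
}

# build a centrality_summary pair from the packaged reference summaries
reference_summaries <- function() {
  ref <- sc_centrality_summaries()
  idx <- unique(ref$index)
  mk <- function(mcol, scol, grp) {
    centrality_summary(
      matrix(ref[[mcol]], 7, 3, dimnames = list(sc_measure_names(), idx)),
      matrix(ref[[scol]], 7, 3, dimnames = list(sc_measure_names(), idx)),
      group = grp, B = 1000L)
  }
  list(td = mk("mean_td", "sd_td", "TD"), asd = mk("mean_asd", "sd_asd", "ASD"))
}
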