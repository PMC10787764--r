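# Independent brute-force oracles used to validate the fast implementations.

# Maximum length of an alternating subsequence whose consecutive values
# differ by more than min_change (dynamic programme over all candidate
# reversal sequences). The reversal filter should emit exactly this many
# extrema.
oracle_max_alternating <- function(d, min_change) {
  n <- length(d)
  if (n < 1) return(0L)
  up <- rep(1L, n)   # longest sequence ending at i with a rise into i
  dn <- rep(1L, n)   # ... with a fall into i
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (d[i] - d[j] > min_change && dn[j] + 1L > up[i]) up[i] <- dn[j] + 1L
      if (d[j] - d[i] > min_change && up[j] + 1L > dn[i]) dn[i] <- up[j] + 1L
    }
  }
  max(up, dn)
}

# Connected components of the strict interval-overlap graph by transitive
# closure (Floyd-Warshall style reachability).
oracle_overlap_components <- function(s, e) {
  n <- length(s)
  adj <- outer(seq_len(n), seq_len(n), function(i, j) {
    pmax(s[i], s[j]) < pmin(e[i], e[j])
  })
  diag(adj) <- TRUE
  reach <- adj
  for (k in seq_len(n)) {
    reach <- reach | (outer(reach[, k], reach[k, ], `&`))
  }
  comp <- integer(n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      cid <- cid + 1L
      comp[reach[i, ]] <- cid
    }
  }
  comp
}

# Recount the influence matrix entry-by-entry from an attempts table.
oracle_influence <- function(attempts, ids) {
  P <- matrix(0L, length(ids), length(ids), dimnames = list(ids, ids))
  pulls <- unique(attempts[attempts$outcome == "pull",
                           c("event_id", "initiator", "follower")])
  for (r in seq_len(nrow(pulls))) {
    P[pulls$initiator[r], pulls$follower[r]] <-
      P[pulls$initiator[r], pulls$follower[r]] + 1L
  }
  P
}

# Small helper: a grid built directly from coordinate matrices.
make_grid <- function(x, y, ids = NULL, t0 = 1000L) {
  if (is.null(ids)) ids <- sprintf("A%02d", seq_len(nrow(x)))
  trajectory_grid(ids, t0 + seq_len(ncol(x)) - 1L, x, y)
}

# Two-agent grid where agent A walks `disp` metres east starting at t_go,
# holds, and (optionally) agent B follows east; used for scripted
# classification cases.
scripted_pull_grid <- function(n_t = 120, t_go = 20, disp = 10,
                               follow = TRUE, speed = 1) {
  xa <- numeric(n_t); ya <- numeric(n_t)
  xb <- rep(0, n_t); yb <- rep(-2, n_t)
  dur <- ceiling(disp / speed)
  ramp <- pmin(pmax(seq_len(n_t) - t_go, 0), dur) / dur
  xa <- disp * ramp
  if (follow) {
    t_resp <- t_go + dur + 5
    ramp_b <- pmin(pmax(seq_len(n_t) - t_resp, 0), dur) / dur
    xb <- disp * ramp_b
  } else {
    t_back <- t_go + dur + 5
    ramp_back <- pmin(pmax(seq_len(n_t) - t_back, 0), dur) / dur
    xa <- xa - disp * ramp_back
  }
  make_grid(rbind(xa, xb), rbind(ya, yb), ids = c("A", "B"))
}
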