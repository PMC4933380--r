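# Shared fixtures and independent brute-force oracles used across tests.

# one-species linear decay dy/dt = -k y, y(0) = 1: dy/dk = -t exp(-k t),
# and for k = 1, T = 1 the influence has the closed form
# kappa^2 = int_0^1 t^2 exp(-2 t) dt = 0.25 - 1.25 exp(-2).
decay_network <- function(k = 1) {
  reaction_network(
    "decay",
    species = data.frame(id = "A", initial = 1, protein = "P",
                         stringsAsFactors = FALSE),
    parameters = data.frame(id = "k", value = k, rate_constant = TRUE,
                            stringsAsFactors = FALSE),
    reactions = list(list(id = "deg", stoich = c(A = -1), rate = "k * A"))
  )
}

decay_condition <- function(horizon = 1) {
  stimulation_condition("base", list(), horizon)
}

# Spearman by definition: Pearson product-moment correlation of mid-ranked
# vectors, computed from first principles.
brute_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# Rank-biserial by exhaustive pair counting.
brute_rank_biserial <- function(x, group) {
  g <- as.logical(group)
  x1 <- x[g]; x0 <- x[!g]
  wins <- 0
  for (a in x1) for (b in x0)
    wins <- wins + (a > b) + 0.5 * (a == b)
  2 * wins / (length(x1) * length(x0)) - 1
}

# Betweenness by exhaustive enumeration of all shortest paths (BFS path
# counting), normalized by (n - 1)(n - 2) / 2. Takes an adjacency matrix.
brute_betweenness <- function(adj) {
  n <- nrow(adj)
  btw <- numeric(n)
  if (n < 3) return(btw)
  # all shortest paths between s and t via recursive backtracking on BFS depths
  shortest_paths <- function(s, t) {
    dist <- rep(Inf, n); dist[s] <- 0
    frontier <- s
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) for (w in which(adj[v, ] > 0))
        if (dist[w] > dist[v] + 1) { dist[w] <- dist[v] + 1; nxt <- c(nxt, w) }
      frontier <- unique(nxt)
    }
    if (!is.finite(dist[t])) return(list())
    paths <- list()
    walk <- function(v, acc) {
      if (v == s) { paths[[length(paths) + 1]] <<- rev(c(acc, s)); return() }
      for (u in which(adj[v, ] > 0))
        if (dist[u] == dist[v] - 1) walk(u, c(acc, v))
    }
    walk(t, integer(0))
    paths
  }
  for (s in seq_len(n - 1)) for (t in seq(s + 1, n)) {
    paths <- shortest_paths(s, t)
    if (!length(paths)) next
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      thru <- sum(vapply(paths, function(p) v %in% p[-c(1, length(p))],
                         logical(1)))
      btw[v] <- btw[v] + thru / length(paths)
    }
  }
  btw / ((n - 1) * (n - 2) / 2)
}

# Small two-model covariate fixture with hand-set values.
toy_records <- function() {
  list(
    A = data.frame(
      domain_id = paste0("a", 1:6), protein_id = paste0("pa", c(1, 1, 2, 2, 3, 3)),
      omega = c(0.05, 0.1, 0.2, 0.4, 0.3, 0.15),
      D = c(2.0, 1.5, 1.0, 0.2, 0.4, 1.2),
      B = c(40, 40, 10, 10, 25, 25), X = c(200, 200, 50, 50, 120, 120),
      d = c(9, 9, 3, 3, 6, 6), C = c(0.2, 0.2, 0.05, 0.05, 0.1, 0.1),
      E = c(1, 1, 0, 0, 1, 1), Gr = c(0.9, 0.9, 0.99, 0.99, 0.95, 0.95),
      stringsAsFactors = FALSE),
    B = data.frame(
      domain_id = paste0("b", 1:5), protein_id = paste0("pb", c(1, 1, 2, 3, 3)),
      omega = c(0.3, 0.08, 0.5, 0.12, 0.22),
      D = c(0.5, 3.0, 0.1, 2.0, 1.0),
      B = c(15, 15, 5, 30, 30), X = c(80, 80, 20, 300, 300),
      d = c(4, 4, 2, 11, 11), C = c(0.08, 0.08, 0.02, 0.3, 0.3),
      E = c(0, 0, 1, 1, 1), Gr = c(0.97, 0.97, 0.85, 0.92, 0.92),
      stringsAsFactors = FALSE)
  )
}
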