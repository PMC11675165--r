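# Independent brute-force d-separation oracle: enumerate every undirected
# path between x and y and apply the blocking rules directly. Kept free of
# any package internals except the ase_dag fields (nodes, edges) so it can
# disagree with the implementation.

oracle_descendants <- function(edges, v) {
  seen <- v
  frontier <- v
  while (length(frontier) > 0) {
    ch <- unique(edges[edges[, 1] %in% frontier, 2])
    frontier <- setdiff(ch, seen)
    seen <- c(seen, frontier)
  }
  seen
}

oracle_d_separated <- function(dag, x, y, z) {
  edges <- dag$edges
  neighbours <- function(v) unique(c(edges[edges[, 1] == v, 2], edges[edges[, 2] == v, 1]))
  paths <- list()
  walk <- function(v, acc) {
    if (v == y) {
      paths[[length(paths) + 1]] <<- acc
      return(invisible())
    }
    for (nb in setdiff(neighbours(v), acc)) walk(nb, c(acc, nb))
  }
  walk(x, x)
  blocked <- vapply(paths, function(p) {
    if (length(p) == 2) return(FALSE)  # direct edge: never blocked
    for (i in seq(2, length(p) - 1)) {
      into_left <- any(edges[, 1] == p[i] & edges[, 2] == p[i - 1])   # p[i] -> p[i-1]
      into_right <- any(edges[, 1] == p[i] & edges[, 2] == p[i + 1])  # p[i] -> p[i+1]
      collider <- !into_left && !into_right  # both arrows point into p[i]
      if (collider) {
        if (!any(oracle_descendants(edges, p[i]) %in% z)) return(TRUE)
      } else {
        if (p[i] %in% z) return(TRUE)
      }
    }
    FALSE
  }, logical(1))
  all(blocked)
}

# All labelled DAGs on the given nodes: every orientation (absent, ->, <-)
# of every unordered pair, keeping the acyclic ones.
all_dags <- function(nodes) {
  pairs <- utils::combn(nodes, 2, simplify = FALSE)
  out <- list()
  states <- expand.grid(rep(list(0:2), length(pairs)))
  for (r in seq_len(nrow(states))) {
    em <- matrix(character(0), ncol = 2)
    for (j in seq_along(pairs)) {
      s <- states[r, j]
      if (s == 1) em <- rbind(em, pairs[[j]])
      if (s == 2) em <- rbind(em, rev(pairs[[j]]))
    }
    g <- tryCatch(dag(nodes, em), error = function(e) NULL)
    if (!is.null(g)) out[[length(out) + 1]] <- g
  }
  out
}

# Every statement (x, y, z) with x < y on the dag's nodes.
all_statements <- function(nodes, max_cond = length(nodes) - 2) {
  out <- list()
  for (x in nodes) {
    for (y in nodes[nodes > x]) {
      rest <- setdiff(nodes, c(x, y))
      subs <- list(character(0))
      if (max_cond > 0 && length(rest) > 0) {
        for (k in seq_len(min(max_cond, length(rest)))) {
          subs <- c(subs, utils::combn(rest, k, simplify = FALSE))
        }
      }
      for (z in subs) out[[length(out) + 1]] <- list(x = x, y = y, z = z)
    }
  }
  out
}
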