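# Brute-force oracles, written independently of the package internals (and
# of igraph) so that implementation and check never share a code path.

# All simple paths between s and t by depth-first search on an adjacency
# list; returns a list of vertex sequences.
all_simple_paths_brute <- function(adj, s, t) {
  out <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (v == t) {
      out[[length(out) + 1]] <<- path
      return(invisible())
    }
    for (w in adj[[v]]) {
      if (!(w %in% path)) walk(c(path, w))
    }
  }
  walk(s)
  out
}

# Edge betweenness by exhaustive shortest-path enumeration over unordered
# pairs: sum over s < t of (# shortest s-t paths through the edge) / (#
# shortest s-t paths).
oracle_ebc <- function(edges, n = max(edges$from, edges$to)) {
  adj <- lapply(seq_len(n), function(v) {
    sort(c(edges$to[edges$from == v], edges$from[edges$to == v]))
  })
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  score <- setNames(numeric(nrow(edges)), key(edges$from, edges$to))
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      paths <- all_simple_paths_brute(adj, s, t)
      lens <- vapply(paths, length, integer(1))
      short <- paths[lens == min(lens)]
      for (p in short) {
        ek <- key(p[-length(p)], p[-1])
        for (e in ek) score[e] <- score[e] + 1 / length(short)
      }
    }
  }
  unname(score[key(edges$from, edges$to)])
}

# Minimum spanning tree by hand-written Kruskal (union-find), then all-pairs
# path sums over the tree by depth-first search.
oracle_mc_kernel <- function(edges, n = max(edges$from, edges$to)) {
  ord <- order(edges$weight, edges$from, edges$to)
  parent <- seq_len(n)
  find <- function(v) {
    while (parent[v] != v) v <- parent[v]
    v
  }
  keep <- logical(nrow(edges))
  for (k in ord) {
    a <- find(edges$from[k])
    b <- find(edges$to[k])
    if (a != b) {
      parent[a] <- b
      keep[k] <- TRUE
    }
  }
  te <- edges[keep, ]
  adj <- lapply(seq_len(n), function(v) {
    rbind(
      cbind(te$to[te$from == v], te$weight[te$from == v]),
      cbind(te$from[te$to == v], te$weight[te$to == v]))
  })
  D <- matrix(0, n, n)
  for (s in seq_len(n)) {
    seen <- rep(FALSE, n)
    seen[s] <- TRUE
    frontier <- list(c(s, 0))
    while (length(frontier)) {
      cur <- frontier[[1]]
      frontier <- frontier[-1]
      for (r in seq_len(nrow(adj[[cur[1]]]))) {
        w <- adj[[cur[1]]][r, 1]
        if (!seen[w]) {
          seen[w] <- TRUE
          D[s, w] <- cur[2] + adj[[cur[1]]][r, 2]
          frontier[[length(frontier) + 1]] <- c(w, D[s, w])
        }
      }
    }
  }
  D
}

# Literal step-by-step greedy-routing simulator following the drop rule
# "packet returns to the node it came from", with a hop cap to terminate
# longer loops (which can never deliver).
oracle_greedy <- function(edges, H, n = max(edges$from, edges$to)) {
  adj <- lapply(seq_len(n), function(v) {
    sort(c(edges$to[edges$from == v], edges$from[edges$to == v]))
  })
  P <- matrix(0L, n, n)
  for (s in seq_len(n)) {
    for (t in seq_len(n)) {
      if (s == t) next
      cur <- s
      prev <- 0L
      hops <- 0L
      res <- -1L
      while (hops <= n + 1L) {
        nb <- adj[[cur]]
        nxt <- nb[which.min(H[nb, t])]
        hops <- hops + 1L
        if (nxt == t) {
          res <- hops
          break
        }
        if (nxt == prev) break
        prev <- cur
        cur <- nxt
      }
      P[s, t] <- res
    }
  }
  P
}

# Random connected labeled graph: Erdos-Renyi edges resampled until
# connected (checked by hand-rolled BFS).
random_connected_graph <- function(n, p = 0.4) {
  repeat {
    pairs <- t(combn(n, 2))
    keep <- runif(nrow(pairs)) < p
    if (sum(keep) < n - 1) next
    edges <- tibble::tibble(from = pairs[keep, 1], to = pairs[keep, 2])
    adj <- lapply(seq_len(n), function(v) {
      c(edges$to[edges$from == v], edges$from[edges$to == v])
    })
    seen <- rep(FALSE, n)
    seen[1] <- TRUE
    queue <- 1L
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      for (w in adj[[v]]) {
        if (!seen[w]) {
          seen[w] <- TRUE
          queue <- c(queue, w)
        }
      }
    }
    if (all(seen)) return(edges)
  }
}

# Exact sampler of the discrete power law p(k) = k^-alpha / zeta(alpha,
# xmin) by inverse CDF (analytic Hurwitz-zeta tail beyond the table).
rzeta <- function(n, alpha, xmin = 1, table_max = 100000) {
  ks <- xmin:(xmin + table_max)
  norm <- sum(ks^(-alpha)) +
    (xmin + table_max + 1)^(1 - alpha) / (alpha - 1)
  cdf <- cumsum(ks^(-alpha)) / norm
  xmin + findInterval(runif(n), cdf)
}

random_coords <- function(n, rmax = 5) {
  tibble::tibble(node = seq_len(n), r = runif(n, 0, rmax),
                 theta = runif(n, 0, 2 * pi))
}
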