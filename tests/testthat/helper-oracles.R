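# independent oracles shared by the unit and acceptance suites

# exhaustive path-decomposition oracle: enumerate ALL simple paths, then run
# the same greedy max-bottleneck removal, choosing each round's path by
# scanning the full enumeration (max bottleneck, then shortest, then
# lexicographic) -- independent of the Dijkstra-style search in the package
brute_force_tpt_paths <- function(fnet, source, sink, tol = 1e-8) {
  n <- nrow(fnet)
  all_paths <- list()
  dfs <- function(path) {
    v <- path[length(path)]
    if (v %in% sink) {
      all_paths[[length(all_paths) + 1]] <<- path
      return()
    }
    for (u in which(fnet[v, ] > 0)) if (!(u %in% path)) dfs(c(path, u))
  }
  for (s in source) dfs(s)
  resid <- fnet
  out_paths <- list(); out_flux <- numeric(0)
  total <- sum(fnet[source, , drop = FALSE]) -
    sum(fnet[, source, drop = FALSE])
  repeat {
    bn <- vapply(all_paths, function(p) {
      min(resid[cbind(p[-length(p)], p[-1])])
    }, numeric(1))
    if (length(bn) == 0 || max(bn) <= tol * total) break
    cand <- which(bn == max(bn))
    len <- lengths(all_paths[cand])
    cand <- cand[len == min(len)]
    key <- vapply(all_paths[cand], paste, "", collapse = ",")
    pick <- cand[order(key)][1]
    p <- all_paths[[pick]]
    out_paths[[length(out_paths) + 1]] <- p
    out_flux <- c(out_flux, bn[pick])
    resid[cbind(p[-length(p)], p[-1])] <-
      resid[cbind(p[-length(p)], p[-1])] - bn[pick]
    if (sum(out_flux) >= total * (1 - tol)) break
  }
  ord <- order(-out_flux, vapply(out_paths, paste, "", collapse = ","))
  list(paths = out_paths[ord], flux = out_flux[ord], total = total)
}

# random connected reversible chain via a random symmetric count matrix
random_reversible_chain <- function(n) {
  C <- matrix(runif(n * n), n, n)
  C <- C + t(C)
  for (i in seq_len(n - 1)) C[i, i + 1] <- C[i + 1, i] <- C[i, i + 1] + 1
  C / rowSums(C)
}

# wrap an explicit transition matrix as an msm_model
make_msm <- function(Tm, lag = 1) {
  structure(list(C = Tm, T = Tm, pi = stationary_distribution(Tm),
                 timescales = numeric(0), active = seq_len(nrow(Tm)),
                 dtraj = list(), lag = lag, reversible = TRUE,
                 metastates = NULL), class = "msm_model")
}

# exhaustive simple-path enumeration oracle (no pruning)
all_paths_within <- function(net, src, snk, bound) {
  nn <- nrow(net$nodes)
  adjw <- matrix(Inf, nn, nn)
  adjw[cbind(net$edges$i, net$edges$j)] <- net$edges$weight
  adjw[cbind(net$edges$j, net$edges$i)] <- net$edges$weight
  found <- list(); wts <- numeric(0)
  dfs <- function(path, w) {
    v <- path[length(path)]
    if (v == snk) {
      if (w <= bound + 1e-12) {
        found[[length(found) + 1]] <<- path
        wts <<- c(wts, w)
      }
      return()
    }
    for (u in which(is.finite(adjw[v, ]))) {
      if (!(u %in% path)) dfs(c(path, u), w + adjw[v, u])
    }
  }
  dfs(src, 0)
  ord <- order(wts, vapply(found, paste, "", collapse = ","))
  list(paths = found[ord], weights = wts[ord])
}

# explicit weighted graph as a dynamic_network
fake_net <- function(el, w, n = max(el)) {
  g <- igraph::make_empty_graph(n, directed = FALSE)
  g <- igraph::add_edges(g, t(el))
  igraph::E(g)$weight <- w
  igraph::V(g)$name <- paste0("N", seq_len(n))
  structure(list(graph = g, nodes = data.frame(label = paste0("N", 1:n)),
                 edges = data.frame(i = el[, 1], j = el[, 2], weight = w)),
            class = "dynamic_network")
}
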