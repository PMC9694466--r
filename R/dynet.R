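#' Build a correlation-weighted dynamic network
#'
#' Nodes are protein residues (their Calpha/bead), every ligand heavy atom,
#' each ion, and one reference atom of the nucleotide (its C1'-equivalent).
#' A node pair gets an edge when its minimum heavy-atom distance stays
#' within the cutoff in at least the persistence fraction of frames and the
#' nodes are not sequence-adjacent residues (|i - j| > 1). Edges are
#' weighted by motion correlation: \code{C_ij = <dr_i . dr_j> /
#' sqrt(<|dr_i|^2> <|dr_j|^2>)} over superposed frames and
#' \code{w_ij = -log |C_ij|}, capped for |C| < 1e-6.
#'
#' @param traj a \code{toy_trajectory}.
#' @param structure a \code{param_structure}.
#' @param dist_cutoff contact distance (Angstrom, default 4.5).
#' @param persistence minimum contact fraction (default 0.75, compared
#'   with >=).
#' @param nucleotide_ref atom name used as the nucleotide node.
#' @param w_max weight cap (default -log(1e-6)).
#' @return object of class \code{dynamic_network}: \code{nodes}
#'   (data.frame), \code{persistence} (matrix), \code{C} (correlation
#'   matrix), \code{graph} (igraph, weighted), \code{edges} (data.frame).
#' @export
build_network <- function(traj, structure, dist_cutoff = 4.5,
                          persistence = 0.75, nucleotide_ref = "C1'",
                          w_max = -log(1e-6)) {
  nf <- n_frames(traj)
  if (nf < 2) .fail("network construction needs at least 2 frames")
  a <- structure$atoms
  nodes <- .network_nodes(structure, nucleotide_ref)
  nn <- nrow(nodes)
  # node member atoms (heavy) for the min-distance contact test
  members <- lapply(seq_len(nn), function(k) {
    if (nodes$kind[k] == "residue")
      which(a$resno == nodes$resno[k] & a$role == "protein" & a$elem != "H")
    else nodes$atom[k]
  })
  rep_atom <- nodes$atom
  # persistence fractions
  hit <- matrix(0, nn, nn)
  single <- all(lengths(members) == 1)
  for (t in seq_len(nf)) {
    xyz <- .frame(traj, t)
    if (single) {
      d <- as.matrix(dist(xyz[unlist(members), , drop = FALSE]))
    } else {
      d <- matrix(0, nn, nn)
      for (i in seq_len(nn - 1)) for (j in (i + 1):nn) {
        dd <- .cross_dist(xyz[members[[i]], , drop = FALSE],
                          xyz[members[[j]], , drop = FALSE])
        d[i, j] <- d[j, i] <- min(dd)
      }
    }
    hit <- hit + (d <= dist_cutoff)
  }
  pers <- hit / nf
  diag(pers) <- 1
  # correlations over superposed frames (fit on all nodes)
  pos <- array(0, c(nf, nn, 3))
  ref <- .frame(traj, traj$ref_frame)[rep_atom, , drop = FALSE]
  for (t in seq_len(nf)) {
    xyz <- .frame(traj, t)[rep_atom, , drop = FALSE]
    pos[t, , ] <- apply_transform(xyz, kabsch_superpose(xyz, ref))
  }
  m <- apply(pos, c(2, 3), mean)
  dx <- sweep(pos, c(2, 3), m)
  inner <- matrix(0, nn, nn)
  for (ax in 1:3) inner <- inner + crossprod(dx[, , ax]) / nf
  v <- diag(inner)
  if (any(v < 1e-12))
    .fail("zero fluctuation at node %d: correlations undefined",
          which(v < 1e-12)[1])
  C <- inner / sqrt(outer(v, v))
  C[C > 1] <- 1; C[C < -1] <- -1
  w <- -log(pmax(abs(C), exp(-w_max)))
  adj <- pers >= persistence
  diag(adj) <- FALSE
  seq_adj <- outer(nodes$seqid, nodes$seqid,
                   function(x, y) !is.na(x) & !is.na(y) & abs(x - y) <= 1)
  adj[seq_adj] <- FALSE
  ew <- which(adj & upper.tri(adj), arr.ind = TRUE)
  g <- igraph::make_empty_graph(n = nn, directed = FALSE)
  igraph::V(g)$name <- nodes$label
  if (nrow(ew)) {
    g <- igraph::add_edges(g, t(ew))
    igraph::E(g)$weight <- pmax(w[ew], 0)
  }
  edges <- data.frame(i = ew[, 1], j = ew[, 2],
                      persistence = pers[ew], C = C[ew], weight = w[ew])
  structure(list(nodes = nodes, persistence = pers, C = C, graph = g,
                 edges = edges, dist_cutoff = dist_cutoff,
                 min_persistence = persistence),
            class = "dynamic_network")
}

.network_nodes <- function(structure, nucleotide_ref = "C1'") {
  a <- structure$atoms
  out <- list()
  pres <- sort(unique(a$resno[a$role == "protein"]))
  for (r in pres) {
    cand <- which(a$resno == r & a$role == "protein")
    ca <- cand[a$name[cand] %in% c("CA", "CA ")]
    out[[length(out) + 1]] <- data.frame(
      label = paste0("R", r), kind = "residue", resno = r,
      atom = if (length(ca)) ca[1] else cand[1], seqid = r)
  }
  for (i in which(a$role == "ligand" & a$elem != "H"))
    out[[length(out) + 1]] <- data.frame(
      label = paste0("L:", a$name[i]), kind = "ligand", resno = a$resno[i],
      atom = i, seqid = NA_integer_)
  nuc <- which(a$role == "nucleotide" & a$name == nucleotide_ref)
  if (length(nuc) == 0)
    nuc <- which(a$role == "nucleotide")[1]
  if (length(nuc) && !is.na(nuc))
    out[[length(out) + 1]] <- data.frame(
      label = "NUC", kind = "nucleotide", resno = a$resno[nuc[1]],
      atom = nuc[1], seqid = NA_integer_)
  for (i in which(a$role == "ion"))
    out[[length(out) + 1]] <- data.frame(
      label = paste0("ION:", a$name[i]), kind = "ion", resno = a$resno[i],
      atom = i, seqid = NA_integer_)
  do.call(rbind, out)
}

#' @export
print.dynamic_network <- function(x, ...) {
  cat(sprintf("dynamic_network: %d nodes, %d edges (cutoff %.1f A, persistence >= %.2f)\n",
              nrow(x$nodes), nrow(x$edges), x$dist_cutoff,
              x$min_persistence))
  invisible(x)
}

#' Community decomposition of a dynamic network
#'
#' Girvan-Newman edge-betweenness removal (weights treated as distances),
#' cut at maximum weighted modularity. An edgeless graph yields one
#' community per node with modularity 0.
#'
#' @param net a \code{dynamic_network}.
#' @return list with \code{membership} (integer per node),
#'   \code{n_communities}, \code{modularity}.
#' @export
detect_communities <- function(net) {
  g <- net$graph
  if (igraph::ecount(g) == 0) {
    return(list(membership = seq_len(igraph::vcount(g)),
                n_communities = igraph::vcount(g), modularity = 0))
  }
  # igraph emits an informational warning that the membership is picked at
  # the maximum-modularity cut -- which is exactly the documented behavior
  cl <- suppressWarnings(
    igraph::cluster_edge_betweenness(g, weights = igraph::E(g)$weight,
                                     modularity = TRUE))
  memb <- igraph::membership(cl)
  list(membership = as.integer(memb),
       n_communities = length(unique(memb)),
       modularity = igraph::modularity(g, memb))
}

#' Optimal and suboptimal paths between two nodes
#'
#' The optimal path is the Dijkstra shortest path on the correlation
#' weights; every simple path with total weight within \code{tolerance} of
#' the optimum is enumerated exactly by depth-first search with
#' branch-and-bound pruning (partial weight plus the remaining shortest
#' distance to the sink). Per-node appearance counts cover all reported
#' paths.
#'
#' @param net a \code{dynamic_network}.
#' @param source,sink node indices (or labels).
#' @param tolerance weight tolerance above the optimal path weight.
#' @return object of class \code{path_report}: \code{optimal} (node index
#'   sequence), \code{optimal_weight}, \code{paths} (list, including the
#'   optimal), \code{weights}, \code{node_counts} (named vector).
#' @export
suboptimal_paths <- function(net, source, sink, tolerance = 0) {
  g <- net$graph
  nn <- igraph::vcount(g)
  src <- .node_index(net, source); snk <- .node_index(net, sink)
  dist_to_sink <- as.numeric(igraph::distances(g, v = igraph::V(g), to = snk,
                                               weights = igraph::E(g)$weight))
  if (!is.finite(dist_to_sink[src])) {
    comp <- igraph::components(g)
    .fail("nodes '%s' and '%s' are disconnected (components %d and %d)",
          net$nodes$label[src], net$nodes$label[snk],
          comp$membership[src], comp$membership[snk])
  }
  opt_w <- dist_to_sink[src]
  bound <- opt_w + tolerance + 1e-12
  adjw <- matrix(Inf, nn, nn)
  if (nrow(net$edges)) {
    adjw[cbind(net$edges$i, net$edges$j)] <- net$edges$weight
    adjw[cbind(net$edges$j, net$edges$i)] <- net$edges$weight
  }
  paths <- list(); weights <- numeric(0)
  visit <- rep(FALSE, nn)
  stack_path <- integer(0)
  dfs <- function(v, w) {
    if (v == snk) {
      paths[[length(paths) + 1]] <<- c(stack_path, v)
      weights <<- c(weights, w)
      return()
    }
    visit[v] <<- TRUE
    stack_path <<- c(stack_path, v)
    for (u in which(is.finite(adjw[v, ]))) {
      if (!visit[u] && w + adjw[v, u] + dist_to_sink[u] <= bound)
        dfs(u, w + adjw[v, u])
    }
    visit[v] <<- FALSE
    stack_path <<- stack_path[-length(stack_path)]
  }
  dfs(src, 0)
  ord <- order(weights, vapply(paths, paste, "", collapse = ","))
  paths <- paths[ord]; weights <- weights[ord]
  counts <- table(factor(unlist(paths), levels = seq_len(nn)))
  names(counts) <- net$nodes$label
  structure(list(source = src, sink = snk, optimal = paths[[1]],
                 optimal_weight = weights[1], paths = paths,
                 weights = weights, tolerance = tolerance,
                 node_counts = counts[counts > 0]),
            class = "path_report")
}

.node_index <- function(net, x) {
  if (is.character(x)) {
    i <- match(x, net$nodes$label)
    if (is.na(i)) .fail("unknown node '%s'", x)
    i
  } else as.integer(x)
}

#' @export
print.path_report <- function(x, ...) {
  cat(sprintf("path_report: optimal weight %.4g, %d paths within %.3g\n",
              x$optimal_weight, length(x$paths), x$tolerance))
  invisible(x)
}

#' Per-node change in allosteric path counts between two systems
#'
#' Delta = B - A of the per-node path appearance counts over the union of
#' node labels, sorted descending; a positive value means more signalling
#' pathways pass through the node in system B. The five largest increases
#' and decreases are flagged.
#'
#' @param reportA,reportB \code{path_report} objects (or named count
#'   vectors).
#' @return data.frame node, count_A, count_B, delta, top5_up, top5_down.
#' @export
allosteric_path_delta <- function(reportA, reportB) {
  ca <- if (inherits(reportA, "path_report")) reportA$node_counts else reportA
  cb <- if (inherits(reportB, "path_report")) reportB$node_counts else reportB
  u <- union(names(ca), names(cb))
  va <- as.numeric(ca[u]); va[is.na(va)] <- 0
  vb <- as.numeric(cb[u]); vb[is.na(vb)] <- 0
  out <- data.frame(node = u, count_A = va, count_B = vb, delta = vb - va)
  out <- out[order(-out$delta, out$node), , drop = FALSE]
  ups <- head(order(-out$delta), 5)
  downs <- head(order(out$delta), 5)
  out$top5_up <- seq_len(nrow(out)) %in% ups[out$delta[ups] > 0]
  out$top5_down <- seq_len(nrow(out)) %in% downs[out$delta[downs] < 0]
  rownames(out) <- NULL
  out
}
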