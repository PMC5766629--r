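#' @importFrom stats median p.adjust phyper rnorm runif sd setNames t.test var
#' @importFrom utils read.delim write.table combn head
NULL

#' Construct a simple undirected network
#'
#' Builds the package's basic network container from an edge table. The
#' network is always *simple*: self-loops are dropped and duplicate edges
#' (including reversed duplicates) are collapsed, mirroring how PPI edge
#' exports are cleaned before topological analysis.
#'
#' @param edges two-column character matrix or data frame of endpoints; may
#'   be empty.
#' @param nodes optional character vector of node IDs; defaults to the
#'   endpoints present in `edges`. Extra isolated nodes are allowed.
#' @param node_role optional named character vector mapping node ID to a role
#'   (`compound`, `target`, `protein`, `gene`, `metabolite`, `pathway`).
#' @return an object of class `netmet_network` with elements `nodes`
#'   (sorted character vector), `edges` (m x 2 character matrix in canonical
#'   order: each row sorted, rows sorted), `node_role`, and `n_self_loops`
#'   (count removed during simplification).
#' @export
network_new <- function(edges = NULL, nodes = NULL, node_role = NULL) {
  if (is.null(edges) || NROW(edges) == 0L) {
    em <- matrix(character(0), ncol = 2)
    n_loops <- 0L
  } else {
    em <- as.matrix(edges)[, 1:2, drop = FALSE]
    storage.mode(em) <- "character"
    em[] <- trimws(em)
    loops <- em[, 1] == em[, 2]
    n_loops <- sum(loops)
    em <- em[!loops, , drop = FALSE]
    if (nrow(em) > 0L) {
      swap <- em[, 1] > em[, 2]
      em[swap, ] <- em[swap, c(2, 1), drop = FALSE]
      em <- em[!duplicated(paste(em[, 1], em[, 2], sep = "\r")), , drop = FALSE]
      em <- em[order(em[, 1], em[, 2]), , drop = FALSE]
    }
  }
  nd <- sort(unique(c(as.character(em), trimws(as.character(nodes)))))
  nd <- nd[nd != ""]
  if (!is.null(node_role)) {
    bad <- setdiff(names(node_role), nd)
    if (length(bad)) {
      stop("node_role refers to unknown nodes: ", paste(bad, collapse = ", "))
    }
  }
  structure(
    list(nodes = nd, edges = unname(em), node_role = node_role,
         n_self_loops = as.integer(n_loops)),
    class = "netmet_network"
  )
}

#' @export
print.netmet_network <- function(x, ...) {
  cat("netmet_network:", length(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  if (!is.null(x$node_role)) {
    cat("roles:", paste(names(table(x$node_role)), table(x$node_role),
                        sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of nodes / edges
#' @param net a `netmet_network`.
#' @return integer count.
#' @export
n_nodes <- function(net) length(net$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(net) nrow(net$edges)

as_igraph <- function(net) {
  igraph::graph_from_data_frame(
    d = as.data.frame(net$edges, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = net$nodes, stringsAsFactors = FALSE)
  )
}

#' Read an undirected edge list
#'
#' Parses a delimited two-or-more-column edge list (STRING-export-like).
#' Lines starting with `#` are comments; columns beyond the first two are
#' ignored. The result is simplified: duplicate and reversed-duplicate
#' interactions are collapsed and self-loops are dropped (their count is
#' kept in the returned object and reported via a message).
#'
#' @param path file path or connection.
#' @param delimiter field separator (default tab).
#' @return a `netmet_network`.
#' @export
read_edge_list <- function(path, delimiter = "\t") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty edge list: no non-comment lines")
  parts <- strsplit(lines, delimiter, fixed = TRUE)
  nf <- vapply(parts, function(p) sum(nzchar(trimws(p))), integer(1))
  if (any(nf < 2L)) {
    stop("malformed edge-list line(s) with fewer than 2 fields: line ",
         paste(which(nf < 2L), collapse = ", "))
  }
  em <- t(vapply(parts, function(p) trimws(p[1:2]), character(2)))
  net <- network_new(em)
  if (net$n_self_loops > 0L) {
    message("read_edge_list: dropped ", net$n_self_loops, " self-loop(s)")
  }
  net
}

#' Write an edge list in canonical form
#'
#' Writes the simplified edge set with each edge's endpoints sorted and the
#' rows sorted, so write -> read round-trips to an identical network.
#'
#' @param net a `netmet_network`.
#' @param path output path.
#' @param delimiter field separator (default tab).
#' @export
write_edge_list <- function(net, path, delimiter = "\t") {
  write.table(net$edges, path, sep = delimiter, quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Per-node topology: degree, average shortest path length, betweenness
#'
#' Computes the topological parameters used for key-node analysis of PPI
#' networks. Distances are unweighted hop counts. The average shortest path
#' length of a node is the mean distance to the *other* nodes of its own
#' connected component (isolated nodes get `NA`). Betweenness is Brandes
#' betweenness normalized per component by 2/((N-1)(N-2)), N the component
#' size, so values lie in [0, 1]; components with N <= 2 get 0. This is the
#' NetworkAnalyzer convention under which a star center scores exactly 1.
#'
#' @param net a `netmet_network` with at least one node.
#' @return data frame with columns `node`, `degree`, `avg_shortest_path`,
#'   `betweenness`, `component_size`, one row per node (in `net$nodes` order).
#' @export
node_topology <- function(net) {
  if (n_nodes(net) == 0L) stop("empty network")
  g <- as_igraph(net)
  comp <- igraph::components(g)
  deg <- igraph::degree(g)
  asp <- rep(NA_real_, n_nodes(net))
  btw <- numeric(n_nodes(net))
  for (ci in seq_len(comp$no)) {
    idx <- which(comp$membership == ci)
    N <- length(idx)
    if (N == 1L) next
    sub <- igraph::induced_subgraph(g, idx)
    d <- igraph::distances(sub)
    asp[idx] <- rowSums(d) / (N - 1)
    if (N > 2L) {
      b <- igraph::betweenness(sub, directed = FALSE, normalized = FALSE)
      btw[idx] <- b * 2 / ((N - 1) * (N - 2))
    }
  }
  data.frame(
    node = net$nodes,
    degree = as.integer(deg[net$nodes]),
    avg_shortest_path = asp,
    betweenness = btw,
    component_size = as.integer(comp$csize[comp$membership]),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Average degree of a network
#'
#' @param net a `netmet_network` with at least one node.
#' @return 2 * |edges| / |nodes|.
#' @export
average_degree <- function(net) {
  if (n_nodes(net) == 0L) stop("empty network")
  2 * n_edges(net) / n_nodes(net)
}

#' Assemble a tripartite compound-target-metabolite network
#'
#' Unions three layers into one role-tagged network: compound -> target
#' edges, the target/protein interaction layer, and gene -> metabolite
#' edges. Roles already present in `target_protein_edges` are preserved;
#' other protein-layer nodes are tagged `target` when they appear in the
#' compound map, `gene` when they appear in the gene->metabolite map, and
#' `protein` otherwise.
#'
#' @param compound_target named list: compound ID -> character vector of
#'   target IDs.
#' @param target_protein_edges optional `netmet_network` of the protein
#'   interaction layer (may be NULL).
#' @param gene_metabolite named list: gene ID -> character vector of
#'   metabolite IDs (may be empty).
#' @return a `netmet_network` with `node_role` populated.
#' @export
build_tripartite <- function(compound_target, target_protein_edges = NULL,
                             gene_metabolite = list()) {
  if (length(compound_target) == 0L) stop("compound_target map is empty")
  pair_mat <- function(maplist) {
    do.call(rbind, lapply(names(maplist), function(p) {
      kids <- unique(as.character(maplist[[p]]))
      if (length(kids) == 0L) return(NULL)
      cbind(p, kids)
    }))
  }
  ct <- pair_mat(compound_target)
  gm <- pair_mat(gene_metabolite)
  pp <- if (!is.null(target_protein_edges)) target_protein_edges$edges else NULL
  edges <- rbind(ct, pp, gm)

  role <- character(0)
  add_role <- function(role, ids, r) {
    new <- setdiff(ids, names(role))
    conflict <- intersect(ids, names(role))
    conflict <- conflict[role[conflict] != r]
    if (length(conflict)) {
      stop("node(s) assigned conflicting roles: ", paste(conflict, collapse = ", "))
    }
    c(role, setNames(rep(r, length(new)), new))
  }
  role <- add_role(role, names(compound_target), "compound")
  role <- add_role(role, unique(unlist(compound_target, use.names = FALSE)), "target")
  if (length(gene_metabolite)) {
    role <- add_role(role, names(gene_metabolite), "gene")
    role <- add_role(role, unique(unlist(gene_metabolite, use.names = FALSE)), "metabolite")
  }
  if (!is.null(target_protein_edges)) {
    if (!is.null(target_protein_edges$node_role)) {
      pr <- target_protein_edges$node_role
      for (nm in names(pr)) role <- add_role(role, nm, pr[[nm]])
    }
    rest <- setdiff(target_protein_edges$nodes, names(role))
    role <- add_role(role, rest, "protein")
  }
  network_new(edges, nodes = names(role), node_role = role)
}

#' Node degrees restricted to neighbors of a given role
#'
#' Convenience accessor for tripartite networks, e.g. how many *target*
#' nodes a compound touches.
#'
#' @param net a role-tagged `netmet_network`.
#' @param node node ID.
#' @param role neighbor role to count.
#' @return integer count of neighbors holding `role`.
#' @export
degree_to_role <- function(net, node, role) {
  if (is.null(net$node_role)) stop("network has no node roles")
  e <- net$edges
  nb <- c(e[e[, 1] == node, 2], e[e[, 2] == node, 1])
  sum(net$node_role[nb] == role, na.rm = TRUE)
}
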