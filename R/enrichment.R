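#' Read a gene-set collection in GMT format
#'
#' GMT dialect: one set per line, `name TAB description TAB gene1 TAB ...`.
#' Duplicate genes within a line are stored once; empty sets are dropped
#' with a warning. Unless an explicit `universe` is supplied, the universe
#' is the union of all set members (annotation-restricted semantics).
#'
#' @param path GMT file path or connection.
#' @param universe optional character vector overriding the default universe;
#'   sets are restricted to it.
#' @return list with elements `sets` (named list of character vectors),
#'   `descriptions` (named character), `universe` (character vector).
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3L)) {
    stop("GMT line(s) with fewer than 3 fields: line ",
         paste(which(nf < 3L), collapse = ", "))
  }
  nm <- vapply(parts, `[`, character(1), 1L)
  desc <- vapply(parts, `[`, character(1), 2L)
  sets <- lapply(parts, function(p) unique(trimws(p[-(1:2)])))
  sets <- lapply(sets, function(s) s[nzchar(s)])
  names(sets) <- nm
  names(desc) <- nm
  if (is.null(universe)) {
    universe <- sort(unique(unlist(sets, use.names = FALSE)))
  } else {
    universe <- sort(unique(universe))
    sets <- lapply(sets, intersect, y = universe)
  }
  empty <- lengths(sets) == 0L
  if (any(empty)) {
    warning("dropping ", sum(empty), " empty gene set(s): ",
            paste(nm[empty], collapse = ", "))
    sets <- sets[!empty]
    desc <- desc[!empty]
  }
  list(sets = sets, descriptions = desc, universe = universe)
}

#' Write a gene-set collection in GMT format
#'
#' @param coll collection as returned by [read_gmt()].
#' @param path output path.
#' @export
write_gmt <- function(coll, path) {
  desc <- coll$descriptions
  if (is.null(desc)) desc <- setNames(rep("na", length(coll$sets)), names(coll$sets))
  lines <- vapply(names(coll$sets), function(nm) {
    paste(c(nm, desc[[nm]], coll$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric gene-set over-representation
#'
#' One-sided over-representation test of a query gene list against each set
#' of a collection: p = P[X >= k] with X hypergeometric(|universe|, |set|,
#' |query|) and k the observed overlap. Query genes outside the universe are
#' dropped (with a message). Benjamini-Hochberg FDR is computed across all
#' tested sets; the returned table keeps sets with p <= `p_cutoff`, sorted
#' ascending by p.
#'
#' @param query character vector of gene IDs.
#' @param coll collection from [read_gmt()].
#' @param p_cutoff nominal p-value reporting cutoff (default 0.001, the
#'   convention used for pathway nomination in this workflow).
#' @return data frame with columns `pathway`, `p`, `fdr`, `k`, `set_size`,
#'   `hits` (comma-joined overlapping genes).
#' @export
hypergeom_enrich <- function(query, coll, p_cutoff = 0.001) {
  query <- unique(as.character(query))
  dropped <- setdiff(query, coll$universe)
  if (length(dropped)) {
    message("hypergeom_enrich: dropping ", length(dropped),
            " query gene(s) outside the universe")
  }
  query <- intersect(query, coll$universe)
  if (length(query) == 0L) stop("query is empty after restriction to universe")
  N <- length(coll$universe)
  n <- length(query)
  res <- lapply(names(coll$sets), function(nm) {
    s <- coll$sets[[nm]]
    hits <- intersect(query, s)
    k <- length(hits)
    # P[X >= k]; phyper lower.tail=FALSE gives P[X > k-1]
    p <- phyper(k - 1, length(s), N - length(s), n, lower.tail = FALSE)
    data.frame(pathway = nm, p = p, k = k, set_size = length(s),
               hits = paste(sort(hits), collapse = ","),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$fdr <- bh_fdr(res$p)
  res <- res[res$p <= p_cutoff, , drop = FALSE]
  res <- res[order(res$p, res$pathway), , drop = FALSE]
  rownames(res) <- NULL
  res[, c("pathway", "p", "fdr", "k", "set_size", "hits")]
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment: sorted p-values are scaled by
#' m/i, enforced monotone from the largest down, and capped at 1.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return adjusted values, same order as the input.
#' @export
bh_fdr <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' MetPA-style pathway impact
#'
#' Topological impact of a set of matched (differential) metabolites on a
#' pathway graph: the sum of relative betweenness centrality over matched
#' nodes divided by the sum over all nodes, so impact lies in [0, 1] and
#' equals 1 when every (centrality-carrying) node is matched and 0 when
#' none is. Centralities come from [node_topology()] (per-component
#' normalized betweenness).
#'
#' @param pathway_graph a `netmet_network` of the pathway's metabolites.
#' @param matched character vector of matched metabolite node IDs.
#' @return impact score in [0, 1].
#' @export
pathway_impact <- function(pathway_graph, matched) {
  matched <- unique(as.character(matched))
  missing <- setdiff(matched, pathway_graph$nodes)
  if (length(missing)) {
    stop("matched metabolite(s) absent from pathway graph: ",
         paste(missing, collapse = ", "))
  }
  if (length(matched) == 0L) return(0)
  topo <- node_topology(pathway_graph)
  tot <- sum(topo$betweenness)
  if (tot == 0) return(0)
  sum(topo$betweenness[topo$node %in% matched]) / tot
}
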