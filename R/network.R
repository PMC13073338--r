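#' Select root nodes for network growth
#'
#' The k differentially-expressed genes with the highest degree in the
#' background interactome; ties are broken lexicographically by gene symbol.
#' DEP genes absent from the background are excluded with a warning.
#'
#' @param dep_genes Character vector of DEP gene symbols.
#' @param background Background interactome (igraph, undirected).
#' @param k Number of roots (clamped to the number of in-background DEPs).
#' @return Character vector of root gene symbols.
#' @export
select_roots <- function(dep_genes, background, k = 5L) {
  stopifnot(k >= 1L)
  dep_genes <- unique(dep_genes)
  present <- dep_genes[dep_genes %in% igraph::V(background)$name]
  if (length(present) == 0L) stop("no DEP gene present in the background network")
  if (length(present) < length(dep_genes)) {
    warning(length(dep_genes) - length(present),
            " DEP gene(s) absent from the background network; excluded")
  }
  deg <- igraph::degree(background, v = present)
  present[order(-deg, present)][seq_len(min(k, length(present)))]
}

#' Grow a signaling subnetwork by iterative shortest paths
#'
#' Starting from the root set (a null network with no edges), repeatedly finds
#' the remaining candidate DEP gene with the smallest unweighted shortest-path
#' distance from any current network node, and adds that candidate together
#' with all intermediate nodes and edges of the chosen path. Growth stops when
#' every DEP is in the network or unreachable. Ties are resolved
#' deterministically: the lexicographically smallest candidate symbol first,
#' then the lexicographically smallest path (node sequence read from the
#' network side). Candidates in components containing no network node are
#' reported as unreachable.
#'
#' @param dep_genes Character vector of DEP gene symbols.
#' @param background Background interactome (igraph, undirected, unweighted).
#' @param roots Root symbols, a subset of the in-background DEP genes
#'   (default: [select_roots()] with k = 5).
#' @return A list of class \code{grown_network}: \code{graph} (igraph
#'   subnetwork), \code{nodes} (data frame \code{node, role} with role in
#'   root/dep/connector), \code{unreachable}, and \code{order} (candidate
#'   addition order).
#' @export
grow_network <- function(dep_genes, background, roots = NULL) {
  dep_genes <- unique(dep_genes)
  bg_names <- igraph::V(background)$name
  deps_in <- dep_genes[dep_genes %in% bg_names]
  if (is.null(roots)) roots <- select_roots(dep_genes, background)
  if (!all(roots %in% deps_in)) {
    stop("roots must be DEP genes present in the background network")
  }
  unreachable <- setdiff(dep_genes, deps_in)

  net_nodes <- sort(unique(roots))
  edges <- matrix(character(0), ncol = 2L)
  candidates <- sort(setdiff(deps_in, net_nodes))
  added <- character(0)

  while (length(candidates) > 0L) {
    dmat <- igraph::distances(background, v = candidates, to = net_nodes)
    mind <- apply(dmat, 1L, min)
    if (all(is.infinite(mind))) {
      unreachable <- c(unreachable, candidates)
      break
    }
    gmin <- min(mind)
    chosen <- candidates[mind == gmin][1L]     # candidates sorted -> lexicographic tie rule
    targets <- net_nodes[dmat[chosen, ] == gmin]
    asp <- igraph::all_shortest_paths(background, from = chosen, to = targets)
    paths <- if (!is.null(asp$res)) asp$res else asp$vpaths
    paths <- lapply(paths, function(p) names(p))
    paths <- Filter(function(p) length(p) == gmin + 1L, paths)
    # orient network -> candidate and pick the lexicographically smallest
    keys <- vapply(paths, function(p) paste(rev(p), collapse = "\r"), character(1L))
    path <- rev(paths[[order(keys)[1L]]])      # net node ... candidate
    if (length(path) > 1L) {
      new_edges <- cbind(path[-length(path)], path[-1L])
      edges <- rbind(edges, new_edges)
    }
    net_nodes <- sort(unique(c(net_nodes, path)))
    added <- c(added, chosen)
    candidates <- sort(setdiff(candidates, net_nodes))
  }

  # dedupe undirected edges
  if (nrow(edges) > 0L) {
    key <- apply(edges, 1L, function(e) paste(sort(e), collapse = "\r"))
    edges <- edges[!duplicated(key), , drop = FALSE]
  }
  g <- igraph::graph_from_data_frame(
    if (nrow(edges) > 0L) data.frame(from = edges[, 1L], to = edges[, 2L])
    else data.frame(from = character(0), to = character(0)),
    directed = FALSE,
    vertices = data.frame(name = net_nodes))
  role <- ifelse(net_nodes %in% roots, "root",
                 ifelse(net_nodes %in% dep_genes, "dep", "connector"))
  structure(list(graph = g,
                 nodes = data.frame(node = net_nodes, role = role,
                                    stringsAsFactors = FALSE),
                 unreachable = unname(unreachable), order = added),
            class = "grown_network")
}

#' @export
print.grown_network <- function(x, ...) {
  tab <- table(x$nodes$role)
  cat("Grown signaling subnetwork:", nrow(x$nodes), "nodes,",
      igraph::ecount(x$graph), "edges\n")
  cat("  roles:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  if (length(x$unreachable)) {
    cat("  unreachable DEPs:", paste(x$unreachable, collapse = ", "), "\n")
  }
  invisible(x)
}
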