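#' Build a module's functional-interaction subnetwork
#'
#' Induces the subgraph of a user-supplied undirected edge list on the
#' module's genes. With `use_linkers`, every non-module gene adjacent to at
#' least `min_linker_degree` module genes is admitted as a linker, together
#' with its linker-module edges (linkers only ever add connectivity between
#' module genes; they never mediate module-module edges that already exist).
#' Module genes absent from the edge list are retained as isolated nodes and
#' count as unconnected.
#'
#' @param module A `gene_module` or character vector of gene IDs (non-empty).
#' @param edges An edge list tibble (see [read_edge_list()] / [edge_list()]).
#' @param use_linkers Admit linker genes (default `TRUE`).
#' @param min_linker_degree Minimum number of distinct module neighbors for a
#'   linker (default 2, the usual functional-interaction plugin behavior).
#' @return An `fi_network`: an igraph graph with vertex attributes `role`
#'   (`module_gene` / `linker_gene`).
#' @export
build_fi_subnetwork <- function(module, edges, use_linkers = TRUE,
                                min_linker_degree = 2L) {
  genes <- sort(unique(module_genes(module)))
  if (length(genes) == 0L) stop_comod("module is empty", "comod_validation_error")
  edges <- edge_list(edges)
  in_a <- edges$from %in% genes
  in_b <- edges$to %in% genes
  mod_edges <- edges[in_a & in_b, c("from", "to"), drop = FALSE]
  linkers <- character(0)
  link_edges <- mod_edges[0, ]
  if (use_linkers) {
    half <- edges[xor(in_a, in_b), , drop = FALSE]
    outside <- ifelse(half$from %in% genes, half$to, half$from)
    inside <- ifelse(half$from %in% genes, half$from, half$to)
    deg <- tapply(inside, outside, function(g) length(unique(g)))
    linkers <- sort(names(deg)[deg >= min_linker_degree])
    keep <- outside %in% linkers
    link_edges <- tibble(from = inside[keep], to = outside[keep])
  }
  all_edges <- rbind(mod_edges, link_edges)
  g <- igraph::graph_from_data_frame(
    all_edges, directed = FALSE,
    vertices = tibble(name = c(genes, linkers),
                      role = c(rep("module_gene", length(genes)),
                               rep("linker_gene", length(linkers)))))
  class(g) <- c("fi_network", class(g))
  g
}

#' Fraction of module genes connected in the FI network
#'
#' The proportion of module genes with at least one edge in the subnetwork.
#'
#' @param network An `fi_network`.
#' @return A number in \[0, 1\].
#' @export
connected_fraction <- function(network) {
  role <- igraph::V(network)$role
  deg <- igraph::degree(network)
  mod <- role == "module_gene"
  if (!any(mod)) return(NA_real_)
  mean(deg[mod] >= 1)
}

#' Dissect an FI network into sub-modules
#'
#' Greedy modularity maximization (a deterministic stand-in for the
#' functional-interaction plugin's unnamed clustering), applied to every
#' connected component with at least two nodes; components are processed in
#' lexicographic node order so results are reproducible. Sub-modules are
#' labeled `M1`, `M2`, ... in decreasing size; isolated nodes go to the
#' `residual` group (the genes not connected to the network).
#'
#' @param network An `fi_network`.
#' @param seed Unused by the deterministic algorithm; kept for interface
#'   stability.
#' @return A `submodule_partition` tibble with columns `gene`, `role`,
#'   `degree`, `submodule`, and the total modularity as attribute
#'   `modularity`.
#' @export
cluster_network <- function(network, seed = 1L) {
  nm <- igraph::V(network)$name
  ord <- order(nm)
  # rebuild with lexicographic vertex order so greedy tie-breaks are fixed
  vtab <- tibble(name = nm[ord], role = igraph::V(network)$role[ord])
  etab <- igraph::as_data_frame(network, what = "edges")
  g <- igraph::graph_from_data_frame(etab, directed = FALSE, vertices = vtab)
  comp <- igraph::components(g)
  groups <- list()
  modularity_total <- 0
  for (ci in seq_len(comp$no)) {
    vids <- which(comp$membership == ci)
    if (length(vids) < 2L) next
    sub <- igraph::induced_subgraph(g, vids)
    if (igraph::ecount(sub) == 0L) next
    cl <- igraph::cluster_fast_greedy(sub)
    if (igraph::modularity(cl) > 1e-12) {
      modularity_total <- modularity_total + igraph::modularity(cl)
      groups <- c(groups, unname(igraph::communities(cl)))
    } else {
      # no split beats the undivided component (e.g. a clique)
      groups <- c(groups, list(igraph::V(sub)$name))
    }
  }
  clustered <- unlist(groups)
  sizes <- lengths(groups)
  groups <- groups[order(-sizes, vapply(groups, function(x) sort(x)[1], character(1)))]
  labels <- setNames(rep("residual", igraph::vcount(g)), igraph::V(g)$name)
  for (i in seq_along(groups)) labels[groups[[i]]] <- paste0("M", i)
  out <- tibble(gene = igraph::V(g)$name,
                role = igraph::V(g)$role,
                degree = igraph::degree(g),
                submodule = unname(labels[igraph::V(g)$name]))
  out <- out[order(out$submodule, out$gene), , drop = FALSE]
  attr(out, "modularity") <- modularity_total
  class(out) <- unique(c("submodule_partition", class(out)))
  out
}

#' Hub genes of an FI network
#'
#' Nodes with at least `min_degree` neighbors (default 10), with their role
#' retained so hub counts can be split into module vs linker genes.
#'
#' @param network An `fi_network`.
#' @param min_degree Hub threshold (default 10).
#' @return Tibble with columns `gene`, `degree`, `role`, sorted by
#'   decreasing degree.
#' @export
hub_genes <- function(network, min_degree = 10L) {
  deg <- igraph::degree(network)
  keep <- deg >= min_degree
  out <- tibble(gene = igraph::V(network)$name[keep],
                degree = unname(deg[keep]),
                role = igraph::V(network)$role[keep])
  out[order(-out$degree, out$gene), , drop = FALSE]
}

#' Plot sub-module sizes
#'
#' @param object A `submodule_partition`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot submodule_partition
#' @export
autoplot.submodule_partition <- function(object, ...) {
  counts <- dplyr::count(as_tibble(object), .data$submodule, .data$role)
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$submodule, y = .data$n, fill = .data$role)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "sub-module", y = "genes", fill = NULL,
                  title = "FI sub-module composition")
}
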