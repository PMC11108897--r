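#' Pairwise correlation matrix with significance for network construction
#'
#' Spearman (default) or Pearson correlations between all ASV pairs across
#' samples, with two-sided p-values from the t approximation
#' `t = r * sqrt((n - 2) / (1 - r^2))`. Constant columns correlate with
#' everything at `r = 0`, `p = 1`.
#'
#' @param rel_abund Samples x ASVs matrix (both kingdoms aligned on the
#'   same samples), >= 4 samples.
#' @param method `"spearman"` or `"pearson"`.
#' @return Object of class `corr_matrix`: `r`, `p`, `node_ids`, `method`.
#' @export
correlation_matrix <- function(rel_abund, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  m <- as.matrix(rel_abund)
  n <- nrow(m)
  if (n < 4) stop("at least 4 shared samples are required")
  if (is.null(colnames(m))) colnames(m) <- paste0("node_", seq_len(ncol(m)))
  constant <- apply(m, 2, function(x) stats::var(x) == 0)
  r <- suppressWarnings(stats::cor(m, method = method))
  r[constant, ] <- 0
  r[, constant] <- 0
  diag(r) <- 1
  tstat <- r * sqrt(pmax(n - 2, 0) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(r) >= 1] <- 0
  p[constant, ] <- 1
  p[, constant] <- 1
  diag(p) <- 0
  structure(
    list(r = r, p = p, node_ids = colnames(m), method = method),
    class = "corr_matrix"
  )
}

#' Build a co-occurrence network from a correlation matrix
#'
#' Places an undirected edge between nodes i and j when `|r_ij| >= r_min`
#' and `p_ij < p_max`; isolated nodes are retained; the sign of each
#' correlation is recorded on the edge.
#'
#' @param corr A `corr_matrix`.
#' @param r_min Correlation-magnitude cutoff in `(0, 1)`.
#' @param p_max Significance cutoff.
#' @param node_meta Optional data frame with `node_id` plus annotation
#'   columns (`kingdom`, taxonomy ranks, ...), carried onto the nodes.
#' @return Object of class `cooc_network`: `graph` (igraph), `nodes`
#'   (data frame), `edges` (data frame with `from`, `to`, `r`, `sign`).
#' @export
build_network <- function(corr, r_min = 0.6, p_max = 0.001, node_meta = NULL) {
  if (r_min <= 0 || r_min >= 1) stop("r_min must lie in (0, 1)")
  ids <- corr$node_ids
  adj <- abs(corr$r) >= r_min & corr$p < p_max
  diag(adj) <- FALSE
  idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  edges <- data.frame(
    from = ids[idx[, 1]],
    to = ids[idx[, 2]],
    r = corr$r[idx],
    sign = ifelse(corr$r[idx] >= 0, "positive", "negative"),
    stringsAsFactors = FALSE
  )
  g <- igraph::graph_from_data_frame(
    edges[, c("from", "to")],
    directed = FALSE,
    vertices = data.frame(name = ids, stringsAsFactors = FALSE)
  )
  nodes <- data.frame(node_id = ids, degree = as.numeric(igraph::degree(g)),
                      stringsAsFactors = FALSE)
  if (!is.null(node_meta)) {
    node_meta <- as.data.frame(node_meta, stringsAsFactors = FALSE)
    if (!"node_id" %in% names(node_meta)) stop("node_meta needs a node_id column")
    nodes <- merge(nodes, node_meta, by = "node_id", all.x = TRUE, sort = FALSE)
    nodes <- nodes[match(ids, nodes$node_id), , drop = FALSE]
    rownames(nodes) <- NULL
  }
  structure(list(graph = g, nodes = nodes, edges = edges), class = "cooc_network")
}

#' @export
print.cooc_network <- function(x, ...) {
  cat(sprintf("cooc_network: %d nodes, %d edges", nrow(x$nodes), nrow(x$edges)))
  if ("module" %in% names(x$nodes)) {
    cat(sprintf(", %d modules", length(unique(x$nodes$module))))
  }
  cat("\n")
  invisible(x)
}

#' Detect network modules by greedy modularity maximisation
#'
#' Non-overlapping modules on the unweighted graph via fast-greedy
#' modularity optimisation; singleton (isolated) nodes each form their own
#' module. Deterministic for a fixed graph; `seed` is accepted for
#' interface stability and pins the RNG for reproducibility.
#'
#' @param net A `cooc_network`.
#' @param seed Integer seed.
#' @return The network with a `module` column added to `nodes`.
#' @export
detect_modules <- function(net, seed = 1L) {
  g <- net$graph
  membership <- with_seed(seed, {
    if (igraph::ecount(g) == 0) {
      seq_len(igraph::vcount(g))
    } else {
      as.integer(igraph::membership(igraph::cluster_fast_greedy(g)))
    }
  })
  net$nodes$module <- membership[match(net$nodes$node_id,
                                       igraph::V(g)$name)]
  net
}

#' Within-module degree (Zi) and among-module connectivity (Pi)
#'
#' `Zi` is the z-score of a node's within-module degree relative to all
#' nodes of its module (0 when the module's within-degrees have zero
#' spread). `Pi = 1 - sum_s (k_is / k_i)^2` over modules s, 0 for isolated
#' nodes. Roles follow the keystone taxonomy: module hubs (`Zi > zi_thr`,
#' `Pi <= pi_thr`), connectors (`Zi <= zi_thr`, `Pi > pi_thr`), network
#' hubs (both exceeded), peripherals otherwise.
#'
#' @param net A `cooc_network` with modules assigned.
#' @param zi_thr,pi_thr Role thresholds (defaults 0.25 and 0.62).
#' @return The network with `zi`, `pi`, `role` columns added to `nodes`.
#' @export
zi_pi <- function(net, zi_thr = 0.25, pi_thr = 0.62) {
  if (!"module" %in% names(net$nodes)) stop("run detect_modules() first")
  g <- net$graph
  ids <- net$nodes$node_id
  module <- net$nodes$module
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  adj <- adj[match(ids, rownames(adj)), match(ids, colnames(adj)), drop = FALSE]
  k <- rowSums(adj)
  stopifnot(all(k == net$nodes$degree))
  mods <- sort(unique(module))
  # k_is: links from each node into each module
  k_is <- vapply(mods, function(s) rowSums(adj[, module == s, drop = FALSE]),
                 numeric(length(ids)))
  if (length(ids) == 1) k_is <- matrix(k_is, nrow = 1)
  within <- k_is[cbind(seq_along(ids), match(module, mods))]
  zi <- numeric(length(ids))
  for (s in mods) {
    sel <- module == s
    mu <- mean(within[sel])
    sdev <- stats::sd(within[sel])
    zi[sel] <- if (is.na(sdev) || sdev == 0) 0 else (within[sel] - mu) / sdev
  }
  pi <- ifelse(k == 0, 0, 1 - rowSums((k_is / pmax(k, 1))^2))
  net$nodes$zi <- zi
  net$nodes$pi <- pi
  net$nodes$role <- classify_role(zi, pi, zi_thr = zi_thr, pi_thr = pi_thr)
  net
}

#' Classify a node's topological role from (Zi, Pi)
#'
#' @param zi,pi Numeric vectors of within-module z-scores and participation
#'   coefficients.
#' @param zi_thr,pi_thr Thresholds separating hubs and connectors.
#' @return Character vector over `{"peripheral", "module hub",
#'   "connector", "network hub"}`; every (Zi, Pi) maps to exactly one role.
#' @export
classify_role <- function(zi, pi, zi_thr = 0.25, pi_thr = 0.62) {
  ifelse(zi > zi_thr & pi > pi_thr, "network hub",
    ifelse(zi > zi_thr, "module hub",
      ifelse(pi > pi_thr, "connector", "peripheral")))
}

#' Betweenness centrality
#'
#' Unnormalised shortest-path betweenness: for each node i, the sum over
#' unordered node pairs (s, t), endpoints excluded, of the fraction of
#' shortest s-t paths passing through i.
#'
#' @param net A `cooc_network`.
#' @return Named numeric vector of BC values (>= 0).
#' @export
betweenness_centrality <- function(net) {
  bc <- igraph::betweenness(net$graph, directed = FALSE, normalized = FALSE)
  stats::setNames(as.numeric(bc), igraph::V(net$graph)$name)[net$nodes$node_id]
}

#' Closeness centrality restricted to reachable nodes
#'
#' `CC_i = 1 / d_i`, where `d_i` is the mean shortest-path distance from i
#' to the other nodes of its connected component (reachable nodes only);
#' isolated nodes get `CC = 0`.
#'
#' @param net A `cooc_network`.
#' @return Named numeric vector of CC values (>= 0).
#' @export
closeness_centrality <- function(net) {
  d <- igraph::distances(net$graph)
  cc <- apply(d, 1, function(row) {
    reach <- row[is.finite(row) & row > 0]
    if (!length(reach)) 0 else 1 / mean(reach)
  })
  stats::setNames(as.numeric(cc), rownames(d))[net$nodes$node_id]
}

#' Attach betweenness and closeness centralities to the node table
#'
#' @param net A `cooc_network`.
#' @return The network with `bc` and `cc` columns added to `nodes`.
#' @export
network_centralities <- function(net) {
  net$nodes$bc <- unname(betweenness_centrality(net))
  net$nodes$cc <- unname(closeness_centrality(net))
  net
}

#' Whole-network summary statistics
#'
#' @param net A `cooc_network`.
#' @return List with `n_nodes`, `n_edges`, `average_degree` (`2E/N`),
#'   `average_path_length` (mean shortest-path distance over connected
#'   unordered pairs; `NA` for an edgeless graph), `n_modules` (if
#'   assigned) and `role_counts` (if roles assigned).
#' @export
network_summary <- function(net) {
  n <- nrow(net$nodes)
  e <- nrow(net$edges)
  apl <- if (e == 0) NA_real_ else {
    igraph::mean_distance(net$graph, directed = FALSE, unconnected = TRUE)
  }
  out <- list(
    n_nodes = n,
    n_edges = e,
    average_degree = if (n > 0) 2 * e / n else NA_real_,
    average_path_length = apl
  )
  if ("module" %in% names(net$nodes)) {
    out$n_modules <- length(unique(net$nodes$module))
  }
  if ("role" %in% names(net$nodes)) {
    out$role_counts <- table(factor(net$nodes$role,
      levels = c("peripheral", "module hub", "connector", "network hub")))
  }
  out
}

#' Compare centrality distributions between kingdoms
#'
#' Wilcoxon rank-sum tests of betweenness and closeness centrality between
#' fungal and bacterial nodes, counts of nodes above a betweenness
#' threshold per kingdom, and the roster of non-peripheral (connector/hub)
#' nodes with their annotations.
#'
#' @param net A `cooc_network` whose nodes carry `kingdom` and, for the
#'   role roster, `role`; centralities are computed if absent.
#' @param bc_threshold Betweenness exceedance threshold.
#' @return List with `bc_test`, `cc_test` (statistic + p-value),
#'   `median_bc`, `median_cc` (per kingdom), `exceed_bc` (counts above the
#'   threshold per kingdom) and `keystone_nodes`.
#' @export
cross_kingdom_compare <- function(net, bc_threshold = 1000) {
  if (!"kingdom" %in% names(net$nodes)) stop("nodes carry no kingdom annotation")
  if (!all(c("bc", "cc") %in% names(net$nodes))) net <- network_centralities(net)
  nodes <- net$nodes
  kings <- unique(nodes$kingdom)
  if (!all(c("bacteria", "fungi") %in% kings)) {
    stop("both kingdoms must be present among the nodes")
  }
  fung <- nodes[nodes$kingdom == "fungi", ]
  bact <- nodes[nodes$kingdom == "bacteria", ]
  keystones <- if ("role" %in% names(nodes)) {
    nodes[nodes$role != "peripheral", , drop = FALSE]
  } else NULL
  list(
    bc_test = wilcoxon_rank_sum(fung$bc, bact$bc),
    cc_test = wilcoxon_rank_sum(fung$cc, bact$cc),
    median_bc = c(fungi = stats::median(fung$bc), bacteria = stats::median(bact$bc)),
    median_cc = c(fungi = stats::median(fung$cc), bacteria = stats::median(bact$cc)),
    exceed_bc = c(fungi = sum(fung$bc > bc_threshold),
                  bacteria = sum(bact$bc > bc_threshold)),
    keystone_nodes = keystones
  )
}

#' Write a network to disk
#'
#' Writes the graph as GraphML plus two TSV tables: the edge list
#' (`from`, `to`, `r`, `sign`) and the node metrics.
#'
#' @param net A `cooc_network`.
#' @param graphml_path,edges_path,nodes_path Destinations (any may be
#'   `NULL` to skip).
#' @return Invisibly, `net`.
#' @export
write_network <- function(net, graphml_path = NULL, edges_path = NULL,
                          nodes_path = NULL) {
  if (!is.null(graphml_path)) {
    igraph::write_graph(net$graph, graphml_path, format = "graphml")
  }
  if (!is.null(edges_path)) {
    utils::write.table(net$edges, edges_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(nodes_path)) {
    utils::write.table(net$nodes, nodes_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(net)
}
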