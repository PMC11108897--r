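# Shared fixtures and independent brute-force oracles for the test suite.

# A small hand-checkable table: 3 samples x 4 ASVs across both compartments.
toy_table <- function() {
  counts <- matrix(
    c(5L, 0L, 3L, 2L,
      4L, 1L, 0L, 6L,
      2L, 0L, 1L, 7L),
    nrow = 3, byrow = TRUE,
    dimnames = list(c("s1", "s2", "s3"), c("a1", "a2", "a3", "a4"))
  )
  meta <- data.frame(
    sample_id = c("s1", "s2", "s3"),
    compartment = c("bulk", "rhizosphere", "rhizosphere"),
    host_family = "Gramineae",
    kingdom = "bacteria",
    stringsAsFactors = FALSE
  )
  tax <- data.frame(
    asv_id = c("a1", "a2", "a3", "a4"),
    kingdom = "Bacteria", phylum = "p", class = "c", order = "o",
    family = "f", genus = c("G1", "G1", "G2", "G2"), species = "s",
    stringsAsFactors = FALSE
  )
  asv_table(counts, meta, tax)
}

# Random valid count table for property-style tests.
random_table <- function(n_samples = 6, n_asvs = 10, seed = 1,
                         compartments = NULL) {
  set.seed(seed)
  counts <- matrix(rpois(n_samples * n_asvs, 20), n_samples, n_asvs,
                   dimnames = list(sprintf("s%02d", seq_len(n_samples)),
                                   sprintf("a%02d", seq_len(n_asvs))))
  if (is.null(compartments)) {
    compartments <- rep_len(c("bulk", "rhizosphere"), n_samples)
  }
  meta <- data.frame(
    sample_id = rownames(counts), compartment = compartments,
    host_family = "F", kingdom = "bacteria", stringsAsFactors = FALSE
  )
  asv_table(counts, meta)
}

# Build a cooc_network straight from a 0/1 adjacency matrix.
network_from_adjacency <- function(adj, kingdom = NULL) {
  n <- nrow(adj)
  ids <- rownames(adj)
  if (is.null(ids)) ids <- sprintf("n%02d", seq_len(n))
  dimnames(adj) <- list(ids, ids)
  r <- adj * 0.9
  diag(r) <- 1
  p <- ifelse(adj > 0, 0, 1)
  diag(p) <- 0
  corr <- structure(list(r = r, p = p, node_ids = ids, method = "spearman"),
                    class = "corr_matrix")
  meta <- if (!is.null(kingdom)) {
    data.frame(node_id = ids, kingdom = kingdom, stringsAsFactors = FALSE)
  } else NULL
  build_network(corr, r_min = 0.5, p_max = 0.5, node_meta = meta)
}

random_adjacency <- function(n, p = 0.3, seed = 1) {
  set.seed(seed)
  adj <- matrix(0L, n, n)
  adj[upper.tri(adj)] <- rbinom(n * (n - 1) / 2, 1, p)
  adj <- adj + t(adj)
  dimnames(adj) <- list(sprintf("n%02d", 1:n), sprintf("n%02d", 1:n))
  adj
}

# -- brute-force graph oracles (own BFS; independent of igraph) ---------

bfs_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (s in seq_len(n)) {
    frontier <- s
    dist <- 0
    while (length(frontier)) {
      dist <- dist + 1
      nxt <- integer(0)
      for (v in frontier) {
        for (w in which(adj[v, ] > 0)) {
          if (is.infinite(d[s, w]) && w != s) {
            d[s, w] <- dist
            nxt <- c(nxt, w)
          }
        }
      }
      frontier <- unique(nxt)
    }
  }
  d
}

# Enumerate all shortest s-t paths by DFS constrained to strictly
# decreasing distance-to-target; returns a list of vertex sequences.
enumerate_shortest_paths <- function(adj, d, s, t) {
  if (is.infinite(d[s, t])) return(list())
  paths <- list()
  walk <- function(v, acc) {
    if (v == t) {
      paths[[length(paths) + 1L]] <<- acc
      return(invisible())
    }
    for (w in which(adj[v, ] > 0)) {
      if (d[w, t] == d[v, t] - 1) walk(w, c(acc, w))
    }
  }
  walk(s, s)
  paths
}

# Unnormalised betweenness over unordered pairs, endpoints excluded.
brute_betweenness <- function(adj) {
  n <- nrow(adj)
  d <- bfs_distances(adj)
  bc <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in seq(s + 1, n)) {
      paths <- enumerate_shortest_paths(adj, d, s, t)
      g <- length(paths)
      if (g == 0) next
      for (p in paths) {
        interior <- setdiff(p, c(s, t))
        bc[interior] <- bc[interior] + 1 / g
      }
    }
  }
  bc
}

# Closeness as reciprocal mean distance to reachable nodes; isolated -> 0.
brute_closeness <- function(adj) {
  d <- bfs_distances(adj)
  apply(d, 1, function(row) {
    reach <- row[is.finite(row) & row > 0]
    if (!length(reach)) 0 else 1 / mean(reach)
  })
}

# Direct BH step-up rejection set at level alpha (independent of p.adjust).
bh_reject_direct <- function(p, alpha) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  k <- which(ps <= seq_len(m) / m * alpha)
  rejected <- logical(m)
  if (length(k)) rejected[ord[seq_len(max(k))]] <- TRUE
  rejected
}

# Write a toy count table + metadata pair to temp TSV files.
write_toy_files <- function(table, dir = tempfile("toy")) {
  dir.create(dir, showWarnings = FALSE)
  counts_path <- file.path(dir, "counts.tsv")
  meta_path <- file.path(dir, "meta.tsv")
  tax_path <- file.path(dir, "tax.tsv")
  write_asv_table(table, counts_path, meta_path, tax_path)
  list(counts = counts_path, meta = meta_path, tax = tax_path)
}
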