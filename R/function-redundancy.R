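#' Functional redundancy indices for a community
#'
#' For each function f, let S_f be the set of ASVs that carry the function
#' and have positive relative abundance. The functional redundancy index is
#' the abundance-weighted phylogenetic spread of the carriers,
#'
#'   FRI_f = sum over i, k in S_f of p_i * p_k * d*_ik
#'
#' where d*_ik is the pairwise phylogenetic (or nucleotide) distance for
#' i != k, and the diagonal d*_ii is set to the smallest nonzero
#' off-diagonal distance in the community, so a single-carrier function has
#' a small but positive index (p_i^2 * d_min) — "low" rather than absent.
#' FRI_f = 0 exactly when no ASV carries the function. Two normalisations
#' are reported: rFRI_f divides by the same weighted sum taken over all
#' ASV pairs in the community (so a function carried by every member gets
#' rFRI = 1), and aFRI_f divides by a fixed reference distance `d_ref`
#' (e.g. the mean pairwise distance of a reference phylogeny), which makes
#' values comparable across communities.
#'
#' A high FRI means the function is spread over abundant, phylogenetically
#' distant members; a low FRI means it is confined to one taxon or a tight
#' clade.
#'
#' @param rel_abund Named proportion vector over ASVs, summing to 1.
#' @param traits ASVs x functions incidence matrix (0/1 or copy numbers);
#'   row names are ASV ids, column names function ids.
#' @param dists Symmetric ASV x ASV distance matrix with zero diagonal,
#'   covering the ASVs of `rel_abund`.
#' @param d_ref Positive reference distance for aFRI.
#' @return Data frame with columns `function_id`, `fri`, `rfri`, `afri`,
#'   and attribute `d_ref`.
#' @export
community_fri <- function(rel_abund, traits, dists, d_ref) {
  if (abs(sum(rel_abund) - 1) > 1e-9) stop("rel_abund must sum to 1")
  if (length(d_ref) != 1 || d_ref <= 0) stop("d_ref must be a single positive value")
  ids <- names(rel_abund)
  if (is.null(ids)) stop("rel_abund must be named by ASV id")
  traits <- as.matrix(traits)
  if (any(traits < 0)) stop("trait incidences must be non-negative")
  dists <- as.matrix(dists)[ids, ids]
  if (max(abs(dists - t(dists))) > 1e-9) stop("distance matrix must be symmetric")
  off <- dists[upper.tri(dists)]
  d_min <- if (any(off > 0)) min(off[off > 0]) else 0
  dstar <- dists
  diag(dstar) <- d_min

  p <- rel_abund
  total <- as.numeric(t(p) %*% dstar %*% p)  # all-pairs weighted spread
  fri <- vapply(colnames(traits), function(f) {
    carriers <- ids[ids %in% rownames(traits)[traits[, f] > 0]]
    carriers <- carriers[p[carriers] > 0]
    if (!length(carriers)) return(0)
    pc <- p[carriers]
    as.numeric(t(pc) %*% dstar[carriers, carriers, drop = FALSE] %*% pc)
  }, numeric(1))

  out <- data.frame(
    function_id = colnames(traits),
    fri = unname(fri),
    rfri = if (total > 0) unname(fri) / total else ifelse(fri == 0, 0, NA_real_),
    afri = unname(fri) / d_ref,
    stringsAsFactors = FALSE
  )
  attr(out, "d_ref") <- d_ref
  out
}

#' Rhizosphere-vs-bulk log ratio of absolute functional redundancy
#'
#' `log((aFRI_rhizo + pseudo) / (aFRI_bulk + pseudo))` per function; a
#' value above 0 means the function is more redundant in the rhizosphere
#' community. Antisymmetric under swapping the two communities.
#'
#' @param fri_rhizo,fri_bulk FRI tables from [community_fri()] over the
#'   same function universe.
#' @param pseudo Positive pseudocount guarding absent functions.
#' @return Data frame with `function_id` and `log_ratio`.
#' @export
fri_log_ratio <- function(fri_rhizo, fri_bulk, pseudo = 1e-6) {
  if (!setequal(fri_rhizo$function_id, fri_bulk$function_id)) {
    stop("the two FRI tables cover different function sets")
  }
  if (pseudo <= 0) stop("pseudo must be positive")
  b <- fri_bulk[match(fri_rhizo$function_id, fri_bulk$function_id), ]
  data.frame(
    function_id = fri_rhizo$function_id,
    log_ratio = log((fri_rhizo$afri + pseudo) / (b$afri + pseudo)),
    stringsAsFactors = FALSE
  )
}

#' Differential functions between compartments
#'
#' Per-function Wilcoxon rank-sum comparison of rhizosphere against bulk
#' samples on a samples x functions abundance matrix, with BH adjustment
#' across functions. Effect direction is reported as a log2 fold change of
#' compartment means with a pseudocount. All-zero functions are reported
#' with `p = 1`.
#'
#' @param ko_abund Samples x functions matrix (e.g. KO abundances).
#' @param groups Compartment label per sample (`"bulk"`/`"rhizosphere"`),
#'   each with >= 3 samples.
#' @param pseudo Pseudocount for the fold change.
#' @param q_max Significance threshold on the q-value.
#' @return Data frame in the same shape as [differential_genera()].
#' @export
differential_functions <- function(ko_abund, groups, pseudo = 1e-6,
                                   q_max = 0.05) {
  ko_abund <- as.matrix(ko_abund)
  if (sum(groups == "bulk") < 3 || sum(groups == "rhizosphere") < 3) {
    stop("each compartment needs >= 3 samples")
  }
  res <- differential_matrix(ko_abund, groups, pseudo = pseudo,
                             q_max = q_max, lfc_min = 0, test = "wilcoxon")
  # significance for functions is on q alone; lfc records direction only
  res$significant <- res$q_value < q_max
  res
}
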