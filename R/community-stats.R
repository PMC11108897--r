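#' Shannon diversity of a count or abundance vector
#'
#' `H = -sum(p_i * log(p_i))` over nonzero proportions, natural log.
#'
#' @param counts Non-negative vector with at least one positive entry.
#' @return Shannon entropy (>= 0).
#' @export
shannon <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative")
  total <- sum(counts)
  if (total == 0) stop("all-zero vector has no diversity")
  p <- counts[counts > 0] / total
  -sum(p * log(p))
}

#' Bray-Curtis dissimilarity between two samples
#'
#' `BC = sum(|x - y|) / sum(x + y)`, in `[0, 1]` for non-negative input.
#'
#' @param x,y Non-negative vectors of equal length, not both all-zero.
#' @return Dissimilarity in `[0, 1]`.
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (any(x < 0) || any(y < 0)) stop("inputs must be non-negative")
  denom <- sum(x + y)
  if (denom == 0) stop("both samples are all zero")
  sum(abs(x - y)) / denom
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based permutation test of between-group versus within-group
#' community distances. The R statistic is the difference of mean
#' between-group and mean within-group distance ranks divided by half the
#' number of distance pairs; the permutation p-value carries the +1
#' correction. Delegates to [vegan::anosim()] under a fixed seed.
#'
#' @param dist A `dist` object or symmetric distance matrix.
#' @param groups Group labels, at least 2 groups of >= 2 members each.
#' @param n_perm Number of permutations.
#' @param seed Integer seed for the permutation stream.
#' @return List with elements `R` (in `[-1, 1]`) and `p`.
#' @export
anosim_test <- function(dist, groups, n_perm = 999L, seed = 1L) {
  d <- stats::as.dist(dist)
  groups <- as.factor(groups)
  if (attr(d, "Size") != length(groups)) stop("groups length must match dist size")
  sizes <- table(groups)
  if (length(sizes) < 2) stop("at least two groups are required")
  if (any(sizes < 2)) {
    stop("every group needs >= 2 members; offending: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  fit <- with_seed(seed, vegan::anosim(d, groups, permutations = n_perm))
  list(R = unname(fit$statistic), p = unname(fit$signif))
}

#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test
#'
#' @param x,y Non-empty numeric samples.
#' @return List with `statistic` (Mann-Whitney U for `x`) and `p_value`
#'   (two-sided; exact when both samples are small and tie-free, normal
#'   approximation with tie correction otherwise).
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  exact <- length(x) <= 8 && length(y) <= 8 && !anyDuplicated(c(x, y))
  fit <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = !exact)
  )
  list(statistic = unname(fit$statistic), p_value = fit$p.value)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' @param p_values Vector of p-values in `[0, 1]`.
#' @return Step-up q-values, same order as input.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Differential genera between rhizosphere and bulk compartments
#'
#' Aggregates counts to genus level, converts to per-sample relative
#' abundances, and for each genus computes a rhizosphere-vs-bulk log2 fold
#' change of compartment means (with pseudocount) together with a Welch
#' t-test on log-transformed per-sample relative abundances. P-values are
#' BH-adjusted jointly across genera; a genus is flagged significant when
#' `q < q_max` and `|log2FC| > lfc_min` (volcano-plot convention).
#'
#' Genera that are zero in every sample get `log2FC = 0` and `p = 1`;
#' so do genera with zero variance on both sides and equal means.
#'
#' @param table An `asv_table` containing both compartments, each with at
#'   least 2 samples.
#' @param pseudo Pseudocount added to relative abundances.
#' @param q_max,lfc_min Significance thresholds.
#' @return Data frame with columns `unit_id`, `log2_fold_change`,
#'   `statistic`, `p_value`, `q_value`, `significant`.
#' @export
differential_genera <- function(table, pseudo = 1e-6, q_max = 0.05,
                                lfc_min = 1) {
  comp <- table$sample_meta$compartment
  if (sum(comp == "bulk") < 2 || sum(comp == "rhizosphere") < 2) {
    stop("each compartment needs >= 2 samples")
  }
  genus_counts <- aggregate_genus(table)
  ra <- genus_counts / rowSums(genus_counts)
  differential_matrix(ra, comp, pseudo = pseudo, q_max = q_max,
                      lfc_min = lfc_min, test = "welch")
}

# Sum ASV counts into genus columns; unassigned genera are kept as their
# own "unassigned" unit.
aggregate_genus <- function(table) {
  genus <- table$taxonomy$genus
  groups <- factor(genus, levels = unique(genus))
  out <- t(rowsum(t(table$counts), group = groups))
  colnames(out) <- levels(groups)
  out
}

# Shared engine for per-unit two-group comparisons on a samples x units
# abundance matrix. test: "welch" (on log-transformed values) or "wilcoxon".
differential_matrix <- function(abund, compartments, pseudo = 1e-6,
                                q_max = 0.05, lfc_min = 1, test = "welch") {
  rhizo <- compartments == "rhizosphere"
  bulk <- compartments == "bulk"
  units <- colnames(abund)
  lfc <- stat <- p <- numeric(ncol(abund))
  for (j in seq_len(ncol(abund))) {
    a <- abund[rhizo, j]
    b <- abund[bulk, j]
    lfc[j] <- log2((mean(a) + pseudo) / (mean(b) + pseudo))
    if (length(unique(c(a, b))) == 1) {  # constant column (incl. all-zero)
      stat[j] <- 0; p[j] <- 1
      next
    }
    if (test == "welch") {
      la <- log(a + pseudo); lb <- log(b + pseudo)
      if (stats::sd(la) == 0 && stats::sd(lb) == 0) {
        stat[j] <- 0
        p[j] <- if (mean(la) == mean(lb)) 1 else 0
      } else {
        fit <- stats::t.test(la, lb, var.equal = FALSE)
        stat[j] <- unname(fit$statistic); p[j] <- fit$p.value
      }
    } else {
      fit <- wilcoxon_rank_sum(a, b)
      stat[j] <- fit$statistic; p[j] <- fit$p_value
    }
  }
  q <- bh_adjust(p)
  data.frame(
    unit_id = units,
    log2_fold_change = lfc,
    statistic = stat,
    p_value = p,
    q_value = q,
    significant = q < q_max & abs(lfc) > lfc_min,
    stringsAsFactors = FALSE
  )
}
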