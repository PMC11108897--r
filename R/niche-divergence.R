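#' Kimura two-parameter (K80) distance between two aligned sequences
#'
#' Counts transition (`P`) and transversion (`Q`) proportions over
#' comparable sites — positions where neither sequence carries a gap or an
#' `N` (pairwise deletion) — and applies
#' `d = -1/2 * log(1 - 2P - Q) - 1/4 * log(1 - 2Q)`,
#' in expected substitutions per site.
#'
#' When the observed divergence is beyond what the model can correct
#' (`1 - 2P - Q <= 0` or `1 - 2Q <= 0`, saturation) the distance is
#' undefined and `NA` is returned; callers exclude such pairs.
#'
#' @param seq_a,seq_b DNA strings of equal length over `A,C,G,T,N,-`.
#' @return Distance in substitutions/site, or `NA` on saturation.
#' @export
k80_distance <- function(seq_a, seq_b) {
  a <- toupper(strsplit(seq_a, "", fixed = TRUE)[[1]])
  b <- toupper(strsplit(seq_b, "", fixed = TRUE)[[1]])
  if (length(a) != length(b)) stop("sequences must be aligned to equal length")
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  n <- sum(ok)
  if (n == 0) stop("no comparable sites after pairwise deletion")
  a <- a[ok]; b <- b[ok]
  diff <- a != b
  purine <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
  transition <- diff & (purine[a] == purine[b])
  P <- sum(transition) / n
  Q <- sum(diff & !transition) / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) return(NA_real_)
  -0.5 * log(w1) - 0.25 * log(w2)
}

#' Pairwise K80 distance matrix for an aligned sequence set
#'
#' @param seqs An aligned `sequence_set`.
#' @return Symmetric matrix of distances with `NA` for saturated pairs.
#' @export
k80_matrix <- function(seqs) {
  if (!seqs$aligned) stop("sequences must be aligned")
  ids <- names(seqs$records)
  n <- length(ids)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n < 2) return(d)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      d[i, j] <- d[j, i] <- k80_distance(seqs$records[i], seqs$records[j])
    }
  }
  d
}

#' Centred log-ratio transform of a count block
#'
#' Per sample (row), `a_i = log(x_i + pseudocount) - mean_j log(x_j +
#' pseudocount)`. Each output row sums to zero.
#'
#' @param counts Samples x ASVs matrix of counts or abundances.
#' @param pseudocount Positive value added before the log; defaults to 0.5,
#'   a conventional choice for sequencing counts with structural zeros.
#' @return Matrix of clr values, same shape and dimnames.
#' @export
clr_transform <- function(counts, pseudocount = 0.5) {
  if (length(pseudocount) != 1 || pseudocount <= 0) {
    stop("pseudocount must be a single positive value")
  }
  lx <- log(as.matrix(counts) + pseudocount)
  sweep(lx, 1L, rowMeans(lx), "-")
}

#' Rho proportionality between two log-ratio-transformed vectors
#'
#' `rho = 1 - var(a - b) / (var(a) + var(b))`, the symmetric
#' proportionality coefficient for compositional data; 1 means perfectly
#' proportional, -1 perfectly anti-proportional.
#'
#' @param a,b Numeric vectors of equal length >= 3 (clr values across
#'   samples), not both constant.
#' @return Rho in `[-1, 1]`.
#' @export
rho_proportionality <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must have equal length")
  if (length(a) < 3) stop("at least 3 samples are required")
  va <- stats::var(a)
  vb <- stats::var(b)
  if (va + vb == 0) stop("rho is undefined when both vectors are constant")
  1 - stats::var(a - b) / (va + vb)
}

#' Close ASV pairs within a genus, with divergence and proportionality
#'
#' Enumerates all unordered pairs of ASVs assigned to `genus` that have
#' sequences, keeps those with a defined K80 distance strictly below
#' `d_max` (the "closely related" window), and annotates each pair with
#' the Rho proportionality of the two ASVs' clr-transformed abundances
#' across all samples (bulk and rhizosphere jointly).
#'
#' @param table An `asv_table`.
#' @param seqs An aligned `sequence_set` covering the genus's ASVs.
#' @param genus Genus name as it appears in the taxonomy.
#' @param d_max Nucleotide-distance ceiling (substitutions/site).
#' @param pseudocount Passed to [clr_transform()].
#' @return Data frame with columns `asv_a`, `asv_b`, `genus`, `distance`,
#'   `rho` (zero rows if no pair is close enough).
#' @export
genus_pairs <- function(table, seqs, genus, d_max = 0.5, pseudocount = 0.5) {
  members <- table$taxonomy$asv_id[table$taxonomy$genus == genus]
  if (!length(members)) stop("genus not present in taxonomy: ", genus)
  members <- intersect(members, names(seqs$records))
  members <- intersect(members, asv_ids(table))
  if (length(members) < 2) {
    stop("genus ", genus, " has fewer than 2 ASVs with sequences")
  }
  clr <- clr_transform(table$counts, pseudocount)
  sub <- sequence_set(seqs$records[members], aligned = TRUE)
  d <- k80_matrix(sub)
  pairs <- utils::combn(members, 2)
  keep <- apply(pairs, 2, function(p) {
    dd <- d[p[1], p[2]]
    !is.na(dd) && dd < d_max
  })
  pairs <- pairs[, keep, drop = FALSE]
  data.frame(
    asv_a = pairs[1, ],
    asv_b = pairs[2, ],
    genus = rep(genus, ncol(pairs)),
    distance = apply(pairs, 2, function(p) d[p[1], p[2]]),
    rho = apply(pairs, 2, function(p) {
      rho_proportionality(clr[, p[1]], clr[, p[2]])
    }),
    stringsAsFactors = FALSE
  )
}

#' Linear trend of Rho proportionality against nucleotide divergence
#'
#' Ordinary least squares of `rho` on `distance` for one genus's close
#' pairs, with a two-sided t-test on the slope. The trend is labelled
#' `"differentiation"` when the slope is significantly negative with an
#' adequate fit (`p < p_max`, slope < 0, `R^2 >= r2_min`),
#' `"inconclusive"` when the slope is significant but the fit explains
#' little variance (`R^2 < r2_min`), and `"none"` otherwise. The
#' `r2_min` floor mirrors the practice of setting aside genera whose
#' significant regression has a small R-squared.
#'
#' @param pairs Data frame as returned by [genus_pairs()], >= 3 rows.
#' @param r2_min Minimum R-squared for an interpretable trend.
#' @param p_max Slope-test significance level.
#' @return List with `genus`, `slope`, `intercept`, `r_squared`,
#'   `p_value`, `n_pairs`, `trend`, and `slope_ci` (95% interval).
#' @export
niche_divergence_regression <- function(pairs, r2_min = 0.1, p_max = 0.05) {
  if (nrow(pairs) < 3) stop("at least 3 pairs are required for a fit")
  if (stats::var(pairs$distance) == 0) {
    stop("zero variance in distance; trend is undefined")
  }
  fit <- stats::lm(rho ~ distance, data = pairs)
  sm <- summary(fit)
  slope <- unname(stats::coef(fit)[2])
  p <- sm$coefficients["distance", "Pr(>|t|)"]
  r2 <- sm$r.squared
  ci <- unname(stats::confint(fit, "distance", level = 0.95))
  trend <- if (p < p_max && slope < 0 && r2 >= r2_min) {
    "differentiation"
  } else if (p < p_max && r2 < r2_min) {
    "inconclusive"
  } else {
    "none"
  }
  list(
    genus = if (nrow(pairs)) pairs$genus[1] else NA_character_,
    slope = slope,
    intercept = unname(stats::coef(fit)[1]),
    r_squared = r2,
    p_value = p,
    n_pairs = nrow(pairs),
    trend = trend,
    slope_ci = as.numeric(ci)
  )
}

#' Run the niche-divergence analysis for several genera
#'
#' @param table An `asv_table`.
#' @param seqs Aligned `sequence_set`.
#' @param genera Character vector of genus names; defaults to all genera
#'   with >= 2 sequenced ASVs.
#' @param d_max,r2_min,pseudocount See [genus_pairs()] and
#'   [niche_divergence_regression()].
#' @return Data frame with one row per genus that yielded >= 3 close
#'   pairs: slope, intercept, r_squared, p_value, n_pairs, trend.
#' @export
niche_divergence_scan <- function(table, seqs, genera = NULL, d_max = 0.5,
                                  r2_min = 0.1, pseudocount = 0.5) {
  if (is.null(genera)) {
    tab <- base::table(table$taxonomy$genus[table$taxonomy$asv_id %in% names(seqs$records)])
    genera <- names(tab)[tab >= 2 & names(tab) != "unassigned"]
  }
  rows <- lapply(genera, function(g) {
    pairs <- genus_pairs(table, seqs, g, d_max = d_max, pseudocount = pseudocount)
    if (nrow(pairs) < 3) return(NULL)
    res <- niche_divergence_regression(pairs, r2_min = r2_min)
    data.frame(
      genus = g, slope = res$slope, intercept = res$intercept,
      r_squared = res$r_squared, p_value = res$p_value,
      n_pairs = res$n_pairs, trend = res$trend, stringsAsFactors = FALSE
    )
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
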