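#' Rarefy samples to a fixed sequencing depth
#'
#' Subsamples each sample's reads without replacement (hypergeometric
#' draws) to exactly `depth` reads. Samples whose library size is below
#' `depth` are dropped. Deterministic given `seed`.
#'
#' @param table An `asv_table`.
#' @param depth Target depth per sample (>= 1).
#' @param seed Integer seed.
#' @return A rarefied `asv_table`; every retained sample sums to `depth`.
#' @export
rarefy <- function(table, depth, seed = 1L) {
  if (length(depth) != 1 || is.na(depth) || depth < 1) {
    stop("depth must be a positive integer")
  }
  depth <- as.integer(depth)
  totals <- rowSums(table$counts)
  keep <- which(totals >= depth)
  if (!length(keep)) stop("no sample reaches depth ", depth)
  counts <- table$counts[keep, , drop = FALSE]
  out <- with_seed(seed, {
    t(apply(counts, 1L, subsample_counts, depth = depth))
  })
  dimnames(out) <- dimnames(counts)
  asv_table(out, table$sample_meta, table$taxonomy)
}

# Draw `depth` reads without replacement from one sample's count vector.
subsample_counts <- function(x, depth) {
  total <- sum(x)
  if (total == depth) return(x)
  picked <- sample.int(total, depth)
  tab <- tabulate(findInterval(picked - 1L, cumsum(c(0L, x))), nbins = length(x) + 1L)
  tab[seq_along(x)]
}

# Evaluate expr under a local RNG seed without disturbing the global stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Drop rare ASVs
#'
#' Removes singleton ASVs (total count of 1 across all samples) and ASVs
#' observed in only one sample, the usual guard against spurious or
#' transient sequence variants. Idempotent; ASV order is preserved.
#'
#' @param table An `asv_table`.
#' @return A filtered `asv_table` (possibly with zero ASVs).
#' @export
drop_rare_asvs <- function(table) {
  totals <- colSums(table$counts)
  occ <- colSums(table$counts > 0)
  keep <- totals != 1 & occ != 1
  subset_asv_table(table, asvs = which(keep))
}

#' Relative abundances of an ASV table
#'
#' @param table An `asv_table` in which every sample has a positive total.
#' @return Numeric matrix (samples x ASVs); each row sums to 1.
#' @export
relative_abundance <- function(table) {
  totals <- rowSums(table$counts)
  if (any(totals == 0)) {
    stop("all-zero sample rows: ",
         paste(rownames(table$counts)[totals == 0], collapse = ", "))
  }
  sweep(table$counts, 1L, totals, "/")
}

#' Keep abundant, prevalent ASVs
#'
#' Retains ASVs whose mean relative abundance across all samples is
#' strictly greater than `mean_ra_min` and whose occurrence frequency
#' (fraction of samples with a nonzero count) is strictly greater than
#' `occ_min`. Defaults follow common practice for soil amplicon surveys:
#' mean relative abundance above 0.01% and occurrence above 15% of samples
#' for bacterial libraries or 10% for fungal ones (chosen from the table's
#' sample kingdom when `occ_min` is `NULL`).
#'
#' @param table An `asv_table`.
#' @param mean_ra_min Mean relative-abundance threshold in `[0, 1]`.
#' @param occ_min Occurrence-frequency threshold in `[0, 1]`, or `NULL` to
#'   pick 0.15/0.10 by kingdom.
#' @return The filtered `asv_table`.
#' @export
filter_abundant <- function(table, mean_ra_min = 1e-4, occ_min = NULL) {
  if (is.null(occ_min)) {
    kingdoms <- unique(table$sample_meta$kingdom)
    if (length(kingdoms) != 1) {
      stop("occ_min must be given explicitly for mixed-kingdom tables")
    }
    occ_min <- if (kingdoms == "bacteria") 0.15 else 0.10
  }
  if (mean_ra_min < 0 || mean_ra_min > 1 || occ_min < 0 || occ_min > 1) {
    stop("thresholds must lie in [0, 1]")
  }
  ra <- relative_abundance(table)
  mean_ra <- colMeans(ra)
  occ <- colMeans(table$counts > 0)
  keep <- mean_ra > mean_ra_min & occ > occ_min
  subset_asv_table(table, asvs = which(keep))
}
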