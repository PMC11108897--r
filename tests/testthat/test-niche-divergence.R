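test_that("K80 distance matches closed-form hand values", {
  a <- strrep("A", 100)
  b <- paste(c(rep("G", 10), rep("T", 5), rep("A", 85)), collapse = "")
  # P = 0.1 transitions, Q = 0.05 transversions
  expect_equal(k80_distance(a, b),
               -0.5 * log(1 - 0.25) - 0.25 * log(0.9), tolerance = 1e-12)
  expect_equal(round(k80_distance(a, b), 5), 0.17018)
  expect_equal(k80_distance(a, a), 0)
  expect_equal(k80_distance(a, b), k80_distance(b, a))
})

test_that("K80 signals saturation and handles gaps by pairwise deletion", {
  # P = 0.4, Q = 0.25 -> 1 - 2P - Q < 0
  a <- strrep("A", 100)
  b <- paste(c(rep("G", 40), rep("C", 25), rep("A", 35)), collapse = "")
  expect_true(is.na(k80_distance(a, b)))
  # gap/N positions in either sequence are excluded before counting
  x <- "ACGTNA-A"
  y <- "ACGTAAGG"
  # comparable sites: positions 1-4, 6, 8 (N at 5, gap at 7); one
  # difference at site 8 (A/G transition): P = 1/6, Q = 0
  expect_equal(k80_distance(x, y), -0.5 * log(1 - 2 / 6))
  expect_error(k80_distance("NNN", "ACG"), "comparable")
  expect_error(k80_distance("ACGT", "ACG"), "equal length")
})

test_that("K80 agrees with an independent reference implementation", {
  set.seed(10)
  for (i in 1:25) {
    n <- 300
    a <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    b <- a
    mut <- runif(n) < 0.15
    b[mut] <- vapply(b[mut], function(ch) {
      sample(setdiff(c("A", "C", "G", "T"), ch), 1)
    }, character(1))
    mine <- k80_distance(paste(a, collapse = ""), paste(b, collapse = ""))
    bin <- ape::as.DNAbin(matrix(tolower(rbind(a, b)), nrow = 2))
    ref <- as.numeric(ape::dist.dna(bin, model = "K80",
                                    pairwise.deletion = TRUE))
    expect_equal(mine, ref, tolerance = 1e-9)
  }
})

test_that("K80 reduces to the transition-only form when Q = 0", {
  a <- strrep("A", 200)
  for (k in c(5, 10, 20)) {
    b <- paste(c(rep("G", k), rep("A", 200 - k)), collapse = "")
    P <- k / 200
    expect_equal(k80_distance(a, b), -0.5 * log(1 - 2 * P), tolerance = 1e-12)
  }
})

test_that("clr transform centres every row and matches hand arithmetic", {
  m <- matrix(c(7, 7, 7), 1, 3)
  expect_equal(clr_transform(m, 0.5)[1, ], rep(0, 3))
  row <- matrix(c(1, 10, 100), 1, 3)
  lx <- log(c(1, 10, 100) + 0.5)
  expect_equal(clr_transform(row, 0.5)[1, ], lx - mean(lx))
  set.seed(4)
  big <- matrix(rpois(60, 10), 6, 10)
  expect_true(all(abs(rowSums(clr_transform(big))) < 1e-9))
  expect_error(clr_transform(big, 0), "positive")
})

test_that("rho proportionality matches its defining formula", {
  a <- c(0, 1, 2, 3)
  expect_equal(rho_proportionality(a, a), 1)
  cent <- a - mean(a)
  expect_equal(rho_proportionality(cent, -cent), -1)
  expect_equal(rho_proportionality(a, c(0, 2, 4, 6)), 0.8)
  # symmetry and invariance to a common additive constant
  set.seed(5)
  x <- rnorm(10); y <- rnorm(10)
  expect_equal(rho_proportionality(x, y), rho_proportionality(y, x))
  expect_equal(rho_proportionality(x + 3, y + 3), rho_proportionality(x, y))
  # jointly shifted pair is perfectly proportional
  expect_equal(rho_proportionality(x, x + 2), 1)
  expect_error(rho_proportionality(rep(1, 5), rep(2, 5)), "constant")
})

test_that("genus pair enumeration honours the distance window", {
  # two near-identical ASVs and one divergent one in the same genus
  base <- strrep("ACGT", 100)
  close2 <- sub("^A", "G", base)
  # divergent but unsaturated partner: 40 transitions + 140 transversions
  # over 400 sites (P = 0.1, Q = 0.35 -> d ~ 0.70)
  ch <- strsplit(base, "")[[1]]
  ts <- c(A = "G", G = "A", C = "T", T = "C")
  tv <- c(A = "C", C = "A", G = "T", T = "G")
  ch[1:40] <- ts[ch[1:40]]
  ch[41:180] <- tv[ch[41:180]]
  far <- paste(ch, collapse = "")
  counts <- matrix(rpois(12, 30) + 1L, 4, 3,
                   dimnames = list(sprintf("s%d", 1:4), c("p1", "p2", "p3")))
  meta <- data.frame(sample_id = rownames(counts), compartment = "bulk",
                     host_family = "F", kingdom = "bacteria")
  tax <- data.frame(asv_id = c("p1", "p2", "p3"), kingdom = "B", phylum = "p",
                    class = "c", order = "o", family = "f", genus = "G",
                    species = "s")
  tab <- asv_table(counts, meta, tax)
  seqs <- sequence_set(c(p1 = base, p2 = close2, p3 = far), aligned = TRUE)
  pairs <- genus_pairs(tab, seqs, "G", d_max = 0.5)
  expect_identical(nrow(pairs), 1L)  # only p1-p2 is under the window
  expect_setequal(c(pairs$asv_a, pairs$asv_b), c("p1", "p2"))
  wide <- genus_pairs(tab, seqs, "G", d_max = 10)
  expect_identical(nrow(wide), 3L)   # C(3,2) once the window is open
  expect_error(genus_pairs(tab, seqs, "Nope"), "not present")
})

test_that("genus pairs match exhaustive enumeration on generated data", {
  cfg <- scenario_config(seed = 21, n_genera = 2, asvs_per_genus = 6,
                         distance_scale = 0.35)
  seqs <- simulate_genus_sequences(cfg)
  ab <- simulate_abundance_tables(cfg, seqs)
  d_max <- 0.4
  pairs <- genus_pairs(ab$table, seqs, "Genus_01", d_max = d_max)
  members <- names(attr(seqs, "genus_map"))[attr(seqs, "genus_map") == "Genus_01"]
  expected <- 0L
  for (i in seq_along(members)) {
    for (j in seq_len(i - 1)) {
      d <- k80_distance(seqs$records[[members[i]]], seqs$records[[members[j]]])
      if (!is.na(d) && d < d_max) expected <- expected + 1L
    }
  }
  expect_identical(nrow(pairs), expected)
  expect_true(all(pairs$distance < d_max))
  expect_true(all(pairs$rho >= -1 & pairs$rho <= 1))
})

test_that("regression on an exact line recovers it perfectly", {
  d <- seq(0.05, 0.45, length.out = 10)
  pairs <- data.frame(asv_a = "a", asv_b = "b", genus = "G",
                      distance = d, rho = 1 - 0.8 * d)
  # suppress R's "essentially perfect fit" notice on the noise-free line
  fit <- suppressWarnings(niche_divergence_regression(pairs))
  expect_equal(fit$slope, -0.8, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_identical(fit$trend, "differentiation")
  expect_error(niche_divergence_regression(pairs[1:2, ]), "3 pairs")
  flat <- pairs; flat$distance <- 0.2
  expect_error(niche_divergence_regression(flat), "variance")
})

test_that("regression recovers the planted slope and its sign", {
  cover <- vapply(1:30, function(s) {
    p <- simulate_pair_scenario(scenario_config(seed = s, beta = -0.5,
                                                noise_sd = 0.05))
    fit <- niche_divergence_regression(p)
    fit$slope_ci[1] <= -0.5 && -0.5 <= fit$slope_ci[2]
  }, logical(1))
  expect_gte(mean(cover), 0.9)
  # strong planted effects give the right sign essentially always
  signs <- vapply(1:20, function(s) {
    p <- simulate_pair_scenario(scenario_config(seed = s, beta = -0.3,
                                                noise_sd = 0.05), n_pairs = 30)
    niche_divergence_regression(p)$slope < 0
  }, logical(1))
  expect_gte(mean(signs), 0.95)
})

test_that("no planted slope yields the null trend", {
  trends <- vapply(1:30, function(s) {
    p <- simulate_pair_scenario(scenario_config(seed = s, beta = 0,
                                                noise_sd = 0.05))
    niche_divergence_regression(p)$trend
  }, character(1))
  expect_gte(mean(trends == "none"), 0.9)
})
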