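#' Scenario configuration for the synthetic generators
#'
#' Bundles every knob of the simulated study: community layout, sequence
#' evolution, planted niche structure, compartment effects, trait
#' evolution, and the block structure of the co-occurrence scenario. All
#' generators are pure functions of this object: identical configurations
#' (including `seed`) give byte-identical outputs.
#'
#' @param seed Master seed; each generator derives its own fixed offset.
#' @param n_samples Samples per compartment.
#' @param depth Sequencing depth per sample (multinomial total), >= 100.
#' @param n_genera,asvs_per_genus Community layout.
#' @param seq_length Alignment length in sites.
#' @param kappa Transition/transversion rate ratio of the K80 process.
#' @param distance_scale Expected pairwise nucleotide distance within a
#'   genus (substitutions/site).
#' @param rho0,beta Intercept and slope of the planted proportionality
#'   versus distance relationship within genera.
#' @param differential_frac Fraction of genera given a compartment effect.
#' @param differential_lfc Planted |log2 fold change| of those genera
#'   (signs alternate between enrichment and depletion).
#' @param n_functions Number of KO-like traits to evolve.
#' @param trait_gain_loss Gain/loss rate per unit branch length.
#' @param n_blocks,nodes_per_block Block structure of the network scenario.
#' @param within_r,noise_r Within-block and between-block latent
#'   correlations (`within_r` must exceed `noise_r`).
#' @param n_bridges,bridge_kingdom,bridge_span Connector nodes appended to
#'   the block scenario: how many, their kingdom label, and how many
#'   blocks each spans.
#' @param network_samples Samples for the network scenario.
#' @param noise_sd Residual noise for the pair-level regression scenario.
#' @return A validated list of class `scenario_config`.
#' @export
scenario_config <- function(seed = 1L,
                            n_samples = 60L,
                            depth = 7500L,
                            n_genera = 12L,
                            asvs_per_genus = 8L,
                            seq_length = 1000L,
                            kappa = 2,
                            distance_scale = 0.2,
                            rho0 = 0.9,
                            beta = -0.5,
                            differential_frac = 0.25,
                            differential_lfc = 2,
                            n_functions = 200L,
                            trait_gain_loss = 1,
                            n_blocks = 4L,
                            nodes_per_block = 30L,
                            within_r = 0.7,
                            noise_r = 0.2,
                            n_bridges = 2L,
                            bridge_kingdom = "fungi",
                            bridge_span = 2L,
                            network_samples = 120L,
                            noise_sd = 0.05) {
  cfg <- list(
    seed = as.integer(seed), n_samples = as.integer(n_samples),
    depth = as.integer(depth), n_genera = as.integer(n_genera),
    asvs_per_genus = as.integer(asvs_per_genus),
    seq_length = as.integer(seq_length), kappa = kappa,
    distance_scale = distance_scale, rho0 = rho0, beta = beta,
    differential_frac = differential_frac, differential_lfc = differential_lfc,
    n_functions = as.integer(n_functions), trait_gain_loss = trait_gain_loss,
    n_blocks = as.integer(n_blocks), nodes_per_block = as.integer(nodes_per_block),
    within_r = within_r, noise_r = noise_r, n_bridges = as.integer(n_bridges),
    bridge_kingdom = bridge_kingdom, bridge_span = as.integer(bridge_span),
    network_samples = as.integer(network_samples), noise_sd = noise_sd
  )
  if (cfg$depth < 100) stop("depth must be >= 100")
  if (cfg$n_samples < 3) stop("n_samples must be >= 3")
  if (cfg$distance_scale < 0 || cfg$distance_scale >= 0.8) {
    stop("distance_scale must lie in [0, 0.8) to stay clear of saturation")
  }
  if (cfg$differential_frac < 0 || cfg$differential_frac > 1) {
    stop("differential_frac must lie in [0, 1]")
  }
  if (abs(cfg$rho0) > 1) stop("rho0 must lie in [-1, 1]")
  # target proportionality must be representable over the distance range
  r_far <- cfg$rho0 + cfg$beta * 3 * cfg$distance_scale
  if (cfg$rho0 > 1 || r_far < -1) {
    stop("rho0/beta put the target proportionality outside [-1, 1]")
  }
  if (cfg$within_r <= cfg$noise_r) {
    stop("within_r must exceed noise_r (scenario otherwise unidentifiable)")
  }
  if (cfg$bridge_span < 2 || cfg$bridge_span > cfg$n_blocks) {
    stop("bridge_span must lie in [2, n_blocks]")
  }
  structure(cfg, class = "scenario_config")
}

# Fixed seed offsets keep the generators independent of each other while
# remaining pure functions of the master seed.
seed_for <- function(cfg, stage) {
  offs <- c(sequences = 101L, abundances = 211L, traits = 307L,
            network = 401L, pairs = 503L)
  (cfg$seed %% 1000000L) * 1000L + offs[[stage]]
}

genus_names <- function(cfg) sprintf("Genus_%02d", seq_len(cfg$n_genera))

#' Simulate aligned ASV sequences for each genus
#'
#' For every genus a random bifurcating tree is drawn and rescaled so the
#' mean pairwise (cophenetic) path length equals `distance_scale`; a root
#' sequence then evolves along it under a K80 substitution process with
#' transition bias `kappa`. Tip sequences become the genus's ASVs.
#'
#' @param cfg A `scenario_config`.
#' @return An aligned `sequence_set` with attributes `trees` (named list
#'   of `phylo` objects, branch lengths in substitutions/site) and
#'   `genus_map` (named character vector, asv_id -> genus).
#' @export
simulate_genus_sequences <- function(cfg) {
  with_seed(seed_for(cfg, "sequences"), {
    records <- character(0)
    trees <- list()
    genus_map <- character(0)
    for (g in genus_names(cfg)) {
      tree <- ape::rtree(cfg$asvs_per_genus)
      tree$tip.label <- sprintf("%s_ASV%02d", g, seq_len(cfg$asvs_per_genus))
      coph <- ape::cophenetic.phylo(tree)
      mean_d <- mean(coph[upper.tri(coph)])
      scale <- if (mean_d > 0) cfg$distance_scale / mean_d else 0
      tree$edge.length <- tree$edge.length * scale
      sim <- phangorn::simSeq(tree, l = cfg$seq_length,
                              Q = k80_rates(cfg$kappa),
                              bf = rep(0.25, 4), type = "DNA")
      chars <- toupper(as.character(sim))
      seqs <- apply(chars, 1, paste, collapse = "")
      records <- c(records, stats::setNames(seqs[tree$tip.label],
                                            tree$tip.label))
      genus_map <- c(genus_map,
                     stats::setNames(rep(g, cfg$asvs_per_genus),
                                     tree$tip.label))
      trees[[g]] <- tree
    }
    out <- sequence_set(records, aligned = TRUE)
    attr(out, "trees") <- trees
    attr(out, "genus_map") <- genus_map
    out
  })
}

# K80 exchangeability rates in phangorn's (AC, AG, AT, CG, CT, GT) order:
# transitions (AG, CT) run kappa times faster than transversions.
k80_rates <- function(kappa) c(1, kappa, 1, 1, kappa, 1)

#' Simulate bulk and rhizosphere count tables with planted structure
#'
#' Latent per-sample log-abundances are drawn from a multivariate normal
#' whose within-genus correlations follow the planted line
#' `clip(rho0 + beta * d_ij)` on the true tree distances (independent
#' across genera); the target matrix is repaired to the nearest positive
#' semi-definite correlation by eigenvalue clipping. Rhizosphere samples
#' shift designated differential genera by `differential_lfc` log2 units
#' (alternating enrichment/depletion). Counts are multinomial draws at
#' `depth` reads per sample.
#'
#' @param cfg A `scenario_config`.
#' @param seqs Output of [simulate_genus_sequences()] for the same config.
#' @return List with `table` (a combined bulk + rhizosphere `asv_table`)
#'   and `truth` (planted slope/intercept, differential genera with signed
#'   log2 effects, the target correlation matrix, and tree distances).
#' @export
simulate_abundance_tables <- function(cfg, seqs) {
  trees <- attr(seqs, "trees")
  genus_map <- attr(seqs, "genus_map")
  if (is.null(trees)) stop("seqs must come from simulate_genus_sequences()")
  ids <- names(seqs$records)
  n_asv <- length(ids)

  # planted correlation target: within-genus follows the rho-vs-distance
  # line on true tree distances; between-genus zero
  target <- diag(n_asv)
  dimnames(target) <- list(ids, ids)
  dist_true <- matrix(NA_real_, n_asv, n_asv, dimnames = list(ids, ids))
  for (g in names(trees)) {
    coph <- ape::cophenetic.phylo(trees[[g]])
    tips <- rownames(coph)
    dist_true[tips, tips] <- coph
    rho <- pmax(pmin(cfg$rho0 + cfg$beta * coph, 0.99), -0.99)
    diag(rho) <- 1
    target[tips, tips] <- rho
  }
  sigma <- psd_repair(target)

  n_per <- cfg$n_samples
  genera <- genus_map[ids]
  n_diff <- round(cfg$differential_frac * cfg$n_genera)
  diff_genera <- genus_names(cfg)[seq_len(n_diff)]
  diff_sign <- rep_len(c(1, -1), n_diff)
  shift <- stats::setNames(rep(0, cfg$n_genera), genus_names(cfg))
  shift[diff_genera] <- diff_sign * cfg$differential_lfc * log(2)

  with_seed(seed_for(cfg, "abundances"), {
    mu <- stats::rnorm(n_asv, 0, 1)
    # Weight the enriched and depleted genera so the planted compartment
    # effect is mass-balanced: the closure (renormalisation) of the
    # composition then leaves non-designated genera null on the
    # relative-abundance scale, and the planted log2 fold changes land at
    # their nominal values. Balance requires depleted carriers to hold
    # 2^|lfc| times the enriched carriers' baseline mass.
    up <- genera %in% diff_genera[diff_sign > 0]
    down <- genera %in% diff_genera[diff_sign < 0]
    if (any(up) && any(down)) {
      delta <- cfg$differential_lfc
      w_up <- sum(exp(mu[up])); w_down <- sum(exp(mu[down]))
      w_up_new <- (w_up + w_down) / (1 + 2^delta)
      mu[up] <- mu[up] + log(w_up_new / w_up)
      mu[down] <- mu[down] + log((w_up + w_down - w_up_new) / w_down)
    }
    z <- MASS::mvrnorm(2L * n_per, mu = rep(0, n_asv), Sigma = sigma)
    compartment <- rep(c("bulk", "rhizosphere"), each = n_per)
    host <- sample(c("Gramineae", "Leguminosae", "Solanaceae"),
                   2L * n_per, replace = TRUE)
    counts <- matrix(0L, 2L * n_per, n_asv)
    for (s in seq_len(2L * n_per)) {
      eta <- mu + z[s, ]
      if (compartment[s] == "rhizosphere") eta <- eta + shift[genera]
      p <- exp(eta - max(eta))
      counts[s, ] <- stats::rmultinom(1, cfg$depth, p / sum(p))[, 1]
    }
    sample_id <- sprintf("%s_%03d", ifelse(compartment == "bulk", "B", "R"),
                         c(seq_len(n_per), seq_len(n_per)))
    dimnames(counts) <- list(sample_id, ids)
    meta <- data.frame(
      sample_id = sample_id, compartment = compartment,
      host_family = host, kingdom = "bacteria", stringsAsFactors = FALSE
    )
    taxonomy <- data.frame(
      asv_id = ids, kingdom = "Bacteria", phylum = "Proteobacteria",
      class = "unassigned", order = "unassigned", family = "unassigned",
      genus = unname(genera), species = "unassigned",
      stringsAsFactors = FALSE
    )
    list(
      table = asv_table(counts, meta, taxonomy),
      truth = list(
        rho0 = cfg$rho0, beta = cfg$beta,
        differential_genera = diff_genera,
        differential_log2fc = stats::setNames(diff_sign * cfg$differential_lfc,
                                              diff_genera),
        target_correlation = target,
        tree_distance = dist_true
      )
    )
  })
}

# Nearest positive semi-definite correlation matrix by eigenvalue
# clipping, with the unit diagonal restored.
psd_repair <- function(m, eps = 1e-8) {
  e <- eigen(m, symmetric = TRUE)
  if (min(e$values) >= eps) return(m)
  v <- pmax(e$values, eps)
  out <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(diag(out))
  out <- out / tcrossprod(d)
  dimnames(out) <- dimnames(m)
  out
}

#' Simulate phylogenetically structured binary traits
#'
#' Each of `n_functions` KO-like traits evolves independently along every
#' genus tree under a symmetric binary gain/loss Markov process at rate
#' `trait_gain_loss` per unit branch length (so traits carry phylogenetic
#' signal). Two marker functions with known redundancy ordering are
#' appended: `KO_widespread` (carried by every ASV) and `KO_singleclade`
#' (carried only by the two closest ASVs of the first genus).
#'
#' @param cfg A `scenario_config`.
#' @param seqs Output of [simulate_genus_sequences()].
#' @return ASVs x functions 0/1 incidence matrix.
#' @export
simulate_traits <- function(cfg, seqs) {
  trees <- attr(seqs, "trees")
  if (is.null(trees)) stop("seqs must come from simulate_genus_sequences()")
  ids <- names(seqs$records)
  with_seed(seed_for(cfg, "traits"), {
    fun_ids <- sprintf("KO%05d", seq_len(cfg$n_functions))
    traits <- matrix(0L, length(ids), cfg$n_functions,
                     dimnames = list(ids, fun_ids))
    for (f in seq_len(cfg$n_functions)) {
      for (g in names(trees)) {
        root <- stats::rbinom(1, 1, 0.3)
        tips <- evolve_binary_trait(trees[[g]], cfg$trait_gain_loss, root)
        traits[names(tips), f] <- tips
      }
    }
    # marker functions with a guaranteed redundancy ordering
    widespread <- rep(1L, length(ids))
    single <- rep(0L, length(ids))
    first <- trees[[1]]
    coph <- ape::cophenetic.phylo(first)
    diag(coph) <- Inf
    closest <- arrayInd(which.min(coph), dim(coph))
    single[match(rownames(coph)[closest], ids)] <- 1L
    cbind(traits, KO_widespread = widespread, KO_singleclade = single)
  })
}

# Two-state symmetric Markov walk along a tree; returns tip states named
# by tip label. P(state change over branch t) = (1 - exp(-2 * rate * t)) / 2.
evolve_binary_trait <- function(tree, rate, root_state) {
  n_tip <- length(tree$tip.label)
  states <- integer(n_tip + tree$Nnode)
  states[n_tip + 1L] <- root_state
  tree <- stats::reorder(tree, "cladewise")  # parents before children
  for (k in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[k, 1]
    child <- tree$edge[k, 2]
    p_flip <- 0.5 * (1 - exp(-2 * rate * tree$edge.length[k]))
    flip <- stats::rbinom(1, 1, p_flip)
    states[child] <- if (flip == 1) 1L - states[parent] else states[parent]
  }
  stats::setNames(states[seq_len(n_tip)], tree$tip.label)
}

#' Simulate block-structured abundances for the network scenario
#'
#' Latent factors, one per block, generate within-block correlation
#' `within_r` and between-block correlation `noise_r`. Bridge nodes load
#' evenly on several blocks, planting connectors with high among-module
#' connectivity and betweenness; all bridge nodes carry
#' `bridge_kingdom`, the remaining nodes are bacteria. Node values are
#' exponentiated (lognormal abundances); rank-based correlation is
#' unaffected.
#'
#' @param cfg A `scenario_config` with `within_r > noise_r`.
#' @return List with `abund` (samples x nodes matrix), `node_meta`
#'   (node_id, kingdom), and `truth` (block membership, bridge ids).
#' @export
simulate_block_network_data <- function(cfg) {
  if (cfg$n_blocks < 2) stop("at least 2 blocks are required")
  b <- cfg$n_blocks
  n_reg <- b * cfg$nodes_per_block
  n_nodes <- n_reg + cfg$n_bridges
  n_s <- cfg$network_samples
  c_factor <- cfg$noise_r / cfg$within_r
  fac_cor <- matrix(c_factor, b, b)
  diag(fac_cor) <- 1
  with_seed(seed_for(cfg, "network"), {
    f <- MASS::mvrnorm(n_s, mu = rep(0, b), Sigma = fac_cor)
    w <- cfg$within_r
    block <- rep(seq_len(b), each = cfg$nodes_per_block)
    x <- matrix(0, n_s, n_nodes)
    for (j in seq_len(n_reg)) {
      x[, j] <- sqrt(w) * f[, block[j]] + sqrt(1 - w) * stats::rnorm(n_s)
    }
    bridge_blocks <- vector("list", cfg$n_bridges)
    if (cfg$n_bridges > 0) {
      for (k in seq_len(cfg$n_bridges)) {
        # spread bridges over the block list round-robin
        first <- ((k - 1L) * cfg$bridge_span) %% b
        spanned <- ((first + seq_len(cfg$bridge_span) - 1L) %% b) + 1L
        bridge_blocks[[k]] <- spanned
        a <- sqrt(0.95 / (cfg$bridge_span * (1 + (cfg$bridge_span - 1) * c_factor)))
        load <- rowSums(f[, spanned, drop = FALSE]) * a
        x[, n_reg + k] <- load +
          sqrt(max(1 - a^2 * cfg$bridge_span *
                     (1 + (cfg$bridge_span - 1) * c_factor), 0.01)) *
          stats::rnorm(n_s)
      }
    }
    node_id <- c(sprintf("B%03d", seq_len(n_reg)),
                 if (cfg$n_bridges > 0) sprintf("F%03d", seq_len(cfg$n_bridges)))
    colnames(x) <- node_id
    rownames(x) <- sprintf("S%03d", seq_len(n_s))
    mu <- stats::rnorm(n_nodes, 0, 1)
    abund <- exp(sweep(x, 2L, mu, "+"))
    node_meta <- data.frame(
      node_id = node_id,
      kingdom = c(rep("bacteria", n_reg),
                  rep(cfg$bridge_kingdom, cfg$n_bridges)),
      stringsAsFactors = FALSE
    )
    list(
      abund = abund,
      node_meta = node_meta,
      truth = list(
        block = stats::setNames(c(block, rep(NA_integer_, cfg$n_bridges)),
                                node_id),
        bridge_ids = if (cfg$n_bridges > 0) {
          stats::setNames(node_id[n_reg + seq_len(cfg$n_bridges)], NULL)
        } else character(0),
        bridge_blocks = bridge_blocks
      )
    )
  })
}

#' Simulate a pair-level niche-divergence scenario
#'
#' Draws `n_pairs` nucleotide distances uniformly on `(0, d_max)` and
#' proportionality values on the planted line `rho0 + beta * d` plus
#' Gaussian noise, clipped to `[-1, 1]` — the direct input for
#' [niche_divergence_regression()] recovery studies.
#'
#' @param cfg A `scenario_config` (`noise_sd`, `rho0`, `beta` are used).
#' @param n_pairs Number of pairs.
#' @param d_max Upper bound of the distance range.
#' @return Data frame with `asv_a`, `asv_b`, `genus`, `distance`, `rho`.
#' @export
simulate_pair_scenario <- function(cfg, n_pairs = 60L, d_max = 0.5) {
  with_seed(seed_for(cfg, "pairs"), {
    d <- stats::runif(n_pairs, 0, d_max)
    rho <- cfg$rho0 + cfg$beta * d + stats::rnorm(n_pairs, 0, cfg$noise_sd)
    rho <- pmin(1, pmax(-1, rho))
    data.frame(
      asv_a = sprintf("A%03d", seq_len(n_pairs)),
      asv_b = sprintf("B%03d", seq_len(n_pairs)),
      genus = "Genus_synthetic",
      distance = d,
      rho = rho,
      stringsAsFactors = FALSE
    )
  })
}
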