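#' Pipeline configuration
#'
#' Collects every stage parameter with the field defaults used throughout
#' the package: rarefaction depth 7000 (bacteria) / 4000 (fungi), the
#' abundance filter (mean relative abundance > 1e-4, occurrence > 0.15 or
#' 0.10 by kingdom), the closely-related window `d_max = 0.5` with
#' `r2_min = 0.1`, network cutoffs `r_min = 0.6` and `p_max = 0.001` with
#' an RMT scan grid, and Zi/Pi role thresholds 0.25 / 0.62.
#'
#' @param scenario A `scenario_config` describing the synthetic inputs.
#' @param out_dir Output directory for stage results.
#' @param rarefy_depth_bacteria,rarefy_depth_fungi Rarefaction depths.
#' @param mean_ra_min,occ_min_bacteria,occ_min_fungi Abundance filter.
#' @param d_max,r2_min Niche-divergence parameters.
#' @param r_min,p_max Network edge cutoffs (`r_min` is the fallback when
#'   the RMT scan selects no threshold).
#' @param rmt_grid,rmt_bins RMT scan settings.
#' @param zi_thr,pi_thr Keystone role thresholds.
#' @param bc_threshold Betweenness exceedance threshold for the
#'   cross-kingdom comparison.
#' @param use_rmt Whether the network stage adopts the RMT-chosen cutoff.
#' @param seed Pipeline seed (rarefaction, module detection).
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(scenario = scenario_config(),
                            out_dir = tempfile("rhizonet_run_"),
                            rarefy_depth_bacteria = 7000L,
                            rarefy_depth_fungi = 4000L,
                            mean_ra_min = 1e-4,
                            occ_min_bacteria = 0.15,
                            occ_min_fungi = 0.10,
                            d_max = 0.5,
                            r2_min = 0.1,
                            r_min = 0.6,
                            p_max = 0.001,
                            rmt_grid = seq(0.2, 0.8, by = 0.05),
                            rmt_bins = 12L,
                            zi_thr = 0.25,
                            pi_thr = 0.62,
                            bc_threshold = 1000,
                            use_rmt = TRUE,
                            seed = 1L) {
  cfg <- list(
    scenario = scenario, out_dir = out_dir,
    rarefy_depth_bacteria = as.integer(rarefy_depth_bacteria),
    rarefy_depth_fungi = as.integer(rarefy_depth_fungi),
    mean_ra_min = mean_ra_min, occ_min_bacteria = occ_min_bacteria,
    occ_min_fungi = occ_min_fungi, d_max = d_max, r2_min = r2_min,
    r_min = r_min, p_max = p_max, rmt_grid = rmt_grid,
    rmt_bins = as.integer(rmt_bins), zi_thr = zi_thr, pi_thr = pi_thr,
    bc_threshold = bc_threshold, use_rmt = isTRUE(use_rmt),
    seed = as.integer(seed)
  )
  if (!inherits(scenario, "scenario_config")) {
    stop("scenario must be a scenario_config")
  }
  if (cfg$d_max <= 0) stop("d_max must be positive")
  if (cfg$r2_min < 0 || cfg$r2_min > 1) stop("r2_min must lie in [0, 1]")
  if (cfg$r_min <= 0 || cfg$r_min >= 1) stop("r_min must lie in (0, 1)")
  if (cfg$p_max <= 0 || cfg$p_max > 1) stop("p_max must lie in (0, 1]")
  if (cfg$mean_ra_min < 0 || cfg$mean_ra_min > 1 ||
      cfg$occ_min_bacteria < 0 || cfg$occ_min_bacteria > 1 ||
      cfg$occ_min_fungi < 0 || cfg$occ_min_fungi > 1) {
    stop("filter thresholds must lie in [0, 1]")
  }
  if (cfg$rarefy_depth_bacteria < 1 || cfg$rarefy_depth_fungi < 1) {
    stop("rarefaction depths must be positive")
  }
  structure(cfg, class = "pipeline_config")
}

#' Run the full analysis pipeline on a synthetic scenario
#'
#' Executes, in order: input generation (sequences, count tables, traits,
#' network scenario, all written to and re-read from disk), sample/ASV
#' filtering (rarefaction, rare-ASV removal, abundance filter), community
#' statistics (Shannon diversity, Bray-Curtis + ANOSIM, differential
#' genera), the per-genus niche-divergence regression, functional
#' redundancy (per-compartment FRI with log-ratio contrast and
#' differential KOs), and the co-occurrence network stage (Spearman
#' correlations, RMT threshold scan, graph construction, modules, Zi-Pi
#' roles, centralities, cross-kingdom comparison) for each compartment.
#' Every stage writes TSV outputs under `out_dir/<stage>/`, and a JSON
#' manifest records parameters, seeds, and per-stage row counts.
#' Re-running with an identical configuration reproduces identical files.
#'
#' @param config A `pipeline_config`.
#' @return Invisibly, a list with all stage results plus `manifest`.
#' @export
run_all <- function(config) {
  if (!inherits(config, "pipeline_config")) stop("config must be a pipeline_config")
  out <- config$out_dir
  stages <- c("inputs", "filter", "community", "niche", "fri", "network")
  for (s in stages) dir.create(file.path(out, s), recursive = TRUE,
                               showWarnings = FALSE)
  manifest <- list(package = "rhizonet",
                   version = as.character(utils::packageVersion("rhizonet")),
                   seed = config$seed, scenario_seed = config$scenario$seed,
                   parameters = config[setdiff(names(config),
                                               c("scenario", "out_dir"))],
                   stages = list())
  note <- function(stage, ...) {
    manifest$stages[[stage]] <<- c(list(status = "ok"), list(...))
  }
  fail <- function(stage, e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }

  ## -- inputs ---------------------------------------------------------
  sim <- tryCatch({
    seqs <- simulate_genus_sequences(config$scenario)
    ab <- simulate_abundance_tables(config$scenario, seqs)
    traits <- simulate_traits(config$scenario, seqs)
    netdat <- simulate_block_network_data(config$scenario)
    write_fasta(seqs, file.path(out, "inputs", "asv_sequences.fasta"))
    write_asv_table(ab$table,
                    file.path(out, "inputs", "asv_counts.tsv"),
                    file.path(out, "inputs", "sample_metadata.tsv"),
                    file.path(out, "inputs", "taxonomy.tsv"))
    utils::write.table(
      data.frame(asv_id = rownames(traits), traits, check.names = FALSE),
      file.path(out, "inputs", "traits.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(differential_genera = ab$truth$differential_genera,
           differential_log2fc = as.list(ab$truth$differential_log2fc),
           rho0 = ab$truth$rho0, beta = ab$truth$beta,
           bridge_ids = netdat$truth$bridge_ids),
      file.path(out, "inputs", "ground_truth.json"),
      auto_unbox = TRUE, digits = 10)
    list(seqs = seqs, ab = ab, traits = traits, netdat = netdat)
  }, error = function(e) fail("inputs", e))
  # round-trip: downstream stages consume what was written to disk
  table <- read_asv_table(file.path(out, "inputs", "asv_counts.tsv"),
                          file.path(out, "inputs", "sample_metadata.tsv"),
                          file.path(out, "inputs", "taxonomy.tsv"))
  seqs <- read_fasta(file.path(out, "inputs", "asv_sequences.fasta"),
                     aligned = TRUE)
  note("inputs", n_samples = nrow(table$counts), n_asvs = ncol(table$counts))

  ## -- filter ---------------------------------------------------------
  filtered <- tryCatch({
    kingdom <- unique(table$sample_meta$kingdom)
    depth <- if (identical(kingdom, "fungi")) config$rarefy_depth_fungi else
      config$rarefy_depth_bacteria
    occ <- if (identical(kingdom, "fungi")) config$occ_min_fungi else
      config$occ_min_bacteria
    t1 <- rarefy(table, depth, seed = config$seed)
    t2 <- drop_rare_asvs(t1)
    t3 <- filter_abundant(t2, mean_ra_min = config$mean_ra_min, occ_min = occ)
    write_asv_table(t3, file.path(out, "filter", "filtered_counts.tsv"))
    t3
  }, error = function(e) fail("filter", e))
  note("filter", n_samples = nrow(filtered$counts),
       n_asvs = ncol(filtered$counts))

  ## -- community ------------------------------------------------------
  community <- tryCatch({
    ra <- relative_abundance(filtered)
    alpha <- data.frame(
      sample_id = rownames(ra),
      compartment = filtered$sample_meta$compartment,
      shannon = apply(filtered$counts, 1, shannon),
      stringsAsFactors = FALSE
    )
    bc <- bray_curtis_matrix(ra)
    ano <- anosim_test(bc, filtered$sample_meta$compartment,
                       n_perm = 999L, seed = config$seed)
    diff <- differential_genera(filtered)
    utils::write.table(alpha, file.path(out, "community", "alpha_diversity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(diff, file.path(out, "community", "differential_genera.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(alpha = alpha, anosim = ano, differential = diff)
  }, error = function(e) fail("community", e))
  note("community", anosim_R = community$anosim$R,
       n_significant_genera = sum(community$differential$significant))

  ## -- niche ----------------------------------------------------------
  niche <- tryCatch({
    scan <- niche_divergence_scan(filtered, seqs, d_max = config$d_max,
                                  r2_min = config$r2_min)
    if (!is.null(scan)) {
      utils::write.table(scan, file.path(out, "niche", "niche_divergence.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    scan
  }, error = function(e) fail("niche", e))
  note("niche", n_genera = if (is.null(niche)) 0L else nrow(niche))

  ## -- fri ------------------------------------------------------------
  fri <- tryCatch({
    traits <- sim$traits[asv_ids(filtered), , drop = FALSE]
    dists <- k80_matrix(subset_sequences(seqs, asv_ids(filtered)))
    dists[is.na(dists)] <- max(dists, na.rm = TRUE)  # saturated pairs capped
    off <- dists[upper.tri(dists)]
    d_ref <- mean(off)
    ra <- relative_abundance(filtered)
    comp <- filtered$sample_meta$compartment
    p_bulk <- colMeans(ra[comp == "bulk", , drop = FALSE])
    p_rhizo <- colMeans(ra[comp == "rhizosphere", , drop = FALSE])
    fri_bulk <- community_fri(p_bulk / sum(p_bulk), traits, dists, d_ref)
    fri_rhizo <- community_fri(p_rhizo / sum(p_rhizo), traits, dists, d_ref)
    lr <- fri_log_ratio(fri_rhizo, fri_bulk)
    ko_abund <- ra %*% traits
    diff_ko <- differential_functions(ko_abund, comp)
    utils::write.table(cbind(fri_bulk,
                             afri_rhizo = fri_rhizo$afri,
                             log_ratio = lr$log_ratio),
                       file.path(out, "fri", "fri_contrast.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(diff_ko, file.path(out, "fri", "differential_functions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(bulk = fri_bulk, rhizo = fri_rhizo, log_ratio = lr,
         differential = diff_ko, d_ref = d_ref)
  }, error = function(e) fail("fri", e))
  note("fri", n_functions = nrow(fri$log_ratio),
       n_significant_functions = sum(fri$differential$significant))

  ## -- network (one per compartment) ----------------------------------
  network <- tryCatch({
    lapply(c(bulk = "bulk", rhizosphere = "rhizosphere"), function(comp) {
      # compartment-specific half of the block scenario samples
      nd <- sim$netdat
      n_s <- nrow(nd$abund)
      rows <- if (comp == "bulk") seq_len(n_s %/% 2) else
        seq(n_s %/% 2 + 1, n_s)
      corr <- correlation_matrix(nd$abund[rows, , drop = FALSE])
      scan <- rmt_threshold(corr, grid = config$rmt_grid,
                            bins = config$rmt_bins)
      r_use <- if (config$use_rmt && !is.na(scan$chosen_threshold)) {
        scan$chosen_threshold
      } else config$r_min
      net <- build_network(corr, r_min = r_use, p_max = config$p_max,
                           node_meta = nd$node_meta)
      net <- detect_modules(net, seed = config$seed)
      net <- zi_pi(net, zi_thr = config$zi_thr, pi_thr = config$pi_thr)
      net <- network_centralities(net)
      cmp <- cross_kingdom_compare(net, bc_threshold = config$bc_threshold)
      summ <- network_summary(net)
      write_network(
        net,
        graphml_path = file.path(out, "network", paste0(comp, ".graphml")),
        edges_path = file.path(out, "network", paste0(comp, "_edges.tsv")),
        nodes_path = file.path(out, "network", paste0(comp, "_nodes.tsv")))
      utils::write.table(scan$scan,
                         file.path(out, "network", paste0(comp, "_rmt_scan.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      list(net = net, rmt = scan, summary = summ, compare = cmp,
           r_used = r_use)
    })
  }, error = function(e) fail("network", e))
  note("network",
       bulk_degree = network$bulk$summary$average_degree,
       rhizosphere_degree = network$rhizosphere$summary$average_degree)

  manifest$stages <- manifest$stages[stages]
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = 10, null = "null")
  invisible(list(
    table = table, filtered = filtered, community = community,
    niche = niche, fri = fri, network = network, truth = sim$ab$truth,
    network_truth = sim$netdat$truth, manifest = manifest,
    out_dir = out
  ))
}

#' All-pairs Bray-Curtis dissimilarity matrix
#'
#' @param abund Samples x ASVs abundance matrix.
#' @return Symmetric dissimilarity matrix with zero diagonal.
#' @export
bray_curtis_matrix <- function(abund) {
  m <- as.matrix(abund)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      d[i, j] <- d[j, i] <- bray_curtis(m[i, ], m[j, ])
    }
  }
  d
}

#' Subset a sequence set by id
#'
#' @param seqs A `sequence_set`.
#' @param ids ASV ids to keep (all must be present).
#' @return A `sequence_set` with the same `aligned` flag.
#' @export
subset_sequences <- function(seqs, ids) {
  missing <- setdiff(ids, names(seqs$records))
  if (length(missing)) {
    stop("sequences missing for: ", paste(missing, collapse = ", "))
  }
  sequence_set(seqs$records[ids], aligned = seqs$aligned)
}
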