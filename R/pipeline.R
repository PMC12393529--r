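derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 1000003 + k) %% 2147483647)
}

#' Run the full phylosymbiosis analysis from a YAML configuration
#'
#' Executes the requested stages in dependency order — simulate (or load
#' inputs), pangenome, phylogroups, network, cophylogeny, pangwas,
#' profiles — writing one TSV per result plus a JSON run manifest
#' recording the configuration snapshot, per-stage seeds, input file
#' digests and output paths. All randomized stages draw their seeds
#' deterministically from the top-level `seed`, which is required
#' whenever any randomized stage runs: re-running an identical
#' configuration reproduces identical outputs.
#'
#' The configuration holds one block per stage (see [default_config()]
#' for the threshold defaults), an optional `simulate:` block with
#' sub-blocks `cophylogeny`, `pangenome`, `ani`, `reads` (arguments of
#' the corresponding `simulate_*()` functions), an optional `inputs:`
#' block of file paths (`gene_matrix`, `metadata`, `ani`, `host_tree`,
#' `symbiont_tree`, `assoc`, `counts`, `genome_lengths`,
#' `library_sizes`), and a `stages:` list naming the stages to run.
#'
#' @param config path to a YAML configuration file.
#' @param out_dir output directory (created if missing).
#' @return the run manifest, invisibly (also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- read_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- cfg$stages %||% c("pangenome", "phylogroups", "network",
                              "cophylogeny", "pangwas", "profiles")
  randomized <- length(cfg$simulate) > 0 ||
    any(stages %in% c("pangenome", "cophylogeny", "profiles"))
  if (randomized && is.null(cfg$seed)) {
    stop("config must set a top-level `seed` when randomized stages run",
         call. = FALSE)
  }
  seed <- cfg$seed %||% 0L
  manifest <- list(tool = "symbiopan",
                   version = as.character(utils::packageVersion("symbiopan")),
                   config = cfg, seed = seed, stage_seeds = list(),
                   inputs = list(), outputs = list(), status = "running")
  fail <- function(stage, e) {
    manifest$status <<- sprintf("failed at stage '%s': %s", stage,
                                conditionMessage(e))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  }
  emit <- function(stage, name, path) {
    manifest$outputs[[stage]] <- c(manifest$outputs[[stage]],
                                   stats::setNames(list(path), name))
  }

  ## ---- inputs: simulated or loaded ------------------------------------
  inp <- list()
  tryCatch({
    if (!is.null(cfg$inputs)) {
      ip <- cfg$inputs
      for (nm in names(ip)) {
        manifest$inputs[[nm]] <- list(path = ip[[nm]],
                                      md5 = unname(tools::md5sum(ip[[nm]])))
      }
      if (!is.null(ip$gene_matrix)) inp$gene_matrix <- read_gene_matrix(ip$gene_matrix)
      if (!is.null(ip$metadata)) inp$metadata <- read_metadata(ip$metadata)
      if (!is.null(ip$ani)) inp$ani <- read_square_matrix(ip$ani, "similarity")
      if (!is.null(ip$host_tree)) inp$host_tree <- read_tree(ip$host_tree)
      if (!is.null(ip$symbiont_tree)) inp$symbiont_tree <- read_tree(ip$symbiont_tree)
      if (!is.null(ip$assoc)) inp$assoc <- read_association(ip$assoc)
      if (!is.null(ip$counts)) {
        inp$counts <- read_read_counts(ip$counts, ip$genome_lengths,
                                       ip$library_sizes)
      }
    }
    if (!is.null(cfg$simulate)) {
      sim_dir <- file.path(out_dir, "inputs")
      dir.create(sim_dir, showWarnings = FALSE)
      sm <- cfg$simulate
      if (!is.null(sm$cophylogeny)) {
        s <- derive_seed(seed, 1L)
        manifest$stage_seeds$simulate_cophylogeny <- s
        co <- do.call(simulate_cophylogeny, c(sm$cophylogeny, list(seed = s)))
        inp$host_tree <- co$host
        inp$symbiont_tree <- co$symbiont
        inp$assoc <- co$assoc
        write_tree(co$host, file.path(sim_dir, "host.nwk"))
        write_tree(co$symbiont, file.path(sim_dir, "symbiont.nwk"))
        write_association(co$assoc, file.path(sim_dir, "assoc.csv"))
      }
      if (!is.null(sm$pangenome)) {
        s <- derive_seed(seed, 2L)
        manifest$stage_seeds$simulate_pangenome <- s
        pg <- do.call(simulate_pangenome, c(sm$pangenome, list(seed = s)))
        inp$gene_matrix <- pg$matrix
        inp$metadata <- pg$metadata
        write_gene_matrix(pg$matrix, file.path(sim_dir, "gene_matrix.rtab"))
        write_metadata(pg$metadata, file.path(sim_dir, "metadata.tsv"))
      }
      if (!is.null(sm$ani)) {
        s <- derive_seed(seed, 3L)
        manifest$stage_seeds$simulate_ani <- s
        args <- sm$ani
        args$blocks <- lapply(args$blocks, function(b) c(b[[1L]], b[[2L]]))
        inp$ani <- do.call(simulate_ani, c(args, list(seed = s)))
        write_square_matrix(inp$ani, file.path(sim_dir, "ani.tsv"))
      }
      if (!is.null(sm$reads)) {
        if (is.null(inp$host_tree)) stop("reads simulation needs a cophylogeny block")
        s <- derive_seed(seed, 4L)
        manifest$stage_seeds$simulate_reads <- s
        inp$counts <- do.call(simulate_read_counts,
                              c(list(host_tree = inp$host_tree,
                                     assoc = inp$assoc), sm$reads,
                                list(seed = s)))
        write_read_counts(inp$counts, file.path(sim_dir, "counts.tsv"),
                          file.path(sim_dir, "genome_lengths.tsv"),
                          file.path(sim_dir, "library_sizes.tsv"))
      }
    }
  }, error = function(e) fail("inputs", e))

  summaries <- NULL
  phylo_assign <- NULL

  if ("pangenome" %in% stages) tryCatch({
    s <- derive_seed(seed, 10L)
    manifest$stage_seeds$pangenome <- s
    th <- cfg$pangenome$core_threshold
    meta <- inp$metadata
    all_sum <- partition_gene_families(inp$gene_matrix, th)
    host_sum <- partition_gene_families(
      inp$gene_matrix, th,
      subset = meta$genome_id[meta$lifestyle == "host_associated"],
      subset_label = "host_associated")
    free_sum <- partition_gene_families(
      inp$gene_matrix, th,
      subset = meta$genome_id[meta$lifestyle == "free_living"],
      subset_label = "free_living")
    summaries <- list(all = all_sum, host = host_sum, free = free_sum)
    chi <- gene_class_lifestyle_chisq(host_sum, free_sum)
    curve <- accumulation_curve(inp$gene_matrix,
                                cfg$pangenome$permutations, seed = s)
    tab <- do.call(rbind, lapply(summaries, function(x) {
      data.frame(subset = x$subset_label, n_core = x$n_core,
                 n_accessory = x$n_accessory, n_unique = x$n_unique,
                 pct_core = x$pct_core, pct_accessory = x$pct_accessory,
                 pct_unique = x$pct_unique)
    }))
    p1 <- file.path(out_dir, "pangenome_summary.tsv")
    utils::write.table(tab, p1, sep = "\t", quote = FALSE, row.names = FALSE)
    emit("pangenome", "summary", p1)
    p2 <- file.path(out_dir, "accumulation_curve.tsv")
    utils::write.table(
      data.frame(n_genomes = curve$n_genomes_axis,
                 mean_families = curve$mean_families,
                 sd_families = curve$sd_families), p2, sep = "\t",
      quote = FALSE, row.names = FALSE)
    emit("pangenome", "curve", p2)
    manifest$outputs$pangenome$chisq <- list(statistic = chi$statistic,
                                             df = chi$df,
                                             p_value = chi$p_value)
    manifest$outputs$pangenome$open_pangenome <- curve$open_pangenome
  }, error = function(e) fail("pangenome", e))

  if ("phylogroups" %in% stages) tryCatch({
    pa <- ani_cluster(inp$ani, cfg$phylogroups$ani_threshold,
                      cfg$phylogroups$linkage)
    phylo_assign <- pa
    p1 <- file.path(out_dir, "phylogroups.tsv")
    utils::write.table(
      data.frame(genome_id = names(pa$assignment),
                 phylogroup = unname(pa$assignment)), p1, sep = "\t",
      quote = FALSE, row.names = FALSE)
    emit("phylogroups", "assignment", p1)
    if (!is.null(inp$metadata) &&
        all(names(pa$assignment) %in% inp$metadata$genome_id)) {
      comp <- phylogroup_composition(pa, inp$metadata)
      manifest$outputs$phylogroups$composition <-
        comp[c("n_mixed", "n_host_only", "n_free_only", "pct_mixed",
               "pct_specific", "n_small")]
    }
  }, error = function(e) fail("phylogroups", e))

  if ("network" %in% stages) tryCatch({
    if (is.null(summaries)) {
      summaries <- list(all = partition_gene_families(
        inp$gene_matrix, cfg$pangenome$core_threshold))
    }
    acc <- filter_accessory(inp$gene_matrix, summaries$all,
                            cfg$network$prevalence)
    sim <- genome_similarity(acc, cfg$network$metric)
    pg_attr <- if (!is.null(phylo_assign) &&
                   setequal(names(phylo_assign$assignment), colnames(acc))) {
      phylo_assign
    } else NULL
    net <- build_network(sim, cfg$network$edge_threshold, inp$metadata,
                         pg_attr)
    p1 <- file.path(out_dir, "network_edges.tsv")
    p2 <- file.path(out_dir, "network.graphml")
    export_network(net, graphml_path = p2, edgelist_path = p1)
    emit("network", "edges", p1)
    emit("network", "graphml", p2)
    if (nrow(net$edges) && !is.null(net$nodes$lifestyle)) {
      manifest$outputs$network$assortativity_lifestyle <-
        label_assortativity(net, "lifestyle")
    }
  }, error = function(e) fail("network", e))

  if ("cophylogeny" %in% stages) tryCatch({
    s <- derive_seed(seed, 20L)
    manifest$stage_seeds$cophylogeny <- s
    cc <- cfg$cophylogeny
    pr <- paco(patristic_distances(inp$host_tree),
               patristic_distances(inp$symbiont_tree), inp$assoc,
               n_permutations = cc$permutations, scheme = cc$scheme,
               seed = s)
    rf <- if (length(inp$host_tree$tip.label) >= 4) {
      congruence_rf(inp$host_tree, inp$symbiont_tree, inp$assoc,
                    n_subsamples = cc$rf_subsamples, seed = s)
    } else NULL
    call <- classify_phylosymbiosis(pr$p_value, pr$r2,
                                    rf = if (is.null(rf)) NULL else rf$distance,
                                    alpha = cc$alpha, r2_high = cc$r2_high,
                                    r2_congruence = cc$r2_congruence)
    p1 <- file.path(out_dir, "cophylogeny.tsv")
    utils::write.table(
      data.frame(m2 = pr$m2, r2 = pr$r2, p_value = pr$p_value,
                 n_permutations = pr$n_permutations,
                 generalized_rf = if (is.null(rf)) NA else rf$distance,
                 signal = call$signal, congruence = call$congruence,
                 alpha = cc$alpha, r2_high = cc$r2_high,
                 r2_congruence = cc$r2_congruence),
      p1, sep = "\t", quote = FALSE, row.names = FALSE)
    emit("cophylogeny", "result", p1)
  }, error = function(e) fail("cophylogeny", e))

  if ("pangwas" %in% stages) tryCatch({
    hits <- fisher_association(inp$gene_matrix, inp$metadata,
                               alpha = cfg$pangwas$alpha,
                               fwer_cutoff = cfg$pangwas$fwer)
    p1 <- file.path(out_dir, "pangwas_hits.tsv")
    utils::write.table(hits, p1, sep = "\t", quote = FALSE, row.names = FALSE)
    emit("pangwas", "hits", p1)
    manifest$outputs$pangwas$n_passing <- sum(hits$passes)
  }, error = function(e) fail("pangwas", e))

  if ("profiles" %in% stages) tryCatch({
    s <- derive_seed(seed, 30L)
    manifest$stage_seeds$profiles <- s
    prof <- compute_rpkm(inp$counts, cfg$profiles$rpkm_threshold)
    p1 <- file.path(out_dir, "rpkm.tsv")
    utils::write.table(
      data.frame(sample = rownames(prof$rpkm), prof$rpkm,
                 check.names = FALSE), p1, sep = "\t", quote = FALSE,
      row.names = FALSE)
    emit("profiles", "rpkm", p1)
    bc <- bray_curtis(prof)
    p2 <- file.path(out_dir, "bray_curtis.tsv")
    write_square_matrix(bc, p2)
    emit("profiles", "bray_curtis", p2)
    dend <- upgma(bc)
    p3 <- file.path(out_dir, "profile_dendrogram.nwk")
    write_tree(dend, p3)
    emit("profiles", "dendrogram", p3)
    conc <- profile_concordance(inp$host_tree, prof,
                                n_permutations = cfg$profiles$permutations,
                                seed = s)
    manifest$outputs$profiles$concordance <- list(m2 = conc$m2, r2 = conc$r2,
                                                  p_value = conc$p_value)
  }, error = function(e) fail("profiles", e))

  ## digests make byte-identical reruns checkable
  all_paths <- character(0)
  for (st in manifest$outputs) {
    for (x in st) {
      if (is.character(x) && length(x) == 1 && file.exists(x)) {
        all_paths <- c(all_paths, x)
      }
    }
  }
  manifest$digests <- lapply(stats::setNames(all_paths, basename(all_paths)),
                             function(p) unname(tools::md5sum(p)))
  manifest$status <- "ok"
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  sp_log("run_pipeline: completed stages [%s] -> %s",
         paste(stages, collapse = ", "), out_dir)
  invisible(manifest)
}
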