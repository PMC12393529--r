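#' Filter the accessory genome by prevalence
#'
#' Keeps exactly the families classified accessory whose prevalence
#' strictly exceeds `prevalence` (core and unique families are
#' excluded). This is the input filter of the genome-genome network
#' stage.
#'
#' @param m binary family x genome matrix the summary was computed on.
#' @param summary `pangenome_summary` carrying the classification.
#' @param prevalence minimum prevalence fraction (strict `>`), default 0.05.
#' @return the filtered family x genome matrix.
#' @export
filter_accessory <- function(m, summary, prevalence = 0.05) {
  m <- validate_gene_matrix(m)
  stopifnot(inherits(summary, "pangenome_summary"))
  cls <- summary$classification
  if (is.null(cls)) stop("summary carries no per-family classification",
                         call. = FALSE)
  if (!all(names(cls) %in% rownames(m))) {
    stop("summary families not found in matrix", call. = FALSE)
  }
  acc <- names(cls)[cls == "accessory"]
  prev <- rowSums(m[acc, , drop = FALSE]) / ncol(m)
  keep <- acc[prev > prevalence]
  if (!length(keep)) {
    stop("no accessory families above prevalence ", prevalence,
         "; lower the filter or check the classification", call. = FALSE)
  }
  sp_log("filter_accessory: %d of %d accessory families above prevalence %g",
         length(keep), length(acc), prevalence)
  m[keep, , drop = FALSE]
}

#' Pairwise genome similarity from gene-family content
#'
#' Jaccard similarity (intersection over union of family sets; 0/0 is
#' defined as 0) or simple matching (agreeing cells over all families).
#'
#' @param m binary family x genome matrix.
#' @param metric `"jaccard"` or `"simple_matching"`.
#' @return a symmetric genome x genome similarity matrix.
#' @export
genome_similarity <- function(m, metric = c("jaccard", "simple_matching")) {
  metric <- match.arg(metric)
  if (!nrow(m) || !ncol(m)) stop("empty matrix", call. = FALSE)
  storage.mode(m) <- "double"
  inter <- crossprod(m)
  cs <- colSums(m)
  if (metric == "jaccard") {
    uni <- outer(cs, cs, "+") - inter
    s <- inter / uni
    s[uni == 0] <- 0
  } else {
    s <- (inter + (nrow(m) - (outer(cs, cs, "+") - inter))) / nrow(m)
  }
  s <- (s + t(s)) / 2
  attr(s, "mode") <- "similarity"
  s
}

#' Build a genome-genome network from a similarity matrix
#'
#' Edges connect every genome pair with similarity at or above
#' `edge_threshold`; isolated nodes are retained so lifestyle and
#' phylogroup attributes stay complete.
#'
#' @param sim symmetric similarity matrix.
#' @param edge_threshold minimum similarity for an edge, default 0.5.
#' @param metadata optional metadata data.frame (`genome_id`, `lifestyle`).
#' @param phylogroups optional `phylogroup_assignment`.
#' @return a `genome_network` with `nodes` and `edges` data.frames.
#' @export
build_network <- function(sim, edge_threshold = 0.5, metadata = NULL,
                          phylogroups = NULL) {
  sim <- validate_square_matrix(sim, "similarity")
  g <- rownames(sim)
  nodes <- data.frame(genome_id = g, stringsAsFactors = FALSE)
  if (!is.null(metadata)) {
    metadata <- validate_metadata(metadata)
    nodes$lifestyle <- stats::setNames(metadata$lifestyle,
                                       metadata$genome_id)[g]
  }
  if (!is.null(phylogroups)) {
    nodes$phylogroup <- phylogroups$assignment[g]
  }
  idx <- which(upper.tri(sim) & sim >= edge_threshold, arr.ind = TRUE)
  edges <- data.frame(from = g[idx[, 1L]], to = g[idx[, 2L]],
                      weight = sim[idx], stringsAsFactors = FALSE)
  sp_log("build_network: %d nodes, %d edges at similarity >= %g",
         length(g), nrow(edges), edge_threshold)
  structure(list(nodes = nodes, edges = edges,
                 edge_threshold = edge_threshold),
            class = "genome_network")
}

#' Convert a genome network to an igraph object
#' @param net a `genome_network`.
#' @return an undirected weighted [igraph::graph].
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "genome_network"))
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = net$nodes)
}

#' Export a genome network as GraphML and edge-list TSV
#' @param net a `genome_network`.
#' @param graphml_path,edgelist_path output files (either may be NULL).
#' @return invisibly, the written paths.
#' @export
export_network <- function(net, graphml_path = NULL, edgelist_path = NULL) {
  if (!is.null(graphml_path)) {
    igraph::write_graph(as_igraph(net), graphml_path, format = "graphml")
  }
  if (!is.null(edgelist_path)) {
    utils::write.table(net$edges, edgelist_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(c(graphml_path, edgelist_path))
}

#' Weighted categorical assortativity of a labeled network
#'
#' Newman's categorical assortativity coefficient generalized to edge
#' weights: with `e[i, j]` the fraction of total edge weight joining
#' labels i and j (each edge counted in both directions) and
#' `a = rowSums(e)`, the coefficient is
#' `(sum(diag(e)) - sum(a^2)) / (1 - sum(a^2))`. Values near 1 indicate
#' that edges stay within label classes (e.g. accessory-genome
#' similarity structured by phylogroup); values near 0 indicate mixing
#' (e.g. no grouping by lifestyle).
#'
#' @param net a `genome_network` with at least one edge.
#' @param label `"lifestyle"` or `"phylogroup"` (must be present among
#'   node attributes), or a named vector of labels.
#' @return the assortativity coefficient in \[-1, 1\] (NA when all nodes
#'   share one label).
#' @export
label_assortativity <- function(net, label = c("lifestyle", "phylogroup")) {
  stopifnot(inherits(net, "genome_network"))
  if (!nrow(net$edges)) stop("assortativity is undefined on an edgeless network",
                             call. = FALSE)
  if (is.character(label) && length(label) == 1L) {
    label <- match.arg(label)
    if (is.null(net$nodes[[label]])) {
      stop("network nodes carry no '", label, "' attribute", call. = FALSE)
    }
    labs <- stats::setNames(net$nodes[[label]], net$nodes$genome_id)
  } else {
    labs <- label
  }
  if (anyNA(labs[net$edges$from]) || anyNA(labs[net$edges$to])) {
    stop("labels missing for some endpoint genomes", call. = FALSE)
  }
  lev <- sort(unique(labs))
  e <- matrix(0, length(lev), length(lev), dimnames = list(lev, lev))
  w <- net$edges$weight
  lf <- as.character(labs[net$edges$from])
  lt <- as.character(labs[net$edges$to])
  for (k in seq_along(w)) {
    e[lf[k], lt[k]] <- e[lf[k], lt[k]] + w[k]
    e[lt[k], lf[k]] <- e[lt[k], lf[k]] + w[k]
  }
  e <- e / sum(e)
  a <- rowSums(e)
  denom <- 1 - sum(a^2)
  if (denom <= .Machine$double.eps) {
    sp_log("label_assortativity: single label class; coefficient undefined")
    return(NA_real_)
  }
  (sum(diag(e)) - sum(a^2)) / denom
}
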