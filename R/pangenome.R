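#' Build a pangenome summary from class counts
#'
#' Percentages are each count over the total, times 100, rounded to two
#' decimals.
#'
#' @param n_core,n_accessory,n_unique non-negative family counts.
#' @param core_threshold the prevalence fraction defining core families.
#' @param subset_label label of the genome subset the counts describe.
#' @param classification optional named factor recording each family's
#'   class (used downstream to filter the accessory genome).
#' @return a `pangenome_summary` object.
#' @export
pangenome_summary <- function(n_core, n_accessory, n_unique,
                              core_threshold = 0.95, subset_label = "all",
                              classification = NULL) {
  counts <- c(core = n_core, accessory = n_accessory, unique = n_unique)
  stopifnot(all(counts >= 0))
  total <- sum(counts)
  if (total == 0) stop("empty pangenome summary", call. = FALSE)
  pct <- round(100 * counts / total, 2)
  structure(list(n_core = n_core, n_accessory = n_accessory,
                 n_unique = n_unique, total = total,
                 pct_core = unname(pct["core"]),
                 pct_accessory = unname(pct["accessory"]),
                 pct_unique = unname(pct["unique"]),
                 core_threshold = core_threshold,
                 subset_label = subset_label,
                 classification = classification),
            class = "pangenome_summary")
}

#' @export
print.pangenome_summary <- function(x, ...) {
  cat(sprintf(
    "Pangenome [%s]: %d families | core %d (%.2f%%), accessory %d (%.2f%%), unique %d (%.2f%%); core prevalence > %g\n",
    x$subset_label, x$total, x$n_core, x$pct_core, x$n_accessory,
    x$pct_accessory, x$n_unique, x$pct_unique, x$core_threshold))
  invisible(x)
}

#' Partition gene families into core, accessory and unique
#'
#' A family present in exactly one genome of the subset is unique; a
#' family whose prevalence strictly exceeds `core_threshold` is core;
#' everything else is accessory. Families absent from the subset are
#' dropped before classification, so lifestyle-restricted pangenomes
#' have independent totals.
#'
#' @param m binary family x genome matrix.
#' @param core_threshold prevalence fraction (strict `>`), default 0.95.
#' @param subset optional genome IDs restricting the pangenome (>= 2).
#' @param subset_label label recorded in the summary.
#' @return a `pangenome_summary` with per-family `classification`.
#' @export
partition_gene_families <- function(m, core_threshold = 0.95, subset = NULL,
                                    subset_label = if (is.null(subset)) "all" else "subset") {
  m <- validate_gene_matrix(m)
  if (!is.null(subset)) {
    if (length(subset) == 0) stop("empty genome subset", call. = FALSE)
    bad <- setdiff(subset, colnames(m))
    if (length(bad)) stop("unknown genomes in subset: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    m <- m[, subset, drop = FALSE]
  }
  if (ncol(m) < 2) stop("need at least 2 genomes", call. = FALSE)
  cnt <- rowSums(m)
  present <- cnt > 0
  cnt <- cnt[present]
  prev <- cnt / ncol(m)
  cls <- ifelse(cnt == 1, "unique",
                ifelse(prev > core_threshold, "core", "accessory"))
  cls <- factor(cls, levels = c("core", "accessory", "unique"))
  names(cls) <- rownames(m)[present]
  out <- pangenome_summary(sum(cls == "core"), sum(cls == "accessory"),
                           sum(cls == "unique"), core_threshold,
                           subset_label, classification = cls)
  sp_log("partition_gene_families[%s]: %d genomes, %d families -> core %d / accessory %d / unique %d",
         subset_label, ncol(m), length(cls), out$n_core, out$n_accessory,
         out$n_unique)
  out
}

#' Gene accumulation curve and pangenome openness
#'
#' For `n_permutations` seeded random genome orderings, counts the
#' distinct gene families seen in every prefix, and reports the mean and
#' standard deviation per prefix length. Openness follows a Heaps'-law
#' fit `log(mean_families) = log(kappa) + gamma * log(N)` by least
#' squares over N >= 3: the pangenome is called open when `gamma`
#' exceeds `gamma_open` and families are still being gained at the last
#' genome added. With `family_filter = "accessory_only"` the count is
#' restricted to families classified accessory on the full matrix (their
#' curves typically asymptote even when unique genes keep the full
#' pangenome open).
#'
#' @param m binary family x genome matrix.
#' @param n_permutations number of random orderings (>= 1).
#' @param seed RNG seed.
#' @param family_filter `"all"` or `"accessory_only"`.
#' @param core_threshold passed to the classification when filtering.
#' @param gamma_open Heaps exponent above which the pangenome is open.
#' @return an `accumulation_curve` object with `n_genomes_axis`,
#'   `mean_families`, `sd_families`, `heaps_kappa`, `heaps_gamma`,
#'   `open_pangenome`.
#' @export
accumulation_curve <- function(m, n_permutations = 100, seed = 1,
                               family_filter = c("all", "accessory_only"),
                               core_threshold = 0.95, gamma_open = 0.02) {
  family_filter <- match.arg(family_filter)
  m <- validate_gene_matrix(m)
  stopifnot(n_permutations >= 1)
  if (family_filter == "accessory_only") {
    cls <- partition_gene_families(m, core_threshold)$classification
    keep <- names(cls)[cls == "accessory"]
    if (!length(keep)) stop("no accessory families to accumulate", call. = FALSE)
    m <- m[keep, , drop = FALSE]
  }
  n <- ncol(m)
  curves <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(b) {
      ord <- sample.int(n)
      first <- max.col(m[, ord, drop = FALSE], ties.method = "first")
      cumsum(tabulate(first, nbins = n))
    }, numeric(n))
  })
  curves <- matrix(curves, nrow = n)
  mu <- rowMeans(curves)
  sdv <- apply(curves, 1L, stats::sd)
  if (n_permutations == 1L) sdv <- rep(0, n)
  fit_n <- which(seq_len(n) >= 3 & mu > 0)
  if (length(fit_n) >= 2) {
    fit <- stats::lm(log(mu[fit_n]) ~ log(fit_n))
    kappa <- exp(unname(coef(fit)[1L]))
    gamma <- unname(coef(fit)[2L])
  } else {
    kappa <- mu[n]
    gamma <- 0
  }
  gain <- if (n >= 2) mu[n] - mu[n - 1L] else 0
  open <- gamma > gamma_open && gain > 0
  sp_log("accumulation_curve[%s]: %d genomes, %d permutations, gamma %.4f -> %s",
         family_filter, n, n_permutations, gamma,
         if (open) "open" else "closed")
  structure(list(n_genomes_axis = seq_len(n), mean_families = mu,
                 sd_families = sdv, n_permutations = n_permutations,
                 seed = seed, family_filter = family_filter,
                 heaps_kappa = kappa, heaps_gamma = gamma,
                 open_pangenome = open),
            class = "accumulation_curve")
}

#' Chi-squared test of gene class against lifestyle
#'
#' Pearson's chi-squared test (no continuity correction, df = 2) on the
#' 2 x 3 lifestyle-by-class count table built from two pangenome
#' summaries.
#'
#' @param host_summary,free_summary `pangenome_summary` objects for the
#'   host-associated and free-living genome subsets.
#' @return a list with `statistic`, `df`, `p_value` and the count
#'   `table`.
#' @export
gene_class_lifestyle_chisq <- function(host_summary, free_summary) {
  stopifnot(inherits(host_summary, "pangenome_summary"),
            inherits(free_summary, "pangenome_summary"))
  tab <- rbind(
    host_associated = c(core = host_summary$n_core,
                        accessory = host_summary$n_accessory,
                        unique = host_summary$n_unique),
    free_living = c(core = free_summary$n_core,
                    accessory = free_summary$n_accessory,
                    unique = free_summary$n_unique))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 1)) {
    sp_log("gene_class_lifestyle_chisq: expected cell below 1; chi-square approximation is unreliable")
  }
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = res$p.value, table = tab)
}
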