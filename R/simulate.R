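#' Simulate a host-symbiont cophylogeny
#'
#' Simulates a pure-birth (Yule) host tree forward in time and lets
#' symbiont lineages track it. At every host bifurcation each resident
#' symbiont lineage codiverges with probability
#' `1 - switch_prob - loss_prob`, jumps to a uniformly random co-existing
#' host branch with probability `switch_prob`, or is lost with
#' probability `loss_prob`. Losses are re-drawn (between codivergence
#' and switching, renormalized) whenever they would leave both daughter
#' hosts empty; daughters may still start empty when every resident
#' switches away, and empty hosts can be re-colonized by later
#' switches. Any host tip still empty at the present is colonized by a
#' terminal host switch -- a new tip grafted near a uniformly chosen
#' extant symbiont -- so every host ends with at least one symbiont.
#' Each host tip additionally gains `Poisson(multi_assoc_rate)` extra
#' symbiont lineages grafted near the tips of its resident symbionts.
#' Branch lengths accumulate host time, so under pure codivergence the
#' symbiont tree is an exact relabeled copy of the host tree.
#'
#' @param n_hosts number of host tips (>= 3).
#' @param birth_rate host speciation rate (> 0).
#' @param switch_prob per-bifurcation host-switch probability.
#' @param loss_prob per-bifurcation loss probability;
#'   `switch_prob + loss_prob` must not exceed 1.
#' @param multi_assoc_rate expected extra symbiont lineages per host tip.
#' @param seed RNG seed; the simulation is a pure function of its
#'   arguments.
#' @return a list with elements `host` (phylo), `symbiont` (phylo) and
#'   `assoc` (binary host x symbiont matrix).
#' @export
simulate_cophylogeny <- function(n_hosts, birth_rate = 1, switch_prob = 0,
                                 loss_prob = 0, multi_assoc_rate = 0,
                                 seed = 1) {
  stopifnot(n_hosts >= 3, birth_rate > 0, multi_assoc_rate >= 0)
  if (switch_prob < 0 || loss_prob < 0 || switch_prob + loss_prob > 1) {
    stop("switch_prob and loss_prob must be >= 0 with sum <= 1", call. = FALSE)
  }
  with_seed(seed, {
    ## --- host tree, forward in time ------------------------------------
    h_birth <- c(0)            # birth time per host lineage id
    h_split <- NA_real_        # split time (NA while unsplit)
    h_kids <- list(NULL)
    active <- 1L
    events <- list()           # chronological: (time, host, child1, child2)
    t <- 0
    while (length(active) < n_hosts) {
      t <- t + rexp(1L, birth_rate * length(active))
      h <- active[sample.int(length(active), 1L)]
      k1 <- length(h_birth) + 1L
      k2 <- k1 + 1L
      h_birth[c(k1, k2)] <- t
      h_split[c(k1, k2)] <- NA_real_
      h_split[h] <- t
      h_kids[[h]] <- c(k1, k2)
      h_kids[c(k1, k2)] <- list(NULL, NULL)
      active <- c(setdiff(active, h), k1, k2)
      events[[length(events) + 1L]] <- list(t = t, host = h, kids = c(k1, k2))
    }
    present <- t + rexp(1L, birth_rate * n_hosts)

    ## --- symbiont lineages tracking host events ------------------------
    s_host <- c(1L)            # current host per symbiont lineage
    s_birth <- c(0)
    s_end <- NA_real_
    s_kind <- "alive"          # alive | split | dead | tip
    s_kids <- list(NULL)
    host_active <- 1L
    for (ev in events) {
      host_active <- c(setdiff(host_active, ev$host), ev$kids)
      res <- which(s_kind == "alive" & s_host == ev$host)
      if (!length(res)) next     # empty host branch splits unobserved
      u <- runif(length(res))
      act <- ifelse(u < 1 - switch_prob - loss_prob, "codiv",
                    ifelse(u < 1 - loss_prob, "switch", "loss"))
      ## a loss may not leave both daughters empty: re-draw it between
      ## codivergence and switching (all-switch outcomes are allowed)
      if (!any(act == "codiv") && any(act == "loss")) {
        p_codiv <- if (switch_prob + loss_prob >= 1) 0 else
          (1 - switch_prob - loss_prob) / (1 - loss_prob)
        redraw <- act == "loss"
        act[redraw] <- ifelse(runif(sum(redraw)) < p_codiv, "codiv", "switch")
        if (!any(act == "codiv") && p_codiv > 0) {
          act[sample.int(length(res), 1L)] <- "codiv"
        }
      }
      for (i in seq_along(res)) {
        s <- res[i]
        if (act[i] == "codiv") {
          s_end[s] <- ev$t
          s_kind[s] <- "split"
          k1 <- length(s_host) + 1L
          k2 <- k1 + 1L
          s_host[c(k1, k2)] <- ev$kids
          s_birth[c(k1, k2)] <- ev$t
          s_end[c(k1, k2)] <- NA_real_
          s_kind[c(k1, k2)] <- "alive"
          s_kids[[s]] <- c(k1, k2)
          s_kids[c(k1, k2)] <- list(NULL, NULL)
        } else if (act[i] == "switch") {
          s_host[s] <- host_active[sample.int(length(host_active), 1L)]
        } else {
          s_end[s] <- ev$t
          s_kind[s] <- "dead"
        }
      }
    }
    tips <- which(s_kind == "alive")
    s_end[tips] <- present
    s_kind[tips] <- "tip"

    ## --- grafted lineages: colonizers of empty hosts + multi-association
    extras <- vector("list", length(s_host))  # per target tip: extra ids
    extra_host <- integer(0)                  # extra id -> host
    n_extra <- 0L
    graft <- function(tgt, h) {
      n_extra <<- n_extra + 1L
      extras[[tgt]] <<- c(extras[[tgt]], n_extra)
      extra_host[n_extra] <<- h
    }
    for (h in sort(host_active)) {            # terminal colonization
      if (!any(s_kind == "tip" & s_host == h)) {
        graft(tips[sample.int(length(tips), 1L)], h)
      }
    }
    if (multi_assoc_rate > 0) {
      for (h in sort(host_active)) {
        res <- which(s_kind == "tip" & s_host == h)
        k <- rpois(1L, multi_assoc_rate)
        if (k > 0L && length(res)) {
          for (j in seq_len(k)) {
            graft(res[sample.int(length(res), 1L)], h)
          }
        }
      }
    }

    ## --- assemble Newick strings ----------------------------------------
    host_nwk <- function(h) {
      len <- (if (is.na(h_split[h])) present else h_split[h]) - h_birth[h]
      if (is.null(h_kids[[h]])) {
        sprintf("H%d:%.10g", h, len)
      } else {
        sprintf("(%s,%s):%.10g", host_nwk(h_kids[[h]][1L]),
                host_nwk(h_kids[[h]][2L]), len)
      }
    }
    sym_nwk <- function(s) {   # returns list(str, len) or NULL if extinct
      len <- s_end[s] - s_birth[s]
      if (s_kind[s] == "dead") return(NULL)
      if (s_kind[s] == "tip") {
        lab <- sprintf("S%d", s)
        ex <- extras[[s]]
        if (length(ex)) {      # graft extras near the tip (10% of the branch)
          kids <- c(sprintf("%s:%.10g", lab, 0.1 * len),
                    sprintf("X%d:%.10g", ex, 0.1 * len))
          return(list(str = sprintf("(%s)", paste(kids, collapse = ",")),
                      len = 0.9 * len))
        }
        return(list(str = lab, len = len))
      }
      a <- sym_nwk(s_kids[[s]][1L])
      b <- sym_nwk(s_kids[[s]][2L])
      if (is.null(a) && is.null(b)) return(NULL)
      if (is.null(a)) return(list(str = b$str, len = b$len + len))
      if (is.null(b)) return(list(str = a$str, len = a$len + len))
      list(str = sprintf("(%s:%.10g,%s:%.10g)", a$str, a$len, b$str, b$len),
           len = len)
    }
    root <- sym_nwk(1L)
    host <- ape::read.tree(text = sprintf("%s;", sub(":[0-9.eE+-]+$", "",
                                                     host_nwk(1L))))
    symb <- ape::read.tree(text = sprintf("%s;", root$str))

    ## --- association matrix ---------------------------------------------
    tip_host <- integer(0)
    for (s in which(s_kind == "tip")) {
      tip_host[sprintf("S%d", s)] <- s_host[s]
      for (e in extras[[s]]) tip_host[sprintf("X%d", e)] <- extra_host[e]
    }
    assoc <- matrix(0L, nrow = n_hosts, ncol = length(tip_host),
                    dimnames = list(sprintf("H%d", sort(host_active)),
                                    names(tip_host)))
    for (nm in names(tip_host)) {
      assoc[sprintf("H%d", tip_host[[nm]]), nm] <- 1L
    }
    sp_log("simulate_cophylogeny: %d hosts, %d symbiont tips, seed %d",
           n_hosts, ncol(assoc), as.integer(seed))
    list(host = validate_tree(host), symbiont = validate_tree(symb),
         assoc = validate_association(assoc))
  })
}

#' Simulate a structured pangenome presence/absence matrix
#'
#' Generates `n_core` families at prevalence 1, `n_accessory` families
#' whose per-family prevalence is drawn from a Beta distribution
#' truncated to (1/n_genomes, 0.95), Poisson-distributed genome-unique
#' singleton families, and optionally `n_trait_genes` lifestyle-associated
#' families whose presence odds differ between host-associated and
#' free-living genomes by `trait_odds_ratio` (baseline presence
#' probability 0.3 in free-living genomes). Families that end up absent
#' from every genome are dropped.
#'
#' @param n_genomes number of genomes.
#' @param n_core,n_accessory family counts; their sum must be positive.
#' @param accessory_prevalence_ab Beta shape parameters for accessory
#'   prevalence.
#' @param unique_per_genome_mean Poisson mean of singleton families per
#'   genome.
#' @param n_trait_genes number of planted lifestyle-associated families.
#' @param trait_odds_ratio population odds ratio of the planted families.
#' @param lifestyle_fraction fraction of genomes labeled host_associated.
#' @param seed RNG seed.
#' @return list with `matrix` (binary families x genomes) and `metadata`
#'   (data.frame with `genome_id`, `lifestyle`, `pigmentation`).
#' @export
simulate_pangenome <- function(n_genomes = 60, n_core = 150,
                               n_accessory = 2000,
                               accessory_prevalence_ab = c(0.5, 1.5),
                               unique_per_genome_mean = 20,
                               n_trait_genes = 0, trait_odds_ratio = 1,
                               lifestyle_fraction = 0.6, seed = 1) {
  stopifnot(n_genomes >= 2, n_core >= 0, n_accessory >= 0,
            unique_per_genome_mean >= 0, n_trait_genes >= 0,
            trait_odds_ratio > 0,
            lifestyle_fraction > 0, lifestyle_fraction < 1)
  if (n_core + n_accessory + n_trait_genes == 0) {
    stop("need at least one core, accessory or trait family", call. = FALSE)
  }
  with_seed(seed, {
    genomes <- sprintf("G%03d", seq_len(n_genomes))
    n_host <- round(lifestyle_fraction * n_genomes)
    lifestyle <- rep(c("host_associated", "free_living"),
                     c(n_host, n_genomes - n_host))
    blocks <- list()
    if (n_core > 0) {
      core <- matrix(1L, n_core, n_genomes,
                     dimnames = list(sprintf("core_%04d", seq_len(n_core)), genomes))
      blocks <- c(blocks, list(core))
    }
    if (n_accessory > 0) {
      a <- accessory_prevalence_ab[1L]
      b <- accessory_prevalence_ab[2L]
      lo <- stats::pbeta(1 / n_genomes, a, b)
      hi <- stats::pbeta(0.95, a, b)
      prev <- stats::qbeta(runif(n_accessory, lo, hi), a, b)
      acc <- matrix(rbinom(n_accessory * n_genomes, 1L, rep(prev, n_genomes)),
                    nrow = n_accessory,
                    dimnames = list(sprintf("acc_%04d", seq_len(n_accessory)),
                                    genomes))
      blocks <- c(blocks, list(acc))
    }
    if (n_trait_genes > 0) {
      p0 <- 0.3
      odds1 <- trait_odds_ratio * p0 / (1 - p0)
      p1 <- odds1 / (1 + odds1)
      pg <- ifelse(lifestyle == "host_associated", p1, p0)
      tg <- matrix(rbinom(n_trait_genes * n_genomes, 1L,
                          rep(pg, each = n_trait_genes)),
                   nrow = n_trait_genes,
                   dimnames = list(sprintf("trait_%03d", seq_len(n_trait_genes)),
                                   genomes))
      blocks <- c(blocks, list(tg))
    }
    if (unique_per_genome_mean > 0) {
      k <- rpois(n_genomes, unique_per_genome_mean)
      if (sum(k) > 0) {
        uq <- matrix(0L, sum(k), n_genomes, dimnames = list(NULL, genomes))
        rn <- character(sum(k))
        r <- 0L
        for (g in seq_len(n_genomes)) {
          for (j in seq_len(k[g])) {
            r <- r + 1L
            uq[r, g] <- 1L
            rn[r] <- sprintf("uniq_%s_%d", genomes[g], j)
          }
        }
        rownames(uq) <- rn
        blocks <- c(blocks, list(uq))
      }
    }
    m <- do.call(rbind, blocks)
    storage.mode(m) <- "integer"
    drop <- rowSums(m) == 0L
    if (any(drop)) {
      sp_log("simulate_pangenome: dropping %d families absent everywhere",
             sum(drop))
      m <- m[!drop, , drop = FALSE]
    }
    meta <- data.frame(genome_id = genomes, lifestyle = lifestyle,
                       pigmentation = rep(c("pigmented", "nonpigmented"),
                                          length.out = n_genomes),
                       stringsAsFactors = FALSE)
    sp_log("simulate_pangenome: %d families x %d genomes, seed %d",
           nrow(m), n_genomes, as.integer(seed))
    list(matrix = validate_gene_matrix(m), metadata = validate_metadata(meta))
  })
}

#' Simulate a block-structured ANI similarity matrix
#'
#' @param blocks list of planted phylogroups, each a vector
#'   `c(size, within_sim)`.
#' @param between_sim similarity between genomes of different blocks;
#'   must be below every within-block similarity.
#' @param noise_sd standard deviation of symmetric Gaussian noise added
#'   to off-diagonal entries (values clipped to \[0, 1\]).
#' @param seed RNG seed.
#' @return a symmetric similarity matrix with unit diagonal; the planted
#'   block of each genome is stored in `attr(, "block")`.
#' @export
simulate_ani <- function(blocks, between_sim = 0.85, noise_sd = 0, seed = 1) {
  sizes <- vapply(blocks, function(b) b[[1L]], numeric(1))
  within <- vapply(blocks, function(b) b[[2L]], numeric(1))
  if (any(sizes < 1) || any(sizes != round(sizes))) {
    stop("block sizes must be positive integers", call. = FALSE)
  }
  if (any(within <= between_sim)) {
    stop("within-block similarity must exceed between_sim", call. = FALSE)
  }
  if (any(within > 1) || between_sim < 0) stop("similarities must lie in [0,1]",
                                               call. = FALSE)
  with_seed(seed, {
    n <- sum(sizes)
    block <- rep(seq_along(sizes), sizes)
    m <- matrix(between_sim, n, n)
    for (k in seq_along(sizes)) {
      idx <- which(block == k)
      m[idx, idx] <- within[k]
    }
    if (noise_sd > 0) {
      e <- matrix(0, n, n)
      e[upper.tri(e)] <- rnorm(n * (n - 1) / 2, 0, noise_sd)
      m <- m + e + t(e)
    }
    m <- pmin(pmax(m, 0), 1)
    diag(m) <- 1
    dimnames(m) <- list(sprintf("G%03d", seq_len(n)), sprintf("G%03d", seq_len(n)))
    attr(m, "mode") <- "similarity"
    attr(m, "block") <- stats::setNames(block, rownames(m))
    m
  })
}

#' Clade-block host-genome association
#'
#' Builds an association in which every clade of the host tree
#' contributes one symbiont genome linked to all of the clade's hosts
#' (plus one host-specific genome per tip). Two hosts then share as
#' many genomes as they have common ancestors, so read-recruitment
#' profiles simulated over this association mirror the host tree's
#' block structure -- the pattern a phylosymbiotic symbiont community
#' leaves in per-host metagenomes.
#'
#' @param host_tree a `phylo` host tree.
#' @return a binary host x genome association matrix.
#' @export
clade_association <- function(host_tree) {
  tips <- host_tree$tip.label
  n <- length(tips)
  clades <- ape::prop.part(host_tree)
  labs <- attr(clades, "labels")
  blocks <- c(lapply(clades, function(s) labs[s]), as.list(tips))
  assoc <- matrix(0L, n, length(blocks),
                  dimnames = list(tips, sprintf("CG%02d", seq_along(blocks))))
  for (j in seq_along(blocks)) assoc[blocks[[j]], j] <- 1L
  validate_association(assoc)
}

#' Simulate read-recruitment counts over a host-symbiont association
#'
#' One sample per host tip. Counts are Poisson with mean
#' `depth_mean * enrichment` for genomes linked to the sample's host and
#' `depth_mean` otherwise. Genome lengths are uniform on 3-6 Mbp;
#' library sizes are ten times each sample's mapped total (floored at 1
#' so an all-zero sample still yields a valid, all-zero RPKM row).
#'
#' @param host_tree host phylogeny whose tips define the samples.
#' @param assoc binary host x genome association matrix.
#' @param depth_mean baseline Poisson mean per genome.
#' @param enrichment fold enrichment on host-linked genomes (>= 1).
#' @param seed RNG seed.
#' @return a `read_count_table`; `attr(, "sample_host")` maps each
#'   sample to its host tip.
#' @export
simulate_read_counts <- function(host_tree, assoc, depth_mean = 2,
                                 enrichment = 50, seed = 1) {
  if (enrichment < 1) stop("enrichment must be >= 1", call. = FALSE)
  stopifnot(depth_mean >= 0)
  hosts <- host_tree$tip.label
  if (!setequal(hosts, rownames(assoc))) {
    stop("association hosts must match host tree tips", call. = FALSE)
  }
  assoc <- assoc[hosts, , drop = FALSE]
  with_seed(seed, {
    genomes <- colnames(assoc)
    lambda <- depth_mean * (1 + (enrichment - 1) * assoc)
    counts <- matrix(rpois(length(lambda), lambda), nrow = nrow(assoc),
                     dimnames = list(paste0("sample_", hosts), genomes))
    len <- round(runif(length(genomes), 3e6, 6e6))
    names(len) <- genomes
    lib <- pmax(rowSums(counts) * 10, 1)
    names(lib) <- rownames(counts)
    rc <- read_count_table(counts, len, lib)
    attr(rc, "sample_host") <- stats::setNames(hosts, rownames(counts))
    sp_log("simulate_read_counts: %d samples x %d genomes, seed %d",
           nrow(counts), ncol(counts), as.integer(seed))
    rc
  })
}
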