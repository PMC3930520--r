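#' Signed interaction counts within and between modules
#'
#' Intra-module counts are edges with both endpoints in the module.
#' Inter-module counts for a module pair are edges with one endpoint
#' exclusively in each module: genes shared by the two modules are excluded
#' from that pair's count, so multi-membership can never manufacture
#' crosstalk out of a single gene.
#'
#' @param net A `gi_network`.
#' @param modules A `module_set`.
#' @return Data.frame: module_a, module_b (module_a == module_b rows are
#'   intra counts), n_aggravating, n_alleviating, n_total.
#' @export
count_module_gis <- function(net, modules) {
  stopifnot(inherits(net, "gi_network"), inherits(modules, "module_set"))
  counts_from_membership(net$edges, modules$genes, modules$id)
}

counts_from_membership <- function(edges, gene_lists, ids) {
  nm <- length(gene_lists)
  out <- list()
  for (i in seq_len(nm)) {
    for (j in i:nm) {
      if (i == j) {
        mem <- gene_lists[[i]]
        sel <- edges$gene_a %in% mem & edges$gene_b %in% mem
      } else {
        ea <- setdiff(gene_lists[[i]], gene_lists[[j]])
        eb <- setdiff(gene_lists[[j]], gene_lists[[i]])
        sel <- (edges$gene_a %in% ea & edges$gene_b %in% eb) |
          (edges$gene_a %in% eb & edges$gene_b %in% ea)
      }
      out[[length(out) + 1L]] <- data.frame(
        module_a = ids[i], module_b = ids[j],
        n_aggravating = sum(sel & edges$sign == "aggravating"),
        n_alleviating = sum(sel & edges$sign == "alleviating"),
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  res$n_total <- res$n_aggravating + res$n_alleviating
  res
}

## 0/1 symmetric adjacency per sign over a fixed gene index
sign_adjacency <- function(edges, gene_index) {
  ng <- length(gene_index)
  one <- function(sel) {
    A <- matrix(0, ng, ng)
    if (any(sel)) {
      ia <- gene_index[edges$gene_a[sel]]
      ib <- gene_index[edges$gene_b[sel]]
      A[cbind(ia, ib)] <- A[cbind(ia, ib)] + 1
      A <- A + t(A)
    }
    A
  }
  agg <- edges$sign == "aggravating"
  list(agg = one(agg), all = one(!agg))
}

## module-pair count matrix from adjacency A and 0/1 incidence M
## (genes x modules); exact when no two modules share a gene. For sharing
## pairs the caller applies the exclusion correction.
counts_from_A <- function(A, M) {
  C <- crossprod(M, A %*% M)
  diag(C) <- diag(C) / 2
  C
}

## subtract contributions of genes shared between modules i and j from the
## inter count: exclusion rule counts only edges between exclusive members
apply_sharing_correction <- function(C, A, M, sharing_pairs) {
  for (k in seq_len(nrow(sharing_pairs))) {
    i <- sharing_pairs[k, 1]; j <- sharing_pairs[k, 2]
    ea <- M[, i] == 1 & M[, j] == 0
    eb <- M[, j] == 1 & M[, i] == 0
    C[i, j] <- C[j, i] <- sum(A[ea, eb, drop = FALSE])
  }
  C
}

#' Permutation enrichment of module-pair interaction counts
#'
#' Builds a null by permuting gene-to-module assignments among the tested
#' genes (preserving module sizes and each gene's number of memberships) —
#' or, alternatively, by degree-preserving rewiring of the network's edges —
#' and reports, per module pair, the observed signed counts, the null mean
#' and sd, the Z-score, and an add-one empirical p. A pair is classified
#' aggravating- or alleviating-enriched when its per-sign count passes
#' `Z >= z_min`, `p <= p_max` and (for inter-module pairs) at least
#' `min_edges` interactions.
#'
#' @param net A `gi_network`.
#' @param modules A `module_set`; genes outside the network's tested genes
#'   are dropped first.
#' @param n_perm Number of permutations (>= 100).
#' @param z_min,p_max,min_edges Significance conjunction thresholds
#'   (defaults 2.5, 0.05, 3).
#' @param rng_seed Optional seed.
#' @param null `"module_labels"` (default) or `"edge_rewire"`.
#' @return Data.frame of class `module_enrichment`: module_a, module_b,
#'   intra flag, per-sign observed counts, null mean/sd, Z (total count),
#'   empirical p, per-sign Z and p, and `classification` in
#'   {aggravating-enriched, alleviating-enriched, ns}. `Z` is `NA` when the
#'   null sd is zero; the empirical tail p is still reported.
#' @export
permutation_enrichment <- function(net, modules, n_perm = 1000, z_min = 2.5,
                                   p_max = 0.05, min_edges = 3,
                                   rng_seed = NULL,
                                   null = c("module_labels", "edge_rewire")) {
  stopifnot(inherits(net, "gi_network"), inherits(modules, "module_set"))
  null <- match.arg(null)
  if (n_perm < 100L) stop("n_perm must be >= 100", call. = FALSE)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  modules <- restrict_modules(modules, net$nodes)
  genes <- net$nodes
  ng <- length(genes)
  gene_index <- stats::setNames(seq_len(ng), genes)
  nm <- length(modules$id)
  M <- matrix(0, ng, nm, dimnames = list(genes, modules$id))
  for (j in seq_len(nm)) M[gene_index[modules$genes[[j]]], j] <- 1
  Asgn <- sign_adjacency(net$edges, gene_index)

  shared <- crossprod(M)
  sharing_pairs <- which(upper.tri(shared) & shared > 0, arr.ind = TRUE)
  count_both <- function(Aa, Av, Mb) {
    Ca <- counts_from_A(Aa, Mb); Cv <- counts_from_A(Av, Mb)
    if (nrow(sharing_pairs)) {
      Ca <- apply_sharing_correction(Ca, Aa, Mb, sharing_pairs)
      Cv <- apply_sharing_correction(Cv, Av, Mb, sharing_pairs)
    }
    list(agg = Ca, all = Cv)
  }
  obs <- count_both(Asgn$agg, Asgn$all, M)

  ut <- which(upper.tri(obs$agg, diag = TRUE), arr.ind = TRUE)
  obs_a <- obs$agg[ut]; obs_v <- obs$all[ut]; obs_t <- obs_a + obs_v
  np <- nrow(ut)
  sum_a <- sum2_a <- sum_v <- sum2_v <- sum_t <- sum2_t <- numeric(np)
  exc_a <- exc_v <- exc_t <- integer(np)

  for (b in seq_len(n_perm)) {
    if (null == "module_labels") {
      Mb <- M[sample.int(ng), , drop = FALSE]
      cnt <- count_both(Asgn$agg, Asgn$all, Mb)
    } else {
      g <- as_igraph(net, isolates = TRUE)
      g2 <- igraph::rewire(g, igraph::keeping_degseq(niter = 10 * igraph::ecount(g)))
      ends <- igraph::as_edgelist(g2)
      e2 <- data.frame(gene_a = ends[, 1], gene_b = ends[, 2],
                       sign = sample(net$edges$sign), stringsAsFactors = FALSE)
      Ab <- sign_adjacency(e2, gene_index)
      cnt <- count_both(Ab$agg, Ab$all, M)
    }
    a_b <- cnt$agg[ut]; v_b <- cnt$all[ut]; t_b <- a_b + v_b
    sum_a <- sum_a + a_b; sum2_a <- sum2_a + a_b^2
    sum_v <- sum_v + v_b; sum2_v <- sum2_v + v_b^2
    sum_t <- sum_t + t_b; sum2_t <- sum2_t + t_b^2
    exc_a <- exc_a + (a_b >= obs_a)
    exc_v <- exc_v + (v_b >= obs_v)
    exc_t <- exc_t + (t_b >= obs_t)
  }
  mstat <- function(s, s2) {
    mu <- s / n_perm
    sd <- sqrt(pmax(0, s2 / n_perm - mu^2) * n_perm / max(1, n_perm - 1))
    list(mu = mu, sd = sd)
  }
  st_a <- mstat(sum_a, sum2_a); st_v <- mstat(sum_v, sum2_v)
  st_t <- mstat(sum_t, sum2_t)
  zof <- function(obs, st) ifelse(st$sd > 0, (obs - st$mu) / st$sd, NA_real_)
  res <- data.frame(
    module_a = modules$id[ut[, 1]],
    module_b = modules$id[ut[, 2]],
    intra = ut[, 1] == ut[, 2],
    n_aggravating = obs_a, n_alleviating = obs_v, n_total = obs_t,
    null_mean = st_t$mu, null_sd = st_t$sd,
    Z = zof(obs_t, st_t),
    p = (1 + exc_t) / (1 + n_perm),
    Z_aggravating = zof(obs_a, st_a),
    p_aggravating = (1 + exc_a) / (1 + n_perm),
    Z_alleviating = zof(obs_v, st_v),
    p_alleviating = (1 + exc_v) / (1 + n_perm),
    stringsAsFactors = FALSE
  )
  edge_floor <- ifelse(res$intra, 1, min_edges)
  sig_a <- !is.na(res$Z_aggravating) & res$Z_aggravating >= z_min &
    res$p_aggravating <= p_max & res$n_aggravating >= edge_floor
  sig_v <- !is.na(res$Z_alleviating) & res$Z_alleviating >= z_min &
    res$p_alleviating <= p_max & res$n_alleviating >= edge_floor
  res$classification <- ifelse(
    sig_a & (!sig_v | res$Z_aggravating >= res$Z_alleviating), "aggravating-enriched",
    ifelse(sig_v, "alleviating-enriched", "ns"))
  class(res) <- c("module_enrichment", "data.frame")
  res
}

#' Interaction crosstalk between chaperone/protease families
#'
#' Counts network interactions within and between gene families (e.g.
#' Hsp40/70/90/100, small HSPs, ATP-dependent proteases, trigger factor)
#' and assigns each family pair a hypergeometric upper-tail p against the
#' background of all pairs among the listed genes present in the network.
#'
#' @param net A `gi_network`.
#' @param family_map Data.frame with columns `gene` and `family` (no
#'   missing/empty family labels).
#' @param p_max Significance threshold annotated on the output
#'   (default 0.09).
#' @return Data.frame: family_a, family_b, n_aggravating, n_alleviating,
#'   n_total, p, significant.
#' @export
chaperone_family_crosstalk <- function(net, family_map, p_max = 0.09) {
  stopifnot(inherits(net, "gi_network"), is.data.frame(family_map),
            all(c("gene", "family") %in% names(family_map)))
  if (any(is.na(family_map$family) | !nzchar(family_map$family)))
    stop("unknown (missing/empty) family label in family_map", call. = FALSE)
  fam <- family_map[family_map$gene %in% net$nodes, ]
  listed <- unique(fam$gene)
  families <- sort(unique(fam$family))
  fam_lists <- lapply(families, function(f) fam$gene[fam$family == f])
  names(fam_lists) <- families
  ed <- net$edges[net$edges$gene_a %in% listed & net$edges$gene_b %in% listed, ]
  cnt <- counts_from_membership(ed, fam_lists, families)
  names(cnt)[names(cnt) == "module_a"] <- "family_a"
  names(cnt)[names(cnt) == "module_b"] <- "family_b"
  n_listed <- length(listed)
  N_pairs <- choose(n_listed, 2)
  n_edges <- nrow(ed)
  sizes <- lengths(fam_lists)
  cap <- mapply(function(a, b) {
    if (a == b) choose(sizes[[a]], 2)
    else sizes[[a]] * sizes[[b]]
  }, cnt$family_a, cnt$family_b)
  cnt$p <- mapply(function(k, K) {
    if (K <= 0 || n_edges == 0) return(1)
    stats::phyper(k - 1, K, N_pairs - K, n_edges, lower.tail = FALSE)
  }, cnt$n_total, cap)
  cnt$significant <- cnt$p <= p_max & cnt$n_total > 0
  cnt
}

#' Jaccard similarity of interactor sets
#'
#' `J(A, B) = |A intersect B| / |A union B|` for every pair of the supplied
#' sets (e.g. the non-chaperone interactors of chaperone-containing
#' complexes). Undefined (NA) when both sets are empty.
#'
#' @param sets Named list of character vectors.
#' @return Symmetric matrix of Jaccard indices.
#' @export
shared_interactor_jaccard <- function(sets) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  n <- length(sets)
  J <- matrix(NA_real_, n, n, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(n)) {
    for (j in i:n) {
      u <- length(union(sets[[i]], sets[[j]]))
      J[i, j] <- J[j, i] <- if (u == 0) NA_real_ else
        length(intersect(sets[[i]], sets[[j]])) / u
    }
  }
  J
}

#' Per-gene interaction census with exclusive-partner analysis
#'
#' For each listed gene, its aggravating/alleviating degree in the network;
#' additionally flags the partners that interact with exactly one of the
#' listed genes ("exclusive" partners, interacting preferentially with a
#' single family member). Genes absent from the network get zero counts.
#'
#' @param net A `gi_network`.
#' @param genes Character vector of genes of interest.
#' @return List with `census` (data.frame: gene, n_aggravating,
#'   n_alleviating, n_total, n_exclusive_partners) and
#'   `exclusive_partners` (named list gene -> partners exclusive to it).
#' @export
per_gene_interaction_census <- function(net, genes) {
  stopifnot(inherits(net, "gi_network"))
  ed <- net$edges
  partner_of <- function(g) {
    c(ed$gene_b[ed$gene_a == g], ed$gene_a[ed$gene_b == g])
  }
  partners <- lapply(genes, partner_of)
  names(partners) <- genes
  signs <- lapply(genes, function(g) {
    c(ed$sign[ed$gene_a == g], ed$sign[ed$gene_b == g])
  })
  tab <- table(unlist(lapply(partners, unique)))
  exclusive <- lapply(genes, function(g) {
    p <- setdiff(unique(partners[[g]]), genes)
    p[tab[p] == 1L]
  })
  names(exclusive) <- genes
  census <- data.frame(
    gene = genes,
    n_aggravating = vapply(signs, function(s) sum(s == "aggravating"), 0L),
    n_alleviating = vapply(signs, function(s) sum(s == "alleviating"), 0L),
    stringsAsFactors = FALSE
  )
  census$n_total <- census$n_aggravating + census$n_alleviating
  census$n_exclusive_partners <- lengths(exclusive)
  list(census = census, exclusive_partners = exclusive)
}
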