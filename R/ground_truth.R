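#' Generate the ground truth behind a synthetic screen
#'
#' Draws the latent state of a synthetic eSGA-style screen: single-mutant
#' fitness for every gene, chromosome coordinates on a single circular
#' chromosome, planted functional modules (some laid out as operons, i.e.
#' contiguous on the chromosome), bioprocess annotations, the query gene set,
#' and a sparse map of planted epistasis deviations. Planted interactions
#' are concentrated inside designated coupled module pairs (with a fixed
#' sign per coupling, so module-level monochromaticity and crosstalk are
#' recoverable downstream) on top of a uniform background, with the overall
#' planting rate per tested pair held at `frac_aggravating` /
#' `frac_alleviating`.
#'
#' Deletion strains are mostly planted at fitness 1 (no defect on rich
#' medium) with a sick minority; hypomorphic alleles of essential genes draw
#' from a narrower, higher range because they are viable partial-function
#' alleles. Every arrayed strain has fitness > 0.
#'
#' @param config A [screen_config()].
#' @return An object of class `ground_truth`: list with `genes` (data.frame:
#'   gene, fitness, class, coordinate, operon_id, operon_pos, module_id,
#'   process), `queries`, `epsilon` (data.frame: query, recipient, epsilon),
#'   `modules` (a [module_set()]), `couplings` (data.frame), and the
#'   chromosome length.
#' @export
generate_ground_truth <- function(config) {
  stopifnot(inherits(config, "screen_config"))
  validate_screen_config(config)
  set.seed(config$rng_seed)
  n <- config$n_recipients
  genes <- sprintf("g%05d", seq_len(n))

  n_hyp <- round(config$frac_hypomorph * n)
  hypomorphs <- if (n_hyp > 0) sample(genes, n_hyp) else character(0)
  cls <- ifelse(genes %in% hypomorphs, "hypomorph", "deletion")

  fitness <- rep(1, n)
  is_del <- cls == "deletion"
  sick <- is_del & (stats::runif(n) < config$frac_sick_deletion)
  fitness[sick] <- stats::runif(sum(sick), config$sick_fitness_range[1],
                                config$sick_fitness_range[2])
  is_hyp <- !is_del
  fitness[is_hyp] <- stats::runif(sum(is_hyp), config$hypomorph_fitness_range[1],
                                  config$hypomorph_fitness_range[2])
  names(fitness) <- genes

  ## --- modules -------------------------------------------------------
  k <- config$module_size
  n_ess_mod <- if (n_hyp >= 3L) max(1L, floor(n_hyp / k / 2)) else 0L
  mod_genes <- list()
  mod_ess <- logical(0)
  pool_hyp <- sample(hypomorphs)
  for (i in seq_len(n_ess_mod)) {
    take <- min(k, length(pool_hyp))
    if (take < 3L) break
    mod_genes[[length(mod_genes) + 1L]] <- pool_hyp[seq_len(take)]
    pool_hyp <- pool_hyp[-seq_len(take)]
    mod_ess <- c(mod_ess, TRUE)
  }
  n_ess_mod <- length(mod_genes)
  n_rest <- max(0L, config$n_modules - n_ess_mod)
  pool_del <- sample(genes[is_del])
  for (i in seq_len(n_rest)) {
    if (length(pool_del) < k) break
    mod_genes[[length(mod_genes) + 1L]] <- pool_del[seq_len(k)]
    pool_del <- pool_del[-seq_len(k)]
    mod_ess <- c(mod_ess, FALSE)
  }
  n_mod <- length(mod_genes)
  names(mod_genes) <- sprintf("M%03d", seq_len(n_mod))
  ## alternate complexes and pathways; every other non-essential module is
  ## operonic (members contiguous on the chromosome)
  mod_type <- ifelse(seq_len(n_mod) %% 2L == 1L, "complex", "pathway")
  operonic <- !mod_ess & (seq_len(n_mod) %% 2L == 0L)

  ## --- coordinates ---------------------------------------------------
  L <- config$chromosome_length_bp
  coord <- sample.int(L, n)
  names(coord) <- genes
  for (m in which(operonic)) {
    mem <- mod_genes[[m]]
    anchor <- coord[mem[1]]
    coord[mem] <- (anchor + (seq_along(mem) - 1L) * 1000) %% L
  }
  while (anyDuplicated(coord)) {
    dup <- duplicated(coord)
    coord[dup] <- (coord[dup] + sample.int(997L, sum(dup), replace = TRUE)) %% L
  }

  operon_id <- rep(NA_character_, n)
  operon_pos <- rep(NA_integer_, n)
  names(operon_id) <- names(operon_pos) <- genes
  op_i <- 0L
  for (m in which(operonic)) {
    op_i <- op_i + 1L
    mem <- mod_genes[[m]]
    operon_id[mem] <- sprintf("op%03d", op_i)
    operon_pos[mem] <- seq_along(mem)
  }

  ## --- queries -------------------------------------------------------
  ## queries are seeded into modules (3 per "query module") so that coupled
  ## module pairs have several query-side members, giving recipients in the
  ## partner module correlated GI profiles; essential modules come first so
  ## hypomorph hubs exist, then non-operonic/operonic non-essential modules.
  ord <- c(which(mod_ess),
           which(!mod_ess & !operonic),
           which(!mod_ess & operonic))
  per_mod <- 3L
  query_mods <- ord[seq_len(min(length(ord), config$n_queries %/% per_mod))]
  queries <- character(0)
  for (m in query_mods) {
    queries <- c(queries, sample(mod_genes[[m]], min(per_mod, length(mod_genes[[m]]))))
  }
  queries <- unique(queries)
  if (length(queries) > config$n_queries) queries <- queries[seq_len(config$n_queries)]
  if (length(queries) < config$n_queries) {
    extra <- setdiff(genes, c(queries, unlist(mod_genes)))
    if (length(extra) < config$n_queries - length(queries))
      extra <- setdiff(genes, queries)
    queries <- c(queries, sample(extra, config$n_queries - length(queries)))
  }

  ## --- bioprocess annotations ---------------------------------------
  proc_lab <- sprintf("P%02d", seq_len(config$n_processes))
  process <- rep(NA_character_, n)
  names(process) <- genes
  for (m in seq_len(n_mod)) {
    process[mod_genes[[m]]] <- proc_lab[(m - 1L) %% config$n_processes + 1L]
  }
  unmod <- is.na(process)
  lab_draw <- stats::runif(sum(unmod)) < 0.8
  process[unmod][lab_draw] <- sample(proc_lab, sum(lab_draw), replace = TRUE)

  ## --- couplings -----------------------------------------------------
  ## essential query modules: aggravating within-module wiring; non-essential
  ## non-operonic query modules: alleviating within-module wiring (operonic
  ## self-pairs would be linkage-masked, so they are not self-coupled);
  ## every query module additionally crosses to a random non-query module.
  coup <- list()
  non_query_mods <- setdiff(seq_len(n_mod), query_mods)
  cross_sign <- c("aggravating", "alleviating")
  ci <- 0L
  for (j in seq_along(query_mods)) {
    m <- query_mods[j]
    if (mod_ess[m]) {
      coup[[length(coup) + 1L]] <- list(a = m, b = m, sign = "aggravating")
    } else if (!operonic[m]) {
      coup[[length(coup) + 1L]] <- list(a = m, b = m, sign = "alleviating")
    }
    if (length(non_query_mods) > 0L) {
      ci <- ci + 1L
      b <- non_query_mods[(ci - 1L) %% length(non_query_mods) + 1L]
      coup[[length(coup) + 1L]] <- list(a = m, b = b,
                                        sign = cross_sign[(ci - 1L) %% 2L + 1L])
    }
  }
  couplings <- if (length(coup)) {
    data.frame(
      module_a = names(mod_genes)[vapply(coup, `[[`, 0L, "a")],
      module_b = names(mod_genes)[vapply(coup, `[[`, 0L, "b")],
      sign = vapply(coup, `[[`, "", "sign"),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(module_a = character(0), module_b = character(0),
               sign = character(0), stringsAsFactors = FALSE)
  }

  ## --- planted epsilon -----------------------------------------------
  q_idx <- match(queries, genes)
  nq <- length(queries)
  key_of <- function(qi, ri) (as.numeric(qi) - 1) * n + ri
  ## coupled candidate pairs, deduplicated, first coupling wins
  cand_key <- numeric(0)
  cand_sign <- character(0)
  for (i in seq_len(nrow(couplings))) {
    ga <- mod_genes[[couplings$module_a[i]]]
    gb <- mod_genes[[couplings$module_b[i]]]
    qa <- intersect(queries, ga)
    if (length(qa) == 0L) next
    grid <- expand.grid(q = match(qa, genes), r = match(gb, genes))
    grid <- grid[grid$q != grid$r, , drop = FALSE]
    if (nrow(grid) == 0L) next
    kk <- key_of(grid$q, grid$r)
    new <- !kk %in% cand_key
    cand_key <- c(cand_key, kk[new])
    cand_sign <- c(cand_sign, rep(couplings$sign[i], sum(new)))
  }
  n_tot <- as.numeric(nq) * n - nq      # tested pairs (q, r), r != q
  n_coup_a <- sum(cand_sign == "aggravating")
  n_coup_v <- sum(cand_sign == "alleviating")
  n_bg <- n_tot - length(cand_key)

  plant_probs <- function(frac, n_coup) {
    target <- frac * n_tot
    p_hi <- config$coupled_density
    if (n_coup > 0 && p_hi * n_coup > target) p_hi <- target / n_coup
    p_bg <- if (n_bg > 0) max(0, (target - p_hi * n_coup) / n_bg) else 0
    c(p_hi = p_hi, p_bg = p_bg)
  }
  pa <- plant_probs(config$frac_aggravating, n_coup_a)
  pv <- plant_probs(config$frac_alleviating, n_coup_v)

  ## coupled draws
  keep_a <- cand_sign == "aggravating" & stats::runif(length(cand_key)) < pa["p_hi"]
  keep_v <- cand_sign == "alleviating" & stats::runif(length(cand_key)) < pv["p_hi"]
  eps_key <- cand_key[keep_a | keep_v]
  eps_sign <- ifelse(keep_a[keep_a | keep_v], "aggravating", "alleviating")

  ## background draws: binomial counts, then uniform pair indices avoiding
  ## self pairs and coupled candidates
  draw_bg <- function(count, avoid) {
    if (count == 0L) return(numeric(0))
    got <- numeric(0)
    while (length(got) < count) {
      idx <- sample(n_tot + nq, 2L * (count - length(got)) + 10L, replace = TRUE)
      qi <- (idx - 1) %/% n + 1
      ri <- (idx - 1) %% n + 1
      ok <- q_idx[qi] != ri
      kk <- key_of(q_idx[qi][ok], ri[ok])
      kk <- kk[!kk %in% avoid & !kk %in% got]
      got <- c(got, unique(kk))
    }
    got[seq_len(count)]
  }
  n_bg_a <- stats::rbinom(1L, max(0L, round(n_bg)), pa["p_bg"])
  avoid <- c(cand_key, eps_key)
  bg_a <- draw_bg(n_bg_a, avoid)
  n_bg_v <- stats::rbinom(1L, max(0L, round(n_bg)), pv["p_bg"])
  bg_v <- draw_bg(n_bg_v, c(avoid, bg_a))

  all_key <- c(eps_key, bg_a, bg_v)
  all_sign <- c(eps_sign, rep("aggravating", length(bg_a)),
                rep("alleviating", length(bg_v)))
  qi <- (all_key - 1) %/% n + 1
  ri <- (all_key - 1) %% n + 1
  eps_val <- numeric(length(all_key))
  is_a <- all_sign == "aggravating"
  eps_val[is_a] <- stats::runif(sum(is_a), config$eps_aggravating[1],
                                config$eps_aggravating[2])
  eps_val[!is_a] <- stats::runif(sum(!is_a), config$eps_alleviating[1],
                                 config$eps_alleviating[2])
  epsilon <- data.frame(
    query = genes[qi],
    recipient = genes[ri],
    epsilon = eps_val,
    coupled = all_key %in% eps_key,
    stringsAsFactors = FALSE
  )

  gene_df <- data.frame(
    gene = genes,
    fitness = unname(fitness),
    class = cls,
    coordinate = unname(coord),
    operon_id = unname(operon_id),
    operon_pos = unname(operon_pos),
    module_id = NA_character_,
    process = unname(process),
    stringsAsFactors = FALSE
  )
  for (m in seq_len(n_mod)) gene_df$module_id[match(mod_genes[[m]], genes)] <- names(mod_genes)[m]

  modules <- if (n_mod > 0) {
    module_set(mod_genes, type = mod_type)
  } else {
    NULL
  }

  out <- list(
    genes = gene_df,
    queries = queries,
    epsilon = epsilon,
    modules = modules,
    module_essential = stats::setNames(mod_ess, names(mod_genes)),
    module_operonic = stats::setNames(operonic, names(mod_genes)),
    couplings = couplings,
    chromosome_length_bp = L,
    config = config
  )
  class(out) <- "ground_truth"
  out
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("ground_truth: %d genes (%d hypomorphs), %d queries, %d modules, %d planted interactions\n",
              nrow(x$genes), sum(x$genes$class == "hypomorph"),
              length(x$queries),
              if (is.null(x$modules)) 0L else length(x$modules),
              nrow(x$epsilon)))
  invisible(x)
}

#' Circular chromosome distance between coordinates
#'
#' @param a,b Coordinates in bp.
#' @param chromosome_length_bp Circle length in bp.
#' @return The shorter arc distance, elementwise.
#' @export
circular_distance <- function(a, b, chromosome_length_bp) {
  d <- abs(a - b) %% chromosome_length_bp
  pmin(d, chromosome_length_bp - d)
}
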