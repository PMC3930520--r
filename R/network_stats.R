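#' Topology of the signed GI network
#'
#' Degree (total and per sign), normalized shortest-path betweenness on the
#' unsigned graph, the network average clustering coefficient (mean local
#' clustering over all nodes, nodes with degree < 2 contributing 0 — the
#' Watts-Strogatz average), and the list of hubs at `hub_min_degree`.
#' Only genes incident to at least one edge are scored; the hub threshold
#' default matches a genome-scale screen and should be lowered for small
#' networks.
#'
#' @param net A `gi_network`.
#' @param hub_min_degree Total degree at or above which a node is a hub
#'   (default 640).
#' @return A list of class `topology_report`: `node_stats` (data.frame:
#'   gene, degree, degree_aggravating, degree_alleviating, betweenness),
#'   `acc` (average clustering coefficient), `hubs`.
#' @export
gi_topology <- function(net, hub_min_degree = 640) {
  stopifnot(inherits(net, "gi_network"))
  if (nrow(net$edges) == 0L) stop("empty network", call. = FALSE)
  g <- as_igraph(net, isolates = FALSE)
  deg <- igraph::degree(g)
  agg <- net$edges$sign == "aggravating"
  deg_a <- table(factor(c(net$edges$gene_a[agg], net$edges$gene_b[agg]),
                        levels = names(deg)))
  deg_v <- table(factor(c(net$edges$gene_a[!agg], net$edges$gene_b[!agg]),
                        levels = names(deg)))
  btw <- igraph::betweenness(g, directed = FALSE, normalized = TRUE)
  loc <- igraph::transitivity(g, type = "local", isolates = "zero")
  node_stats <- data.frame(
    gene = names(deg),
    degree = as.integer(deg),
    degree_aggravating = as.integer(deg_a),
    degree_alleviating = as.integer(deg_v),
    betweenness = unname(btw),
    stringsAsFactors = FALSE
  )
  out <- list(node_stats = node_stats,
              acc = mean(loc),
              hubs = names(deg)[deg >= hub_min_degree])
  class(out) <- "topology_report"
  out
}

#' @export
print.topology_report <- function(x, ...) {
  cat(sprintf("topology_report: %d connected genes, ACC = %.3f, %d hubs\n",
              nrow(x$node_stats), x$acc, length(x$hubs)))
  invisible(x)
}

#' Contrast network centrality of essential vs non-essential genes
#'
#' Compares the degree and betweenness distributions of essential
#' (hypomorph) and non-essential (deletion) genes with a two-sided
#' Mann-Whitney rank-sum test.
#'
#' @param report A [gi_topology()] result.
#' @param annotations Data.frame with columns `gene` and `essential`
#'   (logical) or `class` (`"hypomorph"` / `"deletion"`).
#' @return List with per-class medians and rank-sum p-values for degree and
#'   betweenness.
#' @export
essentiality_contrast <- function(report, annotations) {
  stopifnot(inherits(report, "topology_report"))
  ess <- essential_flag(annotations)
  ns <- report$node_stats
  flag <- ess[ns$gene]
  if (all(flag, na.rm = TRUE) || !any(flag, na.rm = TRUE))
    stop("both essential and non-essential genes are required", call. = FALSE)
  keep <- !is.na(flag)
  ns <- ns[keep, ]; flag <- flag[keep]
  wt_deg <- stats::wilcox.test(ns$degree[flag], ns$degree[!flag], exact = FALSE)
  wt_btw <- stats::wilcox.test(ns$betweenness[flag], ns$betweenness[!flag],
                               exact = FALSE)
  ## complete ties leave the normal approximation undefined: no evidence of
  ## a difference
  if (is.nan(wt_deg$p.value)) wt_deg$p.value <- 1
  if (is.nan(wt_btw$p.value)) wt_btw$p.value <- 1
  list(
    median_degree = c(essential = stats::median(ns$degree[flag]),
                      non_essential = stats::median(ns$degree[!flag])),
    median_betweenness = c(essential = stats::median(ns$betweenness[flag]),
                           non_essential = stats::median(ns$betweenness[!flag])),
    p_degree = wt_deg$p.value,
    p_betweenness = wt_btw$p.value,
    n = c(essential = sum(flag), non_essential = sum(!flag))
  )
}

essential_flag <- function(annotations) {
  stopifnot(is.data.frame(annotations), "gene" %in% names(annotations))
  if ("essential" %in% names(annotations)) {
    stats::setNames(as.logical(annotations$essential), annotations$gene)
  } else if ("class" %in% names(annotations)) {
    stats::setNames(annotations$class == "hypomorph", annotations$gene)
  } else {
    stop("annotations need an 'essential' or 'class' column", call. = FALSE)
  }
}

#' Aggravating-to-alleviating ratio within essential vs non-essential complexes
#'
#' Counts network edges whose two endpoints share a complex, splits them by
#' the complex's essentiality (a complex is essential when at least half its
#' members are essential), and tests the 2x2 sign-by-essentiality table with
#' a two-sided Fisher's exact test.
#'
#' @param net A `gi_network`.
#' @param modules A `module_set`; only `type == "complex"` entries are used.
#' @param annotations See [essentiality_contrast()].
#' @return List with the 2x2 `table` (rows: essential/non-essential
#'   complexes; columns: aggravating/alleviating), per-class ratios, and the
#'   Fisher p-value.
#' @export
complex_sign_ratio <- function(net, modules, annotations) {
  stopifnot(inherits(net, "gi_network"), inherits(modules, "module_set"))
  ess <- essential_flag(annotations)
  cx <- which(modules$type == "complex")
  if (length(cx) == 0L) stop("no complexes in module set", call. = FALSE)
  cx_ess <- vapply(cx, function(i) {
    mean(ess[modules$genes[[i]]], na.rm = TRUE) >= 0.5
  }, logical(1))
  counts <- matrix(0L, 2, 2,
                   dimnames = list(c("essential", "non_essential"),
                                   c("aggravating", "alleviating")))
  ed <- net$edges
  for (k in seq_along(cx)) {
    mem <- modules$genes[[cx[k]]]
    inmod <- ed$gene_a %in% mem & ed$gene_b %in% mem
    if (!any(inmod)) next
    row <- if (cx_ess[k]) 1L else 2L
    counts[row, 1] <- counts[row, 1] + sum(inmod & ed$sign == "aggravating")
    counts[row, 2] <- counts[row, 2] + sum(inmod & ed$sign == "alleviating")
  }
  if (sum(counts) == 0L)
    stop("no within-complex edges; ratio not computable", call. = FALSE)
  ft <- stats::fisher.test(counts, alternative = "two.sided")
  list(table = counts,
       ratio = c(essential = counts[1, 1] / max(1L, counts[1, 2]),
                 non_essential = counts[2, 1] / max(1L, counts[2, 2])),
       p = ft$p.value)
}
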