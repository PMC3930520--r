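#' Build the recipient array layout
#'
#' Recipients are distributed over layout plates at `plate_density /
#' n_colony_duplicates` unique strains per plate, each strain occupying
#' `n_colony_duplicates` randomly placed positions. The layout is fixed
#' across queries and replicate screens, as in a pinned arrayed collection.
#' Unfilled positions on the last plate are empty (recipient `NA`).
#'
#' @param truth A [generate_ground_truth()] result.
#' @param config The matching [screen_config()].
#' @return A `strain_layout` data.frame: layout_plate, row, col, recipient,
#'   dup_group.
#' @keywords internal
build_layouts <- function(truth, config) {
  dims <- plate_dims(config$plate_density)
  n_per_plate <- config$plate_density %/% config$n_colony_duplicates
  genes <- truth$genes$gene
  n <- length(genes)
  n_plates <- ceiling(n / n_per_plate)
  if (n_plates < 1L)
    stop("layout error: no recipients to array", call. = FALSE)
  order_g <- sample(genes)
  ## balance occupancy so no plate is left nearly empty: plate scale can
  ## only be anchored against the plate's own strain-fitness distribution,
  ## which needs a decent number of resident strains
  sizes <- rep(n %/% n_plates, n_plates)
  if (n %% n_plates) sizes[seq_len(n %% n_plates)] <- sizes[seq_len(n %% n_plates)] + 1L
  bounds <- cumsum(c(0L, sizes))
  out <- vector("list", n_plates)
  pos_grid <- expand.grid(row = seq_len(dims["rows"]), col = seq_len(dims["cols"]))
  for (p in seq_len(n_plates)) {
    mem <- order_g[(bounds[p] + 1L):bounds[p + 1L]]
    slots <- rep(c(mem, rep(NA_character_, n_per_plate - length(mem))),
                 times = config$n_colony_duplicates)
    dup <- rep(seq_len(n_per_plate), times = config$n_colony_duplicates)
    perm <- sample.int(config$plate_density)
    out[[p]] <- data.frame(
      layout_plate = p,
      row = pos_grid$row,
      col = pos_grid$col,
      recipient = slots[perm],
      dup_group = ifelse(is.na(slots[perm]), NA_integer_, dup[perm]),
      stringsAsFactors = FALSE
    )
  }
  layouts <- do.call(rbind, out)
  class(layouts) <- c("strain_layout", "data.frame")
  layouts
}

#' Simulate colony-array plates for a synthetic screen
#'
#' Colony sizes follow the multiplicative model: plate scale (with lognormal
#' batch wobble) x smooth sinusoidal row/column gradients with an additive
#' edge boost x query fitness x recipient fitness x (1 + planted epistasis
#' deviation) x lognormal measurement noise. Pairs whose loci lie within
#' the linkage window on the circular chromosome are additionally suppressed
#' by a fixed multiplicative factor, mimicking reduced recombination between
#' closely linked markers. Each pair is measured
#' `n_colony_duplicates * n_replicate_screens * 2` times (duplicate colonies,
#' replicate screens, and two pinned plate copies per screen).
#'
#' @param truth A [generate_ground_truth()] result.
#' @param config The matching [screen_config()].
#' @return A list of class `screen_plates` with `plates` (long data.frame:
#'   plate_id, query, replicate, copy, layout_plate, batch, row, col, size)
#'   and `layouts` (the [build_layouts()] data.frame).
#' @export
simulate_plates <- function(truth, config) {
  stopifnot(inherits(truth, "ground_truth"), inherits(config, "screen_config"))
  if (nrow(truth$genes) != config$n_recipients)
    stop("truth and config disagree on the number of recipients", call. = FALSE)
  set.seed(config$rng_seed + 1L)
  dims <- plate_dims(config$plate_density)
  layouts <- build_layouts(truth, config)

  genes <- truth$genes$gene
  fit <- stats::setNames(truth$genes$fitness, genes)
  coord <- stats::setNames(truth$genes$coordinate, genes)
  L <- truth$chromosome_length_bp

  ## positive smooth gradients + additive edge boost
  rows <- seq_len(dims["rows"]); cols <- seq_len(dims["cols"])
  row_f <- 1 + config$spatial_row_amp * sin(2 * pi * (rows - 1) / max(1, dims["rows"] - 1)) +
    config$edge_boost * (rows %in% c(1L, dims["rows"]))
  col_f <- 1 + config$spatial_col_amp * cos(2 * pi * (cols - 1) / max(1, dims["cols"] - 1)) +
    config$edge_boost * (cols %in% c(1L, dims["cols"]))

  lp_split <- split(seq_len(nrow(layouts)), layouts$layout_plate)
  n_lp <- length(lp_split)
  queries <- truth$queries
  nrep <- config$n_replicate_screens
  ncopy <- 2L
  cells_per_plate <- config$plate_density
  n_plate_total <- length(queries) * nrep * ncopy * n_lp

  res <- vector("list", n_plate_total)
  pl_i <- 0L
  for (q in queries) {
    eps_vec <- stats::setNames(rep(0, length(genes)), genes)
    sel <- truth$epsilon$query == q
    if (any(sel)) eps_vec[truth$epsilon$recipient[sel]] <- truth$epsilon$epsilon[sel]
    linked_vec <- circular_distance(coord[q], coord, L) < config$linkage_window_bp
    f_q <- fit[q]
    for (rep_i in seq_len(nrep)) {
      for (copy_i in seq_len(ncopy)) {
        for (lp in seq_len(n_lp)) {
          lay <- layouts[lp_split[[lp]], ]
          scale_p <- config$plate_scale *
            exp(stats::rnorm(1L, 0, config$batch_effect_sd))
          rec <- lay$recipient
          occ <- !is.na(rec)
          size <- numeric(cells_per_plate)
          if (any(occ)) {
            f_r <- fit[rec[occ]]
            ee <- 1 + eps_vec[rec[occ]]
            supp <- ifelse(linked_vec[rec[occ]], config$linkage_factor, 1)
            ## per-strain plating effect, shared by the duplicate colonies
            ## pinned from the same source on this plate copy
            u_rec <- unique(rec[occ])
            strain_fac <- stats::setNames(
              exp(stats::rnorm(length(u_rec), 0, config$replicate_effect_sd)),
              u_rec)
            size[occ] <- scale_p * row_f[lay$row[occ]] * col_f[lay$col[occ]] *
              f_q * f_r * ee * supp * strain_fac[rec[occ]] *
              exp(stats::rnorm(sum(occ), 0, config$noise_sd))
          }
          pl_i <- pl_i + 1L
          res[[pl_i]] <- data.frame(
            plate_id = sprintf("%s_r%d_c%d_p%02d", q, rep_i, copy_i, lp),
            query = q,
            replicate = rep_i,
            copy = copy_i,
            layout_plate = lp,
            batch = rep_i,
            row = lay$row,
            col = lay$col,
            size = size,
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  plates <- do.call(rbind, res)
  rownames(plates) <- NULL
  out <- list(plates = plates, layouts = layouts)
  class(out) <- "screen_plates"
  out
}

#' @export
print.screen_plates <- function(x, ...) {
  cat(sprintf("screen_plates: %d plates (%d colonies), %d queries, %d layout plates\n",
              length(unique(x$plates$plate_id)), nrow(x$plates),
              length(unique(x$plates$query)),
              length(unique(x$layouts$layout_plate))))
  invisible(x)
}

#' Extract one plate as a row x column matrix
#'
#' @param plates The `plates` data.frame of a `screen_plates` object (or a
#'   normalized equivalent).
#' @param plate_id Plate identifier.
#' @return Numeric matrix of colony sizes (0 = absent colony).
#' @export
plate_grid <- function(plates, plate_id) {
  p <- plates[plates$plate_id == plate_id, ]
  if (nrow(p) == 0L) stop("unknown plate_id: ", plate_id, call. = FALSE)
  m <- matrix(0, max(p$row), max(p$col))
  m[cbind(p$row, p$col)] <- p$size
  m
}
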