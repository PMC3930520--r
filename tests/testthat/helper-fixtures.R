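# Shared fixtures, built once per test run. The small screen is the
# workhorse for module-level tests; the 20 x 400 screen matches the
# parameter-recovery study condition and is built lazily by the tests that
# need it.

small_config <- function(seed = 42, ...) {
  screen_config(n_queries = 8, n_recipients = 120, rng_seed = seed, ...)
}

.fixture_env <- new.env(parent = emptyenv())

small_screen <- function(seed = 42) {
  key <- paste0("small_", seed)
  if (is.null(.fixture_env[[key]])) {
    cfg <- small_config(seed)
    truth <- generate_ground_truth(cfg)
    norm <- normalize_plates(simulate_plates(truth, cfg))
    sm <- score_screens(norm)
    coords <- stats::setNames(truth$genes$coordinate, truth$genes$gene)
    sm <- mask_linked(sm, coords, cfg$linkage_window_bp, truth$chromosome_length_bp)
    .fixture_env[[key]] <- list(cfg = cfg, truth = truth, norm = norm,
                                sm = sm, net = threshold_network(sm, 3))
  }
  .fixture_env[[key]]
}

recovery_screen <- function(seed = 101) {
  key <- paste0("recovery_", seed)
  if (is.null(.fixture_env[[key]])) {
    cfg <- screen_config(n_queries = 20, n_recipients = 400, rng_seed = seed)
    truth <- generate_ground_truth(cfg)
    norm <- normalize_plates(simulate_plates(truth, cfg))
    sm <- score_screens(norm)
    coords <- stats::setNames(truth$genes$coordinate, truth$genes$gene)
    sm <- mask_linked(sm, coords, cfg$linkage_window_bp, truth$chromosome_length_bp)
    .fixture_env[[key]] <- list(cfg = cfg, truth = truth, norm = norm,
                                sm = sm, net = threshold_network(sm, 3))
  }
  .fixture_env[[key]]
}

# hand-built signed network for combinatorial tests
toy_network <- function() {
  edges <- data.frame(
    gene_a = c("a", "a", "b", "c", "d"),
    gene_b = c("b", "c", "c", "d", "e"),
    S = c(-4, 5, -3.5, 3, -6),
    stringsAsFactors = FALSE
  )
  gi_network(edges, nodes = letters[1:8])
}
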