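# Shared fixtures. Default-condition worlds are expensive, so they are built
# lazily once per test run and cached.

.world_cache <- new.env(parent = emptyenv())

# world + simulated screens + matched, time-split datasets at the default
# study conditions
worldBundle <- function(seed) {
  key <- paste0("w", seed)
  if (is.null(.world_cache[[key]])) {
    world <- buildWorld(worldConfig(seed = seed))
    cs <- simulateCompoundScreen(world)
    sh <- simulateShrnaScreen(world)
    .world_cache[[key]] <- list(
      world = world, compound = cs, shrna = sh,
      dsC = composeDatasets(cs$signatures, cs$viability, tag = "compound"),
      dsS = composeDatasets(sh$signatures, sh$viability, tag = "shrna"))
  }
  .world_cache[[key]]
}

# small hand-made SignatureSet
tinySigset <- function(n = 4, G = 5, type = "compound", seed = 42) {
  set.seed(seed)
  X <- matrix(rnorm(n * G), n, G,
              dimnames = list(NULL, paste0("g", seq_len(G))))
  info <- data.frame(
    instance_id = paste0("i", seq_len(n)),
    cell_line_id = rep_len(c("A", "B"), n),
    perturbagen_id = rep_len(c("p1", "p2"), n),
    perturbagen_type = type,
    dose_um = if (type == "compound") seq_len(n) else NA_real_,
    time_h = 24, stringsAsFactors = FALSE)
  SignatureSet(X, info)
}

# small matched dataset with controllable structure
tinyMatched <- function(n = 20, G = 6, seed = 7, y = NULL) {
  set.seed(seed)
  X <- matrix(rnorm(n * G), n, G,
              dimnames = list(NULL, paste0("g", seq_len(G))))
  if (is.null(y)) y <- rnorm(n)
  meta <- data.frame(instance_id = paste0("i", seq_len(n)),
                     cell_line_id = rep_len(c("A", "B"), n),
                     perturbagen_id = rep_len(paste0("p", 1:4), n),
                     time_h = 24,
                     dose_signature_um = 1, dose_viability_um = 1,
                     delta_log10_dose = 0, stringsAsFactors = FALSE)
  MatchedDataset(X, y, meta, "fraction", "tiny")
}
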