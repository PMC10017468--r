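# Shared fixtures, built once per test run and memoised.

.fixture_cache <- new.env(parent = emptyenv())

# Full pipeline on a generated cohort: profiles -> calibration -> CU-derived
# cutoffs -> staging, with cohort covariates joined.
staged_fixture <- function(n = 900, seed = 42) {
  key <- paste0("staged_", n, "_", seed)
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  cfg <- cohort_config(n_participants = n)
  sim <- generate_cohort(cfg, seed = seed)
  calibs <- calibrations_from_anchors(generate_anchor_sets(cfg, seed = seed))
  cu_ids <- sim$cohort$participant_id[sim$cohort$diagnosis == "CU"]
  cutoffs <- lapply(stats::setNames(c("FBB", "FMM"), c("FBB", "FMM")),
                    function(lg) {
    derive_regional_cutoffs(
      sim$profiles[sim$profiles$ligand == lg &
                     sim$profiles$participant_id %in% cu_ids, ],
      lg
    )
  })
  staged <- stage_cohort(sim$profiles, cutoffs, calibs)
  out <- list(
    config = cfg, sim = sim, calibs = calibs, cutoffs = cutoffs,
    staged = staged,
    data = dplyr::left_join(sim$cohort, staged,
                            by = c("participant_id", "ligand"))
  )
  .fixture_cache[[key]] <- out
  out
}

# A profile tibble built directly from a region-by-participant matrix.
profiles_from_matrix <- function(m, ligand = "FBB", global_suvr = NULL) {
  stopifnot(ncol(m) == 10)
  colnames(m) <- region_names()
  out <- tibble::as_tibble(m)
  out$participant_id <- sprintf("P%03d", seq_len(nrow(m)))
  out$ligand <- ligand
  out$global_suvr <- global_suvr %||% rowMeans(m)
  out[, c("participant_id", "ligand", region_names(), "global_suvr")]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Regional cutoffs that come out at exactly `level` in every region
# (derived from a constant reference sample at level / 1.025).
unit_cutoffs <- function(ligand = "FBB", level = 1.2) {
  m <- matrix(level / 1.025, nrow = 10, ncol = 10)
  derive_regional_cutoffs(profiles_from_matrix(m, ligand = ligand), ligand)
}

# Independently coded type-7 quantile (interpolation of order statistics),
# used by the brute-force cutoff oracle.
quantile7 <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p
  lo <- floor(h)
  x[lo + 1] + (h - lo) * (x[min(lo + 2, length(x))] - x[lo + 1])
}

# Naive re-implementation of the iterative Tukey-fence loop.
naive_iterative_cutoff <- function(values, k = 1.5, f = 0.025) {
  retained <- values
  repeat {
    q1 <- quantile7(retained, 0.25)
    q3 <- quantile7(retained, 0.75)
    iqr <- q3 - q1
    keep <- retained >= q1 - k * iqr & retained <= q3 + k * iqr
    if (all(keep)) break
    retained <- retained[keep]
  }
  list(retained = retained, cutoff = (1 + f) * max(retained))
}
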