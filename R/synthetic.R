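# Synthetic cohort generator: two-ligand regional SUVR profiles with a
# planted global/focal group structure, plus covariates and outcomes with
# planted group effects. One latent amyloid-burden scalar per participant
# drives regional uptake through lobe-specific onsets, so involvement spreads
# parietal -> frontal/temporal -> cingulate -> striatum as burden grows.

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the structure of a memory-clinic amyloid PET cohort:
#' a CU/aMCI/dementia case mix with a rising fraction of global amyloid
#' positivity across diagnoses, a small (~6%) global-negative focal-positive
#' stratum, FBB SUVR scales above FMM, lobar involvement frequencies ordered
#' parietal > frontal ~ temporal > cingulate > striatum among focal-type
#' participants, heavy right tails of burden in impaired participants, and
#' group-ordered outcomes (memory, global cognition, hippocampal volume,
#' AD-signature cortical thickness) confounded with age. See the methods
#' vignette for the rationale behind each default.
#'
#' @param n_participants Cohort size (default 900).
#' @param ligand_split Fraction of participants scanned with FBB
#'   (default 0.514; the rest get FMM).
#' @param diagnosis_mix Probabilities over `CU`, `aMCI`, `dementia`.
#' @param p_global_pos Probability of latent global positivity per diagnosis.
#' @param p_focal_given_negative Probability of the focal-positive stratum
#'   among latent global-negatives, per diagnosis.
#' @param ligand_scale Per-ligand `baseline` SUVR (amyloid-free level) and
#'   `gain` (multiplier on amyloid-driven signal); FBB baseline > FMM.
#' @param noise SDs of the subject-level offset, the lobe-level noise
#'   (shared between hemispheres), and the hemisphere-level noise, in SUVR.
#' @param lobe_involvement_props Target lobar involvement frequencies among
#'   focal-type participants.
#' @param burden Parameters of the latent burden distributions per stratum
#'   and of the ADCI anchor group.
#' @param amplitude `intercept` and `slope` of the SUVR increment an involved
#'   region gains as a function of burden.
#' @param diffuse Sub-threshold diffuse uptake slope applied to uninvolved
#'   regions.
#' @param onsets Burden level at which each lobe becomes involved for
#'   globally positive participants (striatum last).
#' @param onset_jitter SD of the per-subject-per-lobe jitter on the onsets.
#' @param hemi_logistic `center`/`scale` of the logistic curve giving the
#'   probability that an involved lobe involves both hemispheres.
#' @param global_lobe_weights Lobe weights of the global cortical target
#'   (striatum excluded; split evenly between hemispheres).
#' @param effect_sizes Named list of per-group outcome means
#'   (order G-F-, G-F+, G+) for `mmse`, `svlt`, `hv`, `thickness`.
#' @param outcome_sd,age_slope Residual SDs and linear age slopes
#'   (per year, centered at age 72) of the outcomes.
#' @param age_by_group,education_by_group Mean/SD of age and education per
#'   group.
#' @param apoe_freq,female_freq,va_freq APOE4 carrier, female, and
#'   visual-read-positive probabilities per group.
#' @return A validated config list of class `cohort_config`.
#' @export
cohort_config <- function(
    n_participants = 900,
    ligand_split = 0.514,
    diagnosis_mix = c(CU = 0.236, aMCI = 0.413, dementia = 0.351),
    p_global_pos = c(CU = 0.206, aMCI = 0.568, dementia = 0.847),
    p_focal_given_negative = c(CU = 0.09, aMCI = 0.18, dementia = 0.27),
    ligand_scale = list(FBB = list(baseline = 1.10, gain = 1.00),
                        FMM = list(baseline = 1.00, gain = 0.90)),
    noise = c(subject = 0.04, lobe = 0.03, hemisphere = 0.015),
    lobe_involvement_props = c(parietal = 0.388, frontal = 0.325,
                               lateral_temporal = 0.324, cingulate = 0.261,
                               striatum = 0.130),
    burden = list(negative = c(scale = 0.15, shape1 = 2, shape2 = 5),
                  focal = c(min = 0.25, range = 0.15, shape1 = 2, shape2 = 2),
                  positive = c(offset = 0.70, shape = 2, rate = 3),
                  adci_anchor = c(mean = 1.9, sd = 0.15)),
    amplitude = c(intercept = 0.12, slope = 0.45),
    diffuse = 0.05,
    onsets = c(parietal = 0.30, frontal = 0.38, lateral_temporal = 0.40,
               cingulate = 0.44, striatum = 0.58),
    onset_jitter = 0.05,
    hemi_logistic = c(center = 0.35, scale = 0.08),
    global_lobe_weights = c(frontal = 0.40, lateral_temporal = 0.22,
                            parietal = 0.30, cingulate = 0.08),
    effect_sizes = list(mmse = c(26.5, 24.5, 22.0),
                        svlt = c(7.0, 5.2, 3.0),
                        hv = c(3400, 3250, 2900),
                        thickness = c(3.05, 2.98, 2.82)),
    outcome_sd = c(mmse = 4.0, svlt = 2.2, hv = 350, thickness = 0.12),
    age_slope = c(mmse = -0.10, svlt = -0.06, hv = -12, thickness = -0.006),
    age_by_group = list(mean = c(70.9, 74.9, 71.6), sd = c(8.1, 6.6, 8.3)),
    education_by_group = list(mean = c(12.0, 11.5, 11.5),
                              sd = c(4.9, 5.4, 4.8)),
    apoe_freq = c(0.158, 0.327, 0.605),
    female_freq = c(0.506, 0.516, 0.587),
    va_freq = c(0.041, 0.129, 0.931)) {
  cfg <- as.list(environment())
  check_probs <- function(p, name) {
    if (any(p < 0) || any(p > 1)) stop(name, " must lie in [0, 1]")
  }
  if (n_participants < 0) stop("n_participants must be nonnegative")
  if (abs(sum(diagnosis_mix) - 1) > 1e-8) {
    stop("diagnosis_mix must sum to 1")
  }
  check_probs(diagnosis_mix, "diagnosis_mix")
  check_probs(ligand_split, "ligand_split")
  check_probs(p_global_pos, "p_global_pos")
  check_probs(p_focal_given_negative, "p_focal_given_negative")
  check_probs(lobe_involvement_props, "lobe_involvement_props")
  check_probs(apoe_freq, "apoe_freq")
  stopifnot(all(noise > 0), all(outcome_sd > 0),
            setequal(names(lobe_involvement_props), lobe_names()),
            setequal(names(onsets), lobe_names()))
  if (ligand_scale$FBB$baseline <= ligand_scale$FMM$baseline) {
    stop("FBB baseline SUVR must exceed FMM baseline")
  }
  structure(cfg, class = "cohort_config")
}

# Per-lobe Bernoulli probabilities for the focal stratum such that,
# conditional on at least one lobe being involved, the marginal involvement
# frequencies match the configured targets. Fixed-point iteration on
# pi = target * P(>= 1 involved).
focal_lobe_probs <- function(targets) {
  p <- targets
  for (i in 1:50) {
    p_any <- 1 - prod(1 - p)
    p_new <- pmin(targets * p_any, 0.999)
    if (max(abs(p_new - p)) < 1e-12) break
    p <- p_new
  }
  p
}

truth_levels <- function() group_levels()

#' Generate a synthetic amyloid PET cohort
#'
#' Draws a cohort from [cohort_config()]: each participant gets a diagnosis,
#' a ligand, a latent stratum (amyloid-negative, focal-positive with
#' subthreshold global burden, or globally positive), a latent burden scalar,
#' lobe/region involvement, regional and global SUVR values, and covariates
#' and outcomes with planted group effects. Output is deterministic given
#' `seed` and the config; the caller's RNG stream is left untouched.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @return A list with elements
#'   \describe{
#'     \item{`cohort`}{Tibble of covariates and outcomes (one row per
#'       participant): `participant_id`, `ligand`, `diagnosis`, `age`,
#'       `female`, `education`, `apoe4`, `visual_read_positive`, `mmse`,
#'       `svlt`, `hv`, `icv`, `thickness`.}
#'     \item{`profiles`}{Regional SUVR profile tibble as produced by
#'       [aggregate_profiles()].}
#'     \item{`truth`}{Ground-truth tibble (`true_group`, `burden`, latent
#'       per-lobe involvement flags) — for validation only, never an input to
#'       the pipeline.}
#'   }
#' @export
#' @examples
#' sim <- generate_cohort(cohort_config(n_participants = 50), seed = 1)
#' dplyr::count(sim$truth, true_group)
generate_cohort <- function(config = cohort_config(), seed = 1L) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_participants
  if (n == 0) return(empty_cohort())

  with_preserved_rng(seed, generate_cohort_impl(config, n))
}

generate_cohort_impl <- function(config, n) {
  lobes <- lobe_names()
  id <- sprintf("S%04d", seq_len(n))
  ligand <- ifelse(stats::runif(n) < config$ligand_split, "FBB", "FMM")
  dx <- sample(names(config$diagnosis_mix), n, replace = TRUE,
               prob = config$diagnosis_mix)

  # latent stratum: G+ with diagnosis-specific probability; focal-positive
  # among the remaining global-negatives
  u1 <- stats::runif(n)
  u2 <- stats::runif(n)
  gpos <- u1 < config$p_global_pos[dx]
  focal <- !gpos & u2 < config$p_focal_given_negative[dx]
  true_group <- factor(
    ifelse(gpos, "G+", ifelse(focal, "G-F+", "G-F-")),
    levels = truth_levels()
  )
  gi <- as.integer(true_group)  # 1 = G-F-, 2 = G-F+, 3 = G+

  # latent burden per stratum (disjoint supports with gaps, so the staged
  # labels are recoverable; the G+ stratum has a heavy right tail)
  bn <- config$burden$negative
  bf <- config$burden$focal
  bp <- config$burden$positive
  burden <- numeric(n)
  burden[gi == 1] <- bn[["scale"]] *
    stats::rbeta(sum(gi == 1), bn[["shape1"]], bn[["shape2"]])
  burden[gi == 2] <- bf[["min"]] + bf[["range"]] *
    stats::rbeta(sum(gi == 2), bf[["shape1"]], bf[["shape2"]])
  burden[gi == 3] <- bp[["offset"]] +
    stats::rgamma(sum(gi == 3), shape = bp[["shape"]], rate = bp[["rate"]])

  # lobe involvement (n x 5 logical)
  lobe_inv <- matrix(FALSE, n, 5, dimnames = list(NULL, lobes))
  if (any(gi == 3)) {
    # burden-ordered onsets with per-subject jitter: parietal first,
    # striatum last
    idx <- which(gi == 3)
    jit <- matrix(stats::rnorm(length(idx) * 5, 0, config$onset_jitter),
                  ncol = 5)
    lobe_inv[idx, ] <- sweep(jit, 2, config$onsets[lobes], "-") +
      burden[idx] > 0
  }
  if (any(gi == 2)) {
    pi_l <- focal_lobe_probs(config$lobe_involvement_props[lobes])
    idx <- which(gi == 2)
    repeat {
      draw <- matrix(stats::runif(length(idx) * 5), ncol = 5) <
        matrix(pi_l, length(idx), 5, byrow = TRUE)
      lobe_inv[idx, ] <- draw
      none <- idx[rowSums(lobe_inv[idx, , drop = FALSE]) == 0]
      if (length(none) == 0) break
      idx <- none  # redraw participants that drew no involvement
    }
  }

  # hemisphere spread: involved lobes involve both hemispheres with a
  # probability that grows with burden
  hl <- config$hemi_logistic
  p_both <- stats::plogis((burden - hl[["center"]]) / hl[["scale"]])
  both <- matrix(stats::runif(n * 5), ncol = 5) < p_both
  left_if_one <- matrix(stats::runif(n * 5), ncol = 5) < 0.5
  region_inv <- matrix(FALSE, n, 10, dimnames = list(NULL, region_names()))
  for (j in seq_along(lobes)) {
    region_inv[, paste0(lobes[j], "_left")] <-
      lobe_inv[, j] & (both[, j] | left_if_one[, j])
    region_inv[, paste0(lobes[j], "_right")] <-
      lobe_inv[, j] & (both[, j] | !left_if_one[, j])
  }

  # regional SUVR = ligand baseline + subject offset
  #   + gain * (involved ? amplitude(burden) : diffuse * burden)
  #   + lobe noise (shared between hemispheres) + hemisphere noise
  baseline <- vapply(ligand, function(l) config$ligand_scale[[l]]$baseline,
                     numeric(1))
  gain <- vapply(ligand, function(l) config$ligand_scale[[l]]$gain,
                 numeric(1))
  amp <- config$amplitude[["intercept"]] +
    config$amplitude[["slope"]] * burden
  subj_off <- stats::rnorm(n, 0, config$noise[["subject"]])
  lobe_noise <- matrix(stats::rnorm(n * 5, 0, config$noise[["lobe"]]),
                       ncol = 5, dimnames = list(NULL, lobes))
  hemi_noise <- matrix(stats::rnorm(n * 10, 0,
                                    config$noise[["hemisphere"]]), ncol = 10)
  suvr <- matrix(0, n, 10, dimnames = list(NULL, region_names()))
  for (r in region_names()) {
    l <- lobe_of(r)
    signal <- ifelse(region_inv[, r], amp, config$diffuse * burden)
    suvr[, r] <- baseline + subj_off + gain * signal +
      lobe_noise[, l] + hemi_noise[, match(r, region_names())]
  }
  suvr[suvr < 0] <- 0

  # global cortical SUVR: lobe-weighted mean over the cortical regions
  w <- region_weights(config$global_lobe_weights)
  global_suvr <- as.vector(suvr[, names(w), drop = FALSE] %*% w)

  profiles <- tibble::tibble(participant_id = id, ligand = ligand) |>
    dplyr::bind_cols(tibble::as_tibble(suvr)) |>
    dplyr::mutate(global_suvr = global_suvr)

  # covariates and outcomes with planted group effects; outcomes carry a
  # linear age slope so covariate adjustment matters
  ab <- config$age_by_group
  age <- pmin(pmax(stats::rnorm(n, ab$mean[gi], ab$sd[gi]), 55), 95)
  eb <- config$education_by_group
  education <- round(pmin(pmax(stats::rnorm(n, eb$mean[gi], eb$sd[gi]),
                               0), 22))
  female <- stats::runif(n) < config$female_freq[gi]
  apoe4 <- stats::runif(n) < config$apoe_freq[gi]
  va <- stats::runif(n) < config$va_freq[gi]
  age_c <- age - 72

  draw_outcome <- function(name, lo = -Inf, hi = Inf, digits = NULL) {
    m <- config$effect_sizes[[name]][gi] +
      config$age_slope[[name]] * age_c
    x <- stats::rnorm(n, m, config$outcome_sd[[name]])
    x <- pmin(pmax(x, lo), hi)
    if (!is.null(digits)) x <- round(x, digits)
    x
  }
  mmse <- draw_outcome("mmse", 0, 30, 0)
  svlt <- draw_outcome("svlt", 0, 12, 0)
  hv <- draw_outcome("hv", 0)
  thickness <- draw_outcome("thickness", 0)
  icv <- stats::rnorm(n, 1.45e6, 1.4e5)

  cohort <- tibble::tibble(
    participant_id = id, ligand = ligand,
    diagnosis = factor(dx, levels = c("CU", "aMCI", "dementia")),
    age = age, female = female, education = education, apoe4 = apoe4,
    visual_read_positive = va,
    mmse = mmse, svlt = svlt, hv = hv, icv = icv, thickness = thickness
  )
  truth <- tibble::tibble(
    participant_id = id, true_group = true_group, burden = burden
  ) |>
    dplyr::bind_cols(
      tibble::as_tibble(lobe_inv) |>
        dplyr::rename_with(~ paste0("inv_", .x))
    )

  list(cohort = cohort, profiles = profiles, truth = truth)
}

region_weights <- function(lobe_weights) {
  lobe_weights <- lobe_weights / sum(lobe_weights)
  regions <- as.vector(outer(names(lobe_weights), c("left", "right"),
                             paste, sep = "_"))
  stats::setNames(rep(lobe_weights / 2, 2), regions)
}

empty_cohort <- function() {
  sim <- with_preserved_rng(1L, generate_cohort_impl(
    cohort_config(n_participants = 1), 1))
  list(cohort = sim$cohort[0, ], profiles = sim$profiles[0, ],
       truth = sim$truth[0, ])
}

#' Generate anchor samples for the Centiloid calibration
#'
#' Draws, per ligand, a young-control anchor sample (zero amyloid burden)
#' and an ADCI anchor sample (high burden, every region involved), whose
#' global SUVR means define the 0 and 100 points of the dcCL scale. By
#' construction, converting each group's mean SUVR through the resulting
#' calibration returns exactly 0 and 100.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @param n_young,n_adci Anchor sample sizes (default 20 each).
#' @return A tibble with columns `ligand`, `anchor_group`
#'   (`"young_control"` / `"adci"`), `suvr`.
#' @export
#' @examples
#' anchors <- generate_anchor_sets(seed = 42)
#' calib <- calibrations_from_anchors(anchors)
#' suvr_to_cl(calib$FBB$suvr_yc0, calib$FBB)  # 0 by construction
generate_anchor_sets <- function(config = cohort_config(), seed = 1L,
                                 n_young = 20, n_adci = 20) {
  stopifnot(inherits(config, "cohort_config"))
  with_preserved_rng(seed, {
    purrr::map_dfr(c("FBB", "FMM"), function(lg) {
      sc <- config$ligand_scale[[lg]]
      aa <- config$burden$adci_anchor
      yc <- sc$baseline +
        stats::rnorm(n_young, 0, config$noise[["subject"]])
      b <- stats::rnorm(n_adci, aa[["mean"]], aa[["sd"]])
      adci <- sc$baseline +
        stats::rnorm(n_adci, 0, config$noise[["subject"]]) +
        sc$gain * (config$amplitude[["intercept"]] +
                     config$amplitude[["slope"]] * b)
      tibble::tibble(
        ligand = lg,
        anchor_group = rep(c("young_control", "adci"),
                           c(n_young, n_adci)),
        suvr = c(yc, adci)
      )
    })
  })
}

#' Build per-ligand calibrations from anchor samples
#'
#' @param anchors Anchor tibble from [generate_anchor_sets()] (or any table
#'   with columns `ligand`, `anchor_group`, `suvr`).
#' @return Named list of [ligand_calibration()] objects by ligand.
#' @export
calibrations_from_anchors <- function(anchors) {
  stopifnot(all(c("ligand", "anchor_group", "suvr") %in% names(anchors)))
  means <- anchors |>
    dplyr::group_by(.data$ligand, .data$anchor_group) |>
    dplyr::summarise(suvr = mean(.data$suvr), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "anchor_group", values_from = "suvr")
  out <- purrr::pmap(means, function(ligand, young_control, adci) {
    ligand_calibration(ligand, suvr_yc0 = young_control,
                       suvr_adci100 = adci)
  })
  stats::setNames(out, means$ligand)
}

#' Synthetic VOI-level uptake table
#'
#' A small VOI-level table (one row per VOI per participant, plus the
#' whole-cerebellum reference row) for exercising [aggregate_profiles()] and
#' [extract_voi_means()] without image data. Uptake values are arbitrary but
#' reproducible; volumes are fixed per VOI.
#'
#' @param n Number of participants.
#' @param seed Integer seed.
#' @param ligand Ligand label for all participants (default `"FBB"`).
#' @param map Region map whose VOIs to emit.
#' @return Tibble with columns `participant_id`, `ligand`, `voi_name`,
#'   `mean_uptake`, `volume`.
#' @export
synthetic_voi_table <- function(n = 3, seed = 1L, ligand = "FBB",
                                map = default_region_map()) {
  map <- validate_region_map(map)
  with_preserved_rng(seed, {
    vols <- stats::setNames(round(stats::runif(nrow(map), 2000, 15000)),
                            map$voi_name)
    purrr::map_dfr(seq_len(n), function(i) {
      ref_uptake <- stats::rnorm(1, 1.0, 0.05)
      tibble::tibble(
        participant_id = sprintf("V%03d", i),
        ligand = ligand,
        voi_name = c(map$voi_name, "Cerebellum_Whole"),
        mean_uptake = abs(c(
          ref_uptake * stats::rnorm(nrow(map), 1.15, 0.10),
          ref_uptake
        )),
        volume = c(unname(vols), 30000)
      )
    })
  })
}
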