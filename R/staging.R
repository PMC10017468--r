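# Global/focal amyloid group classification.

#' Group label levels
#'
#' The three-group partition: global-negative focal-negative (`G-F-`),
#' global-negative focal-positive (`G-F+`), and global-positive (`G+`).
#'
#' @return Character vector of the three group labels, in severity order.
#' @export
group_levels <- function() c("G-F-", "G-F+", "G+")

#' Flag regional amyloid positivity against ligand-specific cutoffs
#'
#' A region is involved when its SUVR strictly exceeds the region's cutoff
#' (a value exactly at the cutoff is negative; the convention is exposed via
#' `boundary`).
#'
#' @param profiles Profile tibble (see [aggregate_profiles()]).
#' @param cutoffs A `regional_cutoffs` object whose ligand matches every
#'   profile row.
#' @param boundary `"exclusive"` (default, SUVR > cutoff) or `"inclusive"`
#'   (SUVR >= cutoff).
#' @return A tibble with `participant_id` and ten logical `pos_<region>`
#'   columns.
#' @export
flag_regions <- function(profiles, cutoffs,
                         boundary = c("exclusive", "inclusive")) {
  boundary <- match.arg(boundary)
  profiles <- validate_profiles(profiles)
  stopifnot(inherits(cutoffs, "regional_cutoffs"))
  if (!all(profiles$ligand == cutoffs$ligand)) {
    stop("ligand mismatch: cutoffs are for ", cutoffs$ligand)
  }
  cuts <- cutoff_values(cutoffs)
  out <- tibble::tibble(participant_id = profiles$participant_id)
  for (r in region_names()) {
    out[[paste0("pos_", r)]] <- if (boundary == "exclusive") {
      profiles[[r]] > cuts[[r]]
    } else {
      profiles[[r]] >= cuts[[r]]
    }
  }
  out
}

#' Stage a cohort into global/focal amyloid groups
#'
#' For every participant: converts the global SUVR to Centiloid units,
#' determines global positivity against the Centiloid threshold, flags the
#' ten composite regions against the ligand-specific regional cutoffs, and
#' assigns the group label and subtype. Global-negatives with at least one
#' involved region form the `G-F+` group; all global-positives form `G+`.
#' The subtype distinguishes no involvement (`none`), involvement in 1-9
#' regions (`focal`), and involvement in all 10 regions (`whole_brain`);
#' `discordant` marks global-positive participants with zero involved
#' regions.
#'
#' @param profiles Profile tibble, possibly mixing ligands.
#' @param cutoffs A `regional_cutoffs` object, or a named list of them
#'   (`list(FBB = ..., FMM = ...)`) when profiles mix ligands.
#' @param calibration A [ligand_calibration()], or a named list by ligand.
#' @param threshold A [global_threshold()] or bare Centiloid cutoff
#'   (default 25.11 CL).
#' @param boundary Regional boundary convention, see [flag_regions()].
#' @return A tibble of class `amyloid_staging` with one row per participant:
#'   `participant_id`, `ligand`, `global_suvr`, `global_cl`,
#'   `global_positive`, ten `pos_<region>` columns, `n_involved`, `group`
#'   (factor over [group_levels()]), `subtype`, `discordant`.
#' @export
#' @examples
#' sim <- generate_cohort(cohort_config(n_participants = 80), seed = 7)
#' calib <- calibrations_from_anchors(generate_anchor_sets(seed = 7))
#' cuts <- derive_regional_cutoffs(
#'   dplyr::filter(sim$profiles, sim$cohort$diagnosis == "CU",
#'                 ligand == "FBB"), "FBB")
#' staged <- stage_cohort(dplyr::filter(sim$profiles, ligand == "FBB"),
#'                        cuts, calib$FBB)
#' group_counts(staged)
stage_cohort <- function(profiles, cutoffs, calibration,
                         threshold = global_threshold(),
                         boundary = c("exclusive", "inclusive")) {
  boundary <- match.arg(boundary)
  profiles <- validate_profiles(profiles)
  if (!inherits(threshold, "global_threshold")) {
    threshold <- global_threshold(threshold)
  }
  cutoffs_by_ligand <- as_by_ligand(cutoffs, "regional_cutoffs")
  calib_by_ligand <- as_by_ligand(calibration, "ligand_calibration")
  ligands <- unique(profiles$ligand)
  for (lg in ligands) {
    if (is.null(cutoffs_by_ligand[[lg]])) {
      stop("no regional cutoffs supplied for ligand ", lg)
    }
    if (is.null(calib_by_ligand[[lg]])) {
      stop("no calibration supplied for ligand ", lg)
    }
  }

  staged <- purrr::map(ligands, function(lg) {
    p <- profiles[profiles$ligand == lg, ]
    flags <- flag_regions(p, cutoffs_by_ligand[[lg]], boundary = boundary)
    cl <- suvr_to_cl(p$global_suvr, calib_by_ligand[[lg]])
    flag_mat <- as.matrix(flags[, paste0("pos_", region_names())])
    n_inv <- rowSums(flag_mat)
    gpos <- is_global_positive(cl, threshold)
    tibble::tibble(
      participant_id = p$participant_id,
      ligand = lg,
      global_suvr = p$global_suvr,
      global_cl = cl,
      global_positive = gpos
    ) |>
      dplyr::bind_cols(flags[, -1]) |>
      dplyr::mutate(
        n_involved = as.integer(n_inv),
        group = factor(
          dplyr::case_when(
            gpos ~ "G+",
            n_inv >= 1 ~ "G-F+",
            TRUE ~ "G-F-"
          ),
          levels = group_levels()
        ),
        subtype = dplyr::case_when(
          n_inv == 0 ~ "none",
          n_inv == 10 ~ "whole_brain",
          TRUE ~ "focal"
        ),
        discordant = gpos & n_inv == 0
      )
  }) |>
    dplyr::bind_rows()

  # restore input order
  staged <- staged[match(profiles$participant_id, staged$participant_id), ]
  attr(staged, "threshold") <- threshold
  class(staged) <- c("amyloid_staging", class(staged))
  staged
}

as_by_ligand <- function(x, cls) {
  if (inherits(x, cls)) {
    return(stats::setNames(list(x), x$ligand))
  }
  if (is.list(x) && all(vapply(x, inherits, logical(1), cls))) {
    return(stats::setNames(x, vapply(x, function(e) e$ligand, character(1))))
  }
  stop("expected a ", cls, " object or a named list of them by ligand")
}

#' Group counts of a staged cohort
#'
#' @param staging A staging tibble from [stage_cohort()].
#' @return A tibble with one row per group label (all three always present)
#'   and columns `group`, `n`, `proportion`.
#' @export
group_counts <- function(staging) {
  stopifnot(is.data.frame(staging), "group" %in% names(staging))
  staging |>
    dplyr::count(.data$group, .drop = FALSE) |>
    dplyr::mutate(proportion = .data$n / sum(.data$n))
}

#' Three-level Centiloid band grouping
#'
#' Alternative grouping by global Centiloid level alone: negative
#' (`cl < lower`), subthreshold (`lower <= cl < upper`), positive
#' (`cl >= upper`). Used to contrast the global/focal grouping with a purely
#' level-based one (see [compare_groupings_aic()]).
#'
#' @param cl Numeric vector of Centiloid values.
#' @param cl_bands Two increasing band edges (default `c(10, 25.11)`).
#' @return Factor with levels `negative`, `subthreshold`, `positive`.
#' @export
cl_band_grouping <- function(cl, cl_bands = c(10, 25.11)) {
  stopifnot(length(cl_bands) == 2, cl_bands[1] < cl_bands[2])
  cut(cl, breaks = c(-Inf, cl_bands, Inf),
      labels = c("negative", "subthreshold", "positive"),
      right = FALSE)
}
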