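# Composite-region definitions and SUVR aggregation.

#' Names of the ten composite regions
#'
#' The staging scheme works on ten composite regions: five lobes (frontal,
#' lateral temporal, parietal, cingulate, striatum) in each hemisphere.
#'
#' @return Character vector of length 10, `"<lobe>_<hemisphere>"`.
#' @export
#' @examples
#' region_names()
region_names <- function() {
  as.vector(outer(lobe_names(), c("left", "right"), paste, sep = "_"))
}

#' Names of the five lobes
#'
#' @return Character vector of length 5.
#' @export
lobe_names <- function() {
  c("frontal", "lateral_temporal", "parietal", "cingulate", "striatum")
}

#' Lobe of a composite region
#'
#' @param region Character vector of composite-region names as returned by
#'   [region_names()].
#' @return Character vector of lobe names.
#' @export
lobe_of <- function(region) {
  sub("_(left|right)$", "", region)
}

#' Default VOI-to-region map
#'
#' Maps 28 volumes of interest (VOIs) onto the ten composite regions:
#' 14 VOIs per hemisphere. Parietal, lateral temporal, cingulate, and striatal
#' VOIs follow the AAL parcel naming directly (superior/inferior parietal,
#' supramarginal, angular, precuneus; superior/middle/inferior temporal;
#' anterior/posterior cingulate; caudate, putamen). The frontal lobe is
#' represented by two composite VOIs per hemisphere: a dorsomedial composite
#' (superior and middle frontal gyri, medial superior frontal gyrus, opercular
#' and triangular inferior frontal gyrus, supplementary motor area) and an
#' orbital composite (superior, middle, and inferior orbital gyri); the nine
#' frontal AAL parcels are pooled so the map keeps 28 entries. Pass a custom
#' map to [aggregate_profiles()] to use a different parcellation — any table
#' with columns `voi_name`, `lobe`, `hemisphere` works, as long as all ten
#' composite regions are reachable.
#'
#' @return A tibble with columns `voi_name`, `lobe`, `hemisphere`, `region`.
#' @seealso [read_region_map()] to load a map from CSV/YAML/JSON.
#' @export
#' @examples
#' default_region_map()
default_region_map <- function() {
  one_hemi <- tibble::tribble(
    ~voi_name,            ~lobe,
    "Frontal_DorsoMedial", "frontal",
    "Frontal_Orbital",     "frontal",
    "Temporal_Sup",        "lateral_temporal",
    "Temporal_Mid",        "lateral_temporal",
    "Temporal_Inf",        "lateral_temporal",
    "Parietal_Sup",        "parietal",
    "Parietal_Inf",        "parietal",
    "SupraMarginal",       "parietal",
    "Angular",             "parietal",
    "Precuneus",           "parietal",
    "Cingulum_Ant",        "cingulate",
    "Cingulum_Post",       "cingulate",
    "Caudate",             "striatum",
    "Putamen",             "striatum"
  )
  map <- dplyr::bind_rows(
    dplyr::mutate(one_hemi, hemisphere = "left",
                  voi_name = paste0(.data$voi_name, "_L")),
    dplyr::mutate(one_hemi, hemisphere = "right",
                  voi_name = paste0(.data$voi_name, "_R"))
  )
  dplyr::mutate(map, region = paste(.data$lobe, .data$hemisphere, sep = "_"))
}

#' Read a VOI-to-region map from file
#'
#' Accepts CSV/TSV (columns `voi_name`, `lobe`, `hemisphere`), YAML, or JSON
#' (a list of records with the same fields).
#'
#' @param path File path; format inferred from the extension.
#' @return A validated region-map tibble (see [default_region_map()]).
#' @export
read_region_map <- function(path) {
  ext <- tolower(tools::file_ext(path))
  map <- switch(ext,
    csv  = utils::read.csv(path, stringsAsFactors = FALSE),
    tsv  = utils::read.delim(path, stringsAsFactors = FALSE),
    yaml = ,
    yml  = dplyr::bind_rows(lapply(yaml::read_yaml(path), tibble::as_tibble)),
    json = dplyr::bind_rows(lapply(jsonlite::read_json(path), tibble::as_tibble)),
    stop("unsupported region-map format: ", ext)
  )
  map <- tibble::as_tibble(map)
  validate_region_map(map)
}

validate_region_map <- function(map) {
  needed <- c("voi_name", "lobe", "hemisphere")
  missing <- setdiff(needed, names(map))
  if (length(missing) > 0) {
    stop("region map lacks column(s): ", paste(missing, collapse = ", "))
  }
  bad_lobe <- setdiff(unique(map$lobe), lobe_names())
  if (length(bad_lobe) > 0) {
    stop("unknown lobe(s) in region map: ", paste(bad_lobe, collapse = ", "))
  }
  bad_hemi <- setdiff(unique(map$hemisphere), c("left", "right"))
  if (length(bad_hemi) > 0) {
    stop("hemisphere must be 'left' or 'right', got: ",
         paste(bad_hemi, collapse = ", "))
  }
  if (anyDuplicated(map$voi_name)) {
    stop("duplicated voi_name in region map: ",
         paste(unique(map$voi_name[duplicated(map$voi_name)]), collapse = ", "))
  }
  if (!"region" %in% names(map)) {
    map$region <- paste(map$lobe, map$hemisphere, sep = "_")
  }
  reachable <- unique(map$region)
  if (!setequal(reachable, region_names())) {
    stop("region map must reach all 10 composite regions; missing: ",
         paste(setdiff(region_names(), reachable), collapse = ", "))
  }
  tibble::as_tibble(map)
}

#' Default global cortical target VOI list
#'
#' The global cortical SUVR target is the union of the frontal, lateral
#' temporal, parietal, and cingulate VOIs of the supplied map, excluding the
#' striatum. This approximates a cortical target VOI built from group
#' difference images, which cannot be reconstructed from tabular data; see the
#' methods vignette.
#'
#' @param map A region map (default [default_region_map()]).
#' @return Character vector of VOI names.
#' @export
default_global_vois <- function(map = default_region_map()) {
  map <- validate_region_map(map)
  map$voi_name[map$lobe != "striatum"]
}

#' Aggregate VOI uptake into regional SUVR profiles
#'
#' Computes, per participant, the SUVR of each of the ten composite regions
#' and of the global cortical target. A region's SUVR is the volume-weighted
#' mean uptake of its VOIs divided by the reference (whole cerebellum) uptake;
#' with equal volumes this degenerates to the unweighted mean. Volume
#' weighting corresponds to pooling voxels across parcels.
#'
#' @param vois A data frame with columns `participant_id`, `ligand`
#'   (`"FBB"` or `"FMM"`), `voi_name`, `mean_uptake`, `volume`. Must contain
#'   every mapped VOI exactly once per participant, plus the reference VOI.
#' @param map Region map tibble (see [default_region_map()]).
#' @param reference_voi Name of the reference VOI row within `vois`
#'   (default `"Cerebellum_Whole"`).
#' @param global_vois Character vector of VOI names for the global cortical
#'   target (default [default_global_vois()] of `map`).
#' @return A tibble with one row per participant: `participant_id`, `ligand`,
#'   ten `<lobe>_<hemisphere>` SUVR columns, and `global_suvr`.
#' @export
#' @examples
#' vois <- synthetic_voi_table(n = 2, seed = 1)
#' aggregate_profiles(vois)
aggregate_profiles <- function(vois,
                               map = default_region_map(),
                               reference_voi = "Cerebellum_Whole",
                               global_vois = default_global_vois(map)) {
  map <- validate_region_map(map)
  stopifnot(all(c("participant_id", "ligand", "voi_name",
                  "mean_uptake", "volume") %in% names(vois)))
  if (any(vois$volume <= 0)) stop("all VOI volumes must be positive")
  if (any(vois$mean_uptake < 0)) stop("VOI mean uptake must be nonnegative")
  unknown_global <- setdiff(global_vois, map$voi_name)
  if (length(unknown_global) > 0) {
    stop("global_vois not in region map: ",
         paste(unknown_global, collapse = ", "))
  }

  split(tibble::as_tibble(vois), vois$participant_id) |>
    purrr::map(aggregate_one_profile, map = map,
               reference_voi = reference_voi, global_vois = global_vois) |>
    dplyr::bind_rows()
}

aggregate_one_profile <- function(pv, map, reference_voi, global_vois) {
  id <- pv$participant_id[[1]]
  ligand <- unique(pv$ligand)
  if (length(ligand) != 1) {
    stop("participant ", id, " has multiple ligands: ",
         paste(ligand, collapse = ", "))
  }
  ref <- pv[pv$voi_name == reference_voi, ]
  if (nrow(ref) != 1) {
    stop("participant ", id, ": reference VOI '", reference_voi,
         "' must appear exactly once (found ", nrow(ref), ")")
  }
  if (ref$mean_uptake <= 0) {
    stop("participant ", id, ": reference uptake must be positive")
  }
  missing <- setdiff(map$voi_name, pv$voi_name)
  if (length(missing) > 0) {
    stop("participant ", id, ": missing VOI(s): ",
         paste(missing, collapse = ", "))
  }
  dup <- map$voi_name[tabulate(match(pv$voi_name, map$voi_name),
                               nbins = nrow(map)) > 1]
  if (length(dup) > 0) {
    stop("participant ", id, ": duplicated VOI(s): ",
         paste(dup, collapse = ", "))
  }

  joined <- dplyr::inner_join(map, pv, by = "voi_name")
  regional <- joined |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(
      suvr = stats::weighted.mean(.data$mean_uptake, .data$volume) /
        ref$mean_uptake,
      .groups = "drop"
    )
  gsub_tbl <- joined[joined$voi_name %in% global_vois, ]
  global_suvr <- stats::weighted.mean(gsub_tbl$mean_uptake, gsub_tbl$volume) /
    ref$mean_uptake

  out <- tibble::tibble(participant_id = id, ligand = ligand)
  suvr <- stats::setNames(regional$suvr, regional$region)
  for (r in region_names()) out[[r]] <- unname(suvr[[r]])
  out$global_suvr <- global_suvr
  out
}

validate_profiles <- function(profiles) {
  needed <- c("participant_id", "ligand", region_names(), "global_suvr")
  missing <- setdiff(needed, names(profiles))
  if (length(missing) > 0) {
    stop("profile table lacks column(s): ", paste(missing, collapse = ", "))
  }
  vals <- as.matrix(profiles[, c(region_names(), "global_suvr")])
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("all SUVR values must be finite and nonnegative")
  }
  bad <- setdiff(unique(profiles$ligand), c("FBB", "FMM"))
  if (length(bad) > 0) stop("unknown ligand(s): ", paste(bad, collapse = ", "))
  tibble::as_tibble(profiles)
}

#' Extract per-VOI mean uptake from an intensity volume and a label volume
#'
#' Computes, for each labeled parcel present in the label volume, the mean of
#' the intensity voxels carrying that label and their count (as `volume`).
#' Labels listed in `label_table` but absent from the image are omitted.
#'
#' @param intensity 3-D numeric array, or a NIfTI file path (requires the
#'   RNifti package).
#' @param labels 3-D integer array (or NIfTI path) on the same voxel grid.
#' @param label_table Named mapping from label value to VOI name: either a
#'   named character vector (names are label integers) or a data frame with
#'   columns `label` and `voi_name`.
#' @return A tibble with columns `voi_name`, `mean_uptake`, `volume`.
#' @export
extract_voi_means <- function(intensity, labels, label_table) {
  intensity <- as_volume(intensity)
  labels <- as_volume(labels)
  if (!identical(dim(intensity), dim(labels))) {
    stop("intensity and label volumes have different shapes: ",
         paste(dim(intensity), collapse = "x"), " vs ",
         paste(dim(labels), collapse = "x"))
  }
  if (is.data.frame(label_table)) {
    stopifnot(all(c("label", "voi_name") %in% names(label_table)))
    lt <- stats::setNames(label_table$voi_name, label_table$label)
  } else {
    lt <- label_table
  }
  lab_values <- as.integer(names(lt))
  if (any(is.na(lab_values)) || any(lab_values < 0)) {
    stop("label_table labels must be nonnegative integers")
  }

  lab_vec <- as.integer(labels)
  keep <- lab_vec %in% lab_values
  means <- tapply(as.numeric(intensity)[keep], lab_vec[keep], mean)
  counts <- tapply(lab_vec[keep], lab_vec[keep], length)
  tibble::tibble(
    voi_name = unname(lt[names(means)]),
    mean_uptake = as.numeric(means),
    volume = as.numeric(counts)
  )
}

as_volume <- function(x) {
  if (is.character(x)) {
    if (!requireNamespace("RNifti", quietly = TRUE)) {
      stop("reading NIfTI volumes requires the RNifti package")
    }
    x <- RNifti::readNifti(x)
  }
  x <- unclass(x)
  if (length(dim(x)) != 3) stop("expected a 3-D volume")
  x
}
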