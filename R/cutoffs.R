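# Regional SUVR positivity cutoffs by iterative Tukey-fence outlier removal.

#' Iterative-outlier SUVR cutoff for one region
#'
#' Repeatedly computes the first and third quartiles of the retained sample,
#' removes every value outside the Tukey inner fences
#' `[Q1 - k*IQR, Q3 + k*IQR]` (both tails in the same pass), and stops when a
#' pass removes nothing. Removed values never re-enter. The positivity cutoff
#' is the maximum of the final outlier-free sample increased by
#' `increment_fraction` of itself, i.e. `cutoff = (1 + f) * max(retained)`
#' with the default f = 0.025 (2.5%).
#'
#' @param values Numeric vector of SUVR values from the reference sample;
#'   at least `min_n` finite values are required — quartiles of tiny samples
#'   make the fences meaningless.
#' @param fence_multiplier Fence width k in IQR units (default 1.5, the Tukey
#'   inner fence).
#' @param increment_fraction Relative increment above the retained maximum
#'   (default 0.025).
#' @param quartile_type Quartile convention passed to [stats::quantile()]
#'   (default 7, linear interpolation between order statistics; use 2 for
#'   Tukey-hinge-like quartiles).
#' @param min_n Minimum admissible sample size (default 8).
#' @return An object of class `cutoff_trace`: a list with `cutoff`,
#'   `final_max`, `n_input`, and `iterations`, a tibble with one row per pass
#'   (`n_retained`, `q1`, `q3`, `iqr`, `lower_bound`, `upper_bound`,
#'   `n_removed`). The last pass always has `n_removed == 0`.
#' @export
#' @examples
#' trace <- iterative_outlier_cutoff(c(rnorm(100, 1.1, 0.05), 2.5, 3.0))
#' trace
#' tidy(trace)
iterative_outlier_cutoff <- function(values,
                                     fence_multiplier = 1.5,
                                     increment_fraction = 0.025,
                                     quartile_type = 7,
                                     min_n = 8) {
  values <- as.numeric(values)
  if (anyNA(values) || any(!is.finite(values))) {
    stop("values must be finite and non-missing")
  }
  if (length(values) < min_n) {
    stop("need at least ", min_n, " values to derive a cutoff (got ",
         length(values), ")")
  }
  stopifnot(fence_multiplier >= 0, increment_fraction > 0)

  retained <- values
  rows <- list()
  repeat {
    q <- stats::quantile(retained, c(0.25, 0.75),
                         type = quartile_type, names = FALSE)
    iqr <- q[2] - q[1]
    lo <- q[1] - fence_multiplier * iqr
    hi <- q[2] + fence_multiplier * iqr
    inside <- retained >= lo & retained <= hi
    n_removed <- sum(!inside)
    rows[[length(rows) + 1]] <- tibble::tibble(
      n_retained = length(retained), q1 = q[1], q3 = q[2], iqr = iqr,
      lower_bound = lo, upper_bound = hi, n_removed = n_removed
    )
    if (n_removed == 0) break
    retained <- retained[inside]
    # Tukey fences always keep the inter-quartile core, but assert anyway.
    if (length(retained) == 0) stop("retained set emptied; cannot happen")
  }

  final_max <- max(retained)
  structure(
    list(
      iterations = dplyr::bind_rows(rows),
      final_max = final_max,
      cutoff = (1 + increment_fraction) * final_max,
      n_input = length(values),
      n_final = length(retained),
      fence_multiplier = fence_multiplier,
      increment_fraction = increment_fraction,
      quartile_type = quartile_type
    ),
    class = "cutoff_trace"
  )
}

#' @export
print.cutoff_trace <- function(x, ...) {
  cat(sprintf(
    "iterative-outlier cutoff: %.4f (= %.4f x max retained %.4f)\n",
    x$cutoff, 1 + x$increment_fraction, x$final_max))
  cat(sprintf("  %d -> %d values over %d pass(es)\n",
              x$n_input, x$n_final, nrow(x$iterations)))
  invisible(x)
}

#' @rdname iterative_outlier_cutoff
#' @param x A `cutoff_trace`.
#' @param ... Unused.
#' @export
tidy.cutoff_trace <- function(x, ...) {
  dplyr::mutate(x$iterations, iteration = dplyr::row_number(),
                .before = 1)
}

#' @rdname iterative_outlier_cutoff
#' @export
glance.cutoff_trace <- function(x, ...) {
  tibble::tibble(
    cutoff = x$cutoff, final_max = x$final_max,
    n_input = x$n_input, n_final = x$n_final,
    n_iterations = nrow(x$iterations),
    n_removed_total = x$n_input - x$n_final
  )
}

#' Derive per-region cutoffs from a cognitively unimpaired reference sample
#'
#' Applies [iterative_outlier_cutoff()] independently to each of the ten
#' composite regions' SUVR vectors, using only profiles acquired with the
#' stated ligand. Cutoffs are ligand-specific because the two tracers sit on
#' different SUVR scales.
#'
#' @param cu_profiles Profile tibble (see [aggregate_profiles()]) of the
#'   cognitively unimpaired reference sample; every row must carry `ligand`.
#' @param ligand `"FBB"` or `"FMM"`; all profiles must match.
#' @param ... Passed on to [iterative_outlier_cutoff()].
#' @return An object of class `regional_cutoffs`: `ligand`, `reference_n`,
#'   and `per_region`, a named list of `cutoff_trace` objects.
#' @export
derive_regional_cutoffs <- function(cu_profiles, ligand, ...) {
  ligand <- match.arg(ligand, c("FBB", "FMM"))
  cu_profiles <- validate_profiles(cu_profiles)
  if (!all(cu_profiles$ligand == ligand)) {
    stop("cu_profiles mixes ligands; expected all ", ligand)
  }
  traces <- purrr::map(
    stats::setNames(region_names(), region_names()),
    function(r) iterative_outlier_cutoff(cu_profiles[[r]], ...)
  )
  structure(
    list(ligand = ligand, per_region = traces,
         reference_n = nrow(cu_profiles)),
    class = "regional_cutoffs"
  )
}

#' @export
print.regional_cutoffs <- function(x, ...) {
  cat(sprintf("regional SUVR cutoffs [%s], reference n = %d\n",
              x$ligand, x$reference_n))
  print(tidy(x), n = 10)
  invisible(x)
}

#' @rdname derive_regional_cutoffs
#' @param x A `regional_cutoffs` object.
#' @param ... Unused (tidier methods).
#' @export
tidy.regional_cutoffs <- function(x, ...) {
  purrr::map_dfr(x$per_region, glance, .id = "region") |>
    dplyr::mutate(ligand = x$ligand, .before = 1)
}

#' Extract the named cutoff vector from a `regional_cutoffs` object
#'
#' @param cutoffs A `regional_cutoffs` object.
#' @return Named numeric vector over the ten regions.
#' @export
cutoff_values <- function(cutoffs) {
  stopifnot(inherits(cutoffs, "regional_cutoffs"))
  vapply(cutoffs$per_region, function(t) t$cutoff, numeric(1))
}

#' Write / read regional cutoffs as JSON (with full derivation traces)
#'
#' @param cutoffs A `regional_cutoffs` object.
#' @param path Output JSON path.
#' @return `path`, invisibly (`write_regional_cutoffs`); a
#'   `regional_cutoffs` object (`read_regional_cutoffs`).
#' @export
write_regional_cutoffs <- function(cutoffs, path) {
  stopifnot(inherits(cutoffs, "regional_cutoffs"))
  payload <- list(
    ligand = cutoffs$ligand,
    reference_n = cutoffs$reference_n,
    per_region = purrr::map(cutoffs$per_region, function(t) {
      list(cutoff = t$cutoff, final_max = t$final_max,
           n_input = t$n_input, n_final = t$n_final,
           fence_multiplier = t$fence_multiplier,
           increment_fraction = t$increment_fraction,
           quartile_type = t$quartile_type,
           iterations = t$iterations)
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_regional_cutoffs
#' @export
read_regional_cutoffs <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  traces <- purrr::map(payload$per_region, function(t) {
    structure(
      list(iterations = tibble::as_tibble(t$iterations),
           final_max = t$final_max, cutoff = t$cutoff,
           n_input = t$n_input, n_final = t$n_final,
           fence_multiplier = t$fence_multiplier,
           increment_fraction = t$increment_fraction,
           quartile_type = t$quartile_type),
      class = "cutoff_trace"
    )
  })
  structure(
    list(ligand = payload$ligand, per_region = traces,
         reference_n = payload$reference_n),
    class = "regional_cutoffs"
  )
}
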