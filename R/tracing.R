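#' Validate a tract-tracing count table
#'
#' One row per (case, slice, region): labeled-cell count and the measured
#' region area on that coronal slice. Regions are the centromedian-type
#' comparisons used for afferent quantification: `CM`, `CL_ipsi`,
#' `CL_contra`.
#'
#' @param counts Data frame with columns `case_id`, `afferent`,
#'   `slice_index`, `region`, `count`, `area_mm2`.
#' @return The validated data frame, class `tracing_counts`.
#' @export
tracing_counts <- function(counts) {
  need <- c("case_id", "afferent", "slice_index", "region", "count",
            "area_mm2")
  miss <- setdiff(need, names(counts))
  if (length(miss)) {
    stop("counts table missing column(s): ", paste(miss, collapse = ", "))
  }
  bad <- setdiff(unique(counts$region), c("CM", "CL_ipsi", "CL_contra"))
  if (length(bad)) {
    stop("unknown region(s): ", paste(bad, collapse = ", "))
  }
  if (any(counts$count < 0)) stop("counts must be nonnegative")
  if (any(counts$area_mm2 <= 0)) stop("areas must be positive")
  structure(counts, class = c("tracing_counts", "data.frame"))
}

#' Simulate Poisson tract-tracing counts
#'
#' Labeled-cell counts per slice and region drawn as Poisson variates with
#' mean `base_count * ratios[region] * area`, for testing the ratio
#' quantification with known ground truth.
#'
#' @param ratios Named numeric vector of expected relative densities per
#'   region, e.g. `c(CM = 2, CL_ipsi = 1, CL_contra = 1)`; all positive.
#' @param base_count Expected count at ratio 1 and area 1 (> 0).
#' @param n_slices Slices per case, default 3.
#' @param case_id,afferent Labels for the output rows.
#' @param area_mm2 Region area per slice, default 1.
#' @param seed Optional integer seed.
#' @return A `tracing_counts` table.
#' @export
simulate_tracing_counts <- function(ratios = c(CM = 1, CL_ipsi = 1,
                                               CL_contra = 1),
                                    base_count = 1000, n_slices = 3,
                                    case_id = "case1", afferent = "afferent",
                                    area_mm2 = 1, seed = NULL) {
  stop_if_not_scalar_number(base_count, "base_count", positive = TRUE)
  if (is.null(names(ratios)) || any(ratios <= 0)) {
    stop("`ratios` must be a named vector of positive values")
  }
  with_seed(seed, {
    grid <- expand.grid(slice_index = seq_len(n_slices),
                        region = names(ratios), stringsAsFactors = FALSE)
    grid$case_id <- case_id
    grid$afferent <- afferent
    grid$area_mm2 <- area_mm2
    grid$count <- stats::rpois(nrow(grid),
                               base_count * ratios[grid$region] * area_mm2)
    tracing_counts(grid[, c("case_id", "afferent", "slice_index", "region",
                            "count", "area_mm2")])
  })
}

#' Strong-difference flag for a density ratio
#'
#' A comparison is flagged strong when the two densities differ by at
#' least 40% of the larger one, i.e. `min / max <= 0.6` (equivalently the
#' ratio is >= 5/3 or <= 0.6); the boundary is inclusive and the flag is
#' direction-agnostic.
#'
#' @param ratio Positive finite ratio(s) of two densities.
#' @return Logical vector.
#' @examples
#' strength_flag(100 / 60)  # TRUE: exactly 40% difference
#' strength_flag(100 / 61)  # FALSE
#' @export
strength_flag <- function(ratio) {
  if (any(!is.finite(ratio)) || any(ratio <= 0)) {
    stop("`ratio` must be finite and positive")
  }
  pmin(ratio, 1 / ratio) <= 0.6 + 1e-12
}

per_slice_ratio <- function(df, num_region, den_region) {
  slices <- sort(unique(df$slice_index))
  vals <- vapply(slices, function(s) {
    sl <- df[df$slice_index == s, , drop = FALSE]
    num <- sl[sl$region == num_region, , drop = FALSE]
    den <- sl[sl$region == den_region, , drop = FALSE]
    if (nrow(num) == 0L || nrow(den) == 0L) return(NA_real_)
    d_num <- sum(num$count) / sum(num$area_mm2)
    d_den <- sum(den$count) / sum(den$area_mm2)
    if (d_den == 0) {
      warning(sprintf("slice %s: zero %s density; slice excluded",
                      as.character(s), den_region))
      return(NA_real_)
    }
    d_num / d_den
  }, numeric(1))
  vals[!is.na(vals)]
}

#' Area-corrected cell-count density ratios
#'
#' For every coronal slice, the ratio of area-corrected cell densities
#' (count / area) is formed for the two stereotyped comparisons, CM versus
#' ipsilateral CL and ipsilateral CL versus contralateral CL; slice ratios
#' are averaged within each case and the case means are averaged across
#' cases. Slices with a zero denominator density are excluded with a
#' warning; a comparison with no usable slice in any case is an error.
#'
#' @param counts A `tracing_counts` table (single afferent).
#' @return A `connectivity_summary`: list with `ratio_cm_ipsicl`,
#'   `ratio_ipsicl_contracl`, the corresponding [strength_flag()]s,
#'   per-case means, and `n_cases`.
#' @export
density_ratios <- function(counts) {
  counts <- tracing_counts(as.data.frame(counts))
  cases <- unique(counts$case_id)
  per_case <- lapply(cases, function(cs) {
    df <- counts[counts$case_id == cs, , drop = FALSE]
    c(cm_ipsicl = mean(per_slice_ratio(df, "CM", "CL_ipsi")),
      ipsicl_contracl = mean(per_slice_ratio(df, "CL_ipsi", "CL_contra")))
  })
  mat <- do.call(rbind, per_case)
  rownames(mat) <- cases
  means <- colMeans(mat, na.rm = TRUE)
  if (any(!is.finite(means))) {
    stop("all slices excluded for at least one ratio; cannot summarize")
  }
  structure(list(ratio_cm_ipsicl = unname(means["cm_ipsicl"]),
                 ratio_ipsicl_contracl = unname(means["ipsicl_contracl"]),
                 strong_cm_ipsicl = strength_flag(means["cm_ipsicl"]),
                 strong_ipsicl_contracl =
                   strength_flag(means["ipsicl_contracl"]),
                 per_case = mat, n_cases = length(cases)),
            class = "connectivity_summary")
}

#' @export
print.connectivity_summary <- function(x, ...) {
  cat(sprintf(
    "<connectivity_summary> %d case(s)\n  CM : ipsi CL      = %.3f%s\n  ipsi CL : contra CL = %.3f%s\n",
    x$n_cases, x$ratio_cm_ipsicl,
    if (x$strong_cm_ipsicl) "  [strong]" else "",
    x$ratio_ipsicl_contracl,
    if (x$strong_ipsicl_contracl) "  [strong]" else ""))
  invisible(x)
}

#' Summary table across afferents
#'
#' Builds the per-afferent diagram table: mean density ratios, strong-
#' difference flags, and the number of contributing cases. Accepts either a
#' `tracing_counts` table spanning several afferents or a list of
#' `connectivity_summary` objects (one per case of one afferent).
#'
#' @param x A `tracing_counts` data frame or a nonempty list of
#'   `connectivity_summary` objects.
#' @return Data frame with one row per afferent: `afferent`, `n_cases`,
#'   `ratio_cm_ipsicl`, `strong_cm_ipsicl`, `ratio_ipsicl_contracl`,
#'   `strong_ipsicl_contracl`.
#' @export
summarize_afferent <- function(x) {
  if (is.data.frame(x)) {
    x <- tracing_counts(x)
    affs <- unique(x$afferent)
    rows <- lapply(affs, function(a) {
      s <- density_ratios(x[x$afferent == a, , drop = FALSE])
      data.frame(afferent = a, n_cases = s$n_cases,
                 ratio_cm_ipsicl = s$ratio_cm_ipsicl,
                 strong_cm_ipsicl = s$strong_cm_ipsicl,
                 ratio_ipsicl_contracl = s$ratio_ipsicl_contracl,
                 strong_ipsicl_contracl = s$strong_ipsicl_contracl)
    })
    return(do.call(rbind, rows))
  }
  if (!is.list(x) || length(x) == 0L ||
      !all(vapply(x, inherits, logical(1), "connectivity_summary"))) {
    stop("`x` must be a tracing_counts table or a nonempty list of connectivity_summary objects")
  }
  r1 <- mean(vapply(x, `[[`, numeric(1), "ratio_cm_ipsicl"))
  r2 <- mean(vapply(x, `[[`, numeric(1), "ratio_ipsicl_contracl"))
  data.frame(afferent = "combined", n_cases = length(x),
             ratio_cm_ipsicl = r1, strong_cm_ipsicl = strength_flag(r1),
             ratio_ipsicl_contracl = r2,
             strong_ipsicl_contracl = strength_flag(r2))
}
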