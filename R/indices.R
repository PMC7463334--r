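check_index_inputs <- function(dfst, areas, T) {
  stopifnot(is.matrix(dfst), nrow(dfst) == ncol(dfst),
            length(areas) == nrow(dfst), all(areas > 0), T >= 0)
}

index_compare <- function(x, T, strict) if (strict) x < T else x <= T

#' Outbound connectivity index (OCI)
#'
#' Total area (km2) of the neighboring destination reefs that the focal
#' reef can reach within a dFST threshold:
#' `OCI(i) = sum_{j != i} area_j * [dfst(i -> j) < T]`. The focal cell's
#' own area is excluded.
#'
#' @param dfst directed dFST matrix (rows = origins, cols = destinations).
#' @param areas reef areas (km2), aligned with the matrix.
#' @param T dFST threshold.
#' @param strict strict `< T` comparison (default) or `<= T`.
#' @param include_focal include the focal reef's own area (sensitivity
#'   option; off by default).
#' @return numeric vector of OCI values (km2).
#' @export
oci <- function(dfst, areas, T = 0.02, strict = TRUE,
                include_focal = FALSE) {
  check_index_inputs(dfst, areas, T)
  A <- index_compare(dfst, T, strict)
  if (!include_focal) diag(A) <- FALSE
  as.vector(A %*% areas)
}

#' Inbound connectivity index (ICI)
#'
#' Total area (km2) of the neighboring departure reefs that can reach the
#' focal reef within a dFST threshold:
#' `ICI(i) = sum_{j != i} area_j * [dfst(j -> i) < T]`.
#'
#' @inheritParams oci
#' @return numeric vector of ICI values (km2).
#' @export
ici <- function(dfst, areas, T = 0.02, strict = TRUE,
                include_focal = FALSE) {
  oci(t(dfst), areas, T, strict, include_focal)
}

#' Adaptive potential index (API)
#'
#' ICI with each contributing reef's area weighted by its probability of
#' carrying adaptive genotypes:
#' `API(i) = sum_{j != i} area_j * pa_j * [dfst(j -> i) < T]` (km2).
#'
#' @inheritParams oci
#' @param pa per-reef probabilities in `[0, 1]`.
#' @return numeric vector of API values (km2).
#' @export
api <- function(dfst, areas, pa, T = 0.02, strict = TRUE,
                include_focal = FALSE) {
  check_index_inputs(dfst, areas, T)
  if (any(pa < 0 | pa > 1, na.rm = TRUE)) stop("pa must lie in [0, 1]")
  A <- index_compare(t(dfst), T, strict)
  if (!include_focal) diag(A) <- FALSE
  as.vector(A %*% (areas * pa))
}

#' Per-reef index table
#'
#' Convenience wrapper computing OCI, ICI and (when `pa` is given) API for
#' every reef cell at one threshold.
#'
#' @inheritParams api
#' @param cells cell ids.
#' @param pa per-reef PA, or `NULL` to skip API.
#' @return data frame `cell`, `area_km2`, `OCI`, `ICI`, `API` (NA when no
#'   `pa`), plus the threshold as the `"threshold"` attribute.
#' @export
index_table <- function(dfst, areas, pa = NULL, T = 0.02,
                        cells = rownames(dfst) %||% seq_along(areas),
                        strict = TRUE) {
  out <- data.frame(cell = cells, area_km2 = areas,
                    OCI = oci(dfst, areas, T, strict),
                    ICI = ici(dfst, areas, T, strict),
                    API = if (is.null(pa)) NA_real_
                          else api(dfst, areas, pa, T, strict))
  attr(out, "threshold") <- T
  out
}
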