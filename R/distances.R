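#' Bray-Curtis dissimilarity between samples
#'
#' d(x, y) = 1 - 2 * sum_k min(x_k, y_k) / (sum_k x_k + sum_k y_k). On
#' relative-abundance rows this equals half the L1 distance. Counts and
#' relative abundances of a rarefied table give identical matrices (the
#' uniform depth cancels).
#'
#' @param x An [otu_table()] or relative-abundance matrix with >= 2 samples.
#' @param as_similarity Return 1 - d instead of d.
#' @return A `dist` object with attribute `metric = "bray_curtis"`.
#' @export
bray_curtis <- function(x, as_similarity = FALSE) {
  m <- unclass(x)
  if (nrow(m) < 2L) stop("need at least 2 samples", call. = FALSE)
  zero <- rowSums(m) == 0
  if (sum(zero) >= 2L) {
    stop("Bray-Curtis undefined for a pair of all-zero samples: ",
         paste(rownames(m)[zero], collapse = ", "), call. = FALSE)
  }
  d <- vegan::vegdist(m, method = "bray")
  if (as_similarity) d <- 1 - d
  attr(d, "metric") <- "bray_curtis"
  d
}

#' Euclidean distance between samples in environmental space
#'
#' Each covariate except pH is log(x+1)-transformed (to tame right-skewed
#' concentration data), then all are standardized to zero mean and unit
#' variance before the Euclidean distance is taken, so no single variable's
#' units dominate.
#'
#' @param meta Sample metadata ([read_sample_metadata()] format).
#' @param variables Character vector of covariate columns to use.
#' @return A `dist` labeled by `sample_id`, attribute `metric = "euclidean"`.
#' @export
env_distance <- function(meta, variables) {
  miss <- setdiff(variables, names(meta))
  if (length(miss)) {
    stop("metadata missing variable(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  m <- transform_env(meta, variables)
  d <- stats::dist(m, method = "euclidean")
  attr(d, "metric") <- "euclidean"
  d
}

# log(x+1) all quantitative covariates except pH, then center/scale;
# constant columns are centered but left unscaled (sd 0)
transform_env <- function(meta, variables) {
  m <- as.matrix(meta[, variables, drop = FALSE])
  if (!is.numeric(m)) stop("environmental variables must be numeric",
                           call. = FALSE)
  if (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)
    stop("missing environmental value(s): ",
         paste(sprintf("%s/%s", meta$sample_id[idx[, 1L]],
                       variables[idx[, 2L]]), collapse = ", "),
         call. = FALSE)
  }
  rownames(m) <- meta$sample_id
  keep_raw <- tolower(variables) %in% c("ph")
  m[, !keep_raw] <- log1p(m[, !keep_raw, drop = FALSE])
  sds <- apply(m, 2L, stats::sd)
  scale(m, center = TRUE, scale = ifelse(sds > 0, sds, 1))
}

#' Great-circle distance between sampling sites
#'
#' Haversine distance in kilometres on a sphere of radius 6,371 km.
#'
#' @param meta Sample metadata with `latitude` and `longitude` in decimal
#'   degrees.
#' @return A `dist` labeled by `sample_id`, attribute `metric = "geographic"`.
#' @export
geographic_distance <- function(meta) {
  if (!all(c("latitude", "longitude") %in% names(meta))) {
    stop("metadata must have latitude and longitude columns", call. = FALSE)
  }
  lat <- meta$latitude
  lon <- meta$longitude
  if (anyNA(lat) || anyNA(lon) || any(abs(lat) > 90) || any(abs(lon) > 180)) {
    stop("coordinates missing or outside valid ranges", call. = FALSE)
  }
  pts <- cbind(lon, lat)
  n <- nrow(pts)
  km <- matrix(0, n, n, dimnames = list(meta$sample_id, meta$sample_id))
  for (i in seq_len(n)) {
    km[i, ] <- geosphere::distHaversine(pts[i, ], pts, r = 6371000) / 1000
  }
  km <- (km + t(km)) / 2
  diag(km) <- 0
  d <- stats::as.dist(km)
  attr(d, "metric") <- "geographic"
  d
}

# lower-triangle vector of a dist/matrix, used by MultiCoLA and Mantel
lower_tri <- function(dm) {
  m <- as.matrix(dm)
  m[lower.tri(m)]
}
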