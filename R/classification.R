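#' Fit a k-means classifier to droplet signatures
#'
#' Recovers the fluorophore groups of a mixed droplet population by
#' standard k-means clustering of the 3-channel signature magnitudes
#' (Euclidean distance on raw, background-subtracted volts; 10 random
#' restarts by default). Each centroid is then assigned a palette label by
#' thresholding every channel at the midpoint of that channel's centroid
#' range (high iff above the midpoint), giving the binary palette encoding.
#'
#' @param signatures data.frame from [group_peaks()]; only complete
#'   signatures are used.
#' @param k number of clusters (default 8, the full palette).
#' @param seed integer seed for centroid initialization.
#' @param nstart number of k-means restarts.
#' @return An object of class `droplet_classifier` with `type = "kmeans"`,
#'   `centroids` (k x 3 matrix, channels blue/green/red) and `labels`
#'   (palette index per centroid).
#' @export
fit_kmeans <- function(signatures, k = 8, seed = 1L, nstart = 10) {
  x <- signature_matrix(signatures)
  if (nrow(x) < k)
    stop("need at least `k` complete signatures (got ", nrow(x), ")",
         call. = FALSE)
  km <- withr_rng(seed, kmeans(x, centers = k, nstart = nstart,
                               iter.max = 100))
  cen <- km$centers
  mids <- (apply(cen, 2, min) + apply(cen, 2, max)) / 2
  lv <- t(t(cen) > mids) * 1L
  structure(
    list(type = "kmeans", centroids = cen, labels = palette_index(lv),
         channel_mids = mids),
    class = "droplet_classifier"
  )
}

#' Per-channel threshold classifier
#'
#' The supervised classifier used for live sorting decisions: each channel
#' is called "high" iff its magnitude exceeds a fixed decision threshold.
#' Thresholds must lie strictly between the low and high calibration means
#' of their channel; [calibrate_thresholds()] places them at the midpoint.
#'
#' @param thresholds length-3 numeric vector of decision thresholds (volts)
#'   in channel order (blue, green, red).
#' @return An object of class `droplet_classifier` with `type = "threshold"`.
#' @export
threshold_model <- function(thresholds) {
  stopifnot(is.numeric(thresholds), length(thresholds) == 3)
  structure(list(type = "threshold", thresholds = as.numeric(thresholds)),
            class = "droplet_classifier")
}

#' @rdname threshold_model
#' @param group_means matrix of per-group channel means (e.g.
#'   [default_group_means()]); each channel must show exactly two levels.
#' @return `calibrate_thresholds()`: a threshold `droplet_classifier` with
#'   each threshold at the midpoint of its channel's low and high means.
#' @export
calibrate_thresholds <- function(group_means = default_group_means()) {
  thr <- apply(group_means, 2, function(v) {
    u <- sort(unique(v))
    if (length(u) != 2)
      stop("each channel needs exactly two calibration levels", call. = FALSE)
    mean(u)
  })
  threshold_model(thr)
}

#' Classify droplet signatures onto the palette
#'
#' Maps each complete signature to a palette index (0-7): nearest centroid
#' (Euclidean) for a k-means model, or a per-channel high/low test for a
#' threshold model. Ties between centroids go to the lowest palette index.
#' Incomplete signatures are refused and returned as `NA` — they flag a
#' droplet the sorter must not deflect.
#'
#' @param signatures data.frame from [group_peaks()] (or a numeric matrix
#'   of magnitudes, all rows treated as complete).
#' @param model a `droplet_classifier` from [fit_kmeans()],
#'   [threshold_model()] or [calibrate_thresholds()].
#' @return Integer vector of palette indices (0-7), `NA` for incomplete
#'   signatures.
#' @export
classify_signatures <- function(signatures, model) {
  stopifnot(inherits(model, "droplet_classifier"))
  if (is.matrix(signatures)) {
    x <- signatures
    complete <- rep(TRUE, nrow(x))
  } else {
    x <- signature_matrix(signatures, complete_only = FALSE)
    complete <- signatures$complete
  }
  out <- rep(NA_integer_, nrow(x))
  if (!any(complete)) return(out)
  xc <- x[complete, , drop = FALSE]
  lab <- if (model$type == "threshold") {
    lv <- t(t(xc) > model$thresholds) * 1L
    palette_index(lv)
  } else {
    cen <- model$centroids
    d2 <- outer(rowSums(xc^2), rep(1, nrow(cen))) -
      2 * xc %*% t(cen) + outer(rep(1, nrow(xc)), rowSums(cen^2))
    apply(d2, 1, function(row) {
      # tie-break: among equidistant centroids pick the lowest palette index
      cand <- which(row <= min(row) + 1e-12)
      as.integer(min(model$labels[cand]))
    })
  }
  out[complete] <- lab
  out
}

signature_matrix <- function(signatures, complete_only = TRUE) {
  mag_cols <- grep("^mag[0-9]+$", names(signatures), value = TRUE)
  if (length(mag_cols) == 0)
    stop("`signatures` has no magnitude columns", call. = FALSE)
  keep <- if (complete_only) signatures$complete else rep(TRUE, nrow(signatures))
  as.matrix(signatures[keep, mag_cols, drop = FALSE])
}

#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions of the same items;
#' 1 for identical partitions, ~0 for independent ones. Used to score
#' k-means population recovery against synthetic ground truth.
#'
#' @param a,b label vectors of equal length (any types coercible to factor).
#' @return The adjusted Rand index (numeric scalar).
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
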