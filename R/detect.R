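#' Nucleus detection parameters
#'
#' @param smoothing_sigma Gaussian smoothing sigma, um.
#' @param threshold_method \code{"valley"} (automatic histogram-valley
#'   threshold on the smoothed image) or \code{"fixed"}.
#' @param threshold_value threshold, a.u. (required when fixed).
#' @param min_area,max_area nuclear area limits, um^2.
#' @param expansion_distance perinuclear expansion distance, um (default 5).
#' @param pixel_size um/px; may also come from image metadata.
#' @param watershed_tolerance minimum object-depth for splitting touching
#'   nuclei, in pixels of the distance map.
#' @param positivity_thresholds optional named per-channel thresholds, a.u.
#' @return an object of class \code{detection_params}.
#' @export
detection_params <- function(smoothing_sigma = 1,
                             threshold_method = c("valley", "fixed"),
                             threshold_value = NULL,
                             min_area = 5, max_area = 500,
                             expansion_distance = 5,
                             pixel_size = NULL,
                             watershed_tolerance = 1,
                             positivity_thresholds = NULL) {
  threshold_method <- match.arg(threshold_method)
  if (threshold_method == "fixed" && is.null(threshold_value))
    stop("threshold_value is required for the fixed method", call. = FALSE)
  if (min_area <= 0 || max_area <= min_area)
    stop("need 0 < min_area < max_area", call. = FALSE)
  if (expansion_distance < 0)
    stop("expansion_distance must be >= 0", call. = FALSE)
  if (!is.null(pixel_size) && pixel_size <= 0)
    stop("pixel_size must be positive", call. = FALSE)
  structure(list(smoothing_sigma = smoothing_sigma,
                 threshold_method = threshold_method,
                 threshold_value = threshold_value,
                 min_area = min_area, max_area = max_area,
                 expansion_distance = expansion_distance,
                 pixel_size = pixel_size,
                 watershed_tolerance = watershed_tolerance,
                 positivity_thresholds = positivity_thresholds),
            class = "detection_params")
}

#' Histogram-valley threshold for bimodal data
#'
#' Kernel density estimate; the threshold is the density minimum between the
#' two most prominent modes. Falls back to an inter-mean split when the
#' density has fewer than two modes.
#'
#' @param values numeric vector.
#' @return threshold value.
#' @export
valley_threshold <- function(values) {
  values <- values[is.finite(values)]
  if (length(unique(values)) < 3) return(max(values))
  d <- stats::density(values, n = 512)
  y <- d$y
  peaks <- which(diff(sign(diff(y))) == -2) + 1L
  if (length(peaks) >= 2) {
    top2 <- sort(peaks[order(y[peaks], decreasing = TRUE)][1:2])
    seg <- top2[1]:top2[2]
    return(d$x[seg[which.min(y[seg])]])
  }
  ## fallback: iterated inter-mean split (two-class Lloyd on 1-D data)
  t0 <- mean(range(values))
  for (i in 1:50) {
    lo <- values[values <= t0]; hi <- values[values > t0]
    if (!length(lo) || !length(hi)) break
    t1 <- (mean(lo) + mean(hi)) / 2
    if (abs(t1 - t0) < 1e-8) break
    t0 <- t1
  }
  t0
}

pixel_size_of <- function(image, params = NULL) {
  px <- attr(image, "pixel_size")
  if (is.null(px) && !is.null(params)) px <- params$pixel_size
  if (is.null(px))
    stop("metadata error: pixel size missing from image and parameters",
         call. = FALSE)
  px
}

#' Detect nuclei in a DAPI channel
#'
#' Gaussian smoothing, global threshold (fixed or histogram-valley), hole
#' filling, distance-transform watershed to split touching nuclei, and an
#' area filter. Returns an integer label matrix (background 0, nuclei
#' 1..K relabelled sequentially) carrying the pixel-size (and, when
#' present, origin) metadata of the input.
#'
#' @param dapi_image single-channel matrix with a \code{pixel_size}
#'   attribute (e.g. from \code{\link{get_channel}}).
#' @param params a \code{detection_params}.
#' @return integer label matrix.
#' @export
detect_nuclei <- function(dapi_image, params = detection_params()) {
  px <- pixel_size_of(dapi_image, params)
  img <- unclass(dapi_image)
  sm <- if (params$smoothing_sigma > 0)
    EBImage::imageData(EBImage::gblur(img, sigma = params$smoothing_sigma / px))
  else img
  thr <- if (params$threshold_method == "fixed") params$threshold_value
  else valley_threshold(as.vector(sm))
  mask <- sm > thr
  if (!any(mask)) {
    lab <- matrix(0L, nrow(img), ncol(img))
  } else {
    mask <- EBImage::imageData(EBImage::fillHull(EBImage::Image(mask * 1)))
    dm <- EBImage::distmap(mask)
    ws <- EBImage::watershed(dm, tolerance = params$watershed_tolerance,
                             ext = 1)
    lab <- matrix(as.integer(EBImage::imageData(ws)), nrow(img), ncol(img))
    ## area filter in um^2, relabel sequentially
    cnt <- tabulate(lab)
    areas <- cnt * px^2
    keep <- which(areas >= params$min_area & areas <= params$max_area)
    map <- integer(length(cnt))
    map[keep] <- seq_along(keep)
    lab[lab > 0] <- map[lab[lab > 0]]
  }
  attr(lab, "pixel_size") <- px
  attr(lab, "origin") <- attr(dapi_image, "origin")
  lab
}

#' Expand nuclei into perinuclear "pseudoplasm" annuli
#'
#' Every background pixel whose centre lies within \code{expansion_distance}
#' of some nucleus pixel is assigned to its nearest nucleus (Euclidean
#' distance between pixel centres); annuli therefore never overlap each
#' other or any nucleus. Equidistant ties go to the lower label id.
#'
#' @param labels integer nucleus label matrix (from
#'   \code{\link{detect_nuclei}}).
#' @param expansion_distance um (default 5, the QuPath-style cell
#'   expansion used for cytoplasmic sampling).
#' @param pixel_size um/px; defaults to the label-matrix metadata.
#' @return integer annulus label matrix (same ids as \code{labels}).
#' @export
expand_pseudoplasm <- function(labels, expansion_distance = 5,
                               pixel_size = attr(labels, "pixel_size")) {
  if (is.null(pixel_size))
    stop("metadata error: pixel size missing", call. = FALSE)
  if (expansion_distance < 0)
    stop("parameter error: expansion_distance must be >= 0", call. = FALSE)
  nx <- nrow(labels); ny <- ncol(labels)
  ann <- matrix(0L, nx, ny)
  attr(ann, "pixel_size") <- pixel_size
  attr(ann, "origin") <- attr(labels, "origin")
  ids <- sort(unique(labels[labels > 0]))
  if (expansion_distance == 0 || !length(ids)) return(ann)
  D <- expansion_distance / pixel_size
  pad <- ceiling(D) + 1L
  best_d <- matrix(Inf, nx, ny)
  for (id in ids) {
    w <- which(labels == id, arr.ind = TRUE)
    i0 <- max(1L, min(w[, 1]) - pad); i1 <- min(nx, max(w[, 1]) + pad)
    j0 <- max(1L, min(w[, 2]) - pad); j1 <- min(ny, max(w[, 2]) + pad)
    loc <- labels[i0:i1, j0:j1, drop = FALSE]
    m <- (loc != id) * 1  # non-id pixels are "foreground" for distmap
    dloc <- EBImage::imageData(EBImage::distmap(m))
    cand <- dloc > 0 & dloc <= D & loc == 0
    if (!any(cand)) next
    sub_d <- best_d[i0:i1, j0:j1, drop = FALSE]
    sub_a <- ann[i0:i1, j0:j1, drop = FALSE]
    upd <- cand & (dloc < sub_d)  # strict: ties stay with the lower id
    sub_d[upd] <- dloc[upd]
    sub_a[upd] <- id
    best_d[i0:i1, j0:j1] <- sub_d
    ann[i0:i1, j0:j1] <- sub_a
  }
  ann
}

#' Measure per-cell compartment intensities
#'
#' For every nucleus label: centroid (um, pixel-centre convention, offset by
#' the image origin when present), nuclear area (um^2), and the mean
#' intensity over nuclear pixels and over annulus pixels for every channel.
#' Cells whose annulus is empty get \code{NA} annulus means.
#'
#' @param labels nucleus label matrix.
#' @param annuli annulus label matrix (same ids), or \code{NULL} to skip
#'   annulus measurements.
#' @param channel_images named list of channel matrices (or a
#'   \code{sim_image}).
#' @param pixel_size um/px; defaults to label-matrix metadata.
#' @return data.frame with one row per cell: \code{cell_id, x, y,
#'   nuclear_area}, then \code{nuclear_mean_<ch>} and
#'   \code{annulus_mean_<ch>} per channel.
#' @export
measure_cells <- function(labels, annuli, channel_images,
                          pixel_size = attr(labels, "pixel_size")) {
  if (inherits(channel_images, "sim_image"))
    channel_images <- channel_images$channels
  if (is.null(pixel_size))
    stop("metadata error: pixel size missing", call. = FALSE)
  for (ch in names(channel_images))
    if (!identical(dim(channel_images[[ch]]), dim(labels)))
      stop("shape error: channel ", ch, " does not match label dimensions",
           call. = FALSE)
  if (!is.null(annuli) && !identical(dim(annuli), dim(labels)))
    stop("shape error: annulus mask does not match label dimensions",
         call. = FALSE)
  ids <- sort(unique(labels[labels > 0]))
  orig <- attr(labels, "origin")
  if (is.null(orig)) orig <- c(x = 0, y = 0)
  if (!length(ids)) {
    out <- data.frame(cell_id = integer(0), x = numeric(0), y = numeric(0),
                      nuclear_area = numeric(0))
    for (ch in names(channel_images)) {
      out[[paste0("nuclear_mean_", ch)]] <- numeric(0)
      out[[paste0("annulus_mean_", ch)]] <- numeric(0)
    }
    return(out)
  }
  idx <- which(labels > 0)
  lab_v <- labels[idx]
  ij <- arrayInd(idx, dim(labels))
  cnt <- as.vector(rowsum(rep(1, length(idx)), lab_v))
  cx <- as.vector(rowsum(ij[, 1] - 1, lab_v)) / cnt * pixel_size + orig[["x"]]
  cy <- as.vector(rowsum(ij[, 2] - 1, lab_v)) / cnt * pixel_size + orig[["y"]]
  out <- data.frame(cell_id = ids, x = cx, y = cy,
                    nuclear_area = cnt * pixel_size^2)
  a_idx <- if (is.null(annuli)) integer(0) else which(annuli > 0)
  a_lab <- if (length(a_idx)) annuli[a_idx] else integer(0)
  for (ch in names(channel_images)) {
    v <- channel_images[[ch]]
    nm <- as.vector(rowsum(v[idx], lab_v)) / cnt
    out[[paste0("nuclear_mean_", ch)]] <- nm
    am <- rep(NA_real_, length(ids))
    if (length(a_idx)) {
      acnt <- rowsum(rep(1, length(a_idx)), a_lab)
      asum <- rowsum(v[a_idx], a_lab)
      aid <- as.integer(rownames(acnt))
      am[match(aid, ids)] <- as.vector(asum) / as.vector(acnt)
    }
    out[[paste0("annulus_mean_", ch)]] <- am
  }
  out
}

#' Classify marker-positive cells by intensity threshold
#'
#' A cell is positive when its nuclear mean intensity strictly exceeds the
#' threshold; a value exactly at the threshold is negative.
#'
#' @param cells measurement table from \code{\link{measure_cells}} (or any
#'   table with \code{nuclear_mean_<channel>} columns).
#' @param channel channel name.
#' @param threshold intensity threshold, a.u.
#' @return \code{cells} with a logical \code{positive_<channel>} column.
#' @export
classify_positive <- function(cells, channel, threshold) {
  col <- paste0("nuclear_mean_", channel)
  if (!col %in% names(cells)) {
    avail <- sub("^nuclear_mean_", "",
                 grep("^nuclear_mean_", names(cells), value = TRUE))
    stop(sprintf("unknown channel %s; available channels: %s",
                 sQuote(channel), paste(avail, collapse = ", ")),
         call. = FALSE)
  }
  pos <- cells[[col]] > threshold
  cells[[paste0("positive_", channel)]] <- pos
  message(sprintf("classify_positive: %d of %d cells positive for %s (threshold %g)",
                  sum(pos, na.rm = TRUE), nrow(cells), channel, threshold))
  cells
}
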