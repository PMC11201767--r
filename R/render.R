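#' Render a synthetic multi-channel fluorescence image
#'
#' Draws each nucleus as an isotropic Gaussian blob centred on its centroid,
#' with blob sigma proportional to the equivalent nuclear radius
#' (\code{sigma = blob_sigma_factor * sqrt(area/pi)}) and amplitude
#' proportional to the channel intensity (constant for DAPI, so DAPI
#' amplitude carries no marker information). A constant background is added
#' and, optionally, Poisson shot noise is applied pixel-wise.
#'
#' Pixel convention: channel matrices are indexed [x, y]; the pixel at
#' index (i, j) has its centre at physical coordinates
#' \code{origin + (i-1, j-1) * pixel_size} (um).
#'
#' @param cells ground-truth cell table (needs \code{x, y, nuclear_area}
#'   and, for marker channels, \code{i53bp1} / \code{p16_nuclear}).
#' @param geometry a \code{tissue_geometry} (supplies extent and pixel size).
#' @param channels subset of \code{c("DAPI", "53BP1", "p16")}.
#' @param seed seed for the shot noise.
#' @param background constant background level, a.u.
#' @param dapi_amplitude blob amplitude in the DAPI channel, a.u.
#' @param blob_sigma_factor blob sigma as a fraction of the equivalent
#'   nuclear radius.
#' @param noise apply Poisson shot noise?
#' @param margin extra border around the ribbon, um.
#' @param pixel_budget maximum allowed number of pixels per channel.
#' @return an object of class \code{sim_image}: a list with \code{channels}
#'   (named list of matrices), \code{pixel_size} and \code{origin}.
#' @export
render_image <- function(cells, geometry,
                         channels = c("DAPI", "53BP1", "p16"),
                         seed = 1L, background = 10,
                         dapi_amplitude = 100, blob_sigma_factor = 0.5,
                         noise = TRUE, margin = 10, pixel_budget = 2.5e7) {
  stopifnot(inherits(geometry, "tissue_geometry"))
  bad <- setdiff(channels, c("DAPI", "53BP1", "p16"))
  if (length(bad))
    stop("unknown channel(s): ", paste(bad, collapse = ", "), call. = FALSE)
  px <- geometry$pixel_size
  A <- geometry$curvature_amplitude
  x0 <- -margin
  y0 <- -A - margin
  nx <- ceiling((geometry$width + 2 * margin) / px) + 1L
  ny <- ceiling((geometry$depth + 2 * A + 2 * margin) / px) + 1L
  if (as.numeric(nx) * ny > pixel_budget)
    stop(sprintf("size error: raster %d x %d exceeds pixel budget %g",
                 nx, ny, pixel_budget), call. = FALSE)
  amp_for <- function(ch) {
    switch(ch,
           DAPI = rep(dapi_amplitude, nrow(cells)),
           `53BP1` = cells$i53bp1,
           p16 = cells$p16_nuclear)
  }
  imgs <- lapply(channels, function(ch) matrix(0, nx, ny))
  names(imgs) <- channels
  if (nrow(cells)) {
    for (ch in channels) {
      if (is.null(amp_for(ch)))
        stop(sprintf("cells table lacks the intensity column for channel %s",
                     ch), call. = FALSE)
    }
    r_eq <- sqrt(cells$nuclear_area / pi)
    sig_px <- blob_sigma_factor * r_eq / px
    cx <- (cells$x - x0) / px + 1  # fractional pixel index
    cy <- (cells$y - y0) / px + 1
    for (k in seq_len(nrow(cells))) {
      s <- sig_px[k]
      w <- ceiling(4 * s)
      i0 <- max(1L, floor(cx[k]) - w); i1 <- min(nx, floor(cx[k]) + w)
      j0 <- max(1L, floor(cy[k]) - w); j1 <- min(ny, floor(cy[k]) + w)
      if (i0 > i1 || j0 > j1) next
      gx <- exp(-((i0:i1 - cx[k])^2) / (2 * s^2))
      gy <- exp(-((j0:j1 - cy[k])^2) / (2 * s^2))
      blob <- outer(gx, gy)
      for (ch in channels) {
        a <- amp_for(ch)[k]
        imgs[[ch]][i0:i1, j0:j1] <- imgs[[ch]][i0:i1, j0:j1] + a * blob
      }
    }
  }
  set.seed(seed)
  for (ch in channels) {
    lam <- imgs[[ch]] + background
    imgs[[ch]] <- if (noise)
      matrix(stats::rpois(length(lam), lam), nx, ny) else lam
    attr(imgs[[ch]], "pixel_size") <- px
  }
  structure(list(channels = imgs, pixel_size = px, origin = c(x = x0, y = y0)),
            class = "sim_image")
}

#' @export
print.sim_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("Synthetic image: %d x %d px at %g um/px, channels: %s\n",
              d[1], d[2], x$pixel_size,
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Extract one channel as a matrix with pixel-size metadata
#' @param image a \code{sim_image}.
#' @param channel channel name.
#' @return matrix with \code{pixel_size} and \code{origin} attributes.
#' @export
get_channel <- function(image, channel) {
  if (!channel %in% names(image$channels))
    stop(sprintf("unknown channel %s; available: %s", sQuote(channel),
                 paste(names(image$channels), collapse = ", ")),
         call. = FALSE)
  m <- image$channels[[channel]]
  attr(m, "pixel_size") <- image$pixel_size
  attr(m, "origin") <- image$origin
  m
}

#' Write a multi-channel image as TIFF with sidecar metadata
#'
#' Channels are written as pages of one 16-bit TIFF; pixel size, origin,
#' channel names and the intensity scale are written to a JSON sidecar
#' (\code{<path>.json}) so the image round-trips losslessly to the stated
#' quantisation.
#'
#' @param image a \code{sim_image}.
#' @param path output TIFF path.
#' @return \code{path}, invisibly.
#' @export
write_image_tiff <- function(image, path) {
  stopifnot(inherits(image, "sim_image"))
  mx <- max(1, vapply(image$channels, max, 0))
  pages <- lapply(image$channels, function(m) t(m) / mx)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  meta <- list(pixel_size = image$pixel_size,
               origin = as.list(image$origin),
               channels = names(image$channels),
               intensity_scale = mx)
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multi-channel TIFF written by \code{write_image_tiff}
#' @param path TIFF path (expects \code{<path>.json} sidecar).
#' @return a \code{sim_image}.
#' @export
read_image_tiff <- function(path) {
  meta_path <- paste0(path, ".json")
  if (!file.exists(meta_path))
    stop("metadata error: missing sidecar ", meta_path, call. = FALSE)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  chans <- lapply(pages, function(p) {
    m <- t(p) * meta$intensity_scale
    attr(m, "pixel_size") <- meta$pixel_size
    m
  })
  names(chans) <- meta$channels
  structure(list(channels = chans, pixel_size = meta$pixel_size,
                 origin = unlist(meta$origin)),
            class = "sim_image")
}
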