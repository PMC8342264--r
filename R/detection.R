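#' Segment microspheres by green-channel intensity
#'
#' Fluorescent microspheres are far brighter than the ink-darkened tissue
#' background, so a fixed 8-bit threshold on the green channel separates
#' them: pixels with intensity below `low` are background, pixels from `low`
#' up to `high` are microsphere signal. The default band is 140-255 of an
#' 8-bit image, with 140 itself classified as microsphere.
#'
#' @param img Section image (`[y, x]` matrix or `[y, x, 3]` RGB array) with
#'   8-bit intensities; values outside 0-255 raise a bit-depth error rather
#'   than being rescaled silently.
#' @param low,high Inclusive intensity band treated as microsphere signal.
#' @param channel Channel used for RGB input (default `"green"`).
#' @return Binary `[y, x]` mask (integer 0/1) with attribute
#'   `provenance = "automated"`.
#' @export
threshold_microspheres <- function(img, low = 140, high = 255,
                                   channel = "green") {
  rng <- range(img)
  if (rng[1] < 0 || rng[2] > 255) {
    stop("expected an 8-bit image (intensities 0-255); got range [",
         rng[1], ", ", rng[2], "] -- rescale explicitly before thresholding",
         call. = FALSE)
  }
  ch <- section_channel(img, channel)
  mask <- matrix(as.integer(ch >= low & ch <= high), nrow(ch), ncol(ch))
  attr(mask, "provenance") <- "automated"
  mask
}

#' Threshold every section of a stack
#'
#' @param stack A [blockface_stack].
#' @inheritParams threshold_microspheres
#' @return List of binary masks, one per section.
#' @export
threshold_stack <- function(stack, low = 140, high = 255, channel = "green") {
  lapply(stack$sections, threshold_microspheres,
         low = low, high = high, channel = channel)
}

# pixel indices of a filled disk centred at continuous 0-based (x, y);
# always contains at least the pixel under the centre
disk_pixels <- function(x, y, r_px, dim) {
  h <- dim[1]; w <- dim[2]
  cols <- max(1L, floor(x - r_px) + 1L):min(w, ceiling(x + r_px) + 1L)
  rows <- max(1L, floor(y - r_px) + 1L):min(h, ceiling(y + r_px) + 1L)
  cx <- cols - 0.5; cy <- rows - 0.5
  dd <- outer((cy - y)^2, (cx - x)^2, `+`)
  sel <- which(dd <= r_px^2, arr.ind = TRUE)
  out <- cbind(rows[sel[, 1]], cols[sel[, 2]])
  if (nrow(out) == 0L) {
    out <- cbind(min(max(1L, floor(y) + 1L), h), min(max(1L, floor(x) + 1L), w))
  }
  out
}

#' Turn manually clicked points into a segmentation mask
#'
#' Each manually identified microsphere (a single clicked pixel) is dilated
#' to a filled disk matching the physical sphere diameter, so manual and
#' automated masks can run through the identical serial-subtraction path.
#'
#' @param points Data frame or matrix with columns `x`, `y` (continuous
#'   0-based pixel coordinates).
#' @param dim Image dimensions `c(height, width)`.
#' @param pixel_size_um Micrometres per pixel.
#' @param diameter_um Sphere diameter in micrometres (default 20).
#' @return Binary mask with attribute `provenance = "manual"`; each point
#'   becomes a disk of at least one pixel.
#' @export
points_to_mask <- function(points, dim, pixel_size_um, diameter_um = 20) {
  mask <- matrix(0L, dim[1], dim[2])
  attr(mask, "provenance") <- "manual"
  points <- as.data.frame(points)
  if (nrow(points) == 0L) return(mask)
  oob <- points$x < 0 | points$x >= dim[2] | points$y < 0 | points$y >= dim[1]
  if (any(oob)) {
    stop("point(s) out of bounds at index ",
         paste(which(oob), collapse = ", "), call. = FALSE)
  }
  r_px <- diameter_um / pixel_size_um / 2
  for (i in seq_len(nrow(points))) {
    mask[disk_pixels(points$x[i], points$y[i], r_px, dim)] <- 1L
  }
  mask
}

label_components <- function(mask) {
  lab <- EBImage::bwlabel(as_eb(mask))
  t(EBImage::imageData(lab))
}

component_table <- function(lab) {
  n <- max(lab)
  if (n == 0L) {
    return(tibble::tibble(component = integer(0), x = numeric(0),
                          y = numeric(0), area = integer(0)))
  }
  idx <- which(lab > 0, arr.ind = TRUE)
  comp <- lab[idx]
  tibble::tibble(
    component = seq_len(n),
    x = as.numeric(tapply(idx[, 2] - 0.5, comp, mean)),
    y = as.numeric(tapply(idx[, 1] - 0.5, comp, mean)),
    area = as.integer(tabulate(comp, n))
  )
}

#' Resolve each sphere's true section by serial mask subtraction
#'
#' Microspheres are visible through several hundred micrometres of tissue,
#' so the same sphere shows up in consecutive block-face images before it is
#' finally cut away. Subtracting each section's mask from its successor
#' keeps only the *last* image in which a sphere is detected -- its true
#' z-plane. The default mode matches connected components between adjacent
#' sections by centroid distance, which tolerates residual alignment error;
#' `mode = "pixel"` performs the literal pixelwise subtraction
#' `mask[i] & !mask[i + 1]`.
#'
#' @param masks List of aligned binary masks, ordered by section.
#' @param match_radius_px Maximum centroid distance (pixels) for a component
#'   in section `i` to be considered the same sphere as one in `i + 1`
#'   (component mode). A sensible default is one sphere diameter in pixels.
#' @param mode `"component"` (default) or `"pixel"`.
#' @param max_chain_sections Longest run of sections one sphere may span
#'   (visibility depth / section thickness; e.g. 4 for 400 um visibility at
#'   100 um sections). Longer component chains are split from the deep end
#'   with a warning. `NULL` disables splitting.
#' @return List of final binary masks, one per section: section `i` keeps
#'   only components with no match in section `i + 1`; the last section's
#'   mask passes through unchanged.
#' @export
resolve_z_by_serial_subtraction <- function(masks, match_radius_px = 4,
                                            mode = c("component", "pixel"),
                                            max_chain_sections = NULL) {
  mode <- match.arg(mode)
  n <- length(masks)
  if (n == 0L) return(list())
  if (mode == "pixel") {
    out <- vector("list", n)
    for (i in seq_len(n)) {
      out[[i]] <- if (i < n) {
        m <- masks[[i]] * (1L - masks[[i + 1]])
        matrix(as.integer(m), nrow(m), ncol(m))
      } else {
        masks[[i]]
      }
    }
    return(out)
  }

  labs <- lapply(masks, label_components)
  comps <- lapply(labs, component_table)

  # a component survives iff no component of the next section lies within
  # the match radius (the last section always survives); noise can shatter
  # a deep, dim sphere into several fragments, all of which are absorbed by
  # the brighter appearance one section deeper
  keep <- vector("list", n)
  next_match <- vector("list", n)  # nearest next-section component (or NA)
  for (i in seq_len(n)) {
    a <- comps[[i]]
    if (i == n || nrow(a) == 0L) {
      keep[[i]] <- rep(TRUE, nrow(a))
      next_match[[i]] <- rep(NA_integer_, nrow(a))
      next
    }
    b <- comps[[i + 1]]
    if (nrow(b) == 0L) {
      keep[[i]] <- rep(TRUE, nrow(a))
      next_match[[i]] <- rep(NA_integer_, nrow(a))
      next
    }
    dmat <- sqrt(outer(a$x, b$x, `-`)^2 + outer(a$y, b$y, `-`)^2)
    nearest <- apply(dmat, 1, which.min)
    dmin <- dmat[cbind(seq_len(nrow(a)), nearest)]
    keep[[i]] <- dmin > match_radius_px
    next_match[[i]] <- ifelse(dmin > match_radius_px, NA_integer_, nearest)
  }

  # chains (followed along nearest matches) longer than the visibility
  # limit are split from the deep end, each block keeping its deepest
  # component
  if (!is.null(max_chain_sections)) {
    entered <- lapply(comps, function(tb) rep(FALSE, nrow(tb)))
    long_chain <- FALSE
    for (i in seq_len(n)) {
      for (c0 in seq_len(nrow(comps[[i]]))) {
        if (entered[[i]][c0]) next
        s <- i; cc <- c0
        run <- list(c(s, cc))
        entered[[s]][cc] <- TRUE
        while (s < n && !is.na(next_match[[s]][cc])) {
          cc <- next_match[[s]][cc]
          s <- s + 1
          if (entered[[s]][cc]) break
          entered[[s]][cc] <- TRUE
          run[[length(run) + 1L]] <- c(s, cc)
        }
        len <- length(run)
        if (len > max_chain_sections) {
          long_chain <- TRUE
          ends <- rev(seq(len, 1, by = -max_chain_sections))
          for (e in ends) keep[[run[[e]][1]]][run[[e]][2]] <- TRUE
        }
      }
    }
    if (long_chain) {
      warning("component chain(s) longer than max_chain_sections = ",
              max_chain_sections, " were split")
    }
  }
  out <- vector("list", n)
  for (i in seq_len(n)) {
    kept_ids <- which(keep[[i]])
    m <- matrix(0L, nrow(masks[[i]]), ncol(masks[[i]]))
    if (length(kept_ids)) m[labs[[i]] %in% kept_ids] <- 1L
    out[[i]] <- m
  }
  out
}

#' Extract sphere detections from final masks
#'
#' Connected components of each final mask become detections, filtered by a
#' plausible single-sphere area band. Components larger than the band are
#' flagged as merged spheres and split by a watershed on the distance map
#' (each watershed basin becomes its own detection).
#'
#' @param masks List of binary masks (typically the output of
#'   [resolve_z_by_serial_subtraction()]).
#' @param pixel_size_um Micrometres per pixel.
#' @param diameter_um Nominal sphere diameter (default 20 um), used for the
#'   default area band.
#' @param min_area_px,max_area_px Area band in pixels; defaults are 0.25x
#'   and 4x the nominal disk area of one sphere. Set
#'   `min_area_px = 0, max_area_px = Inf` to disable filtering.
#' @return Tibble of detections: `id`, `section_index` (0-based), `x_px`,
#'   `y_px` (0-based centroid), `area_px2`, `equiv_diameter_um`, `merged`.
#' @export
extract_centroids <- function(masks, pixel_size_um, diameter_um = 20,
                              min_area_px = NULL, max_area_px = NULL) {
  nominal <- pi * (diameter_um / pixel_size_um / 2)^2
  min_area_px <- min_area_px %||% max(1, floor(0.25 * nominal))
  max_area_px <- max_area_px %||% ceiling(4 * nominal)
  rows <- list()
  for (i in seq_along(masks)) {
    lab <- label_components(masks[[i]])
    tb <- component_table(lab)
    for (j in seq_len(nrow(tb))) {
      if (tb$area[j] < min_area_px) next
      if (tb$area[j] <= max_area_px) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          section_index = i - 1L, x_px = tb$x[j], y_px = tb$y[j],
          area_px2 = tb$area[j], merged = FALSE)
      } else {
        sub <- matrix(0L, nrow(lab), ncol(lab))
        sub[lab == tb$component[j]] <- 1L
        ws <- EBImage::watershed(EBImage::distmap(as_eb(sub)),
                                 tolerance = 0.5)
        wl <- t(EBImage::imageData(ws))
        wt <- component_table(wl)
        if (nrow(wt) < 2L) wt <- tb[j, , drop = FALSE]
        for (k in seq_len(nrow(wt))) {
          rows[[length(rows) + 1L]] <- tibble::tibble(
            section_index = i - 1L, x_px = wt$x[k], y_px = wt$y[k],
            area_px2 = wt$area[k], merged = TRUE)
        }
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(section_index = integer(0), x_px = numeric(0),
                          y_px = numeric(0), area_px2 = integer(0),
                          merged = logical(0))
  }
  out$equiv_diameter_um <- 2 * sqrt(out$area_px2 / pi) * pixel_size_um
  out$id <- seq_len(nrow(out))
  out[, c("id", "section_index", "x_px", "y_px", "area_px2",
          "equiv_diameter_um", "merged")]
}

#' Compare automated and manual per-section sphere counts
#'
#' @param automated,manual Equal-length vectors of per-section counts.
#' @return A `count_comparison` object: tibble `section_index`, `automated`,
#'   `manual`, `diff` with the totals as attributes; [generics::tidy()]
#'   returns the table, [generics::glance()] the totals.
#' @export
compare_counts <- function(automated, manual) {
  if (length(automated) != length(manual)) {
    stop("count vectors differ in length (", length(automated), " vs ",
         length(manual), ")", call. = FALSE)
  }
  out <- tibble::tibble(
    section_index = seq_along(automated) - 1L,
    automated = as.numeric(automated),
    manual = as.numeric(manual),
    diff = as.numeric(automated) - as.numeric(manual)
  )
  structure(out,
            class = c("count_comparison", class(out)),
            totals = c(automated = sum(out$automated),
                       manual = sum(out$manual)))
}

#' @export
print.count_comparison <- function(x, ...) {
  tot <- attr(x, "totals")
  cat(sprintf("<count_comparison> %d sections; totals: automated %g, manual %g\n",
              nrow(x), tot["automated"], tot["manual"]))
  NextMethod()
}

#' @importFrom generics tidy
#' @export
tidy.count_comparison <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @importFrom generics glance
#' @export
glance.count_comparison <- function(x, ...) {
  tot <- attr(x, "totals")
  tibble::tibble(n_sections = nrow(x),
                 total_automated = unname(tot["automated"]),
                 total_manual = unname(tot["manual"]))
}
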