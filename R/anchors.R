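#' Anchor specifications and section-to-atlas mappings
#'
#' An anchor assigns a linear 2D-to-3D mapping to one section: the atlas
#' coordinate `o = (ox, oy, oz)` of the section image's top-left corner, a
#' vector `u = (ux, uy, uz)` spanning the image width, and a vector
#' `v = (vx, vy, vz)` spanning the image height (the QuickNII convention, in
#' continuous 0-based voxel units). Pixel `(x, y)` of a `W x H` section then
#' maps to `o + (x/W) u + (y/H) v`.
#'
#' @param section_index 0-based section index.
#' @param o,u,v Numeric length-3 vectors.
#' @return A one-row tibble with columns `section_index`,
#'   `ox, oy, oz, ux, uy, uz, vx, vy, vz`.
#' @export
#' @examples
#' anchor_spec(0, o = c(0, 0, 0), u = c(100, 0, 0), v = c(0, 80, 0))
anchor_spec <- function(section_index, o, u, v) {
  stopifnot(length(o) == 3, length(u) == 3, length(v) == 3)
  cr <- c(u[2] * v[3] - u[3] * v[2],
          u[3] * v[1] - u[1] * v[3],
          u[1] * v[2] - u[2] * v[1])
  if (sqrt(sum(cr^2)) <= 0) {
    stop("anchor vectors u and v are parallel", call. = FALSE)
  }
  tibble::tibble(
    section_index = as.integer(section_index),
    ox = o[1], oy = o[2], oz = o[3],
    ux = u[1], uy = u[2], uz = u[3],
    vx = v[1], vy = v[2], vz = v[3]
  )
}

mapping_cols <- c("ox", "oy", "oz", "ux", "uy", "uz", "vx", "vy", "vz")

#' Propagate anchors across an image series
#'
#' Anchoring a handful of sections fixes their atlas mappings; the remaining
#' sections receive mappings by piecewise-linear interpolation of each
#' mapping component (`o`, `u`, `v`) against section index. Outside the
#' anchored range the nearest segment's linear trend is extrapolated. With a
#' single anchor the origin advances along the atlas anterior-posterior axis
#' by one section thickness per section while `u` and `v` stay constant.
#'
#' @param anchors Tibble of anchors (rows as produced by [anchor_spec()]).
#' @param n_sections Number of sections in the series.
#' @param section_thickness_um,voxel_size_um Required only for the
#'   single-anchor case, to convert section spacing into voxels.
#' @param mode `"all"` (default) interpolates `o`, `u` and `v`; `"ap-only"`
#'   interpolates only the origin `o`, holding `u` and `v` at the nearest
#'   anchor's values.
#' @return A tibble with one mapping row per section (`section_index`
#'   0 to `n_sections - 1`); rows at anchored sections equal their anchors.
#' @export
propagate_anchors <- function(anchors, n_sections,
                              section_thickness_um = NULL,
                              voxel_size_um = NULL,
                              mode = c("all", "ap-only")) {
  mode <- match.arg(mode)
  if (is.null(anchors) || nrow(anchors) == 0L) {
    stop("at least one anchor is required", call. = FALSE)
  }
  if (anyDuplicated(anchors$section_index)) {
    stop("duplicate anchor section indices", call. = FALSE)
  }
  if (any(anchors$section_index < 0 | anchors$section_index >= n_sections)) {
    stop("anchor section_index outside the stack", call. = FALSE)
  }
  anchors <- anchors[order(anchors$section_index), , drop = FALSE]
  s <- 0:(n_sections - 1)
  out <- tibble::tibble(section_index = s)

  if (nrow(anchors) == 1L) {
    if (is.null(section_thickness_um) || is.null(voxel_size_um)) {
      stop("single-anchor propagation needs section_thickness_um and voxel_size_um",
           call. = FALSE)
    }
    step <- section_thickness_um / voxel_size_um
    for (cc in mapping_cols) out[[cc]] <- rep(anchors[[cc]], n_sections)
    out$oz <- anchors$oz + (s - anchors$section_index) * step
    return(out)
  }

  xa <- anchors$section_index
  lin_extrap <- function(ya) {
    # piecewise linear between anchors; nearest segment extrapolated outside
    yi <- stats::approx(xa, ya, xout = s, rule = 1)$y
    n <- length(xa)
    lo <- s < xa[1]
    hi <- s > xa[n]
    if (any(lo)) {
      slope <- (ya[2] - ya[1]) / (xa[2] - xa[1])
      yi[lo] <- ya[1] + slope * (s[lo] - xa[1])
    }
    if (any(hi)) {
      slope <- (ya[n] - ya[n - 1]) / (xa[n] - xa[n - 1])
      yi[hi] <- ya[n] + slope * (s[hi] - xa[n])
    }
    yi
  }
  nearest_anchor <- function(ya) {
    i <- vapply(s, function(si) which.min(abs(xa - si)), integer(1))
    ya[i]
  }
  for (cc in mapping_cols) {
    out[[cc]] <- if (mode == "ap-only" && !startsWith(cc, "o")) {
      nearest_anchor(anchors[[cc]])
    } else {
      lin_extrap(anchors[[cc]])
    }
  }
  out
}

#' Map section pixels to atlas coordinates
#'
#' Applies the linear anchoring model `p = o + (x/W) u + (y/H) v`. Pixel
#' coordinates follow the pixel-corner convention: `x` in `[0, W)`, `y` in
#' `[0, H)`, with the top-left corner of the image at `o` exactly.
#'
#' @param mapping A one-row mapping (from [propagate_anchors()]) or a tibble
#'   with one row per point.
#' @param x_px,y_px Pixel coordinates (vectors).
#' @param width,height Section image size in pixels.
#' @return Tibble with columns `ax`, `ay`, `az` (continuous voxel coords).
#' @export
pixel_to_atlas <- function(mapping, x_px, y_px, width, height) {
  n <- max(length(x_px), length(y_px))
  x_px <- rep_len(x_px, n); y_px <- rep_len(y_px, n)
  if (any(x_px < 0 | x_px >= width | y_px < 0 | y_px >= height, na.rm = TRUE)) {
    stop("pixel coordinates outside the image", call. = FALSE)
  }
  if (nrow(mapping) == 1L) mapping <- mapping[rep(1L, n), , drop = FALSE]
  stopifnot(nrow(mapping) == n)
  fx <- x_px / width
  fy <- y_px / height
  tibble::tibble(
    ax = mapping$ox + fx * mapping$ux + fy * mapping$vx,
    ay = mapping$oy + fx * mapping$uy + fy * mapping$vy,
    az = mapping$oz + fx * mapping$uz + fy * mapping$vz
  )
}

#' Anchor / midline JSON round trip
#'
#' Anchors are stored as a JSON array of objects with `section_index` and the
#' nine mapping fields; midlines as an array of
#' `{section_index, points: [{x, y}, ...]}`.
#'
#' @param path File path.
#' @return [read_anchors_json()] returns an anchor tibble;
#'   [read_midlines_json()] a named list of per-section polyline data frames.
#' @export
read_anchors_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  tibble::as_tibble(x)[, c("section_index", mapping_cols)]
}

#' @rdname read_anchors_json
#' @param anchors Anchor tibble.
#' @export
write_anchors_json <- function(anchors, path) {
  jsonlite::write_json(anchors, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname read_anchors_json
#' @export
read_midlines_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  out <- list()
  for (m in x) {
    pts <- dplyr::bind_rows(lapply(m$points, function(p) {
      tibble::tibble(x = p$x, y = p$y)
    }))
    out[[as.character(m$section_index)]] <- pts
  }
  out
}

#' @rdname read_anchors_json
#' @param midlines Named list of per-section polylines (names = 0-based
#'   section indices; each element a data frame with `x`, `y`).
#' @export
write_midlines_json <- function(midlines, path) {
  recs <- purrr::imap(midlines, function(pts, idx) {
    list(section_index = as.integer(idx),
         points = purrr::map2(pts$x, pts$y, function(x, y) list(x = x, y = y)))
  })
  jsonlite::write_json(unname(recs), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Assign detections to hemispheres from midline delineations
#'
#' The midline of each section is delineated as a polyline running from the
#' top to the bottom of the image. A detection left of the polyline (at the
#' detection's own `y`) is in the left hemisphere, right of it -- or exactly
#' on it, by convention -- in the right. Sections without a delineation
#' inherit the polyline of the nearest delineated section. With no midline
#' anywhere, every detection is `"unassigned"`.
#'
#' @param midlines Named list of polylines as in [read_midlines_json()].
#' @param detections Data frame with `section_index`, `x_px`, `y_px`.
#' @return Character vector `"left"` / `"right"` / `"unassigned"`.
#' @export
assign_hemisphere <- function(midlines, detections) {
  n <- nrow(detections)
  if (is.null(midlines) || length(midlines) == 0L) {
    return(rep("unassigned", n))
  }
  secs <- as.integer(names(midlines))
  line_x_at <- function(pts, y) {
    if (nrow(pts) == 1L) return(pts$x)
    ord <- order(pts$y)
    stats::approx(pts$y[ord], pts$x[ord], xout = y, rule = 2)$y
  }
  vapply(seq_len(n), function(i) {
    si <- detections$section_index[i]
    use <- secs[which.min(abs(secs - si))]
    mx <- line_x_at(midlines[[as.character(use)]], detections$y_px[i])
    if (detections$x_px[i] < mx) "left" else "right"
  }, character(1))
}
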