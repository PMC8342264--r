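#' Serial block-face image stack
#'
#' An ordered series of coronal block-face images photographed from the cut
#' surface of the tissue block before each vibratome section, together with
#' the physical calibration needed to convert pixels and sections to
#' micrometres. Sections are ordered anterior-first in cutting sequence
#' (0-based indices throughout). Each section is a `[height, width]` matrix
#' or `[height, width, 3]` RGB array of 8-bit intensities (0-255).
#'
#' @param sections List of section images, all with identical dimensions.
#' @param pixel_size_um In-plane calibration, micrometres per pixel.
#' @param section_thickness_um Vibratome section thickness in micrometres
#'   (this is also the z-resolution of any sphere localization).
#' @return A `blockface_stack` object.
#' @export
blockface_stack <- function(sections, pixel_size_um, section_thickness_um) {
  stopifnot(is.list(sections), length(sections) >= 1L)
  check_positive_scalar(pixel_size_um, "pixel_size_um")
  check_positive_scalar(section_thickness_um, "section_thickness_um")
  dims <- lapply(sections, function(s) dim(s)[1:2])
  if (length(unique(lapply(dims, as.integer))) != 1L) {
    stop("sections have mixed dimensions", call. = FALSE)
  }
  structure(
    list(sections = sections,
         pixel_size_um = pixel_size_um,
         section_thickness_um = section_thickness_um),
    class = "blockface_stack"
  )
}

#' @export
print.blockface_stack <- function(x, ...) {
  d <- section_dim(x$sections[[1]])
  cat(sprintf(
    "<blockface_stack> %d sections, %d x %d px @ %g um/px, %g um thick\n",
    length(x$sections), d["width"], d["height"],
    x$pixel_size_um, x$section_thickness_um))
  invisible(x)
}

#' @export
length.blockface_stack <- function(x) length(x$sections)

read_one_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- tryCatch(
    switch(ext,
      png = png::readPNG(path),
      tif = ,
      tiff = tiff::readTIFF(path),
      stop("unsupported image format: ", ext)
    ),
    error = function(e) {
      stop(sprintf("cannot read image '%s': %s", path, conditionMessage(e)),
           call. = FALSE)
    }
  )
  if (length(dim(img)) == 3L && dim(img)[3] > 3L) img <- img[, , 1:3]
  round(img * 255)
}

#' Read a serial image series into a stack
#'
#' Files are read in the order given (sort them beforehand if needed, e.g.
#' with a natural sort of the acquisition numbering).
#'
#' @param paths Character vector of PNG/TIFF paths, anterior first.
#' @inheritParams blockface_stack
#' @return A [blockface_stack].
#' @export
read_image_series <- function(paths, pixel_size_um, section_thickness_um) {
  stopifnot(length(paths) >= 1L)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("file(s) not found: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  sections <- lapply(paths, read_one_image)
  blockface_stack(sections, pixel_size_um, section_thickness_um)
}

#' Write a stack as a PNG series
#'
#' @param stack A [blockface_stack].
#' @param dir Output directory (created if absent).
#' @param prefix File-name prefix; files are `prefix_0000.png`, ...
#' @return Character vector of written paths, invisibly.
#' @export
write_image_series <- function(stack, dir, prefix = "section") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, sprintf("%s_%04d.png", prefix,
                                  seq_along(stack$sections) - 1L))
  for (i in seq_along(stack$sections)) {
    png::writePNG(pmin(pmax(stack$sections[[i]], 0), 255) / 255, paths[i])
  }
  invisible(paths)
}

# ---- rigid 2D transforms ----------------------------------------------------

#' Rigid 2D transforms
#'
#' A rigid transform rotates image content by `rotation_deg` about the image
#' centre and then translates it by `(dx, dy)` pixels. Positive angles follow
#' the convention `(x, y) -> (x cos t - y sin t, x sin t + y cos t)` in pixel
#' coordinates (x right, y down).
#'
#' @param rotation_deg Rotation in degrees.
#' @param dx,dy Translation in pixels.
#' @return A one-row tibble (`rotation_deg`, `dx`, `dy`).
#' @export
rigid_transform <- function(rotation_deg = 0, dx = 0, dy = 0) {
  tibble::tibble(rotation_deg = rotation_deg, dx = dx, dy = dy)
}

rot_mat <- function(deg) {
  t <- deg * pi / 180
  matrix(c(cos(t), sin(t), -sin(t), cos(t)), 2, 2)
}

#' @rdname rigid_transform
#' @param tf,first,second Rigid transforms (one-row tibbles).
#' @export
invert_rigid <- function(tf) {
  Rinv <- rot_mat(-tf$rotation_deg)
  t2 <- -Rinv %*% c(tf$dx, tf$dy)
  rigid_transform(-tf$rotation_deg, t2[1], t2[2])
}

#' @rdname rigid_transform
#' @export
compose_rigid <- function(first, second) {
  # transform equivalent to applying `first`, then `second`
  R2 <- rot_mat(second$rotation_deg)
  t12 <- R2 %*% c(first$dx, first$dy) + c(second$dx, second$dy)
  rigid_transform(first$rotation_deg + second$rotation_deg, t12[1], t12[2])
}

#' Apply a rigid transform to a section image
#'
#' @param img Section image (`[y, x]` matrix or `[y, x, 3]` array).
#' @param tf A [rigid_transform()].
#' @param filter `"bilinear"` for intensity images, `"nearest"` for binary
#'   masks (keeps masks binary).
#' @return Transformed image with unchanged dimensions; exposed canvas is
#'   filled with 0 (black).
#' @export
apply_rigid_transform <- function(img, tf, filter = c("bilinear", "nearest")) {
  filter <- match.arg(filter)
  ebf <- if (filter == "bilinear") "bilinear" else "none"
  one <- function(mat) {
    e <- as_eb(mat)
    if (tf$rotation_deg != 0) {
      e <- EBImage::rotate(e, tf$rotation_deg, filter = ebf,
                           output.dim = dim(e), bg.col = 0)
    }
    if (tf$dx != 0 || tf$dy != 0) {
      e <- EBImage::translate(e, c(tf$dx, tf$dy), filter = ebf, bg.col = 0)
    }
    from_eb(e)
  }
  if (length(dim(img)) == 3L) {
    out <- img
    for (k in 1:3) out[, , k] <- one(img[, , k])
    out
  } else {
    one(img)
  }
}

#' Transform pixel coordinates the way [apply_rigid_transform()] moves pixels
#'
#' @param xy Two-column matrix/data frame of pixel coordinates.
#' @inheritParams apply_rigid_transform
#' @param dim_in,dim_out Image dimensions `c(height, width)` before and after
#'   (equal unless the canvas was expanded, e.g. by midline rotation).
#' @return Matrix of transformed coordinates.
#' @export
transform_points <- function(xy, tf, dim_in, dim_out = dim_in) {
  xy <- as.matrix(xy)
  cin <- c(dim_in[2] / 2, dim_in[1] / 2)
  cout <- c(dim_out[2] / 2, dim_out[1] / 2)
  R <- rot_mat(tf$rotation_deg)
  sweep(t(R %*% t(sweep(xy, 2, cin))), 2,
        cout + c(tf$dx, tf$dy), `+`)
}

# ---- midline rotation -------------------------------------------------------

#' Rotate a whole stack so a drawn midline becomes vertical
#'
#' The user draws a line down the brain midline on one section; a single
#' rotation angle is computed that makes this line vertical and is applied to
#' every section of the stack. The canvas is expanded so that no content is
#' clipped (exposed canvas is black, consistent with the dark-background
#' embedding of the block). If atlas anchors are used downstream they must be
#' specified on the rotated images.
#'
#' @param stack A [blockface_stack].
#' @param midline Two distinct points on the midline: a 2x2 matrix or data
#'   frame with columns `x`, `y` (pixel coordinates).
#' @return A list with `stack` (rotated, possibly larger canvas),
#'   `rotation_deg` (the single angle applied to all sections), and
#'   `transform_xy(xy)`, a function mapping original pixel coordinates into
#'   the rotated canvas.
#' @export
rotate_stack_by_midline <- function(stack, midline) {
  midline <- as.matrix(as.data.frame(midline)[, c("x", "y")])
  if (nrow(midline) != 2L || all(midline[1, ] == midline[2, ])) {
    stop("midline must be two distinct points", call. = FALSE)
  }
  d <- midline[2, ] - midline[1, ]
  angle <- unname(atan2(d[1], d[2]) * 180 / pi)  # line's angle from vertical
  # rotating content by `angle` zeroes the x-component of the line direction
  dim_in <- dim(stack$sections[[1]])[1:2]
  rotated <- lapply(stack$sections, function(img) {
    one <- function(mat) from_eb(EBImage::rotate(as_eb(mat), angle,
                                                 filter = "bilinear",
                                                 bg.col = 0))
    if (length(dim(img)) == 3L) {
      ch <- lapply(1:3, function(k) one(img[, , k]))
      array(c(ch[[1]], ch[[2]], ch[[3]]), dim = c(dim(ch[[1]]), 3))
    } else {
      one(img)
    }
  })
  dim_out <- dim(rotated[[1]])[1:2]
  out <- blockface_stack(rotated, stack$pixel_size_um,
                         stack$section_thickness_um)
  tf <- rigid_transform(angle, 0, 0)
  list(
    stack = out,
    rotation_deg = angle,
    transform_xy = function(xy) transform_points(xy, tf, dim_in, dim_out)
  )
}

# ---- rigid stack alignment --------------------------------------------------

to_gray <- function(img) {
  if (length(dim(img)) == 3L) pmax(img[, , 1], img[, , 2], img[, , 3]) else img
}

# Phase correlation between two equal-size matrices. Returns the translation
# (dx, dy) that moves `moving` onto `fixed`, with subpixel parabola
# refinement, plus the correlation peak height as a match score.
phase_correlate <- function(fixed, moving) {
  F1 <- stats::fft(fixed)
  F2 <- stats::fft(moving)
  R <- F1 * Conj(F2)
  R <- R / (Mod(R) + 1e-12)
  r <- Re(stats::fft(R, inverse = TRUE)) / length(R)
  p <- which(r == max(r), arr.ind = TRUE)[1, ]
  n <- dim(r)
  refine <- function(axis) {
    i <- p[axis]
    im <- if (i == 1) n[axis] else i - 1
    ip <- if (i == n[axis]) 1 else i + 1
    idx <- function(j) if (axis == 1) r[j, p[2]] else r[p[1], j]
    denom <- idx(im) - 2 * idx(i) + idx(ip)
    if (denom >= 0) 0 else (idx(im) - idx(ip)) / (2 * denom)
  }
  shift <- c(p[1] - 1 + refine(1), p[2] - 1 + refine(2))
  shift <- ifelse(shift > n / 2, shift - n, shift)
  list(dy = shift[1], dx = shift[2], score = max(r))
}

register_pair <- function(fixed, moving, max_rotation_deg = 5) {
  score_at <- function(theta) {
    m <- if (theta == 0) moving else {
      from_eb(EBImage::rotate(as_eb(moving), theta, filter = "bilinear",
                              output.dim = dim(as_eb(moving)), bg.col = 0))
    }
    pc <- phase_correlate(fixed, m)
    pc$theta <- theta
    pc
  }
  if (max_rotation_deg <= 0) {
    best <- score_at(0)
  } else {
    grid <- seq(-max_rotation_deg, max_rotation_deg, by = 0.5)
    coarse <- lapply(grid, score_at)
    i <- which.max(vapply(coarse, `[[`, numeric(1), "score"))
    lo <- max(-max_rotation_deg, grid[i] - 0.5)
    hi <- min(max_rotation_deg, grid[i] + 0.5)
    opt <- stats::optimize(function(t) score_at(t)$score, c(lo, hi),
                           maximum = TRUE, tol = 0.02)
    best <- score_at(opt$maximum)
    if (coarse[[i]]$score > best$score) best <- coarse[[i]]
  }
  rigid_transform(best$theta, best$dx, best$dy)
}

#' Rigidly align a block-face stack
#'
#' Registers each section to its predecessor under a rigid-body model
#' (rotation + translation, no scaling or shear) by maximizing the image
#' cross-correlation: the translation is found by phase correlation and the
#' rotation by bounded search over candidate angles. Pairwise transforms are
#' chained so every section is expressed in the frame of a single reference
#' section (the middle one by default, which halves drift accumulation).
#'
#' @param stack A [blockface_stack].
#' @param reference 0-based reference section index (default: middle).
#' @param max_rotation_deg Rotation search bound in degrees; set 0 for
#'   translation-only alignment.
#' @return List with `stack` (aligned) and `transforms`, a tibble with one
#'   [rigid_transform()] row per section mapping it into the reference frame.
#'   All-black sections get an identity transform with a warning.
#' @export
rigid_align_stack <- function(stack, reference = NULL, max_rotation_deg = 5) {
  n <- length(stack$sections)
  if (n < 2L) stop("alignment needs at least two sections", call. = FALSE)
  if (is.null(reference)) reference <- (n - 1L) %/% 2L
  stopifnot(reference >= 0, reference < n)
  g <- lapply(stack$sections, to_gray)
  blank <- vapply(g, function(m) max(m) == 0, logical(1))
  if (any(blank)) {
    warning("all-black section(s) at index ",
            paste(which(blank) - 1L, collapse = ", "),
            "; identity transform used")
  }
  idtf <- rigid_transform()
  pair <- vector("list", n)  # pair[[i]] maps section i-1 (0-based) onto i-2
  for (i in 2:n) {
    pair[[i]] <- if (blank[i] || blank[i - 1]) idtf else
      register_pair(g[[i - 1]], g[[i]], max_rotation_deg)
  }
  chain <- vector("list", n)
  r <- reference + 1L
  chain[[r]] <- idtf
  if (r < n) for (i in (r + 1L):n) {
    chain[[i]] <- compose_rigid(pair[[i]], chain[[i - 1]])
  }
  if (r > 1L) for (i in (r - 1L):1L) {
    chain[[i]] <- compose_rigid(invert_rigid(pair[[i + 1]]), chain[[i + 1]])
  }
  transforms <- dplyr::bind_rows(chain)
  transforms$section_index <- 0:(n - 1)
  transforms <- transforms[, c("section_index", "rotation_deg", "dx", "dy")]
  aligned <- lapply(seq_len(n), function(i) {
    apply_rigid_transform(stack$sections[[i]], chain[[i]], "bilinear")
  })
  list(
    stack = blockface_stack(aligned, stack$pixel_size_um,
                            stack$section_thickness_um),
    transforms = transforms
  )
}

#' Write / read alignment transforms as JSON
#'
#' @param transforms Tibble from [rigid_align_stack()].
#' @param path File path.
#' @export
write_transforms_json <- function(transforms, path) {
  jsonlite::write_json(transforms, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transforms_json
#' @export
read_transforms_json <- function(path) {
  tibble::as_tibble(jsonlite::read_json(path, simplifyVector = TRUE))
}

# ---- brain volume -----------------------------------------------------------

#' Whole-brain volume from foreground areas
#'
#' The embedding (India-ink agarose or surface ink) makes the background
#' black by design, so brain tissue is simply everything brighter than a
#' small threshold. The volume is the summed foreground area of all
#' sections multiplied by the section thickness.
#'
#' @param stack A [blockface_stack].
#' @param foreground_threshold Intensity (of 255) above which a pixel counts
#'   as tissue, evaluated on the per-pixel maximum over channels; default 15.
#' @return Brain volume in mm^3.
#' @export
compute_brain_volume <- function(stack, foreground_threshold = 15) {
  px_area_um2 <- stack$pixel_size_um^2
  n_fg <- vapply(stack$sections, function(img) {
    sum(to_gray(img) > foreground_threshold)
  }, numeric(1))
  sum(n_fg) * px_area_um2 * stack$section_thickness_um * 1e-9
}
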