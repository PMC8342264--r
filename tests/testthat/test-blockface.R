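make_brain_section <- function(h = 120, w = 160, seed = 1, rgb = FALSE) {
  set.seed(seed)
  yy <- matrix(seq_len(h) - 0.5, h, w)
  xx <- matrix(rep(seq_len(w) - 0.5, each = h), h, w)
  ell <- ((xx - w / 2) / (0.38 * w))^2 + ((yy - h / 2) / (0.38 * h))^2 <= 1
  img <- matrix(0, h, w)
  img[ell] <- 40 + 20 * sin(xx[ell] / 9) * cos(yy[ell] / 7)  # some texture
  img <- pmax(img, 0)
  if (!rgb) return(img)
  array(rep(img, 3), dim = c(h, w, 3))
}

test_that("stack construction validates dimensions and calibration", {
  s <- list(matrix(0, 10, 12), matrix(0, 10, 12))
  st <- blockface_stack(s, 6.5, 100)
  expect_s3_class(st, "blockface_stack")
  expect_length(st, 2L)
  expect_error(blockface_stack(list(matrix(0, 10, 12), matrix(0, 11, 12)),
                               6.5, 100),
               "mixed dimensions")
  expect_error(blockface_stack(s, -1, 100), "pixel_size_um")
  expect_error(blockface_stack(s, 6.5, 0), "section_thickness_um")
})

test_that("an image series round-trips through PNG files with metadata", {
  dir <- withr::local_tempdir()
  st0 <- blockface_stack(
    lapply(1:5, function(i) {
      m <- matrix(0, 20, 30)
      m[5 + i, 10] <- 200
      m
    }), 6.5, 100)
  paths <- write_image_series(st0, dir)
  st <- read_image_series(paths, pixel_size_um = 6.5,
                          section_thickness_um = 100)
  expect_length(st, 5L)
  expect_equal(st$pixel_size_um, 6.5)
  expect_equal(st$section_thickness_um, 100)
  expect_equal(st$sections, st0$sections, ignore_attr = TRUE)
  expect_error(read_image_series(c(paths, "no-such-file.png"), 6.5, 100),
               "no-such-file")
  # mixed dimensions refuse to stack
  png::writePNG(matrix(0, 21, 30), file.path(dir, "odd.png"))
  expect_error(read_image_series(c(paths[1], file.path(dir, "odd.png")),
                                 6.5, 100),
               "mixed dimensions")
})

test_that("rigid transforms compose and invert to identity", {
  for (tf in list(rigid_transform(13, 4.5, -2.25),
                  rigid_transform(-91, -10, 3),
                  rigid_transform(0.01, 0, 0))) {
    id <- compose_rigid(tf, invert_rigid(tf))
    expect_lt(abs(id$rotation_deg), 1e-9)
    expect_lt(abs(id$dx), 1e-9)
    expect_lt(abs(id$dy), 1e-9)
  }
})

test_that("midline rotation makes the drawn line vertical on all sections", {
  img <- make_brain_section()
  st <- blockface_stack(list(img, img, img), 6.5, 100)

  # already vertical -> identity
  res0 <- rotate_stack_by_midline(st, data.frame(x = c(80, 80),
                                                 y = c(10, 110)))
  expect_equal(res0$rotation_deg, 0)
  expect_equal(dim(res0$stack$sections[[1]]), dim(img))

  # 10 degrees off vertical -> endpoints share x after rotation
  ang <- 10 * pi / 180
  ml <- data.frame(x = c(80, 80 + sin(ang) * 50), y = c(30, 30 + cos(ang) * 50))
  res <- rotate_stack_by_midline(st, ml)
  expect_equal(abs(res$rotation_deg), 10, tolerance = 1e-6)
  pts <- res$transform_xy(as.matrix(ml))
  expect_lt(abs(pts[1, 1] - pts[2, 1]), 0.5)
  # one angle applied to every section: all rotated sections identical here
  expect_equal(res$stack$sections[[1]], res$stack$sections[[3]])
  # canvas expanded, nothing clipped: total intensity preserved within
  # interpolation loss
  expect_gt(sum(res$stack$sections[[1]]) / sum(img), 0.98)

  expect_error(rotate_stack_by_midline(st, data.frame(x = c(5, 5),
                                                      y = c(9, 9))),
               "distinct")
})

test_that("rigid alignment recovers known shifts and rotations", {
  img <- make_brain_section(h = 140, w = 180, seed = 3)

  ident <- rigid_align_stack(blockface_stack(list(img, img, img), 6.5, 100))
  expect_true(all(abs(ident$transforms$dx) < 0.1))
  expect_true(all(abs(ident$transforms$dy) < 0.1))
  expect_true(all(abs(ident$transforms$rotation_deg) < 0.1))

  cases <- list(
    rigid_transform(0, 7, -3),
    rigid_transform(2, 0, 0),
    rigid_transform(-1.4, 3.5, 2.25)
  )
  for (tf in cases) {
    moved <- apply_rigid_transform(img, tf, "bilinear")
    al <- rigid_align_stack(blockface_stack(list(img, moved), 6.5, 100),
                            reference = 0)
    rec <- al$transforms[2, ]
    inv <- invert_rigid(tf)
    expect_lt(abs(rec$rotation_deg - inv$rotation_deg), 0.2)
    expect_lt(abs(rec$dx - inv$dx), 0.5)
    expect_lt(abs(rec$dy - inv$dy), 0.5)
  }

  # all-black section warns and gets identity
  blk <- matrix(0, 140, 180)
  expect_warning(
    al <- rigid_align_stack(blockface_stack(list(img, blk), 6.5, 100),
                            reference = 0),
    "all-black")
  expect_equal(al$transforms$dx[2], 0)
})

test_that("alignment transforms chain through a perturbed series", {
  img <- make_brain_section(h = 140, w = 180, seed = 4)
  true_tf <- list(rigid_transform(0, -3, 2), rigid_transform(0, 0, 0),
                  rigid_transform(0, 4, 1), rigid_transform(0, -2, -5))
  sections <- lapply(true_tf, function(tf) {
    apply_rigid_transform(img, tf, "bilinear")
  })
  al <- rigid_align_stack(blockface_stack(sections, 6.5, 100),
                          max_rotation_deg = 0)
  ref <- 1L  # middle of 4 sections, 0-based
  for (i in seq_along(true_tf)) {
    # aligning section i into the reference frame should recover
    # jitter_ref - jitter_i
    expect_lt(abs(al$transforms$dx[i] -
                    (true_tf[[ref + 1]]$dx - true_tf[[i]]$dx)), 0.5)
    expect_lt(abs(al$transforms$dy[i] -
                    (true_tf[[ref + 1]]$dy - true_tf[[i]]$dy)), 0.5)
  }
  tj <- withr::local_tempfile(fileext = ".json")
  write_transforms_json(al$transforms, tj)
  expect_equal(as.data.frame(read_transforms_json(tj)),
               as.data.frame(al$transforms))
})

test_that("rigid motion preserves foreground component counts", {
  # nearest-neighbour resampling of a mask keeps it binary and keeps the
  # number of connected components
  mask <- matrix(0L, 100, 100)
  for (p in list(c(20, 20), c(50, 70), c(80, 35))) {
    mask[disk_pixels_for_test(p[1], p[2], 4, c(100, 100))] <- 1L
  }
  n0 <- max(EBImage::bwlabel(t(mask)))
  moved <- apply_rigid_transform(mask, rigid_transform(7, 3, -2), "nearest")
  expect_true(all(moved %in% c(0, 1)))
  expect_equal(max(EBImage::bwlabel(t(moved))), n0)
})

test_that("brain volume follows area x thickness arithmetic", {
  # 1e6 foreground pixels at 6.5 um/px and 100 um thickness -> 4.225 mm^3
  big <- matrix(255, 1000, 1000)
  st <- blockface_stack(list(big), 6.5, 100)
  expect_equal(compute_brain_volume(st), 1e6 * 6.5^2 * 100 * 1e-9)
  expect_equal(compute_brain_volume(st), 4.225)

  # all-black -> 0
  st0 <- blockface_stack(list(matrix(0, 50, 50)), 6.5, 100)
  expect_equal(compute_brain_volume(st0), 0)

  # duplicating every section doubles the volume
  img <- make_brain_section()
  v1 <- compute_brain_volume(blockface_stack(list(img), 6.5, 100))
  v2 <- compute_brain_volume(blockface_stack(list(img, img), 6.5, 100))
  expect_equal(v2, 2 * v1)

  # volume is invariant under rigid motion (within interpolation effects)
  moved <- apply_rigid_transform(img, rigid_transform(5, 4, -3), "bilinear")
  vm <- compute_brain_volume(blockface_stack(list(moved), 6.5, 100))
  expect_lt(abs(vm - v1) / v1, 0.01)
})
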