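#' Generate a toy hierarchical atlas
#'
#' Builds a small stand-in for a reference brain atlas: an ellipsoidal
#' "brain" inside a 3D label volume, recursively partitioned into nested
#' axis-aligned regions that form a rooted ontology. Level 1 is the root;
#' level 2 splits the brain into gray matter, fiber tracts and ventricular
#' systems; deeper levels subdivide each region along alternating axes.
#' Children exactly partition their parent, so region volumes are additive
#' up the tree. Some branches terminate before `depth` (the first
#' ventricular subregion always does, and others stop at random), so that
#' level-wise queries exercise the "not at this level" state.
#'
#' @param depth Deepest ontology level to generate (>= 3).
#' @param branching Number of children per subdivided region (>= 2).
#' @param dim Label volume dimensions `c(nx, ny, nz)`; the third axis is
#'   anterior-posterior.
#' @param voxel_size_um Isotropic voxel size in micrometres.
#' @param seed Random seed fixing the early-termination pattern.
#' @param p_early_stop Probability that an internal region at level >= 3
#'   stops subdividing before `depth`.
#' @param section_step Number of voxels per coronal section along the
#'   anterior-posterior axis; the brain outline is held constant within
#'   each such slab, as in a volume reconstructed from serial sections
#'   (default 4, i.e. 100-um sections at 25-um voxels).
#' @return List with `ontology` (an [atlas_ontology]) and `annotation` (an
#'   [annotation_volume] whose labels are the ontology's leaf regions).
#' @export
generate_toy_atlas <- function(depth = 7, branching = 2,
                               dim = c(96, 80, 96), voxel_size_um = 25,
                               seed = 1, p_early_stop = 0.15,
                               section_step = 4) {
  stopifnot(depth >= 3, branching >= 2, length(dim) == 3)
  set.seed(seed)

  # ellipsoidal brain mask; along the cutting axis the outline is evaluated
  # at slab centres so each section sees one constant cross-section
  ctr <- dim / 2
  ax <- 0.45 * dim
  g <- expand.grid(x = seq_len(dim[1]), y = seq_len(dim[2]),
                   z = seq_len(dim[3]))
  slab_centre <- floor((g$z - 1) / section_step) * section_step +
    section_step / 2
  inside <- ((g$x - 0.5 - ctr[1]) / ax[1])^2 +
    ((g$y - 0.5 - ctr[2]) / ax[2])^2 +
    ((slab_centre - ctr[3]) / ax[3])^2 <= 1
  brain <- array(inside, dim = dim)

  labels <- array(0L, dim = dim)
  nodes <- list()
  next_id <- 0L
  new_node <- function(name, parent_id) {
    next_id <<- next_id + 1L
    if (is.null(name)) name <- sprintf("region %d", next_id)
    nodes[[next_id]] <<- tibble::tibble(id = next_id, name = name,
                                        parent_id = parent_id)
    next_id
  }
  set_label <- function(id, box) {
    sub <- brain[box$x[1]:box$x[2], box$y[1]:box$y[2], box$z[1]:box$z[2]]
    cur <- labels[box$x[1]:box$x[2], box$y[1]:box$y[2], box$z[1]:box$z[2]]
    cur[sub] <- id
    labels[box$x[1]:box$x[2], box$y[1]:box$y[2], box$z[1]:box$z[2]] <<- cur
  }
  split_box <- function(box, axis, k) {
    nm <- c("x", "y", "z")[axis]
    lo <- box[[nm]][1]; hi <- box[[nm]][2]
    cuts <- floor(seq(lo - 1, hi, length.out = k + 1))
    lapply(seq_len(k), function(j) {
      b <- box
      b[[nm]] <- c(cuts[j] + 1, cuts[j + 1])
      b
    })
  }
  # recursive subdivision; axis cycles x, y, z with the region's level
  subdivide <- function(id, box, level, force_leaf = FALSE) {
    axis <- (level %% 3) + 1L
    nm <- c("x", "y", "z")[axis]
    can_split <- (box[[nm]][2] - box[[nm]][1] + 1) >= branching
    if (level >= depth || force_leaf ||
        (level >= 3 && stats::runif(1) < p_early_stop)) {
      set_label(id, box)
      return(invisible(NULL))
    }
    if (!can_split) {
      stop("volume too small to nest depth ", depth,
           " with branching ", branching, call. = FALSE)
    }
    kids <- split_box(box, axis, branching)
    for (b in kids) {
      cid <- new_node(NULL, id)
      subdivide(cid, b, level + 1)
    }
  }

  root <- new_node("root", NA_integer_)
  full <- list(x = c(1, dim[1]), y = c(1, dim[2]), z = c(1, dim[3]))
  # level 2: coarse anterior-posterior slabs of the brain
  slabs <- split_box(full, 3L, 3L)
  l2names <- c("gray matter", "fiber tracts", "ventricular systems")
  for (j in 1:3) {
    cid <- new_node(l2names[j], root)
    if (j == 3) {
      # ventricular systems: two subregions, the first always terminates
      # early (shallow branch, exercising "not at this level")
      vkids <- split_box(slabs[[j]], 1L, 2L)
      c1 <- new_node("ventricle A", cid)
      subdivide(c1, vkids[[1]], 3, force_leaf = TRUE)
      c2 <- new_node("ventricle B", cid)
      subdivide(c2, vkids[[2]], 3)
    } else {
      kids <- split_box(slabs[[j]], (2L %% 3) + 1L, branching)
      for (b in kids) {
        cid2 <- new_node(NULL, cid)
        subdivide(cid2, b, 3)
      }
    }
  }

  ontology <- atlas_ontology(dplyr::bind_rows(nodes))
  list(ontology = ontology,
       annotation = annotation_volume(labels, voxel_size_um))
}

#' Place microspheres in a toy atlas
#'
#' Samples ground-truth sphere positions inside labelled voxels. Placement
#' is uniform over brain voxels by default, or weighted per region, so
#' expected per-region counts are proportional to weight times volume.
#' Sphere centres are jittered inside the central part of their voxel
#' (keeping a margin from voxel faces) and a minimum in-plane separation is
#' enforced between spheres that are close along the cutting axis, mimicking
#' the sparse, non-overlapping way 20-um beads lodge in the vasculature.
#'
#' @param atlas Output of [generate_toy_atlas()] (list with `ontology`,
#'   `annotation`).
#' @param n_spheres Number of spheres (default 2000, a typical injected
#'   bolus).
#' @param weights Optional named numeric vector of per-region weights (names
#'   are ontology ids or names; a weight applies to the region and all its
#'   descendants). Unknown names are an error. `NULL` = uniform.
#' @param seed Random seed; the same seed reproduces the scene exactly.
#' @param min_separation_um Minimum in-plane distance between spheres within
#'   `sep_depth_um` of each other along the cutting axis (default 60).
#' @param sep_depth_um Cutting-axis window for the separation rule.
#' @param voxel_margin Fraction of the voxel edge kept clear at each face
#'   when jittering the centre (default 0.2).
#' @param diameter_um Sphere diameter (default 20).
#' @return A `sphere_scene`: list with `spheres` (tibble `id`, `ax`, `ay`,
#'   `az` voxel coords, `region_id`), `diameter_um`, `seed`, and the atlas.
#' @export
generate_scene <- function(atlas, n_spheres = 2000, weights = NULL,
                           seed = 1, min_separation_um = 60,
                           sep_depth_um = 500, voxel_margin = 0.2,
                           diameter_um = 20) {
  stopifnot(n_spheres >= 0)
  set.seed(seed)
  labels <- atlas$annotation$labels
  vox <- atlas$annotation$voxel_size_um
  cand <- which(labels > 0L)
  lab_cand <- labels[cand]
  prob <- NULL
  if (!is.null(weights)) {
    ont <- atlas$ontology
    ids <- names(weights)
    by_name <- match(ids, ont$name)
    by_id <- suppressWarnings(as.integer(ids))
    wid <- ifelse(!is.na(by_name), ont$id[by_name], by_id)
    if (any(is.na(wid)) || !all(wid %in% ont$id)) {
      stop("weights name unknown region(s): ",
           paste(ids[is.na(wid) | !(wid %in% ont$id)], collapse = ", "),
           call. = FALSE)
    }
    w_vox <- rep(0, length(cand))
    for (j in seq_along(wid)) {
      # weight covers the region and everything below it
      desc <- wid[j]
      repeat {
        more <- ont$id[!is.na(ont$parent_id) & ont$parent_id %in% desc &
                         !(ont$id %in% desc)]
        if (!length(more)) break
        desc <- c(desc, more)
      }
      w_vox[lab_cand %in% desc] <- w_vox[lab_cand %in% desc] + weights[j]
    }
    prob <- w_vox
    if (sum(prob) <= 0) stop("weights select no voxels", call. = FALSE)
  }
  if (n_spheres == 0L) {
    return(structure(list(
      spheres = tibble::tibble(id = integer(0), ax = numeric(0),
                               ay = numeric(0), az = numeric(0),
                               region_id = integer(0)),
      diameter_um = diameter_um, seed = seed, atlas = atlas),
      class = "sphere_scene"))
  }
  d <- dim(labels)
  acc <- matrix(numeric(0), 0, 3)
  reg <- integer(0)
  tries <- 0L
  max_tries <- 200L * n_spheres + 1000L
  while (nrow(acc) < n_spheres && tries < max_tries) {
    tries <- tries + 1L
    vi <- if (is.null(prob)) cand[sample.int(length(cand), 1L)] else
      cand[sample.int(length(cand), 1L, prob = prob)]
    co <- arrayInd(vi, d) - 1L
    p <- co + voxel_margin + stats::runif(3) * (1 - 2 * voxel_margin)
    if (min_separation_um > 0 && nrow(acc)) {
      near_ap <- abs(acc[, 3] - p[3]) * vox <= sep_depth_um
      if (any(near_ap)) {
        dxy <- sqrt((acc[near_ap, 1] - p[1])^2 +
                      (acc[near_ap, 2] - p[2])^2) * vox
        if (any(dxy < min_separation_um)) next
      }
    }
    acc <- rbind(acc, p)
    reg <- c(reg, labels[vi])
  }
  if (nrow(acc) < n_spheres) {
    stop("could not place ", n_spheres,
         " spheres at the requested separation", call. = FALSE)
  }
  structure(list(
    spheres = tibble::tibble(id = seq_len(n_spheres),
                             ax = acc[, 1], ay = acc[, 2], az = acc[, 3],
                             region_id = reg),
    diameter_um = diameter_um, seed = seed, atlas = atlas),
    class = "sphere_scene")
}

#' @export
print.sphere_scene <- function(x, ...) {
  cat(sprintf("<sphere_scene> %d spheres (seed %s)\n",
              nrow(x$spheres), format(x$seed)))
  invisible(x)
}

attenuated_intensity <- function(depth_um, visibility_depth_um,
                                 peak = 255, floor_level = 140,
                                 curve = c("linear", "exponential")) {
  curve <- match.arg(curve)
  f <- depth_um / visibility_depth_um
  switch(curve,
    linear = peak - (peak - floor_level) * f,
    # reaches floor_level exactly at the visibility depth, like the linear
    # curve, but with a faster initial falloff
    exponential = floor_level + (peak - floor_level) *
      (exp(-3 * f) - exp(-3)) / (1 - exp(-3))
  )
}

#' Render a sphere scene into a block-face stack
#'
#' Produces the image series a block-face camera would record while the
#' scene's brain is serially sectioned anterior-first: the cut surface shows
#' dim tissue foreground on a black (ink-embedded) background, and every
#' sphere is visible not only in its own section but also in the preceding
#' images while it still lies within the visibility depth of the surface,
#' with green-channel intensity attenuated (and the disk slightly widened,
#' mimicking scatter) as depth increases. The attenuation keeps every
#' rendered sphere at or above the detection threshold within the visibility
#' depth, so noise-free renders are fully detectable by construction.
#' Optional per-section rigid jitter and Gaussian pixel noise are applied
#' after rendering.
#'
#' @param scene A [generate_scene()] result.
#' @param pixel_size_um In-plane resolution (default 6.5 um/px).
#' @param section_thickness_um Section thickness (default 100 um).
#' @param visibility_depth_um Depth to which spheres remain visible
#'   (default 400 um).
#' @param attenuation `"linear"` (default) or `"exponential"` depth falloff
#'   from `peak_intensity` at the surface towards `threshold_level`.
#' @param peak_intensity Green intensity of a surfaced sphere (default 255).
#' @param threshold_level Intensity reached at the visibility depth
#'   (default 140, the segmentation threshold).
#' @param background Tissue foreground intensity, all channels (default 40).
#' @param noise_sd Gaussian noise SD in 8-bit counts (default 0).
#' @param jitter_px Per-section translation jitter: integer shifts drawn
#'   uniformly from `-jitter_px..jitter_px` on each axis (default 0).
#' @param jitter_deg Per-section rotation jitter bound in degrees
#'   (default 0).
#' @param seed Seed for jitter and noise.
#' @return List with `stack` (a [blockface_stack]), `truth` (tibble `id`,
#'   `section_index`, `x_px`, `y_px`, `ax`, `ay`, `az`, `region_id`,
#'   `hemisphere` in unjittered geometry), `mappings` (the true per-section
#'   atlas mappings, [propagate_anchors()]-shaped), `midlines` (true
#'   vertical midline per section), `jitter` (tibble of applied per-section
#'   transforms), and `params`.
#' @export
render_blockface_stack <- function(scene,
                                   pixel_size_um = 6.5,
                                   section_thickness_um = 100,
                                   visibility_depth_um = 400,
                                   attenuation = c("linear", "exponential"),
                                   peak_intensity = 255,
                                   threshold_level = 140,
                                   background = 40,
                                   noise_sd = 0,
                                   jitter_px = 0,
                                   jitter_deg = 0,
                                   seed = NULL) {
  attenuation <- match.arg(attenuation)
  stopifnot(visibility_depth_um >= section_thickness_um)
  if (!is.null(seed)) set.seed(seed)
  ann <- scene$atlas$annotation
  vox <- ann$voxel_size_um
  d <- dim(ann$labels)
  n_sections <- ceiling(d[3] * vox / section_thickness_um)
  W <- ceiling(d[1] * vox / pixel_size_um)
  H <- ceiling(d[2] * vox / pixel_size_um)

  # true mappings: pixel (x, y) of section i -> atlas voxel coords; each
  # section is anchored at its mid-plane (the section's nominal position)
  mappings <- tibble::tibble(
    section_index = 0:(n_sections - 1),
    ox = 0, oy = 0,
    oz = (0:(n_sections - 1) + 0.5) * section_thickness_um / vox,
    ux = W * pixel_size_um / vox, uy = 0, uz = 0,
    vx = 0, vy = H * pixel_size_um / vox, vz = 0
  )

  sp <- scene$spheres
  truth <- tibble::tibble(
    id = sp$id,
    section_index = as.integer(floor(sp$az * vox / section_thickness_um)),
    x_px = sp$ax * vox / pixel_size_um,
    y_px = sp$ay * vox / pixel_size_um,
    ax = sp$ax, ay = sp$ay, az = sp$az,
    region_id = sp$region_id
  )
  mid_x <- d[1] / 2 * vox / pixel_size_um
  truth$hemisphere <- ifelse(truth$x_px < mid_x, "left", "right")

  # per-pixel foreground lookup grid, shared by all sections
  col_ax <- pmin(pmax(floor((seq_len(W) - 0.5) * pixel_size_um / vox), 0),
                 d[1] - 1) + 1
  row_ay <- pmin(pmax(floor((seq_len(H) - 0.5) * pixel_size_um / vox), 0),
                 d[2] - 1) + 1

  r0_px <- scene$diameter_um / pixel_size_um / 2
  jitter <- tibble::tibble(section_index = 0:(n_sections - 1),
                           rotation_deg = 0, dx = 0L, dy = 0L)
  if (jitter_px > 0) {
    jitter$dx <- sample(-jitter_px:jitter_px, n_sections, replace = TRUE)
    jitter$dy <- sample(-jitter_px:jitter_px, n_sections, replace = TRUE)
  }
  if (jitter_deg > 0) {
    jitter$rotation_deg <- stats::runif(n_sections, -jitter_deg, jitter_deg)
  }

  sections <- vector("list", n_sections)
  for (i in seq_len(n_sections)) {
    az_mid <- pmin(floor(((i - 0.5) * section_thickness_um) / vox), d[3] - 1) + 1
    fg <- matrix(ann$labels[cbind(rep(col_ax, each = H),
                                  rep(row_ay, times = W),
                                  az_mid)] > 0L, H, W)
    base <- matrix(0, H, W)
    base[fg] <- background
    rch <- base; gch <- base; bch <- base

    surf_um <- (i - 1) * section_thickness_um
    depth_um <- truth$az * vox - surf_um
    vis <- which(depth_um >= 0 & depth_um < visibility_depth_um)
    for (k in vis) {
      inten <- attenuated_intensity(depth_um[k], visibility_depth_um,
                                    peak_intensity, threshold_level,
                                    attenuation)
      r_px <- r0_px * (1 + 0.1 * depth_um[k] / 100)
      px <- disk_pixels(truth$x_px[k], truth$y_px[k], r_px, c(H, W))
      gch[px] <- pmax(gch[px], inten)
    }
    img <- array(c(rch, gch, bch), dim = c(H, W, 3))
    tf <- rigid_transform(jitter$rotation_deg[i], jitter$dx[i], jitter$dy[i])
    if (tf$rotation_deg != 0 || tf$dx != 0 || tf$dy != 0) {
      img <- apply_rigid_transform(img, tf, "bilinear")
    }
    if (noise_sd > 0) {
      img <- img + array(stats::rnorm(length(img), 0, noise_sd), dim = dim(img))
      img <- pmin(pmax(round(img), 0), 255)
    }
    sections[[i]] <- img
  }

  midlines <- list()
  for (i in seq_len(n_sections)) {
    midlines[[as.character(i - 1L)]] <-
      tibble::tibble(x = c(mid_x, mid_x), y = c(0, H - 1))
  }

  list(
    stack = blockface_stack(sections, pixel_size_um, section_thickness_um),
    truth = truth,
    mappings = mappings,
    midlines = midlines,
    jitter = jitter,
    params = list(pixel_size_um = pixel_size_um,
                  section_thickness_um = section_thickness_um,
                  visibility_depth_um = visibility_depth_um,
                  attenuation = attenuation,
                  peak_intensity = peak_intensity,
                  threshold_level = threshold_level,
                  background = background,
                  noise_sd = noise_sd,
                  jitter_px = jitter_px, jitter_deg = jitter_deg,
                  seed = seed)
  )
}
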