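#' Brute-force 3D labelling of sphere chains in a mask stack
#'
#' Reference method for validating serial mask subtraction: the binary masks
#' are stacked into a 3D volume and connected components are found under
#' 26-connectivity (8-connected in plane, plus the full 3x3 pixel
#' neighbourhood across adjacent sections). Each 3D component is one sphere
#' chain; its true z-plane is the deepest section it reaches. This walks the
#' voxel adjacency directly and shares no logic with
#' [resolve_z_by_serial_subtraction()].
#'
#' @param masks List of binary `[y, x]` masks, ordered by section.
#' @return Tibble with one row per chain: `chain`, `z_last` (0-based index
#'   of the deepest section), `x`, `y` (centroid of the chain's pixels in
#'   its deepest section), `n_sections` (sections spanned).
#' @export
label_sphere_chains_3d <- function(masks) {
  n <- length(masks)
  empty <- tibble::tibble(chain = integer(0), z_last = integer(0),
                          x = numeric(0), y = numeric(0),
                          n_sections = integer(0))
  if (n == 0L) return(empty)
  labs <- lapply(masks, label_components)
  counts <- vapply(labs, function(l) as.integer(max(l)), integer(1))
  total <- sum(counts)
  if (total == 0L) return(empty)
  offset <- as.integer(cumsum(c(0L, counts))[seq_len(n)])

  # union-find over per-section 2D components
  parent <- seq_len(total)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }

  h <- nrow(masks[[1]]); w <- ncol(masks[[1]])
  enc <- function(idx) idx[, 1] + (idx[, 2] - 1L) * (h + 2L)  # pad-safe code
  for (i in seq_len(n - 1)) {
    if (counts[i] == 0 || counts[i + 1] == 0) next
    a_idx <- which(labs[[i]] > 0, arr.ind = TRUE)
    b_idx <- which(labs[[i + 1]] > 0, arr.ind = TRUE)
    a_comp <- labs[[i]][a_idx]
    b_comp <- labs[[i + 1]][b_idx]
    # dilate section i's pixels by the 8-neighbourhood: a pixel pair in
    # adjacent sections is 26-adjacent iff Chebyshev distance <= 1
    off <- expand.grid(dy = -1:1, dx = -1:1)
    a_codes <- lapply(seq_len(nrow(off)), function(k) {
      enc(cbind(a_idx[, 1] + off$dy[k], a_idx[, 2] + off$dx[k]))
    })
    b_code <- enc(b_idx)
    for (k in seq_along(a_codes)) {
      hit <- match(a_codes[[k]], b_code)
      ok <- which(!is.na(hit))
      for (m in ok) {
        union(offset[i] + as.integer(a_comp[m]),
              offset[i + 1] + as.integer(b_comp[hit[m]]))
      }
    }
  }

  roots <- vapply(seq_len(total), find, integer(1))
  chain_id <- match(roots, unique(roots))
  rows <- list()
  for (ch in seq_len(max(chain_id))) {
    members <- which(chain_id == ch)
    secs <- findInterval(members - 0.5, cumsum(c(0, counts)))
    z_last <- max(secs)
    comp_in_last <- members[secs == z_last] - offset[z_last]
    ll <- labs[[z_last]]
    idx <- which(matrix(ll %in% comp_in_last, nrow(ll)), arr.ind = TRUE)
    rows[[ch]] <- tibble::tibble(
      chain = ch, z_last = z_last - 1L,
      x = mean(idx[, 2] - 0.5), y = mean(idx[, 1] - 0.5),
      n_sections = length(unique(secs))
    )
  }
  dplyr::bind_rows(rows)
}

#' Generate a random synthetic mask stack of sphere chains
#'
#' Builds per-section binary masks containing disk "spheres" that persist
#' over short runs of consecutive sections (as a microsphere seen through
#' tissue does), with small in-plane centroid drift between sections.
#' Distinct chains are kept well separated in plane so that each rendered
#' chain is unambiguous; ground truth records each chain's deepest section.
#'
#' @param n_sections Number of sections.
#' @param dim Mask dimensions `c(height, width)`; allow roughly
#'   `(dim/20)^2` chains at the default separation.
#' @param n_chains Number of sphere chains.
#' @param max_chain_len Maximum sections a chain may span (default 4, the
#'   visibility limit of 400 um seen at 100-um sections).
#' @param drift_px Maximum per-section centroid drift on each axis
#'   (integer, default 2).
#' @param min_separation_px Minimum in-plane distance between different
#'   chains at any section (default 8; centres are placed further apart to
#'   leave room for drift).
#' @param radius_px Disk radius in pixels (default 1.6, a 20-um sphere at
#'   6.5 um/px).
#' @param seed Random seed.
#' @return List with `masks` (list of binary matrices) and `truth` (tibble
#'   `chain`, `z_last`, `x`, `y` of the chain's centre in its last section,
#'   `len`).
#' @export
generate_chain_stack <- function(n_sections = 16, dim = c(160, 160),
                                 n_chains = 30, max_chain_len = 4,
                                 drift_px = 2, min_separation_px = 8,
                                 radius_px = 1.6, seed = 1) {
  set.seed(seed)
  margin <- ceiling(radius_px + drift_px * (max_chain_len - 1) + 2)
  centres <- matrix(numeric(0), 0, 2)
  tries <- 0L
  while (nrow(centres) < n_chains && tries < 500L * n_chains) {
    tries <- tries + 1L
    # integer-aligned centres: a 1.6-px disk then rasterizes to a full 3x3
    # block, so adjacent sections of a chain always overlap even at the
    # maximum drift
    p <- round(c(stats::runif(1, margin, dim[2] - margin),
                 stats::runif(1, margin, dim[1] - margin)))
    if (nrow(centres) == 0 ||
        all(sqrt((centres[, 1] - p[1])^2 + (centres[, 2] - p[2])^2) >=
              min_separation_px + 2 * drift_px * (max_chain_len - 1))) {
      centres <- rbind(centres, p)
    }
  }
  if (nrow(centres) < n_chains) {
    stop("could not place ", n_chains, " chains at this separation",
         call. = FALSE)
  }
  masks <- lapply(seq_len(n_sections), function(i) matrix(0L, dim[1], dim[2]))
  truth <- list()
  for (ch in seq_len(n_chains)) {
    len <- sample.int(max_chain_len, 1)
    z_last <- sample(seq(len, n_sections), 1) - 1L  # 0-based
    pos <- centres[ch, ]
    xs <- numeric(len); ys <- numeric(len)
    for (j in seq_len(len)) {   # walk from the shallow end down to z_last
      s <- z_last - len + j     # 0-based section
      xs[j] <- pos[1]; ys[j] <- pos[2]
      masks[[s + 1L]][disk_pixels(pos[1], pos[2], radius_px, dim)] <- 1L
      pos <- pos + sample(-drift_px:drift_px, 2, replace = TRUE)
    }
    truth[[ch]] <- tibble::tibble(chain = ch, z_last = z_last,
                                  x = xs[len], y = ys[len], len = len)
  }
  list(masks = masks, truth = dplyr::bind_rows(truth))
}
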