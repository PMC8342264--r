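# Shared fixtures, built in code at test time.

# Small hand-written ontology:
#   1 root (L1)
#   +-- 2 gray (L2)
#   |   +-- 4 cortex (L3)
#   |   |   +-- 6 motor (L4)
#   |   |   +-- 7 visual (L4)
#   |   +-- 5 thalamus (L3)          <- early-terminating branch
#   +-- 3 fiber tracts (L2)
#       +-- 8 callosum (L3)
tiny_ontology <- function() {
  atlas_ontology(data.frame(
    id = 1:8,
    name = c("root", "gray", "fiber tracts", "cortex", "thalamus",
             "motor", "visual", "callosum"),
    parent_id = c(NA, 1, 1, 2, 2, 4, 4, 3)
  ))
}

# Matching 3D annotation: 8 x 4 x 4 voxels, x split motor|visual|thalamus|
# callosum in two-voxel slabs, with a one-voxel rim of 0 kept at x = 7..8.
tiny_annotation <- function(voxel_size_um = 50) {
  labels <- array(0L, dim = c(8, 4, 4))
  labels[1:2, , ] <- 6L
  labels[3:4, , ] <- 7L
  labels[5:6, , ] <- 5L
  labels[7, , ] <- 8L
  annotation_volume(labels, voxel_size_um)
}

# Toy atlas shared by the heavier pipeline tests (cached per session).
cached_toy_atlas <- local({
  atl <- NULL
  function() {
    if (is.null(atl)) atl <<- generate_toy_atlas(seed = 1)
    atl
  }
})

# Independent closed-form Pearson correlation (test oracle).
pearson_by_hand <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  r <- sxy / sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(t), df = n - 2)
  list(r = r, t = t, p = p)
}

# Independent pooled-variance t statistic (test oracle).
pooled_t_by_hand <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) /
    (n1 + n2 - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

# Match detections to ground truth by section and in-plane distance;
# returns the index of the matching detection per truth row (NA if none).
match_detections <- function(det, truth, tol_px = 3) {
  vapply(seq_len(nrow(truth)), function(i) {
    cand <- which(det$section_index == truth$section_index[i])
    if (!length(cand)) return(NA_integer_)
    dd <- sqrt((det$x_px[cand] - truth$x_px[i])^2 +
                 (det$y_px[cand] - truth$y_px[i])^2)
    j <- cand[which.min(dd)]
    if (min(dd) <= tol_px) j else NA_integer_
  }, integer(1))
}

# Independent disk rasterizer for building mask fixtures (deliberately not
# the package's own disk_pixels()).
disk_pixels_for_test <- function(x, y, r, dim) {
  g <- expand.grid(row = seq_len(dim[1]), col = seq_len(dim[2]))
  sel <- (g$col - 0.5 - x)^2 + (g$row - 0.5 - y)^2 <= r^2
  cbind(g$row[sel], g$col[sel])
}
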