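test_that("ontology construction derives levels and rejects bad trees", {
  ont <- tiny_ontology()
  expect_equal(ont$level, c(1, 2, 2, 3, 3, 4, 4, 3))
  expect_error(atlas_ontology(data.frame(id = 1:2, name = c("a", "b"),
                                         parent_id = c(NA, NA))),
               "exactly one root")
  expect_error(atlas_ontology(data.frame(id = c(1, 2, 2),
                                         name = c("a", "b", "c"),
                                         parent_id = c(NA, 1, 1))),
               "duplicate")
  expect_error(atlas_ontology(data.frame(id = 1:3, name = c("a", "b", "c"),
                                         parent_id = c(NA, 3, 2))),
               "cycle")
  expect_error(atlas_ontology(data.frame(id = 1:2, name = c("a", "b"),
                                         parent_id = c(NA, 9))),
               "unknown")
})

test_that("ancestor_at_level matches brute-force parent-chain walking", {
  ont <- tiny_ontology()
  parent <- stats::setNames(ont$parent_id, ont$id)
  walk_up <- function(id, k) {
    chain <- id
    while (!is.na(parent[as.character(chain[1])])) {
      chain <- c(parent[as.character(chain[1])], chain)
    }
    if (length(chain) < k) NA_integer_ else as.integer(chain[k])
  }
  for (id in ont$id) {
    for (k in 1:5) {
      expect_identical(ancestor_at_level(ont, id, k), walk_up(id, k),
                       label = sprintf("id %d level %d", id, k))
    }
  }
  # explicit semantics: deeper node queried shallower, shallow node queried
  # deeper ("not at this level"), and everything reaches the root
  expect_equal(ancestor_at_level(ont, 6, 3), 4L)
  expect_true(is.na(ancestor_at_level(ont, 5, 4)))
  expect_equal(ancestor_at_level(ont, c(6, 7, 8), 1), c(1L, 1L, 1L))
  expect_true(is.na(ancestor_at_level(ont, NA_integer_, 2)))
  expect_error(ancestor_at_level(ont, 99, 2), "unknown")
})

test_that("count aggregation conserves totals up the tree", {
  ont <- tiny_ontology()
  agg <- aggregate_counts(ont, tibble::tibble(id = c(6, 7, 5),
                                              n = c(3, 2, 4)))
  expect_equal(agg$n_total[agg$id == 4], 5)   # cortex = motor + visual
  expect_equal(agg$n_total[agg$id == 2], 9)   # gray adds thalamus
  expect_equal(agg$n_total[agg$id == 1], 9)   # root = everything counted
  # vector-of-ids form, with NA (unaccounted) dropped
  agg2 <- aggregate_counts(ont, c(6, 6, 7, NA, 5))
  expect_equal(agg2$n_total[agg2$id == 1], 4)
  # empty counts -> all zeros
  agg0 <- aggregate_counts(ont, integer(0))
  expect_true(all(agg0$n_total == 0))
  expect_error(aggregate_counts(ont, tibble::tibble(id = 77, n = 1)),
               "unknown")
})

test_that("terminal branches follow the minimum-count expansion rule", {
  ont <- tiny_ontology()
  # 4 spheres under cortex (of 14 total): too few to expand -> cortex is
  # terminal at its own level
  base <- c(rep(5, 5), rep(8, 5))
  t4 <- select_terminal_branches(ont, c(rep(6, 2), rep(7, 2), base))
  expect_true(4 %in% t4$id)
  expect_false(any(c(6, 7) %in% t4$id))
  # 5 spheres under cortex: it expands into motor and visual
  t5 <- select_terminal_branches(ont, c(rep(6, 3), rep(7, 2), base))
  expect_false(4 %in% t5$id)
  expect_true(all(c(6, 7) %in% t5$id))
  # leaves are terminal whatever their count
  expect_true(5 %in% t5$id)
  # max_level caps descent
  tcap <- select_terminal_branches(ont, c(rep(6, 3), rep(7, 2), base),
                                   max_level = 3)
  expect_true(4 %in% tcap$id)

  # terminal branches are mutually exclusive and jointly exhaustive
  ids <- c(rep(6, 3), rep(7, 2), rep(5, 1), rep(8, 9))
  tb <- select_terminal_branches(ont, ids)
  assigned <- terminal_branch_of(ont, ids, tb)
  expect_false(any(is.na(assigned)))
  expect_equal(sum(table(factor(assigned, levels = tb$id))), length(ids))
  # no terminal branch is a strict ancestor of another (direct-only rows
  # excepted: they capture spheres sitting on an expanded node itself)
  frontier <- tb$id[!tb$direct_only]
  for (j in frontier) {
    ancestors <- setdiff(ontology_path(ont, j), j)
    expect_length(intersect(ancestors, frontier), 0)
  }
})

test_that("region lookup handles inside, outside and unlabelled voxels", {
  ann <- tiny_annotation()
  expect_equal(assign_region(c(0.5, 0.5, 0.5), ann), 6L)
  expect_equal(assign_region(c(3.9, 1, 1), ann), 7L)
  expect_true(is.na(assign_region(c(7.5, 1, 1), ann)))    # label 0
  expect_true(is.na(assign_region(c(-1, 1, 1), ann)))     # out of bounds
  expect_true(is.na(assign_region(c(1, 1, 99), ann)))
  got <- assign_region(tibble::tibble(ax = c(0.1, 4.2), ay = c(0, 0),
                                      az = c(0, 0)), ann)
  expect_equal(got, c(6L, 5L))
})

test_that("region volumes and densities follow voxel arithmetic", {
  ont <- tiny_ontology()
  ann <- tiny_annotation(voxel_size_um = 50)
  vols <- region_volumes(ann, ont)
  # 2 x 4 x 4 = 32 voxels of 1.25e-4 mm3 each
  expect_equal(vols$volume_mm3[vols$id == 6], 32 * 1.25e-4)
  # cortex volume includes both children
  expect_equal(vols$volume_mm3[vols$id == 4], 64 * 1.25e-4)
  # an 8000-voxel structure at 50 um isotropic is exactly 1 mm3
  big <- annotation_volume(array(5L, dim = c(20, 20, 20)), 50)
  ont2 <- atlas_ontology(data.frame(id = c(1, 5),
                                    name = c("root", "leaf"),
                                    parent_id = c(NA, 1)))
  expect_equal(region_volumes(big, ont2)$volume_mm3[2], 1.0)

  expect_equal(region_density(10, 5), 2.0)
  expect_equal(region_density(0, 3), 0.0)
  expect_error(region_density(2, 0), "zero-volume")
})

test_that("region reports conserve counts and close proportions at 100%", {
  ont <- tiny_ontology()
  ann <- tiny_annotation()
  det <- tibble::tibble(
    id = 1:20,
    region_id = c(rep(6, 6), rep(7, 4), rep(5, 5), rep(8, 3),
                  NA_integer_, NA_integer_))
  rep <- compile_report(det, ont, ann, min_count = 5)
  expect_equal(sum(rep$regions$count) + rep$unaccounted$count, 20)
  expect_equal(rep$totals$proportion_pct, 100, tolerance = 0.1)
  expect_equal(rep$totals$count, 20)
  expect_equal(rep$totals$mean_density_per_mm3,
               mean(rep$regions$density_per_mm3))
  # densities are count / volume
  vols <- region_volumes(ann, ont)
  for (i in seq_len(nrow(rep$regions))) {
    expect_equal(rep$regions$density_per_mm3[i],
                 rep$regions$count[i] /
                   vols$volume_mm3[vols$id == rep$regions$id[i]])
  }
  # the long-format level table covers every detection at every level
  expect_equal(nrow(rep$levels), 20 * 12)
  lvl3 <- rep$levels[rep$levels$level == 3 & rep$levels$id == 1, ]
  expect_equal(lvl3$region_id, 4L)   # a motor sphere sits in cortex at L3
  lvl4_thal <- rep$levels[rep$levels$level == 4 & rep$levels$id == 11, ]
  expect_true(is.na(lvl4_thal$region_id))  # thalamus ends at level 3

  # tidy/glance interface
  td <- tidy(rep)
  expect_equal(td$name[nrow(td)], "unaccounted")
  expect_equal(glance(rep)$n_detections, 20)
})

test_that("ontology and annotation files round-trip", {
  ont <- tiny_ontology()
  f <- withr::local_tempfile(fileext = ".json")
  write_ontology_json(ont, f)
  ont2 <- read_ontology_json(f)
  expect_equal(as.data.frame(ont2), as.data.frame(ont))

  # nested children form (Allen structure-graph style)
  nested <- list(list(
    id = 1, name = "root",
    children = list(
      list(id = 2, name = "a", children = list(
        list(id = 4, name = "a1", children = list()))),
      list(id = 3, name = "b", children = list()))))
  f2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(nested, f2, auto_unbox = TRUE)
  ont3 <- read_ontology_json(f2)
  expect_equal(ont3$level, c(1, 2, 3, 2))

  ann <- tiny_annotation()
  f3 <- withr::local_tempfile(fileext = ".nii.gz")
  write_annotation_nifti(ann, f3)
  ann2 <- read_annotation_nifti(f3)
  expect_equal(ann2$labels, ann$labels, ignore_attr = TRUE)
  expect_equal(ann2$voxel_size_um, ann$voxel_size_um, tolerance = 1e-6)
})
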