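#' Compile a region report from atlas-assigned detections
#'
#' Produces the standard summary of a microsphere localization run: one row
#' per terminal branch of the ontology (selected by the minimum-count
#' criterion, see [select_terminal_branches()]) with the sphere count, the
#' proportion of all detections (unaccounted included), and the density per
#' mm^3 of the structure; an unaccounted row for detections whose atlas
#' coordinate fell outside any labelled structure; and a totals row whose
#' count and proportion are column sums and whose density is the mean of the
#' per-region densities. A long-format companion table gives every
#' detection's ancestor at each ontology level (`NA` where the structure
#' does not extend that deep).
#'
#' @param detections Data frame with at least `id` and `region_id` (`NA`
#'   for unaccounted detections), e.g. from [localize_microspheres()].
#' @param ontology An [atlas_ontology].
#' @param annotation An [annotation_volume] (used for structure volumes).
#' @param min_count Minimum-count criterion for terminal branches
#'   (default 5).
#' @param max_level Optional deepest reporting level.
#' @param levels Levels of the long-format table (default `1:12`).
#' @return A `region_report`: list with `regions` (terminal-branch tibble:
#'   `id`, `name`, `level`, `count`, `proportion_pct`, `volume_mm3`,
#'   `density_per_mm3`), `unaccounted` (count + proportion), `totals`, and
#'   `levels` (long table `id`, `level`, `region_id`, `region_name`).
#'   [generics::tidy()] returns the region table with the unaccounted row
#'   appended; [generics::glance()] the totals.
#' @export
compile_report <- function(detections, ontology, annotation,
                           min_count = 5, max_level = NULL, levels = 1:12) {
  stopifnot(all(c("id", "region_id") %in% names(detections)))
  n_total <- nrow(detections)
  counts <- aggregate_counts(ontology, detections$region_id)
  terminal <- select_terminal_branches(ontology, counts,
                                       min_count = min_count,
                                       max_level = max_level)
  # recount per terminal branch by walking each detection up the tree,
  # which guarantees count conservation by construction
  tb_of <- terminal_branch_of(ontology, detections$region_id, terminal)
  cnt <- table(factor(tb_of, levels = terminal$id))
  terminal$count <- as.integer(cnt[as.character(terminal$id)])

  vols <- region_volumes(annotation, ontology)
  terminal$volume_mm3 <- vols$volume_mm3[match(terminal$id, vols$id)]
  terminal$density_per_mm3 <- region_density(terminal$count,
                                             terminal$volume_mm3)
  terminal$proportion_pct <- if (n_total > 0) {
    100 * terminal$count / n_total
  } else {
    rep(0, nrow(terminal))
  }
  n_unacc <- sum(is.na(detections$region_id))
  unaccounted <- tibble::tibble(
    count = n_unacc,
    proportion_pct = if (n_total > 0) 100 * n_unacc / n_total else 0
  )
  totals <- tibble::tibble(
    n_detections = n_total,
    count = sum(terminal$count) + n_unacc,
    proportion_pct = sum(terminal$proportion_pct) +
      unaccounted$proportion_pct,
    mean_density_per_mm3 = if (nrow(terminal)) {
      mean(terminal$density_per_mm3)
    } else {
      NA_real_
    }
  )

  lev_tab <- tidyr::expand_grid(id = detections$id, level = levels)
  reg_by_id <- stats::setNames(detections$region_id, detections$id)
  nm <- attr(ontology, "node_name")
  lev_tab <- dplyr::group_by(lev_tab, .data$level)
  lev_tab <- dplyr::mutate(
    lev_tab,
    region_id = ancestor_at_level(ontology,
                                  unname(reg_by_id[as.character(.data$id)]),
                                  .data$level[1])
  )
  lev_tab <- dplyr::ungroup(lev_tab)
  lev_tab$region_name <- unname(nm[as.character(lev_tab$region_id)])

  regions <- terminal[, c("id", "name", "level", "count", "proportion_pct",
                          "volume_mm3", "density_per_mm3", "direct_only")]
  structure(
    list(regions = regions, unaccounted = unaccounted, totals = totals,
         levels = lev_tab, min_count = min_count),
    class = "region_report"
  )
}

#' @export
print.region_report <- function(x, ...) {
  cat(sprintf(
    "<region_report> %d detections, %d terminal regions (>= %d criterion), %d unaccounted\n",
    x$totals$n_detections, nrow(x$regions), x$min_count,
    x$unaccounted$count))
  print(x$regions, ...)
  cat(sprintf("totals: count %d, proportion %.1f%%, mean density %.3f /mm3\n",
              x$totals$count, x$totals$proportion_pct,
              x$totals$mean_density_per_mm3))
  invisible(x)
}

#' @export
tidy.region_report <- function(x, ...) {
  un <- tibble::tibble(
    id = NA_integer_, name = "unaccounted", level = NA_integer_,
    count = x$unaccounted$count,
    proportion_pct = x$unaccounted$proportion_pct,
    volume_mm3 = NA_real_, density_per_mm3 = NA_real_, direct_only = FALSE
  )
  dplyr::bind_rows(x$regions, un)
}

#' @export
glance.region_report <- function(x, ...) x$totals

#' Write a region report to CSV files
#'
#' @param report A [compile_report()] result.
#' @param regions_path CSV path for the terminal-region table (with the
#'   unaccounted row).
#' @param levels_path Optional CSV path for the long-format level table.
#' @return `regions_path`, invisibly.
#' @export
write_report_csv <- function(report, regions_path, levels_path = NULL) {
  utils::write.csv(tidy(report), regions_path, row.names = FALSE)
  if (!is.null(levels_path)) {
    utils::write.csv(report$levels, levels_path, row.names = FALSE)
  }
  invisible(regions_path)
}
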