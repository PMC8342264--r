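#' Bundled validation counts
#'
#' Two small count tables from a validation experiment for this kind of
#' block-face microsphere-localization workflow, shipped so the package's
#' agreement statistics can be exercised on realistic numbers without any
#' imaging data.
#'
#' `validation_allocation_counts()` holds the gross-region comparison: all
#' spheres from five brains were allocated both by the automated workflow
#' and by a blinded rater to seven regions easily identifiable in
#' block-face images, and counted as agreement or disagreement per region.
#'
#' `validation_agreement_counts()` holds the level-wise comparison: a
#' systematic sample of 52 spheres was allocated by a blinded rater from
#' histology and compared, at each ontology level, against either the
#' block-face workflow (`"blockface"`) or against registering the
#' histologic sections themselves (`"histology"`).
#'
#' @return `validation_allocation_counts()`: tibble `region`, `agreement`,
#'   `disagreement`. `validation_agreement_counts()`: an
#'   [agreement_table] for the chosen workflow, with the printed level
#'   labels kept in a `level_label` column (`"3/4"` and `"1/2"` are the
#'   collapsed shallow levels).
#' @export
validation_allocation_counts <- function() {
  path <- system.file("extdata", "validation_allocation_counts.csv",
                      package = "embolocate", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname validation_allocation_counts
#' @param workflow Which comparison to return: the block-face imaging
#'   workflow (`"blockface"`) or QuickNII-style registration of the
#'   histologic sections (`"histology"`).
#' @export
validation_agreement_counts <- function(workflow = c("blockface",
                                                     "histology")) {
  workflow <- match.arg(workflow)
  path <- system.file("extdata", "validation_agreement_levels.csv",
                      package = "embolocate", mustWork = TRUE)
  x <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  x <- x[x$workflow == workflow, , drop = FALSE]
  # numeric rank for the collapsed labels, deepest first in the source
  x$level <- vapply(strsplit(x$level_label, "/"), function(p) {
    min(as.numeric(p))
  }, numeric(1))
  out <- agreement_table(x[, c("level", "agreement", "not_at_level",
                               "disagreement")])
  out$level_label <- x$level_label
  out
}

#' Totals and proportions for a per-region allocation comparison
#'
#' Summarizes a gross-region agreement table (as returned by
#' [validation_allocation_counts()], or assembled from any rater-versus-
#' workflow comparison): per-region totals with their share of all spheres,
#' per-region agreement percentages, and the overall agreement.
#'
#' @param counts Tibble with columns `region`, `agreement`, `disagreement`.
#' @return List with `regions` (tibble `region`, `agreement`,
#'   `disagreement`, `total`, `proportion_pct`, `agreement_pct`) and
#'   `overall` (tibble `agreement`, `disagreement`, `total`,
#'   `agreement_pct`). Percentages are rounded half-up to one decimal.
#' @export
#' @examples
#' summarize_allocation_counts(validation_allocation_counts())$overall
summarize_allocation_counts <- function(counts) {
  stopifnot(all(c("region", "agreement", "disagreement") %in% names(counts)))
  regions <- tibble::as_tibble(counts)
  regions$total <- regions$agreement + regions$disagreement
  grand <- sum(regions$total)
  regions$proportion_pct <- percent_agreement(regions$total, grand)
  regions$agreement_pct <- percent_agreement(regions$agreement,
                                             regions$total)
  overall <- tibble::tibble(
    agreement = sum(regions$agreement),
    disagreement = sum(regions$disagreement),
    total = grand,
    agreement_pct = percent_agreement(sum(regions$agreement), grand)
  )
  list(regions = regions, overall = overall)
}
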