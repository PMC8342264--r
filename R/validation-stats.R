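#' Percent agreement
#'
#' @param agree Number of agreeing items.
#' @param total Total items (> 0).
#' @return `100 * agree / total`, rounded half-up to one decimal, matching
#'   the convention of printed agreement tables.
#' @export
#' @examples
#' percent_agreement(49, 52) # 94.2
percent_agreement <- function(agree, total) {
  if (any(total <= 0)) stop("total must be positive", call. = FALSE)
  round_half_up(100 * agree / total, 1)
}

#' Level-wise agreement between two sets of sphere allocations
#'
#' Compares, at every level of the ontology, where a reference rater and a
#' test workflow placed each sphere. At level `k` a sphere counts as
#' *agreement* when both allocations have the same ancestor at that level;
#' as *not at this level* when the reference structure itself does not
#' extend to level `k` (shallow branches of the tree); otherwise as
#' *disagreement*. The *sum of agreement* -- spheres correctly allocated up
#' to that level -- is agreement plus not-at-level.
#'
#' @param reference,test Data frames with columns `id` (sphere id) and
#'   `region_id` (ontology structure); the same ids must appear in both.
#' @param ontology An [atlas_ontology].
#' @param levels Levels to tabulate (default `1:12`).
#' @return An `agreement_table`: tibble with one row per level
#'   (`level`, `agreement`, `not_at_level`, `sum_of_agreement`,
#'   `disagreement`, `total`, and `*_pct` columns rounded half-up to one
#'   decimal).
#' @export
agreement_by_level <- function(reference, test, ontology, levels = 1:12) {
  if (nrow(reference) != nrow(test) ||
      !setequal(reference$id, test$id) ||
      anyDuplicated(reference$id) || anyDuplicated(test$id)) {
    stop("reference and test must contain the same sphere ids exactly once",
         call. = FALSE)
  }
  test <- test[match(reference$id, test$id), , drop = FALSE]
  lev <- ontology_level(ontology)
  ref_level <- unname(lev[as.character(reference$region_id)])
  rows <- lapply(levels, function(k) {
    ra <- ancestor_at_level(ontology, reference$region_id, k)
    ta <- ancestor_at_level(ontology, test$region_id, k)
    not_at <- ref_level < k
    agree <- !not_at & !is.na(ra) & !is.na(ta) & ra == ta
    tibble::tibble(
      level = k,
      agreement = sum(agree),
      not_at_level = sum(not_at),
      disagreement = sum(!agree & !not_at),
      total = length(ra)
    )
  })
  agreement_table(dplyr::bind_rows(rows))
}

#' Build an agreement table from raw level-wise counts
#'
#' @param counts Data frame with columns `level`, `agreement`,
#'   `not_at_level`, `disagreement` (and optionally `total`).
#' @return An `agreement_table` (see [agreement_by_level()]).
#' @export
agreement_table <- function(counts) {
  counts <- tibble::as_tibble(counts)
  if (!"total" %in% names(counts)) {
    counts$total <- counts$agreement + counts$not_at_level +
      counts$disagreement
  }
  stopifnot(all(counts$agreement + counts$not_at_level +
                  counts$disagreement == counts$total))
  counts$sum_of_agreement <- counts$agreement + counts$not_at_level
  counts$agreement_pct <- percent_agreement(counts$agreement, counts$total)
  counts$not_at_level_pct <- percent_agreement(counts$not_at_level,
                                               counts$total)
  counts$sum_of_agreement_pct <- percent_agreement(counts$sum_of_agreement,
                                                   counts$total)
  counts$disagreement_pct <- percent_agreement(counts$disagreement,
                                               counts$total)
  counts <- counts[, c("level", "agreement", "not_at_level",
                       "sum_of_agreement", "disagreement", "total",
                       "agreement_pct", "not_at_level_pct",
                       "sum_of_agreement_pct", "disagreement_pct")]
  structure(counts, class = c("agreement_table", class(counts)))
}

#' @export
print.agreement_table <- function(x, ...) {
  cat("<agreement_table> level-wise allocation agreement\n")
  NextMethod()
}

#' @export
tidy.agreement_table <- function(x, ...) tibble::as_tibble(unclass(x))

#' @export
glance.agreement_table <- function(x, ...) {
  tibble::tibble(
    n_levels = nrow(x),
    min_sum_of_agreement_pct = min(x$sum_of_agreement_pct),
    max_sum_of_agreement_pct = max(x$sum_of_agreement_pct)
  )
}

#' Pearson correlation between manual and automated counts
#'
#' @param x,y Numeric vectors of equal length (n >= 3), e.g. per-section
#'   manual and automated sphere counts.
#' @return Tibble `r`, `r_squared`, `statistic` (t), `df`, `p_value`
#'   (two-sided, from the t distribution with n - 2 df).
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in x or y", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  tibble::tibble(
    r = unname(ct$estimate),
    r_squared = unname(ct$estimate)^2,
    statistic = unname(ct$statistic),
    df = unname(ct$parameter),
    p_value = ct$p.value
  )
}

#' Paired or independent-samples t test for sphere counts
#'
#' Thin wrapper with the conventions used for count comparisons in this
#' workflow: two-sided, alpha 0.05, and (for the independent test)
#' pooled-variance Student's t by default, with Welch's correction available
#' via `welch = TRUE`.
#'
#' @param a,b Numeric vectors (equal length when `mode = "paired"`).
#' @param mode `"paired"` or `"independent"`.
#' @param welch Use Welch's unequal-variance t (independent mode only).
#' @return Tibble `statistic` (t), `df`, `p_value`, `mean_a`, `mean_b`,
#'   `significant` (p < 0.05).
#' @export
t_test_counts <- function(a, b, mode = c("paired", "independent"),
                          welch = FALSE) {
  mode <- match.arg(mode)
  if (mode == "paired") {
    if (length(a) != length(b)) {
      stop("paired test needs equal lengths", call. = FALSE)
    }
    if (length(a) < 2) stop("need at least 2 pairs", call. = FALSE)
    if (stats::sd(a - b) == 0) {
      if (all(a == b)) {
        # identical samples: t is 0 by definition, not indeterminate
        return(tibble::tibble(statistic = 0, df = length(a) - 1,
                              p_value = 1, mean_a = mean(a),
                              mean_b = mean(b), significant = FALSE))
      }
      stop("paired differences have zero variance", call. = FALSE)
    }
    tt <- stats::t.test(a, b, paired = TRUE)
  } else {
    if (length(a) < 2 || length(b) < 2) {
      stop("need at least 2 observations per group", call. = FALSE)
    }
    tt <- stats::t.test(a, b, paired = FALSE, var.equal = !welch)
  }
  tibble::tibble(
    statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = tt$p.value,
    mean_a = mean(a), mean_b = mean(b),
    significant = tt$p.value < 0.05
  )
}

#' Percentage of spheres lost between block-face imaging and histology
#'
#' Sections handled after cutting can shed spheres; comparing counts from
#' block-face images (taken before the section is removed) with counts on
#' the mounted histologic sections measures that loss.
#'
#' @param blockface_count Spheres counted in block-face images (> 0).
#' @param histology_count Spheres recovered on histologic sections.
#' @return Percent lost, `100 * (blockface - histology) / blockface`. A
#'   histology count exceeding the block-face count yields a warning and a
#'   negative loss.
#' @export
#' @examples
#' loss_percentage(200, 185) # 7.5
loss_percentage <- function(blockface_count, histology_count) {
  if (any(blockface_count <= 0)) {
    stop("blockface_count must be positive", call. = FALSE)
  }
  if (any(histology_count > blockface_count)) {
    warning("histology count exceeds block-face count; negative loss")
  }
  100 * (blockface_count - histology_count) / blockface_count
}
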