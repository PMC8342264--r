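#' Hierarchical atlas ontology
#'
#' An atlas ontology is a rooted tree of brain structures in the style of the
#' Allen mouse brain structure graph: every node has an integer `id`, a
#' `name`, and a `parent_id` (`NA` for the root). Levels are counted from the
#' root, which sits at level 1; in the reference atlas level 2 splits into
#' gray matter, fiber tracts and ventricular systems, and branches extend to
#' at most level 12. Not every branch reaches the same depth, which is why
#' level-wise queries can return "not at this level".
#'
#' @param nodes A data frame with columns `id`, `name`, `parent_id`
#'   (`NA` for the single root). A `level` column, if present, is validated;
#'   otherwise levels are derived by walking parent chains.
#' @return An `atlas_ontology` object: a tibble of nodes
#'   (`id`, `name`, `parent_id`, `level`) with lookup tables attached.
#' @export
#' @examples
#' ont <- atlas_ontology(data.frame(
#'   id = 1:4, name = c("root", "gray", "fiber", "cortex"),
#'   parent_id = c(NA, 1, 1, 2)
#' ))
#' ont$level
atlas_ontology <- function(nodes) {
  nodes <- tibble::as_tibble(nodes)
  req <- c("id", "name", "parent_id")
  if (!all(req %in% names(nodes))) {
    stop("`nodes` needs columns id, name, parent_id", call. = FALSE)
  }
  if (anyDuplicated(nodes$id)) stop("duplicate ontology ids", call. = FALSE)
  roots <- which(is.na(nodes$parent_id))
  if (length(roots) != 1L) {
    stop("ontology must have exactly one root (parent_id = NA)", call. = FALSE)
  }
  parent <- nodes$parent_id
  names(parent) <- as.character(nodes$id)
  missing_parent <- !is.na(parent) & !(parent %in% nodes$id)
  if (any(missing_parent)) {
    stop("parent_id refers to unknown node(s): ",
         paste(parent[missing_parent], collapse = ", "), call. = FALSE)
  }

  # derive levels by parent-chain depth; also detects cycles
  level <- rep(NA_integer_, nrow(nodes))
  names(level) <- names(parent)
  for (i in seq_len(nrow(nodes))) {
    id <- as.character(nodes$id[i])
    chain <- character(0)
    cur <- id
    while (is.na(level[cur])) {
      chain <- c(chain, cur)
      p <- parent[cur]
      if (is.na(p)) {
        level[cur] <- 1L
        break
      }
      cur <- as.character(p)
      if (cur %in% chain) stop("ontology contains a cycle", call. = FALSE)
    }
    if (length(chain)) {
      base <- level[cur]
      # chain runs from the query node down to the first resolved ancestor
      level[chain] <- base + rev(seq_along(chain)) -
        if (chain[length(chain)] == cur) 1L else 0L
    }
  }
  if ("level" %in% names(nodes) &&
      !all(nodes$level == unname(level[as.character(nodes$id)]))) {
    stop("supplied `level` column disagrees with parent-chain depth",
         call. = FALSE)
  }
  nodes$level <- unname(level[as.character(nodes$id)])
  nodes <- nodes[, c("id", "name", "parent_id", "level")]
  structure(nodes,
            class = c("atlas_ontology", class(nodes)),
            parent = parent,
            node_level = level,
            node_name = stats::setNames(nodes$name, as.character(nodes$id)))
}

#' @export
print.atlas_ontology <- function(x, ...) {
  cat(sprintf("<atlas_ontology> %d structures, levels 1-%d\n",
              nrow(x), max(x$level)))
  NextMethod()
}

#' Read an ontology from an Allen-style structure-graph JSON file
#'
#' Accepts either a flat array of objects with `id`, `name` and
#' `parent_structure_id` fields, or the nested form where each node carries a
#' `children` array (the `msg` wrapper of the Allen API is unwrapped if
#' present).
#'
#' @param path Path to the JSON file.
#' @return An [atlas_ontology].
#' @export
read_ontology_json <- function(path) {
  x <- jsonlite::read_json(path)
  if (!is.null(x$msg)) x <- x$msg
  flat <- list()
  walk <- function(node, parent_id) {
    flat[[length(flat) + 1L]] <<- tibble::tibble(
      id = as.integer(node$id),
      name = as.character(node$name),
      parent_id = parent_id
    )
    for (ch in node$children %||% list()) walk(ch, as.integer(node$id))
  }
  if (length(x) && !is.null(x[[1]]$children)) {
    for (nd in x) walk(nd, NA_integer_)
    nodes <- dplyr::bind_rows(flat)
  } else {
    nodes <- dplyr::bind_rows(lapply(x, function(nd) tibble::tibble(
      id = as.integer(nd$id),
      name = as.character(nd$name),
      parent_id = if (is.null(nd$parent_structure_id) ||
                      is.na(nd$parent_structure_id)) NA_integer_
                  else as.integer(nd$parent_structure_id)
    )))
  }
  atlas_ontology(nodes)
}

#' Write an ontology to flat structure-graph JSON
#'
#' @param ontology An [atlas_ontology].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ontology_json <- function(ontology, path) {
  recs <- purrr::pmap(
    list(ontology$id, ontology$name, ontology$parent_id),
    function(id, name, parent_id) {
      list(id = id, name = name,
           parent_structure_id = if (is.na(parent_id)) NULL else parent_id)
    }
  )
  jsonlite::write_json(recs, path, auto_unbox = TRUE, null = "null")
  invisible(path)
}

ontology_parent <- function(ontology) attr(ontology, "parent")
ontology_level <- function(ontology) attr(ontology, "node_level")

#' Ancestor of a structure at a given ontology level
#'
#' Walks the parent chain of each structure until the requested level is
#' reached. A structure whose own level is shallower than `level` has no
#' ancestor there; such queries return `NA`, the "not at this level" state
#' used by level-wise agreement tables.
#'
#' @param ontology An [atlas_ontology].
#' @param ids Integer vector of structure ids (`NA` passes through as `NA`).
#' @param level Target level (1 = root).
#' @return Integer vector: the ancestor-or-self id at `level`, or `NA` when
#'   the structure does not extend to that level.
#' @export
ancestor_at_level <- function(ontology, ids, level) {
  stopifnot(length(level) == 1L, level >= 1)
  parent <- ontology_parent(ontology)
  lev <- ontology_level(ontology)
  key <- as.character(ids)
  unknown <- !is.na(ids) & !(key %in% names(lev))
  if (any(unknown)) {
    stop("unknown ontology id(s): ",
         paste(unique(ids[unknown]), collapse = ", "), call. = FALSE)
  }
  vapply(key, function(k) {
    if (is.na(k) || k == "NA") return(NA_integer_)
    if (lev[k] < level) return(NA_integer_)  # not at this level
    while (lev[k] > level) k <- as.character(parent[k])
    as.integer(k)
  }, integer(1), USE.NAMES = FALSE)
}

#' Full root-to-structure path
#'
#' @param ontology An [atlas_ontology].
#' @param id A single structure id.
#' @return Integer vector of ids from the root down to `id`.
#' @export
ontology_path <- function(ontology, id) {
  parent <- ontology_parent(ontology)
  k <- as.character(id)
  if (!k %in% names(parent)) stop("unknown ontology id: ", id, call. = FALSE)
  path <- integer(0)
  while (!is.na(k) && k != "NA") {
    path <- c(as.integer(k), path)
    k <- as.character(parent[k])
  }
  path
}

#' Roll leaf counts up the ontology
#'
#' Computes, for every structure, its direct count and its cumulative count
#' (direct plus all descendants). Counts on ids absent from the ontology are
#' an error; the root's cumulative count therefore equals the total of all
#' supplied counts.
#'
#' @param ontology An [atlas_ontology].
#' @param counts Either a data frame with columns `id` and `n`, or a vector
#'   of structure ids (one per detection) to be tabulated; `NA` ids
#'   (unaccounted detections) are dropped with no contribution.
#' @return A tibble `id`, `name`, `level`, `n_direct`, `n_total`, ordered as
#'   the ontology.
#' @export
aggregate_counts <- function(ontology, counts) {
  if (is.data.frame(counts)) {
    stopifnot(all(c("id", "n") %in% names(counts)))
    ids <- counts$id
    n <- counts$n
  } else {
    tab <- table(counts[!is.na(counts)])
    ids <- as.integer(names(tab))
    n <- as.integer(tab)
  }
  if (any(is.na(ids))) {
    keep <- !is.na(ids)
    ids <- ids[keep]; n <- n[keep]
  }
  if (!all(ids %in% ontology$id)) {
    stop("counts on unknown ontology id(s): ",
         paste(setdiff(ids, ontology$id), collapse = ", "), call. = FALSE)
  }
  direct <- stats::setNames(rep(0, nrow(ontology)), as.character(ontology$id))
  if (length(ids)) {
    agg <- tapply(n, as.character(ids), sum)
    direct[names(agg)] <- direct[names(agg)] + as.numeric(agg)
  }
  total <- direct
  parent <- ontology_parent(ontology)
  # push counts upward, deepest level first
  ord <- order(ontology$level, decreasing = TRUE)
  for (i in ord) {
    k <- as.character(ontology$id[i])
    p <- parent[k]
    if (!is.na(p)) {
      total[as.character(p)] <- total[as.character(p)] + total[k]
    }
  }
  tibble::tibble(
    id = ontology$id,
    name = ontology$name,
    level = ontology$level,
    n_direct = unname(direct[as.character(ontology$id)]),
    n_total = unname(total[as.character(ontology$id)])
  )
}

#' Select terminal reporting branches by a minimum-count criterion
#'
#' Walks the ontology from the root and only descends into a structure's
#' subdivisions when that structure holds at least `min_count` spheres
#' (cumulative); otherwise the structure is reported as a terminal branch at
#' its own level. Children of an expanded structure that themselves fail the
#' criterion become terminal where they stand. The resulting terminal set is
#' a frontier: every counted sphere belongs to exactly one terminal branch.
#'
#' @param ontology An [atlas_ontology].
#' @param counts Output of [aggregate_counts()], or anything it accepts.
#' @param min_count Minimum cumulative spheres required to keep subdividing
#'   (default 5).
#' @param max_level Optional deepest level to descend to.
#' @param expand_rule `"parent"` (default) tests the structure being expanded
#'   against `min_count`; `"children"` instead requires each child to meet it
#'   before that child may be expanded further (the parent is always split
#'   whenever any child has spheres).
#' @return Tibble of terminal branches: `id`, `name`, `level`, `count`, plus
#'   `direct_only` marking rows that capture spheres recorded directly on an
#'   expanded structure (rather than on its subdivisions).
#' @export
select_terminal_branches <- function(ontology, counts, min_count = 5,
                                     max_level = NULL,
                                     expand_rule = c("parent", "children")) {
  expand_rule <- match.arg(expand_rule)
  if (!is.data.frame(counts) || !all(c("n_total", "n_direct") %in% names(counts))) {
    counts <- aggregate_counts(ontology, counts)
  }
  n_total <- stats::setNames(counts$n_total, as.character(counts$id))
  n_direct <- stats::setNames(counts$n_direct, as.character(counts$id))
  lev <- ontology_level(ontology)
  nm <- attr(ontology, "node_name")
  children <- split(ontology$id, as.character(ontology$parent_id))
  root <- ontology$id[is.na(ontology$parent_id)]

  out <- list()
  add <- function(id, count, direct_only) {
    out[[length(out) + 1L]] <<- tibble::tibble(
      id = id, name = unname(nm[as.character(id)]),
      level = unname(lev[as.character(id)]),
      count = count, direct_only = direct_only
    )
  }
  visit <- function(id) {
    k <- as.character(id)
    kids <- children[[k]]
    expandable <- length(kids) > 0 &&
      (is.null(max_level) || lev[k] < max_level)
    expand <- expandable && switch(expand_rule,
      parent = n_total[k] >= min_count,
      children = n_total[k] >= min_count && any(n_total[as.character(kids)] > 0)
    )
    if (!expand) {
      add(id, unname(n_total[k]), FALSE)
      return(invisible(NULL))
    }
    if (n_direct[k] > 0) add(id, unname(n_direct[k]), TRUE)
    for (ch in kids) {
      if (expand_rule == "children" && n_total[as.character(ch)] < min_count) {
        add(ch, unname(n_total[as.character(ch)]), FALSE)
      } else {
        visit(ch)
      }
    }
  }
  visit(root)
  dplyr::bind_rows(out)
}

#' Map structures to their covering terminal branch
#'
#' @param ontology An [atlas_ontology].
#' @param ids Structure ids (possibly `NA` for unaccounted detections).
#' @param terminal Output of [select_terminal_branches()].
#' @return Integer vector of terminal branch ids (`NA` where unaccounted).
#' @export
terminal_branch_of <- function(ontology, ids, terminal) {
  parent <- ontology_parent(ontology)
  tset <- as.character(terminal$id[!terminal$direct_only])
  tset_direct <- as.character(terminal$id)
  vapply(as.character(ids), function(k) {
    if (is.na(k) || k == "NA") return(NA_integer_)
    k0 <- k
    while (!is.na(k) && k != "NA") {
      if (k %in% tset || (k == k0 && k %in% tset_direct)) return(as.integer(k))
      k <- as.character(parent[k])
    }
    NA_integer_
  }, integer(1), USE.NAMES = FALSE)
}
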