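## Hierarchical flow-cytometry gate counts and proportions.
##
## Gates are stored as raw counts; proportions are derived on demand so the
## ten-cell parent-gate validity rule is applied uniformly at analysis time.

#' Build a gating tree from count records
#'
#' @param count_records Tibble with columns `gate_path` (slash-separated,
#'   e.g. `CD3/TCRgdpos/Vd1/CD103pos`) and `cell_count`; optional
#'   `patient_id` and `compartment` are carried along. All records must
#'   belong to one sample. Every non-root path must have its parent present
#'   and no child count may exceed its parent count.
#'
#' @return Object of class `gating_tree`: named integer count vector plus
#'   sample identity.
#' @export
build_gating_tree <- function(count_records) {
  stopifnot(all(c("gate_path", "cell_count") %in% names(count_records)))
  counts <- count_records$cell_count
  paths <- count_records$gate_path
  if (anyDuplicated(paths)) {
    abort(sprintf("duplicated gate path(s): %s",
                  paste(unique(paths[duplicated(paths)]), collapse = ", ")),
          class = "tcrdens_consistency_error")
  }
  if (any(is.na(counts)) || any(counts < 0)) {
    abort("cell counts must be non-negative", class = "tcrdens_consistency_error")
  }
  names(counts) <- paths
  is_root <- !grepl("/", paths, fixed = TRUE)
  if (!any(is_root)) {
    abort("gating tree has no root gate", class = "tcrdens_consistency_error")
  }
  parents <- parent_path(paths)
  for (i in which(!is_root)) {
    p <- parents[i]
    if (!p %in% paths) {
      abort(sprintf("gate '%s' has no parent gate '%s'", paths[i], p),
            class = "tcrdens_consistency_error")
    }
    if (counts[[paths[i]]] > counts[[p]]) {
      abort(sprintf("gate '%s' (%d cells) exceeds its parent '%s' (%d cells)",
                    paths[i], counts[[paths[i]]], p, counts[[p]]),
            class = "tcrdens_consistency_error")
    }
  }
  structure(
    list(
      counts = counts,
      patient_id = if ("patient_id" %in% names(count_records))
        count_records$patient_id[1] else NA_character_,
      compartment = if ("compartment" %in% names(count_records))
        count_records$compartment[1] else NA_character_
    ),
    class = "gating_tree"
  )
}

parent_path <- function(path) sub("/[^/]+$", "", path)

#' @export
print.gating_tree <- function(x, ...) {
  cat("<gating_tree>", length(x$counts), "gates;",
      x$patient_id, x$compartment, "\n")
  invisible(x)
}

#' Gate proportion under the ten-cell parent rule
#'
#' The proportion of a child gate relative to its parent gate is defined only
#' when the parent contains at least ten cells; otherwise the proportion is
#' undefined and flagged invalid.
#'
#' @param tree A [build_gating_tree()] result.
#' @param child_path Slash-separated gate path (must not be a root).
#' @return Object of class `gate_proportion`: `value` (fraction or `NA`),
#'   `parent_count`, `child_count`, `valid`.
#' @export
gate_proportion <- function(tree, child_path) {
  stopifnot(inherits(tree, "gating_tree"))
  if (!child_path %in% names(tree$counts)) {
    abort(sprintf("unknown gate path '%s'", child_path),
          class = "tcrdens_lookup_error")
  }
  if (!grepl("/", child_path, fixed = TRUE)) {
    abort(sprintf("'%s' is a root gate and has no parent", child_path),
          class = "tcrdens_lookup_error")
  }
  parent <- parent_path(child_path)
  pc <- unname(tree$counts[[parent]])
  cc <- unname(tree$counts[[child_path]])
  valid <- pc >= 10L
  structure(
    list(value = if (valid) cc / pc else NA_real_,
         parent_count = pc, child_count = cc, valid = valid,
         child_path = child_path),
    class = "gate_proportion"
  )
}

#' @export
print.gate_proportion <- function(x, ...) {
  cat(sprintf("<gate_proportion> %s: %s (%d/%d, %s)\n", x$child_path,
              if (x$valid) format(x$value) else "undefined",
              x$child_count, x$parent_count,
              if (x$valid) "valid" else "parent < 10 cells"))
  invisible(x)
}

#' CD45RA x CD27 memory quadrant proportions of a lineage gate
#'
#' Returns the four quadrant proportions (T_EM = CD45RA-CD27-, T_CM =
#' CD45RA-CD27+, naive_like = CD45RA+CD27+, T_EMRA = CD45RA+CD27-) sharing
#' the lineage gate as parent. When all four are valid the defined
#' proportions sum to 1 (within 1e-9) provided the quadrants partition the
#' parent.
#'
#' @param tree A [build_gating_tree()] result.
#' @param lineage_path Path of the lineage gate (e.g. `CD3/TCRgdpos/Vd1`).
#' @return Named list of [gate_proportion()] objects
#'   (`T_EM`, `T_CM`, `naive_like`, `T_EMRA`).
#' @export
memory_quadrants <- function(tree, lineage_path) {
  paths <- paste0(lineage_path, "/", .quadrant_gates)
  missing_gates <- paths[!paths %in% names(tree$counts)]
  if (length(missing_gates) > 0) {
    abort(sprintf("missing quadrant gate(s): %s",
                  paste(missing_gates, collapse = ", ")),
          class = "tcrdens_lookup_error")
  }
  out <- lapply(paths, gate_proportion, tree = tree)
  names(out) <- names(.quadrant_gates)
  out
}
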