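#' Constraint hierarchies
#'
#' A constraint hierarchy is a single-rooted tree of clusters. Each node
#' carries the constraints specific to it: an alignment column, an allowed
#' residue set, and a positive weight in nats (the log-likelihood
#' contribution describing how specific the constraint is to the cluster).
#' The *effective* constraint set of a node is the union of its own and all
#' its ancestors' constraints — members of a subcluster are expected to
#' satisfy the supercluster's constraints as well as their own.
#'
#' Stored as a tibble with one row per node and columns `id`, `name`,
#' `parent_id` (`NA` for the root), `constraints` (list of tibbles with
#' `column`, `residues`, `weight`) and `members` (list of character vectors
#' of sequence ids; may be empty for model files). Attributes carry
#' `n_columns` and, when computed, `total_lpr`.
#'
#' @param nodes A data frame with columns `id`, `name`, `parent_id`,
#'   `constraints` and optionally `members`.
#' @param n_columns Width of the alignment the hierarchy refers to.
#' @param total_lpr Optional total log-probability ratio in nats.
#' @return A `kc_hierarchy` tibble.
#' @export
constraint_hierarchy <- function(nodes, n_columns, total_lpr = NULL) {
  nodes <- as_tibble(nodes)
  req <- c("id", "name", "parent_id", "constraints")
  if (!all(req %in% names(nodes))) {
    abort("`nodes` must have id, name, parent_id and constraints columns")
  }
  if (anyDuplicated(nodes$id)) abort("duplicated node ids")
  roots <- which(is.na(nodes$parent_id))
  if (length(roots) != 1) abort("hierarchy must have exactly one root")
  known <- nodes$parent_id %in% nodes$id | is.na(nodes$parent_id)
  if (!all(known)) abort("parent_id refers to unknown node")
  nodes$constraints <- map(nodes$constraints, validate_constraints,
                           n_columns = n_columns)
  if (!"members" %in% names(nodes)) {
    nodes$members <- rep(list(character(0)), nrow(nodes))
  }
  # reachability / acyclicity check via repeated parent hops
  for (id in nodes$id) {
    seen <- character(0)
    cur <- id
    repeat {
      if (cur %in% seen) abort("cycle detected in hierarchy")
      seen <- c(seen, cur)
      p <- nodes$parent_id[nodes$id == cur]
      if (is.na(p)) break
      cur <- p
    }
  }
  out <- new_tibble(nodes[, c("id", "name", "parent_id", "constraints",
                              "members")],
                    class = "kc_hierarchy")
  attr(out, "n_columns") <- as.integer(n_columns)
  attr(out, "total_lpr") <- total_lpr
  out
}

validate_constraints <- function(cons, n_columns) {
  cons <- as_tibble(cons)
  if (nrow(cons) == 0) {
    return(tibble(column = integer(0), residues = character(0),
                  weight = numeric(0)))
  }
  if (!all(c("column", "residues", "weight") %in% names(cons))) {
    abort("constraints need column, residues, weight")
  }
  if (any(cons$weight <= 0)) abort("constraint weights must be positive")
  if (any(cons$column < 1 | cons$column > n_columns)) {
    abort("constraint column out of range")
  }
  if (anyDuplicated(cons$column)) {
    abort("constraint columns must be unique within a node")
  }
  bad <- !map_lgl(strsplit(cons$residues, "", fixed = TRUE),
                  function(r) length(r) > 0 && all(r %in% kc_alphabet))
  if (any(bad)) abort("constraint residue sets must be non-empty amino acids")
  cons$column <- as.integer(cons$column)
  cons
}

#' @export
print.kc_hierarchy <- function(x, ...) {
  cat(sprintf(
    "# Constraint hierarchy: %d nodes, %d constraints, %d alignment columns\n",
    nrow(x), sum(map_int(x$constraints, nrow)), attr(x, "n_columns")))
  if (!is.null(attr(x, "total_lpr"))) {
    cat(sprintf("# Total LPR: %.2f nats\n", attr(x, "total_lpr")))
  }
  NextMethod()
}

hierarchy_root <- function(h) h$id[is.na(h$parent_id)]

hierarchy_children <- function(h, id) h$id[!is.na(h$parent_id) &
                                             h$parent_id == id]

hierarchy_leaves <- function(h) {
  h$id[!(h$id %in% h$parent_id[!is.na(h$parent_id)])]
}

#' Ancestor node ids, root first, excluding the node itself
#' @param h A `kc_hierarchy`.
#' @param id Node id.
#' @return Character vector of ancestor ids.
#' @export
node_ancestors <- function(h, id) {
  out <- character(0)
  cur <- h$parent_id[h$id == id]
  while (length(cur) == 1 && !is.na(cur)) {
    out <- c(cur, out)
    cur <- h$parent_id[h$id == cur]
  }
  out
}

node_path <- function(h, id) c(node_ancestors(h, id), id)

node_subtree <- function(h, id) {
  out <- id
  frontier <- id
  while (length(frontier) > 0) {
    kids <- h$id[!is.na(h$parent_id) & h$parent_id %in% frontier]
    out <- c(out, kids)
    frontier <- kids
  }
  out
}

node_members <- function(h, id) h$members[[which(h$id == id)]]

node_constraints <- function(h, id) h$constraints[[which(h$id == id)]]

#' Effective constraints of a node
#'
#' The node's own constraints plus those of every ancestor (nested
#' semantics). The returned tibble gains an `origin` column naming the node
#' each constraint was defined on.
#'
#' @inheritParams node_ancestors
#' @return Tibble with `origin`, `column`, `residues`, `weight`.
#' @export
effective_constraints <- function(h, id) {
  if (!id %in% h$id) abort(sprintf("unknown node '%s'", id))
  ids <- node_path(h, id)
  bind_rows(lapply(ids, function(i) {
    cons <- node_constraints(h, i)
    if (nrow(cons) == 0) return(NULL)
    mutate(cons, origin = i, .before = 1)
  }))
}

#' Serialize a constraint hierarchy to JSON
#'
#' The JSON model file is the interchange format between inference and
#' scoring: a `nodes` array with `id`, `name`, `parent_id` and
#' `constraints` (1-based `column`, `residues`, `weight`), plus `n_columns`
#' and `total_lpr`.
#'
#' @param h A `kc_hierarchy`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(h, path) {
  nodes <- lapply(seq_len(nrow(h)), function(i) {
    list(id = h$id[i], name = h$name[i],
         parent_id = if (is.na(h$parent_id[i])) NULL else h$parent_id[i],
         constraints = lapply(seq_len(nrow(h$constraints[[i]])), function(j) {
           cc <- h$constraints[[i]][j, ]
           list(column = cc$column, residues = cc$residues,
                weight = cc$weight)
         }))
  })
  obj <- list(n_columns = attr(h, "n_columns"),
              total_lpr = attr(h, "total_lpr"),
              nodes = nodes)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a constraint hierarchy from a JSON model file
#' @param path Path to a model written by [write_model()].
#' @return A `kc_hierarchy` (with empty memberships).
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path)
  nodes <- tibble(
    id = map_chr(obj$nodes, "id"),
    name = map_chr(obj$nodes, "name"),
    parent_id = map_chr(obj$nodes, function(n) n$parent_id %||%
                          NA_character_),
    constraints = map(obj$nodes, function(n) {
      if (length(n$constraints) == 0) {
        tibble(column = integer(0), residues = character(0),
               weight = numeric(0))
      } else {
        tibble(column = map_int(n$constraints, function(cc)
          as.integer(cc$column)),
          residues = map_chr(n$constraints, "residues"),
          weight = map_dbl(n$constraints, "weight"))
      }
    })
  )
  constraint_hierarchy(nodes, n_columns = obj$n_columns,
                       total_lpr = obj$total_lpr)
}

#' @describeIn constraint_hierarchy Tidy the constraints: one row per
#'   (node, constraint).
#' @param x A `kc_hierarchy`.
#' @param ... Unused.
#' @method tidy kc_hierarchy
#' @export
tidy.kc_hierarchy <- function(x, ...) {
  out <- bind_rows(lapply(seq_len(nrow(x)), function(i) {
    cons <- x$constraints[[i]]
    if (nrow(cons) == 0) return(NULL)
    mutate(cons, node_id = x$id[i], name = x$name[i],
           parent_id = x$parent_id[i], .before = 1)
  }))
  if (is.null(out) || nrow(out) == 0) {
    return(tibble(node_id = character(0), name = character(0),
                  parent_id = character(0), column = integer(0),
                  residues = character(0), weight = numeric(0)))
  }
  out
}

#' @describeIn constraint_hierarchy One-row summary of the model.
#' @method glance kc_hierarchy
#' @export
glance.kc_hierarchy <- function(x, ...) {
  tibble(
    n_nodes = nrow(x),
    n_leaves = length(hierarchy_leaves(x)),
    n_constraints = sum(map_int(x$constraints, nrow)),
    n_columns = attr(x, "n_columns"),
    total_lpr = attr(x, "total_lpr") %||% NA_real_
  )
}
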