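#' Construct a directed acyclic graph over named variables
#'
#' A lightweight DAG container used throughout the package: an ordered node
#' set plus a set of directed edges. Construction validates acyclicity,
#' rejects self-loops and duplicate edges, and requires every edge endpoint
#' to be a declared node.
#'
#' @param nodes character vector of variable names (order is kept and used
#'   for display; canonical orderings elsewhere are alphabetical).
#' @param edges edges as a two-column matrix/data.frame (parent, child), a
#'   character vector of `"parent->child"` strings, or `NULL` for an
#'   edgeless graph.
#' @return An object of class `ase_dag` with elements `nodes` (character)
#'   and `edges` (two-column character matrix with columns `from`, `to`).
#' @examples
#' g <- dag(c("X", "Y", "Z"), c("X->Y", "Y->Z"))
#' is_d_separated(g, "X", "Z", "Y")
#' @export
dag <- function(nodes, edges = NULL) {
  stopifnot(is.character(nodes), length(nodes) >= 1, !anyDuplicated(nodes))
  em <- parse_edges(edges)
  if (nrow(em) > 0) {
    unknown <- setdiff(c(em), nodes)
    if (length(unknown) > 0) {
      stop("edge endpoint(s) not in node set: ", paste(unknown, collapse = ", "))
    }
    if (any(em[, 1] == em[, 2])) stop("self-loops are not allowed")
    if (anyDuplicated(paste(em[, 1], em[, 2]))) stop("duplicate edges are not allowed")
  }
  g <- structure(list(nodes = nodes, edges = em), class = "ase_dag")
  if (is.null(topological_order(g))) stop("graph is cyclic: no topological order exists")
  g
}

parse_edges <- function(edges) {
  if (is.null(edges) || (is.atomic(edges) && length(edges) == 0)) {
    return(matrix(character(0), ncol = 2, dimnames = list(NULL, c("from", "to"))))
  }
  if (is.character(edges) && !is.matrix(edges)) {
    parts <- strsplit(gsub("\\s", "", edges), "->", fixed = TRUE)
    if (any(lengths(parts) != 2)) stop("edge strings must look like 'parent->child'")
    em <- do.call(rbind, parts)
  } else {
    em <- as.matrix(edges)
    if (ncol(em) != 2) stop("edges must have two columns (parent, child)")
    em <- matrix(as.character(em), ncol = 2)
  }
  dimnames(em) <- list(NULL, c("from", "to"))
  em
}

#' @export
print.ase_dag <- function(x, ...) {
  cat("DAG with", length(x$nodes), "nodes:", paste(x$nodes, collapse = ", "), "\n")
  if (nrow(x$edges) == 0) cat("  (no edges)\n")
  else cat("  edges:", paste(paste0(x$edges[, 1], "->", x$edges[, 2]), collapse = ", "), "\n")
  invisible(x)
}

edge_labels <- function(dag) {
  if (nrow(dag$edges) == 0) character(0)
  else paste0(dag$edges[, 1], "->", dag$edges[, 2])
}

has_edge <- function(dag, from, to) {
  any(dag$edges[, 1] == from & dag$edges[, 2] == to)
}

dag_parents <- function(dag, node) dag$edges[dag$edges[, 2] == node, 1]

dag_children <- function(dag, node) dag$edges[dag$edges[, 1] == node, 2]

# Kahn's algorithm; NULL when the graph has a cycle.
topological_order <- function(dag) {
  nodes <- dag$nodes
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  for (i in seq_len(nrow(dag$edges))) indeg[dag$edges[i, 2]] <- indeg[dag$edges[i, 2]] + 1L
  out <- character(0)
  avail <- names(indeg)[indeg == 0L]
  while (length(avail) > 0) {
    v <- avail[1]
    avail <- avail[-1]
    out <- c(out, v)
    for (ch in dag_children(dag, v)) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) avail <- c(avail, ch)
    }
  }
  if (length(out) != length(nodes)) NULL else out
}

# Reflexive-transitive closure along edge direction.
dag_ancestors <- function(dag, nodes) {
  seen <- nodes
  frontier <- nodes
  while (length(frontier) > 0) {
    pa <- unique(unlist(lapply(frontier, dag_parents, dag = dag)))
    frontier <- setdiff(pa, seen)
    seen <- union(seen, frontier)
  }
  seen
}

dag_descendants <- function(dag, nodes) {
  seen <- nodes
  frontier <- nodes
  while (length(frontier) > 0) {
    ch <- unique(unlist(lapply(frontier, dag_children, dag = dag)))
    frontier <- setdiff(ch, seen)
    seen <- union(seen, frontier)
  }
  seen
}

check_names <- function(dag, vars, what = "variable") {
  unknown <- setdiff(vars, dag$nodes)
  if (length(unknown) > 0) {
    stop("unknown ", what, " name(s): ", paste(unknown, collapse = ", "))
  }
  invisible(TRUE)
}

#' The ASE causal graphs
#'
#' `dag_j0()` returns the directed acyclic graph implied by the allostatic
#' self-efficacy theory over age (A), gender (G), metacognition of allostatic
#' control (M), fatigue (F), general self-efficacy (S) and depression (D):
#' age and gender feed every questionnaire variable, metacognition drives
#' fatigue, and fatigue and self-efficacy drive depression. `dag_j1()` is the
#' revised graph that additionally lets metacognition of allostatic control
#' influence general self-efficacy (edge M->S), the single-edge revision
#' favoured by conditional-independence testing on the PBIHB cohort.
#'
#' @return An `ase_dag`.
#' @examples
#' is_d_separated(dag_j0(), "M", "S", c("A", "G"))  # TRUE
#' is_d_separated(dag_j1(), "M", "S", c("A", "G"))  # FALSE
#' @export
dag_j0 <- function() {
  dag(
    c("A", "G", "M", "F", "S", "D"),
    c(
      "A->M", "G->M",
      "M->F", "A->F", "G->F",
      "A->S", "G->S",
      "F->D", "S->D", "A->D", "G->D"
    )
  )
}

#' @rdname dag_j0
#' @export
dag_j1 <- function() {
  g0 <- dag_j0()
  dag(g0$nodes, rbind(g0$edges, c("M", "S")))
}

#' Construct a conditional-independence statement
#'
#' @param x,y variable names (distinct).
#' @param z character vector of conditioning variables (may be empty); must
#'   not contain `x` or `y`.
#' @return An object of class `ase_ci_statement` with elements `x`, `y`, `z`
#'   (`z` sorted alphabetically).
#' @export
ci_statement <- function(x, y, z = character(0)) {
  stopifnot(is.character(x), is.character(y), length(x) == 1, length(y) == 1)
  z <- as.character(z)
  if (x == y) stop("x and y must differ")
  if (x %in% z || y %in% z) stop("conditioning set must not contain x or y")
  structure(list(x = x, y = y, z = sort(z)), class = "ase_ci_statement")
}

#' @export
print.ase_ci_statement <- function(x, ...) {
  cat(format_ci_statement(x), "\n")
  invisible(x)
}

format_ci_statement <- function(s) {
  if (length(s$z) == 0) paste0(s$x, " _||_ ", s$y)
  else paste0(s$x, " _||_ ", s$y, " | ", paste(s$z, collapse = ","))
}

#' Decide d-separation in a DAG
#'
#' Tests whether `x` and `y` are d-separated given the set `z`, i.e. whether
#' every path between them is blocked: a chain or fork is blocked when its
#' middle node is in `z`; a collider is blocked when neither the collider nor
#' any of its descendants is in `z`. The implementation uses reachability on
#' the moralized ancestral subgraph, which is equivalent to the path
#' definition.
#'
#' @param dag an `ase_dag`.
#' @param x,y variable names.
#' @param z character vector of conditioning variables (possibly empty).
#' @return `TRUE` iff `x` and `y` are d-separated by `z`. Symmetric in
#'   `x` and `y`.
#' @export
is_d_separated <- function(dag, x, y, z = character(0)) {
  z <- as.character(z)
  check_names(dag, c(x, y, z))
  s <- ci_statement(x, y, z)
  # ancestral subgraph of {x, y} union z
  keep <- dag_ancestors(dag, c(s$x, s$y, s$z))
  em <- dag$edges[dag$edges[, 1] %in% keep & dag$edges[, 2] %in% keep, , drop = FALSE]
  # moralize: undirected skeleton plus marriages between co-parents
  adj <- lapply(stats::setNames(nm = keep), function(v) character(0))
  link <- function(a, b) {
    adj[[a]] <<- union(adj[[a]], b)
    adj[[b]] <<- union(adj[[b]], a)
  }
  for (i in seq_len(nrow(em))) link(em[i, 1], em[i, 2])
  for (v in keep) {
    pa <- em[em[, 2] == v, 1]
    if (length(pa) > 1) {
      for (i in seq_len(length(pa) - 1)) {
        for (j in seq(i + 1, length(pa))) link(pa[i], pa[j])
      }
    }
  }
  # delete z, then check connectivity x -- y
  frontier <- s$x
  seen <- c(s$z, s$x)  # z acts as removed
  while (length(frontier) > 0) {
    nb <- setdiff(unique(unlist(adj[frontier])), seen)
    if (s$y %in% nb) return(FALSE)
    seen <- c(seen, nb)
    frontier <- nb
  }
  TRUE
}

#' Enumerate the conditional independencies a DAG implies
#'
#' Returns every statement `x _||_ y | z` with `|z| <= max_cond_size` that
#' holds by d-separation, in a canonical deterministic order: pairs with
#' `x < y` alphabetically, ordered lexicographically by `x`, then `y`, then
#' the sorted conditioning set.
#'
#' @param dag an `ase_dag`.
#' @param max_cond_size largest conditioning-set size to enumerate; must be
#'   at most `length(dag$nodes) - 2`.
#' @return A list of `ase_ci_statement` objects.
#' @export
implied_ci_statements <- function(dag, max_cond_size) {
  stopifnot(max_cond_size >= 0, max_cond_size <= length(dag$nodes) - 2)
  nodes <- sort(dag$nodes)
  out <- list()
  for (x in nodes) {
    for (y in nodes[nodes > x]) {
      rest <- setdiff(nodes, c(x, y))
      subs <- all_subsets(rest, max_cond_size)
      keys <- vapply(subs, function(z) paste(z, collapse = ","), character(1))
      subs <- subs[order(keys)]
      for (z in subs) {
        if (is_d_separated(dag, x, y, z)) out[[length(out) + 1]] <- ci_statement(x, y, z)
      }
    }
  }
  out
}

all_subsets <- function(set, max_size) {
  out <- list(character(0))
  if (length(set) == 0 || max_size == 0) return(out)
  for (k in seq_len(min(max_size, length(set)))) {
    cmb <- utils::combn(set, k, simplify = FALSE)
    out <- c(out, cmb)
  }
  out
}

#' Check the backdoor criterion for an adjustment set
#'
#' A set `z` is a valid adjustment set (VAS) for estimating the effect of
#' `treatments` on `outcome` when (i) `z` contains no descendant of any
#' treatment and (ii) `z` blocks every backdoor path, i.e. every path from a
#' treatment to the outcome that starts with an edge into the treatment.
#' Condition (ii) is checked as d-separation in the graph with all edges out
#' of the treatments removed.
#'
#' @param dag an `ase_dag`.
#' @param treatments character vector of treatment variables.
#' @param outcome outcome variable name.
#' @param z candidate adjustment set (character, possibly empty).
#' @return `TRUE` iff `z` satisfies the backdoor criterion.
#' @export
is_valid_adjustment_set <- function(dag, treatments, outcome, z = character(0)) {
  z <- as.character(z)
  check_names(dag, c(treatments, outcome, z))
  if (length(intersect(treatments, z)) > 0) stop("treatments and z must be disjoint")
  if (outcome %in% c(treatments, z)) stop("outcome must not be a treatment or in z")
  desc <- dag_descendants(dag, treatments)
  if (length(intersect(z, desc)) > 0) return(FALSE)
  keep <- !(dag$edges[, 1] %in% treatments)
  g_back <- dag(dag$nodes, dag$edges[keep, , drop = FALSE])
  all(vapply(
    treatments,
    function(tr) is_d_separated(g_back, tr, outcome, union(z, setdiff(treatments, tr))),
    logical(1)
  ))
}

#' Score single-edge revisions of a DAG against CI test decisions
#'
#' Given the outcome of conditional-independence tests (per statement, was
#' the independence null rejected?), ranks the graphs obtained by adding one
#' directed edge to `dag` (plus the unmodified graph as baseline) by how well
#' their d-separation verdicts predict the decisions: a d-separated statement
#' predicts "not rejected", a d-connected one predicts "rejected"; each
#' disagreement counts one mismatch.
#'
#' By default candidate edges are restricted to pairs among the endogenous
#' questionnaire variables present in the graph (M, F, S, D) since age and
#' gender act as exogenous demographics; set `restrict_to = NULL` to consider
#' every node pair. Edges whose addition would create a cycle are skipped.
#'
#' @param dag an `ase_dag`.
#' @param decisions a list of entries `list(statement = <ase_ci_statement>,
#'   rejected = <logical>)`, or a data.frame with columns `x`, `y`, `z`
#'   (comma-separated names) and `rejected`.
#' @param restrict_to nodes among which candidate edges are drawn; default
#'   the intersection of `c("M","F","S","D")` with the graph's nodes, or all
#'   nodes when that intersection is empty. `NULL` lifts the restriction.
#' @return A data.frame with columns `edge` (`""` for the baseline graph),
#'   `mismatch`, sorted by ascending mismatch with lexicographic edge-label
#'   tie-break (the baseline sorts first in its group), and an attribute
#'   `dags` holding the candidate `ase_dag` objects in the same order.
#' @export
reconcile_single_edge <- function(dag, decisions, restrict_to = NULL) {
  decisions <- as_decision_list(dag, decisions)
  if (length(decisions) == 0) stop("decisions must be nonempty")
  if (is.null(restrict_to)) {
    pool <- intersect(c("M", "F", "S", "D"), dag$nodes)
    if (length(pool) == 0) pool <- dag$nodes
  } else if (identical(restrict_to, "all") || length(restrict_to) == 0) {
    pool <- dag$nodes
  } else {
    check_names(dag, restrict_to)
    pool <- restrict_to
  }
  cands <- list(list(edge = "", dag = dag))
  for (from in pool) {
    for (to in setdiff(pool, from)) {
      if (has_edge(dag, from, to)) next
      g_try <- tryCatch(dag(dag$nodes, rbind(dag$edges, c(from, to))), error = function(e) NULL)
      if (is.null(g_try)) next  # cycle
      cands[[length(cands) + 1]] <- list(edge = paste0(from, "->", to), dag = g_try)
    }
  }
  mism <- vapply(cands, function(cd) {
    sum(vapply(decisions, function(d) {
      dsep <- is_d_separated(cd$dag, d$statement$x, d$statement$y, d$statement$z)
      dsep == d$rejected  # verdict disagrees with decision
    }, logical(1)))
  }, integer(1))
  lab <- vapply(cands, `[[`, character(1), "edge")
  ord <- order(mism, lab)
  res <- data.frame(edge = lab[ord], mismatch = mism[ord], stringsAsFactors = FALSE)
  attr(res, "dags") <- lapply(cands[ord], `[[`, "dag")
  res
}

as_decision_list <- function(dag, decisions) {
  if (is.data.frame(decisions)) {
    decisions <- lapply(seq_len(nrow(decisions)), function(i) {
      z <- decisions$z[i]
      z <- if (is.na(z) || z == "") character(0) else strsplit(z, ",", fixed = TRUE)[[1]]
      list(
        statement = ci_statement(decisions$x[i], decisions$y[i], trimws(z)),
        rejected = as.logical(decisions$rejected[i])
      )
    })
  }
  for (d in decisions) {
    stopifnot(inherits(d$statement, "ase_ci_statement"), is.logical(d$rejected))
    check_names(dag, c(d$statement$x, d$statement$y, d$statement$z))
  }
  decisions
}

#' Read and write DAGs as edge-list text, and export DOT
#'
#' The edge-list format has one `"parent child"` pair per line; isolated
#' nodes can be listed on lines of their own. `dag_to_dot()` renders the
#' graph in Graphviz DOT syntax for visualization.
#'
#' @param dag an `ase_dag`.
#' @param path file path.
#' @param nodes optional node set for `read_edgelist()`; defaults to the
#'   names appearing in the file, in order of appearance.
#' @return `read_edgelist()` returns an `ase_dag`; `write_edgelist()` returns
#'   `path` invisibly; `dag_to_dot()` returns a character scalar.
#' @export
write_edgelist <- function(dag, path) {
  lines <- paste(dag$edges[, 1], dag$edges[, 2])
  isolated <- setdiff(dag$nodes, unique(c(dag$edges)))
  writeLines(c(lines, isolated), path)
  invisible(path)
}

#' @rdname write_edgelist
#' @export
read_edgelist <- function(path, nodes = NULL) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  toks <- strsplit(lines, "\\s+")
  em <- do.call(rbind, lapply(toks[lengths(toks) == 2], function(p) p))
  if (is.null(em)) em <- matrix(character(0), ncol = 2)
  seen <- unique(c(t(em), unlist(toks[lengths(toks) == 1])))
  dag(if (is.null(nodes)) seen else nodes, em)
}

#' @rdname write_edgelist
#' @export
dag_to_dot <- function(dag) {
  body <- c(
    paste0("  ", dag$nodes, ";"),
    if (nrow(dag$edges) > 0) paste0("  ", dag$edges[, 1], " -> ", dag$edges[, 2], ";")
  )
  paste(c("digraph {", body, "}"), collapse = "\n")
}
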