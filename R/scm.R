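#' Construct a linear-Gaussian structural causal model
#'
#' Each node is generated as intercept + linear combination of its parents +
#' independent noise; one optional multiplicative interaction term between
#' two parents of a common child is supported (the ASE model's fatigue x
#' self-efficacy term in the depression equation). Noise is Gaussian for
#' continuous nodes and Bernoulli for binary exogenous nodes (gender).
#'
#' @param dag an `ase_dag`.
#' @param coefficients named numeric vector of edge coefficients with names
#'   `"parent->child"`; every name must be an edge of `dag`. Edges without a
#'   coefficient default to 0.
#' @param noise named list, one entry per node, each either
#'   `list(dist = "gaussian", mean =, sd =)` with `sd > 0` or
#'   `list(dist = "bernoulli", p =)` with `p` in (0, 1).
#' @param intercepts named numeric vector of per-node intercepts (default 0).
#' @param interaction optional `list(parents = c(a, b), child =, coef =)`
#'   adding `coef * a * b` to the child's equation; both `a->child` and
#'   `b->child` must be edges of `dag`. The interaction is an extra term in
#'   the structural equation, not a graph edge, so d-separation semantics on
#'   `dag` are unchanged.
#' @return An object of class `ase_scm`.
#' @export
linear_gaussian_scm <- function(dag, coefficients = numeric(0), noise,
                                intercepts = numeric(0), interaction = NULL) {
  stopifnot(inherits(dag, "ase_dag"))
  labs <- edge_labels(dag)
  if (length(coefficients) > 0) {
    bad <- setdiff(names(coefficients), labs)
    if (length(bad) > 0) stop("coefficient name(s) not an edge of the DAG: ", paste(bad, collapse = ", "))
  }
  coefs <- stats::setNames(numeric(length(labs)), labs)
  coefs[names(coefficients)] <- coefficients
  if (!setequal(names(noise), dag$nodes)) stop("noise must name every node exactly once")
  for (v in dag$nodes) {
    nv <- noise[[v]]
    if (identical(nv$dist, "gaussian")) {
      if (!is.numeric(nv$sd) || nv$sd <= 0) stop("gaussian sd must be > 0 for node ", v)
    } else if (identical(nv$dist, "bernoulli")) {
      if (!is.numeric(nv$p) || nv$p <= 0 || nv$p >= 1) stop("bernoulli p must be in (0,1) for node ", v)
    } else stop("unknown noise law for node ", v)
  }
  ic <- stats::setNames(numeric(length(dag$nodes)), dag$nodes)
  ic[names(intercepts)] <- intercepts
  if (!is.null(interaction)) {
    stopifnot(length(interaction$parents) == 2, length(interaction$child) == 1)
    for (p in interaction$parents) {
      if (!has_edge(dag, p, interaction$child)) {
        stop("interaction requires edge ", p, "->", interaction$child, " in the DAG")
      }
    }
  }
  structure(
    list(dag = dag, coefficients = coefs, noise = noise, intercepts = ic,
         interaction = interaction),
    class = "ase_scm"
  )
}

#' @export
print.ase_scm <- function(x, ...) {
  cat("Linear-Gaussian SCM on", length(x$dag$nodes), "nodes\n")
  nz <- x$coefficients[x$coefficients != 0]
  if (length(nz) > 0) {
    cat("  coefficients:", paste(names(nz), signif(nz, 4), sep = " = ", collapse = ", "), "\n")
  }
  if (!is.null(x$interaction)) {
    cat("  interaction:", paste(x$interaction$parents, collapse = "*"), "->",
        x$interaction$child, "=", x$interaction$coef, "\n")
  }
  invisible(x)
}

# Fixed noise-draw order so a seed means the same thing regardless of which
# equations are intervened on: the canonical ASE order first, then any other
# nodes in declaration order.
noise_draw_order <- function(scm) {
  canon <- intersect(c("A", "G", "M", "S", "F", "D"), scm$dag$nodes)
  c(canon, setdiff(scm$dag$nodes, canon))
}

draw_noise <- function(scm, n) {
  draws <- list()
  for (v in noise_draw_order(scm)) {
    nv <- scm$noise[[v]]
    draws[[v]] <- if (identical(nv$dist, "gaussian")) {
      stats::rnorm(n, mean = if (is.null(nv$mean)) 0 else nv$mean, sd = nv$sd)
    } else {
      stats::rbinom(n, 1L, nv$p)
    }
  }
  draws
}

evaluate_equations <- function(scm, noise_draws, n, assignments = list()) {
  vals <- list()
  for (v in topological_order(scm$dag)) {
    if (v %in% names(assignments)) {
      vals[[v]] <- rep(assignments[[v]], n)
      next
    }
    pa <- dag_parents(scm$dag, v)
    xv <- rep(scm$intercepts[[v]], n) + noise_draws[[v]]
    for (p in pa) xv <- xv + scm$coefficients[[paste0(p, "->", v)]] * vals[[p]]
    ia <- scm$interaction
    if (!is.null(ia) && identical(ia$child, v)) {
      xv <- xv + ia$coef * vals[[ia$parents[1]]] * vals[[ia$parents[2]]]
    }
    vals[[v]] <- xv
  }
  as.data.frame(vals)[, scm$dag$nodes, drop = FALSE]
}

#' Sample the observational distribution of an SCM
#'
#' Draws `n` i.i.d. rows by first drawing all noise variables (in a fixed
#' node order so seeds are portable across calls) and then evaluating the
#' structural equations in topological order.
#'
#' @param scm an `ase_scm`.
#' @param n positive number of rows.
#' @param seed integer seed; identical `(scm, n, seed)` give identical tables.
#' @return A data.frame with one column per node, in the DAG's node order.
#' @export
sample_observational <- function(scm, n, seed) {
  stopifnot(inherits(scm, "ase_scm"))
  if (!is.numeric(n) || n < 1) stop("n must be a positive integer")
  n <- as.integer(n)
  set.seed(as.integer(seed))
  evaluate_equations(scm, draw_noise(scm, n), n)
}

#' Sample an interventional distribution of an SCM
#'
#' Replaces the structural equation of every intervened node by the assigned
#' constant (`do(V := v)`) and leaves all other equations untouched. Noise is
#' still drawn for intervened nodes (and discarded) so that a given seed
#' produces coupled samples across different interventions.
#'
#' @param scm an `ase_scm`.
#' @param intervention named numeric vector or named list, e.g.
#'   `c(M = 0)` for `do(M := 0)`. An empty intervention reproduces
#'   observational sampling exactly.
#' @param n positive number of rows.
#' @param seed integer seed.
#' @return A data.frame as in [sample_observational()].
#' @export
sample_interventional <- function(scm, intervention, n, seed) {
  stopifnot(inherits(scm, "ase_scm"))
  intervention <- as.list(intervention)
  if (length(intervention) > 0) {
    if (is.null(names(intervention)) || any(names(intervention) == "")) {
      stop("intervention values must be named by node")
    }
    if (anyDuplicated(names(intervention))) stop("a node cannot be assigned twice")
    check_names(scm$dag, names(intervention), "intervention target")
  }
  if (!is.numeric(n) || n < 1) stop("n must be a positive integer")
  n <- as.integer(n)
  set.seed(as.integer(seed))
  evaluate_equations(scm, draw_noise(scm, n), n, assignments = intervention)
}

directed_paths <- function(dag, from, to) {
  paths <- list()
  walk <- function(v, acc) {
    if (v == to) {
      paths[[length(paths) + 1]] <<- acc
      return(invisible())
    }
    for (ch in dag_children(dag, v)) walk(ch, c(acc, ch))
  }
  walk(from, from)
  paths
}

#' Analytic average causal effect in a linear SCM
#'
#' In a linear SCM the average causal effect of a unit shift in `treatment`
#' on `outcome` under `do(treatment := t)` equals the sum over all directed
#' paths of the products of edge coefficients along each path. When the SCM
#' carries a multiplicative interaction term whose child lies on such a path
#' (with nonzero coefficient) the per-unit effect is no longer constant and
#' this function raises an error; use [analytic_interaction_ace()] for the
#' interaction effect itself.
#'
#' @param scm an `ase_scm`.
#' @param treatment,outcome node names (distinct).
#' @return The path-coefficient sum, e.g. the M->F coefficient for the
#'   ASE model's metacognition-to-fatigue effect.
#' @export
analytic_ace <- function(scm, treatment, outcome) {
  stopifnot(inherits(scm, "ase_scm"))
  check_names(scm$dag, c(treatment, outcome))
  if (treatment == outcome) stop("treatment and outcome must differ")
  paths <- directed_paths(scm$dag, treatment, outcome)
  ia <- scm$interaction
  if (!is.null(ia) && ia$coef != 0) {
    uses_ia <- any(vapply(paths, function(p) {
      any(p[-length(p)] %in% ia$parents & p[-1] == ia$child)
    }, logical(1)))
    if (uses_ia) {
      stop("unsupported structure: a nonzero interaction term lies on a ",
           treatment, "->", outcome, " path; the per-unit effect is not constant")
    }
  }
  if (length(paths) == 0) return(0)
  sum(vapply(paths, function(p) {
    prod(scm$coefficients[paste0(p[-length(p)], "->", p[-1])])
  }, numeric(1)))
}

#' Analytic interaction effect in the ASE SCM
#'
#' Returns the mixed derivative of the interventional mean of the
#' interaction's child with respect to its two parents, i.e. the coefficient
#' of the multiplicative term (the fatigue x self-efficacy effect on
#' depression in the ASE model).
#'
#' @param scm an `ase_scm` carrying an interaction term.
#' @return The interaction coefficient.
#' @export
analytic_interaction_ace <- function(scm) {
  stopifnot(inherits(scm, "ase_scm"))
  if (is.null(scm$interaction)) {
    stop("unsupported structure: the SCM has no interaction term")
  }
  scm$interaction$coef
}
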