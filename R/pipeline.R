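#' Load a questionnaire cohort from CSV
#'
#' Reads a per-participant CSV and returns the analysis table with columns
#' A (age), G (gender, 0/1), M (metacognition of allostatic control: sum of
#' MAIA subscales 3 and 8), F (fatigue, FSS), S (general self-efficacy,
#' GSES), D (depression, CES-D). `column_map` maps each analysis variable to
#' one or more candidate column names in the file; the first present
#' candidate is used. When the entry for M names two or more columns that are
#' all present (subscale-level MAIA data), M is computed as their row sum.
#'
#' A two-level non-numeric gender column is recoded to 0/1 (alphabetical
#' order of the labels, with a message); more than two observed levels is an
#' error since the model assumes a Bernoulli gender variable. Rows with any
#' missing mapped value are dropped listwise with a warning stating the
#' count. Non-numeric cells in numeric columns raise a parse error naming the
#' row.
#'
#' @param path CSV file path (comma-separated, header row, UTF-8).
#' @param column_map named list with entries A, G, M, F, S, D; each a
#'   character vector of candidate column names. Defaults cover the
#'   identity names plus common questionnaire headings.
#' @return A data.frame with columns A, G, M, F, S, D.
#' @export
load_cohort_csv <- function(path, column_map = default_column_map()) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("A", "G", "M", "F", "S", "D")
  miss <- setdiff(need, names(column_map))
  if (length(miss) > 0) stop("schema error: column_map lacks entries for ", paste(miss, collapse = ", "))
  out <- list()
  for (v in need) {
    cand <- column_map[[v]]
    if (v == "M" && length(cand) > 1 && all(cand %in% names(raw))) {
      cols <- lapply(cand, function(cn) parse_numeric_column(raw[[cn]], cn))
      out[[v]] <- Reduce(`+`, cols)
      next
    }
    hit <- cand[cand %in% names(raw)][1]
    if (is.na(hit)) {
      stop("schema error: no column found for ", v, " among: ", paste(cand, collapse = ", "))
    }
    out[[v]] <- if (v == "G") parse_gender_column(raw[[hit]], hit) else parse_numeric_column(raw[[hit]], hit)
  }
  tab <- as.data.frame(out)
  keep <- stats::complete.cases(tab)
  if (any(!keep)) {
    warning(sum(!keep), " row(s) dropped listwise due to missing values", call. = FALSE)
    tab <- tab[keep, , drop = FALSE]
    rownames(tab) <- NULL
  }
  attr(tab, "source") <- list(file = path, n = nrow(tab))
  tab
}

parse_numeric_column <- function(x, name) {
  if (is.numeric(x)) return(x)
  v <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & x != "" & is.na(v))
  if (length(bad) > 0) {
    stop("parse error: non-numeric value in column '", name, "' at row ", bad[1])
  }
  v[x == ""] <- NA_real_
  v
}

parse_gender_column <- function(x, name) {
  if (is.numeric(x)) {
    lev <- sort(unique(x[!is.na(x)]))
  } else {
    lev <- sort(unique(x[!is.na(x) & x != ""]))
  }
  if (length(lev) > 2) {
    stop("gender column '", name, "' has ", length(lev),
         " observed levels; the model assumes a binary (Bernoulli) gender ",
         "variable - recode or subset the data first")
  }
  if (is.numeric(x)) {
    if (all(lev %in% c(0, 1))) return(x)
    message("recoding gender levels ", paste(lev, collapse = "/"), " to 0/1")
    return(as.numeric(match(x, lev) - 1))
  }
  message("recoding gender labels ", paste(lev, collapse = "/"), " to 0/1")
  out <- as.numeric(match(x, lev) - 1)
  out[x == ""] <- NA_real_
  out
}

#' @rdname load_cohort_csv
#' @export
default_column_map <- function() {
  list(
    A = c("A", "age", "Age"),
    G = c("G", "gender", "Gender", "sex", "Sex"),
    M = c("M", "MAIA38", "MAIA_3_8", "maia38", c("MAIA_notworrying", "MAIA_trusting")),
    F = c("F", "FSS", "fss", "fatigue"),
    S = c("S", "GSES", "gses", "self_efficacy"),
    D = c("D", "CESD", "CES_D", "cesd", "depression")
  )
}

#' The five structural conditional-independence statements
#'
#' The testable implications of the ASE graph examined by the structural
#' hypothesis: M _||_ S | A,G; M _||_ D | F,A,G; M _||_ D | F,A,G,S;
#' F _||_ S | A,G; F _||_ S | A,G,M.
#'
#' @return A list of five `ase_ci_statement` objects, in that order.
#' @export
h1_statements <- function() {
  list(
    ci_statement("M", "S", c("A", "G")),
    ci_statement("M", "D", c("F", "A", "G")),
    ci_statement("M", "D", c("F", "A", "G", "S")),
    ci_statement("F", "S", c("A", "G")),
    ci_statement("F", "S", c("A", "G", "M"))
  )
}

new_report <- function(hypothesis, results, family_alpha, per_test_alpha, table, seed) {
  structure(
    list(
      hypothesis = hypothesis, results = results,
      family_alpha = family_alpha, per_test_alpha = per_test_alpha,
      provenance = list(
        n = nrow(table),
        input = attr(table, "source"),
        seed = seed,
        package_version = as.character(utils::packageVersion("aseCausal"))
      )
    ),
    class = "ase_hypothesis_report"
  )
}

#' @export
print.ase_hypothesis_report <- function(x, ...) {
  cat(x$hypothesis, "report (n =", x$provenance$n,
      ", per-test alpha =", x$per_test_alpha, ")\n")
  df <- if (x$hypothesis == "H1") ci_results_to_df(x$results) else effects_to_df(x$results)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Test the structural hypothesis: the graph's conditional independencies
#'
#' Evaluates the five statements of [h1_statements()] with each requested
#' test family and applies a Bonferroni family of five at family level 0.05
#' (per-test 0.01) within each family. The layout mirrors the published
#' statement-by-method results table for the PBIHB cohort.
#'
#' @param table cohort data.frame with columns A, G, M, F, S, D.
#' @param methods subset of `c("MIcg", "GCM", "KCI")`.
#' @param family_alpha family-wise level (default 0.05 over five tests).
#' @param seed integer seed passed to the seeded test families.
#' @return An `ase_hypothesis_report` whose `results` is a list of
#'   `ase_ci_result` (statements nested within methods).
#' @export
run_hypothesis_1 <- function(table, methods = c("MIcg", "GCM", "KCI"),
                             family_alpha = 0.05, seed = 1) {
  methods <- match.arg(methods, several.ok = TRUE)
  sts <- h1_statements()
  res <- list()
  for (m in methods) {
    fam <- lapply(sts, function(s) {
      switch(m,
        MIcg = micg_test(table, s),
        GCM = gcm_test(table, s, seed = seed),
        KCI = kci_test(table, s, seed = seed)
      )
    })
    res <- c(res, bonferroni_decide(fam, family_size = length(sts), family_alpha = family_alpha))
  }
  new_report("H1", res, family_alpha, family_alpha / length(sts), table, seed)
}

#' Estimate the metacognition-to-fatigue effect (directional hypothesis)
#'
#' Estimates the average causal effect of metacognition of allostatic
#' control (M) on fatigue (F) with all three estimators, for the primary
#' adjustment set {A, G} and the sensitivity set {A, G, S} (both valid under
#' the ASE graph), each with a one-sided test of a negative effect at
#' `alpha` (default 0.017, Bonferroni over the three estimators).
#'
#' @param table cohort data.frame.
#' @param dag working DAG for backdoor verification (default [dag_j0()]).
#' @param alpha one-sided decision level.
#' @param folds,seed cross-fitting controls for the DML estimator.
#' @return An `ase_hypothesis_report` whose `results` is a list of
#'   `ase_effect` objects.
#' @export
run_hypothesis_2 <- function(table, dag = dag_j0(), alpha = 0.017,
                             folds = 5, seed = 1) {
  res <- list()
  for (z in list(c("A", "G"), c("A", "G", "S"))) {
    res <- c(res, list(
      ace_regression(table, "M", "F", z, dag = dag, alpha = alpha),
      ace_propensity(table, "M", "F", z, dag = dag, alpha = alpha),
      ace_dml(table, "M", "F", z, dag = dag, alpha = alpha, folds = folds, seed = seed)
    ))
  }
  new_report("H2", res, alpha * 3, alpha, table, seed)
}

#' Estimate the fatigue x self-efficacy interaction effect on depression
#'
#' Estimates the interaction coefficient (F*S on D) with all three
#' estimators for the adjustment sets {A, G} and {A, G, M}, each with a
#' one-sided test of a negative effect at `alpha`.
#'
#' @inheritParams run_hypothesis_2
#' @return An `ase_hypothesis_report` of `ase_effect` objects with target
#'   `"theta10"`.
#' @export
run_hypothesis_3 <- function(table, alpha = 0.017, folds = 5, seed = 1) {
  res <- list()
  for (z in list(c("A", "G"), c("A", "G", "M"))) {
    res <- c(res, list(
      interaction_ace(table, "D", z, "regression", alpha = alpha),
      interaction_ace(table, "D", z, "propensity", alpha = alpha),
      interaction_ace(table, "D", z, "dml", alpha = alpha, folds = folds, seed = seed)
    ))
  }
  new_report("H3", res, alpha * 3, alpha, table, seed)
}

#' Majority-vote decisions across CI test families
#'
#' Aggregates a structural-hypothesis report into one decision per
#' statement: a statement counts as rejected when strictly more than half of
#' the test families reject it (so with three families, two must agree).
#'
#' @param h1 an `ase_hypothesis_report` from [run_hypothesis_1()].
#' @return A data.frame with columns `x`, `y`, `z`, `rejected`.
#' @export
majority_decisions <- function(h1) {
  df <- ci_results_to_df(h1$results)
  key <- paste(df$x, df$y, df$z, sep = "|")
  agg <- lapply(split(df, factor(key, levels = unique(key))), function(d) {
    data.frame(x = d$x[1], y = d$y[1], z = d$z[1],
               rejected = mean(d$rejected) > 0.5, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out
}

#' Run the full analysis and the graph-revision step
#'
#' Runs the structural hypothesis (H1), both effect hypotheses (H2, H3),
#' aggregates the H1 decisions by majority vote across test families, and
#' scores single-edge revisions of the working graph against those decisions
#' via [reconcile_single_edge()]. On PBIHB-like data whose tests reject the
#' M/S-related independencies, the top-ranked revision is the added edge
#' M->S.
#'
#' @param table cohort data.frame.
#' @param methods CI test families for H1.
#' @param dag working DAG (default [dag_j0()]).
#' @param alpha one-sided level for H2/H3 (default 0.017).
#' @param folds,seed cross-fitting controls.
#' @return A list of class `ase_full_report` with elements `h1`, `h2`, `h3`,
#'   `decisions` (majority table), `reconciliation` (ranked candidates) and
#'   `top_edge` (label of the best-scoring revision, `""` for the baseline
#'   graph).
#' @export
full_report <- function(table, methods = c("MIcg", "GCM", "KCI"),
                        dag = dag_j0(), alpha = 0.017, folds = 5, seed = 1) {
  h1 <- run_hypothesis_1(table, methods = methods, seed = seed)
  h2 <- run_hypothesis_2(table, dag = dag, alpha = alpha, folds = folds, seed = seed)
  h3 <- run_hypothesis_3(table, alpha = alpha, folds = folds, seed = seed)
  dec <- majority_decisions(h1)
  rec <- reconcile_single_edge(dag, dec)
  structure(
    list(h1 = h1, h2 = h2, h3 = h3, decisions = dec, reconciliation = rec,
         top_edge = rec$edge[1]),
    class = "ase_full_report"
  )
}

#' @export
print.ase_full_report <- function(x, ...) {
  print(x$h1)
  print(x$h2)
  print(x$h3)
  cat("\nMajority decisions across CI test families:\n")
  print(x$decisions, row.names = FALSE)
  cat("\nSingle-edge reconciliation (ascending mismatch):\n")
  print(x$reconciliation, row.names = FALSE)
  if (nzchar(x$top_edge)) {
    cat("\nSuggested revision: add edge", x$top_edge, "\n")
  } else {
    cat("\nNo revision needed: the working graph fits the decisions best\n")
  }
  invisible(x)
}

#' Serialize a full report to JSON and back
#'
#' `report_to_json()` renders the tabular content of a full report (H1/H2/H3
#' tables, majority decisions, reconciliation ranking, provenance) as a JSON
#' string that round-trips through `parse_report_json()`:
#' re-serializing the parsed object reproduces the identical string.
#'
#' @param report an `ase_full_report`.
#' @param json a JSON string from `report_to_json`.
#' @return `report_to_json`: a JSON character scalar; `parse_report_json`:
#'   the parsed list of data.frames.
#' @export
report_to_json <- function(report) {
  payload <- list(
    h1 = ci_results_to_df(report$h1$results),
    h2 = effects_to_df(report$h2$results),
    h3 = effects_to_df(report$h3$results),
    decisions = report$decisions,
    reconciliation = data.frame(edge = report$reconciliation$edge,
                                mismatch = report$reconciliation$mismatch),
    top_edge = report$top_edge,
    provenance = report$h1$provenance[c("n", "seed", "package_version")]
  )
  as.character(jsonlite::toJSON(payload, digits = NA, auto_unbox = TRUE))
}

#' @rdname report_to_json
#' @export
parse_report_json <- function(json) {
  jsonlite::fromJSON(json, simplifyVector = TRUE)
}

#' Write the report tables as CSV files
#'
#' Emits `h1_ci_tests.csv`, `h2_effect_m_to_f.csv`, `h3_interaction.csv`,
#' `decisions.csv` and `reconciliation.csv` under `dir` with fixed column
#' names and row order.
#'
#' @param report an `ase_full_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report_csv <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(ci_results_to_df(report$h1$results),
                   file.path(dir, "h1_ci_tests.csv"), row.names = FALSE)
  utils::write.csv(effects_to_df(report$h2$results),
                   file.path(dir, "h2_effect_m_to_f.csv"), row.names = FALSE)
  utils::write.csv(effects_to_df(report$h3$results),
                   file.path(dir, "h3_interaction.csv"), row.names = FALSE)
  utils::write.csv(report$decisions, file.path(dir, "decisions.csv"), row.names = FALSE)
  utils::write.csv(report$reconciliation, file.path(dir, "reconciliation.csv"),
                   row.names = FALSE)
  invisible(dir)
}
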