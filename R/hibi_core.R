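#' Default and strict per-study caps on added cases
#'
#' The default cap of 3 added cases per double-zero study comes from the
#' rule of three: for a sample of size n with zero observed cases, the
#' upper 95% confidence limit of the case rate is 3/n, so seeing more than
#' 3 cases in such a study has under 5% probability. The stricter cutoff,
#' `round(-log(0.007)) = 5`, corresponds to a 99.3% confidence interval in
#' the same way.
#'
#' @return An integer: 3 for `default_max_cases()`, 5 for
#'   `strict_cutoff()` (computed, not hard-coded).
#' @export
default_max_cases <- function() 3L

#' @rdname default_max_cases
#' @export
strict_cutoff <- function() as.integer(round(-log(1 - 0.993)))

#' Enumerate case-addition combinations for the exact method
#'
#' One combination assigns to each double-zero study (ordered largest
#' first) a number of added cases between 0 and `min(m, cap_j)`, where
#' `cap_j` is that study's target-arm sample size. The sequence contains
#' every such vector exactly once — `prod(min(m, cap_j) + 1)` rows,
#' `(m+1)^n` when no cap binds — ordered by ascending total added cases,
#' ties broken by concentrating cases in the larger (earlier-ranked)
#' studies. The all-zero reference combination comes first.
#'
#' @param n Number of double-zero studies.
#' @param m Maximum cases added per study (default 3, the rule of three).
#' @param caps Optional integer vector of per-study arm sizes that bound
#'   the additions; recycled checks apply `min(m, caps)` per study.
#' @param budget Maximum number of combinations the exact method will
#'   enumerate (default `4^10`); exceeded means the approximating method
#'   should be used instead.
#' @param force Set `TRUE` to enumerate past the budget.
#' @return An integer matrix with one row per combination and `n` columns.
#' @export
enumerate_combinations <- function(n, m = default_max_cases(), caps = NULL,
                                   budget = 4^10, force = FALSE) {
  stopifnot(n >= 1, m >= 1)
  if (is.null(caps)) caps <- rep.int(m, n)
  stopifnot(length(caps) == n, all(caps >= 1))
  per_study <- pmin(m, caps)
  total <- count_combinations(n, m, caps)
  if (total > budget && !force) {
    stop(sprintf(
      "combinatorial budget exceeded: %.0f combinations > %.0f; use the approximating method or force = TRUE",
      total, budget), call. = FALSE)
  }
  grid <- as.matrix(expand.grid(lapply(per_study, function(cap) 0:cap),
                                KEEP.OUT.ATTRS = FALSE))
  dimnames(grid) <- NULL
  storage.mode(grid) <- "integer"
  tot <- rowSums(grid)
  keys <- c(list(tot), lapply(seq_len(n), function(j) -grid[, j]))
  grid[do.call(order, keys), , drop = FALSE]
}

#' Size of the exact method's search space
#'
#' @inheritParams enumerate_combinations
#' @return `prod(min(m, caps) + 1)` (a double, to allow large counts),
#'   equal to `(m+1)^n` when no arm-size cap binds.
#' @export
count_combinations <- function(n, m = default_max_cases(), caps = NULL) {
  stopifnot(n >= 1, m >= 1)
  if (is.null(caps)) caps <- rep.int(m, n)
  stopifnot(length(caps) == n)
  prod(pmin(m, caps) + 1)
}

#' Apply a case-addition combination to a dataset
#'
#' Places `added[j]` cases in the chosen arm of the j-th double-zero study
#' (studies ordered by [rank_double_zero()]). Sample sizes never change:
#' added cases displace non-cases. All other studies are untouched.
#'
#' @param ds A [meta_dataset()].
#' @param added Integer vector, one entry per double-zero study in
#'   descending-size order.
#' @param arm `"treatment"` or `"control"`.
#' @return A [meta_dataset()] with the combination applied.
#' @export
apply_combination <- function(ds, added, arm = c("treatment", "control")) {
  arm <- match.arg(arm)
  dz <- rank_double_zero(ds)
  stopifnot(length(added) == length(dz), all(added >= 0))
  col_cases <- if (arm == "treatment") "t_cases" else "c_cases"
  col_n <- if (arm == "treatment") "t_n" else "c_n"
  if (any(added > ds[[col_n]][dz])) {
    stop("added cases exceed the target arm's sample size", call. = FALSE)
  }
  out <- ds
  out[[col_cases]][dz] <- as.integer(added)
  out$zero_class[dz] <- ifelse(added > 0L, "single_zero", "double_zero")
  out
}

#' Did a combination change the conclusion?
#'
#' A change is a direction flip (the pooled OR/RR crosses 1: the product
#' of the two directions is -1; a direction of exactly 0 never counts as
#' a crossing) or a significance flip in either direction.
#'
#' @param ref,new `pooled_result` objects from the same engine.
#' @param alpha Two-sided significance level.
#' @return Logical scalar.
#' @export
detect_change <- function(ref, new, alpha = 0.05) {
  r <- significance_and_direction(ref, alpha)
  s <- significance_and_direction(new, alpha)
  (r$direction * s$direction == -1) || (r$significant != s$significant)
}

pool_safely <- function(ds, model, alpha) {
  res <- tryCatch(pool_meta(ds, model, alpha), error = function(e) e)
  if (inherits(res, "error")) {
    return(list(result = NULL, estimable = FALSE, note = conditionMessage(res)))
  }
  if (!res$converged) {
    return(list(result = res, estimable = FALSE,
                note = "engine did not converge"))
  }
  list(result = res, estimable = TRUE, note = "")
}

trace_row <- function(added, arm, fit, ref, alpha) {
  total <- sum(added)
  if (fit$estimable) {
    r <- fit$result
    sd_ <- significance_and_direction(r, alpha)
    changed <- if (is.null(ref)) FALSE else detect_change(ref, r, alpha)
    data.frame(
      combination = paste(added, collapse = "+"),
      arm = arm, total = total,
      log_effect = r$log_effect, se = r$se, p_value = r$p_value,
      direction = sd_$direction, significant = sd_$significant,
      changed = changed, estimable = TRUE,
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(
      combination = paste(added, collapse = "+"),
      arm = arm, total = total,
      log_effect = NA_real_, se = NA_real_, p_value = NA_real_,
      direction = NA_real_, significant = NA,
      changed = NA, estimable = FALSE,
      stringsAsFactors = FALSE
    )
  }
}

reference_pool <- function(ds, model, alpha) {
  dz <- zero_classes(ds)$double_zero
  ref_ds <- ds[-dz, , drop = FALSE]
  class(ref_ds) <- c("meta_dataset", "data.frame")
  pool_meta(ref_ds, model, alpha)
}

#' Exact harms/benefits index by exhaustive enumeration
#'
#' Implements the exact method: (1) pool the meta-analysis with every
#' double-zero study excluded (the reference); (2) enumerate all
#' case-addition combinations for the chosen arm in ascending-total order;
#' (3) re-pool the full dataset under each combination (double-zero
#' studies included, with their added cases); (4) the index is the total
#' of the first — equivalently minimum-total — combination that changes
#' the direction or significance relative to the reference, or 0 if none
#' does. `arm = "treatment"` yields Hi, `arm = "control"` yields Bi.
#'
#' Combinations on which the engine fails (for example beta-binomial
#' non-convergence) are recorded in the trace as inestimable and skipped;
#' if more than 10% are inestimable the result is flagged.
#'
#' @param ds A [meta_dataset()] that passes [check_applicability()].
#' @param arm `"treatment"` (Hi) or `"control"` (Bi).
#' @param model Pooling engine: `"peto"`, `"mh"`, or `"betabin"`.
#' @param alpha Two-sided significance level.
#' @param m Per-study cap on added cases (default 3).
#' @param budget,force Passed to [enumerate_combinations()].
#' @return A list: `index` (integer), `combination` (integer vector or
#'   NULL), `reference` (`pooled_result`), `trace` (data frame, one row
#'   per evaluated combination, reference first), `n_inestimable`,
#'   `warn_inestimable`.
#' @export
compute_index_exact <- function(ds, arm = c("treatment", "control"),
                                model = "peto", alpha = 0.05,
                                m = default_max_cases(),
                                budget = 4^10, force = FALSE) {
  arm <- match.arg(arm)
  app <- check_applicability(ds)
  if (!app$applicable) stop("Hi-Bi not applicable: ", app$reason,
                            call. = FALSE)
  dz <- rank_double_zero(ds)
  n <- length(dz)
  caps <- if (arm == "treatment") ds$t_n[dz] else ds$c_n[dz]
  ref <- reference_pool(ds, model, alpha)

  combos <- enumerate_combinations(n, m, caps, budget = budget, force = force)
  rows <- vector("list", nrow(combos))
  rows[[1]] <- trace_row(combos[1, ], arm,
                         list(result = ref, estimable = TRUE, note = ""),
                         NULL, alpha)
  index <- 0L
  winning <- NULL
  for (i in 2:nrow(combos)) {
    added <- combos[i, ]
    fit <- pool_safely(apply_combination(ds, added, arm), model, alpha)
    rows[[i]] <- trace_row(added, arm, fit, ref, alpha)
    if (index == 0L && fit$estimable && rows[[i]]$changed) {
      index <- as.integer(sum(added))
      winning <- added
    }
  }
  trace <- do.call(rbind, rows)
  n_bad <- sum(!trace$estimable)
  list(index = index, combination = winning, reference = ref,
       trace = trace, n_inestimable = n_bad,
       warn_inestimable = n_bad > 0.1 * nrow(trace))
}

#' Choose the pivot study for the approximating method
#'
#' Tentatively adds 1 case to the treatment arm of each double-zero study
#' in turn and scores that study's weighted effect contribution under the
#' Peto method (its O - E term, i.e. weight times per-study effect). The
#' pivot is the study with the largest score; ties go to the larger total
#' sample size, then input order. The same pivot is used for both arms.
#'
#' @param ds A [meta_dataset()] with at least one double-zero study.
#' @return The row index (in `ds`) of the pivot study.
#' @export
select_pivot_study <- function(ds) {
  dz <- zero_classes(ds)$double_zero
  if (length(dz) == 0) stop("no double-zero study", call. = FALSE)
  score <- vapply(dz, function(i) {
    study_peto_contribution(1L, ds$t_n[i], 0L, ds$c_n[i])$o_minus_e
  }, numeric(1))
  tot <- ds$t_n[dz] + ds$c_n[dz]
  dz[order(-score, -tot, seq_along(dz))][1]
}

#' Approximate harms/benefits index via a single pivot study
#'
#' Restricts the search to the pivot double-zero study (the one with the
#' largest weighted effect after a tentative +1 treatment case,
#' [select_pivot_study()]): with n double-zero studies, g = 1, ..., 3n
#' cases are added to the pivot's target arm while the other double-zero
#' studies stay at zero, for at most 3n + 1 poolings per index including
#' the reference. When the pivot arm holds fewer than 3n participants the
#' cap drops to the arm size. The index is the smallest changing g, or 0.
#'
#' @inheritParams compute_index_exact
#' @return As [compute_index_exact()], plus `pivot` (row index) and
#'   `max_added` (the cap actually used).
#' @export
compute_index_approx <- function(ds, arm = c("treatment", "control"),
                                 model = "peto", alpha = 0.05,
                                 m = default_max_cases()) {
  arm <- match.arg(arm)
  app <- check_applicability(ds)
  if (!app$applicable) stop("Hi-Bi not applicable: ", app$reason,
                            call. = FALSE)
  dz <- rank_double_zero(ds)
  n <- length(dz)
  pivot <- select_pivot_study(ds)
  pivot_pos <- match(pivot, dz)
  arm_size <- if (arm == "treatment") ds$t_n[pivot] else ds$c_n[pivot]
  max_added <- min(m * n, arm_size)
  ref <- reference_pool(ds, model, alpha)

  rows <- vector("list", max_added + 1)
  zero_vec <- integer(n)
  rows[[1]] <- trace_row(zero_vec, arm,
                         list(result = ref, estimable = TRUE, note = ""),
                         NULL, alpha)
  index <- 0L
  winning <- NULL
  for (g in seq_len(max_added)) {
    added <- zero_vec
    added[pivot_pos] <- g
    fit <- pool_safely(apply_combination(ds, added, arm), model, alpha)
    rows[[g + 1]] <- trace_row(added, arm, fit, ref, alpha)
    if (index == 0L && fit$estimable && rows[[g + 1]]$changed) {
      index <- as.integer(g)
      winning <- added
    }
  }
  trace <- do.call(rbind, rows)
  n_bad <- sum(!trace$estimable)
  list(index = index, combination = winning, reference = ref,
       trace = trace, n_inestimable = n_bad,
       warn_inestimable = n_bad > 0.1 * nrow(trace),
       pivot = pivot, max_added = max_added)
}

#' Classify an index value into an impact category
#'
#' An index of 0 means the double-zero studies have no impact within the
#' cap. An index above the cutoff means so many added cases would be
#' needed that impact is implausible under the rule of three ("almost no
#' impact"). Anything in between is a potential impact and the double-zero
#' studies should not be excluded from the synthesis.
#'
#' @param index Nonnegative integer Hi or Bi value.
#' @param cutoff 3 (default, rule of three) or 5 (stricter, 99.3% level).
#' @return One of `"no_impact"`, `"potential_impact"`,
#'   `"almost_no_impact"`.
#' @export
classify_impact <- function(index, cutoff = default_max_cases()) {
  stopifnot(length(index) == 1, index >= 0, index == round(index))
  if (!cutoff %in% c(default_max_cases(), strict_cutoff())) {
    stop("cutoff must be 3 (default) or 5 (strict)", call. = FALSE)
  }
  if (index == 0) "no_impact"
  else if (index > cutoff) "almost_no_impact"
  else "potential_impact"
}

#' Harms index and benefits index of a meta-analysis
#'
#' Orchestrates the full analysis: applicability gate, engine choice,
#' exact or approximating search for both arms, impact classification,
#' and the reporting bundle (subtype, number of double-zero studies,
#' indices, categories, method, model). Under `method = "auto"` the exact
#' method is used for fewer than 7 double-zero studies and the
#' approximating method from 7 on.
#'
#' @param ds A [meta_dataset()].
#' @param measure `"or"` or `"rr"`. The supported engine pairings are
#'   OR with `"peto"` (default) or `"betabin"`, and RR with `"mh"`.
#' @param model `"peto"`, `"mh"`, or `"betabin"`.
#' @param alpha Two-sided significance level (default 0.05).
#' @param max_cases Per-study cap on added cases (default 3).
#' @param cutoff Impact-category cutoff, 3 or 5.
#' @param method `"auto"`, `"exact"`, or `"approx"`.
#' @param budget,force Exact-method enumeration guard; see
#'   [enumerate_combinations()].
#' @return A `hibi_result` with elements `hi`, `bi`, `hi_combination`,
#'   `bi_combination`, `hi_category`, `bi_category`, `reference`,
#'   `method`, `model`, `measure`, `alpha`, `max_cases`, `cutoff`,
#'   `subtype`, `n_double_zero`, `traces` (list with `hi` and `bi` data
#'   frames), and `warn_inestimable`.
#' @examples
#' ds <- meta_dataset(data.frame(
#'   study_id = c("A", "B"),
#'   t_cases = c(0, 1), t_n = c(10, 50),
#'   c_cases = c(0, 3), c_n = c(10, 50)
#' ))
#' hibi(ds)
#' @export
hibi <- function(ds, measure = c("or", "rr"), model = NULL, alpha = 0.05,
                 max_cases = default_max_cases(),
                 cutoff = default_max_cases(),
                 method = c("auto", "exact", "approx"),
                 budget = 4^10, force = FALSE) {
  measure <- match.arg(measure)
  method <- match.arg(method)
  if (is.null(model)) model <- if (measure == "rr") "mh" else "peto"
  allowed <- list(or = c("peto", "betabin"), rr = "mh")
  if (!model %in% allowed[[measure]]) {
    stop(sprintf("model '%s' cannot estimate measure '%s'; allowed: %s",
                 model, measure, paste(allowed[[measure]], collapse = ", ")),
         call. = FALSE)
  }
  app <- check_applicability(ds)
  if (!app$applicable) {
    stop(structure(class = c("hibi_not_applicable", "error", "condition"),
                   list(message = paste0("Hi-Bi not applicable: ", app$reason),
                        call = NULL)))
  }
  n_dz <- length(zero_classes(ds)$double_zero)
  if (method == "auto") method <- if (n_dz >= 7) "approx" else "exact"

  run <- function(arm) {
    if (method == "exact") {
      compute_index_exact(ds, arm, model, alpha, m = max_cases,
                          budget = budget, force = force)
    } else {
      compute_index_approx(ds, arm, model, alpha, m = max_cases)
    }
  }
  hi_res <- run("treatment")
  bi_res <- run("control")

  structure(list(
    hi = hi_res$index, bi = bi_res$index,
    hi_combination = hi_res$combination, bi_combination = bi_res$combination,
    hi_category = classify_impact(hi_res$index, cutoff),
    bi_category = classify_impact(bi_res$index, cutoff),
    reference = hi_res$reference,
    method = method, model = model, measure = toupper(measure),
    alpha = alpha, max_cases = max_cases, cutoff = cutoff,
    subtype = classify_zero_structure(ds),
    n_double_zero = n_dz,
    traces = list(hi = hi_res$trace, bi = bi_res$trace),
    warn_inestimable = hi_res$warn_inestimable || bi_res$warn_inestimable
  ), class = "hibi_result")
}

#' @export
print.hibi_result <- function(x, ...) {
  cat(sprintf("Hi-Bi analysis (%s method, %s model, measure %s)\n",
              x$method, x$model, x$measure))
  cat(sprintf("subtype %s; %d double-zero studies; cap %d cases/study; alpha %g\n",
              x$subtype, x$n_double_zero, x$max_cases, x$alpha))
  cat(sprintf("reference: log %s = %.4f (SE %.4f), p = %.4g\n",
              x$measure, x$reference$log_effect, x$reference$se,
              x$reference$p_value))
  cat(sprintf("Hi = %d (%s)", x$hi, x$hi_category))
  if (!is.null(x$hi_combination)) {
    cat(sprintf("  [cases added: %s]", paste(x$hi_combination, collapse = "+")))
  }
  cat(sprintf("\nBi = %d (%s)", x$bi, x$bi_category))
  if (!is.null(x$bi_combination)) {
    cat(sprintf("  [cases added: %s]", paste(x$bi_combination, collapse = "+")))
  }
  cat("\n")
  if (x$hi == 0 && x$bi == 0) {
    cat("double-zero studies do not alter direction or significance\n")
  }
  if (x$warn_inestimable) {
    cat("warning: >10% of combinations were inestimable\n")
  }
  invisible(x)
}
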