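#' Specification for a simulated meta-analysis
#'
#' Describes a meta-analysis of k two-arm trials with binomially sampled
#' case counts: control-arm risk `p0`, a true odds ratio `true_or` acting
#' on the logit scale, per-arm sample sizes drawn uniformly from
#' `n_range`, a treatment:control size ratio, and a required number of
#' double-zero studies enforced by rejection sampling (the data-generating
#' process stays honest binomial; zeros arise from low risk, they are not
#' imposed cell-wise).
#'
#' @param k Number of studies (>= 2).
#' @param n_range Length-2 integer interval for the control-arm size.
#' @param p0 Control-arm risk, in (0, 1).
#' @param true_or True odds ratio (> 0).
#' @param ratio Treatment:control sample-size ratio (default 1).
#' @param n_dz_target Required number of double-zero studies (< k).
#' @param seed Integer seed; generation is fully reproducible from it.
#' @return A `sim_spec` list.
#' @export
sim_spec <- function(k, n_range, p0, true_or, ratio = 1,
                     n_dz_target = 1L, seed = 1L) {
  stopifnot(k >= 2, length(n_range) == 2, n_range[1] >= 1,
            n_range[2] >= n_range[1],
            p0 > 0, p0 < 1, true_or > 0, ratio > 0,
            n_dz_target >= 0, n_dz_target < k)
  structure(list(k = as.integer(k), n_range = as.integer(n_range),
                 p0 = p0, true_or = true_or, ratio = ratio,
                 n_dz_target = as.integer(n_dz_target),
                 seed = as.integer(seed)),
            class = "sim_spec")
}

with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Generate a simulated meta-analysis
#'
#' Draws the dataset described by a [sim_spec()]: per-study control sizes
#' uniform on `n_range`, treatment sizes `round(ratio * n_c)`, control
#' cases `Binomial(n_c, p0)` and treatment cases `Binomial(n_t, p1)` with
#' `logit(p1) = logit(p0) + log(true_or)`. Whole datasets are redrawn
#' until exactly `n_dz_target` studies are double-zero, up to `max_draws`
#' rejections.
#'
#' @param spec A [sim_spec()].
#' @param max_draws Rejection bound (default 1e5 dataset draws).
#' @return A [meta_dataset()] with exactly `spec$n_dz_target` double-zero
#'   studies.
#' @export
generate_meta <- function(spec, max_draws = 1e5) {
  stopifnot(inherits(spec, "sim_spec"))
  p1 <- stats::plogis(stats::qlogis(spec$p0) + log(spec$true_or))
  with_local_seed(spec$seed, {
    for (draw in seq_len(max_draws)) {
      sizes <- spec$n_range[1]:spec$n_range[2]
      n_c <- sizes[sample.int(length(sizes), spec$k, replace = TRUE)]
      n_t <- pmax(1L, as.integer(round(spec$ratio * n_c)))
      c_cases <- stats::rbinom(spec$k, n_c, spec$p0)
      t_cases <- stats::rbinom(spec$k, n_t, p1)
      n_dz <- sum(c_cases == 0L & t_cases == 0L)
      if (n_dz == spec$n_dz_target) {
        return(meta_dataset(data.frame(
          study_id = sprintf("S%02d", seq_len(spec$k)),
          t_cases = t_cases, t_n = n_t,
          c_cases = c_cases, c_n = n_c,
          stringsAsFactors = FALSE
        )))
      }
    }
    stop(sprintf(
      "rejection bound exceeded (%g draws) without hitting %d double-zero studies; lower p0 or the target",
      max_draws, spec$n_dz_target), call. = FALSE)
  })
}

#' Compare the exact and approximating methods on simulated batches
#'
#' For each spec, generates a dataset, computes Hi and Bi by both the
#' exact and the approximating method, classifies each analysis as
#' impacted (0 < index <= cutoff) or not, and summarizes agreement with
#' the exact method as the gold standard: a 2x2 agreement table per index,
#' sensitivity, specificity, and — among datasets impacted by both
#' methods — the share where the approximating index needs exactly one
#' more case than the exact index.
#'
#' @param specs A list of [sim_spec()] objects (nonempty).
#' @param model,alpha,max_cases,cutoff Analysis settings, as in [hibi()].
#' @return A `comparison_summary` list with `per_dataset` (data frame) and
#'   per-index summaries `hi` and `bi`, each containing `table`,
#'   `sensitivity`, `specificity`, `frac_one_more`.
#' @export
compare_exact_approx <- function(specs, model = "peto", alpha = 0.05,
                                 max_cases = default_max_cases(),
                                 cutoff = default_max_cases()) {
  if (length(specs) == 0) stop("empty spec list", call. = FALSE)
  rows <- lapply(seq_along(specs), function(i) {
    ds <- generate_meta(specs[[i]])
    ex_hi <- compute_index_exact(ds, "treatment", model, alpha, max_cases)
    ex_bi <- compute_index_exact(ds, "control", model, alpha, max_cases)
    ap_hi <- compute_index_approx(ds, "treatment", model, alpha, max_cases)
    ap_bi <- compute_index_approx(ds, "control", model, alpha, max_cases)
    data.frame(dataset = i, n_dz = specs[[i]]$n_dz_target,
               hi_exact = ex_hi$index, bi_exact = ex_bi$index,
               hi_approx = ap_hi$index, bi_approx = ap_bi$index)
  })
  per_dataset <- do.call(rbind, rows)

  impacted <- function(idx) idx > 0 & idx <= cutoff
  summarize <- function(exact, approx) {
    gold <- impacted(exact)
    test <- impacted(approx)
    tab <- table(factor(test, levels = c(TRUE, FALSE)),
                 factor(gold, levels = c(TRUE, FALSE)),
                 dnn = c("approx", "exact"))
    sens <- if (sum(gold) > 0) sum(test & gold) / sum(gold) else NA_real_
    spec_ <- if (sum(!gold) > 0) sum(!test & !gold) / sum(!gold) else NA_real_
    both <- exact > 0 & approx > 0
    frac1 <- if (any(both)) mean(approx[both] == exact[both] + 1) else NA_real_
    list(table = tab, sensitivity = sens, specificity = spec_,
         frac_one_more = frac1)
  }
  structure(list(
    per_dataset = per_dataset,
    hi = summarize(per_dataset$hi_exact, per_dataset$hi_approx),
    bi = summarize(per_dataset$bi_exact, per_dataset$bi_approx),
    cutoff = cutoff, model = model, alpha = alpha,
    n_datasets = nrow(per_dataset)
  ), class = "comparison_summary")
}

#' @export
print.comparison_summary <- function(x, ...) {
  cat(sprintf("exact vs approximating comparison on %d simulated meta-analyses (%s model)\n",
              x$n_datasets, x$model))
  for (nm in c("hi", "bi")) {
    s <- x[[nm]]
    cat(sprintf("%s: sensitivity %.3f, specificity %.3f, approx = exact+1 share %.3f\n",
                toupper(nm), s$sensitivity, s$specificity, s$frac_one_more))
  }
  invisible(x)
}
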