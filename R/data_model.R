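#' Construct a meta-analysis dataset of 2x2 binary-outcome counts
#'
#' Validates per-study counts and derives the zero-structure partition used
#' throughout the package: every study is exactly one of *nonzero* (at least
#' one case in each arm), *single-zero* (zero cases in exactly one arm), or
#' *double-zero* (zero cases in both arms). Counts are cases, not events: a
#' participant contributes at most one case, so a count can never exceed the
#' arm's sample size.
#'
#' @param studies A data frame (or object coercible to one) with columns
#'   `study_id`, `t_cases`, `t_n`, `c_cases`, `c_n`: label, treatment-arm
#'   cases and sample size, control-arm cases and sample size.
#' @return An object of class `meta_dataset`: the validated data frame with
#'   a `zero_class` column (`"nonzero"`, `"single_zero"`, `"double_zero"`)
#'   and the original input order preserved in row order.
#' @examples
#' ds <- meta_dataset(data.frame(
#'   study_id = c("A", "B"),
#'   t_cases = c(0, 1), t_n = c(10, 50),
#'   c_cases = c(0, 3), c_n = c(10, 50)
#' ))
#' zero_classes(ds)
#' @seealso [read_meta_csv()], [classify_zero_structure()],
#'   [check_applicability()]
#' @export
meta_dataset <- function(studies) {
  studies <- as.data.frame(studies, stringsAsFactors = FALSE)
  required <- c("study_id", "t_cases", "t_n", "c_cases", "c_n")
  missing_cols <- setdiff(required, names(studies))
  if (length(missing_cols) > 0) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  studies <- studies[, required]
  if (nrow(studies) < 1) stop("dataset must contain at least one study",
                              call. = FALSE)

  studies$study_id <- as.character(studies$study_id)
  for (col in c("t_cases", "t_n", "c_cases", "c_n")) {
    x <- studies[[col]]
    if (is.character(x)) x <- suppressWarnings(as.numeric(x))
    if (anyNA(x) || any(x != round(x))) {
      stop("column '", col, "' must contain integers (counts of cases)",
           call. = FALSE)
    }
    studies[[col]] <- as.integer(round(x))
  }

  if (any(studies$t_n < 1L) || any(studies$c_n < 1L)) {
    stop("sample sizes must be >= 1 in both arms", call. = FALSE)
  }
  if (any(studies$t_cases < 0L) || any(studies$c_cases < 0L)) {
    stop("case counts must be nonnegative", call. = FALSE)
  }
  bad <- studies$t_cases > studies$t_n | studies$c_cases > studies$c_n
  if (any(bad)) {
    stop("cases exceed sample size in: ",
         paste(studies$study_id[bad], collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(studies$study_id)) {
    warning("duplicate study_id values present", call. = FALSE)
  }

  studies$zero_class <- ifelse(
    studies$t_cases == 0L & studies$c_cases == 0L, "double_zero",
    ifelse(studies$t_cases == 0L | studies$c_cases == 0L,
           "single_zero", "nonzero")
  )
  rownames(studies) <- NULL
  class(studies) <- c("meta_dataset", "data.frame")
  studies
}

#' Read a meta-analysis dataset from CSV
#'
#' Expects a UTF-8, comma-delimited file with header
#' `study_id,t_cases,t_n,c_cases,c_n`.
#'
#' @param path Path to the CSV file.
#' @return A [meta_dataset()].
#' @export
read_meta_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  meta_dataset(raw)
}

#' @export
print.meta_dataset <- function(x, ...) {
  parts <- zero_classes(x)
  cat(sprintf(
    "meta_dataset: %d studies (%d nonzero, %d single-zero, %d double-zero)\n",
    nrow(x), length(parts$nonzero), length(parts$single_zero),
    length(parts$double_zero)))
  cat(sprintf("zero-structure subtype: %s\n", classify_zero_structure(x)))
  print.data.frame(as.data.frame(x), ...)
  invisible(x)
}

#' Zero-structure partition of a dataset
#'
#' @param ds A [meta_dataset()].
#' @return A list with integer index vectors `nonzero`, `single_zero`,
#'   `double_zero` (row indices in input order); the three sets partition
#'   the studies.
#' @export
zero_classes <- function(ds) {
  stopifnot(inherits(ds, "meta_dataset"))
  list(
    nonzero     = which(ds$zero_class == "nonzero"),
    single_zero = which(ds$zero_class == "single_zero"),
    double_zero = which(ds$zero_class == "double_zero")
  )
}

#' Rank the double-zero studies by sample size
#'
#' Case addition starts in the largest double-zero study, so enumeration
#' orders those studies by descending total sample size, ties broken by
#' descending treatment-arm size, then input order.
#'
#' @param ds A [meta_dataset()].
#' @return Integer row indices of the double-zero studies, largest first.
#' @export
rank_double_zero <- function(ds) {
  idx <- zero_classes(ds)$double_zero
  if (length(idx) == 0) return(integer(0))
  tot <- ds$t_n[idx] + ds$c_n[idx]
  idx[order(-tot, -ds$t_n[idx], seq_along(idx))]
}

#' Classify the zero-structure subtype of a meta-analysis
#'
#' Labels a dataset by which kinds of zero-cell studies it contains:
#' `MA-SZ` (single-zero studies alongside nonzero studies), `MA-CSZ`
#' (single-zero studies only), `MA-DZ` (double-zero alongside nonzero),
#' `MA-CDZ` (double-zero only), and the mixtures `MA-MZ`/`MA-CMZ` when both
#' zero kinds are present. `NONE` means no study has a zero cell.
#'
#' The boundary between the two mixture labels is implemented as: `MA-CMZ`
#' when single-zero, double-zero and fully-nonzero studies are all present
#' and neither arm's total case count across studies is zero; `MA-MZ` for
#' any other mixture. This rule is this package's reading of the subtype
#' framework and is echoed in the JSON report.
#'
#' @param ds A [meta_dataset()].
#' @return A single string, one of `"MA-SZ"`, `"MA-CSZ"`, `"MA-DZ"`,
#'   `"MA-CDZ"`, `"MA-MZ"`, `"MA-CMZ"`, `"NONE"`.
#' @export
classify_zero_structure <- function(ds) {
  stopifnot(inherits(ds, "meta_dataset"))
  parts <- zero_classes(ds)
  n_nz <- length(parts$nonzero)
  n_sz <- length(parts$single_zero)
  n_dz <- length(parts$double_zero)

  if (n_sz == 0 && n_dz == 0) return("NONE")
  if (n_dz == nrow(ds)) return("MA-CDZ")
  if (n_sz == nrow(ds)) return("MA-CSZ")
  if (n_dz == 0) return("MA-SZ")
  if (n_sz == 0) return("MA-DZ")
  # both zero kinds present
  arm_totals_positive <- sum(ds$t_cases) > 0 && sum(ds$c_cases) > 0
  if (n_nz > 0 && arm_totals_positive) "MA-CMZ" else "MA-MZ"
}

#' Is the Hi-Bi method applicable to this dataset?
#'
#' The indices measure the impact of double-zero studies, so the dataset
#' must contain at least one double-zero study and at least one study with
#' a case somewhere. When every study is double-zero (`MA-CDZ`) there is
#' nothing to measure: the data already show no risk difference.
#'
#' @param ds A [meta_dataset()].
#' @return A list with `applicable` (logical) and `reason` (string, empty
#'   when applicable).
#' @export
check_applicability <- function(ds) {
  stopifnot(inherits(ds, "meta_dataset"))
  parts <- zero_classes(ds)
  if (length(parts$double_zero) == nrow(ds)) {
    return(list(applicable = FALSE,
                reason = "MA-CDZ: no study with cases"))
  }
  if (length(parts$double_zero) == 0) {
    return(list(applicable = FALSE, reason = "no double-zero study"))
  }
  list(applicable = TRUE, reason = "")
}

#' Exchange the treatment and control arms of every study
#'
#' Useful for symmetry checks: pooled log-effects negate under an arm swap
#' and the harms/benefits indices exchange roles.
#'
#' @param ds A [meta_dataset()].
#' @return A [meta_dataset()] with arms swapped; the zero-structure
#'   partition is unchanged as a set.
#' @export
swap_arms <- function(ds) {
  stopifnot(inherits(ds, "meta_dataset"))
  out <- as.data.frame(ds)
  out[, c("t_cases", "t_n", "c_cases", "c_n")] <-
    out[, c("c_cases", "c_n", "t_cases", "t_n")]
  meta_dataset(out[, c("study_id", "t_cases", "t_n", "c_cases", "c_n")])
}
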