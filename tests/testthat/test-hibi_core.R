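test_that("enumeration obeys the count law, with and without binding caps", {
  expect_equal(nrow(enumerate_combinations(3, 3)), 64)
  expect_equal(nrow(enumerate_combinations(3, 5)), 216)
  expect_equal(nrow(enumerate_combinations(3, 10)), 1331)
  expect_equal(count_combinations(10, 3), 4^10)
  # a cap below m binds: arm of size 2 admits only 0, 1, 2
  expect_equal(nrow(enumerate_combinations(1, 3, caps = 2)), 3)
  expect_equal(count_combinations(2, 3, caps = c(2, 10)), 3 * 4)
})

test_that("enumeration order is ascending total, concentrated-first, unique", {
  for (case in list(list(n = 2, m = 3), list(n = 3, m = 2),
                    list(n = 3, m = 3, caps = c(3, 2, 1)))) {
    combos <- enumerate_combinations(case$n, case$m, case$caps)
    expect_equal(combos[1, ], rep(0L, case$n))          # reference first
    tot <- rowSums(combos)
    expect_true(all(diff(tot) >= 0))                    # ascending totals
    expect_equal(anyDuplicated(combos), 0)              # each vector once
    # ties concentrate cases in earlier-ranked (larger) studies:
    # within a total, rows sorted descending lexicographically
    for (t_val in unique(tot)) {
      block <- combos[tot == t_val, , drop = FALSE]
      if (nrow(block) > 1) {
        keys <- do.call(order, lapply(seq_len(ncol(block)),
                                      function(j) -block[, j]))
        expect_equal(keys, seq_len(nrow(block)))
      }
    }
  }
  # n = 2, m = 1: the only total-2 combination is one case in each study
  expect_equal(enumerate_combinations(2, 1)[4, ], c(1L, 1L))
})

test_that("the enumeration budget guard triggers and can be forced", {
  expect_error(enumerate_combinations(11, 3), "budget exceeded")
  expect_silent(enumerate_combinations(11, 3, budget = 4^11))
})

test_that("apply_combination places cases without touching sample sizes", {
  ds <- worked_dataset()
  mod <- apply_combination(ds, added = 3L, arm = "treatment")
  expect_equal(mod$t_cases, c(3L, 1L))
  expect_equal(mod$t_n, ds$t_n)
  expect_equal(mod$c_cases, ds$c_cases)
  expect_equal(zero_classes(mod)$single_zero, 1L)

  # reference combination is the identity
  same <- apply_combination(ds, added = 0L, arm = "control")
  expect_equal(as.data.frame(same), as.data.frame(ds))

  two <- meta_dataset(data.frame(
    study_id = c("A", "B", "C"),
    t_cases = c(0, 0, 1), t_n = c(20, 10, 50),
    c_cases = c(0, 0, 3), c_n = c(20, 10, 50)
  ))
  mod2 <- apply_combination(two, added = c(1L, 1L), arm = "control")
  expect_equal(mod2$c_cases, c(1L, 1L, 3L))

  expect_error(apply_combination(ds, added = 11L, arm = "treatment"),
               "exceed")
})

test_that("change detection is a direction crossing or a significance flip", {
  mk <- function(log_effect, se) {
    ds <- worked_dataset()
    r <- peto_pool(ds)
    r$log_effect <- log_effect
    r$se <- se
    r$p_value <- 2 * pnorm(-abs(log_effect / se))
    r
  }
  ref <- mk(-1.03, 1.02)                       # negative, ns
  expect_true(detect_change(ref, mk(0.30, 1.1)))   # sign crossing
  expect_false(detect_change(ref, mk(0, 1.1)))     # zero is not a crossing
  expect_false(detect_change(ref, mk(-0.2, 1.0)))  # same side, still ns
  # significance flip with the same sign
  ref2 <- mk(-1, -1 / qnorm(0.02))             # p = 0.04
  new2 <- mk(-1, -1 / qnorm(0.03))             # p = 0.06
  expect_equal(ref2$p_value, 0.04, tolerance = 1e-12)
  expect_equal(new2$p_value, 0.06, tolerance = 1e-12)
  expect_true(detect_change(ref2, new2))
  expect_true(detect_change(new2, ref2))       # symmetric
})

test_that("exact indices on the worked dataset match the hand enumeration", {
  ds <- worked_dataset()
  hi <- compute_index_exact(ds, "treatment", "peto")
  expect_equal(hi$index, 3L)
  expect_equal(sum(hi$combination), 3)
  # intermediate totals from the hand oracle: -0.410, 0.000, +0.305
  tr <- hi$trace
  expect_equal(tr$log_effect[tr$total == 0], -1.031250, tolerance = 1e-6)
  # exact fractions: -(1/2)/(32/33 + 1/4) and (1/2)/(32/33 + 51/76)
  expect_equal(tr$log_effect[tr$total == 1], -66 / 161, tolerance = 1e-12)
  expect_equal(tr$log_effect[tr$total == 2], 0, tolerance = 1e-12)
  expect_equal(tr$log_effect[tr$total == 3], 1254 / 4115, tolerance = 1e-12)

  bi <- compute_index_exact(ds, "control", "peto")
  expect_equal(bi$index, 0L)
  expect_null(bi$combination)
  # at total = 3 the z statistic stays just under the 1.96 threshold
  z3 <- with(bi$trace[bi$trace$total == 3, ], abs(log_effect / se))
  expect_lt(z3, qnorm(0.975))
  expect_gt(z3, 1.9)
})

test_that("the exact trace is complete and the index is the minimal change", {
  for (seed in c(2, 5, 9, 14, 21)) {
    ds <- rand_meta(seed, k = 5, n_dz = 2, n_lo = 3, n_hi = 40)
    res <- compute_index_exact(ds, "treatment", "peto")
    dz <- rank_double_zero(ds)
    expect_equal(nrow(res$trace),
                 count_combinations(length(dz), 3, ds$t_n[dz]))
    # independent re-scan of the trace for the minimum changing total
    changed_totals <- res$trace$total[which(res$trace$changed)]
    if (length(changed_totals) == 0) {
      expect_equal(res$index, 0L)
    } else {
      expect_equal(res$index, min(changed_totals))
    }
  }
})

test_that("pivot selection prefers weighted effect, then size, then order", {
  two <- meta_dataset(data.frame(
    study_id = c("nz", "small", "big"),
    t_cases = c(1, 0, 0), t_n = c(50, 10, 100),
    c_cases = c(3, 0, 0), c_n = c(50, 10, 100)
  ))
  expect_equal(two$study_id[select_pivot_study(two)], "big")

  one <- worked_dataset()
  expect_equal(one$study_id[select_pivot_study(one)], "A")

  twins <- meta_dataset(data.frame(
    study_id = c("first", "second", "nz"),
    t_cases = c(0, 0, 1), t_n = c(30, 30, 50),
    c_cases = c(0, 0, 3), c_n = c(30, 30, 50)
  ))
  expect_equal(twins$study_id[select_pivot_study(twins)], "first")

  # unbalanced arms: larger control share gives the larger O - E
  unb <- meta_dataset(data.frame(
    study_id = c("lopsided", "balanced", "nz"),
    t_cases = c(0, 0, 1), t_n = c(10, 50, 50),
    c_cases = c(0, 0, 3), c_n = c(90, 50, 50)
  ))
  expect_equal(unb$study_id[select_pivot_study(unb)], "lopsided")
})

test_that("the approximating method respects its evaluation budget", {
  ds <- meta_dataset(data.frame(
    study_id = c(sprintf("DZ%02d", 1:10), "NZ1", "NZ2"),
    t_cases = c(rep(0, 10), 2, 1), t_n = c(rep(60, 10), 100, 80),
    c_cases = c(rep(0, 10), 5, 3), c_n = c(rep(60, 10), 100, 80)
  ))
  res <- compute_index_approx(ds, "treatment", "peto")
  expect_equal(res$max_added, 30)           # 3 * n cases at most
  expect_equal(nrow(res$trace), 31)         # 3n + 1 poolings incl. reference

  # a small pivot arm caps the additions at the arm size
  small <- meta_dataset(data.frame(
    study_id = c(sprintf("DZ%02d", 1:10), "NZ1"),
    t_cases = c(rep(0, 10), 2), t_n = c(rep(5, 10), 100),
    c_cases = c(rep(0, 10), 5), c_n = c(rep(5, 10), 100)
  ))
  res_small <- compute_index_approx(small, "treatment", "peto")
  expect_equal(res_small$max_added, 5)
  expect_equal(nrow(res_small$trace), 6)
})

test_that("with one double-zero study exact and approximating agree exactly", {
  for (seed in 1:200) {
    ds <- rand_meta(seed, k = sample(3:7, 1), n_dz = 1, n_lo = 3, n_hi = 60)
    for (arm in c("treatment", "control")) {
      ex <- compute_index_exact(ds, arm, "peto")
      ap <- compute_index_approx(ds, arm, "peto")
      expect_equal(ap$index, ex$index)
    }
  }
})

test_that("impact categories follow the cutoff rules", {
  expect_equal(classify_impact(0), "no_impact")
  expect_equal(classify_impact(2, 3), "potential_impact")
  expect_equal(classify_impact(3, 3), "potential_impact")
  expect_equal(classify_impact(4, 3), "almost_no_impact")
  expect_equal(classify_impact(4, 5), "potential_impact")
  expect_equal(classify_impact(6, 5), "almost_no_impact")
  expect_error(classify_impact(1, 4), "cutoff")
  expect_equal(strict_cutoff(), 5L)
})

test_that("hibi orchestrates both indices with the auto method switch", {
  ds <- worked_dataset()
  res <- hibi(ds)
  expect_s3_class(res, "hibi_result")
  expect_equal(res$hi, 3L)
  expect_equal(res$bi, 0L)
  expect_equal(res$hi_category, "potential_impact")
  expect_equal(res$bi_category, "no_impact")
  expect_equal(res$method, "exact")
  expect_equal(res$n_double_zero, 1L)

  # 8 double-zero studies flip auto mode to the approximating method
  big <- meta_dataset(data.frame(
    study_id = c(sprintf("DZ%d", 1:8), "NZ"),
    t_cases = c(rep(0, 8), 2), t_n = c(rep(40, 8), 100),
    c_cases = c(rep(0, 8), 6), c_n = c(rep(40, 8), 100)
  ))
  res_big <- hibi(big)
  expect_equal(res_big$method, "approx")
  res_forced <- hibi(big, method = "exact", budget = 4^8)
  expect_equal(res_forced$method, "exact")
})

test_that("hibi rejects forbidden measure/model pairs and inapplicable data", {
  ds <- worked_dataset()
  expect_error(hibi(ds, measure = "rr", model = "peto"), "cannot estimate")
  expect_error(hibi(ds, measure = "or", model = "mh"), "cannot estimate")
  expect_equal(hibi(ds, measure = "rr")$model, "mh")

  cdz <- meta_dataset(data.frame(study_id = c("A", "B"),
                                 t_cases = c(0, 0), t_n = c(10, 20),
                                 c_cases = c(0, 0), c_n = c(10, 20)))
  err <- tryCatch(hibi(cdz), error = function(e) e)
  expect_s3_class(err, "hibi_not_applicable")
  expect_match(conditionMessage(err), "MA-CDZ")
})

test_that("arm-swap duality exchanges Hi and Bi under the Peto engine", {
  for (seed in 1:100) {
    ds <- rand_meta(seed, k = sample(3:6, 1), n_dz = sample(1:2, 1),
                    n_lo = 5, n_hi = 60)
    a <- hibi(ds)
    b <- hibi(swap_arms(ds))
    expect_equal(b$hi, a$bi)
    expect_equal(b$bi, a$hi)
  }
})

test_that("zero-stability: no changing combination means both indices zero", {
  ds <- tourniquet_fixture()
  res <- hibi(ds)
  expect_false(any(res$traces$hi$changed))
  expect_false(any(res$traces$bi$changed))
  expect_equal(res$hi, 0L)
  expect_equal(res$bi, 0L)
  expect_equal(res$hi_category, "no_impact")
  expect_equal(res$bi_category, "no_impact")
})

test_that("pooled Peto effect rises monotonically with added treatment cases", {
  checked <- 0
  for (seed in 1:40) {
    ds <- rand_meta(seed, k = 4, n_dz = 1, n_lo = 8, n_hi = 60)
    if (peto_pool(ds)$log_effect > 0) next
    effects <- vapply(0:3, function(g) {
      peto_pool(apply_combination(ds, g, "treatment"))$log_effect
    }, numeric(1))
    expect_true(all(diff(effects) > 0))
    checked <- checked + 1
  }
  expect_gt(checked, 5)
})
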