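# a tiny deterministic count table + FR set used across several blocks
toy_counts <- function() {
  dplyr::bind_rows(
    tibble::tibble(pool = "supercoiled", time = 0,
                   sequence = c("s0", "s1", "s2"),
                   count = c(50L, 30L, 20L), n_mm = c(0L, 1L, 2L)),
    tibble::tibble(pool = "supercoiled", time = 5,
                   sequence = c("s0", "s1", "s2"),
                   count = c(10L, 40L, 50L), n_mm = c(0L, 1L, 2L))
  )
}

toy_fr <- function() {
  tibble::tibble(pool = "supercoiled", time = c(0, 5), fr = c(0.95, 0.4))
}

test_that("mismatch fractions partition the pool", {
  tab <- toy_counts()[toy_counts()$time == 0, ]
  f <- mismatch_fraction(tab)
  expect_equal(sum(f$f), 1)
  expect_equal(f$f[f$n == 0], 0.5)
  one <- mismatch_fraction(tibble::tibble(count = 7L, n_mm = 2L))
  expect_equal(one$f, 1)
  expect_error(mismatch_fraction(tibble::tibble(count = integer(), n_mm = integer())),
               class = "cas9profiler_data_error")
})

test_that("estimated and relative abundance follow the scaling identities", {
  expect_equal(estimated_abundance(c(0.5, 0.5), 0), c(0, 0))
  expect_equal(estimated_abundance(1, 1), 1)
  f <- c(0.2, 0.3, 0.5)
  expect_equal(sum(estimated_abundance(f, 0.37)), 0.37)
  expect_error(estimated_abundance(0.5, 1.2), class = "cas9profiler_data_error")

  expect_equal(relative_abundance(0.3, 0.3), 1)
  expect_equal(relative_abundance(0, 0.2), 0)
  expect_true(is.na(relative_abundance(0.1, 0)))  # missing, never Inf
})

test_that("log fold change floors exact zeros and flags them", {
  expect_equal(as.numeric(log_fold_change(1)), 0)
  expect_equal(as.numeric(log_fold_change(0.5)), -1)
  x <- log_fold_change(c(1, 0.25, 0))
  expect_equal(as.numeric(x)[1:2], c(0, -2))
  expect_identical(attr(x, "floored"), c(FALSE, FALSE, TRUE))
  expect_equal(as.numeric(x)[3], log2(0.25 / 2))  # half the smallest positive
  expect_error(log_fold_change(-0.1), class = "cas9profiler_domain_error")
})

test_that("off-target aggregation is a ratio of sums over strata 1-5", {
  ea_t <- c(0.1, 0.2, 0.3, 0.1, 0.05, 0.01)
  ea_0 <- c(0.2, 0.25, 0.3, 0.15, 0.08, 0.02)
  got <- off_target_abundance(ea_t, ea_0, n = 0:5)
  expect_equal(got, sum(ea_t[2:6]) / sum(ea_0[2:6]))
  expect_equal(off_target_abundance(ea_0, ea_0, n = 0:5), 1)
  expect_equal(off_target_abundance(rep(0, 5), ea_0[2:6], n = 1:5), 0)
  expect_true(is.na(off_target_abundance(ea_t[2:6], rep(0, 5), n = 1:5)))
})

test_that("cleaved fractions, specificity score and propagation behave", {
  cf <- cleaved_fractions(0, 1)
  expect_equal(cf$on, 1)
  expect_equal(cf$off, 0)
  cf <- cleaved_fractions(1.2, 0.5)
  expect_true(cf$on_flagged)  # enrichment beyond control, kept as-is

  expect_equal(specificity_score(1, 0.5)$ss, 2)
  expect_equal(specificity_score(0.3, 0.3)$ss, 1)
  expect_true(is.na(specificity_score(1, 0)$ss))
  expect_true(specificity_score(0.5, -0.1)$unreliable)

  rel <- relative_specificity(
    tibble::tibble(time = 1, ss = 1, sem = 0.1),
    tibble::tibble(time = 1, ss = 1, sem = 0.1)
  )
  expect_equal(rel$relative_ss, 1)
  expect_equal(rel$sem, sqrt(0.02), tolerance = 1e-12)  # ~0.141
  rel2 <- relative_specificity(
    tibble::tibble(time = c(1, 5), ss = c(2, 2)),
    tibble::tibble(time = c(1, 5), ss = c(4, 4))
  )
  expect_equal(rel2$relative_ss, c(0.5, 0.5))
})

test_that("abundance courses satisfy the framework identities", {
  ab <- abundance_course(toy_counts(), toy_fr(), n_max = 5)
  sums <- ab |> dplyr::group_by(time) |> dplyr::summarise(f = sum(f), ea = sum(ea))
  expect_equal(sums$f, c(1, 1))
  expect_equal(sums$ea, toy_fr()$fr)
  ctrl <- dplyr::filter(ab, time == 0, f > 0)
  expect_true(all(ctrl$ra == 1))
  expect_true(all(ctrl$log2fc == 0))
  # hand-computed RA for the 0-mismatch stratum at t = 5
  expect_equal(dplyr::filter(ab, time == 5, n == 0)$ra,
               (0.1 * 0.4) / (0.5 * 0.95))
  expect_error(abundance_course(toy_counts(), toy_fr()[1, ]),
               class = "cas9profiler_data_error")
})

test_that("abundance on noise-free simulation matches closed-form aggregation", {
  run <- fixture_run("wt", depth = 30000L)
  ab <- abundance_course(run$truth, run$fr)
  # closed-form: EA_n(t) = sum of member weights * pool fraction in stratum
  agg <- run$states |>
    dplyr::left_join(dplyr::select(run$members, sequence, n_mm), by = "sequence") |>
    dplyr::group_by(time, n = n_mm) |>
    dplyr::summarise(ea_sc = sum(weight * sc), .groups = "drop")
  j <- dplyr::inner_join(dplyr::filter(ab, pool == "supercoiled"), agg,
                         by = c("time", "n"))
  # multinomial sampling error at depth 30k: generous uniform bound
  expect_true(all(abs(j$ea - j$ea_sc) < 0.02))
})

test_that("specificity course of a WT-like run keeps on >= off", {
  run <- fixture_run("wt", depth = 30000L)
  sc <- specificity_course(abundance_course(run$truth, run$fr))
  late <- dplyr::filter(sc, time > 0)
  expect_true(all(late$on >= late$off - 1e-9))
  expect_equal(dplyr::filter(sc, time == 0)$ra_on, 1)
  expect_equal(dplyr::filter(sc, time == 0)$ra_off, 1)
})
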