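test_that("undoped and fully doped libraries are degenerate as designed", {
  ts <- fixture_spec()
  lib0 <- sample_library(ts, doping_scheme(0), n_members = 1000, seed = 1)
  expect_identical(nrow(lib0), 1L)
  expect_identical(lib0$sequence, ts$protospacer)
  expect_equal(lib0$weight, 1)
  expect_identical(lib0$n_mm, 0L)

  lib1 <- sample_library(ts, doping_scheme(1), n_members = 500, seed = 1)
  ref_chars <- strsplit(ts$protospacer, "")[[1]]
  mats <- strsplit(lib1$sequence, "")
  expect_true(all(vapply(mats, function(x) all(x != ref_chars), logical(1))))
})

test_that("sampled library composition follows the doping scheme", {
  ts <- fixture_spec()
  lib <- sample_library(ts, fixture_scheme(), n_members = 50000, seed = 42)
  expect_equal(sum(lib$weight), 1, tolerance = 1e-12)
  # per-position reference-base frequency near 1 - f
  mat <- matrix(unlist(strsplit(lib$sequence, "")), ncol = 20, byrow = TRUE)
  ref_chars <- strsplit(ts$protospacer, "")[[1]]
  freq <- vapply(1:20, function(j) {
    sum(lib$weight[mat[, j] == ref_chars[j]])
  }, numeric(1))
  expect_true(all(abs(freq - 0.85) < 0.015))
  # mismatch-count histogram converges on the binomial model
  hist_n <- tapply(lib$weight, lib$n_mm, sum)
  expected <- mismatch_probability(as.integer(names(hist_n)), 20, 0.15)
  expect_true(all(abs(hist_n - expected) < 0.01))
  # weights are consistent with annotations
  expect_true(all(lib$n_mm == lengths(lib$mm_pos)))
})

test_that("kinetic assignment multiplies penalties per mismatch position", {
  ts <- fixture_spec()
  prof <- hf_profile()
  lib <- sample_library(ts, fixture_scheme(), n_members = 5000, seed = 3)
  lib <- assign_kinetics(lib, prof)
  # perfect target gets the base rates
  perfect <- lib[lib$n_mm == 0, ]
  expect_equal(perfect$k1, prof$k_nick_base)
  expect_equal(perfect$k2, prof$k_lin_base)
  # independent recomputation of the product formula for every member
  k1_direct <- vapply(lib$mm_pos, function(p) {
    prof$k_nick_base * prod(prof$position_penalties[p])
  }, numeric(1))
  k2_direct <- vapply(lib$mm_pos, function(p) {
    prof$k_lin_base * prof$distal_second_strand_penalty^sum(p > prof$seed_len)
  }, numeric(1))
  expect_equal(lib$k1, k1_direct, tolerance = 1e-12)
  expect_equal(lib$k2, k2_direct, tolerance = 1e-12)
  # one seed mismatch: k1 scaled by that penalty, k2 untouched
  one_seed <- lib[lib$n_mm == 1 & vapply(lib$mm_pos, function(p)
    all(p <= prof$seed_len), logical(1)), ]
  expect_true(all(abs(one_seed$k2 - prof$k_lin_base) < 1e-12))
  expect_true(all(abs(one_seed$k1 -
    prof$k_nick_base * prof$position_penalties[unlist(one_seed$mm_pos)]) < 1e-12))
})

test_that("pool evolution matches numerical ODE integration", {
  skip_if_not_installed("deSolve")
  grid <- expand.grid(
    k1 = c(0, 0.01, 0.1, 1, 2),
    k2 = c(0, 0.1, 0.100000001, 1.7),
    t = c(0.5, 5, 60)
  )
  worst <- 0
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    got <- evolve_pools(g$k1, g$k2, g$t)
    want <- ode_pools(g$k1, g$k2, g$t)
    worst <- max(worst, abs(got$sc - want[["sc"]]),
                 abs(got$nicked - want[["nicked"]]),
                 abs(got$linear - want[["linear"]]))
  }
  expect_lt(worst, 1e-8)
})

test_that("pool fractions obey conservation, limits and monotonicity", {
  st0 <- evolve_pools(1, 1, 0)
  expect_equal(unlist(st0[c("sc", "nicked", "linear")]),
               c(sc = 1, nicked = 0, linear = 0))
  # pure nickase limit
  stn <- evolve_pools(0.3, 0, c(1, 10, 100))
  expect_equal(stn$linear, rep(0, 3), tolerance = 1e-12)
  expect_equal(stn$nicked, 1 - exp(-0.3 * c(1, 10, 100)), tolerance = 1e-12)
  # equal-rate limit
  st <- evolve_pools(0.1, 0.1, 10)
  expect_equal(st$nicked, exp(-1), tolerance = 1e-9)
  # conservation and monotone SC on a dense grid
  tt <- seq(0, 180, by = 0.5)
  st <- evolve_pools(0.7, 0.2, tt)
  expect_true(all(abs(st$sc + st$nicked + st$linear - 1) < 1e-9))
  expect_true(all(diff(st$sc) < 0))
  expect_true(all(diff(st$linear) >= -1e-12))
  expect_error(evolve_pools(1, 1, -1), class = "cas9profiler_domain_error")
})

test_that("simulated runs conserve depth and respect pool structure", {
  run <- fixture_run("wt", depth = 30000L)
  tot <- dplyr::count(run$truth, pool, time, wt = count)
  expect_true(all(tot$n == 30000L))
  # gel masses sum to 1 at every time
  expect_equal(run$gel$i_sc + run$gel$i_n + run$gel$i_l,
               rep(1, nrow(run$gel)), tolerance = 1e-9)
  # t = 0 supercoiled pool reproduces the library composition
  t0 <- dplyr::filter(run$truth, pool == "supercoiled", time == 0)
  f0 <- tapply(t0$count, t0$n_mm, sum) / sum(t0$count)
  expected <- mismatch_probability(as.integer(names(f0)), 20, 0.15)
  expect_true(all(abs(f0 - expected) < 0.015))
})

test_that("noise-free gel lanes reproduce aggregate pool fractions exactly", {
  run <- fixture_run("wt", depth = 30000L)
  lanes <- render_gel(run, noise_sd = 0)
  fr <- pool_fractions(lanes)
  agg <- run$states |>
    dplyr::group_by(time) |>
    dplyr::summarise(sc = sum(weight * sc), n = sum(weight * nicked))
  expect_equal(fr$fr_sc, agg$sc, tolerance = 1e-12)
  expect_equal(fr$fr_n, agg$n, tolerance = 1e-12)
  # WT-like vs HF-like: HF lane keeps a higher nicked:linear ratio at 60 min
  hf <- fixture_run("hf", depth = 30000L)
  g60w <- lanes[lanes$t == 60, ]
  g60h <- render_gel(hf)[render_gel(hf)$t == 60, ]
  expect_gt(g60h$i_n / g60h$i_l, g60w$i_n / g60w$i_l)
})

test_that("fully linearized members vanish from both sequenced pools", {
  ts <- fixture_spec()
  members <- tibble::tibble(
    sequence = c(ts$protospacer, "AAAAAAAAAAAAAAAAAAAA"),
    weight = c(0.5, 0.5)
  )
  st <- evolve_pools(c(50, 0), c(50, 0), t = 60)
  expect_lt(st$sc[1] + st$nicked[1], 1e-12)  # fast member fully linear
  expect_equal(st$sc[2], 1)                  # inert member untouched
})

test_that("variant profile validation rejects out-of-range penalties", {
  expect_error(variant_profile("x", 1, 1, position_penalties = rep(1.5, 20)),
               class = "cas9profiler_domain_error")
  expect_error(variant_profile("x", -1, 1), class = "cas9profiler_domain_error")
  expect_error(variant_profile("x", 1, 1, distal_second_strand_penalty = 0),
               class = "cas9profiler_domain_error")
})
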