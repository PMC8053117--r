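# Shared fixtures: a 55% GC synthetic target and small simulated runs.

fixture_spec <- function() {
  target_spec("GGTGATCCAGGCACTTAAGC", pam = "TGG", seed_len = 10L)
}

fixture_scheme <- function(f = 0.15) doping_scheme(f)

# cache small paired runs so several test files can share them
fixture_run <- local({
  cache <- list()
  function(profile = c("wt", "hf"), depth = 30000L, seed = 11L) {
    profile <- match.arg(profile)
    key <- paste(profile, depth, seed, sep = "_")
    if (is.null(cache[[key]])) {
      prof <- if (profile == "wt") wt_profile() else hf_profile()
      cache[[key]] <<- simulate_cleavage_run(
        fixture_spec(), fixture_scheme(), prof,
        depth = depth, n_members = depth, seed = seed
      )
    }
    cache[[key]]
  }
})

# Exhaustive enumeration oracle: all 4^L sequences of length L with their
# doping probabilities against a reference; used to validate the binomial
# model and combination counts independently of the closed forms.
enumerate_library <- function(ref, f) {
  L <- nchar(ref)
  ref_chars <- strsplit(ref, "", fixed = TRUE)[[1]]
  bases <- c("A", "C", "G", "T")
  grids <- rep(list(bases), L)
  all_seqs <- do.call(expand.grid, c(grids, stringsAsFactors = FALSE))
  mm <- 0L
  prob <- 1
  for (j in seq_len(L)) {
    is_ref <- all_seqs[[j]] == ref_chars[j]
    mm <- mm + !is_ref
    prob <- prob * ifelse(is_ref, 1 - f, f / 3)
  }
  data.frame(n = mm, prob = prob)
}

# Numerical ODE oracle for the sequential first-order scheme.
ode_pools <- function(k1, k2, t, sc0 = 1, n0 = 0) {
  deriv <- function(t, y, parms) {
    with(as.list(c(y, parms)), {
      list(c(dSC = -k1 * SC, dN = k1 * SC - k2 * N))
    })
  }
  out <- deSolve::ode(
    y = c(SC = sc0, N = n0), times = c(0, t),
    func = deriv, parms = c(k1 = k1, k2 = k2),
    method = "lsoda", rtol = 1e-10, atol = 1e-12
  )
  last <- out[nrow(out), ]
  c(sc = unname(last["SC"]), nicked = unname(last["N"]),
    linear = 1 - unname(last["SC"]) - unname(last["N"]))
}
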