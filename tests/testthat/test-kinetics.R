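test_that("TST rates have the correct prefactor and barrier dependence", {
  kT <- kT_kcal(300)
  net <- ktn(data.frame(V = c(0, 0), logProd = 27, pgOrder = 1),
             data.frame(V = 0, logProd = 27, pgOrder = 1,
                        min1 = 1, min2 = 2))
  expect_equal(tst_rate(net, 1, 1, 300), 1)   # pure prefactor

  raised <- net
  raised$ts$V <- kT * log(10)
  expect_equal(tst_rate(raised, 1, 1, 300), 0.1, tolerance = 1e-12)

  expect_error(tst_rate(net, 1, 99, 300), "no transition state")
  three <- ktn(data.frame(V = 0:2, logProd = 27, pgOrder = 1),
               data.frame(V = 3, logProd = 27, pgOrder = 1,
                          min1 = 1, min2 = 2))
  expect_error(tst_rate(three, 3, 1, 300), "not adjacent")
})

test_that("TST rates satisfy detailed balance with the harmonic weights", {
  net <- generate_random_ktn(12, seed = 4)
  lw <- log_weight(net, 350)
  for (r in seq_len(n_ts(net))) {
    a <- net$ts$min1[r]; b <- net$ts$min2[r]
    if (a == b) next
    flux_ab <- tst_rate(net, a, r, 350) * exp(lw[a])
    flux_ba <- tst_rate(net, b, r, 350) * exp(lw[b])
    expect_equal(flux_ab, flux_ba, tolerance = 1e-12)
  }
})

test_that("exchange decomposition is definitional arithmetic", {
  r <- exchange_to_microrates(474, 0.004)
  expect_equal(r$k_f, 1.896)
  expect_equal(r$k_r, 472.104)
  r <- exchange_to_microrates(100, 0.5)
  expect_equal(r$k_f, r$k_r)
  r <- exchange_to_microrates(100, 1e-12)
  expect_equal(r$k_f, 1e-10)
  expect_equal(r$k_r, 100, tolerance = 1e-10)
  expect_error(exchange_to_microrates(100, 0), "p_minor")
  expect_error(exchange_to_microrates(-1, 0.2), "k_ex")
})

test_that("Eyring conversion and its inverse are exact", {
  for (temperature in c(200, 310.15, 400)) {
    expect_equal(eyring_barrier(kT_over_h(temperature), temperature), 0)
    for (dG in c(0.3, 5, 17.8)) {
      expect_equal(eyring_barrier(barrier_to_rate(dG, temperature),
                                  temperature), dG, tolerance = 1e-12)
    }
  }
  expect_error(eyring_barrier(0, 300), "positive")
})

test_that("rate matrix columns sum to zero and respect detailed balance", {
  ## 1x1 zero matrix for a single minimum
  one <- ktn(data.frame(V = 0, logProd = 27, pgOrder = 1))
  expect_equal(build_rate_matrix(one, 300), matrix(0, 1, 1),
               ignore_attr = TRUE)

  ## symmetric two-state fixture
  net2 <- ktn(data.frame(V = c(0, 0), logProd = 27, pgOrder = 1),
              data.frame(V = 1, logProd = 26, pgOrder = 1,
                         min1 = 1, min2 = 2))
  K2 <- build_rate_matrix(net2, 300)
  expect_equal(K2[2, 1], K2[1, 2])

  for (seed in c(3, 13)) {
    net <- generate_random_ktn(10, seed = seed)
    K <- build_rate_matrix(net, 310.15)
    expect_lt(max(abs(colSums(K))), 1e-12 * max(abs(K)))
    p <- equilibrium_occupations(net, 310.15)$p
    off <- which(K > 0 & row(K) != col(K), arr.ind = TRUE)
    resid <- apply(off, 1L, function(idx) {
      b <- idx[1]; a <- idx[2]
      abs(K[b, a] * p[a] - K[a, b] * p[b]) / (K[b, a] * p[a])
    })
    expect_lt(max(resid), 1e-10)
  }
})

test_that("parallel transition states add their rates", {
  net <- ktn(data.frame(V = c(0, 0.5), logProd = 27, pgOrder = 1),
             data.frame(V = c(2, 2.5), logProd = 26, pgOrder = 1,
                        min1 = c(1, 1), min2 = c(2, 2)))
  K <- build_rate_matrix(net, 300)
  expect_equal(K[2, 1],
               tst_rate(net, 1, 1, 300) + tst_rate(net, 1, 2, 300))
})

test_that("two-state rates on a 2-minimum network equal the TST rates exactly", {
  net <- generate_two_state(7.5, 5.1, 298)
  ts2 <- two_state_rates(net, 1, 2, 298)
  expect_equal(ts2$k_f, tst_rate(net, 1, 1, 298), tolerance = 1e-12)
  expect_equal(ts2$k_r, tst_rate(net, 2, 1, 298), tolerance = 1e-12)
  ## and the forward/reverse ratio equals the population ratio
  occ <- equilibrium_occupations(net, 298)
  expect_equal(ts2$k_f / ts2$k_r, occ$p[2] / occ$p[1], tolerance = 1e-8)
})

test_that("constructed barriers are recovered through the full rate pipeline", {
  net <- generate_two_state(17.8, 14.3, 310.15)
  ts2 <- two_state_rates(net, 1, 2, 310.15)
  expect_equal(ts2$dG_f, 17.8, tolerance = 1e-6)
  expect_equal(ts2$dG_r, 14.3, tolerance = 1e-6)
})

test_that("MFPT rates match the matrix-exponential oracle on a deep two-state network", {
  net <- generate_random_ktn(6, seed = 5, deep = c(1, 6))
  occ <- equilibrium_occupations(net, 310.15)
  expect_lt(sum(occ$p[2:5]), 1e-3)
  ts2 <- two_state_rates(net, 1, 6, 310.15)
  orc <- expm_rate_oracle(net, 1, 6, 310.15)
  expect_equal(ts2$k_f, orc$k_f, tolerance = 0.01)
  expect_equal(ts2$k_r, orc$k_r, tolerance = 0.01)
  ## forward/reverse ratio deviates from equilibrium only at the level of
  ## the intermediate population
  ratio_dev <- abs(ts2$k_f / ts2$k_r * occ$p[1] / occ$p[6] - 1)
  expect_lt(ratio_dev, 10 * sum(occ$p[2:5]) + 1e-10)
})

test_that("a high-intermediate chain follows the steady-state two-step formula", {
  kT <- kT_kcal(300)
  net <- ktn(data.frame(V = c(0, 6, 0.3), logProd = 27, pgOrder = 1),
             data.frame(V = c(8, 8.4), logProd = 26.5, pgOrder = 1,
                        min1 = c(1, 2), min2 = c(2, 3)),
             kappa = 3)
  occ <- equilibrium_occupations(net, 300)
  expect_lt(occ$p[2], 1e-3)
  k1 <- tst_rate(net, 1, 1, 300); km1 <- tst_rate(net, 2, 1, 300)
  k2 <- tst_rate(net, 2, 2, 300)
  kss <- k1 * k2 / (km1 + k2)
  ts2 <- two_state_rates(net, 1, 3, 300)
  expect_equal(ts2$k_f, kss, tolerance = 0.01)
})

test_that("unreachable targets raise a singularity error", {
  net <- ktn(data.frame(V = c(0, 0, 1), logProd = 27, pgOrder = 1),
             data.frame(V = 2, logProd = 26, pgOrder = 1,
                        min1 = 1, min2 = 2))
  expect_error(two_state_rates(net, 1, 3, 300), "unreachable|singular")
})

test_that("fastest path handles the trivial cases", {
  net <- generate_two_state(5, 4, 300)
  p0 <- fastest_path(net, 1, 1, 300)
  expect_equal(nrow(p0), 1L)
  expect_true(is.na(p0$ts[1]))
  p1 <- fastest_path(net, 1, 2, 300)
  expect_equal(p1$min, c(1L, 2L))
  expect_equal(p1$ts[2], 1L)
})

test_that("fastest path equals exhaustive enumeration over branching probabilities", {
  for (seed in c(5, 17, 29)) {
    net <- generate_random_ktn(6, seed = seed, extra_edge_frac = 1)
    got <- fastest_path(net, 1, 6, 310.15)
    best <- bf_fastest_path(net, 1, 6, 310.15)
    ## equal score; the minimum-id tie-break may pick an equally good path
    K <- build_rate_matrix(net, 310.15)
    esc <- -diag(K)
    score <- sum(vapply(seq_len(nrow(got) - 1L), function(i) {
      a <- got$min[i]; b <- got$min[i + 1L]
      -log(K[b, a] / esc[a])
    }, numeric(1)))
    expect_equal(score, best$score, tolerance = 1e-10)
  }
})

test_that("disconnected minima give a no-path error", {
  net <- ktn(data.frame(V = c(0, 0, 1), logProd = 27, pgOrder = 1),
             data.frame(V = 2, logProd = 26, pgOrder = 1,
                        min1 = 1, min2 = 2))
  expect_error(fastest_path(net, 1, 3, 300), "no path")
})
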