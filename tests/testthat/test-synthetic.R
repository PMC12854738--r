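test_that("generators are deterministic under a fixed seed", {
  a <- generate_funnel_ktn(seed = 2)
  b <- generate_funnel_ktn(seed = 2)
  expect_identical(a$ktn$minima, b$ktn$minima)
  expect_identical(a$ktn$ts, b$ktn$ts)
  expect_identical(a$merge_energy, b$merge_energy)
  c_ <- generate_funnel_ktn(seed = 3)
  expect_false(identical(a$ktn$minima$V, c_$ktn$minima$V))

  r1 <- generate_random_ktn(9, seed = 5)
  r2 <- generate_random_ktn(9, seed = 5)
  expect_identical(r1$minima, r2$minima)

  ## the generator does not disturb the caller's RNG stream
  set.seed(123); before <- stats::runif(1)
  set.seed(123); invisible(generate_random_ktn(5, seed = 9))
  expect_identical(stats::runif(1), before)
})

test_that("funnel generator obeys its declared construction", {
  gen <- generate_funnel_ktn(n_funnels = 2, minima_per_funnel = 5,
                             intra_barrier = 3, inter_barrier = 12,
                             energy_spread = 2, seed = 2)
  net <- gen$ktn
  expect_equal(n_minima(net), 10L)
  expect_equal(gen$membership, rep(1:2, each = 5))
  ## intra-funnel TS sit intra_barrier above the higher of each chain pair
  ets <- net$ts[1:8, ]
  expect_equal(ets$V, pmax(net$minima$V[ets$min1], net$minima$V[ets$min2]) + 3)
  ## single inter-funnel TS at inter_barrier above the global minimum
  inter <- net$ts[9, ]
  expect_equal(inter$V, min(net$minima$V) + 12)
  ## generated network passes validation untouched
  expect_equal(attr(validate_ktn(net, "error"), "report")$n_below, 0L)
  ## single-minimum degenerate spec
  tiny <- generate_funnel_ktn(n_funnels = 1, minima_per_funnel = 1, seed = 1)
  expect_equal(n_minima(tiny$ktn), 1L)
  expect_equal(n_ts(tiny$ktn), 0L)
  expect_error(generate_funnel_ktn(intra_barrier = 5, inter_barrier = 4),
               "inter_barrier")
})

test_that("funnel ground-truth merge energies equal the brute-force minimax", {
  gen <- generate_funnel_ktn(seed = 2)
  for (i in 1:9) for (j in (i + 1):10) {
    expect_equal(gen$merge_energy[i, j], bf_minimax(gen$ktn, i, j),
                 tolerance = 1e-12)
  }
})

test_that("two-state construction is the exact inverse of barrier extraction", {
  for (bars in list(c(17.8, 14.3), c(5, 5), c(10, 10 - kB * 310.15 * log(2)))) {
    net <- generate_two_state(bars[1], bars[2], 310.15)
    ts2 <- two_state_rates(net, 1, 2, 310.15)
    expect_equal(ts2$dG_f, bars[1], tolerance = 1e-6)
    expect_equal(ts2$dG_r, bars[2], tolerance = 1e-6)
  }
  ## equal barriers give a symmetric population
  sym <- generate_two_state(6, 6, 300)
  expect_equal(equilibrium_occupations(sym, 300)$p, c(0.5, 0.5))
  ## a barrier difference of kT ln 2 gives a 2:1 population ratio
  asym <- generate_two_state(10, 10 - kB * 310.15 * log(2), 310.15)
  p <- equilibrium_occupations(asym, 310.15)$p
  expect_equal(p[1] / p[2], 2, tolerance = 1e-10)
})

test_that("helix fixtures carry their constructed ground truth", {
  seqs <- c("G", "G", "C", "G", "G", "C", "G", "C", "U", "G", "C", "C")
  fx <- build_helix_fixture(seqs, cbind(1:6, 12:7))
  expect_equal(nrow(fx$pairs), 6L)
  bp <- annotate_base_pairs(bio3d::read.pdb(fx$file, verbose = FALSE))
  expect_setequal(paste(bp$i, bp$j), paste(fx$pairs$i, fx$pairs$j))
  expect_true(all(bp$category == "cWW"))
  ## wobble pairs are supported
  expect_equal(sum(seqs[bp$i] == "G" & seqs[bp$j] == "U" |
                     seqs[bp$i] == "U" & seqs[bp$j] == "G"), 1L)
  ## non-complementary pairings are rejected
  expect_error(build_helix_fixture(c("A", "G"), cbind(1, 2)),
               "no pairing recipe")
})

test_that("slippage shifts the pairing register as constructed", {
  ## hairpin-like strand: 5 + loop + 6, slippage moves partners by one
  seqs <- c("G", "G", "G", "G", "G", "A", "A", "C", "C", "C", "C", "C", "C")
  pairing <- cbind(1:5, 12:8)
  fx0 <- build_helix_fixture(seqs, pairing, slippage = 0)
  fx1 <- build_helix_fixture(seqs, pairing, slippage = 1)
  expect_equal(fx1$pairs$j, fx0$pairs$j + 1L)
  bp1 <- annotate_base_pairs(bio3d::read.pdb(fx1$file, verbose = FALSE))
  expect_setequal(paste(bp1$i, bp1$j), paste(fx1$pairs$i, fx1$pairs$j))
})

test_that("path annotation tracks pairing changes along a constructed path", {
  seqs <- c("G", "C", "A", "U", "G", "U", "A", "C", "A", "U", "G", "C")
  pairing <- cbind(1:6, 12:7)
  paired <- build_helix_fixture(seqs, pairing)
  unpaired <- build_helix_fixture(seqs, matrix(numeric(0), 0, 2))
  net <- ktn(data.frame(V = c(0, 2), logProd = 28, pgOrder = 1,
                        coordsRef = c(paired$file, unpaired$file)),
             data.frame(V = 5, logProd = 27, pgOrder = 1,
                        min1 = 1, min2 = 2),
             kappa = 3)
  path <- fastest_path(net, 1, 2, 310.15)
  ann <- path_annotation(net, path)
  expect_equal(sum(ann$step == 1), 6L)   # duplex fully paired
  expect_equal(sum(ann$step == 2), 0L)   # single strand has no pairs

  ## an unchanged structure gives identical pair sets at every step
  net2 <- ktn(data.frame(V = c(0, 1), logProd = 28, pgOrder = 1,
                         coordsRef = paired$file),
              data.frame(V = 4, logProd = 27, pgOrder = 1,
                         min1 = 1, min2 = 2), kappa = 3)
  ann2 <- path_annotation(net2, c(1, 2))
  expect_equal(ann2[ann2$step == 1, c("i", "j")],
               ann2[ann2$step == 2, c("i", "j")], ignore_attr = TRUE)

  ## registry-shift series: the slipped step shows the shifted partners
  hseq <- c("G", "G", "G", "G", "G", "A", "A", "C", "C", "C", "C", "C", "C")
  hpair <- cbind(1:5, 12:8)
  s0 <- build_helix_fixture(hseq, hpair, slippage = 0)
  s1 <- build_helix_fixture(hseq, hpair, slippage = 1)
  net3 <- ktn(data.frame(V = c(0, 1), logProd = 28, pgOrder = 1,
                         coordsRef = c(s0$file, s1$file)),
              data.frame(V = 4, logProd = 27, pgOrder = 1,
                         min1 = 1, min2 = 2), kappa = 3)
  ann3 <- path_annotation(net3, c(1, 2))
  j_by_step <- split(ann3$j[ann3$i == 1], ann3$step[ann3$i == 1])
  expect_equal(j_by_step[["2"]], j_by_step[["1"]] + 1L)

  bad <- ktn(data.frame(V = 0, logProd = 28, pgOrder = 1))
  expect_error(path_annotation(bad, 1), "minimum 1")
})
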