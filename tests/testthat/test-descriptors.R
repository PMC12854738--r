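## shared fixtures: a 6-bp duplex and a bent two-stem helix
duplex_seq <- c("G", "C", "A", "U", "G", "U", "A", "C", "A", "U", "G", "C")
duplex_pairing <- cbind(1:6, 12:7)
duplex <- build_helix_fixture(duplex_seq, duplex_pairing)
duplex_pdb <- bio3d::read.pdb(duplex$file, verbose = FALSE)

bent_seq <- rep(c("G", "C", "A", "U", "G", "C"), 4)
bent_pairing <- cbind(1:12, 24:13)
stem1 <- cbind(1:6, 24:19)
stem2 <- cbind(7:12, 18:13)

test_that("base frames are equivariant under rigid motions", {
  res <- ktnr:::.nt_residues(duplex_pdb)[[1]]
  fr <- base_frame(res$xyz)
  ## orthonormal right-handed axes; normal perpendicular to the ring plane
  expect_equal(crossprod(fr$axes), diag(3), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(det(fr$axes), 1, tolerance = 1e-10)
  ring <- res$xyz[intersect(c("N1", "C2", "N3", "C4", "C5", "C6"),
                            rownames(res$xyz)), ]
  spread <- sweep(ring, 2L, fr$origin)
  expect_lt(max(abs(spread %*% fr$axes[, 3])), 0.1)  # near-planar ring

  shifted <- res$xyz + matrix(c(5, -3, 11), nrow(res$xyz), 3, byrow = TRUE)
  fr2 <- base_frame(shifted)
  expect_equal(fr2$axes, fr$axes, tolerance = 1e-10)
  expect_equal(fr2$origin, fr$origin + c(5, -3, 11), tolerance = 1e-10)

  th <- 0.7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  rot <- res$xyz %*% t(R)
  rownames(rot) <- rownames(res$xyz)
  fr3 <- base_frame(rot)
  expect_equal(fr3$axes, R %*% fr$axes, tolerance = 1e-8)

  expect_error(base_frame(res$xyz[c("C1'", "N9"), ]), "ring atoms")
})

test_that("the duplex fixture annotates as exactly its constructed cWW pairs", {
  bp <- annotate_base_pairs(duplex_pdb)
  expect_equal(nrow(bp), 6L)
  expect_setequal(paste(bp$i, bp$j), paste(1:6, 12:7))
  expect_true(all(bp$category == "cWW"))
  expect_true(all(bp$orientation == "cis"))
})

test_that("single nucleotides and rigid motions behave as expected", {
  single <- build_helix_fixture("G", pairing = matrix(numeric(0), 0, 2))
  expect_equal(nrow(annotate_base_pairs(
    bio3d::read.pdb(single$file, verbose = FALSE))), 0L)

  ## global rotation + translation leaves the annotation unchanged
  at <- duplex_pdb$atom
  th <- 1.1
  R <- matrix(c(cos(th), 0, -sin(th), 0, 1, 0, sin(th), 0, cos(th)), 3, 3)
  xyz <- as.matrix(at[, c("x", "y", "z")]) %*% t(R)
  at2 <- at
  at2$x <- xyz[, 1] + 20; at2$y <- xyz[, 2] - 7; at2$z <- xyz[, 3] + 3
  bp2 <- annotate_base_pairs(at2)
  bp1 <- annotate_base_pairs(duplex_pdb)
  expect_equal(bp2[order(bp2$i), ], bp1[order(bp1$i), ],
               ignore_attr = TRUE)
})

test_that("sliding one base along the helix axis removes or declassifies its pair", {
  at <- duplex_pdb$atom
  sel <- at$resno == 12
  at$z[sel] <- at$z[sel] + 3      # shift along the helix (z) axis
  bp <- annotate_base_pairs(at)
  pair_1_12 <- bp[bp$i == 1 & bp$j == 12, ]
  expect_true(nrow(pair_1_12) == 0L || pair_1_12$category == "XXX")
  others <- bp[bp$i != 1 & bp$j != 12, ]
  expect_equal(nrow(others), 5L)
  expect_true(all(others$category == "cWW"))
})

test_that("WC-edge nitrogen distances report pairing proximity", {
  d <- wc_edge_distance(duplex_pdb, 1, 12)
  expect_lt(abs(d - 3), 0.3)    # paired G-C, around 3 Angstrom
  expect_equal(wc_edge_distance(duplex_pdb, 4, 4), 0)
  ## direct geometric check on a constructed two-atom case
  at <- data.frame(resno = c(1, 2), resid = c("A", "U"),
                   elety = c("N1", "N3"), elesy = "N",
                   x = c(0, 3), y = 0, z = 0)
  ## bases lacking ring atoms cannot be framed, but the distance only
  ## needs the WC nitrogens
  expect_equal(wc_edge_distance(at, 1, 2), 3)
  expect_error(wc_edge_distance(duplex_pdb, 1, 99), "99")
})

test_that("pucker phase matches an independent torsion-by-torsion oracle", {
  residues <- ktnr:::.nt_residues(duplex_pdb)
  for (r in residues[c(1, 5, 9)]) {
    got <- pucker_phase(r$xyz)
    expect_equal(got$P, oracle_pucker(r$xyz), tolerance = 1e-8)
    expect_gt(abs(got$amplitude), 5)
  }
  ## mirror image negates every torsion, mapping P to (P + 180) mod 360
  r <- residues[[2]]
  mirror <- r$xyz %*% diag(c(1, 1, -1))
  rownames(mirror) <- rownames(r$xyz)
  expect_equal(pucker_phase(mirror)$P,
               (pucker_phase(r$xyz)$P + 180) %% 360, tolerance = 1e-8)
  expect_equal(pucker_phase(mirror)$amplitude,
               pucker_phase(r$xyz)$amplitude, tolerance = 1e-8)
  ## a planar (convex) ring has every endocyclic torsion zero: degenerate
  ring <- c("C4'", "O4'", "C1'", "C2'", "C3'")
  th <- 2 * pi * (0:4) / 5
  flat <- cbind(1.2 * cos(th), 1.2 * sin(th), 0)
  rownames(flat) <- ring
  degen <- pucker_phase(flat)
  expect_true(is.na(degen$P))
  expect_equal(degen$amplitude, 0)
  expect_error(pucker_phase(r$xyz[setdiff(rownames(r$xyz), "O4'"), ]),
               "sugar")
})

test_that("inter-helical angles recover constructed bends", {
  coax <- build_helix_fixture(bent_seq, bent_pairing, bend_angle = 0)
  a0 <- interhelical_angles(bio3d::read.pdb(coax$file, verbose = FALSE),
                            stem1, stem2)
  expect_lt(a0["beta"], 1)

  for (bend in c(30, 90)) {
    fx <- build_helix_fixture(bent_seq, bent_pairing, bend_angle = bend,
                              bend_after = 6)
    ang <- interhelical_angles(bio3d::read.pdb(fx$file, verbose = FALSE),
                               stem1, stem2)
    expect_lt(abs(ang["beta"] - bend), 2)
  }
  expect_error(interhelical_angles(duplex_pdb, cbind(1:2, 12:11), stem2),
               "3 base pairs")
})

test_that("SASA reproduces analytic sphere areas and occlusion", {
  atom <- function(resno, elety, elesy, x, y = 0, z = 0)
    data.frame(resno = resno, resid = "G", elety = elety, elesy = elesy,
               x = x, y = y, z = z)
  one <- atom(1, "P", "P", 0)
  expect_equal(sasa(one), 4 * pi * (1.8 + 1.4)^2, tolerance = 0.01)

  far <- rbind(one, atom(2, "N1", "N", 100))
  expect_equal(sasa(far),
               4 * pi * ((1.8 + 1.4)^2 + (1.55 + 1.4)^2), tolerance = 0.01)

  ## an atom fully enclosed in a tight shell has zero accessible surface
  sphere_dirs <- function(n) {
    i <- seq_len(n) - 0.5
    z <- 1 - 2 * i / n
    phi <- pi * (sqrt(5) - 1) * i
    rho <- sqrt(1 - z^2)
    cbind(rho * cos(phi), rho * sin(phi), z)
  }
  shell <- sphere_dirs(60) * 2.2
  buried <- rbind(one,
                  data.frame(resno = 2, resid = "G", elety = "C1",
                             elesy = "C", x = shell[, 1], y = shell[, 2],
                             z = shell[, 3]))
  expect_equal(sasa(buried, resno = 1), 0)

  expect_error(sasa(atom(1, "XX", "XX", 0)), "radius")
})

test_that("descriptor matrices are complete for generated fixtures", {
  files <- c(duplex$file,
             build_helix_fixture(duplex_seq, duplex_pairing,
                                 slippage = 0)$file)
  X <- compute_descriptors(files,
                           pairs = cbind(c(1, 2), c(12, 11)),
                           pucker_res = 3:4,
                           stem1 = cbind(1:3, 12:10),
                           stem2 = cbind(4:6, 9:7),
                           sasa_res = 6)
  expect_equal(nrow(X), 2L)
  expect_false(anyNA(X))
  expect_named(X, c("d_1_12", "d_2_11", "pucker_3", "pucker_4",
                    "alpha", "beta", "gamma", "sasa_6"))
})

test_that("PCA standardises, orders components and projects consistently", {
  ## perfectly collinear 2D cloud
  x <- seq(-1, 1, length.out = 40)
  line <- cbind(a = x, b = 2 * x)
  m <- fit_pca(line)
  expect_equal(m$explained_var_ratio, c(1, 0), tolerance = 1e-12)

  set.seed(7)
  iso <- matrix(stats::rnorm(1e4 * 3), ncol = 3)
  colnames(iso) <- c("u", "v", "w")
  mi <- fit_pca(iso)
  ## isotropic cloud: all ratios near 1/3 within sampling error
  expect_lt(max(abs(mi$explained_var_ratio - 1 / 3)), 0.02)
  expect_equal(crossprod(mi$loadings), diag(3), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_true(all(diff(mi$explained_var_ratio) <= 1e-12))

  ## training rows project onto the fitted scores
  sc <- scale(iso, mi$means, mi$scales) %*% mi$loadings
  expect_equal(project_pca(mi, iso), sc, tolerance = 1e-12)

  ## per-feature affine rescaling is absorbed by the standardisation
  ## (anisotropic cloud so the components are non-degenerate)
  set.seed(8)
  u <- stats::rnorm(300)
  anis <- cbind(a = u + 0.1 * stats::rnorm(300),
                b = u + 0.4 * stats::rnorm(300),
                c = stats::rnorm(300))
  ma <- fit_pca(anis)
  rescaled <- sweep(sweep(anis, 2L, c(2, -0.5, 10), `*`), 2L,
                    c(1, 2, 3), `+`)
  colnames(rescaled) <- colnames(anis)
  mr <- fit_pca(rescaled)
  expect_equal(mr$explained_var_ratio, ma$explained_var_ratio,
               tolerance = 1e-10)
  expect_equal(abs(project_pca(mr, rescaled)), abs(project_pca(ma, anis)),
               tolerance = 1e-8, ignore_attr = TRUE)

  expect_error(fit_pca(iso[1, , drop = FALSE]), "2 rows")
  withvar0 <- cbind(iso, const = 1)
  expect_warning(m0 <- fit_pca(withvar0), "zero-variance")
  expect_equal(length(m0$explained_var_ratio), 3L)
})
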