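## Structure-level RNA descriptors: base-pair annotation, order parameters,
## sugar pucker, inter-helical angles, solvent-accessible surface area.
##
## Base-pair detection follows the r-vector idea: project the 6-ring centre
## of base j into the reference frame of base i and require BOTH mutual
## r-vectors to fall inside an ellipsoid (in-plane semi-axis `a_axis`,
## normal semi-axis `b_axis`). Interacting edges are assigned from the
## in-plane azimuth of the partner centre using per-base-type sectors, and
## cis/trans from the glycosidic torsion C1'(i)-N(i)-N(j)-C1'(j). Pairs that
## satisfy the distance criterion but resist edge/orientation assignment are
## reported as category "XXX".

.RNA_RESNAMES <- c(A = "A", RA = "A", ADE = "A", C = "C", RC = "C",
                   CYT = "C", G = "G", RG = "G", GUA = "G", U = "U",
                   RU = "U", URA = "U")
.RING6 <- c("N1", "C2", "N3", "C4", "C5", "C6")

## split a bio3d pdb (or an atom data.frame) into per-residue coordinate
## matrices with atom-name rownames; non-RNA residues are skipped with a
## warning
.nt_residues <- function(pdb) {
  at <- if (inherits(pdb, "pdb")) pdb$atom else as.data.frame(pdb)
  at$elety <- gsub("\\*", "'", at$elety)
  key <- paste(at$chain, at$resno, sep = "_")
  out <- list()
  skipped <- character(0)
  for (k in unique(key)) {
    rows <- at[key == k, , drop = FALSE]
    rn <- rows$resid[1]
    base <- .RNA_RESNAMES[trimws(rn)]
    if (is.na(base)) {
      skipped <- c(skipped, rn)
      next
    }
    xyz <- as.matrix(rows[, c("x", "y", "z")])
    rownames(xyz) <- rows$elety
    out[[length(out) + 1L]] <- list(resno = rows$resno[1], base = base,
                                    xyz = xyz)
  }
  if (length(skipped))
    warning("skipping non-RNA residue(s): ",
            paste(unique(skipped), collapse = ", "))
  out[order(vapply(out, `[[`, numeric(1), "resno"))]
}

.res_by_no <- function(residues, resno) {
  hit <- which(vapply(residues, `[[`, numeric(1), "resno") == resno)
  if (!length(hit)) stop("no RNA residue with number ", resno)
  residues[[hit[1]]]
}

#' Reference frame of a nucleobase
#'
#' Origin at the centroid of the six-membered ring; z along the ring normal
#' (Newell construction over the ordered ring atoms N1, C2, N3, C4, C5, C6,
#' so the sign is deterministic for a fixed atom order); x in-plane towards
#' the Watson-Crick edge nitrogen (N1 for purines, N3 for pyrimidines);
#' y completes a right-handed frame.
#'
#' @param xyz Numeric matrix of residue coordinates with atom-name rownames
#'   (at least C2, C4 and C6 must be present).
#' @param base Base type, one of "A", "C", "G", "U" (used only to name the
#'   residue in error messages; purine/pyrimidine is read off the atoms).
#' @return List with `origin` (length-3) and `axes` (3x3 matrix whose
#'   columns are x, y, z).
#' @export
base_frame <- function(xyz, base = "?") {
  have <- intersect(.RING6, rownames(xyz))
  if (!all(c("C2", "C4", "C6") %in% have))
    stop("missing base ring atoms for residue ", base,
         " (need at least C2, C4, C6)")
  ring <- xyz[have, , drop = FALSE]
  o <- colMeans(ring)
  ## Newell normal over the ordered ring polygon
  z <- c(0, 0, 0)
  ord <- ring[order(match(rownames(ring), .RING6)), , drop = FALSE]
  nr <- nrow(ord)
  for (i in seq_len(nr)) {
    u <- ord[i, ] - o
    v <- ord[if (i == nr) 1L else i + 1L, ] - o
    z <- z + c(u[2] * v[3] - u[3] * v[2],
               u[3] * v[1] - u[1] * v[3],
               u[1] * v[2] - u[2] * v[1])
  }
  z <- z / sqrt(sum(z^2))
  wc_atom <- if ("N9" %in% rownames(xyz)) "N1" else "N3"
  if (!wc_atom %in% rownames(xyz))
    stop("missing Watson-Crick edge atom ", wc_atom, " for residue ", base)
  x <- xyz[wc_atom, ] - o
  x <- x - sum(x * z) * z
  x <- x / sqrt(sum(x^2))
  y <- c(z[2] * x[3] - z[3] * x[2],
         z[3] * x[1] - z[1] * x[3],
         z[1] * x[2] - z[2] * x[1])
  list(origin = o, axes = cbind(x = x, y = y, z = z))
}

## dihedral angle (degrees, (-180, 180]) over four points
.dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cross <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                            u[3] * v[1] - u[1] * v[3],
                            u[1] * v[2] - u[2] * v[1])
  n1 <- cross(b1, b2); n2 <- cross(b2, b3)
  m1 <- cross(n1, b2 / sqrt(sum(b2^2)))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

## per-base-type azimuth sectors for edge assignment (degrees);
## calibrated on the ideal nucleotide templates: purine Hoogsteen atoms
## (N7, C8) sit at negative azimuth in the frame above, pyrimidine C-H
## edge atoms (C5, C6) at positive azimuth
.edge_from_azimuth <- function(theta, purine) {
  if (abs(theta) <= 60) return("WC")
  if (purine) {
    if (theta < -60) "Hoogsteen" else "Sugar"
  } else {
    if (theta > 60) "Hoogsteen" else "Sugar"
  }
}

#' Annotate base pairs in an RNA structure
#'
#' @param pdb A `bio3d` pdb object (or atom data.frame) of an RNA chain.
#' @param a_axis,b_axis Ellipsoid semi-axes of the mutual r-vector pairing
#'   criterion, in Angstrom: in-plane (`a_axis`, default 6.5) and normal
#'   (`b_axis`, default 2.0). The in-plane default accommodates the 5.5-5.9 A
#'   ring-centre separations of canonical Watson-Crick geometry; the normal
#'   default rejects helically stacked neighbours (rise ~2.8 A).
#' @return data.frame with columns `i`, `j` (residue numbers, `i < j`),
#'   `edge_i`, `edge_j` (WC / Hoogsteen / Sugar), `orientation`
#'   (cis / trans) and `category` (e.g. "cWW", or "XXX" when the geometric
#'   criterion is met but edge/orientation assignment failed).
#' @export
annotate_base_pairs <- function(pdb, a_axis = 6.5, b_axis = 2.0) {
  residues <- .nt_residues(pdb)
  n <- length(residues)
  empty <- data.frame(i = integer(0), j = integer(0),
                      edge_i = character(0), edge_j = character(0),
                      orientation = character(0), category = character(0))
  if (n < 2L) return(empty)
  frames <- lapply(residues, function(r)
    base_frame(r$xyz, paste0(r$base, r$resno)))
  rows <- list()
  for (ii in seq_len(n - 1L)) {
    for (jj in (ii + 1L):n) {
      fi <- frames[[ii]]; fj <- frames[[jj]]
      rij <- drop(crossprod(fi$axes, fj$origin - fi$origin))
      rji <- drop(crossprod(fj$axes, fi$origin - fj$origin))
      inside <- function(r) (r[1] / a_axis)^2 + (r[2] / a_axis)^2 +
        (r[3] / b_axis)^2 <= 1
      if (!(inside(rij) && inside(rji))) next
      ri <- residues[[ii]]; rj <- residues[[jj]]
      th_i <- atan2(rij[2], rij[1]) * 180 / pi
      th_j <- atan2(rji[2], rji[1]) * 180 / pi
      edge_i <- .edge_from_azimuth(th_i, "N9" %in% rownames(ri$xyz))
      edge_j <- .edge_from_azimuth(th_j, "N9" %in% rownames(rj$xyz))
      ## orientation from the glycosidic torsion
      gly <- function(r) {
        natom <- if ("N9" %in% rownames(r$xyz)) "N9" else "N1"
        if (!all(c("C1'", natom) %in% rownames(r$xyz))) return(NULL)
        list(c1 = r$xyz["C1'", ], nn = r$xyz[natom, ])
      }
      gi <- gly(ri); gj <- gly(rj)
      if (is.null(gi) || is.null(gj)) {
        orientation <- NA_character_
        category <- "XXX"
      } else {
        tau <- .dihedral(gi$c1, gi$nn, gj$nn, gj$c1)
        orientation <- if (abs(tau) <= 90) "cis" else "trans"
        category <- paste0(substr(orientation, 1, 1),
                           substr(edge_i, 1, 1), substr(edge_j, 1, 1))
      }
      rows[[length(rows) + 1L]] <-
        data.frame(i = ri$resno, j = rj$resno, edge_i = edge_i,
                   edge_j = edge_j, orientation = orientation,
                   category = category)
    }
  }
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

#' Watson-Crick edge nitrogen distance
#'
#' Distance between the WC-edge nitrogen atoms of two residues (N1 for A and
#' G, N3 for C and U); around 3 A indicates base pairing. The order
#' parameter used for colouring disconnectivity graphs.
#'
#' @param pdb A `bio3d` pdb object or atom data.frame.
#' @param i,j Residue numbers.
#' @return Distance in Angstrom.
#' @export
wc_edge_distance <- function(pdb, i, j) {
  residues <- .nt_residues(pdb)
  get_n <- function(resno) {
    r <- .res_by_no(residues, resno)
    atom <- if (r$base %in% c("A", "G")) "N1" else "N3"
    if (!atom %in% rownames(r$xyz))
      stop("missing atom ", atom, " in residue ", resno)
    r$xyz[atom, ]
  }
  sqrt(sum((get_n(i) - get_n(j))^2))
}

#' Sugar pucker pseudorotation phase
#'
#' Altona-Sundaralingam phase from the five endocyclic torsions nu0..nu4:
#' `tan P = ((nu4 + nu1) - (nu3 + nu0)) / (2 nu2 (sin 36 + sin 72))`,
#' quadrant-corrected by the sign of nu2 and reported in degrees [0, 360).
#' C3'-endo sugars fall near P = 18, C2'-endo near P = 162.
#'
#' @param pdb A `bio3d` pdb object, atom data.frame, or a residue
#'   coordinate matrix with atom-name rownames.
#' @param resno Residue number (ignored when `pdb` is a coordinate matrix).
#' @return Named list: `P` (degrees; `NA` for a planar ring), `amplitude`
#'   (degrees).
#' @export
pucker_phase <- function(pdb, resno = NULL) {
  xyz <- if (is.matrix(pdb)) pdb
         else .res_by_no(.nt_residues(pdb), resno)$xyz
  ring <- c("C4'", "O4'", "C1'", "C2'", "C3'")
  if (!all(ring %in% rownames(xyz)))
    stop("missing sugar ring atoms: ",
         paste(setdiff(ring, rownames(xyz)), collapse = ", "))
  at <- function(a) xyz[a, ]
  ## nu_j is the torsion about the bond following ring position j
  nu <- c(.dihedral(at("C4'"), at("O4'"), at("C1'"), at("C2'")),
          .dihedral(at("O4'"), at("C1'"), at("C2'"), at("C3'")),
          .dihedral(at("C1'"), at("C2'"), at("C3'"), at("C4'")),
          .dihedral(at("C2'"), at("C3'"), at("C4'"), at("O4'")),
          .dihedral(at("C3'"), at("C4'"), at("O4'"), at("C1'")))
  ## tan P = num / (2 nu2 (sin36 + sin72)); evaluated as atan2 so the
  ## quadrant correction by the sign of nu2 is automatic
  s2 <- 2 * (sin(36 * pi / 180) + sin(72 * pi / 180))
  sin_term <- (nu[5] + nu[2] - nu[4] - nu[1]) / s2   # tau_m sin P
  amplitude <- sqrt(nu[3]^2 + sin_term^2)
  if (amplitude < 1e-6)
    return(list(P = NA_real_, amplitude = 0))
  P <- (atan2(sin_term, nu[3]) * 180 / pi) %% 360
  list(P = P, amplitude = amplitude)
}

#' Inter-helical Euler angles between two stems
#'
#' Fits a helical axis per stem from the C1' atoms of its base pairs (first
#' principal direction of the pair-midpoint cloud, oriented along the pair
#' order), builds a reference frame with the x-axis from the first pair's
#' C1'-C1' vector, and reports the z-y-z Euler decomposition of the
#' rotation carrying the first stem frame onto the second. `beta` is the
#' inter-helical bend angle.
#'
#' @param pdb A `bio3d` pdb object or atom data.frame.
#' @param stem1,stem2 data.frames (or 2-column matrices) of paired residue
#'   numbers `(i, j)`, at least 3 pairs each.
#' @return Named numeric vector `c(alpha, beta, gamma)` in degrees.
#' @export
interhelical_angles <- function(pdb, stem1, stem2) {
  residues <- .nt_residues(pdb)
  stem_frame <- function(stem) {
    stem <- as.matrix(stem)
    if (nrow(stem) < 3L) stop("need at least 3 base pairs per stem")
    c1 <- function(resno) {
      r <- .res_by_no(residues, resno)
      if (!"C1'" %in% rownames(r$xyz))
        stop("missing C1' in residue ", resno)
      r$xyz["C1'", ]
    }
    mids <- t(apply(stem, 1L, function(p) (c1(p[1]) + c1(p[2])) / 2))
    ctr <- colMeans(mids)
    sv <- svd(sweep(mids, 2L, ctr))
    axis <- sv$v[, 1]
    if (sv$d[1] < 1e-8) stop("degenerate axis fit for stem")
    ## orient along pair order
    if (sum((mids[nrow(mids), ] - mids[1, ]) * axis) < 0) axis <- -axis
    x <- c1(stem[1, 2]) - c1(stem[1, 1])
    x <- x - sum(x * axis) * axis
    x <- x / sqrt(sum(x^2))
    y <- c(axis[2] * x[3] - axis[3] * x[2],
           axis[3] * x[1] - axis[1] * x[3],
           axis[1] * x[2] - axis[2] * x[1])
    cbind(x = x, y = y, z = axis)
  }
  R1 <- stem_frame(stem1)
  R2 <- stem_frame(stem2)
  M <- R2 %*% t(R1)
  beta <- acos(max(-1, min(1, M[3, 3]))) * 180 / pi
  if (abs(M[3, 3]) > 1 - 1e-12) {
    ## gimbal-degenerate: fold the full rotation into alpha
    alpha <- atan2(M[2, 1], M[1, 1]) * 180 / pi
    gamma <- 0
  } else {
    alpha <- atan2(M[2, 3], M[1, 3]) * 180 / pi
    gamma <- atan2(M[3, 2], -M[3, 1]) * 180 / pi
  }
  c(alpha = alpha, beta = beta, gamma = gamma)
}

.DEFAULT_RADII <- c(C = 1.70, N = 1.55, O = 1.52, P = 1.80, S = 1.80,
                    H = 1.20)

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Deterministic Fibonacci-lattice sphere sampling with `n_points` test
#' points per atom and a 1.4 A water probe by default.
#'
#' @param pdb A `bio3d` pdb object or atom data.frame.
#' @param resno Optional residue number; when given, only that residue's
#'   atoms are summed (occlusion still counts all atoms).
#' @param probe Probe radius in Angstrom.
#' @param n_points Sphere test points per atom.
#' @param radii Named vector of van der Waals radii per element.
#' @return SASA in Angstrom^2.
#' @export
sasa <- function(pdb, resno = NULL, probe = 1.4, n_points = 960,
                 radii = .DEFAULT_RADII) {
  at <- if (inherits(pdb, "pdb")) pdb$atom else as.data.frame(pdb)
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == "")) {
    elem <- substr(gsub("[^A-Za-z].*$", "", gsub("'", "", at$elety)), 1, 1)
  }
  elem <- toupper(trimws(elem))
  unknown <- setdiff(unique(elem), names(radii))
  if (length(unknown))
    stop("no radius for element(s): ", paste(unknown, collapse = ", "),
         " (extend `radii`)")
  xyz <- as.matrix(at[, c("x", "y", "z")])
  r_ext <- unname(radii[elem]) + probe
  ## Fibonacci sphere directions
  i <- seq_len(n_points) - 0.5
  zs <- 1 - 2 * i / n_points
  phi <- pi * (sqrt(5) - 1) * i
  rho <- sqrt(pmax(0, 1 - zs^2))
  dirs <- cbind(rho * cos(phi), rho * sin(phi), zs)
  sel <- if (is.null(resno)) seq_len(nrow(at)) else which(at$resno == resno)
  if (!length(sel)) stop("no atoms for residue ", resno)
  total <- 0
  for (k in sel) {
    pts <- sweep(dirs * r_ext[k], 2L, xyz[k, ], `+`)
    ## neighbours that can possibly occlude
    d2 <- rowSums(sweep(xyz, 2L, xyz[k, ])^2)
    nb <- which(d2 < (r_ext + r_ext[k])^2 & seq_len(nrow(at)) != k)
    acc <- rep(TRUE, n_points)
    for (m in nb) {
      dd <- rowSums(sweep(pts, 2L, xyz[m, ])^2)
      acc <- acc & dd > r_ext[m]^2
      if (!any(acc)) break
    }
    total <- total + 4 * pi * r_ext[k]^2 * sum(acc) / n_points
  }
  total
}

#' Geometric descriptor matrix for an ensemble of structures
#'
#' Computes, per structure: WC-edge nitrogen distances for a set of residue
#' pairs, sugar pucker phases for a set of residues, the three inter-helical
#' Euler angles between two stems, and the SASA of one nucleotide. The
#' defaults correspond to the TAR stemloop analysis (1-based numbering with
#' position 1 = G17 of the full RNA): pairs 8-23, 9-23, 10-21, 10-22,
#' 10-23, 11-22, 12-21; puckers A6-U9; SASA of nucleotide 23.
#'
#' @param files Character vector of PDB paths (one structure each).
#' @param pairs 2-column matrix/data.frame of residue pairs for distances.
#' @param pucker_res Residue numbers for pucker phases.
#' @param stem1,stem2 Pair tables for [interhelical_angles()], or `NULL` to
#'   skip the angle block.
#' @param sasa_res Residue number for the SASA column, or `NULL` to skip.
#' @return data.frame, rows = structures, named descriptor columns.
#' @export
compute_descriptors <- function(files,
                                pairs = cbind(c(8, 9, 10, 10, 10, 11, 12),
                                              c(23, 23, 21, 22, 23, 22, 21)),
                                pucker_res = 6:9,
                                stem1 = NULL, stem2 = NULL,
                                sasa_res = 23) {
  pairs <- as.matrix(pairs)
  rows <- lapply(files, function(f) {
    pdb <- bio3d::read.pdb(f, verbose = FALSE)
    v <- c()
    for (r in seq_len(nrow(pairs)))
      v[sprintf("d_%d_%d", pairs[r, 1], pairs[r, 2])] <-
        wc_edge_distance(pdb, pairs[r, 1], pairs[r, 2])
    for (p in pucker_res)
      v[sprintf("pucker_%d", p)] <- pucker_phase(pdb, p)$P
    if (!is.null(stem1) && !is.null(stem2)) {
      ang <- interhelical_angles(pdb, stem1, stem2)
      v["alpha"] <- ang["alpha"]; v["beta"] <- ang["beta"]
      v["gamma"] <- ang["gamma"]
    }
    if (!is.null(sasa_res))
      v[sprintf("sasa_%d", sasa_res)] <- sasa(pdb, sasa_res)
    v
  })
  out <- as.data.frame(do.call(rbind, rows))
  if (anyNA(out))
    stop("descriptor matrix contains missing values (columns: ",
         paste(names(out)[colSums(is.na(out)) > 0], collapse = ", "), ")")
  out
}

#' Principal component analysis of a descriptor matrix
#'
#' Features are z-score standardised before the covariance
#' eigendecomposition; zero-variance columns are dropped with a warning.
#'
#' @param X Numeric matrix or data.frame, rows = structures.
#' @return A `pca_model`: list with `means`, `scales`, `loadings`
#'   (orthonormal columns), `explained_var_ratio` and `columns`.
#' @export
fit_pca <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("PCA needs at least 2 rows")
  vr <- apply(X, 2L, stats::var)
  if (any(vr == 0)) {
    warning("dropping zero-variance column(s): ",
            paste(colnames(X)[vr == 0], collapse = ", "))
    X <- X[, vr > 0, drop = FALSE]
  }
  fit <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  structure(list(means = fit$center, scales = fit$scale,
                 loadings = fit$rotation,
                 explained_var_ratio = fit$sdev^2 / sum(fit$sdev^2),
                 columns = colnames(X)),
            class = "pca_model")
}

#' Project rows onto a fitted PCA model
#'
#' Applies the stored standardisation and loadings; used to place external
#' ensembles on the landscape's principal components.
#'
#' @param model A `pca_model` from [fit_pca()].
#' @param X New rows with the model's columns.
#' @return Score matrix (rows x components).
#' @export
project_pca <- function(model, X) {
  X <- as.matrix(as.data.frame(X)[, model$columns, drop = FALSE])
  scale(X, center = model$means, scale = model$scales) %*% model$loadings
}
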