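## Seeded generators for every input the pipeline consumes: funnelled toy
## KTNs with known topography, two-state networks with prescribed Eyring
## barriers, random KTNs for property tests, and idealised RNA helix
## fixtures whose base pairing is known by construction.

## run code under a fixed seed without disturbing the caller's RNG state
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a funnelled toy KTN with known ground truth
#'
#' Emulates a multi-funnel landscape: each funnel is a chain of minima with
#' intra-funnel transition states `intra_barrier` above the higher of the
#' pair, and consecutive funnels are joined by a single transition state
#' `inter_barrier` above the global minimum. Minimum energies are the
#' funnel base plus Uniform(0, `energy_spread`); vibrational log-products
#' are Uniform(ln 1e12, ln 1e13), point-group orders 1.
#'
#' @param n_funnels,minima_per_funnel Funnel layout.
#' @param intra_barrier,inter_barrier Barrier heights in kcal/mol
#'   (`inter_barrier > intra_barrier > 0`; for clean funnel ground truth,
#'   `inter_barrier` should also exceed `energy_spread + intra_barrier`).
#' @param energy_spread Within-funnel energy spread (kcal/mol).
#' @param seed RNG seed.
#' @param kappa Vibrational degrees of freedom attached to the network.
#' @return List with `ktn`, `membership` (funnel index per minimum) and
#'   `merge_energy` (matrix of exact minimax merge energies for every
#'   minimum pair, from the construction).
#' @export
generate_funnel_ktn <- function(n_funnels = 2, minima_per_funnel = 5,
                                intra_barrier = 3, inter_barrier = 12,
                                energy_spread = 2, seed = 1, kappa = 3) {
  if (!(inter_barrier > intra_barrier && intra_barrier > 0))
    stop("need inter_barrier > intra_barrier > 0")
  if (inter_barrier <= energy_spread + intra_barrier)
    warning("inter_barrier <= energy_spread + intra_barrier: ",
            "funnel merge energies may interleave")
  .with_seed(seed, {
    n <- n_funnels * minima_per_funnel
    membership <- rep(seq_len(n_funnels), each = minima_per_funnel)
    V <- runif(n, 0, energy_spread)
    logProd <- runif(n, log(1e12), log(1e13))
    mins <- data.frame(V = V, logProd = logProd, pgOrder = 1)
    ts <- NULL
    for (f in seq_len(n_funnels)) {
      ids <- which(membership == f)
      if (length(ids) > 1L) {
        for (k in seq_len(length(ids) - 1L)) {
          a <- ids[k]; b <- ids[k + 1L]
          ts <- rbind(ts, data.frame(
            V = max(V[a], V[b]) + intra_barrier,
            logProd = runif(1, log(1e12), log(1e13)), pgOrder = 1,
            min1 = a, min2 = b))
        }
      }
    }
    gmin <- min(V)
    inter_V <- gmin + inter_barrier
    if (n_funnels > 1L) {
      for (f in seq_len(n_funnels - 1L)) {
        a <- which(membership == f)[1]
        b <- which(membership == f + 1L)[1]
        ts <- rbind(ts, data.frame(
          V = inter_V, logProd = runif(1, log(1e12), log(1e13)),
          pgOrder = 1, min1 = a, min2 = b))
      }
    }
    net <- ktn(mins, ts, kappa = kappa)
    ## exact minimax merge energies by construction
    merge_energy <- matrix(NA_real_, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) { merge_energy[i, j] <- V[i]; next }
      if (membership[i] != membership[j]) {
        merge_energy[i, j] <- inter_V
      } else {
        ids <- which(membership == membership[i])
        ki <- match(i, ids); kj <- match(j, ids)
        seg <- ids[seq(min(ki, kj), max(kj, ki) - 1L)]
        merge_energy[i, j] <- max(vapply(seq_along(seg), function(s) {
          a <- seg[s]; b <- ids[match(a, ids) + 1L]
          max(V[a], V[b]) + intra_barrier
        }, numeric(1)))
      }
    }
    list(ktn = net, membership = membership, merge_energy = merge_energy)
  })
}

#' Generate a random connected KTN
#'
#' A random spanning tree plus extra edges; transition-state energies lie a
#' random barrier above the higher of the connected pair, so the network is
#' always valid.
#'
#' @param n_min Number of minima.
#' @param seed RNG seed.
#' @param extra_edge_frac Extra transition states as a fraction of `n_min`.
#' @param v_range Range of minimum energies (kcal/mol).
#' @param barrier_range Range of barrier heights above the higher minimum.
#' @param deep Optional minimum ids placed well below the rest (near
#'   `deep_v`), producing a network dominated by two (or more) deep states
#'   with sparsely populated intermediates.
#' @param deep_v Energy level for the `deep` minima (kcal/mol).
#' @param kappa Vibrational degrees of freedom.
#' @return A `ktn`.
#' @export
generate_random_ktn <- function(n_min, seed = 1, extra_edge_frac = 0.5,
                                v_range = c(0, 5),
                                barrier_range = c(0.5, 4),
                                deep = NULL, deep_v = NULL, kappa = 3) {
  .with_seed(seed, {
    V <- runif(n_min, v_range[1], v_range[2])
    if (!is.null(deep)) {
      if (is.null(deep_v)) deep_v <- v_range[1] - 5
      V[deep] <- deep_v + runif(length(deep), 0, 0.5)
    }
    mins <- data.frame(V = V,
                       logProd = runif(n_min, log(1e12), log(1e13)),
                       pgOrder = sample(c(1, 1, 1, 2), n_min, replace = TRUE))
    edges <- NULL
    if (n_min > 1L) {
      perm <- sample(n_min)
      for (k in 2:n_min)      # random spanning tree
        edges <- rbind(edges, c(perm[k], perm[sample(k - 1L, 1)]))
      n_extra <- round(extra_edge_frac * n_min)
      for (e in seq_len(n_extra)) {
        ab <- sample(n_min, 2)
        edges <- rbind(edges, ab)
      }
    }
    ts <- if (!is.null(edges)) data.frame(
      V = pmax(V[edges[, 1]], V[edges[, 2]]) +
        runif(nrow(edges), barrier_range[1], barrier_range[2]),
      logProd = runif(nrow(edges), log(1e12), log(1e13)),
      pgOrder = 1, min1 = edges[, 1], min2 = edges[, 2]) else NULL
    ktn(mins, ts, kappa = kappa)
  })
}

#' Construct a two-state KTN with prescribed Eyring barriers
#'
#' Builds two minima and one transition state whose harmonic TST rates equal
#' `barrier_to_rate(dG_f)` and `barrier_to_rate(dG_r)` at `temperature`
#' exactly: the forward barrier fixes the transition-state energy, the
#' barrier difference fixes the energy offset of the second minimum, and the
#' vibrational log-products supply the Eyring prefactor.
#'
#' @param dG_f,dG_r Forward and reverse barriers in kcal/mol (> 0).
#' @param temperature Temperature in K.
#' @param kappa Vibrational degrees of freedom.
#' @return A `ktn` with 2 minima and 1 transition state.
#' @export
generate_two_state <- function(dG_f, dG_r, temperature = 310.15,
                               kappa = 3) {
  if (dG_f <= 0 || dG_r <= 0) stop("barriers must be positive")
  lp <- log(kT_over_h(temperature))
  mins <- data.frame(V = c(0, dG_f - dG_r), logProd = c(lp, lp),
                     pgOrder = 1)
  ts <- data.frame(V = dG_f, logProd = 0, pgOrder = 1, min1 = 1, min2 = 2)
  ktn(mins, ts, kappa = kappa)
}

## ---- RNA helix fixtures ---------------------------------------------------

.HBOND_TABLE <- list(
  GC = list(bonds = list(c("N1", "N3", 2.92), c("O6", "N4", 2.91)),
            check = c("N2", "O2")),
  AU = list(bonds = list(c("N1", "N3", 2.82), c("N6", "O4", 2.95)),
            check = NULL),
  GU = list(bonds = list(c("O6", "N3", 2.83), c("N1", "O2", 2.79)),
            check = NULL))

.nt_template <- function(base) {
  path <- system.file("extdata", "nt_templates",
                      paste0(base, ".tsv"), package = "ktnr")
  if (path == "") stop("missing nucleotide template for ", base)
  tab <- utils::read.delim(path)
  xyz <- as.matrix(tab[, c("x", "y", "z")])
  rownames(xyz) <- tab$atom
  attr(xyz, "element") <- tab$element
  xyz
}

## residue coordinates re-expressed in the base's own frame
.canonical_template <- function(base) {
  xyz <- .nt_template(base)
  fr <- base_frame(xyz, base)
  out <- sweep(xyz, 2L, fr$origin) %*% fr$axes
  attr(out, "element") <- attr(xyz, "element")
  out
}

## place `base2` opposite a canonical-frame `base1` (identity frame):
## coplanar, exact 2-point alignment of the hydrogen-bond atoms onto
## targets projected along +x from base1's edge atoms
.place_partner <- function(xyz1, base1, base2) {
  key <- paste0(base1, base2)
  rkey <- paste0(base2, base1)
  ## exact 2-point in-plane alignment of the partner's H-bond atoms onto
  ## targets projected +x from the reference base's edge atoms
  pair_in_ref_frame <- function(ref, par, rec) {
    targets <- lapply(rec$bonds, function(b)
      ref[b[1], c(1, 2)] + c(as.numeric(b[3]), 0))
    pts <- lapply(rec$bonds, function(b) par[b[2], c(1, 2)])
    u <- pts[[2]] - pts[[1]]; v <- targets[[2]] - targets[[1]]
    ang <- atan2(v[2], v[1]) - atan2(u[2], u[1])
    Rot <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
    tr <- (targets[[1]] + targets[[2]]) / 2 -
      drop(Rot %*% ((pts[[1]] + pts[[2]]) / 2))
    placed <- cbind(t(Rot %*% t(par[, c(1, 2)])) +
                      matrix(tr, nrow(par), 2, byrow = TRUE), par[, 3])
    rownames(placed) <- rownames(par)
    attr(placed, "element") <- attr(par, "element")
    placed
  }
  if (!is.null(.HBOND_TABLE[[key]])) {
    par <- .canonical_template(base2)
    return(pair_in_ref_frame(xyz1, par, .HBOND_TABLE[[key]]))
  }
  if (is.null(.HBOND_TABLE[[rkey]]))
    stop("no pairing recipe for ", base1, "-", base2,
         " (canonical pairs and the GU wobble are supported)")
  ## recipe is keyed on base2: build the pair in base2's canonical frame,
  ## then re-express everything in base1's frame (a rigid change of frame,
  ## under which base1 becomes its canonical template again)
  ref2 <- .canonical_template(base2)
  placed1 <- pair_in_ref_frame(ref2, .canonical_template(base1),
                               .HBOND_TABLE[[rkey]])
  fr <- base_frame(placed1, base1)
  out <- sweep(ref2, 2L, fr$origin) %*% fr$axes
  rownames(out) <- rownames(ref2)
  attr(out, "element") <- attr(ref2, "element")
  out
}

## 3D rotations
.Rz <- function(th) matrix(c(cos(th), sin(th), 0,
                             -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
.Rx <- function(th) matrix(c(1, 0, 0, 0, cos(th), sin(th),
                             0, -sin(th), cos(th)), 3, 3)

#' Build an idealised RNA helix fixture with known base pairing
#'
#' Residues are placed on an ideal helical lattice (rise 2.81 A, twist
#' 32.7 deg) from ideal nucleotide templates; each prescribed pair is
#' constructed with canonical hydrogen-bond geometry, so the returned
#' ground-truth pairing is exact by construction. A bend can be applied
#' between two stems (pairs after `bend_after`) and a registry shift
#' (`slippage`) moves every partner index before construction. Unpaired
#' residues are placed flipped out of the helix so that every residue's
#' sugar and base are present in the output.
#'
#' @param sequence Character vector of bases (`"A"`, `"C"`, `"G"`, `"U"`)
#'   or a single string; residue numbers are 1-based positions.
#' @param pairing 2-column matrix/data.frame of (i, j) pairs, `i < j`.
#' @param bend_angle Bend between stems in degrees.
#' @param bend_after Pair index after which the bend is applied (defaults
#'   to the middle pair when `bend_angle != 0`).
#' @param slippage Integer registry shift applied to all partner indices
#'   `j`; shifted pairs falling outside the sequence are dropped.
#' @param rise,twist Helical parameters (Angstrom, degrees).
#' @param file Optional output PDB path; when `NULL` a temporary file is
#'   written.
#' @return List with `file` (PDB path), `pairs` (ground-truth data.frame
#'   `i`, `j`, `category`), and `atoms` (the atom table written).
#' @export
build_helix_fixture <- function(sequence, pairing, bend_angle = 0,
                                bend_after = NULL, slippage = 0,
                                rise = 2.81, twist = 32.7, file = NULL) {
  if (length(sequence) == 1L && nchar(sequence[1]) > 1L)
    sequence <- strsplit(sequence, "")[[1]]
  sequence <- toupper(sequence)
  if (!all(sequence %in% c("A", "C", "G", "U")))
    stop("sequence must consist of A, C, G, U")
  n <- length(sequence)
  pairing <- as.matrix(pairing)
  if (slippage != 0) {
    pairing[, 2] <- pairing[, 2] + slippage
    pairing <- pairing[pairing[, 2] >= 1 & pairing[, 2] <= n &
                         pairing[, 1] < pairing[, 2], , drop = FALSE]
  }
  if (nrow(pairing) && any(pairing[, 1] >= pairing[, 2]))
    stop("pairing must satisfy i < j")
  if (anyDuplicated(c(pairing)))
    stop("a residue appears in more than one pair")
  np <- nrow(pairing)
  if (bend_angle != 0 && is.null(bend_after)) bend_after <- ceiling(np / 2)
  if (is.null(bend_after)) bend_after <- np + 1L

  ## step index per pair (stack order), then per unpaired residue
  step_of <- rep(NA_real_, n)
  if (np) {
    ord <- order(pairing[, 1])
    pairing <- pairing[ord, , drop = FALSE]
    for (k in seq_len(np)) step_of[pairing[k, ]] <- k - 1
  }
  unpaired <- which(is.na(step_of))
  for (r in unpaired) {
    lower <- step_of[seq_len(r - 1L)]
    upper <- if (r < n) step_of[(r + 1L):n] else NA
    lo <- if (any(!is.na(lower))) max(lower, na.rm = TRUE) else NA
    hi <- if (any(!is.na(upper))) min(upper, na.rm = TRUE) else NA
    step_of[r] <- if (!is.na(lo) && !is.na(hi)) (lo + hi) / 2
                  else if (!is.na(lo)) lo + 1 else if (!is.na(hi)) hi - 1
                  else (r - 1)
  }
  ## unpaired residues sharing an interpolated step are staggered so that
  ## no two residues coincide
  if (length(unpaired) > 1L) {
    for (s in unique(step_of[unpaired])) {
      grp <- unpaired[step_of[unpaired] == s]
      if (length(grp) > 1L)
        step_of[grp] <- step_of[grp] + 0.8 * (seq_along(grp) - 1L)
    }
  }

  place_unit <- function(step) {
    th <- step * twist * pi / 180
    shift <- c(0, 0, step * rise)
    bend <- step > (bend_after - 1L) && bend_angle != 0
    function(m) {
      out <- t(.Rz(th) %*% t(m)) +
        matrix(shift, nrow(m), 3, byrow = TRUE)
      if (bend) {
        zj <- (bend_after - 0.5) * rise
        piv <- c(0, 0, zj)
        out <- t(.Rx(bend_angle * pi / 180) %*%
                   t(sweep(out, 2L, piv))) +
          matrix(piv, nrow(m), 3, byrow = TRUE)
      }
      out
    }
  }

  atoms <- NULL
  add_res <- function(resno, xyz) {
    el <- attr(xyz, "element")
    atoms <<- rbind(atoms, data.frame(
      resno = resno, resid = sequence[resno], elety = rownames(xyz),
      elesy = el, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]))
  }
  truth <- NULL
  if (np) {
    for (k in seq_len(np)) {
      i <- pairing[k, 1]; j <- pairing[k, 2]
      b1 <- .canonical_template(sequence[i])
      b2 <- .place_partner(b1, sequence[i], sequence[j])
      ## centre the pair on the helix axis
      f1 <- base_frame(b1, sequence[i]); f2 <- base_frame(b2, sequence[j])
      mid <- (f1$origin + f2$origin) / 2
      tf <- place_unit(step_of[i])
      p1 <- tf(sweep(b1, 2L, mid)); p2 <- tf(sweep(b2, 2L, mid))
      attr(p1, "element") <- attr(b1, "element")
      attr(p2, "element") <- attr(b2, "element")
      rownames(p1) <- rownames(b1); rownames(p2) <- rownames(b2)
      add_res(i, p1); add_res(j, p2)
      truth <- rbind(truth, data.frame(i = i, j = j, category = "cWW"))
    }
  }
  for (r in which(!(seq_len(n) %in% c(pairing)))) {
    b <- .canonical_template(sequence[r])
    b_out <- sweep(b, 2L, c(10, 0, 0), `+`)  # flipped out of the helix
    tf <- place_unit(step_of[r])
    p <- tf(b_out)
    attr(p, "element") <- attr(b, "element")
    rownames(p) <- rownames(b)
    add_res(r, p)
  }
  atoms <- atoms[order(atoms$resno), ]
  if (is.null(file)) file <- tempfile(fileext = ".pdb")
  bio3d::write.pdb(file = file, xyz = as.numeric(t(as.matrix(
    atoms[, c("x", "y", "z")]))), resno = atoms$resno,
    resid = atoms$resid, elety = atoms$elety,
    eleno = seq_len(nrow(atoms)), chain = "A")
  list(file = file,
       pairs = if (is.null(truth))
         data.frame(i = integer(0), j = integer(0),
                    category = character(0)) else truth,
       atoms = atoms)
}
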