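#' Region specification for pentamer geometry
#'
#' @param ecd,tmd Residue-number ranges (length-2 integer vectors,
#'   inclusive) of the extracellular and transmembrane domains; must be
#'   disjoint.
#' @param chains Chain identifiers in pentamer order (>= 3 required for
#'   axis fitting).
#' @return A `region_spec` list.
#' @export
region_spec <- function(ecd, tmd, chains) {
  stopifnot(length(ecd) == 2, length(tmd) == 2)
  ecd <- sort(ecd); tmd <- sort(tmd)
  if (max(ecd[1], tmd[1]) <= min(ecd[2], tmd[2])) {
    stop("ECD and TMD residue ranges must be disjoint", call. = FALSE)
  }
  if (length(chains) < 3) stop("at least 3 chains are required", call. = FALSE)
  structure(list(ecd = ecd, tmd = tmd, chains = as.character(chains)),
            class = "region_spec")
}

.new_frame <- function(atoms, coords, model = 1L) {
  stopifnot(nrow(atoms) == nrow(coords), ncol(coords) == 3)
  if (any(!is.finite(coords))) stop("coordinates must be finite", call. = FALSE)
  structure(list(atoms = tibble::as_tibble(atoms), coords = coords,
                 model = model),
            class = "structure_frame")
}

#' @export
print.structure_frame <- function(x, ...) {
  cat(sprintf("<structure_frame> model %d: %d atoms, %d chains\n",
              x$model, nrow(x$atoms), length(unique(x$atoms$chain))))
  invisible(x)
}

#' @export
print.structure_trajectory <- function(x, ...) {
  cat(sprintf("<structure_trajectory> %d frames, %d atoms\n",
              length(x$frames), nrow(x$frames[[1]]$atoms)))
  invisible(x)
}

#' Load a (multi-model) PDB file as a trajectory
#'
#' Reads coordinates with bio3d. MODEL/ENDMDL blocks become successive
#' frames; alternate locations are resolved deterministically (highest
#' occupancy, then alphabetical altloc); hydrogens are dropped. Chain order
#' is taken from the file unless overridden.
#'
#' @param path One PDB path, or a character vector of single-model paths
#'   concatenated in order.
#' @param chains Optional chain order override.
#' @return A `structure_trajectory` (list of `structure_frame`s).
#' @export
load_trajectory <- function(path, chains = NULL) {
  frames <- list()
  for (p in path) {
    pdb <- tryCatch(bio3d::read.pdb(p, multi = TRUE, rm.alt = FALSE,
                                    verbose = FALSE),
                    error = function(e) stop(sprintf("cannot read '%s': %s",
                                                     p, conditionMessage(e)),
                                             call. = FALSE))
    at <- pdb$atom
    keep <- at$type == "ATOM" | at$type == "HETATM"
    at <- at[keep, , drop = FALSE]
    if (nrow(at) == 0) stop(sprintf("'%s' contains no atoms", p), call. = FALSE)
    # altloc resolution: highest occupancy, ties alphabetical
    at$alt[is.na(at$alt) | at$alt == ""] <- ""
    at$o[is.na(at$o)] <- 1
    key <- paste(at$chain, at$resno, at$elety, sep = "\r")
    ord <- order(key, -at$o, at$alt)
    first <- !duplicated(key[ord])
    sel_idx <- sort(seq_len(nrow(at))[ord][first])
    at_keep <- at[sel_idx, , drop = FALSE]
    elem <- at_keep$elesy
    if (is.null(elem)) elem <- substr(at_keep$elety, 1, 1)
    not_h <- is.na(elem) | toupper(trimws(elem)) != "H"
    at_keep <- at_keep[not_h, , drop = FALSE]
    atoms <- tibble::tibble(chain = at_keep$chain, resno = at_keep$resno,
                            resid = at_keep$resid, atom = at_keep$elety,
                            element = toupper(trimws(elem[not_h])),
                            occupancy = at_keep$o)
    xyz <- pdb$xyz
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
    keep_xyz <- which(keep)[sel_idx][not_h]
    cols <- as.vector(rbind(3 * keep_xyz - 2, 3 * keep_xyz - 1, 3 * keep_xyz))
    for (m in seq_len(nrow(xyz))) {
      co <- matrix(xyz[m, cols], ncol = 3, byrow = TRUE)
      frames[[length(frames) + 1]] <- .new_frame(atoms, co,
                                                 model = length(frames) + 1L)
    }
  }
  chain_order <- if (is.null(chains)) unique(frames[[1]]$atoms$chain) else chains
  structure(list(frames = frames, chains = chain_order),
            class = "structure_trajectory")
}

.as_frames <- function(x) {
  if (inherits(x, "structure_trajectory")) x$frames
  else if (inherits(x, "structure_frame")) list(x)
  else stop("expected a structure_frame or structure_trajectory", call. = FALSE)
}

.frame_chains <- function(frame) unique(frame$atoms$chain)

.region_centroid <- function(frame, chain, resrange) {
  sel <- frame$atoms$chain == chain &
    frame$atoms$resno >= resrange[1] & frame$atoms$resno <= resrange[2]
  if (!any(sel)) {
    stop(sprintf("empty region selection: chain %s residues %d-%d",
                 chain, resrange[1], resrange[2]), call. = FALSE)
  }
  colMeans(frame$coords[sel, , drop = FALSE])
}

# signed dihedral p1-p2-p3-p4 in degrees
.dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- .cross(b1, b2); n2 <- .cross(b2, b3)
  m1 <- .cross(n1, b2 / sqrt(sum(b2^2)))
  x <- sum(n1 * n2); y <- sum(m1 * n2)
  atan2(y, x) * 180 / pi
}

.cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Per-subunit ECD/TMD twist angle
#'
#' For each subunit, the signed pseudo-dihedral formed by (subunit ECD
#' centroid, whole-pentamer ECD centroid, whole-pentamer TMD centroid,
#' subunit TMD centroid), in degrees in (-180, 180]. It quantifies the
#' counter-rotation of the extracellular layer relative to the
#' transmembrane layer; positive values mean the ECD is rotated
#' counterclockwise viewed from the extracellular side. The measure is
#' invariant under rigid-body motion of the whole frame.
#'
#' @param frame A `structure_frame`.
#' @param regions A [region_spec()].
#' @return Named numeric vector of per-subunit angles (degrees).
#' @export
twist_angle <- function(frame, regions) {
  stopifnot(inherits(frame, "structure_frame"), inherits(regions, "region_spec"))
  chains <- regions$chains
  ecd_all <- colMeans(do.call(rbind, lapply(chains, function(ch)
    .region_centroid(frame, ch, regions$ecd))))
  tmd_all <- colMeans(do.call(rbind, lapply(chains, function(ch)
    .region_centroid(frame, ch, regions$tmd))))
  out <- vapply(chains, function(ch) {
    # sign flipped so that a counterclockwise ECD rotation (viewed from the
    # extracellular side, +z toward the viewer) is positive
    -.dihedral(.region_centroid(frame, ch, regions$ecd), ecd_all, tmd_all,
               .region_centroid(frame, ch, regions$tmd))
  }, numeric(1))
  names(out) <- chains
  out
}

.select_atoms <- function(frame, chain, resno, mode, atom_name = NULL) {
  a <- frame$atoms
  base <- a$chain == chain & a$resno == resno
  if (!any(base)) {
    stop(sprintf("no atoms for chain %s residue %d", chain, resno), call. = FALSE)
  }
  idx <- switch(mode,
    CA = which(base & a$atom == "CA"),
    CB = which(base & a$atom == "CB"),
    named_atom = which(base & a$atom == atom_name),
    sidechain_centroid = {
      backbone <- c("N", "CA", "C", "O", "CB", "OXT")
      i <- which(base & !(a$atom %in% backbone))
      if (length(i) == 0) i <- which(base)  # non-standard residue: all heavy atoms
      i
    },
    stop("unknown selection mode: ", mode, call. = FALSE))
  if (length(idx) == 0) {
    stop(sprintf("missing atom (%s%s) in chain %s residue %d", mode,
                 if (!is.null(atom_name)) paste0(" ", atom_name) else "",
                 chain, resno), call. = FALSE)
  }
  colMeans(frame$coords[idx, , drop = FALSE])
}

#' Intra- or inter-subunit pair distances across a trajectory
#'
#' Euclidean distance (Angstrom) between two residue-level points in every
#' frame, for all five subunits (`topology = "intra"`) or all five ordered
#' (i, i+1) interfaces (`topology = "inter"`, chain order from the
#' trajectory). Points are the CA atom, the CB atom, the unweighted
#' centroid of side-chain heavy atoms beyond CB (all heavy atoms for
#' non-standard residues such as a placed fluorophore), or a named atom.
#'
#' @param trajectory A `structure_trajectory` (or single frame).
#' @param selection_a,selection_b Lists `list(resno =, atom = )` (`atom`
#'   only for `mode = "named_atom"`; a per-selection `mode` entry overrides
#'   the global one).
#' @param mode `"CA"`, `"CB"`, `"sidechain_centroid"` or `"named_atom"`.
#' @param topology `"intra"` or `"inter"`.
#' @return A `metric_series` tibble: `frame`, `group` (subunit or
#'   interface), `metric`, `value`, `unit`.
#' @export
pair_distance <- function(trajectory, selection_a, selection_b,
                          mode = c("CA", "CB", "sidechain_centroid", "named_atom"),
                          topology = c("intra", "inter")) {
  mode <- match.arg(mode)
  topology <- match.arg(topology)
  frames <- .as_frames(trajectory)
  chains <- if (inherits(trajectory, "structure_trajectory")) trajectory$chains
            else .frame_chains(trajectory)
  n <- length(chains)
  mode_a <- selection_a$mode %||% mode
  mode_b <- selection_b$mode %||% mode
  rows <- purrr::map_dfr(seq_along(frames), function(fi) {
    fr <- frames[[fi]]
    purrr::map_dfr(seq_len(n), function(i) {
      ch_a <- chains[i]
      ch_b <- if (topology == "intra") chains[i] else chains[i %% n + 1]
      pa <- .select_atoms(fr, ch_a, selection_a$resno, mode_a, selection_a$atom)
      pb <- .select_atoms(fr, ch_b, selection_b$resno, mode_b, selection_b$atom)
      tibble::tibble(
        frame = fi,
        group = if (topology == "intra") ch_a else paste0(ch_a, "-", ch_b),
        metric = sprintf("%s distance %d/%d (%s)", topology,
                         selection_a$resno, selection_b$resno, mode),
        value = sqrt(sum((pa - pb)^2)), unit = "angstrom")
    })
  })
  class(rows) <- c("metric_series", class(rows))
  rows
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Ring radius at a pore-lining residue
#'
#' Approximates the pore radius at a residue ring (e.g. the Ile233 / I9'
#' activation gate): the channel axis is the total-least-squares line
#' through the per-chain ECD and TMD centroids, and the radius is the mean
#' perpendicular distance of the ring atoms from that axis, optionally
#' minus a 1.7-Angstrom carbon van der Waals radius.
#'
#' @param frame A `structure_frame`.
#' @param residue_number Residue whose ring is measured.
#' @param atom_name Ring atom (default `"CA"`).
#' @param subtract_vdw Subtract 1.7 Angstrom (default `FALSE`).
#' @param regions A [region_spec()] defining the centroids for axis
#'   fitting.
#' @return Radius in Angstrom.
#' @export
ring_radius <- function(frame, residue_number, atom_name = "CA",
                        subtract_vdw = FALSE, regions) {
  stopifnot(inherits(frame, "structure_frame"), inherits(regions, "region_spec"))
  chains <- regions$chains
  sel <- frame$atoms$resno == residue_number & frame$atoms$atom == atom_name &
    frame$atoms$chain %in% chains
  ring <- frame$coords[sel, , drop = FALSE]
  if (nrow(ring) < 3) {
    stop("ring atom present in fewer than 3 chains", call. = FALSE)
  }
  cents <- do.call(rbind, lapply(chains, function(ch)
    rbind(.region_centroid(frame, ch, regions$ecd),
          .region_centroid(frame, ch, regions$tmd))))
  ctr <- colMeans(cents)
  sv <- svd(sweep(cents, 2, ctr))
  axis <- sv$v[, 1]
  # degenerate ring: all ring atoms collinear -> cross-section undefined
  ring_c <- sweep(ring, 2, colMeans(ring))
  if (svd(ring_c)$d[2] < 1e-8) {
    stop("ring atoms are collinear: axis/ring geometry degenerate", call. = FALSE)
  }
  rel <- sweep(ring, 2, ctr)
  proj <- rel %*% axis
  perp <- rel - proj %*% t(axis)
  r <- mean(sqrt(rowSums(perp^2)))
  if (subtract_vdw) r - 1.7 else r
}

#' RMSD of every frame to a reference structure
#'
#' Atoms are matched 1:1 by (chain, residue number, atom name); with
#' `superpose = TRUE` an optimal least-squares (Kabsch, no reflection)
#' superposition is applied before the deviation is computed.
#'
#' @param trajectory A `structure_trajectory` or `structure_frame`.
#' @param reference_frame A `structure_frame`.
#' @param selection Optional list with `resno` (vector) and/or `atom`
#'   (vector) restricting the compared atoms.
#' @param superpose Remove rigid-body motion first (default `TRUE`).
#' @return A `metric_series` tibble (`frame`, `group = "all"`, `value` in
#'   Angstrom).
#' @export
rmsd_to_reference <- function(trajectory, reference_frame, selection = NULL,
                              superpose = TRUE) {
  frames <- .as_frames(trajectory)
  stopifnot(inherits(reference_frame, "structure_frame"))
  key <- function(a) paste(a$chain, a$resno, a$atom, sep = "\r")
  pick <- function(fr) {
    k <- rep(TRUE, nrow(fr$atoms))
    if (!is.null(selection$resno)) k <- k & fr$atoms$resno %in% selection$resno
    if (!is.null(selection$atom)) k <- k & fr$atoms$atom %in% selection$atom
    k
  }
  rk <- pick(reference_frame)
  ref_keys <- key(reference_frame$atoms)[rk]
  ref_xyz <- reference_frame$coords[rk, , drop = FALSE]
  rows <- purrr::map_dfr(seq_along(frames), function(fi) {
    fr <- frames[[fi]]
    fk <- pick(fr)
    fr_keys <- key(fr$atoms)[fk]
    m <- match(ref_keys, fr_keys)
    if (any(is.na(m)) || length(ref_keys) != length(fr_keys)) {
      stop(sprintf("atom correspondence mismatch in frame %d", fi), call. = FALSE)
    }
    xyz <- fr$coords[fk, , drop = FALSE][m, , drop = FALSE]
    v <- bio3d::rmsd(as.vector(t(ref_xyz)), as.vector(t(xyz)),
                     fit = superpose)
    tibble::tibble(frame = fi, group = "all", metric = "RMSD", value = v,
                   unit = "angstrom")
  })
  class(rows) <- c("metric_series", class(rows))
  rows
}

#' Per-frame spread statistics of a metric
#'
#' Summarizes per-subunit or per-interface values within each frame (mean,
#' sample SD, range), the statistics used to describe the asymmetry of the
#' extracellular domains along a gating trajectory.
#'
#' @param metric A `metric_series` tibble (>= 2 values per frame).
#' @return A tibble (`frame`, `mean`, `sd`, `range`).
#' @export
asymmetry_stats <- function(metric) {
  stopifnot(all(c("frame", "value") %in% names(metric)))
  counts <- table(metric$frame)
  if (any(counts < 2)) {
    stop("at least 2 values per frame are required", call. = FALSE)
  }
  dplyr::summarise(dplyr::group_by(tibble::as_tibble(metric), frame),
                   mean = mean(value), sd = stats::sd(value),
                   range = diff(range(value)), .groups = "drop")
}

#' Does the per-frame spread decline along the trajectory?
#'
#' Utility for the observation that inter-subunit variability decreases as
#' the pentamer approaches the compact, symmetric conformation: `TRUE` when
#' the SD in the last frame is smaller than in the first.
#'
#' @param metric A `metric_series`.
#' @return Logical.
#' @export
asymmetry_declines <- function(metric) {
  s <- asymmetry_stats(metric)
  s$sd[which.max(s$frame)] < s$sd[which.min(s$frame)]
}

#' Build a synthetic C5-symmetric pseudo-CA pentamer
#'
#' Test fixture with controllable geometry: each subunit has an ECD layer
#' and a TMD layer of pseudo-CA atoms whose per-subunit centroids sit at a
#' known radius and azimuth, an ECD-vs-TMD azimuthal offset (`twist_deg`),
#' a radial ECD compaction factor, and a ring atom (residue 233) at
#' `radius` for pore measurements. All geometry metrics on the result
#' equal their construction parameters.
#'
#' @param radius Ring and layer radius in Angstrom.
#' @param layer_separation Vertical ECD-TMD separation in Angstrom.
#' @param twist_deg ECD azimuthal offset in degrees.
#' @param compaction_scale Radial scale factor applied to the ECD layer.
#' @param n_chains Number of chains (>= 3).
#' @return A `structure_frame` with attribute `regions` (its
#'   [region_spec()]).
#' @export
build_synthetic_pentamer <- function(radius = 20, layer_separation = 40,
                                     twist_deg = 0, compaction_scale = 1,
                                     n_chains = 5) {
  if (n_chains < 3) stop("at least 3 chains are required", call. = FALSE)
  chains <- LETTERS[seq_len(n_chains)]
  rows <- list(); coords <- list()
  for (i in seq_len(n_chains)) {
    base_az <- 2 * pi * (i - 1) / n_chains
    ecd_az <- base_az + twist_deg * pi / 180
    r_ecd <- radius * compaction_scale
    ecd_c <- c(r_ecd * cos(ecd_az), r_ecd * sin(ecd_az), layer_separation / 2)
    tmd_c <- c(radius * cos(base_az), radius * sin(base_az), -layer_separation / 2)
    # two pseudo-CA atoms per layer, symmetric about the layer centroid
    pts <- rbind(ecd_c + c(0, 0, 1), ecd_c - c(0, 0, 1),
                 tmd_c + c(0, 0, 1), tmd_c - c(0, 0, 1))
    resno <- c(10L, 11L, 110L, 111L)
    # gate ring atom at the mid-plane
    pts <- rbind(pts, c(radius * cos(base_az), radius * sin(base_az), 0))
    resno <- c(resno, 233L)
    rows[[i]] <- tibble::tibble(chain = chains[i], resno = resno,
                                resid = "ALA", atom = "CA", element = "C",
                                occupancy = 1)
    coords[[i]] <- pts
  }
  fr <- .new_frame(dplyr::bind_rows(rows), do.call(rbind, coords))
  attr(fr, "regions") <- region_spec(ecd = c(10, 11), tmd = c(110, 111),
                                     chains = chains)
  fr
}

#' Apply a rigid-body transform to a frame
#'
#' @param frame A `structure_frame`.
#' @param rotation 3x3 rotation matrix.
#' @param translation Length-3 translation vector.
#' @return The transformed frame.
#' @export
transform_frame <- function(frame, rotation = diag(3), translation = c(0, 0, 0)) {
  stopifnot(inherits(frame, "structure_frame"))
  frame$coords <- frame$coords %*% t(rotation) +
    matrix(translation, nrow(frame$coords), 3, byrow = TRUE)
  frame
}

#' Write frames as a multi-model PDB file
#'
#' @param frames A `structure_frame`, list of frames, or
#'   `structure_trajectory`.
#' @param path Output PDB path.
#' @return `path`, invisibly.
#' @export
write_frames_pdb <- function(frames, path) {
  if (inherits(frames, "structure_frame")) frames <- list(frames)
  frames <- if (inherits(frames, "structure_trajectory")) frames$frames else frames
  a <- frames[[1]]$atoms
  xyz <- do.call(rbind, lapply(frames, function(f) as.vector(t(f$coords))))
  bio3d::write.pdb(file = path, xyz = xyz, resno = a$resno, resid = a$resid,
                   chain = a$chain, elety = a$atom)
  invisible(path)
}

#' Tidy CSV export of a metric series
#'
#' @param metric A `metric_series` tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_metric_csv <- function(metric, path) {
  readr::write_csv(tibble::as_tibble(metric), path)
  invisible(path)
}
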