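#' Build an in-memory trajectory object
#'
#' Coordinates are in nanometres. Probe particles (the small apolar
#' spheres used for hydrophobicity mapping) are flagged per atom and are
#' always excluded from superposition and clustering selections.
#'
#' @param frames List of `n_atoms x 3` coordinate matrices (nm), all the
#'   same dimension, or a 3-D array `n_frames x n_atoms x 3`.
#' @param atoms Data frame with one row per atom: `name`, `element`,
#'   `resid` (residue name), `resno`, `is_probe`, `is_heavy`.
#' @param box Optional periodic box lengths `c(x, y, z)` in nm.
#' @return Object of class `vh_trajectory`.
#' @export
trajectory <- function(frames, atoms, box = NULL) {
  if (is.array(frames) && length(dim(frames)) == 3L) {
    frames <- lapply(seq_len(dim(frames)[1]), function(i) frames[i, , ])
  }
  n_atoms <- nrow(frames[[1]])
  ok <- vapply(frames, function(f) is.matrix(f) && nrow(f) == n_atoms &&
                 ncol(f) == 3L, logical(1))
  if (!all(ok)) stop("all frames must be n_atoms x 3 matrices of equal size")
  stopifnot(nrow(atoms) == n_atoms,
            all(c("name", "element", "resid", "resno", "is_probe",
                  "is_heavy") %in% names(atoms)))
  if (!is.null(box)) stopifnot(length(box) == 3L, all(box > 0))
  structure(list(frames = frames, atoms = atoms, box = box),
            class = "vh_trajectory")
}

#' @export
print.vh_trajectory <- function(x, ...) {
  cat(sprintf("<trajectory: %d frames, %d atoms (%d probes)%s>\n",
              length(x$frames), nrow(x$atoms), sum(x$atoms$is_probe),
              if (is.null(x$box)) "" else
                sprintf(", box %.2f x %.2f x %.2f nm",
                        x$box[1], x$box[2], x$box[3])))
  invisible(x)
}

#' Default RMSD atom selection: protein backbone
#'
#' Backbone (N, CA, C) atoms of non-probe residues; the conventional
#' selection for conformational RMSD.
#'
#' @param traj `vh_trajectory`.
#' @return Integer atom indices.
#' @export
backbone_selection <- function(traj) {
  which(!traj$atoms$is_probe & traj$atoms$name %in% c("N", "CA", "C"))
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares rigid transform (proper rotation + translation, no
#' reflection) of the mobile coordinates onto the reference, via SVD of
#' the covariance matrix with a determinant sign guard. Returns the
#' post-fit RMSD.
#'
#' @param reference,mobile `n x 3` coordinate matrices (same units).
#' @param selection Optional atom indices used for the fit (default all).
#' @return List: `rotation` (3x3, applied to centered mobile),
#'   `translation`, `rmsd`, and `fitted` (all mobile atoms transformed).
#' @export
superpose <- function(reference, mobile, selection = NULL) {
  if (!is.null(selection)) {
    ref_s <- reference[selection, , drop = FALSE]
    mob_s <- mobile[selection, , drop = FALSE]
  } else {
    ref_s <- reference
    mob_s <- mobile
  }
  if (nrow(ref_s) != nrow(mob_s)) stop("selection length mismatch")
  if (nrow(ref_s) < 2L) stop("degenerate geometry: need at least 2 atoms")
  cr <- colMeans(ref_s)
  cm <- colMeans(mob_s)
  A <- sweep(mob_s, 2, cm)
  B <- sweep(ref_s, 2, cr)
  H <- crossprod(A, B) # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted_s <- sweep(A %*% t(R), 2, cr, "+")
  rmsd <- sqrt(mean(rowSums((fitted_s - ref_s)^2)))
  fitted <- sweep(sweep(mobile, 2, cm) %*% t(R), 2, cr, "+")
  list(rotation = R, translation = cr - as.vector(cm %*% t(R)),
       rmsd = rmsd, fitted = fitted)
}

#' Pairwise post-superposition RMSD matrix
#'
#' @param traj `vh_trajectory` with at least 2 frames.
#' @param selection Atom indices used for fitting and RMSD (default
#'   [backbone_selection()]; falls back to all non-probe atoms when no
#'   backbone names are present).
#' @return Symmetric matrix (nm) with zero diagonal.
#' @export
rmsd_matrix <- function(traj, selection = NULL) {
  stopifnot(inherits(traj, "vh_trajectory"))
  if (length(traj$frames) < 2L) stop("need at least 2 frames")
  if (is.null(selection)) {
    selection <- backbone_selection(traj)
    if (length(selection) == 0L) selection <- which(!traj$atoms$is_probe)
  }
  if (length(selection) == 0L) stop("empty atom selection")
  n <- length(traj$frames)
  M <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      r <- superpose(traj$frames[[i]], traj$frames[[j]], selection)$rmsd
      M[i, j] <- M[j, i] <- r
    }
  }
  M
}

#' Greedy RMSD clustering of frames
#'
#' Dominant-structure clustering: repeatedly pick the unassigned frame
#' with the most unassigned neighbors within the RMSD cutoff as a cluster
#' center, assign the center and those neighbors to a new cluster, remove
#' them, and repeat until all frames are assigned. Ties are broken by the
#' lowest frame index. With the cutoff above every pairwise RMSD this
#' yields one cluster; with it below, one singleton per frame.
#'
#' @param matrix Square symmetric nonnegative RMSD matrix (no NAs).
#' @param cutoff RMSD cutoff (same units as the matrix; 0.2 nm is the
#'   conventional choice for backbone clustering).
#' @return Object of class `cluster_result`: `labels` (cluster id per
#'   frame), `centers` (frame index per cluster id), `sizes`, `cutoff`.
#' @export
greedy_cluster <- function(matrix, cutoff) {
  if (any(is.na(matrix))) stop("NA entries in RMSD matrix")
  n <- nrow(matrix)
  stopifnot(ncol(matrix) == n, cutoff >= 0)
  adj <- matrix <= cutoff
  diag(adj) <- TRUE
  labels <- rep(NA_integer_, n)
  centers <- integer(0)
  cl <- 0L
  unassigned <- rep(TRUE, n)
  while (any(unassigned)) {
    counts <- as.integer(adj %*% unassigned) # neighbors still unassigned
    counts[!unassigned] <- -1L
    center <- which.max(counts) # which.max takes the lowest index on ties
    members <- which(unassigned & adj[center, ])
    cl <- cl + 1L
    labels[members] <- cl
    centers[cl] <- center
    unassigned[members] <- FALSE
  }
  structure(list(labels = labels, centers = centers,
                 sizes = as.integer(table(labels)), cutoff = cutoff),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<clustering: %d clusters at cutoff %.3g; sizes %s>\n",
              length(x$centers), x$cutoff,
              paste(x$sizes, collapse = ", ")))
  invisible(x)
}

# Minimum-image distance-squared between one point and a set of points.
min_image_dist2 <- function(point, coords, box) {
  d <- sweep(coords, 2, point)
  if (!is.null(box)) {
    for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  }
  rowSums(d * d)
}

#' Per-heavy-atom mean probe counts over a trajectory
#'
#' For every protein heavy atom, counts the probe particles within the
#' cutoff distance in each frame (minimum-image distances when a periodic
#' box is declared) and averages over frames. Frames are treated as
#' independent samples. High mean counts mark surface regions that favor
#' contacts with the apolar probes, i.e. context-dependent hydrophobicity.
#'
#' @param traj `vh_trajectory` containing probe and protein atoms.
#' @param cutoff Vicinity cutoff in nm (default 0.5).
#' @param normalize If `TRUE`, divide by the expected count for a uniform
#'   bulk probe density (`n_probes * v_cutoff / v_box`; periodic systems
#'   only), reporting local enrichment instead of raw mean counts.
#' @return Object of class `probe_map`: data frame `atoms` (heavy-atom
#'   metadata + `mean_count`), `cutoff`, `n_frames`, `n_probes`,
#'   `normalized`.
#' @export
probe_density <- function(traj, cutoff = 0.5, normalize = FALSE) {
  stopifnot(inherits(traj, "vh_trajectory"))
  probe_idx <- which(traj$atoms$is_probe)
  heavy_idx <- which(!traj$atoms$is_probe & traj$atoms$is_heavy)
  if (length(probe_idx) == 0L) stop("trajectory contains no probe atoms")
  if (length(heavy_idx) == 0L) stop("trajectory contains no heavy protein atoms")
  if (!is.null(traj$box) && cutoff > min(traj$box) / 2) {
    stop("cutoff exceeds half the smallest box length")
  }
  cut2 <- cutoff^2
  counts <- numeric(length(heavy_idx))
  for (fr in traj$frames) {
    probes <- fr[probe_idx, , drop = FALSE]
    for (i in seq_along(heavy_idx)) {
      d2 <- min_image_dist2(fr[heavy_idx[i], ], probes, traj$box)
      counts[i] <- counts[i] + sum(d2 <= cut2)
    }
  }
  counts <- counts / length(traj$frames)
  normalized <- FALSE
  if (normalize) {
    if (is.null(traj$box)) stop("normalization requires a periodic box")
    bulk <- length(probe_idx) * (4 / 3) * pi * cutoff^3 / prod(traj$box)
    counts <- counts / bulk
    normalized <- TRUE
  }
  structure(list(atoms = cbind(traj$atoms[heavy_idx, , drop = FALSE],
                               mean_count = counts),
                 cutoff = cutoff,
                 n_frames = length(traj$frames),
                 n_probes = length(probe_idx),
                 normalized = normalized),
            class = "probe_map")
}

#' @export
print.probe_map <- function(x, ...) {
  cat(sprintf("<probe_map: %d heavy atoms, cutoff %.2f nm, %d frames, mean count %.3g%s>\n",
              nrow(x$atoms), x$cutoff, x$n_frames, mean(x$atoms$mean_count),
              if (x$normalized) " (bulk-normalized)" else ""))
  invisible(x)
}

#' Read a multi-model PDB trajectory
#'
#' MODEL/ENDMDL records become frames; coordinates are converted from
#' Angstrom to nm. A CRYST1 record, when present, supplies the periodic
#' box. Probe particles are identified by residue name.
#'
#' @param path PDB file.
#' @param probe_resid Residue names marking probe particles.
#' @return `vh_trajectory`.
#' @export
read_trajectory_pdb <- function(path, probe_resid = c("PRB", "CH4")) {
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  xyz <- pdb$xyz # n_frames x (3*n_atoms), Angstrom
  n_atoms <- nrow(pdb$atom)
  frames <- lapply(seq_len(nrow(xyz)), function(i) {
    matrix(xyz[i, ], ncol = 3, byrow = TRUE) / 10
  })
  elem <- pdb$atom$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == "")) {
    elem <- substr(trimws(pdb$atom$elety), 1, 1)
  }
  atoms <- data.frame(name = trimws(pdb$atom$elety),
                      element = trimws(elem),
                      resid = trimws(pdb$atom$resid),
                      resno = pdb$atom$resno,
                      stringsAsFactors = FALSE)
  atoms$is_probe <- atoms$resid %in% probe_resid
  atoms$is_heavy <- toupper(atoms$element) != "H"
  box <- NULL
  cryst <- grep("^CRYST1", readLines(path, warn = FALSE), value = TRUE)
  if (length(cryst) >= 1L) {
    v <- as.numeric(c(substr(cryst[1], 7, 15), substr(cryst[1], 16, 24),
                      substr(cryst[1], 25, 33)))
    if (!any(is.na(v)) && all(v > 0)) box <- v / 10
  }
  trajectory(frames, atoms, box = box)
}

#' Write a trajectory as a multi-model PDB
#'
#' Coordinates are converted from nm to Angstrom; the box, when present,
#' is written as a CRYST1 record.
#'
#' @param traj `vh_trajectory`.
#' @param path Output PDB file.
#' @return `path`, invisibly.
#' @export
write_trajectory_pdb <- function(traj, path) {
  lines <- character(0)
  if (!is.null(traj$box)) {
    lines <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                     traj$box[1] * 10, traj$box[2] * 10, traj$box[3] * 10,
                     90, 90, 90)
  }
  a <- traj$atoms
  for (fi in seq_along(traj$frames)) {
    lines <- c(lines, sprintf("MODEL     %4d", fi))
    xyz <- traj$frames[[fi]] * 10
    lines <- c(lines, sprintf(
      "ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(a)), substr(a$name, 1, 4), substr(a$resid, 1, 3),
      a$resno %% 10000, xyz[, 1], xyz[, 2], xyz[, 3], 1, 0,
      substr(a$element, 1, 2)))
    lines <- c(lines, "ENDMDL")
  }
  lines <- c(lines, "END")
  writeLines(lines, path)
  invisible(path)
}

#' Read a plain per-frame XYZ trajectory
#'
#' Minimal XYZ dialect: repeated blocks of `n_atoms`, a comment line, then
#' `name x y z` rows (nm). All atoms are treated as heavy protein atoms
#' unless their name matches `probe_names`.
#'
#' @param path XYZ file.
#' @param probe_names Atom names marking probes (default `"PRB"`).
#' @param box Optional box lengths (nm); XYZ carries none.
#' @return `vh_trajectory`.
#' @export
read_trajectory_xyz <- function(path, probe_names = "PRB", box = NULL) {
  ln <- readLines(path, warn = FALSE)
  frames <- list()
  names_ref <- NULL
  i <- 1L
  while (i <= length(ln)) {
    if (!nzchar(trimws(ln[i]))) { i <- i + 1L; next }
    n <- as.integer(trimws(ln[i]))
    if (is.na(n)) stop("malformed XYZ: expected atom count at line ", i)
    block <- ln[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(block), "[[:space:]]+")
    nm <- vapply(parts, `[`, character(1), 1)
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (is.null(names_ref)) names_ref <- nm
    else if (!identical(nm, names_ref)) stop("atom order differs between frames")
    frames[[length(frames) + 1L]] <- xyz
    i <- i + 2L + n
  }
  atoms <- data.frame(name = names_ref, element = substr(names_ref, 1, 1),
                      resid = ifelse(names_ref %in% probe_names, "PRB", "PRO"),
                      resno = seq_along(names_ref), stringsAsFactors = FALSE)
  atoms$is_probe <- names_ref %in% probe_names
  atoms$is_heavy <- toupper(atoms$element) != "H"
  trajectory(frames, atoms, box = box)
}

#' Write a probe map as a B-factor-colored structure
#'
#' Writes a single-model PDB of the protein heavy atoms (probes excluded)
#' with each atom's mean probe count (optionally linearly rescaled) in the
#' temperature-factor column, the conventional way to color structures by
#' a per-atom score.
#'
#' @param traj `vh_trajectory` supplying the structure (frame
#'   `frame_index`).
#' @param map `probe_map` covering all heavy atoms of the structure.
#' @param path Output PDB file.
#' @param frame_index Which frame supplies the coordinates (default 1).
#' @param scale Optional `c(a, b)`: write `a + b * count` instead of the
#'   raw count (linear mapping into a plotting range).
#' @return `path`, invisibly.
#' @export
write_map <- function(traj, map, path, frame_index = 1L, scale = NULL) {
  stopifnot(inherits(traj, "vh_trajectory"), inherits(map, "probe_map"))
  heavy_idx <- which(!traj$atoms$is_probe & traj$atoms$is_heavy)
  if (length(heavy_idx) != nrow(map$atoms)) {
    stop("probe map does not cover all heavy atoms of the structure")
  }
  scores <- map$atoms$mean_count
  if (!is.null(scale)) scores <- scale[1] + scale[2] * scores
  a <- traj$atoms[heavy_idx, , drop = FALSE]
  xyz <- traj$frames[[frame_index]][heavy_idx, , drop = FALSE] * 10
  lines <- sprintf(
    "ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(a)), substr(a$name, 1, 4), substr(a$resid, 1, 3),
    a$resno %% 10000, xyz[, 1], xyz[, 2], xyz[, 3], 1, scores,
    substr(a$element, 1, 2))
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Read back per-atom scores from a B-factor-colored PDB
#'
#' @param path PDB file written by [write_map()].
#' @return Numeric vector of temperature-factor scores.
#' @export
read_map_scores <- function(path) {
  pdb <- bio3d::read.pdb(path)
  pdb$atom$b
}
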