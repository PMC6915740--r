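# Backbone mobility analysis: trajectory containers and I/O (multi-model PDB
# via bio3d, plain XYZ frames by hand), Kabsch least-squares superposition,
# iterative average structure, per-atom RMSF and per-loop reporting relative
# to a reference variant.

#' Trajectory container
#'
#' Ordered coordinate frames sharing one atom table. Coordinates are stored
#' as a matrix with one row per frame and columns x1, y1, z1, x2, ... in
#' Angstrom (the layout used by structural-bioinformatics packages).
#'
#' @param atoms Data frame with columns `elety` (atom name), `resno`,
#'   `resid`, `chain`.
#' @param xyz Numeric matrix, `n_frames` x `3 * n_atoms`.
#' @param dt Frame spacing metadata, ps.
#' @return An object of class `flex_trajectory`.
#' @export
flex_trajectory <- function(atoms, xyz, dt = 0.1) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  if (ncol(xyz) != 3 * nrow(atoms))
    stop_coldevb("xyz width must be 3 x number of atoms", "coldevb_format_error")
  if (any(!is.finite(xyz)))
    stop_coldevb("coordinates must be finite", "coldevb_format_error")
  structure(list(atoms = atoms, xyz = xyz, dt = dt), class = "flex_trajectory")
}

#' @export
print.flex_trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d frames, %d atoms, %d residues\n",
              nrow(x$xyz), nrow(x$atoms), length(unique(x$atoms$resno))))
  invisible(x)
}

n_frames <- function(traj) nrow(traj$xyz)

# frame as an n_atoms x 3 matrix
.frame_mat <- function(traj, i) matrix(traj$xyz[i, ], ncol = 3, byrow = TRUE)
.flatten <- function(m) as.numeric(t(m))

#' Backbone atom selection mask
#'
#' @param atoms Atom table of a [flex_trajectory()].
#' @param names Atom names counted as backbone (N, CA, C; O excluded).
#' @return Logical vector over atoms.
#' @export
backbone_mask <- function(atoms, names = c("N", "CA", "C")) {
  atoms$elety %in% names
}

# ---------------------------------------------------------------------------
# I/O

.scan_pdb_models <- function(lines) {
  tag <- substr(lines, 1, 6)
  opens <- grep("^MODEL ?", tag)
  closes <- which(tag == "ENDMDL")
  if (length(opens) != length(closes))
    stop_coldevb("unbalanced MODEL/ENDMDL records", "coldevb_format_error")
  depth <- 0
  counts <- integer(0)
  cur <- 0L
  model_idx <- 0L
  for (ln in lines) {
    t6 <- substr(ln, 1, 6)
    if (grepl("^MODEL ?$", t6) || t6 == "MODEL ") {
      if (depth != 0)
        stop_coldevb(sprintf("malformed MODEL nesting at model %d", model_idx + 1L),
                     "coldevb_format_error")
      depth <- 1; model_idx <- model_idx + 1L; cur <- 0L
    } else if (t6 == "ENDMDL") {
      if (depth != 1)
        stop_coldevb(sprintf("ENDMDL without MODEL near model %d", model_idx),
                     "coldevb_format_error")
      depth <- 0; counts <- c(counts, cur)
    } else if (t6 == "ATOM  " || t6 == "HETATM") {
      cur <- cur + 1L
    }
  }
  if (length(counts) > 1 && length(unique(counts)) != 1) {
    bad <- which(counts != counts[1])[1]
    stop_coldevb(sprintf(
      "inconsistent atom count in model %d (%d atoms, expected %d)",
      bad, counts[bad], counts[1]), "coldevb_format_error")
  }
  length(counts)
}

#' Read a trajectory from a multi-model PDB or XYZ-frame file
#'
#' PDB files are parsed with bio3d after a structural pre-scan of the
#' MODEL/ENDMDL blocks (so malformed nesting or inconsistent atom counts are
#' reported with the offending model index). XYZ files follow the standard
#' frame layout (atom count line, comment line, `name x y z` lines); residue
#' numbers are taken from an optional `atoms` table or inferred from repeated
#' N/CA/C patterns.
#'
#' @param path File path.
#' @param format `"pdb"` or `"xyz"`; guessed from the extension by default.
#' @param atoms Optional atom table for XYZ input.
#' @return A [flex_trajectory()].
#' @export
read_trajectory <- function(path, format = c("auto", "pdb", "xyz"),
                            atoms = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.xyz$", path, ignore.case = TRUE)) "xyz" else "pdb"
  if (!file.exists(path))
    stop_coldevb(sprintf("file not found: %s", path), "coldevb_format_error")
  if (format == "pdb") {
    lines <- readLines(path, warn = FALSE)
    .scan_pdb_models(lines)
    if (!requireNamespace("bio3d", quietly = TRUE))
      stop_coldevb("reading PDB trajectories requires the bio3d package",
                   "coldevb_format_error")
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    at <- pdb$atom
    atoms <- data.frame(elety = at$elety, resno = at$resno,
                        resid = at$resid, chain = at$chain,
                        stringsAsFactors = FALSE)
    xyz <- unclass(pdb$xyz)
    return(flex_trajectory(atoms, xyz))
  }
  lines <- readLines(path, warn = FALSE)
  frames <- list()
  names_seen <- NULL
  i <- 1
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1; next }
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat))
      stop_coldevb(sprintf("expected atom count at line %d", i),
                   "coldevb_format_error")
    block <- lines[(i + 2):(i + 1 + nat)]
    parts <- strsplit(trimws(block), "[[:space:]]+")
    nm <- vapply(parts, `[[`, character(1), 1)
    co <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (is.null(names_seen)) names_seen <- nm
    else if (length(nm) != length(names_seen))
      stop_coldevb(sprintf("inconsistent atom count in XYZ frame %d",
                           length(frames) + 1L), "coldevb_format_error")
    frames[[length(frames) + 1L]] <- .flatten(co)
    i <- i + 2 + nat
  }
  xyz <- do.call(rbind, frames)
  if (is.null(atoms)) {
    resno <- cumsum(names_seen == names_seen[1])
    atoms <- data.frame(elety = names_seen, resno = resno, resid = "ALA",
                        chain = "A", stringsAsFactors = FALSE)
  }
  flex_trajectory(atoms, xyz)
}

#' Write a trajectory to disk
#'
#' Multi-model PDB output uses MODEL/ENDMDL blocks with standard fixed-width
#' ATOM records (coordinates to 0.001 Angstrom); XYZ output writes one
#' standard frame block per trajectory frame.
#'
#' @param traj A [flex_trajectory()].
#' @param path Output path.
#' @param format `"pdb"` or `"xyz"`; guessed from the extension by default.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, format = c("auto", "pdb", "xyz")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.xyz$", path, ignore.case = TRUE)) "xyz" else "pdb"
  at <- traj$atoms
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "pdb") {
    for (f in seq_len(n_frames(traj))) {
      m <- .frame_mat(traj, f)
      writeLines(sprintf("MODEL     %4d", f), con)
      nm <- ifelse(nchar(at$elety) < 4, paste0(" ", at$elety), at$elety)
      writeLines(sprintf(
        "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
        seq_len(nrow(at)), nm, at$resid, at$chain, at$resno,
        m[, 1], m[, 2], m[, 3]), con)
      writeLines("ENDMDL", con)
    }
    writeLines("END", con)
  } else {
    for (f in seq_len(n_frames(traj))) {
      m <- .frame_mat(traj, f)
      writeLines(as.character(nrow(at)), con)
      writeLines(sprintf("frame %d", f), con)
      writeLines(sprintf("%-4s %12.6f %12.6f %12.6f",
                         at$elety, m[, 1], m[, 2], m[, 3]), con)
    }
  }
  invisible(path)
}

#' Read loop-region definitions
#'
#' Delimited text with columns `name`, `chain`, `first`, `last` (whitespace
#' or comma separated, `#` comments allowed).
#'
#' @param path File path.
#' @return Data frame of loop regions.
#' @export
read_regions <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "",
                           comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("name", "first", "last") %in% names(tab)))
    stop_coldevb("region file needs name, first, last columns",
                 "coldevb_format_error")
  if (any(tab$first > tab$last))
    stop_coldevb("region first residue exceeds last", "coldevb_format_error")
  tab
}

# ---------------------------------------------------------------------------
# Superposition and RMSF

#' Kabsch least-squares superposition
#'
#' Optimal proper rotation (determinant +1) and translation minimising the
#' RMSD of the masked atoms of `mobile` onto `reference`, via singular value
#' decomposition of the covariance matrix.
#'
#' @param mobile,reference Coordinate matrices (`n_atoms` x 3) or flat
#'   xyz vectors.
#' @param mask Logical or integer atom selection used for the fit (at least
#'   3 non-collinear atoms); all atoms are transformed.
#' @return List with `rotation` (3 x 3, applied as `x %*% rotation`),
#'   `translation`, post-fit `rmsd` over the masked atoms, and `coords`, the
#'   transformed mobile coordinates.
#' @export
kabsch_superpose <- function(mobile, reference, mask = NULL) {
  P <- if (is.null(dim(mobile))) matrix(mobile, ncol = 3, byrow = TRUE) else mobile
  Q <- if (is.null(dim(reference))) matrix(reference, ncol = 3, byrow = TRUE) else reference
  if (is.null(mask)) mask <- rep(TRUE, nrow(P))
  Pm <- P[mask, , drop = FALSE]; Qm <- Q[mask, , drop = FALSE]
  if (nrow(Pm) < 3 || nrow(Pm) != nrow(Qm))
    stop_coldevb("need at least 3 masked atoms in both structures",
                 "coldevb_degeneracy_error")
  cp <- colMeans(Pm); cq <- colMeans(Qm)
  Pc <- sweep(Pm, 2, cp); Qc <- sweep(Qm, 2, cq)
  sv <- svd(crossprod(Pc, Qc))
  scale <- sqrt(mean(rowSums(Pc^2)))
  if (sv$d[2] <= 1e-10 * max(sv$d[1], scale^2))
    stop_coldevb("masked atoms are collinear or degenerate",
                 "coldevb_degeneracy_error")
  d <- sign(det(sv$u %*% t(sv$v)))
  rot <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  trans <- cq - as.numeric(cp %*% rot)
  fitted <- sweep(P %*% rot, 2, trans, "+")
  rmsd <- sqrt(mean(rowSums((fitted[mask, , drop = FALSE] - Qm)^2)))
  list(rotation = rot, translation = trans, rmsd = rmsd, coords = fitted)
}

#' Iteratively superposed average structure
#'
#' Alternates between superposing every frame onto the current average (fit
#' on the masked atoms) and recomputing the coordinate mean, until the
#' average moves less than `tol` (RMSD over masked atoms) or `max_iter` is
#' reached. This mirrors the iterative-superposition ("iterpose") procedure
#' used for trajectory averaging.
#'
#' @param traj A [flex_trajectory()] with at least 2 frames.
#' @param mask Atom selection for the fit; defaults to backbone atoms.
#' @param tol Convergence tolerance, Angstrom.
#' @param max_iter Maximum iterations.
#' @return List with `xyz` (average coordinates, `n_atoms` x 3), `atoms`,
#'   `iterations`, `converged`, and `superposed` (the frames superposed onto
#'   the final average, as an xyz matrix).
#' @export
iterative_average <- function(traj, mask = NULL, tol = 1e-4, max_iter = 100) {
  if (n_frames(traj) < 2)
    stop_coldevb("need at least 2 frames", "coldevb_format_error")
  if (is.null(mask)) mask <- backbone_mask(traj$atoms)
  if (!any(mask)) stop_coldevb("mask selects no atoms", "coldevb_format_error")
  avg <- .frame_mat(traj, 1)
  nf <- n_frames(traj)
  converged <- FALSE
  iterations <- 0
  sup <- traj$xyz
  for (it in seq_len(max_iter)) {
    iterations <- it
    for (f in seq_len(nf)) {
      fit <- kabsch_superpose(.frame_mat(traj, f), avg, mask)
      sup[f, ] <- .flatten(fit$coords)
    }
    new_avg <- matrix(colMeans(sup), ncol = 3, byrow = TRUE)
    delta <- sqrt(mean(rowSums((new_avg[mask, , drop = FALSE] -
                                avg[mask, , drop = FALSE])^2)))
    avg <- new_avg
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("iterative average did not converge within max_iter; returning best average")
  list(xyz = avg, atoms = traj$atoms, iterations = iterations,
       converged = converged, superposed = sup)
}

#' Per-atom root-mean-square fluctuation
#'
#' Every frame is superposed onto the average structure (fit on the masked
#' atoms); RMSF of atom i is the root of the mean squared deviation of its
#' position from its mean position over the superposed frames.
#'
#' @param traj A [flex_trajectory()].
#' @param average Average structure from [iterative_average()]; computed if
#'   missing.
#' @param mask Fit mask; defaults to backbone atoms.
#' @param discard_fraction Fraction of initial frames discarded before
#'   analysis (the study protocol discards the first sixth: 2 ns
#'   equilibration of 12 ns).
#' @return Numeric vector of per-atom RMSF, Angstrom.
#' @export
rmsf <- function(traj, average = NULL, mask = NULL, discard_fraction = 0) {
  if (is.null(mask)) mask <- backbone_mask(traj$atoms)
  if (!any(mask)) stop_coldevb("mask selects no atoms", "coldevb_format_error")
  if (discard_fraction > 0) {
    drop <- floor(n_frames(traj) * discard_fraction)
    if (drop > 0)
      traj <- flex_trajectory(traj$atoms,
                              traj$xyz[-seq_len(drop), , drop = FALSE],
                              dt = traj$dt)
  }
  if (is.null(average)) average <- iterative_average(traj, mask = mask)
  nf <- n_frames(traj)
  na <- nrow(traj$atoms)
  sup <- matrix(0, nf, 3 * na)
  for (f in seq_len(nf)) {
    fit <- kabsch_superpose(.frame_mat(traj, f), average$xyz, mask)
    sup[f, ] <- .flatten(fit$coords)
  }
  mean_pos <- colMeans(sup)
  dev2 <- sweep(sup, 2, mean_pos)^2
  per_coord <- colMeans(dev2)
  sqrt(per_coord[seq(1, 3 * na, 3)] + per_coord[seq(2, 3 * na, 3)] +
         per_coord[seq(3, 3 * na, 3)])
}

#' Per-loop RMSF report relative to a reference variant
#'
#' For each variant and loop region, averages backbone-atom RMSF over the
#' region's residues (replicate trajectories are averaged at the RMSF level
#' first) and reports the percent change relative to the reference variant:
#' `100 * (variant - reference) / reference`.
#'
#' @param rmsf_by_variant Named list; each element a per-atom RMSF vector or
#'   a list of replicate RMSF vectors.
#' @param atoms Shared atom table.
#' @param regions Data frame with `name`, `first`, `last` (and optionally
#'   `chain`).
#' @param reference Name of the reference variant.
#' @return A `flexibility_report`: data frame with per-variant, per-region
#'   mean RMSF, replicate spread and percent change, plus attribute
#'   `aggregate` (mean percent change across regions per variant).
#' @export
loop_report <- function(rmsf_by_variant, atoms, regions, reference) {
  if (!reference %in% names(rmsf_by_variant))
    stop_coldevb("reference variant missing from input", "coldevb_config_error")
  if (any(regions$first > max(atoms$resno)) || any(regions$last < min(atoms$resno)))
    stop_coldevb("region outside residue range", "coldevb_config_error")
  bb <- backbone_mask(atoms)
  region_mean <- function(r, region) {
    sel <- bb & atoms$resno >= region$first & atoms$resno <= region$last
    if (!is.null(region$chain) && "chain" %in% names(atoms))
      sel <- sel & atoms$chain == region$chain
    if (!any(sel))
      stop_coldevb(sprintf("region %s selects no atoms", region$name),
                   "coldevb_config_error")
    mean(r[sel])
  }
  rows <- list()
  for (v in names(rmsf_by_variant)) {
    reps <- rmsf_by_variant[[v]]
    if (!is.list(reps)) reps <- list(reps)
    for (j in seq_len(nrow(regions))) {
      region <- regions[j, ]
      vals <- vapply(reps, region_mean, numeric(1), region = region)
      rows[[length(rows) + 1L]] <- data.frame(
        variant = v, region = region$name,
        rmsf = mean(vals),
        rmsf_sd = if (length(vals) > 1) sd(vals) else NA_real_,
        n_replicates = length(vals))
    }
  }
  out <- do.call(rbind, rows)
  ref <- out[out$variant == reference, c("region", "rmsf")]
  names(ref)[2] <- ".ref"
  out <- merge(out, ref, by = "region", sort = FALSE)
  out$percent_change <- 100 * (out$rmsf - out$.ref) / out$.ref
  out$.ref <- NULL
  out <- out[order(match(out$variant, names(rmsf_by_variant)),
                   match(out$region, regions$name)), ]
  rownames(out) <- NULL
  agg <- aggregate(percent_change ~ variant, data = out, FUN = mean)
  attr(out, "aggregate") <- agg
  class(out) <- c("flexibility_report", "data.frame")
  out
}
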