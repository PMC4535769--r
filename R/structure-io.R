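#' @keywords internal
"_PACKAGE"

# ---- internal helpers -------------------------------------------------------

# Accept a file path or a character vector of lines.
.as_lines <- function(input) {
  if (length(input) == 1L && !grepl("\n", input, fixed = TRUE) &&
      file.exists(input)) {
    return(readLines(input, warn = FALSE))
  }
  if (length(input) == 1L) return(strsplit(input, "\n", fixed = TRUE)[[1L]])
  as.character(input)
}

.header_comment <- function(what, params = list()) {
  ps <- if (length(params)) {
    paste(names(params), vapply(params, function(p) paste(format(p), collapse = ","),
                                character(1)), sep = "=", collapse = " ")
  } else ""
  sprintf("# groovedyn %s | %s | %s",
          as.character(utils::packageVersion("groovedyn")), what, ps)
}

# Run code under a temporary RNG state so generators are pure functions of
# their seed and never disturb the caller's stream.
.with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("a single finite numeric `seed` is mandatory", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# ---- StructureModel ---------------------------------------------------------

#' Construct a groove structure model
#'
#' A `groove_structure` holds an ordered atom table (PDB-style 1-based residue
#' numbering) plus an `n x 3` coordinate matrix in Angstrom. Atom order is
#' stable and defines the column order of every trajectory frame that
#' references the structure.
#'
#' @param atom data frame with columns `eleno` (atom serial), `elety` (atom
#'   name, e.g. `"CA"`), `resid` (residue name), `chain`, `resno` (1-based
#'   residue number), `x`, `y`, `z`, and optionally `b` (per-atom scalar slot,
#'   used for B-factor export).
#' @return object of class `groove_structure` with elements `atom` (the table)
#'   and `xyz` (numeric `n x 3` matrix).
#' @export
groove_structure <- function(atom) {
  need <- c("eleno", "elety", "resid", "chain", "resno", "x", "y", "z")
  miss <- setdiff(need, names(atom))
  if (length(miss)) stop("atom table lacks columns: ", paste(miss, collapse = ", "))
  if (nrow(atom) == 0L) stop("empty structure: no atoms")
  if (any(atom$resno < 1L)) stop("residue numbers must be strictly positive")
  xyz <- as.matrix(atom[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("non-finite atom coordinates")
  if (is.null(atom$b)) atom$b <- 0
  structure(list(atom = atom, xyz = unname(xyz)), class = "groove_structure")
}

#' @export
print.groove_structure <- function(x, ...) {
  cat(sprintf("groove_structure: %d atoms, residues %d-%d, chains %s\n",
              nrow(x$atom), min(x$atom$resno), max(x$atom$resno),
              paste(unique(x$atom$chain), collapse = ",")))
  invisible(x)
}

#' Read a structure from PDB text
#'
#' Parses fixed-column `ATOM`/`HETATM` records. Residue numbers are taken
#' verbatim (1-based PDB convention); atoms are kept in file order; chains
#' with duplicated residue numbers are retained and distinguished by
#' `chain`.
#'
#' @param input path to a PDB file, a single string of PDB text, or a
#'   character vector of lines.
#' @return a [groove_structure()].
#' @export
read_structure <- function(input) {
  lines <- .as_lines(input)
  rec <- substr(lines, 1L, 6L)
  keep <- which(rec %in% c("ATOM  ", "HETATM") |
                  trimws(rec) %in% c("ATOM", "HETATM"))
  if (!length(keep)) stop("empty input: no ATOM/HETATM records found")
  parse_num <- function(s, ln, what) {
    v <- suppressWarnings(as.numeric(s))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop(sprintf("malformed %s field at line %d: '%s'",
                   what, ln[bad[1L]], s[bad[1L]]))
    v
  }
  ll <- lines[keep]
  short <- which(nchar(ll) < 54L)
  if (length(short))
    stop(sprintf("malformed ATOM record at line %d: fewer than 54 columns",
                 keep[short[1L]]))
  atom <- data.frame(
    eleno = parse_num(substr(ll, 7L, 11L), keep, "atom serial"),
    elety = trimws(substr(ll, 13L, 16L)),
    resid = trimws(substr(ll, 18L, 20L)),
    chain = trimws(substr(ll, 22L, 22L)),
    resno = as.integer(parse_num(substr(ll, 23L, 26L), keep, "residue number")),
    x = parse_num(substr(ll, 31L, 38L), keep, "x coordinate"),
    y = parse_num(substr(ll, 39L, 46L), keep, "y coordinate"),
    z = parse_num(substr(ll, 47L, 54L), keep, "z coordinate"),
    b = {
      bs <- trimws(substr(ll, 61L, 66L))
      bv <- suppressWarnings(as.numeric(bs))
      ifelse(is.finite(bv), bv, 0)
    },
    stringsAsFactors = FALSE
  )
  groove_structure(atom)
}

.fmt_pdb_line <- function(eleno, elety, resid, chain, resno, x, y, z, b) {
  name <- if (nchar(elety) < 4L) sprintf(" %-3s", elety) else substr(elety, 1L, 4L)
  sprintf("ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
          as.integer(eleno) %% 100000L, name, substr(resid, 1L, 3L),
          substr(chain, 1L, 1L), as.integer(resno), x, y, z, 1.00, b)
}

#' Write a structure as PDB text
#'
#' @param structure a [groove_structure()].
#' @param file optional path; if `NULL` the text is returned invisibly only.
#' @param xyz optional replacement coordinate matrix (e.g. one trajectory
#'   frame) with the structure's atom order.
#' @return character vector of PDB lines, invisibly.
#' @export
write_structure <- function(structure, file = NULL, xyz = NULL) {
  stopifnot(inherits(structure, "groove_structure"))
  a <- structure$atom
  if (is.null(xyz)) xyz <- structure$xyz
  lines <- vapply(seq_len(nrow(a)), function(i)
    .fmt_pdb_line(a$eleno[i], a$elety[i], a$resid[i], a$chain[i], a$resno[i],
                  xyz[i, 1L], xyz[i, 2L], xyz[i, 3L], a$b[i]), character(1))
  lines <- c(lines, "END")
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}

#' Write a structure with per-residue values in the B-factor column
#'
#' Export mechanism for per-residue heat maps (e.g. RMSF colored onto the
#' groove): every atom's B-factor column carries its residue's value,
#' formatted `%6.2f`.
#'
#' @param structure a [groove_structure()].
#' @param values named numeric vector mapping residue number to value. Atoms
#'   whose residue is missing from the map get `0.00` with a warning; values
#'   above `999.99` are clamped with a warning.
#' @param file optional output path.
#' @return PDB lines, invisibly.
#' @export
write_bfactor_structure <- function(structure, values, file = NULL) {
  stopifnot(inherits(structure, "groove_structure"))
  if (is.null(names(values))) stop("`values` must be named by residue number")
  v <- as.numeric(values)
  if (!all(is.finite(v))) stop("non-finite per-residue values")
  names(v) <- names(values)
  resno <- structure$atom$resno
  b <- v[as.character(resno)]
  if (anyNA(b)) {
    warning(sprintf("%d residues missing from value map; B-factor set to 0.00",
                    length(unique(resno[is.na(b)]))))
    b[is.na(b)] <- 0
  }
  if (any(b > 999.99)) {
    warning("values > 999.99 clamped to 999.99 for the B-factor column")
    b[b > 999.99] <- 999.99
  }
  s2 <- structure
  s2$atom$b <- unname(b)
  write_structure(s2, file = file)
}

# ---- AtomSelection ----------------------------------------------------------

#' Select atoms from a structure
#'
#' Returns a deterministic, ordered index vector (structure atom order).
#' Missing atoms inside an explicit residue request are an error: ensemble
#' statistics require fixed atom sets.
#'
#' @param structure a [groove_structure()].
#' @param elety atom-name filter (e.g. `"CA"`), or `NULL` for all names.
#' @param resno residue-number filter (inclusive), or `NULL`.
#' @param chain chain filter, or `NULL`.
#' @param require_complete if `TRUE` (default) error when a requested residue
#'   has no matching atom.
#' @return integer vector of atom indices.
#' @export
select_atoms <- function(structure, elety = NULL, resno = NULL, chain = NULL,
                         require_complete = TRUE) {
  stopifnot(inherits(structure, "groove_structure"))
  a <- structure$atom
  keep <- rep(TRUE, nrow(a))
  if (!is.null(elety)) keep <- keep & a$elety %in% elety
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  if (!is.null(resno)) {
    keep <- keep & a$resno %in% resno
    if (require_complete) {
      present <- unique(a$resno[keep])
      missing <- setdiff(intersect(resno, unique(a$resno)), present)
      wanted <- setdiff(resno, unique(a$resno))
      # residues absent from the structure entirely are also an error when an
      # explicit range was requested
      if (length(wanted) || length(missing))
        stop("selection incomplete: residues ",
             paste(sort(c(wanted, missing)), collapse = ","),
             " have no matching atom")
    }
  }
  which(keep)
}

#' Canonical binding-groove selection
#'
#' C-alpha atoms of residues 1-180, the alpha1/alpha2 superdomain that forms
#' the peptide-binding groove and is the analysis scope for all ensemble
#' statistics.
#'
#' @param structure a [groove_structure()].
#' @param resno residue range, default `1:180`.
#' @return integer atom indices.
#' @export
groove_selection <- function(structure, resno = 1:180) {
  have <- intersect(resno, unique(structure$atom$resno))
  if (!length(have)) stop("no groove residues present in structure")
  select_atoms(structure, elety = "CA", resno = have)
}

#' Groove region definitions
#'
#' The groove is split into three regions of opposing helix segments:
#' Region I (A-pocket end, residues 50-59 vs 165-176), Region II (center,
#' 60-72 vs 152-164) and Region III (F-pocket end, 73-84 vs 139-150). Ranges
#' are inclusive, 1-based PDB numbering.
#'
#' @param name `"I"`, `"II"` or `"III"`.
#' @param helix_a,helix_b optional custom residue ranges (must be disjoint).
#' @return list with `name`, `helix_a`, `helix_b`.
#' @export
region_definition <- function(name = c("I", "II", "III"),
                              helix_a = NULL, helix_b = NULL) {
  name <- match.arg(name)
  defaults <- list(I = list(a = 50:59, b = 165:176),
                   II = list(a = 60:72, b = 152:164),
                   III = list(a = 73:84, b = 139:150))
  if (is.null(helix_a)) helix_a <- defaults[[name]]$a
  if (is.null(helix_b)) helix_b <- defaults[[name]]$b
  if (length(intersect(helix_a, helix_b)))
    stop("region helix segments must be disjoint")
  structure(list(name = name, helix_a = helix_a, helix_b = helix_b),
            class = "region_definition")
}

# ---- TrajectoryEnsemble -----------------------------------------------------

#' Construct a trajectory ensemble
#'
#' @param coords list of `n_atoms x 3` matrices (Angstrom) or a 3-D array
#'   `n_atoms x 3 x n_frames`, in the atom order of `reference`.
#' @param times frame times in ns, strictly increasing, non-negative.
#' @param reference the [groove_structure()] whose atom order frames follow.
#' @return object of class `groove_trajectory` with `coords` (3-D array),
#'   `times`, `reference`.
#' @export
groove_trajectory <- function(coords, times, reference) {
  stopifnot(inherits(reference, "groove_structure"))
  n_atoms <- nrow(reference$xyz)
  if (is.list(coords)) {
    bad <- which(vapply(coords, nrow, 1L) != n_atoms)
    if (length(bad))
      stop(sprintf("structural mismatch at frame %d: %d atoms, reference has %d",
                   bad[1L], nrow(coords[[bad[1L]]]), n_atoms))
    coords <- array(unlist(coords), dim = c(n_atoms, 3L, length(coords)))
  }
  if (length(dim(coords)) != 3L || dim(coords)[1L] != n_atoms ||
      dim(coords)[2L] != 3L)
    stop("coords must be n_atoms x 3 x n_frames with n_atoms matching reference")
  n_frames <- dim(coords)[3L]
  times <- as.numeric(times)
  if (length(times) != n_frames) stop("length(times) must equal frame count")
  if (any(times < 0) || any(diff(times) <= 0))
    stop("frame times must be non-negative and strictly increasing")
  structure(list(coords = coords, times = times, reference = reference),
            class = "groove_trajectory")
}

#' @export
print.groove_trajectory <- function(x, ...) {
  cat(sprintf("groove_trajectory: %d frames x %d atoms, t = %g..%g ns\n",
              dim(x$coords)[3L], dim(x$coords)[1L],
              x$times[1L], x$times[length(x$times)]))
  invisible(x)
}

n_frames <- function(traj) dim(traj$coords)[3L]
frame_xyz <- function(traj, i) traj$coords[, , i, drop = TRUE]

#' Read a trajectory from multi-model PDB text or a frame table
#'
#' Two plain-text dialects are supported: (i) multi-model PDB (frames as
#' `MODEL`/`ENDMDL` blocks; frame times are the MODEL indices, in ns), and
#' (ii) a delimited frame table with header columns
#' `frame, time_ns, atom_index, x, y, z`.
#'
#' @param input path or text (see [read_structure()] for the convention).
#' @param reference [groove_structure()] defining atom count and order.
#' @param dialect `"auto"` (default), `"pdb"` or `"table"`.
#' @param reorder_by_serial for the PDB dialect: if `TRUE`, atom lines inside a
#'   model are reordered by atom serial before use; if `FALSE` (default) a
#'   serial order differing from the reference is an error.
#' @return a [groove_trajectory()].
#' @export
read_trajectory <- function(input, reference,
                            dialect = c("auto", "pdb", "table"),
                            reorder_by_serial = FALSE) {
  stopifnot(inherits(reference, "groove_structure"))
  lines <- .as_lines(input)
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    body <- lines[!startsWith(lines, "#")]
    dialect <- if (any(grepl("^(MODEL|ATOM  |HETATM)", body))) "pdb" else "table"
  }
  n_atoms <- nrow(reference$xyz)
  if (dialect == "pdb") {
    model_starts <- which(startsWith(lines, "MODEL"))
    if (!length(model_starts)) model_starts <- 1L
    model_ends <- c(model_starts[-1L] - 1L, length(lines))
    frames <- vector("list", length(model_starts))
    for (m in seq_along(model_starts)) {
      block <- lines[model_starts[m]:model_ends[m]]
      is_atom <- startsWith(block, "ATOM") | startsWith(block, "HETATM")
      if (!any(is_atom)) stop(sprintf("frame %d contains no atoms", m))
      s <- read_structure(block[is_atom])
      if (nrow(s$xyz) != n_atoms)
        stop(sprintf("structural mismatch at frame %d: %d atoms, expected %d",
                     m, nrow(s$xyz), n_atoms))
      ord <- order(s$atom$eleno)
      if (!identical(ord, seq_len(n_atoms))) {
        if (reorder_by_serial) s$xyz <- s$xyz[ord, , drop = FALSE]
        else stop(sprintf("atom order differs from reference in frame %d (set reorder_by_serial = TRUE to sort by serial)", m))
      }
      frames[[m]] <- s$xyz
    }
    groove_trajectory(frames, times = seq_along(frames), reference = reference)
  } else {
    body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
    tab <- utils::read.table(text = body, header = TRUE, sep = "\t")
    need <- c("frame", "time_ns", "atom_index", "x", "y", "z")
    if (!all(need %in% names(tab)))
      stop("frame table must have columns: ", paste(need, collapse = ", "))
    fr_ids <- unique(tab$frame)
    frames <- vector("list", length(fr_ids))
    times <- numeric(length(fr_ids))
    for (i in seq_along(fr_ids)) {
      sub <- tab[tab$frame == fr_ids[i], ]
      if (nrow(sub) != n_atoms)
        stop(sprintf("structural mismatch at frame %s: %d atoms, expected %d",
                     fr_ids[i], nrow(sub), n_atoms))
      sub <- sub[order(sub$atom_index), ]
      frames[[i]] <- as.matrix(sub[, c("x", "y", "z")])
      times[i] <- sub$time_ns[1L]
    }
    groove_trajectory(frames, times = times, reference = reference)
  }
}

#' Write a trajectory as a delimited frame table
#'
#' @param traj a [groove_trajectory()].
#' @param file optional output path.
#' @return the lines, invisibly.
#' @export
write_trajectory_table <- function(traj, file = NULL) {
  stopifnot(inherits(traj, "groove_trajectory"))
  nf <- n_frames(traj); na <- dim(traj$coords)[1L]
  rows <- lapply(seq_len(nf), function(i) {
    xyz <- frame_xyz(traj, i)
    data.frame(frame = i, time_ns = traj$times[i], atom_index = seq_len(na),
               x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L])
  })
  tab <- do.call(rbind, rows)
  hdr <- .header_comment("trajectory frame table",
                         list(n_frames = nf, n_atoms = na))
  lines <- c(hdr, paste(names(tab), collapse = "\t"),
             do.call(paste, c(unname(as.list(tab)), sep = "\t")))
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}
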