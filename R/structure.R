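#' Atomic structure container
#'
#' A light flat table of atoms: one row per atom with element, atom name,
#' residue name/number, chain, coordinates (Angstrom), occupancy, altloc
#' and B factor.
#'
#' @param atoms Data frame with columns `element`, `atom_name`,
#'   `residue_name`, `residue_number`, `chain_id`, `x`, `y`, `z`,
#'   `occupancy`, `altloc`, `b_factor`.
#' @return An object of class `structure_model` (a classed data frame).
#' @export
structure_model <- function(atoms) {
  need <- c("element", "atom_name", "residue_name", "residue_number",
            "chain_id", "x", "y", "z", "occupancy", "altloc", "b_factor")
  stopifnot(is.data.frame(atoms), all(need %in% names(atoms)))
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("coordinates must be finite")
  if (length(unique(atoms$chain_id)) < 1) stop("need at least one chain")
  structure(atoms[need], class = c("structure_model", "data.frame"))
}

# Coordinates of a structure (or of a plain data frame of atoms) as n x 3.
coords <- function(s) as.matrix(s[, c("x", "y", "z")])

# Infer element symbols from PDB atom names where the element column is
# blank ("CA" -> C for protein atoms; two-letter elements only when the
# name starts with a known symbol like FE, ZN, MG, NA, CL).
infer_element <- function(atom_name) {
  two <- c("FE", "ZN", "MG", "MN", "NA", "CL", "BR", "CA")
  nm <- toupper(trimws(atom_name))
  vapply(nm, function(x) {
    first <- substr(gsub("[^A-Z]", "", x), 1, 1)
    if (first == "") "C" else first
  }, character(1), USE.NAMES = FALSE)
}

#' Read a structure from PDB or mmCIF
#'
#' Parsing is delegated to bio3d; the atom table is converted to a
#' [structure_model()]. Alternate locations are resolved by keeping, per
#' (chain, residue, atom name), the highest-occupancy record, ties broken
#' in favour of altloc "A".
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"pdb"` or `"mmcif"`.
#' @param resolve_altloc Apply the altloc policy (default `TRUE`).
#' @return A [structure_model()].
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           resolve_altloc = TRUE) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "mmcif"
              else "pdb"
  }
  # rm.alt = FALSE: keep all alternate-location records so the occupancy
  # policy below (not the reader's default keep-"A" rule) decides.
  pdb <- if (format == "mmcif") bio3d::read.cif(path, rm.alt = FALSE,
                                                verbose = FALSE)
         else bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
  a <- pdb$atom
  elem <- if ("elesy" %in% names(a)) trimws(a$elesy) else ""
  blank <- is.na(elem) | elem == ""
  elem[blank] <- infer_element(a$elety[blank])
  if (any(blank))
    warning(sum(blank), " atoms had no element record; inferred from names")
  atoms <- data.frame(
    element = toupper(elem),
    atom_name = trimws(a$elety),
    residue_name = trimws(a$resid),
    residue_number = a$resno,
    chain_id = ifelse(is.na(a$chain) | a$chain == "", "A", a$chain),
    x = a$x, y = a$y, z = a$z,
    occupancy = ifelse(is.na(a$o), 1, a$o),
    altloc = ifelse(is.na(a$alt) | a$alt == "", "", trimws(a$alt)),
    b_factor = ifelse(is.na(a$b), 0, a$b))
  if (resolve_altloc) atoms <- resolve_altlocs(atoms)
  structure_model(atoms)
}

# Altloc policy: highest occupancy, then altloc "A" (or first).
resolve_altlocs <- function(atoms) {
  key <- paste(atoms$chain_id, atoms$residue_number, atoms$residue_name,
               atoms$atom_name, sep = "|")
  keep <- unlist(lapply(split(seq_len(nrow(atoms)), key), function(idx) {
    if (length(idx) == 1) return(idx)
    sub <- atoms[idx, ]
    best <- idx[sub$occupancy == max(sub$occupancy)]
    if (length(best) > 1) {
      a <- best[atoms$altloc[best] %in% c("", "A")]
      if (length(a) > 0) best <- a
    }
    best[1]
  }), use.names = FALSE)
  out <- atoms[sort(keep), ]
  rownames(out) <- NULL
  out
}

#' Write a structure as a PDB file
#'
#' Standard PDB ATOM/HETATM records (waters as resname HOH become HETATM),
#' no CRYST1 record; writing goes through bio3d.
#'
#' @param s A [structure_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path) {
  stopifnot(inherits(s, "structure_model"))
  het <- s$residue_name %in% c("HOH", "WAT")
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(coords(s))),
                   type = ifelse(het, "HETATM", "ATOM"),
                   resno = s$residue_number,
                   resid = s$residue_name,
                   eleno = seq_len(nrow(s)),
                   elety = s$atom_name,
                   chain = s$chain_id,
                   o = s$occupancy, b = s$b_factor,
                   elesy = s$element)
  invisible(path)
}

#' Select atoms with a simple attribute query
#'
#' Conjunctive filter over chain, residue name, residue number, atom name
#' and element; `NULL` means "any". `heavy_only` drops hydrogens.
#'
#' @param s A [structure_model()].
#' @param chain,resname,resno,name,element Optional filter values
#'   (vectors allowed).
#' @param heavy_only Drop hydrogen atoms (default `FALSE`).
#' @return The matching subset as a [structure_model()] (possibly empty).
#' @export
atom_select <- function(s, chain = NULL, resname = NULL, resno = NULL,
                        name = NULL, element = NULL, heavy_only = FALSE) {
  stopifnot(inherits(s, "structure_model"))
  keep <- rep(TRUE, nrow(s))
  if (!is.null(chain))   keep <- keep & s$chain_id %in% chain
  if (!is.null(resname)) keep <- keep & s$residue_name %in% resname
  if (!is.null(resno))   keep <- keep & s$residue_number %in% resno
  if (!is.null(name))    keep <- keep & s$atom_name %in% name
  if (!is.null(element)) keep <- keep & s$element %in% element
  if (heavy_only)        keep <- keep & s$element != "H"
  out <- s[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("structure_model", "data.frame"))
}

#' Generate an ideal C5-symmetric pentamer structure
#'
#' Five identical helical pseudo-chains related by exact 72-degree
#' rotations about the z axis, plus five water oxygens on a regular
#' pentagon in the z = 0 plane — a synthetic stand-in emulating the
#' pentameric assembly and axial water pentagon of the crystal structure.
#' With `jitter_sd > 0` each chain's atoms receive independent Gaussian
#' displacements, emulating the small coordinate heterogeneity between
#' crystallographic protomers (the C5 symmetry is then only approximate).
#'
#' @param helix_ring_radius Distance of each chain's helical axis from the
#'   pore axis (Angstrom, > 0).
#' @param pentagon_radius Circumradius of the water pentagon (Angstrom,
#'   > 0); adjacent O-O distance is `2 * r * sin(36 deg)`.
#' @param atoms_per_chain Number of backbone atoms per chain (N, CA, C, O
#'   repeating; default 200, i.e. 50 residues).
#' @param jitter_sd Per-coordinate Gaussian jitter (Angstrom, default 0 =
#'   exact symmetry).
#' @param seed RNG seed for the jitter.
#' @return A [structure_model()] with chains A-E and waters (chain W,
#'   resname HOH).
#' @export
gen_ideal_pentamer <- function(helix_ring_radius = 15, pentagon_radius = 2.212,
                               atoms_per_chain = 200, jitter_sd = 0,
                               seed = NULL) {
  if (helix_ring_radius <= 0 || pentagon_radius <= 0)
    stop("radii must be positive")
  n_res <- ceiling(atoms_per_chain / 4)
  # idealized alpha helix: 1.5 A rise and 100 deg turn per residue,
  # backbone at radius 2.3 A around the (vertical) helical axis
  res <- seq_len(n_res)
  phi <- (res - 1) * 100 * pi / 180
  zc <- (res - 1) * 1.5 - (n_res - 1) * 0.75   # centered on z = 0
  offsets <- list(N  = c(0.00,  0.00, -0.60),
                  CA = c(0.00,  0.00,  0.00),
                  C  = c(0.45,  0.45,  0.70),
                  O  = c(1.20,  0.80,  0.90))
  rows <- list()
  for (r in res) {
    cx <- helix_ring_radius + 2.3 * cos(phi[r])
    cy <- 2.3 * sin(phi[r])
    for (an in names(offsets)) {
      o <- offsets[[an]]
      rows[[length(rows) + 1]] <- data.frame(
        element = substr(an, 1, 1), atom_name = an, residue_name = "ALA",
        residue_number = r, chain_id = "A",
        x = cx + o[1], y = cy + o[2], z = zc[r] + o[3],
        occupancy = 1, altloc = "", b_factor = 0)
    }
  }
  chainA <- do.call(rbind, rows)[seq_len(atoms_per_chain), ]
  rot_z <- function(deg) {
    th <- deg * pi / 180
    matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  }
  chains <- lapply(0:4, function(k) {
    ch <- chainA
    xyz <- as.matrix(ch[, c("x", "y", "z")]) %*% t(rot_z(72 * k))
    ch$x <- xyz[, 1]; ch$y <- xyz[, 2]; ch$z <- xyz[, 3]
    ch$chain_id <- LETTERS[k + 1]
    ch
  })
  ang <- 90 + 72 * (0:4)
  waters <- data.frame(
    element = "O", atom_name = "O", residue_name = "HOH",
    residue_number = seq_len(5), chain_id = "W",
    x = pentagon_radius * cos(ang * pi / 180),
    y = pentagon_radius * sin(ang * pi / 180),
    z = 0, occupancy = 1, altloc = "", b_factor = 0)
  atoms <- rbind(do.call(rbind, chains), waters)
  rownames(atoms) <- NULL
  if (jitter_sd > 0) {
    prot <- atoms$chain_id != "W"
    atoms[prot, c("x", "y", "z")] <- atoms[prot, c("x", "y", "z")] +
      with_seed(seed, matrix(rnorm(3 * sum(prot), sd = jitter_sd),
                             ncol = 3))
  }
  structure_model(atoms)
}
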