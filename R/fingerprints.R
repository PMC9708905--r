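#' Enumerate canonical linear fragments (paths) of a molecule
#'
#' All simple paths of 1 to `max_atoms` atoms. Each path is encoded as a
#' text string of atom symbols (lowercase for aromatic atoms, charge
#' suffixed) joined by bond-order symbols `-`, `=`, `#`, `:`; the
#' lexicographically smaller of the two reading directions is kept, so the
#' encoding is independent of atom numbering.
#'
#' @param mol A `mol_graph` from [parse_smiles()].
#' @param max_atoms Maximum path length in atoms (default 7).
#' @return Character vector (multiset) of canonical path strings.
#' @examples
#' sort(unique(enumerate_paths(parse_smiles("CCC"))))  # C, C-C, C-C-C
#' @export
enumerate_paths <- function(mol, max_atoms = 7) {
  stopifnot(inherits(mol, "mol_graph"), max_atoms >= 1)
  cpp_enumerate_paths(nrow(mol$atoms), atom_symbols(mol),
                      as.integer(mol$bonds$i), as.integer(mol$bonds$j),
                      mol$bonds$order, as.integer(max_atoms))
}

#' Enumerate canonical circular fragments (spheres) of a molecule
#'
#' For every atom and every radius 1..`max_layers`, the neighborhood
#' subgraph induced by all atoms within that many bonds is serialized into a
#' canonical string (iterative neighborhood-refinement canonical ordering
#' with individualization; aromaticity and charge are encoded, stereo is
#' not; the central atom is marked). Neighborhoods that stop growing yield
#' identical strings at larger radii.
#'
#' @param mol A `mol_graph`.
#' @param max_layers Maximum radius in bonds (default 5).
#' @return Character vector (multiset) of canonical sphere strings.
#' @export
enumerate_spheres <- function(mol, max_layers = 5) {
  stopifnot(inherits(mol, "mol_graph"), max_layers >= 1)
  cpp_enumerate_spheres(nrow(mol$atoms), atom_symbols(mol),
                        as.integer(mol$bonds$i), as.integer(mol$bonds$j),
                        mol$bonds$order, as.integer(max_layers))
}

new_fingerprint <- function(bits, descriptor, nbits) {
  structure(list(bits = bits, descriptor = descriptor, nbits = nbits),
            class = "chem_fp")
}

#' @export
print.chem_fp <- function(x, ...) {
  cat("chem_fp:", x$descriptor, "-", sum(x$bits), "of", x$nbits, "bits set\n")
  invisible(x)
}

hash_to_bits <- function(strings, nbits) {
  bits <- rep(FALSE, nbits)
  if (length(strings)) bits[cpp_hash_bits(unique(strings), nbits) + 1L] <- TRUE
  bits
}

#' Hashed linear-path binary fingerprint (PathFp)
#'
#' Every canonical path string (see [enumerate_paths()]) is hashed with
#' FNV-1a (64-bit) and the hash modulo the fingerprint length sets the
#' corresponding bit. Deterministic and platform-independent.
#'
#' @param mol A `mol_graph`.
#' @param nbits Fingerprint length (default 512).
#' @param max_atoms Maximum path length in atoms (default 7).
#' @return A `chem_fp` with descriptor `"PathFp"`.
#' @export
path_fingerprint <- function(mol, nbits = 512, max_atoms = 7) {
  new_fingerprint(hash_to_bits(enumerate_paths(mol, max_atoms), nbits),
                  "PathFp", nbits)
}

#' Hashed circular-sphere binary fingerprint (SphereFp)
#'
#' As [path_fingerprint()], over the canonical sphere strings of
#' [enumerate_spheres()].
#'
#' @param mol A `mol_graph`.
#' @param nbits Fingerprint length (default 512).
#' @param max_layers Maximum neighborhood radius (default 5).
#' @return A `chem_fp` with descriptor `"SphereFp"`.
#' @export
sphere_fingerprint <- function(mol, nbits = 512, max_layers = 5) {
  new_fingerprint(hash_to_bits(enumerate_spheres(mol, max_layers), nbits),
                  "SphereFp", nbits)
}

#' Dictionary-fragment binary fingerprint (FragFP)
#'
#' Bit i is set iff dictionary fragment i occurs among the molecule's
#' canonical path or sphere strings. The shipped default dictionary (about a
#' hundred common organic fragments, see [default_fragment_dictionary()])
#' replaces the proprietary 512-fragment dictionary of the original
#' descriptor; bit-compatibility with that software is a non-goal.
#'
#' @param mol A `mol_graph`.
#' @param dictionary Character vector of at most 512 canonical fragment
#'   strings (path and/or sphere notation).
#' @param nbits Fingerprint length (default 512; must be >= dictionary size).
#' @return A `chem_fp` with descriptor `"FragFP"`; bit positions beyond the
#'   dictionary stay 0.
#' @export
frag_fingerprint <- function(mol, dictionary = default_fragment_dictionary(),
                             nbits = 512) {
  if (length(dictionary) > nbits)
    stop("dictionary larger than fingerprint (", length(dictionary), " > ",
         nbits, ")")
  frags <- unique(c(enumerate_paths(mol), enumerate_spheres(mol)))
  bits <- rep(FALSE, nbits)
  bits[seq_along(dictionary)] <- dictionary %in% frags
  new_fingerprint(bits, "FragFP", nbits)
}

#' Default open fragment dictionary for FragFP
#'
#' Built deterministically at call time from the canonical path strings of a
#' fixed panel of prototype molecules (alkanes, alcohols, amines, acids,
#' aromatics, N/O/S heterocycles), truncated to short fragments. No data
#' files are shipped; the dictionary is reproducible from code.
#'
#' @param max_atoms Longest path, in atoms, admitted to the dictionary
#'   (default 4).
#' @return Sorted character vector of canonical fragment strings.
#' @export
default_fragment_dictionary <- function(max_atoms = 4) {
  prototypes <- c(
    "CCCCCC", "CC(C)C", "CCO", "CC=O", "CC(=O)O", "CC(=O)N", "CCN", "CC#N",
    "CCS", "CS(=O)C", "CCCl", "CCBr", "CCF", "CC=C", "CC#C", "COC",
    "c1ccccc1", "c1ccncc1", "c1ccc(O)cc1", "c1ccc(N)cc1", "c1ccc(C)cc1",
    "c1cc[nH]c1", "c1ccoc1", "c1ccsc1", "C1CCNCC1", "C1CCOC1", "C1CCCCC1",
    "[O-]C=O", "[NH3+]C"
  )
  frags <- unlist(lapply(prototypes, function(s)
    enumerate_paths(parse_smiles(s), max_atoms = max_atoms)))
  sort(unique(frags))
}

#' Tanimoto similarity and distance between two fingerprints
#'
#' `|a AND b| / |a OR b|`; two all-zero fingerprints are defined maximally
#' similar (similarity 1). Fingerprints must share descriptor and length.
#'
#' @param fp_a,fp_b `chem_fp` objects.
#' @return Similarity in `[0, 1]`.
#' @export
tanimoto <- function(fp_a, fp_b) {
  stopifnot(inherits(fp_a, "chem_fp"), inherits(fp_b, "chem_fp"))
  if (fp_a$descriptor != fp_b$descriptor)
    stop("descriptor mismatch: ", fp_a$descriptor, " vs ", fp_b$descriptor)
  if (fp_a$nbits != fp_b$nbits) stop("fingerprint length mismatch")
  u <- sum(fp_a$bits | fp_b$bits)
  if (u == 0) return(1)
  sum(fp_a$bits & fp_b$bits) / u
}

#' @rdname tanimoto
#' @export
tanimoto_distance <- function(fp_a, fp_b) 1 - tanimoto(fp_a, fp_b)

#' Tanimoto distances of a molecule panel to a reference molecule
#'
#' Heat-map-ready table: one row per molecule, one column per descriptor,
#' entries are Tanimoto distances to the reference.
#'
#' @param mols Named list of `mol_graph` objects (or SMILES strings, parsed
#'   on the fly).
#' @param reference_mol A `mol_graph` or SMILES string.
#' @param descriptors Subset of `c("PathFp", "SphereFp", "FragFP")`.
#' @return data.frame with a `molecule` column and one distance column per
#'   descriptor.
#' @export
similarity_matrix <- function(mols, reference_mol,
                              descriptors = c("PathFp", "SphereFp", "FragFP")) {
  stopifnot(length(mols) >= 1, length(descriptors) >= 1)
  descriptors <- match.arg(descriptors, several.ok = TRUE)
  as_mol <- function(m) if (inherits(m, "mol_graph")) m else parse_smiles(m)
  mols <- lapply(mols, as_mol)
  ref <- as_mol(reference_mol)
  fp_fun <- list(PathFp = path_fingerprint, SphereFp = sphere_fingerprint,
                 FragFP = frag_fingerprint)
  out <- data.frame(molecule = names(mols) %||na% paste0("mol", seq_along(mols)),
                    stringsAsFactors = FALSE)
  for (d in descriptors) {
    ref_fp <- fp_fun[[d]](ref)
    out[[d]] <- vapply(mols, function(m)
      tanimoto_distance(fp_fun[[d]](m), ref_fp), numeric(1))
  }
  rownames(out) <- NULL
  out
}

`%||na%` <- function(a, b) if (is.null(a)) b else a

#' Randomly relabel the atoms of a molecular graph
#'
#' Utility for isomorphism-invariance checks: applies a random (or given)
#' permutation to atom indices, preserving the molecule itself.
#'
#' @param mol A `mol_graph`.
#' @param perm Optional integer permutation of `1:n_atoms`.
#' @return A `mol_graph` with permuted atom numbering.
#' @export
relabel_mol <- function(mol, perm = sample(nrow(mol$atoms))) {
  stopifnot(inherits(mol, "mol_graph"),
            identical(sort(perm), seq_len(nrow(mol$atoms))))
  new_pos <- integer(nrow(mol$atoms))
  new_pos[perm] <- seq_along(perm)   # atom at old slot perm[k] goes to slot k
  atoms <- mol$atoms[perm, , drop = FALSE]
  rownames(atoms) <- NULL
  bonds <- mol$bonds
  bonds$i <- new_pos[bonds$i]
  bonds$j <- new_pos[bonds$j]
  structure(list(atoms = atoms, bonds = bonds), class = "mol_graph")
}

#' Write fingerprints as hex-encoded bit strings
#'
#' @param fps Named list of `chem_fp` objects (same descriptor/length).
#' @param path Output TSV path (columns: molecule, descriptor, nbits, hex).
#' @export
write_fingerprints <- function(fps, path) {
  rows <- lapply(names(fps), function(nm) {
    fp <- fps[[nm]]
    bytes <- packBits(c(fp$bits, rep(FALSE, (8 - fp$nbits %% 8) %% 8)), "raw")
    data.frame(molecule = nm, descriptor = fp$descriptor, nbits = fp$nbits,
               hex = paste(format(bytes), collapse = ""),
               stringsAsFactors = FALSE)
  })
  data.table::fwrite(do.call(rbind, rows), path, sep = "\t")
  invisible(path)
}
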