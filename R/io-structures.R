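#' Create a structure record
#'
#' Holds the ordered alpha-carbon trace of one protein chain, the raw
#' material for contact maps and point clouds.
#'
#' @param id Structure identifier.
#' @param chain_id Chain identifier.
#' @param ca_coords Numeric matrix with one row per residue and columns
#'   x, y, z (Angstrom).
#' @param resolution Optional resolution in Angstrom.
#' @return An object of class `structure_record`.
#' @export
structure_record <- function(id, chain_id, ca_coords, resolution = NA_real_) {
  ca_coords <- as.matrix(ca_coords)
  if (ncol(ca_coords) != 3L) stopf("ca_coords must have 3 columns")
  if (nrow(ca_coords) < 1L) stopf("structure '%s' has no residues", id)
  if (!all(is.finite(ca_coords))) stopf("non-finite coordinate in structure '%s'", id)
  dimnames(ca_coords) <- list(NULL, c("x", "y", "z"))
  structure(
    list(id = id, chain_id = chain_id, ca_coords = ca_coords,
         resolution = resolution, n_residues = nrow(ca_coords)),
    class = "structure_record"
  )
}

#' Read a single protein chain from a legacy PDB file
#'
#' Implements the monomer-cleanup rules used when curating structures for
#' druggability modelling: all HETATM records (waters, ions, ligands) are
#' dropped, a single protein chain is kept (by default the first chain, in
#' file order, that carries ATOM records with an alpha carbon), alternate
#' locations are resolved by highest occupancy (ties to the first in file
#' order) and residues without a resolved alpha carbon are skipped.
#'
#' @param path Path to a legacy PDB file.
#' @param chain Optional chain identifier; default is the first protein
#'   chain in file order.
#' @param id Identifier stored on the record; defaults to the file name.
#' @return A [structure_record()].
#' @export
read_pdb_monomer <- function(path, chain = NULL, id = NULL) {
  if (!file.exists(path)) stopf("PDB file not found: %s", path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE))
  atoms <- pdb$atom
  ca <- atoms[atoms$type == "ATOM" & atoms$elety == "CA", , drop = FALSE]
  if (nrow(ca) == 0L) stopf("no protein chain in %s", path)
  chains <- unique(ca$chain)
  if (is.null(chain)) {
    chain <- chains[1]
  } else if (!chain %in% chains) {
    stopf("chain '%s' not found; available protein chains: %s",
          chain, paste(chains, collapse = ", "))
  }
  ca <- ca[ca$chain == chain, , drop = FALSE]
  # altloc resolution: per residue keep the alpha carbon with the highest
  # occupancy; which.max takes the first on ties, i.e. file order.
  res_key <- paste(ca$resno, ca$insert %||% "", sep = "_")
  keep <- unlist(lapply(split(seq_len(nrow(ca)), factor(res_key, levels = unique(res_key))),
                        function(idx) {
                          occ <- ca$o[idx]
                          occ[is.na(occ)] <- 1
                          idx[which.max(occ)]
                        }), use.names = FALSE)
  ca <- ca[sort(keep), , drop = FALSE]
  structure_record(
    id = id %||% sub("\\.pdb$", "", basename(path)),
    chain_id = chain,
    ca_coords = cbind(ca$x, ca$y, ca$z)
  )
}

#' Choose the best structure among candidates
#'
#' Candidates that cover less than half of the full protein sequence are
#' discarded; among the survivors the lowest resolution value (best) wins,
#' ties go to the longest coverage, and remaining ties to the first
#' candidate in input order.
#'
#' @param candidates Data.frame (or list of length-2 vectors) with columns
#'   `resolution` (Angstrom) and `covered_length` (residues).
#' @param full_length Full protein sequence length.
#' @return The 1-based index of the chosen candidate.
#' @export
select_best_structure <- function(candidates, full_length) {
  if (full_length < 1L) stopf("full_length must be >= 1")
  if (is.data.frame(candidates)) {
    res <- candidates$resolution
    cov <- candidates$covered_length
  } else {
    res <- vapply(candidates, `[[`, numeric(1), 1L)
    cov <- vapply(candidates, `[[`, numeric(1), 2L)
  }
  survivors <- which(cov / full_length >= 0.5)
  if (length(survivors) == 0L) stopf("no structure covers half the sequence")
  ord <- survivors[order(res[survivors], -cov[survivors], survivors)]
  ord[1]
}

#' Write an alpha-carbon trace as a legacy PDB file
#'
#' Fixed-column ATOM records (one CA per residue, ALA placeholder residue
#' type) terminated by TER/END; round-trips through [read_pdb_monomer()].
#'
#' @param coords Numeric matrix of CA coordinates (rows = residues).
#' @param path Output path.
#' @param chain Chain identifier (single character).
#' @return `path`, invisibly.
#' @export
write_pdb_ca <- function(coords, path, chain = "A") {
  coords <- as.matrix(coords)
  lines <- vapply(seq_len(nrow(coords)), function(i) {
    sprintf("ATOM  %5d  CA  ALA %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
            i, chain, i, coords[i, 1], coords[i, 2], coords[i, 3], 1.00, 0.00)
  }, character(1))
  writeLines(c(lines, "TER", "END"), path)
  invisible(path)
}
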