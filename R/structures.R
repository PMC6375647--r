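#' Parse a protein-ligand complex from PDB text
#'
#' Reads ATOM/HETATM records, drops hydrogens (and deuterium) and waters,
#' resolves alternate locations to the highest-occupancy copy (first record
#' wins on ties), and splits the remaining atoms into the protein structure
#' and hetero groups (candidate ligands).  Non-water hetero groups other
#' than the ligand eventually selected take no part in pocket refinement or
#' energy calculation.
#'
#' @param pdb Path to a PDB file, or a character vector of PDB-format lines.
#' @return A list with elements:
#'   \describe{
#'     \item{structure}{a `typed_structure` holding the protein heavy atoms
#'       (columns `eleno`, `elety`, `elesy`, `resid`, `chain`, `resno`,
#'       `insert`, `x`, `y`, `z`, `o`, `b`, `sybyl`).  `sybyl` is `NA` until
#'       [assign_sybyl_types()] is applied.}
#'     \item{hetero}{a data frame of hetero-group atoms (waters removed).}
#'     \item{hetero_groups}{summary data frame with one row per hetero group
#'       (`resid`, `chain`, `resno`, `n_atoms`).}
#'   }
#' @examples
#' cx <- make_complex(synthetic_spec(seed = 1), class_label = "polar", index = 1)
#' parsed <- parse_structure(cx$pdb)
#' nrow(parsed$structure$atoms)
#' @export
parse_structure <- function(pdb) {
  if (length(pdb) == 1 && !grepl("\n", pdb) && file.exists(pdb)) {
    lines <- readLines(pdb, warn = FALSE)
  } else {
    lines <- unlist(strsplit(as.character(pdb), "\n", fixed = TRUE))
  }
  rec <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(grepl("^ATOM  ", lines)))
    stopf("malformed PDB: no ATOM record found")
  for (i in which(rec)) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stopf("malformed PDB at line %d: record shorter than coordinate fields", i)
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38), substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    if (anyNA(xyz) || !all(is.finite(xyz)))
      stopf("malformed PDB at line %d: unreadable coordinates", i)
  }

  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf))
  writeLines(lines, tf)
  p <- bio3d::read.pdb(tf, rm.alt = FALSE, rm.insert = FALSE, verbose = FALSE)
  at <- p$atom
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$chain[is.na(at$chain)] <- ""
  at$o[is.na(at$o)] <- 1
  at$elesy <- guess_element(at$elesy, at$elety, at$type)

  at <- at[!(at$elesy %in% c("H", "D")), , drop = FALSE]
  at <- at[!(at$resid %in% c("HOH", "WAT", "DOD", "H2O")), , drop = FALSE]
  at <- resolve_altloc(at)

  keep <- c("eleno", "elety", "elesy", "resid", "chain", "resno", "insert",
            "x", "y", "z", "o", "b")
  prot <- at[at$type == "ATOM", keep, drop = FALSE]
  het <- at[at$type == "HETATM", keep, drop = FALSE]
  rownames(prot) <- rownames(het) <- NULL
  prot$sybyl <- NA_character_

  structure_obj <- structure(
    list(atoms = prot, typing_fallbacks = NULL),
    class = "typed_structure")

  if (nrow(het) > 0) {
    gkey <- paste(het$resid, het$chain, het$resno, sep = "|")
    groups <- unique(gkey)
    hg <- do.call(rbind, lapply(groups, function(g) {
      sub <- het[gkey == g, ]
      data.frame(resid = sub$resid[1], chain = sub$chain[1],
                 resno = sub$resno[1], n_atoms = nrow(sub),
                 stringsAsFactors = FALSE)
    }))
  } else {
    hg <- data.frame(resid = character(), chain = character(),
                     resno = integer(), n_atoms = integer())
  }
  list(structure = structure_obj, hetero = het, hetero_groups = hg)
}

#' @noRd
guess_element <- function(elesy, elety, type) {
  two_letter <- c("FE", "ZN", "MG", "MN", "CL", "BR", "NA", "SE", "CU", "NI",
                  "CO", "CD", "HG", "MO")
  miss <- is.na(elesy) | elesy == ""
  fix <- function(name, is_het) {
    nm <- gsub("[^A-Za-z]", "", toupper(name))
    if (nchar(nm) >= 2 && substr(nm, 1, 2) %in% two_letter && is_het)
      return(substr(nm, 1, 2))
    substr(nm, 1, 1)
  }
  elesy[miss] <- mapply(fix, elety[miss], type[miss] == "HETATM")
  toupper(trimws(elesy))
}

#' @noRd
resolve_altloc <- function(at) {
  if (all(at$alt == "")) return(at)
  key <- paste(at$type, at$chain, at$resno, at$insert, at$resid, at$elety,
               sep = "|")
  keep <- unlist(lapply(split(seq_len(nrow(at)), key), function(idx) {
    if (length(idx) == 1) return(idx)
    occ <- at$o[idx]
    idx[which.max(occ)]  # which.max returns the first maximum: ties by order
  }), use.names = FALSE)
  at[sort(keep), , drop = FALSE]
}

#' @export
print.typed_structure <- function(x, ...) {
  cat(sprintf("typed_structure: %d heavy atoms, %d residues, %s\n",
              nrow(x$atoms), length(unique(residue_key(x$atoms))),
              if (all(is.na(x$atoms$sybyl))) "untyped" else "SYBYL-typed"))
  invisible(x)
}

#' Select a ligand (hetero group) from a parsed complex
#'
#' @param parsed Result of [parse_structure()].
#' @param resname Three-letter residue name of the ligand.
#' @param chain Optional chain identifier to disambiguate multiple copies.
#' @return A `ligand` object: list with `atoms` (heavy-atom data frame),
#'   `center` (unweighted mean of the heavy-atom coordinates, in Angstrom),
#'   and the identifying `resname`/`chain`/`resno`.
#' @export
select_ligand <- function(parsed, resname, chain = NULL) {
  hg <- parsed$hetero_groups
  hit <- hg$resid == resname
  if (!is.null(chain)) hit <- hit & hg$chain == chain
  if (!any(hit)) {
    avail <- if (nrow(hg)) paste(sprintf("%s (chain %s, resno %d)", hg$resid,
                                         hg$chain, hg$resno), collapse = ", ")
             else "none"
    stopf("no hetero group '%s'%s; available: %s", resname,
          if (is.null(chain)) "" else sprintf(" in chain %s", chain), avail)
  }
  if (sum(hit) > 1)
    stopf("multiple hetero groups named '%s'; specify a chain (candidates: %s)",
          resname, paste(hg$chain[hit], collapse = ", "))
  g <- hg[hit, ]
  het <- parsed$hetero
  sel <- het$resid == g$resid & het$chain == g$chain & het$resno == g$resno
  atoms <- het[sel, , drop = FALSE]
  structure(list(atoms = atoms,
                 center = colMeans(coords_matrix(atoms)),
                 resname = g$resid, chain = g$chain, resno = g$resno),
            class = "ligand")
}

#' Residues lining a ligand
#'
#' A residue is a binding residue when at least one of its heavy atoms lies
#' within `cutoff` of at least one ligand heavy atom.  The default 5 Angstrom
#' matches the distance used to map class-activation grid points back to
#' residues.
#'
#' @param structure A `typed_structure`.
#' @param ligand A `ligand` from [select_ligand()].
#' @param cutoff Heavy-atom to heavy-atom distance cutoff in Angstrom.
#' @return A `residue_set`: list with `residue_ids` (chain|resno|insert keys)
#'   and `atoms` (the atoms of those residues).
#' @export
binding_residues <- function(structure, ligand, cutoff = 5.0) {
  stopifnot(cutoff > 0)
  atoms <- structure$atoms
  d <- cross_dist(coords_matrix(atoms), coords_matrix(ligand$atoms))
  near <- apply(d, 1, min) <= cutoff
  if (!any(near))
    stopf("no binding residues within %.2f Angstrom; increase cutoff", cutoff)
  keys <- residue_key(atoms)
  ids <- unique(keys[near])
  structure(list(residue_ids = ids,
                 atoms = atoms[keys %in% ids, , drop = FALSE]),
            class = "residue_set")
}

#' Write a structure (plus optional hetero atoms) back to PDB
#'
#' @param structure A `typed_structure`.
#' @param file Output path.
#' @param hetero Optional data frame of hetero atoms to append as HETATM.
#' @return The file path, invisibly.
#' @export
write_structure <- function(structure, file, hetero = NULL) {
  at <- structure$atoms
  type <- rep("ATOM", nrow(at))
  if (!is.null(hetero) && nrow(hetero) > 0) {
    common <- intersect(names(at), names(hetero))
    at <- rbind(at[, common], hetero[, common])
    type <- c(type, rep("HETATM", nrow(hetero)))
  }
  bio3d::write.pdb(pdb = NULL, file = file,
                   xyz = as.numeric(t(coords_matrix(at))),
                   type = type, resno = at$resno, resid = at$resid,
                   eleno = seq_len(nrow(at)), elety = at$elety,
                   chain = at$chain, insert = at$insert,
                   o = at$o, b = at$b, elesy = at$elesy)
  invisible(file)
}
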