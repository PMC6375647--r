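#' The 14 SYBYL probe atom types used as energy channels
#'
#' Carbon (C.2, C.3, C.ar), nitrogen (N.2, N.4, N.am, N.ar, N.pl3), oxygen
#' (O.2, O.3, O.co2), phosphorus (P.3), sulfur (S.3), and halogens (F).
#'
#' @return Character vector of length 14, in canonical channel order.
#' @export
sybyl_probe_types <- function() {
  c("C.2", "C.3", "C.ar", "N.2", "N.4", "N.am", "N.ar", "N.pl3",
    "O.2", "O.3", "O.co2", "P.3", "S.3", "F")
}

# element-level fallback when (residue, atom) has no table entry
.element_fallback <- c(C = "C.3", N = "N.am", O = "O.2", S = "S.3", SE = "S.3",
                       P = "P.3", F = "F", CL = "F", BR = "F", I = "F")

#' Load a residue/atom to SYBYL type table
#'
#' The table is 3-column tab-separated text with a header line
#' (`resid`, `elety`, `sybyl`).  The pseudo-residue `ALL` supplies
#' backbone-atom entries shared by every residue.
#'
#' @param path Path to the table; defaults to the table shipped with the
#'   package, which covers the 20 standard amino acids.
#' @return A data frame with columns `resid`, `elety`, `sybyl`.
#' @export
load_typing_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "sybyl_types.tsv", package = "pocketvox")
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("resid", "elety", "sybyl")
  if (!all(need %in% names(tab)))
    stopf("typing table must have columns %s", paste(need, collapse = ", "))
  tab
}

#' Assign SYBYL atom types to protein heavy atoms
#'
#' Atoms are first looked up by (residue name, atom name); backbone atoms
#' match the table's `ALL` pseudo-residue.  Atoms with no table entry fall
#' back to an element-level default (C to C.3, N to N.am, O to O.2, S to S.3,
#' P to P.3, halogens to F) and are counted in a warning.  Typing is total
#' and idempotent.
#'
#' @param structure A `typed_structure` from [parse_structure()].
#' @param table Typing table from [load_typing_table()].
#' @return The structure with the `sybyl` column filled in and
#'   `typing_fallbacks` set to the number of fallback-typed atoms.
#' @export
assign_sybyl_types <- function(structure, table = load_typing_table()) {
  at <- structure$atoms
  key <- paste(at$resid, at$elety, sep = "|")
  lut <- setNames(table$sybyl, paste(table$resid, table$elety, sep = "|"))
  ty <- unname(lut[key])
  backbone <- is.na(ty)
  ty[backbone] <- unname(lut[paste("ALL", at$elety[backbone], sep = "|")])

  miss <- is.na(ty)
  if (any(miss)) {
    fb <- unname(.element_fallback[at$elesy[miss]])
    fb[is.na(fb)] <- "C.3"
    ty[miss] <- fb
    warning(sprintf("%d atom(s) typed by element fallback", sum(miss)),
            call. = FALSE)
  }
  structure$atoms$sybyl <- ty
  structure$typing_fallbacks <- sum(miss)
  structure
}
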