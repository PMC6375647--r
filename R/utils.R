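#' @keywords internal
#' @noRd
cross_dist <- function(a, b) {
  # pairwise Euclidean distances between rows of a (n x 3) and b (m x 3)
  a <- as.matrix(a); b <- as.matrix(b)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

#' @noRd
residue_key <- function(atoms) {
  paste(atoms$chain, atoms$resno, ifelse(is.na(atoms$insert), "", atoms$insert),
        sep = "|")
}

#' @noRd
coords_matrix <- function(atoms) {
  m <- cbind(atoms$x, atoms$y, atoms$z)
  colnames(m) <- c("x", "y", "z")
  m
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
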