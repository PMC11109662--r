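#' Structure model: an atom table with coordinates
#'
#' A light tabular container for a molecular structure: one row per atom with
#' identifying metadata and coordinates in nm (PDB ingestion converts from
#' Angstrom; see [read_structure()]).
#'
#' @param atoms A data frame with columns `serial`, `name`, `resname`,
#'   `resno`, `chain`, `element`, `x`, `y`, `z` (coordinates in nm).
#' @param source Free-text provenance (e.g. a PDB identifier or "synthetic").
#' @return A tibble of class `structure_model` with a `source` attribute.
#' @export
structure_model <- function(atoms, source = "unknown") {
  required <- c("serial", "name", "resname", "resno", "chain", "element",
                "x", "y", "z")
  missing <- setdiff(required, names(atoms))
  if (length(missing) > 0)
    abort(paste0("atom table lacks column(s): ", paste(missing, collapse = ", ")))
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) abort("atom coordinates must be finite")
  out <- as_tibble(atoms[, required])
  attr(out, "source") <- source
  class(out) <- c("structure_model", class(out))
  out
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> %d atoms, %d residues, source: %s\n",
              nrow(x), length(unique(paste(x$chain, x$resno))),
              attr(x, "source") %||% "unknown"))
  NextMethod()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract the coordinate matrix of a structure model
#'
#' @param model A [structure_model()].
#' @return An n x 3 numeric matrix, nm.
#' @export
coords <- function(model) {
  as.matrix(model[, c("x", "y", "z")])
}

# heavy-atom predicate: hydrogens excluded by element symbol
is_heavy <- function(element) {
  toupper(trimws(element)) != "H"
}

# infer an element symbol from a PDB atom name when the element column is
# blank (digits stripped; two-letter symbols only for common cases)
infer_element <- function(name) {
  nm <- gsub("[0-9']", "", trimws(name))
  first <- toupper(substr(nm, 1, 1))
  ifelse(first == "", "X", first)
}
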