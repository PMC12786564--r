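#' @include AllGenerics.R
NULL

#' Atoms of a given element in a structure or motif
#'
#' @param x A [CifStructure] or [MotifGraph] object.
#' @param symbol Element symbol (case-insensitive, e.g. `"S"`).
#' @return A data frame of atom records (one row per atom, file order
#'   preserved); zero rows if the element is absent.
#' @export
setGeneric("getElementAtoms", function(x, symbol) standardGeneric("getElementAtoms"))

#' Does a structure contain an element?
#'
#' @param x A [CifStructure] object.
#' @param symbol Element symbol (case-insensitive).
#' @return `TRUE` iff at least one atom of that element is present.
#' @export
setGeneric("containsAtom", function(x, symbol) standardGeneric("containsAtom"))

#' Look up one atom by its identifier
#'
#' @param x A [CifStructure] object.
#' @param identifier Atom label as written in the file, e.g. `"N1"`.
#' @return A one-row data frame (the atom record).
#' @export
setGeneric("getParticularAtom", function(x, identifier) standardGeneric("getParticularAtom"))

#' Fixed-radius neighbour search around one atom
#'
#' Emulates a spherical "wave" of the given radius emanating from the target
#' atom and collects every other atom it encompasses (Euclidean distance less
#' than or equal to `radius`).
#'
#' @param x A [CifStructure] object.
#' @param target Atom identifier (string) or a one-row atom record.
#' @param radius Search radius in Angstroms.
#' @return Data frame of atom records within the radius, excluding the target
#'   itself, with a `distance` column appended.
#' @export
setGeneric("getAtomsInRadius", function(x, target, radius) standardGeneric("getAtomsInRadius"))

#' Atom count
#' @param x A [CifStructure] or [MotifGraph].
#' @return Integer number of atoms.
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' Unit cell accessor
#' @param x A [CifStructure].
#' @return The [UnitCell] object.
#' @export
setGeneric("unitCellOf", function(x) standardGeneric("unitCellOf"))

#' Atom table accessor
#' @param x A [CifStructure] or [MotifGraph].
#' @return Data frame of atom records.
#' @export
setGeneric("atomRecords", function(x) standardGeneric("atomRecords"))

#' Metadata accessor
#' @param x A [CifStructure].
#' @return Named character vector of header items preceding the atom loop.
#' @export
setGeneric("cifMetadata", function(x) standardGeneric("cifMetadata"))

#' Add a bond to a motif graph
#'
#' Inserts a symmetric adjacency entry between `existing` (already a node of
#' the graph) and `new`. Re-adding an identical bond is a no-op.
#'
#' @param graph A [MotifGraph].
#' @param existing One-row atom record already present in the graph.
#' @param new One-row atom record to connect to it.
#' @param dist Bond distance in Angstroms.
#' @return The updated [MotifGraph].
#' @export
setGeneric("addBond", function(graph, existing, new, dist) standardGeneric("addBond"))

#' Atoms of a given element among a motif graph's nodes
#'
#' @param graph A [MotifGraph].
#' @param symbol Element symbol.
#' @return Data frame of the matching node atom records (possibly zero rows).
#' @export
setGeneric("returnAtoms", function(graph, symbol) standardGeneric("returnAtoms"))
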