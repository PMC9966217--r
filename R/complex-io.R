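#' @include AllClasses.R AllGenerics.R
NULL

#' @describeIn ComplexStructure-class complex identifier.
#' @param x a \code{ComplexStructure}.
#' @export
setMethod("complexId", "ComplexStructure", function(x) x@complexId)

#' @describeIn ComplexStructure-class target-protein identifier.
#' @export
setMethod("proteinId", "ComplexStructure", function(x) x@proteinId)

#' @describeIn ComplexStructure-class atom table (element, x, y, z, role).
#' @export
setMethod("atoms", "ComplexStructure", function(x) x@atoms)

setMethod("show", "ComplexStructure", function(object) {
    a <- object@atoms
    cat("ComplexStructure", object@complexId,
        sprintf("(protein %s): %d target + %d ligand atoms\n",
                object@proteinId, sum(a$role == "target"), sum(a$role == "ligand")))
})

# Element resolution: PDB element column (77-78) when present, otherwise the
# leading alphabetic characters of the atom name, with the two-letter symbols
# CL and BR recognized before one-letter ones. Many PDB dialects omit the
# element column, and hydrogens matter here, so the fallback is deliberate
# and documented rather than an error.
.resolveElement <- function(elesy, elety) {
    out <- toupper(trimws(ifelse(is.na(elesy), "", elesy)))
    miss <- !nzchar(out)
    if (any(miss)) {
        nm <- toupper(gsub("[^A-Za-z]", "", elety[miss]))
        two <- substr(nm, 1, 2)
        out[miss] <- ifelse(two %in% c("CL", "BR"), two, substr(nm, 1, 1))
    }
    out
}

.readPdbAtoms <- function(path, role) {
    pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                    error = function(e) stop(sprintf(
                        "cannot parse PDB file '%s': %s", path,
                        conditionMessage(e)), call. = FALSE))
    a <- pdb$atom
    # waters out; alternate locations: keep blank or 'A' only
    a <- a[is.na(a$resid) | a$resid != "HOH", , drop = FALSE]
    if ("alt" %in% names(a))
        a <- a[is.na(a$alt) | a$alt %in% c("", "A"), , drop = FALSE]
    el <- .resolveElement(a$elesy, a$elety)
    bad <- !nzchar(el)
    if (any(bad))
        stop(sprintf("unresolvable element for record(s) %s in '%s'",
                     paste(a$eleno[bad], collapse = ", "), path), call. = FALSE)
    data.frame(element = el, x = a$x, y = a$y, z = a$z, role = role,
               stringsAsFactors = FALSE)
}

#' Read a protein-ligand complex from two PDB files
#'
#' All atoms of \code{proteinFile} get role \code{"target"} and all atoms of
#' \code{ligandFile} role \code{"ligand"}. The element is taken from the PDB
#' element column when present, else derived from the atom name (two-letter
#' symbols CL/BR recognized first). Water records (residue HOH) are dropped;
#' alternate locations other than blank or 'A' are dropped; every other
#' hetero record is kept and counted as its element.
#'
#' @param proteinFile,ligandFile paths to PDB files.
#' @param complexId,proteinId identifiers for the resulting structure.
#' @return A \linkS4class{ComplexStructure}.
#' @seealso [readComplexSingle()] for the one-file convenience mode,
#'   [writeComplex()] for the inverse.
#' @export
readComplex <- function(proteinFile, ligandFile, complexId, proteinId) {
    tgt <- .readPdbAtoms(proteinFile, "target")
    lig <- .readPdbAtoms(ligandFile, "ligand")
    ComplexStructure(complexId, proteinId, rbind(tgt, lig))
}

#' Read a complex from a single PDB file
#'
#' Convenience mode: ATOM records become target atoms and HETATM records
#' (waters excluded) become ligand atoms.
#'
#' @inheritParams readComplex
#' @param file path to a PDB file holding both molecules.
#' @return A \linkS4class{ComplexStructure}.
#' @export
readComplexSingle <- function(file, complexId, proteinId) {
    pdb <- tryCatch(bio3d::read.pdb(file, verbose = FALSE),
                    error = function(e) stop(sprintf(
                        "cannot parse PDB file '%s': %s", file,
                        conditionMessage(e)), call. = FALSE))
    a <- pdb$atom
    a <- a[is.na(a$resid) | a$resid != "HOH", , drop = FALSE]
    if ("alt" %in% names(a))
        a <- a[is.na(a$alt) | a$alt %in% c("", "A"), , drop = FALSE]
    el <- .resolveElement(a$elesy, a$elety)
    bad <- !nzchar(el)
    if (any(bad))
        stop(sprintf("unresolvable element for record(s) %s in '%s'",
                     paste(a$eleno[bad], collapse = ", "), file), call. = FALSE)
    ComplexStructure(complexId, proteinId, data.frame(
        element = el, x = a$x, y = a$y, z = a$z,
        role = ifelse(a$type == "HETATM", "ligand", "target"),
        stringsAsFactors = FALSE))
}

.writePdbAtoms <- function(a, path, type) {
    if (any(abs(c(a$x, a$y, a$z)) >= 10000))
        stop("coordinate magnitude exceeds the PDB fixed-width format (|x| < 10000 A)")
    resid <- if (type == "HETATM") "LIG" else "UNK"
    bio3d::write.pdb(file = path, type = rep(type, nrow(a)),
                     eleno = seq_len(nrow(a)), elety = a$element,
                     resid = rep(resid, nrow(a)),
                     chain = rep(if (type == "HETATM") "B" else "A", nrow(a)),
                     resno = rep(1L, nrow(a)),
                     xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                     elesy = a$element)
    invisible(path)
}

#' Write a complex to two fixed-column PDB files
#'
#' Target atoms are written as ATOM records to \code{proteinFile}, ligand
#' atoms as HETATM records to \code{ligandFile}; the element column is
#' populated and coordinates carry 3 decimals (the PDB fixed width), so
#' [readComplex()] round-trips elements, roles and coordinates.
#'
#' @param x a \linkS4class{ComplexStructure}.
#' @param proteinFile,ligandFile output paths.
#' @return invisibly, \code{c(proteinFile, ligandFile)}.
#' @export
writeComplex <- function(x, proteinFile, ligandFile) {
    stopifnot(is(x, "ComplexStructure"))
    validObject(x)
    a <- x@atoms
    .writePdbAtoms(a[a$role == "target", , drop = FALSE], proteinFile, "ATOM")
    .writePdbAtoms(a[a$role == "ligand", , drop = FALSE], ligandFile, "HETATM")
    invisible(c(proteinFile, ligandFile))
}

#' @describeIn ComplexStructure-class report atoms a featurization scheme
#'   would ignore: counts of target-role atoms outside the target species
#'   list and ligand-role atoms outside the ligand species list (the
#'   featurizer skips them silently; this op only surfaces them). Returns a
#'   list with \code{targetOut}, \code{ligandOut} (counts) and
#'   \code{outOfScheme} (the offending rows of the atom table).
#' @export
setMethod("speciesFilterReport",
    signature(x = "ComplexStructure", scheme = "FeaturizationScheme"),
    function(x, scheme) {
        a <- x@atoms
        bad <- (a$role == "target" & !a$element %in% scheme@targetSpecies) |
               (a$role == "ligand" & !a$element %in% scheme@ligandSpecies)
        list(targetOut = sum(bad & a$role == "target"),
             ligandOut = sum(bad & a$role == "ligand"),
             outOfScheme = a[bad, , drop = FALSE])
    })

#' Read a complex database from a CSV manifest
#'
#' The manifest has columns \code{complex_id}, \code{protein_id},
#' \code{protein_file}, \code{ligand_file}, \code{affinity_value},
#' \code{affinity_kind}; file paths are resolved relative to \code{dir}
#' (default: the manifest's directory).
#'
#' @param path manifest CSV path.
#' @param dir base directory for the PDB paths.
#' @return list with \code{complexes} (list of
#'   \linkS4class{ComplexStructure}) and \code{affinities} (data.frame
#'   \code{complexId}, \code{value}, \code{kind}).
#' @export
readManifest <- function(path, dir = dirname(path)) {
    man <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("complex_id", "protein_id", "protein_file", "ligand_file",
              "affinity_value", "affinity_kind")
    if (!all(need %in% names(man)))
        stop("manifest must have columns ", paste(need, collapse = ", "))
    complexes <- lapply(seq_len(nrow(man)), function(i)
        readComplex(file.path(dir, man$protein_file[i]),
                    file.path(dir, man$ligand_file[i]),
                    man$complex_id[i], man$protein_id[i]))
    list(complexes = complexes,
         affinities = data.frame(complexId = man$complex_id,
                                 value = man$affinity_value,
                                 kind = man$affinity_kind,
                                 stringsAsFactors = FALSE))
}
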