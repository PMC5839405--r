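# Mapping candidate substitutions onto a protein-ligand complex.
#
# The screen's substitutions are classified by the minimum heavy-atom
# distance between the substituted residue and the bound ligand:
# interface (<= d1, direct contact), proximal (<= d2), distal. The
# qualitative claim "maps to the binding site or close proximity" is
# thereby re-checkable at any threshold, so raw distances are always
# reported alongside the class.

#' Read a protein-ligand complex from a PDB file
#'
#' Protein atoms come from ATOM records (optionally restricted to one
#' chain); ligand atoms from HETATM records whose residue name matches
#' `ligand_name`. Alternate locations are resolved by first occurrence.
#'
#' @param pdb_file Path to a PDB-format file.
#' @param ligand_name HETATM residue name of the ligand (e.g. `"TG1"`).
#' @param chain Optional protein chain identifier.
#' @return A list of class `structure_complex` with data.frames
#'   `protein` and `ligand` (columns `chain`, `resno`, `resid`,
#'   `atom`, `element`, `x`, `y`, `z`) and `source`.
#' @export
read_structure <- function(pdb_file, ligand_name, chain = NULL) {
  pdb <- bio3d::read.pdb(pdb_file)
  at <- pdb$atom
  # resolve altloc by first occurrence per atom identity
  first <- !duplicated(paste(at$type, at$chain, at$resno, at$resid,
                             at$elety, sep = ":"))
  at <- at[first, , drop = FALSE]
  element <- ifelse(is.na(at$elesy) | at$elesy == "",
                    substring(gsub("[^A-Za-z].*$", "", at$elety), 1L, 1L),
                    at$elesy)
  tab <- data.frame(chain = at$chain, resno = at$resno, resid = at$resid,
                    atom = at$elety, element = toupper(element),
                    x = at$x, y = at$y, z = at$z, stringsAsFactors = FALSE)
  if (any(!is.finite(tab$x) | !is.finite(tab$y) | !is.finite(tab$z))) {
    stop("non-finite coordinates in ", pdb_file, call. = FALSE)
  }
  is_atom <- at$type == "ATOM"
  chain_ok <- if (is.null(chain)) rep(TRUE, nrow(tab)) else tab$chain == chain
  protein <- tab[is_atom & chain_ok, , drop = FALSE]
  ligand <- tab[!is_atom & tab$resid == ligand_name, , drop = FALSE]
  if (!nrow(ligand)) {
    avail <- sort(unique(tab$resid[!is_atom]))
    stop(sprintf("ligand '%s' not found; HETATM residues present: %s",
                 ligand_name,
                 if (length(avail)) paste(avail, collapse = ", ") else "none"),
         call. = FALSE)
  }
  structure(list(protein = protein, ligand = ligand,
                 source = basename(pdb_file)),
            class = "structure_complex")
}

#' @export
print.structure_complex <- function(x, ...) {
  cat(sprintf("structure_complex [%s]: %d protein atoms (%d residues), %d ligand atoms\n",
              x$source, nrow(x$protein),
              length(unique(paste(x$protein$chain, x$protein$resno))),
              nrow(x$ligand)))
  invisible(x)
}

#' Residue-numbering map
#'
#' Reconciles query (e.g. mouse protein) numbering with the structure's
#' (e.g. rabbit or yeast deposit) numbering, either by a constant
#' offset or by explicit one-to-one pairs. No automatic alignment is
#' attempted: cross-species and precursor/mature numbering conventions
#' are for the user to assert.
#'
#' @param offset Added to query residue numbers (default 0).
#' @param pairs Optional named integer vector: names are query residue
#'   numbers, values structure residue numbers.
#' @param chain Optional chain the map applies to.
#' @return An object of class `residue_map`.
#' @export
residue_map <- function(offset = 0L, pairs = NULL, chain = NULL) {
  if (!is.null(pairs)) {
    if (is.null(names(pairs)) || anyDuplicated(names(pairs)) ||
        anyDuplicated(pairs)) {
      stop("pairs must be a named vector defining a one-to-one map",
           call. = FALSE)
    }
  }
  structure(list(offset = as.integer(offset), pairs = pairs, chain = chain),
            class = "residue_map")
}

map_residue <- function(map, query) {
  stopifnot(inherits(map, "residue_map"))
  if (!is.null(map$pairs)) {
    hit <- match(as.character(query), names(map$pairs))
    if (is.na(hit)) return(NA_integer_)
    as.integer(map$pairs[[hit]])
  } else {
    as.integer(query + map$offset)
  }
}

heavy <- function(atoms) atoms[!atoms$element %in% c("H", "D"), , drop = FALSE]

#' Minimum residue-to-ligand heavy-atom distance
#'
#' Minimum Euclidean distance over all pairs of heavy atoms between
#' the mapped residue and the ligand, in Angstrom. All residue atoms
#' (backbone and side chain) are considered.
#'
#' @param complex A [read_structure()] object.
#' @param resno Query residue number.
#' @param map A [residue_map()] (default: identity).
#' @return The minimum distance in Angstrom.
#' @export
min_ligand_distance <- function(complex, resno, map = residue_map()) {
  stopifnot(inherits(complex, "structure_complex"))
  target <- map_residue(map, resno)
  res <- complex$protein
  if (!is.null(map$chain)) res <- res[res$chain == map$chain, , drop = FALSE]
  res <- heavy(res[res$resno %in% target, , drop = FALSE])
  if (is.na(target) || !nrow(res)) {
    stop(sprintf("mapped residue %s not present in structure",
                 ifelse(is.na(target), sprintf("(unmapped %d)", resno),
                        target)),
         call. = FALSE)
  }
  lig <- heavy(complex$ligand)
  a <- as.matrix(res[, c("x", "y", "z")])
  b <- as.matrix(lig[, c("x", "y", "z")])
  d2 <- outer(rowSums(a^2), rep(1, nrow(b))) +
    outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * a %*% t(b)
  sqrt(max(0, min(d2)))
}

parse_substitution <- function(s) {
  m <- regmatches(s, regexec("^([A-Z])([0-9]+)([A-Z*])$", s))[[1L]]
  if (length(m) != 4L) {
    stop(sprintf("cannot parse substitution '%s'", s), call. = FALSE)
  }
  list(ref_aa = m[[2L]], resno = as.integer(m[[3L]]), alt_aa = m[[4L]])
}

#' Classify substitutions by ligand proximity
#'
#' Maps each substitution (e.g. `"F256L"`) onto the structure through
#' the residue map and classifies it as `interface` (min distance <=
#' `d1`), `proximal` (<= `d2`) or `distal`; residues that cannot be
#' resolved in the structure are reported as `unresolved`, never
#' silently dropped.
#'
#' @param substitutions Character vector of one-letter substitutions.
#' @param complex A [read_structure()] object.
#' @param map A [residue_map()].
#' @param d1,d2 Distance cutoffs in Angstrom, `d1 < d2` (defaults 5
#'   and 8: direct contact and close proximity).
#' @return A data.frame: `substitution`, `structure_residue`,
#'   `min_dist`, `class`.
#' @export
classify_substitutions <- function(substitutions, complex,
                                   map = residue_map(), d1 = 5, d2 = 8) {
  if (!(d1 < d2)) stop("require d1 < d2", call. = FALSE)
  if (!length(substitutions)) {
    return(data.frame(substitution = character(),
                      structure_residue = integer(), min_dist = numeric(),
                      class = character(), stringsAsFactors = FALSE))
  }
  rows <- lapply(substitutions, function(s) {
    p <- parse_substitution(s)
    target <- map_residue(map, p$resno)
    dist <- tryCatch(min_ligand_distance(complex, p$resno, map),
                     error = function(e) NA_real_)
    data.frame(
      substitution = s, structure_residue = target, min_dist = dist,
      class = if (is.na(dist)) "unresolved"
              else if (dist <= d1) "interface"
              else if (dist <= d2) "proximal" else "distal",
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a minimal PDB fixture
#'
#' Realizes protein residues and a ligand at exact coordinates as a
#' standards-conformant PDB file that round-trips through
#' [read_structure()] (coordinates to 3 decimals, the PDB fixed-width
#' limit).
#'
#' @param residues data.frame with columns `resno`, `x`, `y`, `z` and
#'   optionally `resid` (default ALA), `atom` (default CA), `element`
#'   (default C), `chain` (default A); one row per atom.
#' @param ligand data.frame with the same columns for HETATM records;
#'   `resid` defaults to LIG. Must contain at least one atom.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
make_fixture_structure <- function(residues, ligand, path) {
  fill <- function(df, ligand = FALSE) {
    df$resid <- df$resid %||% if (ligand) "LIG" else "ALA"
    if (is.null(df$atom)) {
      # unique default atom names within each residue
      df$atom <- paste0("C", stats::ave(seq_len(nrow(df)), df$resno,
                                        FUN = seq_along))
    }
    df$element <- df$element %||% "C"
    df$chain <- df$chain %||% "A"
    df
  }
  if (is.null(ligand) || !nrow(ligand)) {
    stop("fixture requires at least one ligand atom", call. = FALSE)
  }
  residues <- fill(as.data.frame(residues))
  ligand <- fill(as.data.frame(ligand), ligand = TRUE)
  if (any(!is.finite(c(residues$x, residues$y, residues$z,
                       ligand$x, ligand$y, ligand$z)))) {
    stop("fixture coordinates must be finite", call. = FALSE)
  }
  fmt <- function(record, df, serial0) {
    sprintf("%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            record, serial0 + seq_len(nrow(df)),
            ifelse(nchar(df$atom) < 4L, paste0(" ", df$atom), df$atom),
            "", df$resid, df$chain, df$resno, "",
            df$x, df$y, df$z, 1, 0, df$element)
  }
  lines <- c(fmt("ATOM", residues, 0L),
             fmt("HETATM", ligand, nrow(residues)),
             "END")
  writeLines(lines, path)
  invisible(path)
}
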