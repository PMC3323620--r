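#' Structural-analysis parameters
#'
#' Distance cutoff and residue chemistry sets for activation-segment
#' contact analysis. The hydrophobic set is the standard aliphatic/aromatic
#' set (GLY and CYS excluded by default); the charged-negative set holds
#' the carboxylate residues whose introduction disrupts a hydrophobic
#' cluster.
#'
#' @param cutoff Neighbor distance cutoff in Angstrom (default 6).
#' @param hydrophobic 3-letter residue names treated as hydrophobic.
#' @param negative 3-letter residue names treated as charged-negative.
#' @return An object of class `StructureParams`.
#' @export
structureParams <- function(cutoff = 6,
                            hydrophobic = c("ALA", "VAL", "LEU", "ILE",
                                            "PHE", "MET", "TRP", "PRO"),
                            negative = c("ASP", "GLU")) {
  stopifnot(cutoff > 0)
  structure(list(cutoff = cutoff, hydrophobic = hydrophobic,
                 negative = negative), class = "StructureParams")
}

.standardResidues <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU",
                       "GLY", "HIS", "ILE", "LEU", "LYS", "MET", "PHE",
                       "PRO", "SER", "THR", "TRP", "TYR", "VAL")
.polarOrCharged <- c("ARG", "ASN", "ASP", "GLN", "GLU", "HIS", "LYS",
                     "SER", "THR", "TYR")

#' Parse a PDB coordinate file
#'
#' Reads fixed-column ATOM/HETATM records (via the standard PDB reader) and
#' returns heavy atoms; hydrogens are excluded by default since the
#' analysis is heavy-atom based. Records with unparseable coordinates raise
#' an error naming the offending line(s).
#'
#' @param path PDB file.
#' @param dropHydrogens Exclude hydrogen atoms (default TRUE).
#' @return Data frame `serial`, `atom`, `resname`, `chain`, `resno`, `x`,
#'   `y`, `z`, `element`, `hetero`.
#' @export
parsePDB <- function(path, dropHydrogens = TRUE) {
  # validate the fixed-column coordinate fields before handing off: the
  # upstream reader coerces malformed numbers silently
  lines <- readLines(path)
  atomLines <- grep("^(ATOM  |HETATM)", lines)
  coords <- vapply(c(31L, 39L, 47L), function(s)
    suppressWarnings(as.numeric(substr(lines[atomLines], s, s + 7L))),
    numeric(length(atomLines)))
  bad <- which(rowSums(!is.finite(matrix(coords,
                                         nrow = length(atomLines)))) > 0L)
  if (length(bad))
    stop("PDB parse error: non-numeric coordinates at line(s) ",
         paste(atomLines[bad], collapse = ", "))
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, verbose = FALSE)),
    error = function(e) stop("PDB parse error: ", conditionMessage(e)))
  at <- pdb$atom
  df <- data.frame(serial = at$eleno, atom = at$elety, resname = at$resid,
                   chain = at$chain, resno = at$resno,
                   x = at$x, y = at$y, z = at$z,
                   element = at$elesy, hetero = at$type == "HETATM")
  if (dropHydrogens)
    df <- df[!(df$element %in% "H" | grepl("^[0-9]*H", df$atom)), ,
             drop = FALSE]
  df$hetero <- df$hetero | !(df$resname %in% .standardResidues)
  rownames(df) <- NULL
  df
}

#' Residue environment within a distance cutoff
#'
#' Finds every residue with at least one heavy atom within `cutoff` of any
#' heavy atom of the focal residue (minimum-atom-distance criterion), and
#' classifies each neighbor as hydrophobic and/or charged-negative. The
#' focal residue is excluded from its own neighbor list.
#'
#' @param atoms Atom table from [parsePDB()].
#' @param chain Focal chain identifier.
#' @param resno Focal residue number.
#' @param params A [structureParams()].
#' @return List of class `ResidueEnvironment`: `focal` (chain, resno,
#'   resname) and `neighbors` (data frame `chain`, `resno`, `resname`,
#'   `distance`, `hydrophobic`, `negative`).
#' @examples
#' atoms <- parsePDB(toyKinasePDB())
#' residueEnvironment(atoms, "A", 600)
#' @export
residueEnvironment <- function(atoms, chain, resno,
                               params = structureParams()) {
  focal <- atoms[atoms$chain == chain & atoms$resno == resno, ,
                 drop = FALSE]
  if (nrow(focal) == 0L)
    stop("lookup error: residue ", chain, ":", resno, " not found")
  others <- atoms[!(atoms$chain == chain & atoms$resno == resno), ,
                  drop = FALSE]
  fm <- as.matrix(focal[, c("x", "y", "z")])
  om <- as.matrix(others[, c("x", "y", "z")])
  # min distance from each non-focal atom to any focal atom
  d2 <- vapply(seq_len(nrow(om)), function(i)
    min(colSums((t(fm) - om[i, ])^2)), numeric(1))
  others$dist <- sqrt(d2)
  key <- paste(others$chain, others$resno, sep = ":")
  minD <- tapply(others$dist, key, min)
  nb <- others[!duplicated(key), c("chain", "resno", "resname"),
               drop = FALSE]
  nb$distance <- as.numeric(minD[paste(nb$chain, nb$resno, sep = ":")])
  nb <- nb[nb$distance <= params$cutoff, , drop = FALSE]
  nb <- nb[order(nb$distance), , drop = FALSE]
  nb$hydrophobic <- nb$resname %in% params$hydrophobic
  nb$negative <- nb$resname %in% params$negative
  rownames(nb) <- NULL
  structure(list(focal = list(chain = chain, resno = resno,
                              resname = focal$resname[1]),
                 neighbors = nb, params = params),
            class = "ResidueEnvironment")
}

#' @export
print.ResidueEnvironment <- function(x, ...) {
  cat("ResidueEnvironment of", x$focal$resname, paste0(x$focal$chain, ":",
      x$focal$resno), "within", x$params$cutoff, "A:\n")
  print(x$neighbors, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Contact report for a proposed mutation
#'
#' States (a) whether the focal residue participates in a hydrophobic
#' cluster (focal and at least one neighbor hydrophobic), (b) whether the
#' proposed mutant residue is charged-negative and therefore flagged as
#' cluster-disrupting (the codon-600 Glu/Asp pattern that destabilizes the
#' inactive kinase conformation), and (c) for a polar focal residue mutated
#' to a hydrophobic one, the polar/charged neighbor contacts lost (the
#' T599A pattern, losing short-range interactions with Asp residues).
#'
#' @param env A [residueEnvironment()] result.
#' @param mutantResname Proposed mutant residue (3-letter code).
#' @param params A [structureParams()].
#' @return List of class `ContactReport`: `hydrophobicCluster`,
#'   `disrupting`, `lostPolarContacts` (data frame, possibly empty).
#' @export
contactReport <- function(env, mutantResname,
                          params = env$params) {
  mutantResname <- toupper(mutantResname)
  if (!mutantResname %in% .standardResidues)
    stop("domain error: unknown residue name '", mutantResname, "'")
  focalName <- env$focal$resname
  if (!focalName %in% .standardResidues)
    stop("domain error: unknown focal residue '", focalName, "'")
  nb <- env$neighbors
  cluster <- focalName %in% params$hydrophobic && any(nb$hydrophobic)
  disrupting <- mutantResname %in% params$negative
  lost <- nb[integer(0), , drop = FALSE]
  if (focalName %in% .polarOrCharged &&
      mutantResname %in% params$hydrophobic)
    lost <- nb[nb$resname %in% .polarOrCharged | nb$negative, ,
               drop = FALSE]
  structure(list(focal = env$focal, mutant = mutantResname,
                 hydrophobicCluster = cluster, disrupting = disrupting,
                 lostPolarContacts = lost),
            class = "ContactReport")
}

#' @export
print.ContactReport <- function(x, ...) {
  cat(sprintf("%s%d -> %s:\n", x$focal$resname, x$focal$resno, x$mutant))
  cat("  hydrophobic cluster:", x$hydrophobicCluster, "\n")
  cat("  cluster-disrupting (negative charge):", x$disrupting, "\n")
  if (nrow(x$lostPolarContacts)) {
    cat("  polar contacts lost:\n")
    print(x$lostPolarContacts[, c("resname", "resno", "distance")],
          row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Write a residue-environment report as TSV
#'
#' @param env A [residueEnvironment()] result.
#' @param path Output file.
#' @export
writeEnvironmentTSV <- function(env, path) {
  df <- cbind(focal = paste0(env$focal$resname, env$focal$resno),
              env$neighbors)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Bundled synthetic toy kinase structure
#'
#' Path to a small synthetic PDB file whose geometry reproduces the
#' activation-segment contact motifs used in tests: residue 468 (Phe)
#' placed 4.0 A from residue 600 (Val), Asp 576/594 within 6 A of Thr 599,
#' and a distant Gly 596. These are constructed coordinates, not a
#' deposited structure.
#'
#' @return File path.
#' @export
toyKinasePDB <- function() {
  system.file("extdata", "toy_kinase_synthetic.pdb", package = "rafamp",
              mustWork = TRUE)
}
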