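# Scaffolds, ring systems, fragments and functional groups.
#
# Subgraphs are written back out as V2000 SDF text and re-canonicalized by
# OpenBabel, so every extracted substructure is a canonical SMILES.

# render a subgraph (atom index subset, optional element / bond-order
# overrides) as canonical SMILES via an SDF round trip.
.subgraph_smiles <- function(g, atoms, elem = NULL, orders = NULL,
                             charges = NULL) {
  atoms <- sort(unique(atoms))
  if (!length(atoms)) return("")
  idx <- match(seq_len(g$n), atoms) # old -> new
  keep_bond <- g$bonds$i %in% atoms & g$bonds$j %in% atoms
  bi <- idx[g$bonds$i[keep_bond]]
  bj <- idx[g$bonds$j[keep_bond]]
  bo <- if (is.null(orders)) g$bonds$order[keep_bond] else orders[keep_bond]
  el <- if (is.null(elem)) g$elem[atoms] else elem[atoms]
  ch <- if (is.null(charges)) g$charge[atoms] else charges[atoms]
  chg_code <- integer(length(atoms))
  chg_code[ch == 1] <- 3L; chg_code[ch == 2] <- 2L; chg_code[ch == 3] <- 1L
  chg_code[ch == -1] <- 5L; chg_code[ch == -2] <- 6L; chg_code[ch == -3] <- 7L
  na <- length(atoms); nb <- length(bi)
  atom_lines <- sprintf(
    "%10.4f%10.4f%10.4f %-3s 0%3d  0  0  0  0  0  0  0  0  0  0",
    (seq_len(na) - 1) %% 10, (seq_len(na) - 1) %/% 10, 0, el, chg_code)
  bond_lines <- if (nb) sprintf("%3d%3d%3d  0  0  0  0", bi, bj, bo) else character()
  chg_idx <- which(ch != 0)
  chg_line <- if (length(chg_idx)) {
    paste0("M  CHG", sprintf("%3d", length(chg_idx)),
           paste0(sprintf("%4d%4d", chg_idx, ch[chg_idx]), collapse = ""))
  } else character()
  txt <- paste(c(
    "", " genscore", "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb),
    atom_lines, bond_lines, chg_line, "M  END", "$$$$"), collapse = "\n")
  out <- tryCatch(ChemmineOB::convertFormat("SDF", "CAN", txt),
                  error = function(e) "")
  sub("[\t\n ].*$", "", out)
}

# scaffold atom set: iteratively prune non-ring atoms of degree <= 1, then
# pull exocyclic multiply-bonded substituents (e.g. the carbonyl oxygen of
# a ring ketone) back in.
.scaffold_atoms <- function(g) {
  if (!any(g$ring_atom)) return(integer())
  keep <- rep(TRUE, g$n)
  repeat {
    kb <- keep[g$bonds$i] & keep[g$bonds$j]
    deg <- tabulate(c(g$bonds$i[kb], g$bonds$j[kb]), nbins = g$n)
    drop <- keep & !g$ring_atom & deg <= 1
    if (!any(drop)) break
    keep[drop] <- FALSE
  }
  # re-attach atoms double/triple bonded to the retained frame
  multi <- g$bonds$order >= 2
  repeat {
    add <- (keep[g$bonds$i] & !keep[g$bonds$j] & multi) |
           (keep[g$bonds$j] & !keep[g$bonds$i] & multi)
    if (!any(add)) break
    keep[unique(c(g$bonds$i[add], g$bonds$j[add]))] <- TRUE
  }
  which(keep)
}

#' Bemis-Murcko scaffold
#'
#' Ring systems plus connecting linkers with side chains removed
#' (exocyclic multiply-bonded atoms are retained), returned as canonical
#' SMILES. Acyclic molecules have no scaffold and return `""`.
#'
#' @param mol SMILES or a [parse_smiles()] row; must be valid.
#' @return canonical SMILES of the scaffold, or `""`.
#' @export
murcko_scaffold <- function(mol) {
  smi <- .as_canonical(mol)
  if (is.na(smi)) stop("murcko_scaffold() requires a valid molecule", call. = FALSE)
  key <- paste0("murcko|", smi)
  hit <- .cache_get(key)
  if (!is.null(hit)) return(hit)
  g <- mol_graph(smi)
  if (is.null(g)) return(.cache_set(key, ""))
  atoms <- .scaffold_atoms(g)
  .cache_set(key, .subgraph_smiles(g, atoms))
}

#' Generic (topological) scaffold
#'
#' The Murcko scaffold with every atom replaced by carbon and every bond by
#' a single bond, erasing heteroatoms and bond orders; identical for e.g.
#' benzene, pyridine and cyclohexane.
#'
#' @inheritParams murcko_scaffold
#' @return canonical SMILES of the generic framework, or `""` for acyclic
#'   molecules.
#' @export
topological_scaffold <- function(mol) {
  smi <- .as_canonical(mol)
  if (is.na(smi)) stop("topological_scaffold() requires a valid molecule", call. = FALSE)
  key <- paste0("topo|", smi)
  hit <- .cache_get(key)
  if (!is.null(hit)) return(hit)
  g <- mol_graph(smi)
  if (is.null(g)) return(.cache_set(key, ""))
  atoms <- .scaffold_atoms(g)
  if (!length(atoms)) return(.cache_set(key, ""))
  .cache_set(key, .subgraph_smiles(
    g, atoms,
    elem = rep("C", g$n),
    orders = rep(1L, nrow(g$bonds)),
    charges = rep(0L, g$n)))
}

#' Ring systems, fragments and functional groups of a molecule
#'
#' `ring_systems()` returns the connected components of fused rings
#' (exocyclic multiply-bonded atoms retained, so cyclohexanone keeps its
#' carbonyl). `fragments()` cleaves acyclic single bonds at ring/chain
#' junctions and at heteroatom or carbonyl linkages (amides, esters,
#' ethers, amines) and returns the resulting pieces with at least two heavy
#' atoms. `functional_groups()` matches a shipped catalog of functional
#' group SMARTS (see
#' `system.file("extdata", "functional_groups.tsv", package = "genscore")`)
#' and returns one entry per occurrence. All three return canonical SMILES
#' multisets (character vectors with repeats).
#'
#' @inheritParams murcko_scaffold
#' @return character vector (possibly empty).
#' @export
ring_systems <- function(mol) {
  smi <- .as_canonical(mol)
  if (is.na(smi)) stop("ring_systems() requires a valid molecule", call. = FALSE)
  g <- mol_graph(smi)
  if (is.null(g) || !any(g$ring_atom)) return(character())
  sub <- igraph::subgraph_from_edges(
    g$igraph, which(g$ring_bond), delete.vertices = FALSE)
  comp <- igraph::components(sub)$membership
  out <- character()
  for (cid in unique(comp[g$ring_atom])) {
    atoms <- which(comp == cid & g$ring_atom)
    if (length(atoms) < 3) next
    # retain exocyclic multiply-bonded atoms on this system
    keep <- logical(g$n); keep[atoms] <- TRUE
    multi <- g$bonds$order >= 2
    add <- (keep[g$bonds$i] & !keep[g$bonds$j] & multi) |
           (keep[g$bonds$j] & !keep[g$bonds$i] & multi)
    keep[unique(c(g$bonds$i[add], g$bonds$j[add]))] <- TRUE
    out <- c(out, .subgraph_smiles(g, which(keep)))
  }
  sort(out[nzchar(out)])
}

#' @rdname ring_systems
#' @export
fragments <- function(mol) {
  smi <- .as_canonical(mol)
  if (is.na(smi)) stop("fragments() requires a valid molecule", call. = FALSE)
  g <- mol_graph(smi)
  if (is.null(g) || g$n == 0) return(character())
  if (!nrow(g$bonds)) return(character())
  nbr <- .neighbour_list(g)
  is_carbonyl_c <- vapply(seq_len(g$n), function(i) {
    g$elem[i] == "C" && any(vapply(seq_len(nrow(g$bonds)), function(k) {
      (g$bonds$i[k] == i || g$bonds$j[k] == i) && g$bonds$order[k] == 2 &&
        g$elem[if (g$bonds$i[k] == i) g$bonds$j[k] else g$bonds$i[k]] == "O"
    }, logical(1)))
  }, logical(1))
  cut <- logical(nrow(g$bonds))
  for (k in seq_len(nrow(g$bonds))) {
    if (g$ring_bond[k] || g$bonds$order[k] != 1) next
    i <- g$bonds$i[k]; j <- g$bonds$j[k]
    if (g$deg[i] < 2 || g$deg[j] < 2) next   # keep terminal atoms attached
    junction <- xor(g$ring_atom[i], g$ring_atom[j])
    hetero_link <- (g$elem[i] %in% c("N", "O", "S")) ||
                   (g$elem[j] %in% c("N", "O", "S"))
    acyl <- is_carbonyl_c[i] || is_carbonyl_c[j]
    if (junction || hetero_link || acyl) cut[k] <- TRUE
  }
  sub <- igraph::subgraph_from_edges(g$igraph, which(!cut),
                                     delete.vertices = FALSE)
  comp <- igraph::components(sub)$membership
  out <- character()
  for (cid in unique(comp)) {
    atoms <- which(comp == cid)
    if (length(atoms) < 2) next
    frag <- .subgraph_smiles(g, atoms)
    if (nzchar(frag)) out <- c(out, frag)
  }
  sort(out)
}

# locate a shipped data file (source-tree fallback covers devtools-style use)
.extdata <- function(file) {
  p <- system.file("extdata", file, package = "genscore")
  if (nzchar(p)) p else file.path("inst", "extdata", file)
}

# catalog is read once per session
.fg_catalog <- function() {
  hit <- .cache_get("fg_catalog")
  if (!is.null(hit)) return(hit)
  path <- .extdata("functional_groups.tsv")
  # '#' appears inside SMARTS atom primitives, so comments are recognised
  # only at line starts and the file is split by hand.
  ln <- readLines(path, warn = FALSE)
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  ln <- ln[-1] # header
  parts <- strsplit(ln, "\t", fixed = TRUE)
  tab <- data.frame(
    name = vapply(parts, `[[`, character(1), 1),
    smarts = vapply(parts, `[[`, character(1), 2),
    stringsAsFactors = FALSE
  )
  .cache_set("fg_catalog", tab)
}

#' @rdname ring_systems
#' @export
functional_groups <- function(mol) {
  smi <- .as_canonical(mol)
  if (is.na(smi)) stop("functional_groups() requires a valid molecule", call. = FALSE)
  cat <- .fg_catalog()
  counts <- vapply(cat$smarts, function(p) .smarts_count(smi, p), numeric(1))
  rep(cat$name, counts)
}

# unique-match SMARTS occurrence count for one (canonical) SMILES.
# Goes through OBMol directly: the SDFset route breaks on bond-less
# molecules. A SMARTS that fails to compile raises; the compile check at
# config load uses .smarts_compiles().
.smarts_count <- function(smi, smarts) {
  as.numeric(tryCatch(
    ChemmineOB::forEachMol("SMILES", smi, function(m)
      ChemmineOB::smartsSearch_OB(list(m), smarts, uniqueMatches = TRUE))[[1]],
    error = function(e) stop("invalid SMARTS pattern: ", smarts, call. = FALSE)
  ))
}

.smarts_compiles <- function(smarts) {
  tryCatch({
    ChemmineOB::forEachMol("SMILES", "CC(=O)Nc1ccc(O)cc1", function(m)
      ChemmineOB::smartsSearch_OB(list(m), smarts, uniqueMatches = TRUE))
    TRUE
  }, error = function(e) FALSE)
}

#' All substructure multisets of a molecule
#'
#' Convenience wrapper bundling [fragments()], [functional_groups()] and
#' [ring_systems()].
#'
#' @inheritParams murcko_scaffold
#' @return list with elements `fragments`, `functional_groups`,
#'   `ring_systems`.
#' @export
substructure_sets <- function(mol) {
  list(
    fragments = fragments(mol),
    functional_groups = functional_groups(mol),
    ring_systems = ring_systems(mol)
  )
}
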