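# Molecule parsing, canonicalization and the molecular-graph substrate.
#
# All chemistry perception is delegated to OpenBabel through ChemmineOB /
# ChemmineR; graph algorithms that no installed package exposes (ring
# perception bookkeeping, scaffolds, rotatable-bond paths) operate on the
# atom/bond blocks of the OpenBabel-generated SDF via igraph.

# package-local caches: canonical SMILES -> graph / SDF. Parsing is the
# hottest path of the pipeline and molecules recur heavily across batches.
.genscore_cache <- new.env(parent = emptyenv())

#' Clear the internal molecule cache
#'
#' Canonical forms, molecular graphs and fingerprints are memoised in a
#' package-local environment keyed by canonical SMILES. The cache only ever
#' holds immutable derived data, so clearing is never required for
#' correctness; it frees memory after large runs.
#' @return Invisibly, the number of entries dropped.
#' @export
clear_mol_cache <- function() {
  n <- length(ls(.genscore_cache))
  rm(list = ls(.genscore_cache), envir = .genscore_cache)
  invisible(n)
}

.cache_get <- function(key) {
  if (exists(key, envir = .genscore_cache, inherits = FALSE))
    get(key, envir = .genscore_cache, inherits = FALSE)
  else NULL
}
.cache_set <- function(key, value) {
  assign(key, value, envir = .genscore_cache)
  value
}

#' Parse SMILES and canonicalize
#'
#' Parses one or more SMILES strings with OpenBabel. Malformed input is a
#' value, not an error: unparseable entries come back with `valid = FALSE`
#' and `canonical_smiles = NA`. Canonicalization is idempotent and the
#' canonical form is the isomeric canonical SMILES of the toolkit.
#'
#' @param smiles character vector of SMILES (possibly empty or malformed).
#' @return A data.frame with columns `input_smiles`, `canonical_smiles`
#'   (NA when invalid) and `valid`.
#' @examples
#' \donttest{
#' parse_smiles(c("CCO", "OCC", "C1CC", ""))
#' }
#' @export
parse_smiles <- function(smiles) {
  stopifnot(is.character(smiles))
  can <- vapply(smiles, canonical_smiles_one, character(1), USE.NAMES = FALSE)
  data.frame(
    input_smiles = smiles,
    canonical_smiles = ifelse(is.na(can), NA_character_, can),
    valid = !is.na(can),
    stringsAsFactors = FALSE
  )
}

# canonicalize a single SMILES; NA for anything OpenBabel rejects.
# Conversions are done one molecule at a time: OpenBabel stops a batch at
# the first bad record, which would silently misalign outputs.
canonical_smiles_one <- function(smi) {
  if (is.na(smi)) return(NA_character_)
  smi <- trimws(smi)
  if (!nzchar(smi)) return(NA_character_)
  key <- paste0("can|", smi)
  hit <- .cache_get(key)
  if (!is.null(hit)) return(hit)
  out <- tryCatch(
    ChemmineOB::convertFormat("SMI", "CAN", paste0(smi, "\n")),
    error = function(e) ""
  )
  out <- sub("[\t\n ].*$", "", out)
  res <- if (nzchar(out)) out else NA_character_
  .cache_set(key, res)
}

#' Read a `.smi` file
#'
#' One record per line: a SMILES string followed by an optional
#' whitespace-separated name. Lines starting with `#` and blank lines are
#' skipped.
#'
#' @param path file path.
#' @return data.frame with columns `smiles` and `name` (empty string when
#'   no name column is present).
#' @export
read_smi <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) {
    return(data.frame(smiles = character(), name = character(),
                      stringsAsFactors = FALSE))
  }
  parts <- regmatches(lines, regexpr("[ \t]+", lines), invert = TRUE)
  smiles <- vapply(parts, `[[`, character(1), 1L)
  name <- vapply(parts, function(p) if (length(p) > 1) p[[2]] else "",
                 character(1))
  data.frame(smiles = smiles, name = name, stringsAsFactors = FALSE)
}

#' Write a `.smi` file
#'
#' @param smiles character vector of SMILES.
#' @param path output file path.
#' @param names optional record names written as a second column.
#' @return `path`, invisibly.
#' @export
write_smi <- function(smiles, path, names = NULL) {
  lines <- if (is.null(names)) smiles else paste(smiles, names)
  writeLines(lines, path)
  invisible(path)
}

# ---- molecular graph ------------------------------------------------------

# SDF atom-line charge codes (V2000): 1..7 -> +3,+2,+1,radical,-1,-2,-3
.sdf_charge <- c(3L, 2L, 1L, 0L, -1L, -2L, -3L)

.default_valence <- c(
  B = 3L, C = 4L, N = 3L, O = 2L, F = 1L, Si = 4L, P = 3L, S = 2L,
  Cl = 1L, Br = 1L, I = 1L, Se = 2L, H = 1L
)

# Build the heavy-atom graph of a (canonical) SMILES. Returns NULL on
# failure. Fields:
#   n, elem, charge, hcount  - per atom
#   bonds: data.frame(i, j, order)
#   ring_atom, ring_bond     - cycle membership (non-bridge edges)
#   arom_atom                - membership of a perceived aromatic ring
#   sssr                     - list of integer atom cycles (smallest set)
#   deg                      - heavy-atom degree
#   sdf                      - the underlying ChemmineR SDF object
mol_graph <- function(smi) {
  key <- paste0("graph|", smi)
  hit <- .cache_get(key)
  if (!is.null(hit)) return(hit)
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(smi)),
    error = function(e) NULL
  )
  if (is.null(sdf)) return(NULL)
  g <- .graph_from_sdf(sdf[[1]])
  g$sdf <- sdf
  .cache_set(key, g)
}

.graph_from_sdf <- function(sdfobj) {
  ab <- ChemmineR::atomblock(sdfobj)
  bb <- ChemmineR::bondblock(sdfobj)
  n <- nrow(ab)
  elem <- sub("_.*$", "", rownames(ab))
  chg_code <- if ("C6" %in% colnames(ab)) as.integer(ab[, "C6"]) else integer(n)
  charge <- ifelse(chg_code >= 1 & chg_code <= 7, .sdf_charge[pmax(chg_code, 1L)], 0L)
  charge[chg_code == 0 | chg_code > 7] <- 0L
  if (length(bb) == 0 || is.null(dim(bb)) || nrow(bb) == 0 || ncol(bb) < 3) {
    bonds <- data.frame(i = integer(), j = integer(), order = integer())
  } else {
    bonds <- data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
                        order = as.integer(bb[, 3]))
  }
  deg <- tabulate(c(bonds$i, bonds$j), nbins = n)
  valsum <- numeric(n)
  if (nrow(bonds)) {
    for (k in seq_len(nrow(bonds))) {
      o <- bonds$order[k]
      valsum[bonds$i[k]] <- valsum[bonds$i[k]] + o
      valsum[bonds$j[k]] <- valsum[bonds$j[k]] + o
    }
  }
  defv <- unname(.default_valence[elem])
  defv[is.na(defv)] <- 0L
  hcount <- pmax(0, defv + charge - valsum)

  ig <- igraph::graph_from_data_frame(
    if (nrow(bonds)) bonds[, 1:2] else data.frame(i = integer(), j = integer()),
    directed = FALSE, vertices = data.frame(name = seq_len(n))
  )
  ring_bond <- logical(nrow(bonds))
  if (nrow(bonds)) {
    br <- igraph::bridges(ig)
    ring_bond <- !(seq_len(nrow(bonds)) %in% as.integer(br))
  }
  ring_atom <- logical(n)
  if (any(ring_bond)) {
    ring_atom[unique(c(bonds$i[ring_bond], bonds$j[ring_bond]))] <- TRUE
  }
  rings <- .perceive_rings(sdfobj, n)
  g <- list(
    n = n, elem = elem, charge = charge, hcount = hcount,
    bonds = bonds, deg = deg, ring_atom = ring_atom, ring_bond = ring_bond,
    arom_atom = rings$arom_atom, sssr = rings$sssr, igraph = ig
  )
  g
}

# Aromatic rings and an SSSR built greedily (smallest first, GF(2)
# independence over ring-bond incidence). Ring enumeration is capped at
# size 12 to bound the all-rings search on fused systems.
.perceive_rings <- function(sdfobj, n) {
  arom_atom <- logical(n)
  sssr <- list()
  rr <- tryCatch(
    suppressWarnings(ChemmineR::rings(sdfobj, upper = 12, type = "all", arom = TRUE)),
    error = function(e) NULL
  )
  if (is.null(rr) || !length(rr$RINGS)) {
    return(list(arom_atom = arom_atom, sssr = sssr))
  }
  cycles <- lapply(rr$RINGS, function(at) as.integer(sub("^.*_", "", at)))
  arom <- rr$AROMATIC
  for (k in seq_along(cycles)) {
    if (isTRUE(arom[[k]])) arom_atom[cycles[[k]]] <- TRUE
  }
  # greedy SSSR: candidate cycles smallest first, kept when independent in
  # GF(2) edge space (Gaussian elimination, basis in echelon form keyed by
  # the lexicographically smallest edge).
  edge_key <- function(cyc) {
    nxt <- c(cyc[-1], cyc[1])
    sort(paste(pmin(cyc, nxt), pmax(cyc, nxt), sep = "-"))
  }
  xor_set <- function(a, b) {
    u <- c(a, b)
    sort(u[!(duplicated(u) | duplicated(u, fromLast = TRUE))])
  }
  basis <- list() # named by leading edge, values sorted edge sets
  for (k in order(lengths(cycles))) {
    w <- edge_key(cycles[[k]])
    repeat {
      if (!length(w)) break
      b <- basis[[w[1]]]
      if (is.null(b)) break
      w <- xor_set(w, b)
    }
    if (length(w)) {
      basis[[w[1]]] <- w
      sssr[[length(sssr) + 1]] <- cycles[[k]]
    }
  }
  list(arom_atom = arom_atom, sssr = sssr)
}

# Count of SSSR rings whose size exceeds `larger_than`.
.count_large_rings <- function(g, larger_than = 6L) {
  sum(lengths(g$sssr) > larger_than)
}

# Aromatic SSSR ring count: every ring atom flagged aromatic.
.aromatic_ring_count <- function(g) {
  if (!length(g$sssr)) return(0L)
  sum(vapply(g$sssr, function(cyc) all(g$arom_atom[cyc]), logical(1)))
}
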