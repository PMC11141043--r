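# Physicochemical descriptors, QED, a native synthetic-accessibility
# estimate, penalised logP and the consecutive-rotatable-bond descriptor.
#
# MW, logP, TPSA, HBD and HBA come from OpenBabel; graph-derived counts
# (rings, rotatable bonds, charge) are computed on the molecular graph.

.descriptor_names <- c("MW", "logP", "TPSA", "HBD", "HBA", "RotatableBonds",
                       "AromaticRings", "RingCount", "HeavyAtoms",
                       "FormalCharge", "QED", "SA")

#' Supported descriptor names
#' @return character vector of names accepted by [calc_descriptors()].
#' @export
descriptor_names <- function() .descriptor_names

.ob_props <- function(smi) {
  key <- paste0("prop|", smi)
  hit <- .cache_get(key)
  if (!is.null(hit)) return(hit)
  p <- ChemmineOB::forEachMol("SMILES", smi, function(m)
    ChemmineOB::prop_OB(list(m)))[[1]]
  .cache_set(key, p)
}

#' Physicochemical descriptors
#'
#' Units: MW in Da, TPSA in square Angstrom; HBD/HBA follow the toolkit's
#' Lipinski-style donor/acceptor counts; `RingCount` is the SSSR size;
#' `RotatableBonds` counts non-ring single bonds between two non-terminal
#' heavy atoms excluding amide C-N; `QED` is the quantitative estimate of
#' drug-likeness (see [qed()]); `SA` the native synthetic-accessibility
#' estimate (see [sa_score()]).
#'
#' @param mol SMILES or a [parse_smiles()] row; must be valid.
#' @param names descriptors to compute, a subset of [descriptor_names()].
#' @return named numeric vector.
#' @examples
#' \donttest{
#' calc_descriptors("CCO", c("MW", "HBD", "logP"))
#' }
#' @export
calc_descriptors <- function(mol, names = descriptor_names()) {
  smi <- .as_canonical(mol)
  if (is.na(smi)) stop("calc_descriptors() requires a valid molecule", call. = FALSE)
  unknown <- setdiff(names, .descriptor_names)
  if (length(unknown)) {
    stop("unknown descriptor(s): ", paste(unknown, collapse = ", "),
         "; supported: ", paste(.descriptor_names, collapse = ", "),
         call. = FALSE)
  }
  p <- .ob_props(smi)
  g <- mol_graph(smi)
  val <- function(nm) {
    switch(nm,
      MW = p$MW,
      logP = p$logP,
      TPSA = p$TPSA,
      HBD = p$HBD,
      HBA = p$HBA2,
      RotatableBonds = length(.rotatable_bonds(g)),
      AromaticRings = .aromatic_ring_count(g),
      RingCount = length(g$sssr),
      HeavyAtoms = g$n,
      FormalCharge = sum(g$charge),
      QED = qed(smi),
      SA = sa_score(smi)
    )
  }
  out <- vapply(names, val, numeric(1))
  names(out) <- names
  out
}

# indices (rows of g$bonds) of rotatable bonds: acyclic single bonds
# between two heavy atoms of degree >= 2, excluding amide C-N and bonds to
# triple-bond termini (the standard rotatable-bond SMARTS
# [!$(*#*)&!D1]-&!@[!$(*#*)&!D1], amide-excluded, expressed on the graph).
.rotatable_bonds <- function(g) {
  if (is.null(g) || !nrow(g$bonds)) return(integer())
  nbr <- .neighbour_list(g)
  in_triple <- logical(g$n)
  tb <- g$bonds$order == 3
  if (any(tb)) in_triple[unique(c(g$bonds$i[tb], g$bonds$j[tb]))] <- TRUE
  is_amide_cn <- function(i, j) {
    # C-N where the C carries a double-bonded O
    for (pair in list(c(i, j), c(j, i))) {
      ci <- pair[1]; ni <- pair[2]
      if (g$elem[ci] == "C" && g$elem[ni] == "N") {
        for (k in seq_len(nrow(g$bonds))) {
          if (g$bonds$order[k] == 2 &&
              ((g$bonds$i[k] == ci && g$elem[g$bonds$j[k]] == "O") ||
               (g$bonds$j[k] == ci && g$elem[g$bonds$i[k]] == "O"))) {
            return(TRUE)
          }
        }
      }
    }
    FALSE
  }
  out <- integer()
  for (k in seq_len(nrow(g$bonds))) {
    if (g$ring_bond[k] || g$bonds$order[k] != 1) next
    i <- g$bonds$i[k]; j <- g$bonds$j[k]
    if (g$deg[i] < 2 || g$deg[j] < 2) next
    if (in_triple[i] || in_triple[j]) next
    if (is_amide_cn(i, j)) next
    out <- c(out, k)
  }
  out
}

#' Maximum number of consecutive rotatable bonds
#'
#' Length (in bonds) of the longest simple path through the subgraph formed
#' by rotatable bonds only. Flexible linkers score high; benzene scores 0.
#'
#' @inheritParams calc_descriptors
#' @return integer path length in bonds.
#' @export
max_consecutive_rotatable_bonds <- function(mol) {
  smi <- .as_canonical(mol)
  if (is.na(smi)) stop("max_consecutive_rotatable_bonds() requires a valid molecule",
                       call. = FALSE)
  g <- mol_graph(smi)
  rb <- .rotatable_bonds(g)
  if (!length(rb)) return(0L)
  edges <- g$bonds[rb, , drop = FALSE]
  # longest simple path by DFS over the (sparse, near-tree) rotor subgraph
  nodes <- sort(unique(c(edges$i, edges$j)))
  adj <- lapply(nodes, function(v)
    c(edges$j[edges$i == v], edges$i[edges$j == v]))
  names(adj) <- as.character(nodes)
  best <- 0L
  dfs <- function(v, visited, len) {
    best <<- max(best, len)
    for (w in adj[[as.character(v)]]) {
      if (!w %in% visited) dfs(w, c(visited, w), len + 1L)
    }
  }
  for (v in nodes) dfs(v, v, 0L)
  as.integer(best)
}

# ---- QED ------------------------------------------------------------------

# Asymmetric double sigmoid desirability parameters for the eight QED
# descriptors (Bickerton et al. quantitative estimate of drug-likeness).
.qed_ads <- list(
  MW     = c(a = 2.817065973, b = 392.5754953, c = 290.7489764, d = 2.419764353,
             e = 49.22325677, f = 65.37051707, dmax = 104.9805561),
  ALOGP  = c(a = 3.172690585, b = 137.8624751, c = 2.534937431, d = 4.581497897,
             e = 0.822739154, f = 0.576295591, dmax = 131.3186604),
  HBA    = c(a = 2.948620388, b = 160.4605972, c = 3.615294657, d = 4.435986202,
             e = 0.290141953, f = 1.300669958, dmax = 148.7763046),
  HBD    = c(a = 1.618662227, b = 1010.051101, c = 0.985094388, d = 0.000000001,
             e = 0.713820843, f = 0.920922555, dmax = 258.1632616),
  PSA    = c(a = 1.876861559, b = 125.2232657, c = 62.90773554, d = 87.83366614,
             e = 12.01999824, f = 28.51324732, dmax = 104.5686167),
  ROTB   = c(a = 0.010000000, b = 272.4121427, c = 2.558379970, d = 1.565547684,
             e = 1.271567166, f = 2.758063707, dmax = 105.4420403),
  AROM   = c(a = 3.217788970, b = 957.7374108, c = 2.274627939, d = 0.000000001,
             e = 1.317690384, f = 0.375760881, dmax = 312.3372610),
  ALERTS = c(a = 0.010000000, b = 1199.094025, c = -0.09002883, d = 0.000000001,
             e = 0.185904477, f = 0.875193782, dmax = 417.7253140)
)
.qed_weights <- c(MW = 0.66, ALOGP = 0.46, HBA = 0.05, HBD = 0.61, PSA = 0.06,
                  ROTB = 0.65, AROM = 0.48, ALERTS = 0.95)

.ads <- function(x, p) {
  v <- p[["a"]] +
    p[["b"]] / (1 + exp(-(x - p[["c"]] + p[["d"]] / 2) / p[["e"]])) *
      (1 - 1 / (1 + exp(-(x - p[["c"]] - p[["d"]] / 2) / p[["f"]])))
  max(v / p[["dmax"]], 1e-6)
}

#' Quantitative estimate of drug-likeness (QED)
#'
#' Weighted geometric mean of eight desirability functions (MW, logP, HBA,
#' HBD, polar surface area, rotatable bonds, aromatic rings, structural
#' alerts) with the published asymmetric-double-sigmoid parameters. The
#' underlying logP/TPSA values come from OpenBabel and the alert count from
#' this package's curated alert list, so absolute values differ slightly
#' from implementations built on other toolkits.
#'
#' @inheritParams calc_descriptors
#' @return QED in (0, 1].
#' @export
qed <- function(mol) {
  smi <- .as_canonical(mol)
  if (is.na(smi)) stop("qed() requires a valid molecule", call. = FALSE)
  p <- .ob_props(smi)
  g <- mol_graph(smi)
  alerts <- .alert_hits(smi, .alert_catalog("mcf"))
  x <- c(MW = p$MW, ALOGP = p$logP, HBA = p$HBA2, HBD = p$HBD, PSA = p$TPSA,
         ROTB = length(.rotatable_bonds(g)), AROM = .aromatic_ring_count(g),
         ALERTS = alerts)
  d <- vapply(names(x), function(nm) .ads(x[[nm]], .qed_ads[[nm]]), numeric(1))
  exp(sum(.qed_weights * log(d)) / sum(.qed_weights))
}

# number of alert patterns (not occurrences) hit by the molecule
.alert_hits <- function(smi, patterns) {
  sum(vapply(patterns, function(p) .smarts_count(smi, p) > 0, logical(1)))
}

# read a one-SMARTS-per-line alert file (optional tab-separated name)
.read_smarts_file <- function(path) {
  ln <- readLines(path, warn = FALSE)
  ln <- trimws(ln)
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  vapply(strsplit(ln, "\t", fixed = TRUE), `[[`, character(1), 1)
}

.alert_catalog <- function(which = c("mcf", "pains")) {
  which <- match.arg(which)
  key <- paste0("alerts|", which)
  hit <- .cache_get(key)
  if (!is.null(hit)) return(hit)
  .cache_set(key, .read_smarts_file(.extdata(paste0(which, "_alerts.txt"))))
}

# ---- synthetic accessibility ---------------------------------------------

#' Synthetic-accessibility estimate
#'
#' A native complexity-based estimate on the conventional 1 (easy) to 10
#' (hard) scale, combining molecule size, ring-system complexity
#' (fused/bridged/spiro atoms), macrocycles, stereo-centre surrogates
#' (carbons with four distinct heavy substituent classes) and heteroatom
#' load. It intentionally omits the fragment-frequency contribution of
#' database-driven scores, which requires a large precomputed corpus; the
#' estimate is monotone in the same structural penalties and is used by
#' [penalised_logp()].
#'
#' @inheritParams calc_descriptors
#' @return score in [1, 10].
#' @export
sa_score <- function(mol) {
  smi <- .as_canonical(mol)
  if (is.na(smi)) stop("sa_score() requires a valid molecule", call. = FALSE)
  g <- mol_graph(smi)
  n <- g$n
  if (n == 0) return(1)
  # size penalty: gentle past 30 heavy atoms
  size_pen <- max(0, n - 30) ^ 1.005 - max(0, n - 30)
  size_term <- 0.04 * n
  ring_atoms <- sum(g$ring_atom)
  ring_bonds <- sum(g$ring_bond)
  # fusion penalty: extra ring bonds beyond one SSSR ring's worth per atom
  fusion <- max(0, ring_bonds - ring_atoms)
  macro <- sum(lengths(g$sssr) > 8)
  hetero <- sum(!g$elem %in% c("C", "H")) / max(1, n)
  nbr <- .neighbour_list(g)
  quart <- sum(vapply(seq_len(n), function(i)
    g$elem[i] == "C" && g$deg[i] == 4, logical(1)))
  spiro <- sum(vapply(seq_len(n), function(i) {
    if (!g$ring_atom[i]) return(FALSE)
    rb <- sum(vapply(seq_len(nrow(g$bonds)), function(k)
      g$ring_bond[k] && (g$bonds$i[k] == i || g$bonds$j[k] == i), logical(1)))
    rb >= 4
  }, logical(1)))
  raw <- 1 + size_term + size_pen + 0.6 * fusion + 0.8 * macro +
    1.5 * hetero + 0.25 * quart + 0.5 * spiro
  min(10, max(1, raw))
}

#' Penalised logP
#'
#' `logP - SA - ringPenalty`, where `ringPenalty` is the number of SSSR
#' rings larger than six atoms. No training-set z-normalisation is applied:
#' the raw difference is returned.
#'
#' @inheritParams calc_descriptors
#' @return numeric score (unbounded).
#' @export
penalised_logp <- function(mol) {
  smi <- .as_canonical(mol)
  if (is.na(smi)) stop("penalised_logp() requires a valid molecule", call. = FALSE)
  p <- .ob_props(smi)
  g <- mol_graph(smi)
  p$logP - sa_score(smi) - .count_large_rings(g)
}
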