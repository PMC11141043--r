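# Fingerprints and binary similarity coefficients.
#
# ECFP (Morgan), MACCS and the Daylight-style path fingerprint are computed
# by OpenBabel; atom-pair, topological-torsion, Avalon-style feature and
# 2-point pharmacophore fingerprints are hashed natively from the molecular
# graph (no installed R package provides them).

#' Fingerprint specification
#'
#' @param family one of `"ECFP"`, `"AtomPair"`, `"TopologicalTorsion"`,
#'   `"MACCS"`, `"Path"` (alias `"RDKitPath"`: Daylight-style hashed linear
#'   paths, computed by OpenBabel), `"Avalon"` (native feature-class
#'   fingerprint: paths, ring sizes and augmented atoms) or `"Pharm2D"`
#'   (native 2-point topological pharmacophore pairs).
#' @param radius Morgan radius, ECFP only (diameter = 2 * radius); default 2
#'   ("ECFP4").
#' @param n_bits folded length; default 2048. MACCS is a fixed 256-bit key
#'   set and ignores `n_bits`.
#' @param counted keep per-feature counts (AtomPair / TopologicalTorsion
#'   only). Counted vectors use the min/max count generalisation for
#'   Tanimoto and are binarized for every other coefficient.
#' @return An object of class `fp_spec`.
#' @export
fp_spec <- function(family = "ECFP", radius = 2L, n_bits = 2048L,
                    counted = FALSE) {
  family <- switch(family,
    RDKitPath = "Path",
    family
  )
  families <- c("ECFP", "AtomPair", "TopologicalTorsion", "MACCS", "Path",
                "Avalon", "Pharm2D")
  if (!family %in% families) {
    stop("unknown fingerprint family '", family, "'; use one of: ",
         paste(families, collapse = ", "), call. = FALSE)
  }
  radius <- as.integer(radius)
  n_bits <- as.integer(n_bits)
  stopifnot(n_bits > 0, radius >= 0)
  if (family == "ECFP" && radius > 5)
    stop("ECFP radius must be <= 5", call. = FALSE)
  if (counted && !family %in% c("AtomPair", "TopologicalTorsion"))
    stop("counted fingerprints are supported for AtomPair and TopologicalTorsion only",
         call. = FALSE)
  if (family == "MACCS") n_bits <- 256L
  structure(list(family = family, radius = radius, n_bits = n_bits,
                 counted = counted), class = "fp_spec")
}

#' @export
print.fp_spec <- function(x, ...) {
  cat("<fp_spec> ", x$family,
      if (x$family == "ECFP") paste0(" (radius ", x$radius, ")"),
      ", ", x$n_bits, " bits",
      if (x$counted) ", counted", "\n", sep = "")
  invisible(x)
}

# deterministic 31-bit string hash (djb2 with modular arithmetic kept in
# double precision: 2^31 * 33 + 255 < 2^53).
.hash31 <- function(s) {
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 2147483647
  h
}

.new_bitfp <- function(on, n_bits, counts = NULL) {
  structure(list(on = sort(unique(as.integer(on))), counts = counts,
                 n_bits = as.integer(n_bits)), class = "bitfp")
}

#' @export
print.bitfp <- function(x, ...) {
  cat("<bitfp> ", length(x$on), "/", x$n_bits, " bits on",
      if (!is.null(x$counts)) " (counted)", "\n", sep = "")
  invisible(x)
}

# fold a 0-based bit index vector to n bits
.fold_bits <- function(bits, n) sort(unique(bits %% n))

.ob_fingerprint <- function(smi, type) {
  v <- ChemmineOB::forEachMol("SMILES", smi, function(m)
    ChemmineOB::fingerprint_OB(list(m), type))[[1]]
  which(v != 0) - 1L
}

#' Compute a molecular fingerprint
#'
#' Deterministic for a given canonical SMILES and spec: fingerprints are
#' computed from the canonical form, never the raw input.
#'
#' @param mol a SMILES string (canonicalized internally) or one row of
#'   [parse_smiles()] output.
#' @param spec an [fp_spec()].
#' @return A `bitfp`: 0-based `on` bit positions in `[0, n_bits)`, optional
#'   feature `counts`, and `n_bits`.
#' @export
fingerprint <- function(mol, spec = fp_spec()) {
  smi <- .as_canonical(mol)
  if (is.na(smi)) stop("fingerprint() requires a valid molecule", call. = FALSE)
  key <- paste0("fp|", spec$family, "|", spec$radius, "|", spec$n_bits, "|",
                spec$counted, "|", smi)
  hit <- .cache_get(key)
  if (!is.null(hit)) return(hit)
  fp <- switch(spec$family,
    ECFP = {
      bits <- .ob_fingerprint(smi, paste0("ECFP", 2L * spec$radius))
      .new_bitfp(.fold_bits(bits, spec$n_bits), spec$n_bits)
    },
    MACCS = .new_bitfp(.ob_fingerprint(smi, "MACCS"), 256L),
    Path = {
      bits <- .ob_fingerprint(smi, "FP2")
      if (spec$n_bits < 1024L) bits <- .fold_bits(bits, spec$n_bits)
      .new_bitfp(bits, max(spec$n_bits, 1024L))
    },
    AtomPair = .fp_atom_pair(smi, spec),
    TopologicalTorsion = .fp_torsion(smi, spec),
    Avalon = .fp_avalon(smi, spec),
    Pharm2D = .fp_pharm2d(smi, spec)
  )
  .cache_set(key, fp)
}

# accept a SMILES string, a parse_smiles() row, or a list with
# canonical_smiles
.as_canonical <- function(mol) {
  if (is.character(mol) && length(mol) == 1) return(canonical_smiles_one(mol))
  if (is.data.frame(mol)) {
    stopifnot(nrow(mol) == 1)
    return(if (isTRUE(mol$valid)) mol$canonical_smiles else NA_character_)
  }
  if (is.list(mol) && !is.null(mol$canonical_smiles)) {
    return(if (isTRUE(mol$valid)) mol$canonical_smiles else NA_character_)
  }
  stop("cannot interpret 'mol' as a molecule", call. = FALSE)
}

# atom type used by the native pair/torsion fingerprints
.ap_atom_type <- function(g, i) {
  paste0(g$elem[i], ":", g$deg[i], ":", as.integer(g$arom_atom[i]))
}

.counts_to_fp <- function(keys, spec) {
  n_bits <- spec$n_bits
  counted <- isTRUE(spec$counted)
  if (!length(keys)) {
    return(.new_bitfp(integer(), n_bits, counts = if (counted) numeric() else NULL))
  }
  tab <- table(keys)
  bits <- vapply(names(tab), .hash31, numeric(1)) %% n_bits
  counts <- NULL
  if (counted) {
    agg <- tapply(as.numeric(tab), bits, sum)
    counts <- as.numeric(agg)
    names(counts) <- names(agg)
    counts <- counts[order(as.numeric(names(counts)))]
  }
  .new_bitfp(bits, n_bits, counts = counts)
}

.fp_atom_pair <- function(smi, spec) {
  g <- mol_graph(smi)
  if (is.null(g) || g$n == 0) return(.new_bitfp(integer(), spec$n_bits))
  keys <- character()
  if (g$n > 1) {
    d <- igraph::distances(g$igraph)
    for (i in seq_len(g$n - 1)) {
      for (j in seq(i + 1, g$n)) {
        if (!is.finite(d[i, j])) next
        tt <- sort(c(.ap_atom_type(g, i), .ap_atom_type(g, j)))
        keys <- c(keys, paste0("AP|", tt[1], "|", d[i, j], "|", tt[2]))
      }
    }
  } else {
    keys <- paste0("AP|", .ap_atom_type(g, 1), "|0|", .ap_atom_type(g, 1))
  }
  .counts_to_fp(keys, spec)
}

.fp_torsion <- function(smi, spec) {
  g <- mol_graph(smi)
  if (is.null(g) || !nrow(g$bonds)) return(.new_bitfp(integer(), spec$n_bits))
  nbr <- .neighbour_list(g)
  keys <- character()
  for (k in seq_len(nrow(g$bonds))) {
    b <- g$bonds$i[k]; c2 <- g$bonds$j[k]
    for (a in setdiff(nbr[[b]], c2)) {
      for (d in setdiff(nbr[[c2]], b)) {
        if (a == d) next
        fwd <- vapply(c(a, b, c2, d), function(i) .ap_atom_type(g, i), character(1))
        rev <- rev(fwd)
        t <- if (paste(fwd, collapse = "|") <= paste(rev, collapse = "|")) fwd else rev
        keys <- c(keys, paste0("TT|", paste(t, collapse = "|")))
      }
    }
  }
  .counts_to_fp(keys, spec)
}

.neighbour_list <- function(g) {
  nbr <- vector("list", g$n)
  if (nrow(g$bonds)) {
    for (k in seq_len(nrow(g$bonds))) {
      i <- g$bonds$i[k]; j <- g$bonds$j[k]
      nbr[[i]] <- c(nbr[[i]], j)
      nbr[[j]] <- c(nbr[[j]], i)
    }
  }
  nbr
}

# Avalon-style feature-class fingerprint: linear paths (length 0..7 bonds,
# with element/aromaticity and bond orders), SSSR ring sizes, and augmented
# atoms (atom plus sorted neighbour bond/element pairs). Native design;
# not bit-compatible with the Avalon toolkit.
.fp_avalon <- function(smi, spec) {
  g <- mol_graph(smi)
  if (is.null(g) || g$n == 0) return(.new_bitfp(integer(), spec$n_bits))
  nbr <- .neighbour_list(g)
  border <- new.env(parent = emptyenv())
  if (nrow(g$bonds)) {
    for (k in seq_len(nrow(g$bonds))) {
      assign(paste(g$bonds$i[k], g$bonds$j[k]), g$bonds$order[k], envir = border)
      assign(paste(g$bonds$j[k], g$bonds$i[k]), g$bonds$order[k], envir = border)
    }
  }
  at <- function(i) paste0(g$elem[i], as.integer(g$arom_atom[i]))
  keys <- paste0("AV0|", vapply(seq_len(g$n), at, character(1)))
  # DFS path enumeration up to 7 bonds, canonical direction
  paths <- character()
  walk <- function(path) {
    lab <- character(0)
    for (q in seq_along(path)) {
      lab <- c(lab, at(path[q]))
      if (q < length(path))
        lab <- c(lab, get(paste(path[q], path[q + 1]), envir = border))
    }
    fwd <- paste(lab, collapse = "~")
    bwd <- paste(rev(lab), collapse = "~")
    paths <<- c(paths, paste0("AVP|", if (fwd <= bwd) fwd else bwd))
    if (length(path) <= 7) {
      for (nx in setdiff(nbr[[path[length(path)]]], path)) walk(c(path, nx))
    }
  }
  for (i in seq_len(g$n)) walk(i)
  keys <- c(keys, paths)
  if (length(g$sssr)) keys <- c(keys, paste0("AVR|", lengths(g$sssr)))
  aug <- vapply(seq_len(g$n), function(i) {
    env <- sort(vapply(nbr[[i]], function(j)
      paste0(get(paste(i, j), envir = border), at(j)), character(1)))
    paste0("AVA|", at(i), "(", paste(env, collapse = ","), ")")
  }, character(1))
  .counts_to_fp(c(keys, aug), list(n_bits = spec$n_bits, counted = FALSE))
}

# pharmacophore feature assignment on the graph:
# donor: N/O bearing >=1 H; acceptor: N/O (not positively charged and not
# aromatic N with 3 connections); aromatic: aromatic atom; pos/neg: formal
# charge sign; hydrophobe: C with no heteroatom neighbour.
.pharm_features <- function(g) {
  nbr <- .neighbour_list(g)
  feats <- vector("list", 0)
  add <- function(f, i) feats[[length(feats) + 1]] <<- list(f = f, i = i)
  for (i in seq_len(g$n)) {
    e <- g$elem[i]
    if (e %in% c("N", "O") && g$hcount[i] >= 1) add("D", i)
    if (e %in% c("N", "O") && g$charge[i] <= 0 &&
        !(e == "N" && g$arom_atom[i] && g$deg[i] >= 3)) add("A", i)
    if (g$arom_atom[i]) add("R", i)
    if (g$charge[i] > 0) add("P", i)
    if (g$charge[i] < 0) add("G", i)
    if (e == "C" && !g$arom_atom[i] &&
        all(g$elem[nbr[[i]]] %in% c("C", "H"))) add("H", i)
  }
  feats
}

.fp_pharm2d <- function(smi, spec) {
  g <- mol_graph(smi)
  if (is.null(g) || g$n == 0) return(.new_bitfp(integer(), spec$n_bits))
  feats <- .pharm_features(g)
  if (length(feats) < 2) return(.new_bitfp(integer(), spec$n_bits))
  d <- igraph::distances(g$igraph)
  bin <- function(x) findInterval(x, c(0, 3, 6, 9)) # 1..4 distance bins
  keys <- character()
  for (p in seq_len(length(feats) - 1)) {
    for (q in seq(p + 1, length(feats))) {
      dist <- d[feats[[p]]$i, feats[[q]]$i]
      if (!is.finite(dist)) next
      ff <- sort(c(feats[[p]]$f, feats[[q]]$f))
      keys <- c(keys, paste0("PH|", ff[1], ff[2], "|", bin(dist)))
    }
  }
  .counts_to_fp(keys, list(n_bits = spec$n_bits, counted = FALSE))
}

# ---- similarity coefficients ---------------------------------------------

#' Binary fingerprint similarity
#'
#' Coefficients over two bit vectors with `a = |A|`, `b = |B|`,
#' `c = |A & B|`, `d` = bits off in both, `n` = vector length:
#' \itemize{
#' \item Tanimoto: `c / (a + b - c)` (counted vectors: sum-min / sum-max)
#' \item Dice: `2c / (a + b)`
#' \item Cosine: `c / sqrt(a b)`
#' \item AllBit: `(c + d) / n` (fraction of positions that agree)
#' \item OnBit: `c / (a + b - c)` on on-bits only (equals Tanimoto for
#'   binary vectors; kept as a named measure)
#' \item Asymmetric: `c / min(a, b)`
#' \item BraunBlanquet: `c / max(a, b)`
#' \item Kulczynski: `c (a + b) / (2 a b)`
#' \item McConnaughey: `(c (a + b) - a b) / (a b)`, range [-1, 1]
#' \item Russel: `c / n`
#' \item RogotGoldberg: `c / (a + b) + d / (2n - a - b)`
#' \item Sokal: `c / (2a + 2b - 3c)`
#' }
#' Conventions for degenerate inputs: when both vectors are empty every
#' on-bit-based coefficient is 0 (AllBit and RogotGoldberg still see the
#' agreeing off bits).
#'
#' @param a,b `bitfp` objects built with the same spec.
#' @param measure coefficient name (case and punctuation insensitive, e.g.
#'   `"braun blanquet"`).
#' @return similarity value.
#' @export
similarity <- function(a, b, measure = "Tanimoto") {
  stopifnot(inherits(a, "bitfp"), inherits(b, "bitfp"))
  if (a$n_bits != b$n_bits)
    stop("fingerprints built with different specs (n_bits differ)", call. = FALSE)
  m <- gsub("[^a-z]", "", tolower(measure))
  if (m == "tanimoto" && !is.null(a$counts) && !is.null(b$counts)) {
    keys <- union(names(a$counts), names(b$counts))
    ca <- ifelse(keys %in% names(a$counts), a$counts[keys], 0)
    cb <- ifelse(keys %in% names(b$counts), b$counts[keys], 0)
    ca[is.na(ca)] <- 0; cb[is.na(cb)] <- 0
    s <- sum(pmax(ca, cb))
    return(if (s == 0) 0 else sum(pmin(ca, cb)) / s)
  }
  na <- length(a$on); nb <- length(b$on)
  cc <- length(intersect(a$on, b$on))
  n <- a$n_bits
  dd <- n - na - nb + cc
  zero_guard <- function(num, den) if (den == 0) 0 else num / den
  switch(m,
    tanimoto = zero_guard(cc, na + nb - cc),
    onbit = zero_guard(cc, na + nb - cc),
    dice = zero_guard(2 * cc, na + nb),
    cosine = zero_guard(cc, sqrt(na) * sqrt(nb)),
    allbit = (cc + dd) / n,
    asymmetric = zero_guard(cc, min(na, nb)),
    braunblanquet = zero_guard(cc, max(na, nb)),
    kulczynski = zero_guard(cc * (na + nb), 2 * na * nb),
    mcconnaughey = if (na * nb == 0) 0 else (cc * (na + nb) - na * nb) / (na * nb),
    russel = cc / n,
    rogotgoldberg = zero_guard(cc, na + nb) + zero_guard(dd, 2 * n - na - nb),
    sokal = zero_guard(cc, 2 * na + 2 * nb - 3 * cc),
    stop("unknown similarity measure '", measure, "'", call. = FALSE)
  )
}

#' @rdname similarity
#' @export
similarity_measures <- function() {
  c("Tanimoto", "AllBit", "Asymmetric", "BraunBlanquet", "Cosine",
    "McConnaughey", "Dice", "Kulczynski", "Russel", "OnBit",
    "RogotGoldberg", "Sokal")
}
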