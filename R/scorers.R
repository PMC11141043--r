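# Self-contained scoring functions: descriptors, penalised logP,
# consecutive rotatable bonds, fingerprint/isomer similarity, substructure
# match & filters, applicability domain, and a generic property-model slot.
#
# Each scorer maps one valid molecule to one or more named raw values; the
# manager runs scorers only over valid, unseen canonical SMILES.

.scorer_kinds <- c("descriptors", "penalised_logp",
                   "max_consecutive_rotatable_bonds",
                   "fingerprint_similarity", "isomer_similarity",
                   "substructure_match", "substructure_filter",
                   "applicability_domain", "property_model", "custom")

#' Scorer specification
#'
#' @param name unique prefix for this scorer's output columns.
#' @param kind one of `"descriptors"`, `"penalised_logp"`,
#'   `"max_consecutive_rotatable_bonds"`, `"fingerprint_similarity"`,
#'   `"isomer_similarity"`, `"substructure_match"`,
#'   `"substructure_filter"`, `"applicability_domain"`,
#'   `"property_model"`, `"custom"`.
#' @param ... kind-specific parameters:
#' \describe{
#' \item{descriptors}{`names`: subset of [descriptor_names()].}
#' \item{fingerprint_similarity}{`ref_smiles` (character vector) or
#'   `ref_file` (`.smi` path); `fingerprint` (an [fp_spec()] or list of its
#'   arguments); `measure`; `reduce` (`"max"` or `"mean"`).}
#' \item{isomer_similarity}{`formula`, e.g. `"C9H13NO3"`.}
#' \item{substructure_match / substructure_filter}{`smarts` (character
#'   vector) or `smarts_file`; for match, `mode` `"any"` (default) or
#'   `"all"`. Filters score 1 when no pattern matches (alert semantics).}
#' \item{applicability_domain}{`model` (a [domain_model()]) or `model_file`
#'   (JSON); `ad_kind`: `"max_similarity"`, `"feature_range"` or
#'   `"physchem_range"`.}
#' \item{property_model}{`intercept`, `coefficients` (named by descriptor),
#'   optional `link = "logistic"`: a transparent linear stand-in for
#'   externally trained property models.}
#' \item{custom}{`fn`: an R function `(canonical_smiles) -> named numeric`;
#'   programmatic use only (not JSON-serialisable).}
#' }
#' @return object of class `scorer_spec`.
#' @export
scorer_spec <- function(name, kind, ...) {
  params <- list(...)
  if (!is.character(name) || !nzchar(name))
    stop("scorer 'name' must be a nonempty string", call. = FALSE)
  if (!kind %in% .scorer_kinds)
    stop("unknown scorer kind '", kind, "'; use one of: ",
         paste(.scorer_kinds, collapse = ", "), call. = FALSE)
  spec <- structure(list(name = name, kind = kind, params = params),
                    class = "scorer_spec")
  .validate_scorer(spec)
  spec
}

# eager validation: bad configs fail at load time, not at scoring time
.validate_scorer <- function(spec) {
  p <- spec$params
  switch(spec$kind,
    descriptors = {
      nms <- p$names %||% descriptor_names()
      bad <- setdiff(nms, descriptor_names())
      if (length(bad))
        stop("scorer '", spec$name, "': unknown descriptor(s) ",
             paste(bad, collapse = ", "), call. = FALSE)
    },
    fingerprint_similarity = {
      refs <- .resolve_ref_smiles(p)
      if (!length(refs))
        stop("scorer '", spec$name, "': empty reference set", call. = FALSE)
      if (!is.null(p$reduce) && !p$reduce %in% c("max", "mean"))
        stop("scorer '", spec$name, "': reduce must be 'max' or 'mean'",
             call. = FALSE)
      m <- p$measure %||% "Tanimoto"
      ok <- gsub("[^a-z]", "", tolower(m)) %in%
        gsub("[^a-z]", "", tolower(similarity_measures()))
      if (!ok) stop("scorer '", spec$name, "': unknown measure '", m, "'",
                    call. = FALSE)
      .resolve_fp_spec(p) # errors on bad fingerprint args
    },
    isomer_similarity = {
      if (is.null(p$formula))
        stop("scorer '", spec$name, "': 'formula' is required", call. = FALSE)
      .parse_formula(p$formula)
    },
    substructure_match = .compile_smarts_params(spec),
    substructure_filter = .compile_smarts_params(spec),
    applicability_domain = {
      model <- .resolve_domain_model(p)
      kinds <- c("max_similarity", "feature_range", "physchem_range")
      if (is.null(p$ad_kind) || !p$ad_kind %in% kinds)
        stop("scorer '", spec$name, "': 'ad_kind' must be one of ",
             paste(kinds, collapse = ", "), call. = FALSE)
      if (p$ad_kind == "max_similarity" && !length(model$fingerprints))
        stop("scorer '", spec$name, "': domain model has no fingerprints",
             call. = FALSE)
      if (p$ad_kind != "max_similarity" && !length(model$feature_mins))
        stop("scorer '", spec$name, "': domain model has no feature bounds",
             call. = FALSE)
    },
    property_model = {
      if (is.null(p$coefficients) || is.null(names(p$coefficients)))
        stop("scorer '", spec$name, "': named 'coefficients' required",
             call. = FALSE)
      bad <- setdiff(names(p$coefficients), descriptor_names())
      if (length(bad))
        stop("scorer '", spec$name, "': coefficients name unknown descriptor(s) ",
             paste(bad, collapse = ", "), call. = FALSE)
    },
    custom = {
      if (!is.function(p$fn))
        stop("scorer '", spec$name, "': 'fn' must be a function", call. = FALSE)
    },
    NULL
  )
  invisible(spec)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.resolve_ref_smiles <- function(p) {
  if (!is.null(p$ref_smiles)) return(p$ref_smiles)
  if (!is.null(p$ref_file)) return(read_smi(p$ref_file)$smiles)
  character()
}

.resolve_fp_spec <- function(p) {
  fpp <- p$fingerprint
  if (inherits(fpp, "fp_spec")) return(fpp)
  if (is.null(fpp)) return(fp_spec())
  do.call(fp_spec, fpp)
}

.compile_smarts_params <- function(spec) {
  p <- spec$params
  pats <- p$smarts %||% if (!is.null(p$smarts_file))
    .read_smarts_file(p$smarts_file) else character()
  if (!length(pats))
    stop("scorer '", spec$name, "': no SMARTS patterns given", call. = FALSE)
  bad <- pats[!vapply(pats, .smarts_compiles, logical(1))]
  if (length(bad))
    stop("scorer '", spec$name, "': invalid SMARTS pattern(s): ",
         paste(bad, collapse = " ; "), call. = FALSE)
  pats
}

#' Column names a scorer will produce
#' @param spec a [scorer_spec()].
#' @return character vector of `{name}_{metric}` raw column names.
#' @export
scorer_columns <- function(spec) {
  p <- spec$params
  switch(spec$kind,
    descriptors = paste0(spec$name, "_", p$names %||% descriptor_names()),
    penalised_logp = paste0(spec$name, "_penalised_logp"),
    max_consecutive_rotatable_bonds = paste0(spec$name, "_max_consec_rotb"),
    fingerprint_similarity = paste0(spec$name, "_similarity"),
    isomer_similarity = paste0(spec$name, "_isomer"),
    substructure_match = paste0(spec$name, "_match"),
    substructure_filter = paste0(spec$name, "_filter"),
    applicability_domain = paste0(spec$name, "_ad"),
    property_model = paste0(spec$name, "_pred"),
    custom = paste0(spec$name, "_", p$metrics %||% "score")
  )
}

#' Run one scorer on one valid molecule
#'
#' @param spec a [scorer_spec()].
#' @param canonical_smiles canonical SMILES of a valid molecule.
#' @return named numeric vector, names as in [scorer_columns()].
#' @export
run_scorer <- function(spec, canonical_smiles) {
  p <- spec$params
  vals <- switch(spec$kind,
    descriptors = calc_descriptors(canonical_smiles, p$names %||% descriptor_names()),
    penalised_logp = penalised_logp(canonical_smiles),
    max_consecutive_rotatable_bonds = max_consecutive_rotatable_bonds(canonical_smiles),
    fingerprint_similarity = {
      fps <- .resolve_fp_spec(p)
      refs <- .resolve_ref_smiles(p)
      fingerprint_similarity(canonical_smiles, refs, fps,
                             p$measure %||% "Tanimoto", p$reduce %||% "max")
    },
    isomer_similarity = isomer_similarity(canonical_smiles, p$formula),
    substructure_match = substructure_score(
      canonical_smiles, p$smarts %||% .read_smarts_file(p$smarts_file),
      if ((p$mode %||% "any") == "all") "match_all" else "match_any"),
    substructure_filter = substructure_score(
      canonical_smiles, p$smarts %||% .read_smarts_file(p$smarts_file), "filter"),
    applicability_domain = applicability(
      canonical_smiles, .resolve_domain_model(p), p$ad_kind),
    property_model = {
      d <- calc_descriptors(canonical_smiles, names(p$coefficients))
      eta <- (p$intercept %||% 0) + sum(unlist(p$coefficients) * d)
      if (identical(p$link, "logistic")) 1 / (1 + exp(-eta)) else eta
    },
    custom = p$fn(canonical_smiles)
  )
  cols <- scorer_columns(spec)
  vals <- as.numeric(vals)
  if (length(vals) != length(cols))
    stop("scorer '", spec$name, "' returned ", length(vals),
         " values for ", length(cols), " columns", call. = FALSE)
  names(vals) <- cols
  vals
}

#' Fingerprint similarity to a reference set
#'
#' @param mol SMILES or [parse_smiles()] row; must be valid.
#' @param ref_smiles nonempty character vector of reference SMILES.
#' @param spec an [fp_spec()].
#' @param measure a [similarity_measures()] name.
#' @param reduce `"max"` (nearest reference) or `"mean"`.
#' @return similarity in [0,1].
#' @export
fingerprint_similarity <- function(mol, ref_smiles, spec = fp_spec(),
                                   measure = "Tanimoto", reduce = "max") {
  if (!length(ref_smiles)) stop("empty reference set", call. = FALSE)
  fp <- fingerprint(mol, spec)
  sims <- vapply(ref_smiles, function(r)
    similarity(fp, fingerprint(r, spec), measure), numeric(1))
  if (reduce == "mean") mean(sims) else max(sims)
}

# molecular formula -> named element counts (hydrogen included)
.parse_formula <- function(formula) {
  f <- gsub("[+-]+[0-9]*$", "", trimws(formula)) # strip charge suffix
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", f)
  if (m[[1]][1] == -1 || sum(attr(m[[1]], "match.length")) != nchar(f))
    stop("cannot parse molecular formula '", formula, "'", call. = FALSE)
  toks <- regmatches(f, m)[[1]]
  el <- sub("[0-9]*$", "", toks)
  ct <- as.integer(sub("^[A-Za-z]+", "", toks))
  ct[is.na(ct)] <- 1L
  tapply(ct, el, sum)
}

#' Isomer similarity to a target molecular formula
#'
#' Geometric mean of per-element Gaussian agreement terms
#' `exp(-(count - target)^2 / 2)` over all elements occurring in either
#' formula, together with a total-heavy-atom term of the same form
#' (sigma = 1 count unit). Exactly 1 iff the element counts match.
#'
#' @param mol SMILES or [parse_smiles()] row; must be valid.
#' @param formula target molecular formula, e.g. `"C9H13NO3"`.
#' @return score in (0, 1].
#' @export
isomer_similarity <- function(mol, formula) {
  smi <- .as_canonical(mol)
  if (is.na(smi)) stop("isomer_similarity() requires a valid molecule", call. = FALSE)
  target <- .parse_formula(formula)
  have <- .parse_formula(.ob_props(smi)$formula)
  els <- union(names(target), names(have))
  gauss <- function(d) exp(-d^2 / 2)
  terms <- vapply(els, function(e) {
    gauss((if (e %in% names(have)) have[[e]] else 0) -
          (if (e %in% names(target)) target[[e]] else 0))
  }, numeric(1))
  heavy <- function(ct) sum(ct[names(ct) != "H"])
  terms <- c(terms, gauss(heavy(have) - heavy(target)))
  prod(terms) ^ (1 / length(terms))
}

#' Substructure match and alert-filter scoring
#'
#' `match_any` scores 1 when at least one SMARTS matches, `match_all` when
#' every pattern matches, and `filter` scores 1 when *no* pattern matches
#' (structural-alert semantics), so
#' `filter(mol, S) == 1 - match_any(mol, S)`.
#'
#' @param mol SMILES or [parse_smiles()] row; must be valid.
#' @param smarts character vector of SMARTS patterns.
#' @param mode `"match_any"`, `"match_all"` or `"filter"`.
#' @return 0 or 1.
#' @export
substructure_score <- function(mol, smarts, mode = "match_any") {
  smi <- .as_canonical(mol)
  if (is.na(smi)) stop("substructure_score() requires a valid molecule", call. = FALSE)
  hits <- vapply(smarts, function(p) .smarts_count(smi, p) > 0, logical(1))
  switch(mode,
    match_any = as.numeric(any(hits)),
    match_all = as.numeric(all(hits)),
    filter = as.numeric(!any(hits)),
    stop("unknown substructure mode '", mode, "'", call. = FALSE)
  )
}

# ---- applicability domain -------------------------------------------------

#' Applicability-domain model
#'
#' Compiled from a training set: fingerprints for `max_similarity` and
#' per-descriptor min/max bounds for the range checks. `feature_range` and
#' `physchem_range` are the same mechanism over two (configurable)
#' descriptor lists.
#'
#' @param training_smiles nonempty character vector of training SMILES.
#' @param descriptors descriptor names whose training ranges define the
#'   domain.
#' @param fp an [fp_spec()] for the similarity check.
#' @return object of class `domain_model`.
#' @export
domain_model <- function(training_smiles,
                         descriptors = c("MW", "logP", "TPSA", "HBD", "HBA"),
                         fp = fp_spec()) {
  parsed <- parse_smiles(training_smiles)
  valid <- parsed$canonical_smiles[parsed$valid]
  if (!length(valid)) stop("empty or fully invalid training set", call. = FALSE)
  fps <- lapply(valid, function(s) fingerprint(s, fp))
  desc <- t(vapply(valid, function(s) calc_descriptors(s, descriptors),
                   numeric(length(descriptors))))
  structure(list(
    fingerprints = fps,
    fp_spec = fp,
    descriptors = descriptors,
    feature_mins = apply(desc, 2, min),
    feature_maxs = apply(desc, 2, max),
    n_training = length(valid)
  ), class = "domain_model")
}

#' @export
print.domain_model <- function(x, ...) {
  cat("<domain_model> ", x$n_training, " training molecules, descriptors: ",
      paste(x$descriptors, collapse = ", "), "\n", sep = "")
  invisible(x)
}

.resolve_domain_model <- function(p) {
  if (inherits(p$model, "domain_model")) return(p$model)
  if (!is.null(p$model_file)) return(read_domain_model(p$model_file))
  if (!is.null(p$training_smiles)) {
    return(domain_model(p$training_smiles,
                        p$descriptors %||% c("MW", "logP", "TPSA", "HBD", "HBA"),
                        .resolve_fp_spec(p)))
  }
  stop("applicability_domain needs 'model', 'model_file' or 'training_smiles'",
       call. = FALSE)
}

#' Applicability-domain score
#'
#' `max_similarity`: maximum Tanimoto to the training fingerprints.
#' `feature_range` / `physchem_range`: fraction of the model's descriptors
#' whose value lies inside the training [min, max].
#'
#' @param mol SMILES or [parse_smiles()] row; must be valid.
#' @param model a [domain_model()].
#' @param kind `"max_similarity"`, `"feature_range"` or `"physchem_range"`.
#' @return score in [0,1].
#' @export
applicability <- function(mol, model, kind = "max_similarity") {
  stopifnot(inherits(model, "domain_model"))
  if (kind == "max_similarity") {
    fp <- fingerprint(mol, model$fp_spec)
    return(max(vapply(model$fingerprints, function(r)
      similarity(fp, r, "Tanimoto"), numeric(1))))
  }
  if (!kind %in% c("feature_range", "physchem_range"))
    stop("unknown applicability kind '", kind, "'", call. = FALSE)
  d <- calc_descriptors(mol, model$descriptors)
  mean(d >= model$feature_mins & d <= model$feature_maxs)
}

#' Serialize / read a domain model as JSON
#'
#' Fingerprints are stored as hex-encoded bit positions; bounds and the
#' fingerprint spec round-trip exactly.
#'
#' @param model a [domain_model()].
#' @param path JSON file path.
#' @return `path` (write) or a `domain_model` (read).
#' @export
write_domain_model <- function(model, path) {
  obj <- list(
    fp_spec = unclass(model$fp_spec),
    descriptors = model$descriptors,
    feature_mins = as.list(model$feature_mins),
    feature_maxs = as.list(model$feature_maxs),
    n_training = model$n_training,
    n_bits = model$fp_spec$n_bits,
    fingerprints = lapply(model$fingerprints, function(f)
      paste(sprintf("%x", f$on), collapse = ","))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_domain_model
#' @export
read_domain_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  fspec <- do.call(fp_spec, obj$fp_spec[c("family", "radius", "n_bits", "counted")])
  fps <- lapply(obj$fingerprints, function(hx) {
    on <- if (nzchar(hx)) strtoi(strsplit(hx, ",")[[1]], 16L) else integer()
    .new_bitfp(on, obj$n_bits)
  })
  structure(list(
    fingerprints = fps,
    fp_spec = fspec,
    descriptors = obj$descriptors,
    feature_mins = unlist(obj$feature_mins),
    feature_maxs = unlist(obj$feature_maxs),
    n_training = obj$n_training
  ), class = "domain_model")
}
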