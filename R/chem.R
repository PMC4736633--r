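# Molecule handling: parsing/cleaning, descriptor computation and Murcko
# frameworks. Everything chemical goes through OpenBabel (ChemmineOB) and
# ChemmineR connection tables; descriptors are 2D/topological analogues of
# the commercial sets commonly used in toxicity QSAR (see the methods
# vignette and moe_descriptor_map()).

# Canonicalize one SMILES; NA_character_ when OpenBabel cannot parse it.
.canon_one <- function(smi) {
  out <- tryCatch(ChemmineOB::convertFormat("SMI", "CAN", smi),
                  error = function(e) "")
  out <- sub("[ \t].*$", "", sub("\n$", "", out))
  if (!nzchar(out)) NA_character_ else out
}

#' Canonicalize SMILES strings
#'
#' @param smiles character vector of SMILES.
#' @return Canonical SMILES; \code{NA} for strings OpenBabel rejects.
#' @export
canonical_smiles <- function(smiles) {
  vapply(as.character(smiles), .canon_one, character(1), USE.NAMES = FALSE)
}

#' Parse and clean a molecule table
#'
#' Validates SMILES, canonicalizes them, removes duplicates (first
#' occurrence by canonical SMILES wins) and drops molecules whose activity
#' falls outside the accepted band (the pLD50 cleaning rule: values below 0
#' or above 7 are far outside the bulk of oral acute toxicity data). Every
#' rejection is logged with a reason code: \code{parse_fail},
#' \code{duplicate} or \code{activity_range} (\code{descriptor_fail} is
#' appended later by \code{\link{featurize_molecules}}).
#'
#' @param records data.frame with columns \code{id}, \code{smiles} and
#'   optionally \code{activity}.
#' @param activity_min,activity_max accepted activity band (defaults 0, 7).
#' @return List with \code{molecules} (cleaned data.frame, canonical
#'   SMILES) and \code{rejections} (data.frame id/reason/detail).
#' @examples
#' \donttest{
#' parse_and_clean(data.frame(id = "m1", smiles = "c1ccccc1",
#'                            activity = 2))
#' }
#' @export
parse_and_clean <- function(records, activity_min = 0, activity_max = 7) {
  .check(is.data.frame(records) && nrow(records) > 0,
         "parse_and_clean: records must be a non-empty data.frame")
  .check(all(c("id", "smiles") %in% names(records)),
         "parse_and_clean: need columns id, smiles")
  .check(!anyDuplicated(records$id), "parse_and_clean: ids must be unique")
  act <- if ("activity" %in% names(records)) {
    as.numeric(records$activity)
  } else {
    rep(NA_real_, nrow(records))
  }
  can <- canonical_smiles(records$smiles)
  reasons <- character(nrow(records))
  reasons[is.na(can)] <- "parse_fail"
  in_range <- is.na(act) | (act >= activity_min & act <= activity_max)
  reasons[reasons == "" & !in_range] <- "activity_range"
  ok <- reasons == ""
  dup <- ok & duplicated(ifelse(ok, can, NA_character_), incomparables = NA)
  reasons[dup] <- "duplicate"
  keep <- reasons == ""
  .check(any(keep), "parse_and_clean: all records rejected")
  rej <- data.frame(id = records$id[!keep], reason = reasons[!keep],
                    detail = records$smiles[!keep],
                    stringsAsFactors = FALSE)
  mols <- data.frame(id = records$id[keep], smiles = can[keep],
                     activity = act[keep], stringsAsFactors = FALSE)
  list(molecules = mols, rejections = rej)
}

# ---- molecular graph utilities -------------------------------------------

# Connection table of one ChemmineR SDF: atoms (element symbols) and an
# edge list with bond orders. smiles2sdf yields hydrogen-suppressed blocks.
.mol_graph <- function(sdf) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- sub("_.*$", "", rownames(ab))
  n <- nrow(ab)
  edges <- if (is.null(dim(bb)) || nrow(bb) == 0) {
    matrix(integer(0), 0L, 3L)
  } else {
    cbind(as.integer(bb[, 1L]), as.integer(bb[, 2L]), as.integer(bb[, 3L]))
  }
  deg <- tabulate(c(edges[, 1L], edges[, 2L]), n)
  list(elements = elements, n = n, edges = edges, degree = deg)
}

# Number of connected components (union-find).
.n_components <- function(g) {
  parent <- seq_len(g$n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (nrow(g$edges)) {
    for (e in seq_len(nrow(g$edges))) {
      a <- find(g$edges[e, 1L]); b <- find(g$edges[e, 2L])
      if (a != b) parent[a] <- b
    }
  }
  length(unique(vapply(seq_len(g$n), find, integer(1))))
}

# Indices of the 2-core (iterative removal of degree-1 atoms): the ring
# systems plus the linkers connecting them.
.two_core <- function(g) {
  alive <- rep(TRUE, g$n)
  deg <- g$degree
  repeat {
    leaves <- which(alive & deg <= 1L)
    if (!length(leaves)) break
    alive[leaves] <- FALSE
    for (v in leaves) {
      nb <- c(g$edges[g$edges[, 1L] == v, 2L], g$edges[g$edges[, 2L] == v, 1L])
      nb <- nb[alive[nb]]
      deg[nb] <- deg[nb] - 1L
    }
    deg[leaves] <- 0L
  }
  which(alive)
}

# ---- Murcko frameworks ----------------------------------------------------

#' Murcko framework of a molecule
#'
#' Ring systems plus the linkers connecting them, with side chains removed;
#' atoms attached to the retained core by a double or triple bond (e.g.
#' exocyclic carbonyl oxygens) are kept, following the usual framework
#' convention. Acyclic molecules yield the empty string. The result is
#' canonicalized, so frameworks are directly comparable as strings, and the
#' operation is idempotent.
#'
#' @param smiles character vector of (parseable) SMILES.
#' @return Character vector of canonical framework SMILES ("" for acyclic).
#' @examples
#' \donttest{
#' murcko_framework(c("Cc1ccccc1", "CCCCCC"))
#' }
#' @export
murcko_framework <- function(smiles) {
  vapply(as.character(smiles), function(smi) {
    sdfset <- tryCatch(suppressWarnings(ChemmineR::smiles2sdf(smi)),
                       error = function(e) NULL)
    if (is.null(sdfset)) return(NA_character_)
    sdf <- sdfset[[1L]]
    g <- .mol_graph(sdf)
    n_rings <- nrow(g$edges) - g$n + .n_components(g)
    if (n_rings <= 0L) return("")
    core <- .two_core(g)
    # re-attach atoms multi-bonded to the core (exocyclic =O, =N, =S ...)
    multi <- g$edges[g$edges[, 3L] >= 2L, , drop = FALSE]
    extra <- unique(c(multi[multi[, 1L] %in% core, 2L],
                      multi[multi[, 2L] %in% core, 1L]))
    keep <- sort(unique(c(core, extra)))
    if (length(keep) == g$n) {
      return(.canon_one(smi))
    }
    sub <- ChemmineR::atomsubset(sdf, atomrows = keep)
    ss <- methods::new("SDFset", SDF = list(sub), ID = "frame")
    fsmi <- tryCatch(as.character(ChemmineR::sdf2smiles(ss))[1L],
                     error = function(e) NA_character_)
    if (is.na(fsmi)) return(NA_character_)
    .canon_one(fsmi)
  }, character(1), USE.NAMES = FALSE)
}

# ---- descriptors ----------------------------------------------------------

# Zhao-Abraham-Zissimos atomic van der Waals volume contributions (A^3).
.vdw_contrib <- c(H = 7.24, C = 20.58, N = 15.60, O = 14.71, F = 13.31,
                  Cl = 22.45, Br = 26.52, I = 32.52, P = 24.43, S = 24.43,
                  Si = 38.79, B = 40.48, As = 26.52, Se = 28.73)

# Parse a molecular formula ("C7H5F3") into element counts.
.formula_counts <- function(formula) {
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  toks <- regmatches(formula, list(m))[[1]]
  if (!length(toks)) return(NULL)
  el <- sub("[0-9]*$", "", toks)
  ct <- as.integer(sub("^[A-Za-z]+", "", toks))
  ct[is.na(ct)] <- 1L
  tapply(ct, el, sum)
}

# SMARTS used by graph-independent descriptors.
.desc_smarts <- c(
  b_rotN = "[!$(*#*)&!D1]-!@[!$(*#*)&!D1]",
  a_aro = "[a]",
  arom_ring6 = "[aR]1[aR][aR][aR][aR][aR]1",
  arom_ring5 = "[aR]1[aR][aR][aR][aR]1"
)

#' Descriptor registry
#'
#' Names of the molecular descriptors this package can compute. All are 2D
#' or topological; see \code{\link{moe_descriptor_map}} for how they map to
#' the commercial descriptor names common in the toxicity QSAR literature.
#'
#' @return Character vector of descriptor names.
#' @export
descriptor_registry <- function() {
  c("MW", "SlogP", "TPSA", "SMR", "a_acc", "a_don", "a_nF", "a_nN",
    "a_nO", "a_nS", "a_nP", "a_nCl", "a_nBr", "a_nI", "a_heavy", "a_aro",
    "b_count", "b_rotN", "rings", "arom_rings", "chi0", "chi1", "Kier1",
    "Kier2", "KierFlex", "logS", "vdw_vol")
}

#' Map of commercial (MOE-style) descriptor names to implemented analogues
#'
#' The toxicity QSAR literature reports descriptors from commercial
#' toolkits. This package computes open analogues; the table documents the
#' correspondence without claiming numeric parity.
#'
#' @return data.frame with columns \code{moe_name}, \code{analogue},
#'   \code{note}.
#' @export
moe_descriptor_map <- function() {
  data.frame(
    moe_name = c("Weight", "SlogP", "TPSA", "SMR", "a_acc", "a_don",
                 "a_nF", "a_nN", "a_nO", "a_nS", "a_nP", "a_nCl", "a_nBr",
                 "a_nI", "a_heavy", "a_aro", "b_count", "b_rotN", "rings",
                 "rings_arom", "chi0", "chi1", "Kier1", "Kier2", "KierFlex",
                 "logS", "vdw_vol"),
    analogue = c("MW", "SlogP", "TPSA", "SMR", "a_acc", "a_don", "a_nF",
                 "a_nN", "a_nO", "a_nS", "a_nP", "a_nCl", "a_nBr", "a_nI",
                 "a_heavy", "a_aro", "b_count", "b_rotN", "rings",
                 "arom_rings", "chi0", "chi1", "Kier1", "Kier2", "KierFlex",
                 "logS", "vdw_vol"),
    note = c("OpenBabel standard atomic masses",
             "OpenBabel Wildman-Crippen logP",
             "OpenBabel Ertl TPSA",
             "OpenBabel Wildman-Crippen molar refractivity",
             "OpenBabel H-bond acceptor count",
             "OpenBabel H-bond donor count",
             rep("element count from molecular formula", 8),
             "heavy-atom count", "aromatic-atom count",
             "heavy-atom bond count",
             "rotatable-bond SMARTS count",
             "cyclomatic (SSSR) ring count",
             "aromatic 5/6-ring SMARTS count",
             "simple connectivity index order 0",
             "simple connectivity index order 1",
             "Kier kappa-1 shape index", "Kier kappa-2 shape index",
             "Kier molecular flexibility (k1*k2/heavy atoms)",
             "ESOL-style estimated intrinsic solubility",
             "Zhao atomic-contribution van der Waals volume"),
    stringsAsFactors = FALSE
  )
}

#' Compute molecular descriptors
#'
#' Computes the requested descriptors for a vector of molecules.
#' Molecules for which any descriptor cannot be computed are returned as
#' all-NA rows and listed in the \code{failed} attribute; the
#' featurization wrapper drops them with reason \code{descriptor_fail}.
#' Values are deterministic for a fixed OpenBabel version.
#'
#' @param smiles character vector of SMILES (parse-checked beforehand).
#' @param descriptors subset of \code{\link{descriptor_registry}()}.
#' @return Numeric matrix (molecules x descriptors) with attribute
#'   \code{failed} holding the indices of failed molecules.
#' @export
compute_descriptors <- function(smiles, descriptors = descriptor_registry()) {
  unknown <- setdiff(descriptors, descriptor_registry())
  .check(length(unknown) == 0,
         sprintf("unknown descriptor(s): %s", paste(unknown, collapse = ", ")))
  n <- length(smiles)
  ids <- sprintf("m%06d", seq_len(n))
  sdfset <- suppressWarnings(ChemmineR::smiles2sdf(
    stats::setNames(as.character(smiles), ids)))
  props <- tryCatch(ChemmineR::propOB(sdfset), error = function(e) NULL)
  smarts_counts <- .smarts_count_matrix(smiles, .desc_smarts)
  out <- matrix(NA_real_, n, length(descriptors),
                dimnames = list(NULL, descriptors))
  failed <- integer(0)
  for (i in seq_len(n)) {
    row <- tryCatch(
      .descriptor_row(sdfset[[i]],
                      if (is.null(props)) NULL else props[i, ],
                      smarts_counts[i, ], descriptors),
      error = function(e) NULL)
    if (is.null(row) || anyNA(row)) failed <- c(failed, i)
    if (!is.null(row)) out[i, ] <- row
  }
  if (length(failed)) out[failed, ] <- NA_real_
  attr(out, "failed") <- failed
  out
}

.descriptor_row <- function(sdf, prop, scounts, descriptors) {
  g <- .mol_graph(sdf)
  fc <- .formula_counts(if (is.null(prop)) "" else prop$formula)
  cnt <- function(el) if (is.null(fc) || is.na(fc[el])) 0 else unname(fc[el])
  A <- g$n
  B <- nrow(g$edges)
  n_rings <- B - A + .n_components(g)
  deg <- g$degree
  # Kier kappa shape indices on the hydrogen-suppressed graph
  P2 <- if (A >= 3) sum(choose(deg, 2)) else 0
  k1 <- if (B > 0) A * (A - 1)^2 / B^2 else 0
  k2 <- if (P2 > 0) (A - 1) * (A - 2)^2 / P2^2 else 0
  kflex <- if (A > 0) k1 * k2 / A else 0
  chi0 <- sum(1 / sqrt(deg[deg > 0]))
  chi1 <- if (B > 0) {
    sum(1 / sqrt(deg[g$edges[, 1L]] * deg[g$edges[, 2L]]))
  } else 0
  logp <- as.numeric(prop$logP)
  mw <- as.numeric(prop$MW)
  rotn <- scounts[["b_rotN"]]
  naro <- scounts[["a_aro"]]
  arings <- scounts[["arom_ring6"]] + scounts[["arom_ring5"]]
  # ESOL-style intrinsic solubility estimate (Delaney-type regression)
  ap <- if (A > 0) naro / A else 0
  logs <- 0.16 - 0.63 * logp - 0.0062 * mw + 0.066 * rotn - 0.74 * ap
  # Zhao atomic-contribution vdW volume; unparameterized elements fall
  # back on the carbon contribution
  contrib <- .vdw_contrib[names(fc)]
  contrib[is.na(contrib)] <- .vdw_contrib[["C"]]
  n_h <- cnt("H")
  b_total <- B + n_h   # each hydrogen adds one bond
  vdw <- sum(contrib * fc) - 5.92 * b_total - 14.7 * arings -
    3.8 * max(n_rings - arings, 0)
  vals <- c(
    MW = mw, SlogP = logp, TPSA = as.numeric(prop$TPSA),
    SMR = as.numeric(prop$MR),
    a_acc = as.numeric(prop$HBA1), a_don = as.numeric(prop$HBD),
    a_nF = cnt("F"), a_nN = cnt("N"), a_nO = cnt("O"), a_nS = cnt("S"),
    a_nP = cnt("P"), a_nCl = cnt("Cl"), a_nBr = cnt("Br"), a_nI = cnt("I"),
    a_heavy = A, a_aro = naro, b_count = B, b_rotN = rotn,
    rings = n_rings, arom_rings = arings, chi0 = chi0, chi1 = chi1,
    Kier1 = k1, Kier2 = k2, KierFlex = kflex, logS = logs, vdw_vol = vdw)
  vals[descriptors]
}

# Count SMARTS matches for each molecule x pattern; one OpenBabel parse
# per molecule, all patterns matched on it.
.smarts_count_matrix <- function(smiles, patterns) {
  n <- length(smiles)
  inp <- paste(paste(as.character(smiles), sprintf("m%06d", seq_len(n))),
               collapse = "\n")
  res <- ChemmineOB::forEachMol("SMILES", inp, function(m) {
    vapply(patterns,
           function(p) ChemmineOB::smartsSearch_OB(list(m), p)[[1L]],
           integer(1))
  })
  out <- do.call(rbind, res)
  .check(nrow(out) == n, "SMARTS matching dropped molecules (parse failure?)")
  colnames(out) <- names(patterns)
  out
}
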