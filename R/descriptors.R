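#' Parse a ligand-protein complex from a PDB file
#'
#' Separates protein and ligand atoms.  The ligand is taken from the
#' HETATM records, optionally restricted to a named residue; waters are
#' discarded; metal species among the HETATM records are kept on the
#' protein side (they belong to the receptor environment, not the
#' ligand).
#'
#' @param pdb_file Path to a PDB file holding one complex.
#' @param ligand_res Residue name of the ligand; `NULL` takes every
#'   non-water, non-metal HETATM residue.
#' @param complex_id Identifier for the complex (defaults to the file
#'   name without extension).
#' @return An object of class `complex_structure`: data frames `protein`
#'   and `ligand` with columns `element`, `x`, `y`, `z`, `resid`,
#'   `resno`, `chain`, plus `complex_id`.
#' @export
parse_complex <- function(pdb_file, ligand_res = NULL,
                          complex_id = NULL) {
  if (is.null(complex_id))
    complex_id <- sub("\\.[^.]*$", "", basename(pdb_file))
  pdb <- tryCatch(bio3d::read.pdb(pdb_file, verbose = FALSE),
                  error = function(e)
                    stop("cannot parse PDB file '", pdb_file, "': ",
                         conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  at$element <- normalize_element(at$elesy, at$elety)
  if (any(!is.finite(at$x)) || any(!is.finite(at$y)) ||
      any(!is.finite(at$z)))
    stop("non-finite coordinates in '", pdb_file, "'", call. = FALSE)
  water <- at$resid %in% c("HOH", "WAT", "DOD", "H2O")
  at <- at[!water, , drop = FALSE]

  metal <- at$element %in% metal_elements()
  het <- at$type == "HETATM" & !metal
  is_lig <- if (is.null(ligand_res)) het else het & at$resid == ligand_res
  if (!any(is_lig))
    stop("no ligand atoms found in '", pdb_file, "'",
         if (!is.null(ligand_res)) paste0(" for residue ", ligand_res),
         call. = FALSE)
  cols <- c("element", "x", "y", "z", "resid", "resno", "chain")
  structure(list(protein = at[!is_lig, cols, drop = FALSE],
                 ligand = at[is_lig, cols, drop = FALSE],
                 complex_id = complex_id),
            class = "complex_structure")
}

normalize_element <- function(elesy, elety) {
  e <- trimws(elesy)
  missing <- is.na(e) | e == ""
  ## fall back on the first alphabetic character(s) of the atom name
  e[missing] <- sub("^[0-9]*([A-Za-z]).*$", "\\1", elety[missing])
  paste0(toupper(substr(e, 1, 1)),
         tolower(substr(e, 2, nchar(e))))
}

#' Metal elements recognised by the metal-site detector
#' @return Character vector of element symbols.
#' @export
metal_elements <- function() {
  c("Zn", "Fe", "Mg", "Mn", "Ca", "Cu", "Ni", "Co", "Na", "K")
}

heavy <- function(df) df[!df$element %in% c("H", "D"), , drop = FALSE]

pair_dists <- function(a, b) {
  ## |a| x |b| Euclidean distances
  ax <- as.matrix(a[, c("x", "y", "z")])
  bx <- as.matrix(b[, c("x", "y", "z")])
  sqrt(outer(rowSums(ax^2), rowSums(bx^2), `+`) - 2 * tcrossprod(ax, bx))
}

#' Ligand burial as median protein-contact count
#'
#' For every ligand heavy atom, counts the protein heavy atoms within
#' the contact cutoff; the burial descriptor is the median of these
#' per-atom counts (even counts average the two central values).
#'
#' @param cx A [parse_complex()] result.
#' @param cutoff Heavy-atom contact distance in Angstrom (default 4.5).
#' @return Median contact count (numeric; may be half-integral).
#' @export
burial_descriptor <- function(cx, cutoff = 4.5) {
  lig <- heavy(cx$ligand)
  if (!nrow(lig))
    stop("no ligand heavy atoms", call. = FALSE)
  prot <- heavy(cx$protein)
  if (!nrow(prot)) return(0)
  counts <- rowSums(pair_dists(lig, prot) <= cutoff)
  stats::median(counts)
}

#' Mean lipophilicity of the binding-pocket residues
#'
#' The pocket is the set of protein residues with at least one heavy
#' atom within `pocket_cutoff` of any ligand heavy atom; the descriptor
#' is the unweighted mean of a per-residue lipophilicity value over the
#' pocket residues.  The shipped default scale is the Fauchere-Pliska
#' side-chain analog logP table; any named residue-to-value table works.
#'
#' @param cx A [parse_complex()] result.
#' @param pocket_cutoff Pocket membership distance in Angstrom
#'   (default 5.0).
#' @param scale Named numeric vector, residue name -> lipophilicity.
#' @return Mean value over pocket residues.
#' @export
pocket_mean_clogp <- function(cx, pocket_cutoff = 5.0,
                              scale = default_residue_logp()) {
  lig <- heavy(cx$ligand)
  if (!nrow(lig)) stop("no ligand heavy atoms", call. = FALSE)
  ## metal species are flagged separately and carry no residue
  ## lipophilicity; keep them out of the pocket average
  prot <- heavy(cx$protein)
  prot <- prot[!prot$element %in% metal_elements(), , drop = FALSE]
  if (!nrow(prot)) stop("empty pocket: no protein atoms", call. = FALSE)
  near <- rowSums(pair_dists(prot, lig) <= pocket_cutoff) > 0
  if (!any(near)) stop("empty pocket: no residue within ",
                       pocket_cutoff, " Angstrom", call. = FALSE)
  res_key <- paste(prot$chain, prot$resno)
  pocket <- !duplicated(res_key) & res_key %in% res_key[near]
  resnames <- prot$resid[pocket][!duplicated(res_key[pocket])]
  vals <- scale[resnames]
  if (anyNA(vals)) {
    warning("skipping pocket residue(s) without a scale value: ",
            paste(unique(resnames[is.na(vals)]), collapse = ", "))
    vals <- vals[!is.na(vals)]
  }
  if (!length(vals))
    stop("empty pocket after removing unknown residues", call. = FALSE)
  mean(vals)
}

#' Shipped residue lipophilicity scale
#'
#' Fauchere-Pliska side-chain analog logP (pi) values for the 20
#' standard residues, read from a plain-text table under
#' `inst/extdata/`.
#'
#' @return Named numeric vector keyed by three-letter residue name.
#' @export
default_residue_logp <- function() {
  tab <- utils::read.csv(system.file("extdata", "residue_logp.csv",
                                     package = "vstriage",
                                     mustWork = TRUE),
                         stringsAsFactors = FALSE)
  stats::setNames(tab$logp, tab$resname)
}

#' Flag a metal ion in the binding site
#'
#' @param cx A [parse_complex()] result.
#' @param cutoff Distance in Angstrom (default 5.0).
#' @param metals Element symbols treated as metals.
#' @return `TRUE` iff any metal atom lies within `cutoff` of any ligand
#'   heavy atom.
#' @export
detect_metal_site <- function(cx, cutoff = 5.0,
                              metals = metal_elements()) {
  if (!length(metals)) return(FALSE)
  met <- cx$protein[cx$protein$element %in% metals, , drop = FALSE]
  if (!nrow(met)) return(FALSE)
  lig <- heavy(cx$ligand)
  any(pair_dists(met, lig) <= cutoff)
}

atomic_masses <- function() {
  c(H = 1.008, D = 2.014, C = 12.011, N = 14.007, O = 15.999,
    S = 32.06, P = 30.974, F = 18.998, Cl = 35.45, Br = 79.904,
    I = 126.904, Se = 78.971, B = 10.81, Zn = 65.38, Fe = 55.845,
    Mg = 24.305, Mn = 54.938, Ca = 40.078, Cu = 63.546, Ni = 58.693,
    Co = 58.933, Na = 22.99, K = 39.098)
}

mass_of <- function(df) {
  m <- atomic_masses()[df$element]
  if (anyNA(m)) m[is.na(m)] <- 0
  sum(m)
}

#' Descriptor table for a set of complexes
#'
#' Computes the full stratification descriptor row (protein and ligand
#' mass from the atoms present, burial, pocket lipophilicity, metal-site
#' flag) for each complex; per-complex failures are logged as warnings
#' and the row omitted.
#'
#' @param pdb_files Character vector of PDB paths, or a list of
#'   [parse_complex()] results.
#' @param ligand_res Optional ligand residue name passed to the parser.
#' @param contact_cutoff,pocket_cutoff,metal_cutoff Distances in
#'   Angstrom.
#' @return Data frame keyed by `complex_id` with the descriptor columns;
#'   the cutoffs used are recorded as attributes.
#' @export
descriptor_table <- function(pdb_files, ligand_res = NULL,
                             contact_cutoff = 4.5, pocket_cutoff = 5.0,
                             metal_cutoff = 5.0) {
  rows <- list()
  for (f in pdb_files) {
    row <- tryCatch({
      cx <- if (inherits(f, "complex_structure")) f
            else parse_complex(f, ligand_res)
      data.frame(
        complex_id = cx$complex_id,
        protein_mw = mass_of(cx$protein),
        ligand_mw = mass_of(cx$ligand),
        burial_median_contacts = burial_descriptor(cx, contact_cutoff),
        pocket_mean_clogp = pocket_mean_clogp(cx, pocket_cutoff),
        has_metal_in_site = detect_metal_site(cx, metal_cutoff),
        stringsAsFactors = FALSE)
    }, error = function(e) {
      warning("omitting complex (",
              if (is.character(f)) f else f$complex_id, "): ",
              conditionMessage(e), call. = FALSE)
      NULL
    })
    if (!is.null(row)) rows[[length(rows) + 1L]] <- row
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(complex_id = character(0), protein_mw = numeric(0),
               ligand_mw = numeric(0),
               burial_median_contacts = numeric(0),
               pocket_mean_clogp = numeric(0),
               has_metal_in_site = logical(0))
  attr(out, "cutoffs") <- c(contact = contact_cutoff,
                            pocket = pocket_cutoff,
                            metal = metal_cutoff)
  out
}
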