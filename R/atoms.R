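# Atom bookkeeping: the atom table, residue-name -> role classification with
# CHARMM-style defaults, element inference and atomic masses.

.ROLES <- c("protein", "lipid_head", "lipid_tail", "water", "ion",
            "bound_cation")

#' Default atom classification rules
#'
#' Residue-name to role mapping with CHARMM-style defaults (POPC/POPS lipids,
#' TIP3 water, SOD/CLA/POT monovalent ions, CAL bound calcium).  Lipid atoms
#' are split into head group (P, O, N and attached glycerol/choline/serine
#' heavy atoms) and acyl-tail carbons by atom name.  The rules are an editable
#' list so force-field variants can be accommodated.
#'
#' @return a list with components `lipids`, `waters`, `ions`,
#'   `bound_cations`, `head_atom_regex`, and `protein_residues`.
#' @export
defaultClassificationRules <- function() {
  list(
    lipids = c("POPC", "POPS", "POPE", "DOPC", "DOPS"),
    waters = c("TIP3", "HOH", "WAT", "SOL", "SPC"),
    ions = c(SOD = "Na", CLA = "Cl", POT = "K", NA. = "Na", CL = "Cl",
             K = "K", CES = "Cs"),
    bound_cations = c(CAL = "Ca", CA = "Ca", MG = "Mg"),
    # acyl-tail carbons are C2x/C3x in CHARMM lipid nomenclature; every
    # other lipid atom (phosphate, glycerol, choline/serine) is head group
    tail_atom_regex = "^C[23][0-9]+$",
    protein_residues = c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU",
                         "GLY", "HIS", "HSD", "HSE", "HSP", "ILE", "LEU",
                         "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
                         "TYR", "VAL")
  )
}

.SPECIAL_ATOM_ELEMENTS <- c(SOD = "Na", CLA = "Cl", CAL = "Ca", POT = "K",
                            CES = "Cs", MG = "Mg", OH2 = "O", OW = "O",
                            CL = "Cl", "NA" = "Na", K = "K", CA2 = "Ca")

.guessElement <- function(atom_name) {
  nm <- toupper(sub("^[0-9]+", "", atom_name))
  e <- unname(.SPECIAL_ATOM_ELEMENTS[nm])
  e[is.na(e)] <- substr(nm[is.na(e)], 1, 1)
  e
}

.ATOMIC_MASSES <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                    P = 30.974, S = 32.06, Na = 22.990, Cl = 35.453,
                    K = 39.098, Ca = 40.078, Mg = 24.305, Cs = 132.905)

#' Atomic masses for an element vector
#'
#' Unknown elements get unit mass with a warning (enough for centre-of-mass
#' work on pseudo-atoms).
#' @param element character vector of element symbols.
#' @return numeric masses (amu).
#' @export
atomMasses <- function(element) {
  m <- .ATOMIC_MASSES[element]
  if (anyNA(m)) {
    warning("unknown element(s) ",
            paste(unique(element[is.na(m)]), collapse = ", "),
            "; using unit masses")
    m[is.na(m)] <- 1
  }
  unname(m)
}

#' Build and validate an atom table
#'
#' The atom table is the per-atom annotation shared by all analyses: one row
#' per atom with its name, element, residue, subunit and role.  Roles
#' partition the atoms into protein, lipid head group, lipid tail, water,
#' free ion and protein-bound cation.  Every lipid must expose exactly one
#' phosphorus atom as head-group anchor.
#'
#' @param atom_name,residue_name character vectors.
#' @param residue_id integer vector; unique per residue within a subunit.
#' @param subunit_id character vector of subunit labels.
#' @param role one of `protein`, `lipid_head`, `lipid_tail`, `water`, `ion`,
#'   `bound_cation` per atom.
#' @param element element symbols; inferred from atom names when `NULL`.
#' @return a `data.frame` with columns `atom_id`, `atom_name`, `element`,
#'   `residue_name`, `residue_id`, `subunit_id`, `role`.
#' @export
atomTable <- function(atom_name, residue_name, residue_id, subunit_id,
                      role, element = NULL) {
  n <- length(atom_name)
  stopifnot(length(residue_name) == n, length(residue_id) == n,
            length(subunit_id) == n, length(role) == n)
  if (is.null(element)) element <- .guessElement(atom_name)
  bad <- setdiff(unique(role), .ROLES)
  if (length(bad))
    stop("unknown atom role(s): ", paste(bad, collapse = ", "))
  tab <- data.frame(atom_id = seq_len(n), atom_name = atom_name,
                    element = element, residue_name = residue_name,
                    residue_id = as.integer(residue_id),
                    subunit_id = subunit_id, role = role,
                    stringsAsFactors = FALSE)
  # every lipid residue must have exactly one phosphorus head-group anchor
  lip <- tab[tab$role %in% c("lipid_head", "lipid_tail"), ]
  if (nrow(lip)) {
    np <- tapply(lip$element == "P", paste(lip$subunit_id, lip$residue_id),
                 sum)
    if (any(np != 1L))
      stop("every lipid must have exactly one phosphorus head-group anchor; ",
           "offending residue(s): ",
           paste(utils::head(names(np)[np != 1L], 5), collapse = ", "))
  }
  tab
}

#' Classify atoms from residue and atom names
#'
#' Applies a rule set (see [defaultClassificationRules()]) to residue/atom
#' names.  Residues in a polymer chain that are not otherwise recognised are
#' classified `protein`; unrecognised free residues are an error listing the
#' offenders.
#'
#' @param atom_name,residue_name,residue_id,subunit_id per-atom vectors.
#' @param rules classification rule list.
#' @param polymer_chains subunit labels considered polymer (protein) chains;
#'   default: any subunit containing a recognised amino-acid residue.
#' @return role vector aligned with the inputs.
#' @export
classifyAtoms <- function(atom_name, residue_name, residue_id, subunit_id,
                          rules = defaultClassificationRules(),
                          polymer_chains = NULL) {
  role <- rep(NA_character_, length(atom_name))
  rn <- toupper(residue_name)
  if (is.null(polymer_chains))
    polymer_chains <- unique(subunit_id[rn %in% rules$protein_residues])
  is_lip <- rn %in% rules$lipids
  role[is_lip & grepl(rules$tail_atom_regex, atom_name)] <- "lipid_tail"
  role[is_lip & is.na(role)] <- "lipid_head"
  role[rn %in% rules$waters] <- "water"
  role[rn %in% names(rules$ions)] <- "ion"
  role[rn %in% names(rules$bound_cations)] <- "bound_cation"
  in_poly <- subunit_id %in% polymer_chains
  role[is.na(role) & (rn %in% rules$protein_residues | in_poly)] <- "protein"
  if (anyNA(role))
    stop("unclassified residue name(s): ",
         paste(unique(rn[is.na(role)]), collapse = ", "),
         " (not protein, lipid, water or ion under the supplied rules)")
  role
}

# head-group heavy atoms (P/O/N) of one lipid residue, used by coordination
# and contact analyses
.headgroupAtoms <- function(atoms) {
  atoms$role == "lipid_head" & atoms$element %in% c("P", "O", "N")
}
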