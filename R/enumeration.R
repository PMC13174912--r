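#' Parse a substituent SMILES into atoms and bond-order sums
#'
#' Minimal SMILES reader for the substituent grammar used by the library
#' generator: single-letter organic-subset atoms, `=`/`#` bonds, one-digit
#' ring closures and parenthesized branches. Implicit hydrogens are assumed
#' to fill each atom's standard valence.
#'
#' @param smiles SMILES string.
#' @param table Element table, see [element_table()].
#' @return data.frame with columns `symbol` and `bond_sum` (total bond order
#'   to other heavy atoms in the string), one row per atom in string order.
#' @keywords internal
parse_substituent <- function(smiles, table = element_table()) {
  chars <- strsplit(smiles, "")[[1]]
  symbols <- character(0)
  bond_sum <- numeric(0)
  prev_stack <- integer(0)   # branch return points
  prev <- NA_integer_
  pending <- 1
  ring_open <- list()        # digit -> c(atom, order)
  i <- 1
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch %in% names(table$valence)) {
      symbols <- c(symbols, ch)
      bond_sum <- c(bond_sum, 0)
      cur <- length(symbols)
      if (!is.na(prev)) {
        bond_sum[prev] <- bond_sum[prev] + pending
        bond_sum[cur] <- bond_sum[cur] + pending
      }
      prev <- cur
      pending <- 1
    } else if (ch == "=") {
      pending <- 2
    } else if (ch == "#") {
      pending <- 3
    } else if (ch == "(") {
      prev_stack <- c(prev_stack, prev)
    } else if (ch == ")") {
      if (length(prev_stack) == 0) stop("unbalanced ')' in SMILES: ", smiles)
      prev <- prev_stack[length(prev_stack)]
      prev_stack <- prev_stack[-length(prev_stack)]
    } else if (grepl("[0-9]", ch)) {
      if (is.na(prev)) stop("ring closure before any atom in SMILES: ", smiles)
      if (is.null(ring_open[[ch]])) {
        ring_open[[ch]] <- c(prev, pending)
      } else {
        other <- ring_open[[ch]]
        order <- max(pending, other[2])
        bond_sum[prev] <- bond_sum[prev] + order
        bond_sum[other[1]] <- bond_sum[other[1]] + order
        ring_open[[ch]] <- NULL
      }
      pending <- 1
    } else {
      stop("cannot parse SMILES '", smiles, "': unsupported token '", ch, "'")
    }
    i <- i + 1
  }
  if (length(symbols) == 0) stop("SMILES contains no atoms: ", smiles)
  data.frame(symbol = symbols, bond_sum = bond_sum, stringsAsFactors = FALSE)
}

#' Filter substituent SMILES by attachment-atom valence
#'
#' The library generator bonds the FIRST atom of each substituent SMILES to
#' the scaffold site, so a string is usable only if that atom retains at
#' least one free valence for the new single bond after its bonds within the
#' substituent are counted (implicit hydrogens fill the remainder). Two
#' strings need the generator's documented corrections: bare `O`, attached as
#' a hydroxyl rather than a doubly bonded oxygen, and `CO`, attached as a
#' hydroxymethyl rather than a carbonyl; both are emitted with
#' `status = "corrected"` and an explicit-hydrogen corrected SMILES.
#'
#' @param smiles_list Character vector of substituent SMILES.
#' @param table Element table.
#' @return data.frame with columns `smiles`, `attachment_atom`, `status`
#'   (`accepted`/`rejected`/`corrected`), `corrected` and `reason`.
#' @export
filter_substituents <- function(smiles_list, table = element_table()) {
  corrections <- c(O = "[OH]", CO = "C[OH]")
  empty <- data.frame(smiles = character(0), attachment_atom = character(0),
                      status = character(0), corrected = character(0),
                      reason = character(0), stringsAsFactors = FALSE)
  if (length(smiles_list) == 0) return(empty)
  rows <- lapply(smiles_list, function(s) {
    atoms <- parse_substituent(s, table)
    first <- atoms[1, ]
    free <- table$valence[[first$symbol]] - first$bond_sum
    if (free < 1) {
      data.frame(smiles = s, attachment_atom = first$symbol,
                 status = "rejected", corrected = "",
                 reason = sprintf(
                   "attachment atom %s is saturated (valence %d, %g bonds in substituent)",
                   first$symbol, table$valence[[first$symbol]], first$bond_sum),
                 stringsAsFactors = FALSE)
    } else if (s %in% names(corrections)) {
      data.frame(smiles = s, attachment_atom = first$symbol,
                 status = "corrected", corrected = corrections[[s]],
                 reason = "", stringsAsFactors = FALSE)
    } else {
      data.frame(smiles = s, attachment_atom = first$symbol,
                 status = "accepted", corrected = "", reason = "",
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Read a substituent SMILES list
#'
#' One SMILES per line; blank lines and `#` comments are ignored. The 26
#' one-to-three-heavy-atom C/N/O/F substituents used for the training library
#' are bundled at `system.file("extdata", "substituents_gdb3.smi",
#' package = "calixtopo")`.
#'
#' @param path Path to the list file.
#' @return Character vector of SMILES strings.
#' @export
read_substituent_list <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines[nzchar(lines)]
}

#' Scaffold specifications for the four macrocycle families
#'
#' Each family is a calix[4]arene-type macrocycle: four phenol-derived aryl
#' units joined by bridging groups (CH2 for calix, NH for aza, O for oxa, S
#' for thia). Substitution sites are the para and meta ring positions
#' (relative to the hydroxyl), the lower-rim hydroxyl (whose hydrogen is
#' replaced), and -- for calix and aza only, whose bridges carry hydrogens --
#' the bridging atom.
#'
#' @return Named list of scaffold specs with fields `family`, `bridge_symbol`,
#'   `sites`, `bridge_available` and `parent_smiles`.
#' @export
scaffold_specs <- function() {
  bridges <- c(calix = "C", aza = "N", oxa = "O", thia = "S")
  specs <- lapply(names(bridges), function(fam) {
    bridge_ok <- fam %in% c("calix", "aza")
    sites <- c("para", "meta", if (bridge_ok) "bridge", "lower")
    list(family = fam, bridge_symbol = bridges[[fam]], sites = sites,
         bridge_available = bridge_ok,
         parent_smiles = product_smiles(fam, "none", ""))
  })
  names(specs) <- names(bridges)
  specs
}

#' Build the SMILES of a symmetrically functionalized macrocycle
#'
#' All four symmetric positions of the chosen site carry the same
#' substituent, whose first atom bonds to the site (para/meta: an aryl
#' carbon losing its hydrogen; lower: the phenolic oxygen losing its
#' hydrogen; bridge: the bridging C or N).
#'
#' @param family One of `calix`, `aza`, `oxa`, `thia`.
#' @param site One of `para`, `meta`, `bridge`, `lower`, `none`.
#' @param substituent Substituent SMILES (empty for `site = "none"`).
#' @return Product SMILES string.
#' @export
product_smiles <- function(family, site, substituent) {
  bridges <- c(calix = "C", aza = "N", oxa = "O", thia = "S")
  if (!family %in% names(bridges)) stop("unknown family: ", family)
  if (!site %in% .sites) stop("unknown site: ", site)
  if (site == "bridge" && !family %in% c("calix", "aza")) {
    stop("bridge site is not available for family '", family, "'")
  }
  if (site != "none" && !nzchar(substituent)) {
    stop("site '", site, "' requires a substituent")
  }
  sub_branch <- function(on) if (on) paste0("(", substituent, ")") else ""
  unit <- function(last) {
    paste0("c2",
           if (site == "meta") paste0("c", sub_branch(TRUE)) else "c",
           if (site == "para") paste0("c", sub_branch(TRUE)) else "c",
           "c",
           if (last) "c9" else "c",
           "(c2O", if (site == "lower") substituent else "", ")")
  }
  bridge <- function(first) {
    paste0(bridges[[family]], if (first) "9" else "", sub_branch(site == "bridge"))
  }
  paste0(bridge(TRUE), unit(FALSE), bridge(FALSE), unit(FALSE),
         bridge(FALSE), unit(FALSE), bridge(FALSE), unit(TRUE))
}

#' Canonicalize a SMILES string (round-trip validation)
#'
#' Uses Open Babel through ChemmineOB when available. Returns `NA` when the
#' string fails to parse.
#'
#' @param smiles SMILES string.
#' @return Canonical SMILES, or `NA_character_` on failure.
#' @export
canonical_smiles <- function(smiles) {
  if (!requireNamespace("ChemmineOB", quietly = TRUE)) {
    return(NA_character_)
  }
  out <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", smiles)),
    error = function(e) ""
  )
  out <- trimws(strsplit(out, "[\t\n ]")[[1]][1])
  if (is.na(out) || !nzchar(out)) NA_character_ else out
}

#' Enumerate a candidate library by symmetric functionalization
#'
#' One candidate per (family, site, substituent) combination, with all four
#' symmetric positions of the site bearing the same group. With
#' `include_manual_extras`, the unfunctionalized parent and the p-tert-butyl
#' para variant of each family are appended, mirroring the manual additions
#' made to the training database. Product SMILES that fail round-trip
#' canonicalization are retained with `status = "failed"` rather than
#' silently dropped.
#'
#' @param scaffolds Scaffold specs, see [scaffold_specs()]; may be a subset.
#' @param substituents data.frame from [filter_substituents()] (rejected rows
#'   are ignored), or a character vector of SMILES to be filtered first.
#' @param include_manual_extras Append parent + p-tert-butyl rows per family.
#' @param validate Round-trip-parse each product SMILES (needs ChemmineOB).
#' @return data.frame with columns `candidate_id`, `family`, `site`,
#'   `substituent`, `product_smiles`, `status`.
#' @export
enumerate_library <- function(scaffolds = scaffold_specs(),
                              substituents = character(0),
                              include_manual_extras = TRUE,
                              validate = FALSE) {
  if (is.character(substituents)) {
    substituents <- filter_substituents(substituents)
  }
  usable <- substituents[substituents$status %in% c("accepted", "corrected"), ,
                         drop = FALSE]
  rows <- list()
  for (spec in scaffolds) {
    fam <- spec$family
    for (site in spec$sites) {
      for (k in seq_len(nrow(usable))) {
        raw <- usable$smiles[k]
        attach_smiles <- if (usable$status[k] == "corrected") {
          usable$corrected[k]
        } else {
          raw
        }
        rows[[length(rows) + 1]] <- data.frame(
          candidate_id = sprintf("%s_%s_%s", fam, site, raw),
          family = fam, site = site, substituent = raw,
          product_smiles = product_smiles(fam, site, attach_smiles),
          status = "ok", stringsAsFactors = FALSE)
      }
    }
    if (include_manual_extras) {
      rows[[length(rows) + 1]] <- data.frame(
        candidate_id = sprintf("%s_parent", fam), family = fam, site = "none",
        substituent = "", product_smiles = spec$parent_smiles,
        status = "ok", stringsAsFactors = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        candidate_id = sprintf("%s_para_tBu", fam), family = fam,
        site = "para", substituent = "C(C)(C)C",
        product_smiles = product_smiles(fam, "para", "C(C)(C)C"),
        status = "ok", stringsAsFactors = FALSE)
    }
  }
  lib <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(lib)) {
    lib <- data.frame(candidate_id = character(0), family = character(0),
                      site = character(0), substituent = character(0),
                      product_smiles = character(0), status = character(0),
                      stringsAsFactors = FALSE)
  }
  if (anyDuplicated(lib$candidate_id)) {
    stop("duplicate candidate ids in library")
  }
  if (validate && nrow(lib) > 0) {
    canon <- vapply(lib$product_smiles, canonical_smiles, character(1))
    lib$status[is.na(canon)] <- "failed"
  }
  lib
}
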