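#' Element data: Pauling electronegativities and standard valences
#'
#' Lookup table used throughout the package: Pauling-scale electronegativity
#' (dimensionless) and the standard valence of the elements that occur in
#' calixarene hosts and their substituents.
#'
#' @return A list with named numeric vectors `chi` (electronegativity) and
#'   `valence`.
#' @export
element_table <- function() {
  list(
    chi = c(H = 2.20, C = 2.55, N = 3.04, O = 3.44, F = 3.98, S = 2.58),
    valence = c(H = 1, C = 4, N = 3, O = 2, F = 1, S = 2)
  )
}

#' Pauling electronegativity of an element symbol
#'
#' @param symbol Element symbol (case-insensitive).
#' @param table Element table, see [element_table()].
#' @return Electronegativity (dimensionless scalar).
#' @export
electronegativity <- function(symbol, table = element_table()) {
  sym <- normalize_symbol(symbol)
  chi <- table$chi[sym]
  if (any(is.na(chi))) {
    stop("unknown element symbol: ", paste(symbol[is.na(chi)], collapse = ", "))
  }
  unname(chi)
}

normalize_symbol <- function(symbol) {
  s <- tolower(trimws(symbol))
  paste0(toupper(substring(s, 1, 1)), substring(s, 2))
}

#' Construct a molecular point cloud
#'
#' A point cloud is the element-labelled set of Cartesian atom positions of
#' one host structure; it is the sole geometric input to the topological
#' featurization.
#'
#' @param id Structure identifier.
#' @param elements Character vector of element symbols.
#' @param coords Numeric matrix, one row per atom, columns x, y, z in Angstrom.
#' @return An object of class `molecule_cloud`.
#' @export
molecule_cloud <- function(id, elements, coords) {
  coords <- matrix(as.numeric(coords), ncol = 3)
  elements <- normalize_symbol(as.character(elements))
  if (length(elements) != nrow(coords)) {
    stop("element count (", length(elements), ") does not match coordinate rows (",
         nrow(coords), ")")
  }
  tab <- element_table()
  unknown <- setdiff(unique(elements), names(tab$chi))
  if (length(unknown) > 0) {
    stop("unknown element symbol: ", paste(unknown, collapse = ", "))
  }
  if (length(coords) > 0 && !all(is.finite(coords))) {
    stop("non-finite coordinates in cloud '", id, "'")
  }
  structure(list(id = as.character(id), elements = elements, coords = coords),
            class = "molecule_cloud")
}

#' @export
print.molecule_cloud <- function(x, ...) {
  cat("<molecule_cloud>", x$id, "-", length(x$elements), "atoms\n")
  invisible(x)
}

#' Read a molecular geometry from an XYZ file
#'
#' Standard XYZ dialect: line 1 is the atom count, line 2 a free-text comment
#' (ignored), then one `El x y z` line per atom. Symbols are matched
#' case-insensitively and stored capitalized.
#'
#' @param path Path to the file.
#' @param id Structure id; defaults to the file name without extension.
#' @return A [molecule_cloud()].
#' @export
read_xyz <- function(path, id = sub("\\.[^.]*$", "", basename(path))) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 1) stop("empty XYZ file: ", path)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 0) stop("line 1: invalid atom count in ", path)
  body <- lines[-(1:2)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < n) {
    stop("line ", length(body) + 3, ": file declares ", n, " atoms but lists ",
         length(body))
  }
  body <- body[seq_len(n)]
  elements <- character(n)
  coords <- matrix(NA_real_, n, 3)
  for (k in seq_len(n)) {
    parts <- strsplit(trimws(body[k]), "[[:space:]]+")[[1]]
    if (length(parts) < 4) stop("line ", k + 2, ": expected 'El x y z'")
    xyz <- suppressWarnings(as.numeric(parts[2:4]))
    if (any(is.na(xyz))) stop("line ", k + 2, ": non-numeric coordinate")
    elements[k] <- parts[1]
    coords[k, ] <- xyz
  }
  molecule_cloud(id, elements, coords)
}

#' Write a molecular geometry to an XYZ file
#'
#' Coordinates are written with fixed six-decimal formatting; the comment line
#' is left blank.
#'
#' @param cloud A [molecule_cloud()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_xyz <- function(cloud, path) {
  stopifnot(inherits(cloud, "molecule_cloud"))
  n <- length(cloud$elements)
  lines <- c(as.character(n), "")
  if (n > 0) {
    lines <- c(lines, sprintf("%s %.6f %.6f %.6f", cloud$elements,
                              cloud$coords[, 1], cloud$coords[, 2],
                              cloud$coords[, 3]))
  }
  writeLines(lines, path)
  invisible(path)
}

.families <- c("calix", "aza", "oxa", "thia")
.sites <- c("para", "meta", "bridge", "lower", "none")
.conformations <- c("cone", "partial_cone", "alt12", "alt13", "undetermined")

#' Load a dataset manifest
#'
#' The manifest is a CSV with header
#' `structure_id,family,site,substituent,conformation,delta_h` pairing each
#' structure file with its scaffold family, functionalization site,
#' substituent SMILES, conformation label and (for training rows) the CO2
#' adsorption enthalpy in kcal/mol. Rows without `delta_h` are screening
#' candidates. Bridge-site rows are rejected for the oxa and thia families,
#' whose scaffolds carry no substitutable bridge hydrogen.
#'
#' @param path Path to the CSV file.
#' @return A data.frame with one validated row per structure and a logical
#'   column `is_candidate` marking rows with missing enthalpy.
#' @export
load_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  required <- c("structure_id", "family", "site", "substituent",
                "conformation", "delta_h")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("manifest is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  df <- df[required]
  if (nrow(df) == 0) {
    df$delta_h <- numeric(0)
    df$is_candidate <- logical(0)
    return(df)
  }
  bad_family <- !(df$family %in% .families)
  if (any(bad_family)) {
    stop("unknown family: ", paste(unique(df$family[bad_family]), collapse = ", "))
  }
  bad_site <- !(df$site %in% .sites)
  if (any(bad_site)) {
    stop("unknown site: ", paste(unique(df$site[bad_site]), collapse = ", "))
  }
  bad_conf <- !(df$conformation %in% c(.conformations, ""))
  if (any(bad_conf)) {
    stop("unknown conformation: ",
         paste(unique(df$conformation[bad_conf]), collapse = ", "))
  }
  incompatible <- df$family %in% c("oxa", "thia") & df$site == "bridge"
  if (any(incompatible)) {
    stop("bridge-site functionalization is not available for oxa/thia rows: ",
         paste(df$structure_id[incompatible], collapse = ", "))
  }
  dh <- suppressWarnings(as.numeric(df$delta_h))
  bad_dh <- nzchar(trimws(df$delta_h)) & is.na(dh)
  if (any(bad_dh)) {
    stop("non-numeric delta_h for: ",
         paste(df$structure_id[bad_dh], collapse = ", "))
  }
  df$delta_h <- dh
  df$is_candidate <- is.na(dh)
  df
}
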