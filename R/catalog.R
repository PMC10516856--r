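#' Molecule and code catalog
#'
#' The catalog carries the code vocabularies the pipeline needs: the
#' chemotherapy molecules that qualify a patient for inclusion, the hormone
#' and targeted-therapy molecules that disqualify (these define a different
#' receptor-positive population), procedure codes flagged as metastatic
#' disease management, the ICD-10 category prefixes read as metastatic
#' disease, and a mapping from molecule combinations to conventional regimen
#' labels (e.g. doxorubicin + cyclophosphamide = "AC").
#'
#' Defaults are assembled from drugs commonly used for triple-negative
#' breast cancer; every field is overridable, either here or through a
#' YAML/JSON config file read by [read_catalog()]. The default
#' metastatic-management procedure codes are synthetic placeholders
#' (`"MM001"`, `"MM002"`) meant to be replaced with a payer-specific list.
#'
#' @param inclusion_molecules Character vector of qualifying chemotherapy
#'   molecule names.
#' @param exclusion_molecules Character vector of disqualifying hormone /
#'   targeted-therapy molecule names. Must be disjoint from
#'   `inclusion_molecules`.
#' @param metastatic_management_codes Character vector of procedure codes
#'   indicating metastatic disease management.
#' @param metastatic_icd_prefixes ICD-10 category prefixes treated as
#'   metastatic disease codes.
#' @param metastatic_icd_excluded Dotted subcodes excluded from the
#'   metastatic set (axillary/upper-limb secondary nodes by default).
#' @param regimen_names Named character vector mapping a molecule-set key
#'   (sorted molecule names joined by `"+"`) to a regimen label.
#'
#' @return An object of class `molecule_catalog` (a list with the fields
#'   above, molecule names normalized to lowercase ASCII).
#' @examples
#' cat <- molecule_catalog()
#' is_metastatic_code("C78.0", cat)
#' regimen_label(c("cyclophosphamide", "doxorubicin"), cat)
#' @export
molecule_catalog <- function(inclusion_molecules = default_inclusion_molecules(),
                             exclusion_molecules = default_exclusion_molecules(),
                             metastatic_management_codes = c("MM001", "MM002"),
                             metastatic_icd_prefixes = c("C76", "C77", "C78", "C79", "C80"),
                             metastatic_icd_excluded = "C77.3",
                             regimen_names = default_regimen_names()) {
  inclusion_molecules <- normalize_molecule(inclusion_molecules)
  exclusion_molecules <- normalize_molecule(exclusion_molecules)
  overlap <- intersect(inclusion_molecules, exclusion_molecules)
  if (length(overlap) > 0) {
    stop("inclusion and exclusion molecule sets overlap: ",
         paste(overlap, collapse = ", "), call. = FALSE)
  }
  structure(
    list(
      inclusion_molecules = inclusion_molecules,
      exclusion_molecules = exclusion_molecules,
      metastatic_management_codes = as.character(metastatic_management_codes),
      metastatic_icd_prefixes = toupper(metastatic_icd_prefixes),
      metastatic_icd_excluded = normalize_icd10(metastatic_icd_excluded),
      regimen_names = regimen_names
    ),
    class = "molecule_catalog"
  )
}

#' @export
print.molecule_catalog <- function(x, ...) {
  cat("<molecule_catalog>\n")
  cat("  inclusion molecules: ", paste(x$inclusion_molecules, collapse = ", "), "\n")
  cat("  exclusion molecules: ", paste(x$exclusion_molecules, collapse = ", "), "\n")
  cat("  metastatic ICD prefixes: ", paste(x$metastatic_icd_prefixes, collapse = ", "),
      " (excluding ", paste(x$metastatic_icd_excluded, collapse = ", "), ")\n", sep = "")
  cat("  metastatic-management codes: ",
      paste(x$metastatic_management_codes, collapse = ", "), "\n")
  cat("  named regimens: ", length(x$regimen_names), "\n")
  invisible(x)
}

default_inclusion_molecules <- function() {
  c("doxorubicin", "cyclophosphamide", "paclitaxel", "docetaxel",
    "carboplatin", "cisplatin", "gemcitabine", "capecitabine",
    "fluorouracil", "bevacizumab")
}

default_exclusion_molecules <- function() {
  c("tamoxifen", "anastrozole", "letrozole", "exemestane", "fulvestrant",
    "trastuzumab", "pertuzumab", "lapatinib")
}

default_regimen_names <- function() {
  c("cyclophosphamide+doxorubicin" = "AC",
    "cyclophosphamide+doxorubicin+paclitaxel" = "AC-T",
    "cyclophosphamide+doxorubicin+docetaxel" = "AC-T",
    "cyclophosphamide+doxorubicin+fluorouracil" = "FAC",
    "cyclophosphamide+docetaxel" = "TC",
    "bevacizumab+paclitaxel" = "bevacizumab+paclitaxel",
    "cisplatin+gemcitabine" = "gemcitabine+cisplatin")
}

#' Normalize molecule names
#'
#' Lowercases, trims whitespace and strips accents so that case or encoding
#' variants of the same drug name hit the same catalog entry.
#'
#' @param x Character vector of molecule names.
#' @return Normalized character vector.
#' @export
normalize_molecule <- function(x) {
  x <- tolower(trimws(as.character(x)))
  iconv(x, from = "", to = "ASCII//TRANSLIT")
}

#' Normalize an ICD-10 code to the dotted form
#'
#' Claims exports write ICD-10 codes either dotted (`"C78.0"`) or undotted
#' (`"C780"`). Both dialects are accepted; internally codes are uppercased
#' and the dot is inserted after the three-character category.
#'
#' @param code Character vector of ICD-10 codes.
#' @return Character vector in dotted uppercase form; codes of three
#'   characters or fewer are returned uppercased unchanged.
#' @examples
#' normalize_icd10(c("c780", "C78.0", "C50"))
#' @export
normalize_icd10 <- function(code) {
  code <- toupper(gsub("\\.", "", trimws(as.character(code))))
  long <- !is.na(code) & nchar(code) > 3
  code[long] <- paste0(substr(code[long], 1, 3), ".", substring(code[long], 4))
  code
}

#' Is a diagnosis code a metastatic ICD-10 code?
#'
#' A code counts as metastatic when its three-character category is one of
#' the catalog's metastatic prefixes (C76--C80 by default) and the code is
#' not an excluded subcode (C77.3 by default -- secondary and non-specified
#' malignant neoplasm of axillary and upper-limb lymph nodes, which marks
#' regional rather than distant spread). Dotted and undotted forms are
#' equivalent. Malformed codes return `FALSE`.
#'
#' @param code Character vector of ICD-10 codes.
#' @param catalog A [molecule_catalog()].
#' @return Logical vector.
#' @examples
#' cat <- molecule_catalog()
#' is_metastatic_code(c("C78.0", "C773", "C50.9"), cat)
#' @export
is_metastatic_code <- function(code, catalog = molecule_catalog()) {
  norm <- normalize_icd10(code)
  prefix <- substr(norm, 1, 3)
  ok <- !is.na(norm) & prefix %in% catalog$metastatic_icd_prefixes
  ok & !(norm %in% catalog$metastatic_icd_excluded)
}

#' Label a molecule set with its conventional regimen name
#'
#' Looks the sorted molecule set up in the catalog's regimen map; when no
#' named regimen matches, the sorted molecule names joined by `"+"` are used
#' as the label.
#'
#' @param molecules Character vector of molecule names (one regimen).
#' @param catalog A [molecule_catalog()].
#' @return A single regimen label string.
#' @export
regimen_label <- function(molecules, catalog = molecule_catalog()) {
  key <- paste(sort(unique(normalize_molecule(molecules))), collapse = "+")
  label <- unname(catalog$regimen_names[key])
  if (is.na(label) || is.null(label)) key else label
}

#' Read a catalog from a YAML or JSON config file
#'
#' Recognised keys: `inclusion_molecules`, `exclusion_molecules`,
#' `metastatic_management_codes`, `metastatic_icd_prefixes`,
#' `metastatic_icd_excluded`, `regimen_names` (a mapping from `"+"`-joined
#' sorted molecule keys to labels). Missing keys fall back to the defaults
#' of [molecule_catalog()].
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `molecule_catalog`.
#' @export
read_catalog <- function(path) {
  if (!file.exists(path)) stop("catalog file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  defaults <- formals(molecule_catalog)
  args <- list()
  for (field in c("inclusion_molecules", "exclusion_molecules",
                  "metastatic_management_codes", "metastatic_icd_prefixes",
                  "metastatic_icd_excluded")) {
    if (!is.null(cfg[[field]])) args[[field]] <- unlist(cfg[[field]])
  }
  if (!is.null(cfg$regimen_names)) args$regimen_names <- unlist(cfg$regimen_names)
  do.call(molecule_catalog, args)
}
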